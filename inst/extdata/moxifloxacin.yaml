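# Moxifloxacin cardiac ion-channel inhibition parameters.
# conc_um is the average maximum free plasma concentration (Cmax)
# after a 400 mg oral dose.
channels:
  - channel: IKr
    ic50_um: 29
    hill_n: 1
  - channel: INa
    ic50_um: 127.2
    hill_n: 1
  - channel: ICa
    ic50_um: 168.9
    hill_n: 1
conc_um: 3.8
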