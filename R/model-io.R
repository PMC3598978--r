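#' Read or write a complete RR model (regression + AR residual process)
#'
#' Serialises a circadian coefficient set together with its AR residual
#' model (and optional fit diagnostics) to a single YAML file, the format
#' consumed by the command-line interface.
#'
#' @param coefs A [circadian_coefficients] object.
#' @param ar An [ar_model] (or `NULL` for a regression-only file).
#' @param diagnostics Optional named list (e.g. from a `circadian_fit`'s
#'   `diagnostics` element) stored verbatim.
#' @param path File path.
#'
#' @return `read_model_yaml()` returns a list with elements `coefs`
#'   ([circadian_coefficients]), `ar` ([ar_model] or `NULL`) and
#'   `diagnostics`; `write_model_yaml()` returns `path` invisibly.
#' @export
write_model_yaml <- function(coefs, ar = NULL, diagnostics = NULL, path) {
  assert_coefficients(coefs)
  obj <- list(
    coefficients = c(as.list(unname(coefs$beta)), list(coefs$sigma)) |>
      stats::setNames(c(paste0("beta", 0:7), "sigma"))
  )
  if (!is.null(ar)) {
    obj$ar <- list(order = ar$order, tau = ar$tau, alphas = as.list(ar$alphas))
  }
  if (!is.null(diagnostics)) obj$diagnostics <- diagnostics
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$coefficients)) abort(sprintf("%s has no `coefficients` block", path))
  cc <- do.call(circadian_coefficients,
                obj$coefficients[c(paste0("beta", 0:7), "sigma")])
  ar <- if (!is.null(obj$ar)) {
    ar_model(unlist(obj$ar$alphas %||% list()), obj$ar$tau)
  }
  list(coefs = cc, ar = ar, diagnostics = obj$diagnostics)
}
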