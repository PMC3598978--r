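#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats coef fitted lm lm.fit model.matrix pf pt qnorm qt quantile
#'   residuals rnorm runif sd terms uniroot update var
#' @importFrom utils head tail
NULL

# recycle scalar arguments against the longest one; error on incompatible lengths
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- !(lengths(args) %in% c(1L, n))
  if (any(bad)) {
    abort(sprintf(
      "arguments %s have incompatible lengths (must be 1 or %d)",
      paste(names(args)[bad], collapse = ", "), n
    ))
  }
  lapply(args, rep_len, n)
}

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric (got non-finite or non-numeric values)", name))
  }
  invisible(x)
}

assert_sex <- function(sex) {
  assert_finite(sex, "sex")
  if (!all(sex %in% c(0, 1))) {
    abort("`sex` must be coded 0 (female) or 1 (male)")
  }
  invisible(sex)
}

assert_age <- function(age) {
  assert_finite(age, "age")
  if (any(age < 0)) abort("`age` must be non-negative (years)")
  invisible(age)
}

# canonical clock time: any finite real reduced into [0, 24)
hour_mod <- function(hour) hour %% 24

# deterministic child-stream seeds: one root seed, stable per-index rule,
# kept strictly inside the 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 48271 * as.double(i)) %% 2147483629 + 1)
}

# run `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL uses (and advances) the current RNG stream
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
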