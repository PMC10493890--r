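# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
# All exported stochastic operations funnel through this, which is what makes
# them bit-reproducible for a given seed.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Signal a distinctly classed warning for quantities that are undefined on the
# given data (e.g. an induction ratio that never reaches the threshold), and
# return NA. Callers can trap the "sortscreen_undefined" class.
#' @noRd
undefined_value <- function(what) {
  warning(warningCondition(
    paste0(what, " is undefined for these data"),
    class = "sortscreen_undefined"
  ))
  NA_real_
}

#' @noRd
assert_scalar_fraction <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (if (allow_one) x > 1 else x >= 1)) {
    stop(sprintf("`%s` must be a single value in (0, 1%s]", name,
                 if (allow_one) "" else ")"), call. = FALSE)
  }
  invisible(x)
}

# Derive a stage seed from a master seed, staying inside 32-bit integer range.
#' @noRd
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 7919 + offset) %% .Machine$integer.max)
}
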