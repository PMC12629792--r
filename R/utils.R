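#' Round half away from zero
#'
#' Rounding used for reported percentages (one-decimal clinical reporting
#' convention). Unlike [base::round()], which rounds half to even, halves are
#' rounded away from zero, so `76.75` becomes `76.8` and `-0.05` becomes
#' `-0.1`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 1).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_out(c(76.744, 72.727, 80.952))
#' @export
round_half_out <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stop with a consistent error class; message formatted by rlang.
ck_abort <- function(msg, class = "ctkinetics_error") {
  rlang::abort(msg, class = class)
}

# Check a scalar probability.
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    ck_abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ck_abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ), class = "ctkinetics_schema_error")
  }
  invisible(df)
}

# Derive a per-stream 32-bit seed from a base seed and a counter, so patient
# substreams are reproducible regardless of generation order.
substream_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647
}
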