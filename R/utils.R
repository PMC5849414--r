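#' Round half away from zero
#'
#' Report-style rounding: ties go away from zero (2.35 -> 2.4, -2.35 -> -2.4),
#' unlike [base::round()]'s round-half-even. Used only when formatting
#' summary tables; full precision is retained internally.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # small epsilon guards binary representation of values like 2.35
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("enchipms_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("enchipms_io_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_validation(what, " is missing required column(s): ",
                    paste(missing, collapse = ", "))
  }
  invisible(df)
}
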