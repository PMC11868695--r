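# internal helpers shared across modules

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop with a classed condition; all user-facing validation goes through here
tl_abort <- function(msg, class = "tetralink_error", ...) {
  rlang::abort(msg, class = c(class, "tetralink_error"), ...)
}

# assert a scalar numeric in a range, naming the offending field
check_scalar <- function(x, field, min = -Inf, max = Inf,
                         integerish = FALSE, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) && x <= max &&
    (!integerish || abs(x - round(x)) < 1e-8)
  if (!ok) {
    tl_abort(
      sprintf("invalid configuration: field `%s` must be a %s in [%s, %s], got %s",
              field, if (integerish) "whole number" else "number",
              format(min), format(max), paste(format(x), collapse = ", ")),
      class = "tetralink_config_error"
    )
  }
  invisible(x)
}

# required columns present, else error naming the missing ones
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    tl_abort(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")),
             class = "tetralink_validation_error")
  }
  invisible(df)
}

# order sample labels numerically when they all look like numbers (depth strings)
sample_order <- function(labels) {
  u <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else u
}
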