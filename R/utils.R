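# Internal helpers: condition classes and input validation.
#
# Two error classes are used throughout so callers (and the CLI) can
# distinguish bad inputs from statistically infeasible requests:
#   - fgf21val_input_error: malformed or out-of-contract inputs
#   - fgf21val_infeasible:  valid inputs for which the requested statistic
#                           does not exist (e.g. no ROC threshold reaches a
#                           sensitivity floor)

abort_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("fgf21val_input_error", "fgf21val_error")))
}

abort_infeasible <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("fgf21val_infeasible", "fgf21val_error")))
}

abort_fit <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("fgf21val_fit_error", "fgf21val_error")))
}

# require named columns in a data frame
need_cols <- function(df, cols, where) {
  if (!is.data.frame(df)) abort_input("%s: expected a data frame", where)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_input("%s: missing column(s): %s", where, paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_input("%s must be finite numeric", what)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# render-time rounding used by report tables (one decimal, matching how
# immunoassay validation tables are conventionally printed)
round1 <- function(x) round(x, 1)
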