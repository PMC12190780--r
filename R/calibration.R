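# Four-parameter logistic (4PL) calibration: the standard curve family for
# ligand-binding assays.  signal = d + (a - d) / (1 + (x / c)^b), where
#   a = signal at zero concentration (blank asymptote)
#   d = signal at infinite concentration
#   c = inflection concentration (pg/mL), b = slope factor (> 0)
# Sandwich ELISAs are ascending (a < d); competitive formats descending
# (a > d).  Both orientations are supported; orientation is inferred from
# the standards.

#' Evaluate a four-parameter logistic curve
#'
#' @param x Concentration(s), pg/mL (non-negative).
#' @param a Signal asymptote at zero concentration.
#' @param d Signal asymptote at infinite concentration.
#' @param c Inflection concentration, pg/mL (> 0).
#' @param b Slope factor (> 0).
#' @return Predicted signal(s).
#' @export
four_pl <- function(x, a, d, c, b) {
  d + (a - d) / (1 + (x / c)^b)
}

#' Default standard-series concentrations for the FGF21 kit
#'
#' The kit's eight-point standard series (plus blank), spanning the
#' manufacturer's working range 31.3--2000 pg/mL.
#'
#' @return Numeric vector of concentrations in pg/mL, including 0 (blank).
#' @export
kit_standard_concentrations <- function() {
  c(0, 31.3, 62.5, 125, 250, 500, 1000, 2000)
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of the 4PL model to a calibration standard series.
#' Replicate wells at the same concentration are averaged before fitting
#' (uniform weights).  Starting values follow the usual immunoassay recipe:
#' asymptotes from the extreme-concentration signals, inflection at the
#' concentration whose signal is nearest mid-range, slope 1; three perturbed
#' restarts are attempted before a fit failure is declared.
#'
#' @param standards Data frame with columns `concentration` (pg/mL, >= 0),
#'   `signal`, and optionally `replicate`.  At least five distinct non-blank
#'   concentrations are required.
#' @param working_range Length-2 numeric, the assay's quantifiable range in
#'   pg/mL (default the kit's 31.3--2000).
#' @return An object of class `fgf21_curve`: a list with elements `a`, `d`,
#'   `c`, `b`, `working_range`, `fit_residual` (root-mean-square signal
#'   residual), `n_levels`, and the averaged `data`.
#' @export
fit_4pl <- function(standards, working_range = c(31.3, 2000)) {
  need_cols(standards, c("concentration", "signal"), "fit_4pl")
  check_finite(standards$concentration, "fit_4pl: concentration")
  check_finite(standards$signal, "fit_4pl: signal")
  if (any(standards$concentration < 0)) abort_input("fit_4pl: negative concentration")
  if (!is.numeric(working_range) || length(working_range) != 2L ||
      working_range[1] <= 0 || working_range[1] >= working_range[2]) {
    abort_input("fit_4pl: working_range must be increasing positive pair")
  }

  # average replicate wells per concentration
  agg <- stats::aggregate(signal ~ concentration, data = standards, FUN = mean)
  agg <- agg[order(agg$concentration), , drop = FALSE]
  nonblank <- agg[agg$concentration > 0, , drop = FALSE]
  if (nrow(nonblank) < 5L) {
    abort_input("fit_4pl: need >= 5 distinct non-blank concentrations, got %d",
                nrow(nonblank))
  }

  x <- agg$concentration
  y <- agg$signal
  ascending <- y[which.max(x)] >= y[which.min(x)]
  a0 <- if (ascending) min(y) else max(y)
  d0 <- if (ascending) max(y) else min(y)
  mid <- (a0 + d0) / 2
  c0 <- nonblank$concentration[which.min(abs(nonblank$signal - mid))]
  b0 <- 1

  starts <- list(
    c(a = a0, d = d0, c = c0, b = b0),
    c(a = a0, d = d0, c = c0 * 0.5, b = 0.7),
    c(a = a0, d = d0, c = c0 * 2.0, b = 1.5),
    c(a = a0, d = d0, c = c0, b = 2.0)
  )
  lower <- c(a = -Inf, d = -Inf, c = min(nonblank$concentration) / 100, b = 0.05)
  upper <- c(a = Inf, d = Inf, c = max(nonblank$concentration) * 100, b = 20)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d + (a - d) / (1 + (x / c)^b),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort_fit("fit_4pl: 4PL fit did not converge after %d starts", length(starts))
  }

  cf <- stats::coef(best$fit)
  structure(
    list(
      a = unname(cf["a"]), d = unname(cf["d"]),
      c = unname(cf["c"]), b = unname(cf["b"]),
      working_range = as.numeric(working_range),
      fit_residual = sqrt(best$rss / length(y)),
      n_levels = nrow(nonblank),
      data = agg
    ),
    class = "fgf21_curve"
  )
}

#' @export
print.fgf21_curve <- function(x, ...) {
  cat("4PL calibration curve\n")
  cat(sprintf("  signal = %.4g + (%.4g - %.4g) / (1 + (x/%.4g)^%.4g)\n",
              x$d, x$a, x$d, x$c, x$b))
  cat(sprintf("  working range: %.4g - %.4g pg/mL; RMS residual %.3g (%d levels)\n",
              x$working_range[1], x$working_range[2], x$fit_residual, x$n_levels))
  invisible(x)
}

#' Invert a 4PL curve: signal to concentration
#'
#' Closed-form inverse x = c * ((a - d)/(y - d) - 1)^(1/b), orientation-aware.
#' Signals at or beyond an asymptote are returned as censored (`NA`) with a
#' directional flag rather than raising an error; concentrations inside the
#' curve but outside the working range are flagged but still reported.
#'
#' @param curve An `fgf21_curve` (or list with `a`, `d`, `c`, `b`,
#'   `working_range`).
#' @param signal Numeric vector of signals.
#' @return Data frame with columns `signal`, `concentration` (pg/mL, `NA`
#'   when censored beyond an asymptote) and `flag` (one of `"ok"`,
#'   `"below_range"`, `"above_range"`).
#' @export
signal_to_concentration <- function(curve, signal) {
  check_finite(signal, "signal_to_concentration: signal")
  a <- curve$a; d <- curve$d; cc <- curve$c; b <- curve$b
  if (a == d) abort_input("signal_to_concentration: degenerate curve (a == d)")
  wr <- curve$working_range %||% c(0, Inf)

  ascending <- d > a   # signal grows with concentration
  conc <- rep(NA_real_, length(signal))
  flag <- rep("ok", length(signal))

  for (i in seq_along(signal)) {
    y <- signal[i]
    # beyond the zero-concentration asymptote -> censored on the low side;
    # at/beyond the saturation asymptote -> censored on the high side
    low_cens <- if (ascending) y < a else y > a
    high_cens <- if (ascending) y >= d else y <= d
    if (low_cens) {
      flag[i] <- "below_range"
    } else if (high_cens) {
      flag[i] <- "above_range"
    } else {
      ratio <- (a - d) / (y - d) - 1  # = (x/c)^b, >= 0 on the valid branch
      conc[i] <- cc * ratio^(1 / b)
      if (conc[i] < wr[1]) flag[i] <- "below_range"
      else if (conc[i] > wr[2]) flag[i] <- "above_range"
    }
  }
  data.frame(signal = signal, concentration = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Adjust a measured concentration for sample dilution
#'
#' @param concentration Non-negative concentration(s), pg/mL.
#' @param factor Dilution factor(s) >= 1.
#' @return `concentration * factor`.
#' @export
apply_dilution <- function(concentration, factor) {
  check_finite(concentration, "apply_dilution: concentration")
  check_finite(factor, "apply_dilution: factor")
  if (any(concentration < 0)) abort_input("apply_dilution: negative concentration")
  if (any(factor < 1)) abort_input("apply_dilution: dilution factor must be >= 1")
  concentration * factor
}

#' Read a standard-curve CSV
#'
#' Expected columns: `concentration_pg_ml`, `signal`, `replicate`.
#'
#' @param path Path to a delimited text file.
#' @return Data frame with columns `concentration`, `signal`, `replicate`.
#' @export
read_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(df, c("concentration_pg_ml", "signal"), sprintf("read_standards(%s)", path))
  data.frame(
    concentration = as.numeric(df$concentration_pg_ml),
    signal = as.numeric(df$signal),
    replicate = if ("replicate" %in% names(df)) as.integer(df$replicate) else 1L
  )
}

#' Serialize / deserialize a calibration curve as JSON
#'
#' @param curve An `fgf21_curve`.
#' @param path Output (input) file path.
#' @return `curve_to_json` returns `path` invisibly; `curve_from_json`
#'   returns an `fgf21_curve`.
#' @export
curve_to_json <- function(curve, path) {
  obj <- list(
    model = "4PL",
    parameters = list(a = curve$a, d = curve$d, c = curve$c, b = curve$b),
    working_range = curve$working_range,
    fit_residual = curve$fit_residual,
    n_levels = curve$n_levels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname curve_to_json
#' @export
curve_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(a = obj$parameters$a, d = obj$parameters$d,
         c = obj$parameters$c, b = obj$parameters$b,
         working_range = as.numeric(obj$working_range),
         fit_residual = obj$fit_residual %||% NA_real_,
         n_levels = obj$n_levels %||% NA_integer_,
         data = NULL),
    class = "fgf21_curve"
  )
}
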