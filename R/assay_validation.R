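# Analytical-validation statistics for the automated FGF21 ELISA:
# precision CVs, LLOQ from blanks, dilution linearity, spike recovery,
# interference relative bias, stability percent change, and the
# blood-collection-tube comparison.  Acceptance is judged against a CV
# threshold (default 15%) and the total change limit (TCL).

#' Within-run precision summary of a replicate set
#'
#' Computes n, mean, sample SD (n - 1 denominator) and the coefficient of
#' variation CV% = 100 * SD / mean, with a pass flag against the precision
#' acceptance threshold (CV below 15% by convention).
#'
#' @param values Numeric vector of replicate measurements (>= 2 values,
#'   positive mean).
#' @param threshold Acceptance threshold for CV, percent (default 15).
#' @return One-row data frame: `n`, `mean`, `sd`, `cv_percent`, `passes`.
#' @export
precision_summary <- function(values, threshold = 15) {
  check_finite(values, "precision_summary: values")
  if (length(values) < 2L) abort_input("precision_summary: need >= 2 replicates")
  m <- mean(values)
  if (m == 0) abort_input("precision_summary: mean is zero, CV undefined")
  s <- stats::sd(values)
  cv <- 100 * s / m
  data.frame(n = length(values), mean = m, sd = s, cv_percent = cv,
             passes = cv < threshold)
}

#' Between-run (inter-assay) precision summary
#'
#' Pools all values across runs at one concentration level into a single
#' total mean/SD/CV (the convention used when a single inter-assay CV per
#' level is reported).  The run structure is retained in the per-run
#' attribute so a between/within variance decomposition can be added later.
#'
#' @param values Numeric vector of measurements.
#' @param run Run identifier per value (>= 2 distinct runs).
#' @param threshold Acceptance threshold for CV, percent (default 15).
#' @return One-row data frame as [precision_summary()], plus `n_runs`;
#'   attribute `per_run` holds per-run means.
#' @export
inter_assay_summary <- function(values, run, threshold = 15) {
  check_finite(values, "inter_assay_summary: values")
  if (length(values) != length(run)) {
    abort_input("inter_assay_summary: values and run lengths differ")
  }
  runs <- unique(run)
  if (length(runs) < 2L) abort_input("inter_assay_summary: need >= 2 runs")
  out <- precision_summary(values, threshold = threshold)
  out$n_runs <- length(runs)
  attr(out, "per_run") <- stats::aggregate(
    list(mean = values), by = list(run = run), FUN = mean)
  out
}

#' Lower limit of quantification from blank wells
#'
#' The blank signal mean plus `k` standard deviations (default 10) is
#' interpolated through the calibration curve to give the smallest
#' quantifiable concentration.
#'
#' @param blank_signals Numeric vector of blank-well signals (>= 2).
#' @param curve An `fgf21_curve`.
#' @param k SD multiplier (default 10).
#' @return List with `lloq` (pg/mL), `threshold_signal`, `mean`, `sd`, `k`.
#' @export
lloq_from_blanks <- function(blank_signals, curve, k = 10) {
  check_finite(blank_signals, "lloq_from_blanks: blank_signals")
  if (length(blank_signals) < 2L) abort_input("lloq_from_blanks: need >= 2 blanks")
  if (k < 0) abort_input("lloq_from_blanks: k must be >= 0")
  m <- mean(blank_signals)
  s <- stats::sd(blank_signals)
  thr <- m + k * s
  inv <- signal_to_concentration(curve, thr)
  if (is.na(inv$concentration)) {
    abort_input("lloq_from_blanks: threshold signal %.4g outside invertible range", thr)
  }
  list(lloq = inv$concentration, threshold_signal = thr, mean = m, sd = s, k = k)
}

#' Dilution-linearity recovery table
#'
#' For a serial dilution of a high sample, computes per-factor recovery
#' = 100 * observed / expected (both already back-adjusted to neat-sample
#' scale) and determines the linear range: the maximal prefix of dilution
#' factors whose absolute deviation from 100% stays within the deviation
#' limit and whose replicate CV stays below the CV limit.
#'
#' @param series Data frame with columns `factor` (strictly increasing
#'   integers >= 2 typically), `expected` (pg/mL, > 0), `observed` (pg/mL),
#'   optionally `cv` (replicate CV, percent).
#' @param criterion Optional [total_change_limit()] object; its TCL is used
#'   as the deviation limit when `deviation_limit` is not given.
#' @param deviation_limit Maximum |recovery - 100| in percentage points
#'   (default: `criterion$tcl`, else 14).
#' @param cv_limit Maximum replicate CV, percent (default 15).
#' @return Data frame with `factor`, `expected`, `observed`,
#'   `recovery_percent`, `cv_percent`, `within_limits`; attribute
#'   `linear_max_factor` gives the largest factor of the linear prefix
#'   (`NA` if even the first fails).
#' @export
dilution_linearity <- function(series, criterion = NULL, deviation_limit = NULL,
                               cv_limit = 15) {
  need_cols(series, c("factor", "expected", "observed"), "dilution_linearity")
  if (any(series$expected <= 0)) abort_input("dilution_linearity: expected must be > 0")
  if (is.unsorted(series$factor, strictly = TRUE)) {
    abort_input("dilution_linearity: factors must be strictly increasing")
  }
  if (is.null(deviation_limit)) {
    deviation_limit <- if (!is.null(criterion)) criterion$tcl else 14
  }
  rec <- 100 * series$observed / series$expected
  cv <- if ("cv" %in% names(series)) series$cv else rep(NA_real_, nrow(series))
  ok_dev <- abs(rec - 100) <= deviation_limit
  ok_cv <- is.na(cv) | cv <= cv_limit
  within <- ok_dev & ok_cv
  # linear range = maximal prefix of passing factors
  first_fail <- match(FALSE, within)
  linear_max <- if (is.na(first_fail)) max(series$factor)
                else if (first_fail == 1L) NA_real_
                else series$factor[first_fail - 1L]
  out <- data.frame(
    factor = series$factor, expected = series$expected,
    observed = series$observed, recovery_percent = rec,
    cv_percent = cv, within_limits = within
  )
  attr(out, "linear_max_factor") <- linear_max
  attr(out, "deviation_limit") <- deviation_limit
  out
}

#' Spike recovery
#'
#' Two conventions are supported.  `"total"` (default) treats the spiked
#' sample's theoretical concentration as neat + added and reports
#' 100 * measured_spiked / (neat + added); this is the arithmetic used in
#' standard spike-recovery tables.  `"marginal"` reports recovery of the
#' added increment only: 100 * (measured_spiked - neat) / added.  The two
#' coincide when measurement is perfect and when neat = 0.
#'
#' @param neat Measured concentration of the unspiked sample, pg/mL (>= 0).
#' @param spiked_measured Measured concentration of the spiked sample, pg/mL.
#' @param spike_added Added analyte, pg/mL (> 0).
#' @param mode `"total"` or `"marginal"`.
#' @param label Optional label(s) carried through.
#' @return Data frame with `label`, `neat`, `spike_added`, `theoretical`,
#'   `measured`, `recovery_percent`, `mode`.
#' @export
spike_recovery <- function(neat, spiked_measured, spike_added,
                           mode = c("total", "marginal"), label = NA_character_) {
  mode <- match.arg(mode)
  check_finite(neat, "spike_recovery: neat")
  check_finite(spiked_measured, "spike_recovery: spiked_measured")
  check_finite(spike_added, "spike_recovery: spike_added")
  if (any(neat < 0)) abort_input("spike_recovery: neat must be >= 0")
  if (any(spike_added <= 0)) abort_input("spike_recovery: spike_added must be > 0")
  theoretical <- neat + spike_added
  rec <- if (mode == "total") {
    100 * spiked_measured / theoretical
  } else {
    100 * (spiked_measured - neat) / spike_added
  }
  data.frame(label = label, neat = neat, spike_added = spike_added,
             theoretical = theoretical, measured = spiked_measured,
             recovery_percent = rec, mode = mode, stringsAsFactors = FALSE)
}

#' Total change limit (TCL)
#'
#' TCL = sqrt((2.77 * CV_a)^2 + (0.5 * CV_b)^2), where CV_a is the assay's
#' analytical imprecision and CV_b the within-run variability of the tested
#' sample (both percent).  A bias or percent change whose magnitude stays
#' within the TCL is analytically insignificant.
#'
#' @param cv_a Analytical imprecision, percent (>= 0).
#' @param cv_b Within-run variability, percent (>= 0).
#' @return Object of class `stability_criterion`: list `cv_a`, `cv_b`, `tcl`.
#' @export
total_change_limit <- function(cv_a, cv_b) {
  check_finite(cv_a, "total_change_limit: cv_a")
  check_finite(cv_b, "total_change_limit: cv_b")
  if (cv_a < 0 || cv_b < 0) abort_input("total_change_limit: CVs must be >= 0")
  structure(
    list(cv_a = cv_a, cv_b = cv_b,
         tcl = sqrt((2.77 * cv_a)^2 + (0.5 * cv_b)^2)),
    class = "stability_criterion"
  )
}

#' @export
print.stability_criterion <- function(x, ...) {
  cat(sprintf("TCL = %.2f%% (CV_a = %.2f%%, CV_b = %.2f%%)\n",
              x$tcl, x$cv_a, x$cv_b))
  invisible(x)
}

#' Interference relative bias
#'
#' For an interferent titration panel, the relative bias of each observed
#' value against the interferent-free baseline, judged against the TCL.
#'
#' @param baseline Baseline concentration, pg/mL (> 0).
#' @param panel Data frame with columns `interferent`, `level` (dose index
#'   or concentration), `observed` (pg/mL).
#' @param criterion A `stability_criterion`.
#' @return `panel` with added `baseline`, `relative_bias_percent`,
#'   `exceeds_tcl`.
#' @export
interference_bias <- function(baseline, panel, criterion) {
  if (!is.numeric(baseline) || baseline <= 0) {
    abort_input("interference_bias: baseline must be > 0")
  }
  need_cols(panel, c("interferent", "level", "observed"), "interference_bias")
  if (nrow(panel) == 0L) abort_input("interference_bias: empty panel")
  bias <- 100 * (panel$observed - baseline) / baseline
  out <- panel
  out$baseline <- baseline
  out$relative_bias_percent <- bias
  out$exceeds_tcl <- abs(bias) > criterion$tcl
  out
}

#' Stability percent-change series
#'
#' Computes, for each stored/stressed aliquot, the percent change from its
#' matched reference aliquot and flags exceedances of the TCL.  Conditions
#' follow the usual plasma-stability designs: repeated freeze-thaw cycles,
#' refrigerated (4 degrees C) and room-temperature time courses, and
#' long-term storage at -20 degrees C.
#'
#' @param points Data frame with columns `condition`, `exposure` (cycles or
#'   hours), `level`, `reference` (pg/mL, > 0), `measured` (pg/mL).
#' @param criterion A `stability_criterion`.
#' @return `points` ordered by condition, level and exposure, with
#'   `percent_change` and `exceeds_tcl` filled in.
#' @export
stability_series <- function(points, criterion) {
  need_cols(points, c("condition", "exposure", "level", "reference", "measured"),
            "stability_series")
  if (anyNA(points$reference) || any(points$reference <= 0)) {
    abort_input("stability_series: every point needs a positive reference value")
  }
  out <- points
  out$percent_change <- 100 * (out$measured - out$reference) / out$reference
  out$exceeds_tcl <- abs(out$percent_change) > criterion$tcl
  out[order(out$condition, out$level, out$exposure), , drop = FALSE]
}

#' Compare FGF21 measured in two blood-collection tube types
#'
#' Paired comparison of one tube type against another: Spearman rank
#' correlation (midranks for ties), Wilcoxon signed-rank test (zero
#' differences dropped; exact p for n <= 25 without ties, otherwise normal
#' approximation with continuity correction), and an ordinary least-squares
#' fit of `y` on `x`.
#'
#' @param x,y Paired concentrations, pg/mL (same subjects; >= 5 complete
#'   pairs after removing missing values).
#' @param pair Length-2 character label, e.g. `c("heparin", "edta")`.
#' @return Object of class `tube_comparison`: list with `pair`, `n`,
#'   `rank_correlation`, `signed_rank_p`, `slope`, `intercept`.
#' @export
tube_comparison <- function(x, y, pair = c("x", "y")) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) abort_input("tube_comparison: need >= 5 complete pairs")
  rs <- spearman_rank(x, y)
  d <- y - x
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    # all pairs identical: no evidence of a difference
    wt <- list(p.value = 1)
  } else {
    exact <- length(nz) <= 25L && !any(d == 0) && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(
      stats::wilcox.test(y, x, paired = TRUE, exact = exact, correct = TRUE)
    )
  }
  ols <- stats::lm(y ~ x)
  structure(
    list(pair = pair, n = length(x),
         rank_correlation = rs$estimate, rank_correlation_p = rs$p.value,
         signed_rank_p = wt$p.value,
         slope = unname(stats::coef(ols)[2]),
         intercept = unname(stats::coef(ols)[1])),
    class = "tube_comparison"
  )
}

#' @export
print.tube_comparison <- function(x, ...) {
  cat(sprintf("Tube comparison %s vs %s (n = %d)\n", x$pair[1], x$pair[2], x$n))
  cat(sprintf("  Spearman r = %.3f; signed-rank p = %.3g\n",
              x$rank_correlation, x$signed_rank_p))
  cat(sprintf("  OLS: y = %.3fx %+.3g\n", x$slope, x$intercept))
  invisible(x)
}
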