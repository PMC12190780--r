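# Clinical-diagnostics stage: eligibility filtering, FIB-4, ultrasound
# attenuation-based steatosis categories, rank statistics, ROC/AUC and
# dual rule-out / rule-in threshold selection with likelihood ratios.

#' FIB-4 liver-fibrosis index
#'
#' FIB-4 = (AST x age) / (platelets x sqrt(ALT)), with platelets in 10^9/L.
#' Laboratory reports quoting platelets in 10^4/uL convert by multiplying
#' by 10.
#'
#' @param age Age in years (> 0).
#' @param ast AST, U/L (> 0).
#' @param alt ALT, U/L (> 0).
#' @param platelets Platelet count, 10^9/L (> 0).
#' @return FIB-4 index (vectorized).
#' @export
fib4 <- function(age, ast, alt, platelets) {
  check_finite(age, "fib4: age"); check_finite(ast, "fib4: ast")
  check_finite(alt, "fib4: alt"); check_finite(platelets, "fib4: platelets")
  if (any(age <= 0) || any(ast <= 0) || any(alt <= 0) || any(platelets <= 0)) {
    abort_input("fib4: all inputs must be > 0")
  }
  (ast * age) / (platelets * sqrt(alt))
}

# eligibility bounds for the screening cohort
eligibility_defaults <- function() {
  list(age = c(20, 69), bmi_max = 30, fib4_max = 2.67,
       alcohol_weekly_max = c(female = 140, male = 210))
}

#' Screening-cohort eligibility filter
#'
#' A patient is eligible when 20 <= age <= 69, BMI < 30 kg/m^2, FIB-4 < 2.67
#' (excluding likely advanced fibrosis) and weekly alcohol intake below the
#' metabolic-dysfunction criterion (< 140 g for females, < 210 g for males).
#' Inequalities on BMI, FIB-4 and alcohol are strict.
#'
#' @param p A list or one-row data frame with fields `age`, `sex`
#'   (`"male"`/`"female"`), `bmi`, `ast`, `alt`, `platelet_count` (10^9/L),
#'   `weekly_alcohol_g`.
#' @param bounds Eligibility bounds (see `eligibility_defaults`).
#' @return List with `eligible` (logical), `failed_criteria` (character),
#'   `fib4` (the computed index).
#' @export
eligibility_filter <- function(p, bounds = eligibility_defaults()) {
  req <- c("age", "sex", "bmi", "ast", "alt", "platelet_count", "weekly_alcohol_g")
  have <- req %in% names(p)
  if (!all(have)) {
    abort_input("eligibility_filter: missing field(s): %s",
                paste(req[!have], collapse = ", "))
  }
  vals <- p[req]
  if (any(lengths(vals) == 0L)) {
    abort_input("eligibility_filter: empty field(s): %s",
                paste(req[lengths(vals) == 0L], collapse = ", "))
  }
  if (anyNA(vals[setdiff(req, "sex")])) {
    bad <- req[vapply(vals, function(v) anyNA(v), logical(1))]
    abort_input("eligibility_filter: missing value(s) in field(s): %s",
                paste(bad, collapse = ", "))
  }
  f4 <- fib4(p$age, p$ast, p$alt, p$platelet_count)
  failed <- character(0)
  if (p$age < bounds$age[1] || p$age > bounds$age[2]) failed <- c(failed, "age")
  if (p$bmi >= bounds$bmi_max) failed <- c(failed, "bmi")
  if (f4 >= bounds$fib4_max) failed <- c(failed, "fib4")
  limit <- bounds$alcohol_weekly_max[[as.character(p$sex)]]
  if (is.null(limit)) abort_input("eligibility_filter: sex must be 'male' or 'female'")
  if (p$weekly_alcohol_g >= limit) failed <- c(failed, "alcohol")
  list(eligible = length(failed) == 0L, failed_criteria = failed, fib4 = f4)
}

#' Categorize hepatic steatosis from the ultrasound attenuation coefficient
#'
#' Bands: < 0.58 dB/cm/MHz normal; 0.58--0.70 suspected steatotic liver
#' (boundaries inclusive); > 0.70 confirmed steatotic liver.
#'
#' @param att Attenuation coefficient(s), dB/cm/MHz (> 0).
#' @param cutoffs Length-2 numeric band boundaries (default `c(0.58, 0.70)`).
#' @return Factor with levels `normal`, `suspected`, `confirmed`.
#' @export
classify_steatosis <- function(att, cutoffs = c(0.58, 0.70)) {
  check_finite(att, "classify_steatosis: att")
  if (any(att <= 0)) abort_input("classify_steatosis: attenuation must be > 0")
  out <- ifelse(att < cutoffs[1], "normal",
                ifelse(att <= cutoffs[2], "suspected", "confirmed"))
  factor(out, levels = c("normal", "suspected", "confirmed"))
}

#' Spearman rank correlation with p-value
#'
#' Correlation of midranks (tie-corrected).  The p-value uses the
#' t-approximation t = r sqrt((n-2)/(1-r^2)) by default; for small
#' tie-free samples (`exact = TRUE`, n <= 9) the exact permutation null is
#' used.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite.
#' @param exact Logical; exact permutation p (requires no ties, n <= 9).
#'   Default: automatic for n <= 8 without ties.
#' @return List with `estimate`, `p.value`, `n`, `method`.
#' @export
spearman_rank <- function(x, y, exact = NULL) {
  check_finite(x, "spearman_rank: x"); check_finite(y, "spearman_rank: y")
  n <- length(x)
  if (length(y) != n) abort_input("spearman_rank: lengths differ")
  if (n < 3L) abort_input("spearman_rank: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_infeasible("spearman_rank: constant input, correlation undefined")
  }
  r <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (is.null(exact)) exact <- n <= 8L && !ties
  if (exact && !ties && n <= 9L) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(estimate = r, p.value = p, n = n, method = method)
}

#' Mann-Whitney U test
#'
#' U computed from pooled midranks (U for group `a`); two-tailed p-value
#' exact for small tie-free samples, otherwise by normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b Numeric vectors (non-empty; at least 3 per group recommended).
#' @return List with `U` (for `a`), `U_other`, `n1`, `n2`, `p.value`,
#'   `method`.
#' @export
mann_whitney <- function(a, b) {
  check_finite(a, "mann_whitney: a"); check_finite(b, "mann_whitney: b")
  if (length(a) == 0L || length(b) == 0L) abort_input("mann_whitney: empty group")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && n1 + n2 <= 50L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = U, U_other = n1 * n2 - U, n1 = n1, n2 = n2,
       p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' ROC curve and AUC
#'
#' Higher scores indicate the positive class; a point is generated at every
#' distinct threshold `t` with positivity rule `score >= t`.  The AUC uses
#' the rank (Mann-Whitney) method with midrank tie handling, identical to
#' U / (n1 n0).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @return Object of class `fgf21_roc`: list with `auc`, `points` (data
#'   frame `threshold`, `sensitivity`, `specificity`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  check_finite(scores, "roc_auc: scores")
  lab <- as_binary_labels(labels)
  if (length(lab) != length(scores)) abort_input("roc_auc: lengths differ")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) abort_input("roc_auc: both classes required")
  r <- rank(scores)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[lab] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!lab] < t), numeric(1))
  structure(
    list(auc = auc,
         points = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec),
         n_pos = n_pos, n_neg = n_neg),
    class = "fgf21_roc"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) > 2L) abort_input("labels: more than two levels")
    return(labels == levels(labels)[2])
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort_input("labels: numeric labels must be 0/1")
    return(labels == 1)
  }
  abort_input("labels: unsupported type")
}

#' @export
print.fgf21_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.fgf21_roc <- function(x, ...) {
  fpr <- c(0, 1 - x$points$specificity, 1)
  tpr <- c(0, x$points$sensitivity, 1)
  o <- order(fpr, tpr)
  graphics::plot(fpr[o], tpr[o], type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Dual rule-out / rule-in diagnostic thresholds from a ROC curve
#'
#' The rule-out cut-off is the largest threshold whose sensitivity (with
#' positivity `score >= t`) still reaches `sens_floor`; scores below it
#' argue against disease.  The rule-in cut-off is the smallest threshold
#' whose specificity reaches `spec_floor`; scores at or above it support
#' the diagnosis.  Likelihood ratios are reported at each cut-off:
#' LR- = (1 - sens)/spec at the rule-out, LR+ = sens/(1 - spec) at the
#' rule-in.
#'
#' @param scores,labels As in [roc_auc()].
#' @param sens_floor Minimum sensitivity for the rule-out cut-off (default
#'   0.84).
#' @param spec_floor Minimum specificity for the rule-in cut-off (default
#'   0.81).
#' @return Object of class `diagnostic_thresholds`: list with `rule_out`,
#'   `rule_in`, `sens_at_rule_out`, `spec_at_rule_out`, `sens_at_rule_in`,
#'   `spec_at_rule_in`, `lr_neg`, `lr_pos`, `auc`.
#' @export
select_dual_thresholds <- function(scores, labels, sens_floor = 0.84,
                                   spec_floor = 0.81) {
  if (sens_floor <= 0.5 || sens_floor >= 1 || spec_floor <= 0.5 || spec_floor >= 1) {
    abort_input("select_dual_thresholds: floors must lie in (0.5, 1)")
  }
  roc <- roc_auc(scores, labels)
  pts <- roc$points  # thresholds in decreasing order; sens nondecreasing down
  ok_sens <- pts$sensitivity >= sens_floor
  if (!any(ok_sens)) {
    abort_infeasible("select_dual_thresholds: no threshold reaches sensitivity %.2f",
                     sens_floor)
  }
  i_out <- which(ok_sens)[1]  # largest threshold meeting the floor
  ok_spec <- pts$specificity >= spec_floor
  if (!any(ok_spec)) {
    abort_infeasible("select_dual_thresholds: no threshold reaches specificity %.2f",
                     spec_floor)
  }
  i_in <- which(ok_spec)[length(which(ok_spec))]  # smallest such threshold
  sens_out <- pts$sensitivity[i_out]; spec_out <- pts$specificity[i_out]
  sens_in <- pts$sensitivity[i_in]; spec_in <- pts$specificity[i_in]
  structure(
    list(rule_out = pts$threshold[i_out], rule_in = pts$threshold[i_in],
         sens_at_rule_out = sens_out, spec_at_rule_out = spec_out,
         sens_at_rule_in = sens_in, spec_at_rule_in = spec_in,
         lr_neg = (1 - sens_out) / spec_out,
         lr_pos = if (spec_in < 1) sens_in / (1 - spec_in) else Inf,
         auc = roc$auc),
    class = "diagnostic_thresholds"
  )
}

#' @export
print.diagnostic_thresholds <- function(x, ...) {
  cat(sprintf("AUC = %.3f\n", x$auc))
  cat(sprintf("Rule-out: < %.4g pg/mL (sens %.0f%%, LR- = %.2f)\n",
              x$rule_out, 100 * x$sens_at_rule_out, x$lr_neg))
  cat(sprintf("Rule-in:  >= %.4g pg/mL (spec %.0f%%, LR+ = %.2f)\n",
              x$rule_in, 100 * x$spec_at_rule_in, x$lr_pos))
  invisible(x)
}

#' Full clinical-cohort analysis
#'
#' Runs the clinical-validation pipeline on a patient cohort: eligibility
#' filtering (with FIB-4), Spearman correlations of FGF21 with each clinical
#' parameter, steatosis categorization by attenuation coefficient with
#' pairwise Mann-Whitney comparisons of FGF21 across categories, ROC of
#' FGF21 against steatosis defined by the diagnostic attenuation cut-off,
#' and dual rule-out / rule-in thresholds.
#'
#' @param cohort Data frame, one row per patient, with columns `age`, `sex`,
#'   `bmi`, `ast`, `alt`, `ggt`, `total_bilirubin`, `albumin`,
#'   `platelet_count` (10^9/L), `weekly_alcohol_g`, `shear_wave_speed`,
#'   `attenuation_coefficient`, `fgf21`.
#' @param diagnosis_cutoff Attenuation coefficient defining steatosis for
#'   the ROC stage (default 0.66 dB/cm/MHz; positive when `att >= cutoff`).
#' @param category_cutoffs Band boundaries for [classify_steatosis()].
#' @param sens_floor,spec_floor Passed to [select_dual_thresholds()].
#' @param min_eligible Minimum number of eligible records (default 20).
#' @param bonferroni Adjust pairwise category p-values (default FALSE).
#' @return Object of class `fgf21_cohort_report`: list with `n_total`,
#'   `n_eligible`, `exclusions`, `correlations` (data frame), `categories`
#'   (summary data frame), `pairwise` (data frame), `roc`, `thresholds`
#'   (or `NULL` with `threshold_error` if infeasible), and the analyzed
#'   `cohort` (eligible rows with `fib4` and `category` added).
#' @export
cohort_analysis <- function(cohort, diagnosis_cutoff = 0.66,
                            category_cutoffs = c(0.58, 0.70),
                            sens_floor = 0.84, spec_floor = 0.81,
                            min_eligible = 20, bonferroni = FALSE) {
  need_cols(cohort, c("age", "sex", "bmi", "ast", "alt", "ggt",
                      "total_bilirubin", "albumin", "platelet_count",
                      "weekly_alcohol_g", "shear_wave_speed",
                      "attenuation_coefficient", "fgf21"),
            "cohort_analysis")
  n_total <- nrow(cohort)
  elig <- lapply(seq_len(n_total), function(i) eligibility_filter(cohort[i, ]))
  keep <- vapply(elig, `[[`, logical(1), "eligible")
  excl <- table(unlist(lapply(elig[!keep], `[[`, "failed_criteria")))
  cohort$fib4 <- vapply(elig, `[[`, numeric(1), "fib4")
  dat <- cohort[keep, , drop = FALSE]
  if (nrow(dat) < min_eligible) {
    abort_input("cohort_analysis: only %d eligible records (need >= %d)",
                nrow(dat), min_eligible)
  }

  params <- c("age", "bmi", "ast", "alt", "ggt", "total_bilirubin", "albumin",
              "platelet_count", "fib4", "shear_wave_speed",
              "attenuation_coefficient")
  cors <- do.call(rbind, lapply(params, function(pn) {
    s <- spearman_rank(dat[[pn]], dat$fgf21)
    data.frame(parameter = pn, r = s$estimate, p = s$p.value,
               stringsAsFactors = FALSE)
  }))

  dat$category <- classify_steatosis(dat$attenuation_coefficient,
                                     cutoffs = category_cutoffs)
  cat_summary <- do.call(rbind, lapply(levels(dat$category), function(lv) {
    v <- dat$fgf21[dat$category == lv]
    data.frame(category = lv, n = length(v),
               median_fgf21 = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(levels(dat$category), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- dat$fgf21[dat$category == pr[1]]
    b <- dat$fgf21[dat$category == pr[2]]
    if (length(a) < 3L || length(b) < 3L) {
      return(data.frame(group1 = pr[1], group2 = pr[2], U = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(a, b)
    data.frame(group1 = pr[1], group2 = pr[2], U = mw$U, p = mw$p.value,
               stringsAsFactors = FALSE)
  }))
  if (bonferroni) pw$p_adjusted <- stats::p.adjust(pw$p, method = "bonferroni")

  steatotic <- dat$attenuation_coefficient >= diagnosis_cutoff
  roc <- roc_auc(dat$fgf21, steatotic)
  thresholds <- tryCatch(
    select_dual_thresholds(dat$fgf21, steatotic,
                           sens_floor = sens_floor, spec_floor = spec_floor),
    fgf21val_infeasible = function(e) e
  )
  threshold_error <- NULL
  if (inherits(thresholds, "condition")) {
    threshold_error <- conditionMessage(thresholds)
    thresholds <- NULL
  }

  structure(
    list(n_total = n_total, n_eligible = nrow(dat),
         exclusions = excl, correlations = cors,
         categories = cat_summary, pairwise = pw,
         diagnosis_cutoff = diagnosis_cutoff,
         roc = roc, thresholds = thresholds,
         threshold_error = threshold_error,
         cohort = dat),
    class = "fgf21_cohort_report"
  )
}

#' @export
print.fgf21_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d/%d eligible\n", x$n_eligible, x$n_total))
  att <- x$correlations[x$correlations$parameter == "attenuation_coefficient", ]
  cat(sprintf("  FGF21 vs attenuation coefficient: r = %.3f (p = %.3g)\n",
              att$r, att$p))
  cat(sprintf("  Steatosis (att >= %.2f): AUC = %.3f\n",
              x$diagnosis_cutoff, x$roc$auc))
  if (!is.null(x$thresholds)) print(x$thresholds)
  else cat(sprintf("  Thresholds infeasible: %s\n", x$threshold_error))
  invisible(x)
}
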