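# FIB-4, eligibility, steatosis categories, rank statistics, ROC and
# dual-threshold selection.

patient <- function(...) {
  base <- list(age = 50, sex = "male", bmi = 24, ast = 25, alt = 25,
               ggt = 30, total_bilirubin = 0.8, albumin = 4.3,
               platelet_count = 220, weekly_alcohol_g = 50,
               shear_wave_speed = 1.2, attenuation_coefficient = 0.6,
               fgf21 = 300)
  mods <- list(...)
  base[names(mods)] <- mods
  base
}

test_that("fib4 evaluates the index formula", {
  expect_equal(fib4(60, 40, 25, 200), 2400 / 1000)
  # constructed identity: alt = 1, platelets = ast * age
  expect_equal(fib4(56, 20, 1, 56 * 20), 1.0)
  # median-composed inputs (medians do not compose to the median index)
  expect_equal(fib4(56, 20, 21, 233), (20 * 56) / (233 * sqrt(21)),
               tolerance = 1e-12)
  expect_equal(round(fib4(56, 20, 21, 233), 3), 1.049)
  expect_error(fib4(0, 20, 21, 233), class = "fgf21val_input_error")
})

test_that("eligibility_filter enforces each criterion strictly", {
  expect_true(eligibility_filter(patient())$eligible)
  r <- eligibility_filter(patient(age = 70))
  expect_false(r$eligible); expect_equal(r$failed_criteria, "age")
  expect_false(eligibility_filter(patient(age = 19))$eligible)
  expect_false(eligibility_filter(patient(bmi = 30))$eligible)
  # fib4 exactly at the bound is ineligible (strict inequality)
  p <- patient(age = 60, ast = 40, alt = 25, platelet_count = 2400 / (2.67 * 5))
  expect_equal(eligibility_filter(p)$fib4, 2.67, tolerance = 1e-12)
  expect_false(eligibility_filter(p)$eligible)
  # male at 209 g/week is eligible; 210 is not
  expect_true(eligibility_filter(patient(weekly_alcohol_g = 209))$eligible)
  expect_false(eligibility_filter(patient(weekly_alcohol_g = 210))$eligible)
  expect_false(eligibility_filter(patient(sex = "female",
                                          weekly_alcohol_g = 140))$eligible)
  expect_true(eligibility_filter(patient(sex = "female",
                                         weekly_alcohol_g = 139))$eligible)
  # multiple failures enumerated; order of criteria does not affect verdict
  r2 <- eligibility_filter(patient(age = 75, bmi = 31))
  expect_setequal(r2$failed_criteria, c("age", "bmi"))
  p3 <- patient(); p3$bmi <- NULL
  expect_error(eligibility_filter(p3), class = "fgf21val_input_error")
  p4 <- patient(ast = NA)
  expect_error(eligibility_filter(p4), class = "fgf21val_input_error")
})

test_that("classify_steatosis applies the three bands with closed middle", {
  expect_equal(as.character(classify_steatosis(0.55)), "normal")
  expect_equal(as.character(classify_steatosis(0.75)), "confirmed")
  expect_equal(as.character(classify_steatosis(0.58)), "suspected")
  expect_equal(as.character(classify_steatosis(0.70)), "suspected")
  expect_equal(as.character(classify_steatosis(c(0.3, 0.65, 0.97))),
               c("normal", "suspected", "confirmed"))
  expect_error(classify_steatosis(0), class = "fgf21val_input_error")
})

test_that("spearman_rank handles monotone, classical and degenerate cases", {
  y <- c(2, 5, 9, 11, 30)
  expect_equal(spearman_rank(1:5, y)$estimate, 1)
  # classical d^2 formula: sum d^2 = 6 at n = 3 -> r = -0.5
  expect_equal(spearman_rank(c(1, 2, 3), c(3, 1, 2))$estimate, -0.5)
  expect_error(spearman_rank(rep(1, 5), 1:5), class = "fgf21val_infeasible")
  # invariance under monotone transforms of either variable
  set.seed(8)
  x <- rnorm(20); z <- rnorm(20)
  expect_equal(spearman_rank(x, z)$estimate,
               spearman_rank(exp(x), z^3 + 5 * z)$estimate)
})

test_that("spearman_rank matches the exhaustive permutation oracle (n <= 7)", {
  set.seed(13)
  for (i in 1:6) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    got <- spearman_rank(x, y, exact = TRUE)
    oracle <- brute_spearman(x, y)
    expect_equal(got$estimate, oracle$estimate, tolerance = 1e-12)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("mann_whitney computes U and agrees with enumeration", {
  # identical groups: U = n1 n2 / 2, p ~ 1
  m0 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$U, 4.5)
  expect_gt(m0$p.value, 0.9)
  # complete separation: U = 0 (and 9 in the other orientation)
  m1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m1$U, 0)
  expect_equal(m1$U_other, 9)
  expect_error(mann_whitney(numeric(0), 1:3), class = "fgf21val_input_error")

  set.seed(17)
  for (i in 1:6) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    a <- sample(100, n1); b <- sample(100, n2)
    got <- mann_whitney(a, b)
    oracle <- brute_mann_whitney(a, b)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("roc_auc matches pairwise enumeration and has its symmetries", {
  r <- roc_auc(c(0.9, 0.4, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1)
  # label swap: auc' = 1 - auc
  s <- c(0.9, 0.4, 0.3, 0.2); l <- c(1, 0, 1, 0)
  expect_equal(roc_auc(s, 1 - l)$auc, 1 - roc_auc(s, l)$auc)
  # monotone transform invariance
  set.seed(4)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(exp(sc), lb)$auc, roc_auc(sc, lb)$auc)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "fgf21val_input_error")
})

test_that("AUC equals U/(n1 n2) and the pairwise oracle on random instances", {
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    sc <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1)  # rounding forces ties
    lb <- c(rep(1, n1), rep(0, n0))
    auc <- roc_auc(sc, lb)$auc
    expect_equal(auc, brute_auc(sc, lb), tolerance = 1e-12)
    u <- mann_whitney(sc[lb == 1], sc[lb == 0])$U
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("select_dual_thresholds honours floors and LR identities", {
  # perfect classifier: both cut-offs at the separating threshold, LR- = 0
  sc <- c(1, 2, 3, 10, 11, 12); lb <- c(0, 0, 0, 1, 1, 1)
  th <- select_dual_thresholds(sc, lb, sens_floor = 0.9, spec_floor = 0.9)
  expect_equal(th$rule_out, 10)
  expect_equal(th$rule_in, 10)
  expect_equal(th$lr_neg, 0)
  expect_equal(th$sens_at_rule_out, 1)

  # the classical contingency arithmetic: sens .84, spec .80
  expect_equal(0.84 / (1 - 0.80), 4.2)
  expect_equal((1 - 0.84) / 0.80, 0.2)

  set.seed(55)
  sc2 <- rnorm(300) + 1.2 * rep(0:1, 150); lb2 <- rep(0:1, 150)
  th2 <- select_dual_thresholds(sc2, lb2, sens_floor = 0.84, spec_floor = 0.81)
  expect_gte(th2$sens_at_rule_out, 0.84)
  expect_gte(th2$spec_at_rule_in, 0.81)
  expect_lte(th2$rule_out, th2$rule_in)
  # LR identities at each reported threshold
  expect_equal(th2$lr_pos * (1 - th2$spec_at_rule_in), th2$sens_at_rule_in)
  expect_equal(th2$lr_neg * th2$spec_at_rule_out, 1 - th2$sens_at_rule_out)

  expect_error(select_dual_thresholds(sc, lb, sens_floor = 0.4,
                                      spec_floor = 0.9),
               class = "fgf21val_input_error")
  # infeasible floor: with every score tied, no threshold separates the
  # negatives, so no specificity floor can be met
  expect_error(select_dual_thresholds(c(1, 1, 1, 1), c(0, 1, 0, 1),
                                      sens_floor = 0.84, spec_floor = 0.81),
               class = "fgf21val_infeasible")
})

test_that("cohort_analysis runs the full clinical pipeline", {
  cfg <- sim_config(seed = 101)
  coh <- simulate_cohort(cfg)
  rep <- cohort_analysis(coh)
  expect_gte(rep$n_eligible, 0.9 * nrow(coh))
  # rank-correlation target 0.44 recovered within sampling tolerance at n=97
  att_r <- rep$correlations$r[rep$correlations$parameter == "attenuation_coefficient"]
  expect_lt(abs(att_r - 0.44), 0.15)
  expect_equal(nrow(rep$correlations), 11)
  expect_equal(rep$categories$category, c("normal", "suspected", "confirmed"))
  expect_equal(sum(rep$categories$n), rep$n_eligible)
  expect_equal(nrow(rep$pairwise), 3)
  expect_true(!is.null(rep$thresholds) || !is.null(rep$threshold_error))

  # independent FGF21: AUC inside the null sampling band
  coh0 <- simulate_cohort(sim_config(seed = 202,
                                     cohort = list(n = 97, rho = 0,
                                                   fgf21_meanlog = log(300),
                                                   fgf21_sdlog = 0.7,
                                                   att_mean = 0.64, att_sd = 0.13,
                                                   att_range = c(0.32, 0.97))))
  rep0 <- cohort_analysis(coh0)
  expect_gt(rep0$roc$auc, 0.35); expect_lt(rep0$roc$auc, 0.65)

  # deterministic monotone cohort: r = 1 and AUC = 1
  mono <- coh
  mono$fgf21 <- 100 + 500 * mono$attenuation_coefficient
  repm <- cohort_analysis(mono)
  expect_equal(repm$correlations$r[repm$correlations$parameter ==
                                     "attenuation_coefficient"], 1)
  expect_equal(repm$roc$auc, 1)

  expect_error(cohort_analysis(coh[1:10, ]), class = "fgf21val_input_error")
})
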