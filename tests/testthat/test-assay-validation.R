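# Precision, LLOQ, dilution linearity, spike recovery, TCL, interference,
# stability and tube comparison.

test_that("precision_summary computes sample SD and CV", {
  # two-point case by hand: mean 15, sd sqrt(50), cv 100*sqrt(50)/15
  p <- precision_summary(c(10, 20))
  expect_equal(p$mean, 15)
  expect_equal(p$sd, sqrt(50))
  expect_equal(p$cv_percent, 100 * sqrt(50) / 15, tolerance = 1e-12)
  expect_false(p$passes)

  expect_equal(precision_summary(c(100, 100, 100))$cv_percent, 0)
  expect_true(precision_summary(c(100, 100, 100))$passes)

  expect_error(precision_summary(50), class = "fgf21val_input_error")
  expect_error(precision_summary(c(-1, 1)), class = "fgf21val_input_error")
})

test_that("CV is scale-invariant", {
  set.seed(11)
  for (i in 1:10) {
    v <- rlnorm(8, 5, 0.1)
    a <- runif(1, 0.1, 50)
    expect_equal(precision_summary(a * v)$cv_percent,
                 precision_summary(v)$cv_percent, tolerance = 1e-10)
  }
})

test_that("inter_assay_summary pools values across runs", {
  # 2 runs x 2 values {1,3},{2,4}: pooled mean 2.5, sd sqrt(5/3)
  s <- inter_assay_summary(c(1, 3, 2, 4), c("r1", "r1", "r2", "r2"))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s$cv_percent, 100 * sqrt(5 / 3) / 2.5, tolerance = 1e-10)
  expect_equal(s$n_runs, 2L)
  expect_equal(inter_assay_summary(rep(7, 10), rep(1:5, 2))$cv_percent, 0)
  expect_error(inter_assay_summary(1:4, rep("r1", 4)),
               class = "fgf21val_input_error")
})

test_that("lloq_from_blanks inverts mean + k*SD through the curve", {
  crv <- make_curve()
  # zero-SD collapse: all blanks equal
  s0 <- four_pl(8, crv$a, crv$d, crv$c, crv$b)
  res <- lloq_from_blanks(rep(s0, 4), crv)
  expect_equal(res$lloq, 8, tolerance = 1e-8)
  # k = 0 degenerate multiplier
  expect_equal(lloq_from_blanks(rep(s0, 2), crv, k = 0)$lloq, 8,
               tolerance = 1e-8)
  # independent two-line oracle on simulated blanks
  set.seed(99)
  blanks <- crv$a * (1 + rnorm(16, 0, 0.012))
  got <- lloq_from_blanks(blanks, crv, k = 10)$lloq
  thr <- mean(blanks) + 10 * sd(blanks)
  oracle <- crv$c * ((crv$a - crv$d) / (thr - crv$d) - 1)^(1 / crv$b)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("dilution_linearity reproduces recoveries and the linear prefix", {
  series <- read.csv(kit_extdata("kit_dilution_linearity.csv"))
  res <- dilution_linearity(series, deviation_limit = 14)
  expect_equal(round(res$recovery_percent, 1),
               c(100.6, 105.8, 103.5, 97.3, 101.0, 110.8, 101.1, 50.4, 45.8))
  expect_equal(attr(res, "linear_max_factor"), 128)
  expect_equal(res$within_limits, c(rep(TRUE, 7), FALSE, FALSE))

  # perfect observations -> all 100%, full range linear
  perfect <- data.frame(factor = c(2, 4, 8), expected = c(100, 50, 25),
                        observed = c(100, 50, 25))
  resp <- dilution_linearity(perfect)
  expect_true(all(resp$recovery_percent == 100))
  expect_equal(attr(resp, "linear_max_factor"), 8)

  expect_error(dilution_linearity(data.frame(factor = c(4, 2),
                                             expected = c(1, 2),
                                             observed = c(1, 2))),
               class = "fgf21val_input_error")
})

test_that("spike_recovery supports total and marginal conventions", {
  # total mode reproduces the standard table arithmetic
  r1 <- spike_recovery(164, 261, 100, mode = "total")
  expect_equal(r1$theoretical, 264)
  expect_equal(round(r1$recovery_percent, 1), 98.9)
  r2 <- spike_recovery(392, 568, 200, mode = "total")
  expect_equal(round(r2$recovery_percent, 1), 95.9)
  # perfect-recovery fixed point: both modes give exactly 100%
  expect_equal(spike_recovery(150, 250, 100, "total")$recovery_percent, 100)
  expect_equal(spike_recovery(150, 250, 100, "marginal")$recovery_percent, 100)
  # modes coincide when neat = 0
  expect_equal(spike_recovery(0, 95, 100, "total")$recovery_percent,
               spike_recovery(0, 95, 100, "marginal")$recovery_percent)
  expect_error(spike_recovery(100, 150, 0), class = "fgf21val_input_error")
})

test_that("total_change_limit follows the quadrature form", {
  expect_equal(total_change_limit(0, 0)$tcl, 0)
  expect_equal(total_change_limit(5, 0)$tcl, 2.77 * 5)
  expect_equal(total_change_limit(5, 4)$tcl, sqrt(13.85^2 + 2^2))
  expect_equal(round(total_change_limit(5, 4)$tcl, 2), 13.99)
  # monotone nondecreasing in each argument; bounded below by each term
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0, 20); b <- runif(1, 0, 20); eps <- runif(1, 0, 5)
    t0 <- total_change_limit(a, b)$tcl
    expect_gte(total_change_limit(a + eps, b)$tcl, t0)
    expect_gte(total_change_limit(a, b + eps)$tcl, t0)
    expect_gte(t0, max(2.77 * a, 0.5 * b))
  }
  expect_error(total_change_limit(-1, 0), class = "fgf21val_input_error")
})

test_that("interference_bias judges relative bias against the TCL", {
  crit <- total_change_limit(5, 1)  # tcl ~ 13.86
  panel <- data.frame(interferent = "hemoglobin", level = 0:5,
                      observed = rep(200, 6))
  res <- interference_bias(200, panel, crit)
  expect_true(all(res$relative_bias_percent == 0))
  expect_false(any(res$exceeds_tcl))

  res2 <- interference_bias(200, data.frame(interferent = "x", level = 1,
                                            observed = 230), crit)
  expect_equal(res2$relative_bias_percent, 15)
  expect_true(res2$exceeds_tcl)
  res3 <- interference_bias(200, data.frame(interferent = "x", level = 1,
                                            observed = 214), crit)
  expect_equal(res3$relative_bias_percent, 7)
  expect_false(res3$exceeds_tcl)
  expect_error(interference_bias(0, panel, crit), class = "fgf21val_input_error")
})

test_that("stability_series computes percent change and flags exceedances", {
  crit <- total_change_limit(5, 4)
  pts <- data.frame(condition = "room_temp", exposure = c(1, 24),
                    level = "medium", reference = c(500, 500),
                    measured = c(500, 450))
  res <- stability_series(pts, crit)
  expect_equal(res$percent_change, c(0, -10))
  expect_false(any(res$exceeds_tcl))
  # analytic first-order decay sampled at the design times is monotone
  times <- c(1, 2, 4, 24, 72, 168)
  dec <- data.frame(condition = "fridge_4C", exposure = times, level = "high",
                    reference = 600, measured = 600 * exp(-0.001 * times))
  resd <- stability_series(dec, crit)
  expect_true(all(diff(resd$percent_change) <= 0))
  expect_true(any(resd$exceeds_tcl) == (min(resd$percent_change) < -crit$tcl))
  expect_error(stability_series(transform(pts, reference = NA), crit),
               class = "fgf21val_input_error")
})

test_that("tube_comparison: identity, shift and anticorrelated cases", {
  x <- c(10, 25, 40, 55, 80, 120, 150)
  id <- tube_comparison(x, x + c(0.1, -0.1, 0.2, -0.2, 0.1, -0.1, 0.2))
  expect_gt(id$rank_correlation, 0.9)
  ident <- tube_comparison(x, x * 1.0 + 0)  # exact equality
  expect_equal(ident$rank_correlation, 1)
  expect_equal(ident$slope, 1, tolerance = 1e-10)
  expect_equal(ident$intercept, 0, tolerance = 1e-8)

  # constant positive shift: slope 1, intercept c; all-positive tied
  # differences give the smallest p the tie-corrected approximation allows
  sh <- tube_comparison(x, x + 5)
  expect_equal(sh$slope, 1, tolerance = 1e-10)
  expect_equal(sh$intercept, 5, tolerance = 1e-8)
  expect_lt(sh$signed_rank_p, 0.05)
  expect_equal(sh$signed_rank_p, tube_comparison(x, x + 20)$signed_rank_p)

  expect_error(tube_comparison(1:3, 3:1), class = "fgf21val_input_error")
  expect_error(tube_comparison(rep(1, 6), 1:6), class = "fgf21val_infeasible")
})

test_that("signed-rank p matches the exhaustive sign-flip oracle (n <= 7)", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(5:7, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.3, 1)
    got <- tube_comparison(x, y)
    oracle <- brute_signed_rank(x, y)
    expect_equal(got$signed_rank_p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("estimated CV brackets the generating CV on synthetic plates", {
  # 500 replicate 20-well samples at true CV 5%: sampling mean within 0.5
  set.seed(2024)
  cvs <- replicate(500, precision_summary(580 * (1 + rnorm(20, 0, 0.05)))$cv_percent)
  expect_lt(abs(mean(cvs) - 5), 0.5)
})
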