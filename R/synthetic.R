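# Synthetic-data generator: plate reads, every analytical-validation design
# (intra 3x20, inter 5x5 per level, 16 blanks, 9-step serial dilution, 3x3
# spike, 6-point interference panels, stability time courses, 18-subject
# tube comparison) and a patient cohort with a Gaussian-copula rank
# correlation between the attenuation coefficient and log-FGF21.  Every
# output is deterministic under the config seed and comes with ground truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator.  Defaults emulate
#' the validation designs of an automated plasma FGF21 ELISA study: 20
#' intra-assay replicates at three levels, a 5 x 5 inter-assay design, 16
#' blank wells, serial dilution x2..x512, 0/100/200 pg spikes into three
#' plasma samples, four interferent panels at six points, four stability
#' conditions, an 18-subject three-tube comparison, and a 97-patient cohort
#' whose attenuation coefficient and log-FGF21 share Spearman correlation
#' 0.44.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param curve 4PL truth: list `a`, `d`, `c`, `b`.
#' @param noise_cv Per-measurement multiplicative CV, percent.
#' @param blank_noise_cv CV of blank-well signals, percent (blank wells are
#'   quieter than mid-curve wells; this sets the synthetic LLOQ scale).
#' @param run_effect_cv Between-run multiplicative CV, percent.
#' @param n_intra,n_runs,n_per_run,n_blanks,n_lloq Design sizes.
#' @param intra_levels,inter_levels Named true concentrations (pg/mL) for
#'   the low/medium/high precision samples.
#' @param lloq_level True concentration of the near-LLOQ precision sample.
#' @param dilution_top Neat concentration of the dilution-linearity sample.
#' @param dilution_factors Serial dilution factors.
#' @param nonlinear_below,nonlinear_recovery Below this expected
#'   concentration (pg/mL) the assay loses linearity and recovers only this
#'   fraction (emulates signal loss at extreme dilution).
#' @param spike_neat True neat concentrations of the three spike samples.
#' @param spike_levels Added analyte, pg/mL equivalents.
#' @param interference_baseline True concentration of the interference pool.
#' @param interference_bias_max Named per-interferent maximum relative bias
#'   (fraction, at the top dose of the six-point titration).
#' @param stability Per-condition decay: `freeze_thaw` per-cycle fractional
#'   loss, and hourly first-order rates for `fridge_4C`, `room_temp`,
#'   `minus20C`; `noise_cv` is the replicate noise on stability wells.
#' @param tubes List: `n` subjects, lognormal `meanlog`/`sdlog` of true
#'   FGF21, `serum_offset` (fractional serum bias from clotting-time
#'   proteolysis), `noise_cv`.
#' @param cohort List: `n`, Spearman target `rho` between attenuation and
#'   FGF21, lognormal `fgf21_meanlog`/`fgf21_sdlog`, attenuation truncated
#'   normal `att_mean`/`att_sd`/`att_range`.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       curve = list(a = 0.05, d = 2.0, c = 400, b = 1.2),
                       noise_cv = 5,
                       blank_noise_cv = 1.2,
                       run_effect_cv = 5,
                       n_intra = 20L, n_runs = 5L, n_per_run = 5L,
                       n_blanks = 16L, n_lloq = 20L,
                       intra_levels = c(low = 160, medium = 580, high = 1180),
                       inter_levels = c(low = 210, medium = 610, high = 1020),
                       lloq_level = 3,
                       dilution_top = 3000,
                       dilution_factors = 2^(1:9),
                       nonlinear_below = 15, nonlinear_recovery = 0.5,
                       spike_neat = c(165, 220, 390),
                       spike_levels = c(0, 100, 200),
                       interference_baseline = 200,
                       interference_bias_max = c(bilirubin_conjugated = 0.03,
                                                 bilirubin_free = -0.03,
                                                 hemoglobin = 0.04,
                                                 intralipid = -0.04,
                                                 rheumatoid_factor = 0.02),
                       stability = list(freeze_thaw_loss = c(low = 0.008, medium = 0.015, high = 0.015),
                                        fridge_4C_rate = c(low = 0.0002, medium = 0.0009, high = 0.0009),
                                        room_temp_rate = c(low = 0.0021, medium = 0.0021, high = 0.0021),
                                        minus20C_rate = c(low = 0.00004, medium = 0.00004, high = 0.00004),
                                        noise_cv = 2),
                       tubes = list(n = 18L, meanlog = log(250), sdlog = 0.6,
                                    serum_offset = -0.12, noise_cv = 3),
                       cohort = list(n = 97L, rho = 0.44,
                                     fgf21_meanlog = log(300), fgf21_sdlog = 0.7,
                                     att_mean = 0.64, att_sd = 0.13,
                                     att_range = c(0.32, 0.97))) {
  cfg <- list(seed = as.integer(seed), curve = curve, noise_cv = noise_cv,
              blank_noise_cv = blank_noise_cv, run_effect_cv = run_effect_cv,
              n_intra = as.integer(n_intra), n_runs = as.integer(n_runs),
              n_per_run = as.integer(n_per_run), n_blanks = as.integer(n_blanks),
              n_lloq = as.integer(n_lloq),
              intra_levels = intra_levels, inter_levels = inter_levels,
              lloq_level = lloq_level,
              dilution_top = dilution_top, dilution_factors = dilution_factors,
              nonlinear_below = nonlinear_below,
              nonlinear_recovery = nonlinear_recovery,
              spike_neat = spike_neat, spike_levels = spike_levels,
              interference_baseline = interference_baseline,
              interference_bias_max = interference_bias_max,
              stability = stability, tubes = tubes, cohort = cohort)
  if (any(c(cfg$noise_cv, cfg$blank_noise_cv, cfg$run_effect_cv) < 0)) {
    abort_input("sim_config: CVs must be >= 0")
  }
  if (cfg$cohort$n < 10L) abort_input("sim_config: cohort n must be >= 10")
  if (abs(cfg$cohort$rho) >= 1) {
    abort_input("sim_config: cohort rank-correlation target must be in (-1, 1)")
  }
  if (is.null(cfg$curve$a) || is.null(cfg$curve$d) || is.null(cfg$curve$c) ||
      is.null(cfg$curve$b) || cfg$curve$c <= 0 || cfg$curve$b <= 0) {
    abort_input("sim_config: curve needs a, d, c > 0, b > 0")
  }
  structure(cfg, class = "sim_config")
}

true_curve <- function(config) {
  structure(list(a = config$curve$a, d = config$curve$d,
                 c = config$curve$c, b = config$curve$b,
                 working_range = c(31.3, 2000), fit_residual = 0,
                 n_levels = NA_integer_, data = NULL),
            class = "fgf21_curve")
}

# multiplicative mean-zero noise at the given percent CV
mult_noise <- function(n, cv) 1 + stats::rnorm(n, 0, cv / 100)

#' Simulate plate signals for given true concentrations
#'
#' Standards (the kit series, in duplicate) and sample wells are generated
#' as 4PL(true concentration) times multiplicative noise at `noise_cv`.
#'
#' @param config A [sim_config()].
#' @param true_concentrations True sample concentrations, pg/mL (>= 0).
#' @param n_replicates Wells per sample (default 2).
#' @return List with `standards` (concentration, signal, replicate) and
#'   `samples` (sample, true_concentration, replicate, signal).
#' @export
simulate_plate <- function(config, true_concentrations, n_replicates = 2L) {
  check_finite(true_concentrations, "simulate_plate: true_concentrations")
  if (any(true_concentrations < 0)) {
    abort_input("simulate_plate: concentrations must be >= 0")
  }
  set.seed(config$seed)
  cv <- config$noise_cv
  crv <- config$curve
  std_conc <- rep(kit_standard_concentrations(), each = 2L)
  std_sig <- pmax(four_pl(std_conc, crv$a, crv$d, crv$c, crv$b) *
                    mult_noise(length(std_conc), cv), 1e-6)
  samp_conc <- rep(true_concentrations, each = n_replicates)
  samp_sig <- pmax(four_pl(samp_conc, crv$a, crv$d, crv$c, crv$b) *
                     mult_noise(length(samp_conc), cv), 1e-6)
  list(
    standards = data.frame(concentration = std_conc, signal = std_sig,
                           replicate = rep(seq_len(2L), times = length(std_conc) / 2L)),
    samples = data.frame(sample = rep(seq_along(true_concentrations), each = n_replicates),
                         true_concentration = samp_conc,
                         replicate = rep(seq_len(n_replicates),
                                         times = length(true_concentrations)),
                         signal = samp_sig)
  )
}

# retention fraction for one stability condition at a given exposure
stability_retention <- function(condition, exposure, level, stab) {
  switch(condition,
    freeze_thaw = (1 - stab$freeze_thaw_loss[[level]])^exposure,
    fridge_4C = exp(-stab$fridge_4C_rate[[level]] * exposure),
    room_temp = exp(-stab$room_temp_rate[[level]] * exposure),
    minus20C = exp(-stab$minus20C_rate[[level]] * exposure),
    abort_input("unknown stability condition: %s", condition)
  )
}

#' Simulate the full analytical-validation file set
#'
#' Generates every table the validation stage consumes -- standards,
#' precision replicates (intra, inter and near-LLOQ), blank signals, the
#' serial-dilution series, spike samples, interference panels, stability
#' time courses and the three-tube comparison -- together with the ground
#' truth used to generate them.  Measured concentrations carry
#' multiplicative noise at `noise_cv`; inter-assay values additionally
#' carry a lognormal between-run effect at `run_effect_cv`.
#'
#' @param config A [sim_config()].
#' @return List of data frames `standards`, `replicates`, `blanks`,
#'   `dilution`, `spike`, `interference`, `stability`, `tubes`, plus
#'   `truth` (list).  Deterministic given `config$seed`.
#' @export
simulate_validation_suite <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  cv <- config$noise_cv
  crv <- config$curve

  # standards in duplicate
  std_conc <- rep(kit_standard_concentrations(), each = 2L)
  standards <- data.frame(
    concentration_pg_ml = std_conc,
    signal = pmax(four_pl(std_conc, crv$a, crv$d, crv$c, crv$b) *
                    mult_noise(length(std_conc), cv), 1e-6),
    replicate = rep(1:2, times = length(std_conc) / 2L)
  )

  # intra-assay replicates: one run, n_intra per level
  reps <- list()
  for (lv in names(config$intra_levels)) {
    reps[[length(reps) + 1L]] <- data.frame(
      sample_id = paste0("intra_", lv), level = lv, run_id = "run0",
      value = config$intra_levels[[lv]] * mult_noise(config$n_intra, cv)
    )
  }
  # near-LLOQ precision replicates (noise only, no run effect)
  reps[[length(reps) + 1L]] <- data.frame(
    sample_id = "lloq_pool", level = "lloq", run_id = "run0",
    value = config$lloq_level * mult_noise(config$n_lloq, cv)
  )
  # inter-assay: n_runs runs x n_per_run per level, with run effect
  run_eff <- matrix(
    exp(stats::rnorm(config$n_runs * length(config$inter_levels),
                     0, config$run_effect_cv / 100)),
    nrow = config$n_runs
  )
  for (j in seq_along(config$inter_levels)) {
    lv <- names(config$inter_levels)[j]
    for (r in seq_len(config$n_runs)) {
      reps[[length(reps) + 1L]] <- data.frame(
        sample_id = paste0("inter_", lv), level = lv,
        run_id = paste0("run", r),
        value = config$inter_levels[[lv]] * run_eff[r, j] *
          mult_noise(config$n_per_run, cv)
      )
    }
  }
  replicates <- do.call(rbind, reps)

  # blank signals (quieter than mid-curve wells)
  blanks <- data.frame(
    signal = pmax(crv$a * mult_noise(config$n_blanks, config$blank_noise_cv), 1e-6)
  )

  # dilution linearity: duplicates, loss of linearity at extreme dilution
  dil <- do.call(rbind, lapply(config$dilution_factors, function(f) {
    expected <- config$dilution_top / f
    frac <- if (expected < config$nonlinear_below) config$nonlinear_recovery else 1
    obs <- expected * frac * mult_noise(2L, cv)
    data.frame(factor = f, expected = expected,
               observed = mean(obs), cv = 100 * stats::sd(obs) / mean(obs))
  }))

  # spike recovery: 3 samples x 3 spike levels, duplicates
  spk <- do.call(rbind, lapply(seq_along(config$spike_neat), function(i) {
    do.call(rbind, lapply(config$spike_levels, function(s) {
      truev <- config$spike_neat[i] + s
      obs <- truev * mult_noise(2L, cv)
      data.frame(sample_id = paste0("S", i), spike_pg = s,
                 measured = mean(obs), cv = 100 * stats::sd(obs) / mean(obs))
    }))
  }))

  # interference panels: six-point titration per interferent
  intf <- do.call(rbind, lapply(names(config$interference_bias_max), function(nm) {
    bias_top <- config$interference_bias_max[[nm]]
    lev <- 0:5
    truev <- config$interference_baseline * (1 + bias_top * lev / 5)
    data.frame(interferent = nm, level_index = lev,
               observed = truev * mult_noise(6L, cv / 2),
               baseline = config$interference_baseline)
  }))

  # stability: per-condition exposures, three levels
  stab <- config$stability
  design <- rbind(
    expand.grid(condition = "freeze_thaw", exposure = c(1, 2, 3, 5, 7),
                level = names(config$intra_levels), stringsAsFactors = FALSE),
    expand.grid(condition = c("fridge_4C", "room_temp"),
                exposure = c(1, 2, 4, 24, 72, 168),
                level = names(config$intra_levels), stringsAsFactors = FALSE),
    expand.grid(condition = "minus20C", exposure = 720,
                level = names(config$intra_levels), stringsAsFactors = FALSE)
  )
  stability <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    lv <- design$level[i]
    ref <- config$intra_levels[[lv]]
    ret <- stability_retention(design$condition[i], design$exposure[i], lv, stab)
    data.frame(condition = design$condition[i], exposure = design$exposure[i],
               level = lv, reference = ref,
               measured = ref * ret * mult_noise(1L, stab$noise_cv))
  }))

  # tube comparison: latent true value per subject, three tube types
  tb <- config$tubes
  truev <- stats::rlnorm(tb$n, tb$meanlog, tb$sdlog)
  tubes <- data.frame(
    subject_id = seq_len(tb$n),
    heparin = truev * mult_noise(tb$n, tb$noise_cv),
    edta = truev * mult_noise(tb$n, tb$noise_cv),
    serum = truev * (1 + tb$serum_offset) * mult_noise(tb$n, tb$noise_cv)
  )

  # analytic LLOQ implied by the generating parameters (no sampling noise)
  lloq_signal <- crv$a * (1 + 10 * config$blank_noise_cv / 100)
  lloq_true <- signal_to_concentration(true_curve(config), lloq_signal)$concentration

  truth <- list(
    seed = config$seed, noise_cv = cv, run_effect_cv = config$run_effect_cv,
    curve = config$curve,
    intra_levels = as.list(config$intra_levels),
    inter_levels = as.list(config$inter_levels),
    true_intra_cv = cv,
    true_inter_cv = sqrt(cv^2 + config$run_effect_cv^2),
    lloq_true = lloq_true,
    dilution = list(top = config$dilution_top,
                    nonlinear_below = config$nonlinear_below,
                    nonlinear_recovery = config$nonlinear_recovery),
    spike_neat = config$spike_neat,
    true_recovery_percent = 100,
    interference_bias_max = as.list(config$interference_bias_max),
    serum_offset = tb$serum_offset
  )

  list(standards = standards, replicates = replicates, blanks = blanks,
       dilution = dil, spike = spk, interference = intf,
       stability = stability, tubes = tubes, truth = truth)
}

# truncated-normal quantile via probability rescaling
qtruncnorm <- function(p, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

#' Simulate a patient cohort
#'
#' Draws a screening cohort whose attenuation coefficient and FGF21 share a
#' target Spearman correlation via a Gaussian copula: a latent bivariate
#' normal with Pearson correlation `2 sin(pi rho_s / 6)` is transformed to a
#' truncated-normal attenuation marginal and a lognormal FGF21 marginal
#' (Spearman correlation is a copula property, so the target survives both
#' transforms).  Remaining clinical fields are drawn independently within
#' realistic screening-population ranges so that the large majority of
#' records pass the eligibility filter.
#'
#' @param config A [sim_config()]; the `cohort` element controls `n`, the
#'   rank-correlation target and both marginals.
#' @return Data frame of patient records (one row each) with attribute
#'   `truth`: the generating correlation and per-patient steatosis state
#'   (attenuation >= 0.66).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  co <- config$cohort
  set.seed(config$seed + 1L)
  n <- co$n
  rho_lat <- 2 * sin(pi * co$rho / 6)  # latent Pearson hitting the Spearman target
  z1 <- stats::rnorm(n)
  z2 <- rho_lat * z1 + sqrt(1 - rho_lat^2) * stats::rnorm(n)
  att <- qtruncnorm(stats::pnorm(z1), co$att_mean, co$att_sd,
                    co$att_range[1], co$att_range[2])
  fgf21 <- exp(co$fgf21_meanlog + co$fgf21_sdlog * z2)

  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- round(qtruncnorm(stats::runif(n), 54, 11, 27, 69))
  bmi <- qtruncnorm(stats::runif(n), 22.5, 3, 15.4, 29.3)
  ast <- exp(qtruncnorm(stats::runif(n), log(20), 0.25, log(13), log(67)))
  alt <- exp(qtruncnorm(stats::runif(n), log(21), 0.4, log(7), log(134)))
  ggt <- exp(qtruncnorm(stats::runif(n), log(21), 0.6, log(6), log(414)))
  bili <- exp(qtruncnorm(stats::runif(n), log(0.8), 0.35, log(0.3), log(2.8)))
  alb <- qtruncnorm(stats::runif(n), 4.3, 0.3, 3.6, 5.1)
  plt <- qtruncnorm(stats::runif(n), 233, 55, 139, 466)  # 10^9/L
  alcohol <- stats::rgamma(n, shape = 1.5, scale = 25)   # g/week, mostly light
  swe <- qtruncnorm(stats::runif(n), 1.24, 0.12, 0.94, 1.58)

  out <- data.frame(
    patient_id = seq_len(n), age = age, sex = sex, bmi = bmi,
    ast = ast, alt = alt, ggt = ggt, total_bilirubin = bili, albumin = alb,
    platelet_count = plt, weekly_alcohol_g = alcohol,
    shear_wave_speed = swe, attenuation_coefficient = att, fgf21 = fgf21,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(rho_target = co$rho, rho_latent = rho_lat,
                             steatotic = att >= 0.66)
  out
}
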