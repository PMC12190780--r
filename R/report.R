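# Orchestration and report rendering: configuration handling plus the
# three pipeline commands (simulate / validate / diagnose) behind the
# command-line entry point in exec/fgf21val.  Percentages are rounded only
# at render time (one decimal); all internal computation is unrounded.

#' Default run configuration
#'
#' Thresholds and paths used by the pipeline commands: the precision CV
#' limit (15%), TCL inputs, eligibility bounds, attenuation cut-offs
#' (0.58 / 0.66 / 0.70 dB/cm/MHz) and the sensitivity/specificity floors
#' for dual-threshold selection.
#'
#' @param seed Integer seed forwarded to the simulator.
#' @param out_dir Output directory.
#' @return Named list of configuration values.
#' @export
default_run_config <- function(seed = 1L, out_dir = "fgf21val_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cv_threshold = 15,
    tcl = list(cv_a = 5, cv_b = 4),
    eligibility = eligibility_defaults(),
    category_cutoffs = c(0.58, 0.70),
    diagnosis_cutoff = 0.66,
    sens_floor = 0.84,
    spec_floor = 0.81,
    sim = list()
  )
}

#' Load and validate a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()]; thresholds are
#' validated before any computation so a typo fails fast.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL, seed = NULL, out_dir = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_input("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.numeric(cfg$cv_threshold) || cfg$cv_threshold <= 0) {
    abort_input("config: cv_threshold must be > 0")
  }
  if (cfg$tcl$cv_a < 0 || cfg$tcl$cv_b < 0) abort_input("config: TCL CVs must be >= 0")
  if (cfg$sens_floor <= 0.5 || cfg$sens_floor >= 1 ||
      cfg$spec_floor <= 0.5 || cfg$spec_floor >= 1) {
    abort_input("config: sens/spec floors must lie in (0.5, 1)")
  }
  if (length(cfg$category_cutoffs) != 2L ||
      cfg$category_cutoffs[1] >= cfg$category_cutoffs[2]) {
    abort_input("config: category_cutoffs must be an increasing pair")
  }
  cfg
}

config_hash <- function(cfg) {
  # hash the analysis-relevant configuration; the output path is not part
  # of the analysis, so the same run into two directories hashes equal
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Simulate the full input file set
#'
#' Writes every CSV the validation and diagnostics stages consume, plus
#' `truth.json` (ground truth) and `manifest.json` (seed, package version,
#' config hash).
#'
#' @param config A run configuration (see [load_run_config()]).
#' @return Invisibly, the output directory.
#' @export
cmd_simulate <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  suite <- simulate_validation_suite(sim)
  cohort <- simulate_cohort(sim)

  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  wr(suite$standards, "standards.csv")
  wr(suite$replicates, "replicates.csv")
  wr(suite$blanks, "blanks.csv")
  wr(suite$dilution, "dilution.csv")
  wr(suite$spike, "spike.csv")
  wr(suite$interference, "interference.csv")
  wr(suite$stability, "stability.csv")
  wr(suite$tubes, "tubes.csv")
  wr(cohort, "cohort.csv")

  truth <- suite$truth
  truth$cohort <- attr(cohort, "truth")
  jsonlite::write_json(truth, file.path(config$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(seed = config$seed,
                   package = "fgf21val",
                   version = as.character(utils::packageVersion("fgf21val")),
                   config_hash = config_hash(config),
                   files = c("standards.csv", "replicates.csv", "blanks.csv",
                             "dilution.csv", "spike.csv", "interference.csv",
                             "stability.csv", "tubes.csv", "cohort.csv",
                             "truth.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

read_if_present <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p)) return(NULL)
  df <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                 error = function(e) abort_input("malformed CSV %s: %s",
                                                 p, conditionMessage(e)))
  df
}

#' Run every available analytical-validation stage
#'
#' Reads whichever input CSVs are present in `in_dir` (schemas as written
#' by [cmd_simulate()]) and computes the corresponding validation report
#' sections: calibration fit, precision tables (intra / inter / LLOQ-level),
#' LLOQ from blanks, dilution linearity, spike recovery (both modes),
#' interference bias, stability and tube comparison.  Partial input sets
#' yield partial reports.
#'
#' @param in_dir Directory of input CSVs.
#' @param config A run configuration.
#' @return Object of class `fgf21_validation_report` (a list of sections);
#'   written as `validation_report.json` plus per-table CSVs under
#'   `config$out_dir`.
#' @export
cmd_validate <- function(in_dir, config = default_run_config()) {
  if (!dir.exists(in_dir)) abort_input("input directory not found: %s", in_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  criterion <- total_change_limit(config$tcl$cv_a, config$tcl$cv_b)
  report <- list(tcl = unclass(criterion), sections = character(0))

  curve <- NULL
  std <- read_if_present(in_dir, "standards.csv")
  if (!is.null(std)) {
    need_cols(std, c("concentration_pg_ml", "signal"), "standards.csv")
    curve <- fit_4pl(data.frame(concentration = std$concentration_pg_ml,
                                signal = std$signal,
                                replicate = std$replicate %||% 1L))
    report$calibration <- list(a = curve$a, d = curve$d, c = curve$c,
                               b = curve$b, fit_residual = curve$fit_residual,
                               working_range = curve$working_range)
    report$sections <- c(report$sections, "calibration")
  }

  reps <- read_if_present(in_dir, "replicates.csv")
  if (!is.null(reps)) {
    need_cols(reps, c("sample_id", "level", "run_id", "value"), "replicates.csv")
    intra <- reps[!grepl("^inter", reps$sample_id) & reps$level != "lloq", ]
    prec <- do.call(rbind, lapply(split(intra, intra$level), function(g) {
      cbind(data.frame(assay = "intra", level = g$level[1]),
            precision_summary(g$value, threshold = config$cv_threshold))
    }))
    inter <- reps[grepl("^inter", reps$sample_id), ]
    if (nrow(inter) > 0L) {
      prec <- rbind(prec, do.call(rbind, lapply(split(inter, inter$level), function(g) {
        cbind(data.frame(assay = "inter", level = g$level[1]),
              inter_assay_summary(g$value, g$run_id,
                                  threshold = config$cv_threshold)[
                , c("n", "mean", "sd", "cv_percent", "passes")])
      })))
    }
    lloq_reps <- reps[reps$level == "lloq", ]
    if (nrow(lloq_reps) > 0L) {
      prec <- rbind(prec, cbind(data.frame(assay = "lloq", level = "lloq"),
                                precision_summary(lloq_reps$value,
                                                  threshold = config$cv_threshold)))
    }
    rownames(prec) <- NULL
    report$precision <- prec
    report$sections <- c(report$sections, "precision")
    utils::write.csv(within(prec, cv_percent <- round1(cv_percent)),
                     file.path(config$out_dir, "precision_table.csv"),
                     row.names = FALSE)
  }

  blk <- read_if_present(in_dir, "blanks.csv")
  if (!is.null(blk) && !is.null(curve)) {
    need_cols(blk, "signal", "blanks.csv")
    report$lloq <- lloq_from_blanks(blk$signal, curve)
    report$sections <- c(report$sections, "lloq")
  }

  dil <- read_if_present(in_dir, "dilution.csv")
  if (!is.null(dil)) {
    dl <- dilution_linearity(dil, criterion = criterion,
                             cv_limit = config$cv_threshold)
    report$dilution <- dl
    report$dilution_linear_max_factor <- attr(dl, "linear_max_factor")
    report$sections <- c(report$sections, "dilution")
    utils::write.csv(within(dl, {recovery_percent <- round1(recovery_percent)
                                 cv_percent <- round1(cv_percent)}),
                     file.path(config$out_dir, "dilution_table.csv"),
                     row.names = FALSE)
  }

  spk <- read_if_present(in_dir, "spike.csv")
  if (!is.null(spk)) {
    need_cols(spk, c("sample_id", "spike_pg", "measured"), "spike.csv")
    report$spike <- spike_table(spk)
    report$sections <- c(report$sections, "spike")
    utils::write.csv(within(report$spike,
                            {recovery_total <- round1(recovery_total)
                             recovery_marginal <- round1(recovery_marginal)}),
                     file.path(config$out_dir, "spike_table.csv"),
                     row.names = FALSE)
  }

  intf <- read_if_present(in_dir, "interference.csv")
  if (!is.null(intf)) {
    need_cols(intf, c("interferent", "level_index", "observed", "baseline"),
              "interference.csv")
    res <- do.call(rbind, lapply(split(intf, intf$interferent), function(g) {
      interference_bias(g$baseline[1],
                        data.frame(interferent = g$interferent,
                                   level = g$level_index,
                                   observed = g$observed),
                        criterion)
    }))
    rownames(res) <- NULL
    report$interference <- res
    report$sections <- c(report$sections, "interference")
  }

  stab <- read_if_present(in_dir, "stability.csv")
  if (!is.null(stab)) {
    report$stability <- stability_series(stab, criterion)
    report$sections <- c(report$sections, "stability")
    utils::write.csv(within(report$stability,
                            percent_change <- round1(percent_change)),
                     file.path(config$out_dir, "stability_table.csv"),
                     row.names = FALSE)
  }

  tb <- read_if_present(in_dir, "tubes.csv")
  if (!is.null(tb)) {
    need_cols(tb, c("heparin", "edta", "serum"), "tubes.csv")
    report$tubes <- list(
      heparin_edta = unclass(tube_comparison(tb$heparin, tb$edta,
                                             c("heparin", "edta"))),
      heparin_serum = unclass(tube_comparison(tb$heparin, tb$serum,
                                              c("heparin", "serum"))),
      edta_serum = unclass(tube_comparison(tb$edta, tb$serum,
                                           c("edta", "serum")))
    )
    report$sections <- c(report$sections, "tubes")
  }

  class(report) <- "fgf21_validation_report"
  json <- report
  json$config_hash <- config_hash(config)
  jsonlite::write_json(lapply(unclass(json), function(x) {
    if (is.data.frame(x)) x else x
  }), file.path(config$out_dir, "validation_report.json"),
  auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Spike-recovery table in both conventions
#'
#' Expands a spike input table (`sample_id`, `spike_pg`, `measured`, with
#' the `spike_pg = 0` row per sample giving the neat measurement) into
#' total-mode and marginal-mode recoveries side by side.
#'
#' @param spk Spike input data frame.
#' @return Data frame with one row per spiked aliquot.
#' @export
spike_table <- function(spk) {
  need_cols(spk, c("sample_id", "spike_pg", "measured"), "spike_table")
  out <- do.call(rbind, lapply(split(spk, spk$sample_id), function(g) {
    neat_row <- g[g$spike_pg == 0, ]
    if (nrow(neat_row) != 1L) {
      abort_input("spike_table: sample %s needs exactly one spike_pg = 0 row",
                  g$sample_id[1])
    }
    sp <- g[g$spike_pg > 0, ]
    if (nrow(sp) == 0L) return(NULL)
    tot <- spike_recovery(neat_row$measured, sp$measured, sp$spike_pg,
                          mode = "total", label = g$sample_id[1])
    mar <- spike_recovery(neat_row$measured, sp$measured, sp$spike_pg,
                          mode = "marginal", label = g$sample_id[1])
    data.frame(sample_id = g$sample_id[1], spike_pg = sp$spike_pg,
               neat = neat_row$measured, measured = sp$measured,
               theoretical = tot$theoretical,
               recovery_total = tot$recovery_percent,
               recovery_marginal = mar$recovery_percent,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the clinical-diagnostics stage on a cohort file
#'
#' @param cohort_path CSV of patient records (schema of
#'   [simulate_cohort()]'s output) or a data frame.
#' @param config A run configuration.
#' @return The [cohort_analysis()] report; also written as
#'   `clinical_report.json` under `config$out_dir`.
#' @export
cmd_diagnose <- function(cohort_path, config = default_run_config()) {
  cohort <- if (is.data.frame(cohort_path)) cohort_path else {
    if (!file.exists(cohort_path)) abort_input("cohort file not found: %s", cohort_path)
    utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- cohort_analysis(cohort,
                         diagnosis_cutoff = config$diagnosis_cutoff,
                         category_cutoffs = config$category_cutoffs,
                         sens_floor = config$sens_floor,
                         spec_floor = config$spec_floor)
  json <- list(
    n_total = rep$n_total, n_eligible = rep$n_eligible,
    correlations = rep$correlations, categories = rep$categories,
    pairwise = rep$pairwise, auc = rep$roc$auc,
    roc_points = rep$roc$points,
    thresholds = if (!is.null(rep$thresholds)) unclass(rep$thresholds),
    threshold_error = rep$threshold_error,
    diagnosis_cutoff = rep$diagnosis_cutoff,
    config_hash = config_hash(config)
  )
  jsonlite::write_json(json, file.path(config$out_dir, "clinical_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  rep
}
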