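# Orchestration: configuration handling and the simulate -> enrich ->
# analyze -> report pipeline surface. Each cmd_* function reads/writes plain
# CSV/TSV files in a run directory and logs to stderr; a thin Rscript
# wrapper (inst/scripts/pulsekin) exposes them as shell subcommands.

#' Default run configuration
#'
#' All defaults equal the documented module defaults. The configuration
#' round-trips losslessly through YAML.
#'
#' @param master_seed Master seed for the synthetic trial.
#' @param out_dir Output directory of the run.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(master_seed = 1L, out_dir = ".") {
  structure(list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    constants = list(de_novo_fraction_b = 0.65, detection_threshold = 5e-4),
    design = list(n_per_arm = 10L),
    grid = list(dt = 0.1, horizon = 60),
    availability = list(amplitude = 0.05, window_start = 0,
                        window_length = 0.42),
    kinetics = list(
      eosinophil = list(delay_shift = 3.6, delay_mean_extra = 3.0,
                        blood_half_life = 2.5, airway_influx_fraction = 0.1,
                        airway_residence_mean = 5.0,
                        airway_pool_relative = 10, production_scale = 1.0),
      basophil = list(delay_shift = 5.6, delay_mean_extra = 3.5,
                      blood_half_life = 3.5, airway_influx_fraction = 0.1,
                      airway_residence_mean = 5.0,
                      airway_pool_relative = 10, production_scale = 1.0)),
    scenario = list(production_floor = 0.1, production_decay_time = 1.0,
                    phase1_blood_halflife_multiplier = 1.8,
                    phase2_blood_halflife_multiplier = 1.0,
                    airway_influx_multiplier = 0.3,
                    count_noise_cv = 0.25, ms_area_noise_cv = 0.02),
    windows = list(up = c(0, 7), down = c(8, 22)),
    log_level = "info"), class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a `run_config`; `write_config` the path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merged <- utils::modifyList(unclass(base), cfg)
  merged$master_seed <- as.integer(merged$master_seed)
  structure(merged, class = "run_config")
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Apply `key=value` overrides to a configuration
#'
#' Keys use `$`-separated paths (e.g. `scenario$production_floor=0.2` or
#' `design$n_per_arm=1`). Values are parsed as numeric when possible.
#'
#' @param config A `run_config`.
#' @param overrides Character vector of `key=value` strings.
#' @return The updated `run_config`.
#' @export
apply_overrides <- function(config, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed override (want key=value): ", ov)
    keys <- strsplit(kv[1], "$", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val)) val <- kv[2]
    config[[keys]] <- val
  }
  config
}

config_objects <- function(config) {
  list(
    constants = correction_constants(
      config$constants$de_novo_fraction_b,
      config$constants$detection_threshold),
    grid = simulation_grid(config$grid$dt, config$grid$horizon),
    avail = label_availability(config$availability$amplitude,
                               config$availability$window_start,
                               config$availability$window_length),
    params = list(
      eosinophil = do.call(kinetic_parameters,
                           c(list(cell_type = "eosinophil"),
                             config$kinetics$eosinophil)),
      basophil = do.call(kinetic_parameters,
                         c(list(cell_type = "basophil"),
                           config$kinetics$basophil))),
    scenario = do.call(treatment_scenario, config$scenario),
    windows = phase_windows(unlist(config$windows$up),
                            unlist(config$windows$down)))
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(...)
}

provenance <- function(config, seed) {
  list(package = "pulsekin",
       version = as.character(utils::packageVersion("pulsekin")),
       master_seed = seed,
       config = unclass(config))
}

#' Simulate a synthetic trial and write its files
#'
#' Writes `measurements.csv` (GC-MS readings), `counts.csv`, `truth.csv`
#' (sidecar, not consumed by the analysis path), `profiles.csv`,
#' `config.yaml` and `provenance.yaml` into the run directory.
#'
#' @param config A `run_config`.
#' @return Invisibly, the vector of files written.
#' @export
cmd_simulate <- function(config = default_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory: ", config$out_dir)
  obj <- config_objects(config)
  design <- default_design(seed = config$master_seed,
                           n_per_arm = config$design$n_per_arm)
  log_msg(config, "simulating trial with master seed ", config$master_seed)
  trial <- generate_trial(design, obj$params, obj$scenario,
                          master_seed = config$master_seed,
                          grid = obj$grid, constants = obj$constants)
  paths <- file.path(config$out_dir,
                     c("measurements.csv", "counts.csv", "truth.csv",
                       "profiles.csv", "config.yaml", "provenance.yaml"))
  write_num_csv(trial$readings, paths[1])
  write_num_csv(trial$counts, paths[2])
  write_num_csv(trial$truth, paths[3])
  write_num_csv(trial$profiles, paths[4])
  write_config(config, paths[5])
  yaml::write_yaml(provenance(config, config$master_seed), paths[6])
  invisible(paths)
}

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the enrichment pipeline on a simulated or measured run directory
#'
#' Reads `measurements.csv`, writes `enrichment.csv`. Per-row failures are
#' logged and collected; the run fails only when more than half of the DNA
#' rows cannot be processed.
#'
#' @param config A `run_config` whose `out_dir` holds `measurements.csv`.
#' @return Invisibly, the enrichment CSV path.
#' @export
cmd_enrich <- function(config = default_config()) {
  path <- file.path(config$out_dir, "measurements.csv")
  if (!file.exists(path)) stop("missing input file: ", path)
  readings <- read_readings_csv(path)
  if (nrow(readings) == 0L) stop("empty measurements file: ", path)
  obj <- config_objects(config)
  points <- enrichment_pipeline(readings, identity_calibration(),
                                obj$constants)
  errs <- attr(points, "errors")
  if (nrow(errs) > 0L)
    log_msg(config, nrow(errs), " row(s) failed enrichment: ",
            paste(utils::head(errs$reason, 3L), collapse = "; "))
  n_dna <- sum(readings$channel_set == "dna_adenosine_435_437")
  if (nrow(errs) > 0.5 * max(n_dna, 1L))
    stop("more than half of the DNA readings failed enrichment")
  out <- file.path(config$out_dir, "enrichment.csv")
  write_enrichment_csv(points, out)
  if (nrow(errs) > 0L)
    write_num_csv(errs, file.path(config$out_dir, "enrichment_errors.csv"))
  invisible(out)
}

# pooled group points for one phase/compartment/cell type
pool_points <- function(enr, counts_arm, phase, compartment, cell_type, arm) {
  subj <- unique(counts_arm$subject_id[counts_arm$arm == arm])
  enr[enr$phase == phase & enr$compartment == compartment &
        enr$cell_type == cell_type & enr$subject_id %in% subj,
      c("study_day", "normalized_enrichment")]
}

#' Analyze an enriched run directory
#'
#' Reads `enrichment.csv` and `counts.csv`; writes `results.tsv` (test name,
#' groups, window, statistic, p, method, flags), `group_medians.csv`
#' (figure-ready per-day group medians/IQRs) and `dilution_ratios.csv`.
#' Performs: per-phase up/down ANCOVA comparisons (blood eosinophils, sputum
#' eosinophils, blood basophils; placebo vs mepolizumab), per-day
#' Mann-Whitney count comparisons, paired blood-vs-sputum signed-rank tests,
#' and placebo dilution-ratio series.
#'
#' @param config A `run_config`.
#' @return Invisibly, the results TSV path.
#' @export
cmd_analyze <- function(config = default_config()) {
  enr_path <- file.path(config$out_dir, "enrichment.csv")
  cnt_path <- file.path(config$out_dir, "counts.csv")
  for (p in c(enr_path, cnt_path))
    if (!file.exists(p)) stop("missing input file: ", p)
  enr <- utils::read.csv(enr_path, stringsAsFactors = FALSE)
  counts <- utils::read.csv(cnt_path, stringsAsFactors = FALSE)
  need_enr <- c("subject_id", "phase", "study_day", "compartment",
                "cell_type", "normalized_enrichment")
  need_cnt <- c("subject_id", "arm", "phase", "study_day", "cell_type",
                "count")
  miss <- c(setdiff(need_enr, names(enr)), setdiff(need_cnt, names(counts)))
  if (length(miss) > 0L)
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  obj <- config_objects(config)
  arm_of <- unique(counts[, c("subject_id", "arm")])
  enr$arm <- arm_of$arm[match(enr$subject_id, arm_of$subject_id)]

  rows <- list()
  add <- function(test, groups, phase, window, statistic, p, method, flag = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, groups = groups, phase = phase, window = window,
      statistic = statistic, p = p, method = method, flag = flag,
      stringsAsFactors = FALSE)
  }

  # phase-wise ANCOVA per compartment/cell type
  combos <- list(c("blood", "eosinophil"), c("sputum", "eosinophil"),
                 c("blood", "basophil"))
  for (phase in 1:2) for (cmb in combos) {
    ga <- enr[enr$arm == "placebo" & enr$phase == phase &
                enr$compartment == cmb[1] & enr$cell_type == cmb[2], ]
    gb <- enr[enr$arm == "mepolizumab" & enr$phase == phase &
                enr$compartment == cmb[1] & enr$cell_type == cmb[2], ]
    cmp <- compare_phase_regressions(ga, gb, obj$windows)
    for (w in c("up", "down")) {
      res <- cmp[[w]]
      label <- paste("ancova_slope", cmb[1], cmb[2], sep = "_")
      if (is.null(res)) {
        add(label, "placebo_vs_mepolizumab", phase, w, NA_real_, NA_real_,
            "ancova", cmp$not_computable[[w]])
      } else {
        add(label, "placebo_vs_mepolizumab", phase, w, res$F_slope,
            res$p_slope, "ancova",
            if (res$separated) "residuals~0" else "")
        add(paste("ancova_elevation", cmb[1], cmb[2], sep = "_"),
            "placebo_vs_mepolizumab", phase, w, res$F_elev, res$p_elev,
            "ancova", if (res$elevation_valid) "" else "slopes_differ")
      }
    }
  }

  # per-day count rank tests
  for (phase in 1:2) for (ct in c("eosinophil", "basophil")) {
    cc <- counts[counts$phase == phase & counts$cell_type == ct, ]
    for (d in sort(unique(cc$study_day))) {
      x <- cc$count[cc$arm == "placebo" & cc$study_day == d]
      y <- cc$count[cc$arm == "mepolizumab" & cc$study_day == d]
      if (length(x) >= 3L && length(y) >= 3L) {
        rt <- rank_sum_test(x, y)
        add(paste0("count_mwu_", ct, "_day", d), "placebo_vs_mepolizumab",
            phase, "", rt$statistic, rt$p, rt$method,
            if (rt$tie_correction) "ties" else "")
      }
    }
  }

  # paired blood vs sputum enrichment (same subject/day), per arm
  for (phase in 1:2) for (arm in c("placebo", "mepolizumab")) {
    ee <- enr[enr$arm == arm & enr$phase == phase &
                enr$cell_type == "eosinophil", ]
    bl <- ee[ee$compartment == "blood", ]
    sp <- ee[ee$compartment == "sputum", ]
    m <- merge(bl, sp, by = c("subject_id", "study_day"),
               suffixes = c("_blood", "_sputum"))
    if (nrow(m) >= 3L) {
      st <- signed_rank_test(m$normalized_enrichment_blood,
                             m$normalized_enrichment_sputum)
      add("signed_rank_blood_vs_sputum", arm, phase, "", st$statistic,
          st$p, st$method, if (isTRUE(st$all_zero)) "all_zero" else "")
    }
  }
  results <- do.call(rbind, rows)
  res_path <- file.path(config$out_dir, "results.tsv")
  utils::write.table(results, res_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  # figure-ready per-day medians/IQR
  med <- stats::aggregate(
    normalized_enrichment ~ arm + phase + compartment + cell_type + study_day,
    data = enr, FUN = function(v)
      c(median = stats::median(v),
        q1 = unname(stats::quantile(v, 0.25)),
        q3 = unname(stats::quantile(v, 0.75)), n = length(v)))
  med <- cbind(med[, 1:5], as.data.frame(med$normalized_enrichment))
  write_num_csv(med, file.path(config$out_dir, "group_medians.csv"))

  # dilution ratios from placebo per-day medians (blood and sputum)
  dil <- list()
  for (cmp_name in c("blood", "sputum")) {
    mm <- med[med$arm == "placebo" & med$phase == 1 &
                med$compartment == cmp_name & med$cell_type == "eosinophil", ]
    dr <- try(dilution_ratio(mm$study_day, mm$median, ref_day = 7,
                             obj$constants$detection_threshold),
              silent = TRUE)
    if (!inherits(dr, "try-error"))
      dil[[cmp_name]] <- data.frame(compartment = cmp_name,
                                    day = dr$days, ratio = dr$ratios,
                                    stringsAsFactors = FALSE)
  }
  if (length(dil) > 0L)
    write_num_csv(do.call(rbind, dil),
                  file.path(config$out_dir, "dilution_ratios.csv"))
  invisible(res_path)
}

#' Write a human-readable run summary
#'
#' @param config A `run_config` whose `out_dir` holds the analysis outputs.
#' @return Invisibly, the report path (`report.md`).
#' @export
cmd_report <- function(config = default_config()) {
  res_path <- file.path(config$out_dir, "results.tsv")
  med_path <- file.path(config$out_dir, "group_medians.csv")
  if (!file.exists(res_path) || !file.exists(med_path))
    stop("missing analysis outputs in ", config$out_dir,
         " (run cmd_analyze first)")
  results <- utils::read.table(res_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  obj <- config_objects(config)
  lines <- c("# Pulse-chase labeling run summary", "")

  # model landmark: first/last detection days under the configured defaults
  for (ct in c("eosinophil", "basophil")) {
    cv <- simulate_blood_curve(obj$params[[ct]], obj$avail, obj$grid,
                               obj$constants)
    dd <- detection_days(cv, obj$constants$detection_threshold,
                         seq_len(floor(obj$grid$horizon)))
    lines <- c(lines, sprintf(
      "- Model %s blood label detectable from day %s to day %s.",
      ct, format(dd$first_day), format(dd$last_day)))
  }
  lines <- c(lines, "", "## Phase-wise regression comparisons", "")
  anc <- results[grepl("^ancova_slope", results$test), ]
  for (i in seq_len(nrow(anc)))
    lines <- c(lines, sprintf(
      "- %s phase %s %s window: F = %s, p = %s %s",
      anc$test[i], anc$phase[i], anc$window[i],
      format(anc$statistic[i], digits = 4),
      format(anc$p[i], digits = 3),
      ifelse(nzchar(anc$flag[i]), paste0("[", anc$flag[i], "]"), "")))
  dil_path <- file.path(config$out_dir, "dilution_ratios.csv")
  if (file.exists(dil_path)) {
    dil <- utils::read.csv(dil_path, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Dilution ratios (placebo, phase 1, vs day 7)", "")
    for (i in seq_len(nrow(dil)))
      lines <- c(lines, sprintf("- %s day %g: %.3f", dil$compartment[i],
                                dil$day[i], dil$ratio[i]))
  }
  out <- file.path(config$out_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
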