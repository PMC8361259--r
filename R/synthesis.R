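# Synthetic two-arm, two-phase labeling trial generator. Reproduces the
# study design (n = 10 per arm, label intake at absolute days 0 and 84,
# treatment doses at days 4/32/60/88, staggered blood and sputum sampling,
# plasma finger-pricks at 35/185/305 min) and a configurable treatment
# scenario, driving the conveyor-belt forward model per subject and emitting
# GC-MS peak-area readings that the enrichment pipeline can invert. A truth
# sidecar carries the simulated enrichment for round-trip and power testing;
# the analysis path never reads it.

# phase-local candidate post-label blood sampling days
BLOOD_DAY_POOL <- c(2, 4, 5, 6, 7, 8, 10, 12, 14, 18, 22, 27, 32, 42)

#' Default two-arm, two-phase trial design
#'
#' @param seed Integer seed controlling the per-subject staggering of
#'   sampling days.
#' @param n_per_arm Subjects per arm (default 10).
#' @return An object of class `trial_design`: label days (absolute 0 and
#'   84), dose days (absolute 4/32/60/88), per-subject phase-local blood
#'   sampling days (2 pre-label baselines at days -1 and 0 plus 8 post-label
#'   days drawn from the candidate set), 3 sputum days per subject, plasma
#'   times 35/185/305 min.
#' @export
default_design <- function(seed = 1L, n_per_arm = 10L) {
  stopifnot(n_per_arm >= 1L)
  rng <- make_rng(seed)
  arms <- c("placebo", "mepolizumab")
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(2L * n_per_arm)),
    arm = rep(arms, each = n_per_arm),
    stringsAsFactors = FALSE)
  blood_days <- lapply(seq_len(nrow(subjects)), function(i) {
    sort(sample_rng(rng, BLOOD_DAY_POOL, 8L))
  })
  # sputum either close to (days 4-6) or far from (day 14+) label intake
  sputum_days <- lapply(seq_len(nrow(subjects)), function(i) {
    near <- sample_rng(rng, c(4, 5, 6), 1L)
    far <- sample_rng(rng, c(14, 18, 22, 27, 32, 42), 2L)
    sort(c(near, far))
  })
  structure(list(
    n_per_arm = as.integer(n_per_arm),
    arms = arms,
    subjects = subjects,
    label_days = c(0, 84),
    dose_days = c(4, 32, 60, 88),
    baseline_days = c(-1, 0),
    blood_sampling_days = blood_days,
    sputum_sampling_days = sputum_days,
    plasma_times_min = c(35, 185, 305),
    seed = as.integer(seed)), class = "trial_design")
}

#' Treatment scenario: effect of anti-IL-5 on the kinetic parameters
#'
#' The paper-level findings give directions (counts collapse within days of
#' the first dose; phase-1 downlabeling slower; phase-2 kinetics restored);
#' the magnitudes here are package defaults chosen so that the trial-level
#' statistics detect the phase-1 effect at n = 10.
#'
#' @param production_floor Residual IL-5-independent marrow release
#'   (fraction of baseline, default 0.1).
#' @param production_decay_time Time constant of the release collapse after
#'   the first dose, days (default 1).
#' @param phase1_blood_halflife_multiplier Blood half-life multiplier while
#'   under first-phase treatment (default 1.8: slower downlabeling).
#' @param phase2_blood_halflife_multiplier Same for the second phase
#'   (default 1: kinetics restored).
#' @param airway_influx_multiplier Multiplier on the airway influx fraction
#'   under treatment (default 0.3).
#' @param count_noise_cv Lognormal CV of measured cell counts (default
#'   0.25).
#' @param ms_area_noise_cv Multiplicative Gaussian CV of GC-MS peak areas
#'   (default 0.02).
#' @return An object of class `treatment_scenario`.
#' @export
treatment_scenario <- function(production_floor = 0.1,
                               production_decay_time = 1.0,
                               phase1_blood_halflife_multiplier = 1.8,
                               phase2_blood_halflife_multiplier = 1.0,
                               airway_influx_multiplier = 0.3,
                               count_noise_cv = 0.25,
                               ms_area_noise_cv = 0.02) {
  stopifnot(production_floor > 0, production_decay_time > 0,
            phase1_blood_halflife_multiplier > 0,
            phase2_blood_halflife_multiplier > 0,
            airway_influx_multiplier > 0,
            count_noise_cv >= 0, ms_area_noise_cv >= 0)
  structure(list(production_floor = production_floor,
                 production_decay_time = production_decay_time,
                 phase1_blood_halflife_multiplier =
                   phase1_blood_halflife_multiplier,
                 phase2_blood_halflife_multiplier =
                   phase2_blood_halflife_multiplier,
                 airway_influx_multiplier = airway_influx_multiplier,
                 count_noise_cv = count_noise_cv,
                 ms_area_noise_cv = ms_area_noise_cv),
            class = "treatment_scenario")
}

#' Kinetic parameters under a treatment scenario
#'
#' Placebo subjects keep the base parameters. Treated subjects have their
#' marrow release scaled from 1 toward the production floor with the
#' scenario's decay time (t = days since the first dose), the blood
#' half-life multiplied by the phase-specific multiplier, and the airway
#' influx fraction attenuated.
#'
#' @param base A `kinetic_parameters`.
#' @param scenario A `treatment_scenario`.
#' @param arm "placebo" or "mepolizumab".
#' @param phase 1 or 2.
#' @param t Days since the first dose (>= 0 for treated subjects).
#' @return A `kinetic_parameters`.
#' @export
effective_params <- function(base, scenario, arm, phase, t = 0) {
  stopifnot(inherits(base, "kinetic_parameters"),
            inherits(scenario, "treatment_scenario"))
  if (arm == "placebo") return(base)
  if (t < 0) stop("t must be >= 0 (days since first dose) for treated subjects")
  p <- base
  fl <- scenario$production_floor
  p$production_scale <- base$production_scale *
    (fl + (1 - fl) * exp(-t / scenario$production_decay_time))
  mult <- if (phase == 1) scenario$phase1_blood_halflife_multiplier
          else scenario$phase2_blood_halflife_multiplier
  p$blood_half_life <- base$blood_half_life * mult
  p$airway_influx_fraction <- base$airway_influx_fraction *
    scenario$airway_influx_multiplier
  p
}

# release-rate trajectory over the phase-local grid for one arm/phase:
# suppression begins at the first dose and is sustained by repeated dosing
release_trajectory <- function(grid, scenario, arm, phase) {
  if (arm == "placebo") return(rep(1, length(grid$times)))
  fl <- scenario$production_floor
  if (phase == 1) {
    t_dose <- 4                          # first dose, phase-local day 4
    s <- ifelse(grid$times < t_dose, 1,
                fl + (1 - fl) * exp(-(grid$times - t_dose) /
                                      scenario$production_decay_time))
  } else {
    s <- rep(fl, length(grid$times))     # ongoing suppression in phase 2
  }
  s
}

#' Subject profile
#'
#' @param subject_id Identifier.
#' @param arm Treatment arm.
#' @param seed Per-subject RNG seed.
#' @param body_weight_kg Body weight (metadata; label dose is 1 g/kg).
#' @param baseline_eos_count Baseline blood eosinophil count, 1e6/mL
#'   (inclusion floor 0.25 enforced).
#' @param baseline_baso_count Baseline blood basophil count, 1e6/mL.
#' @param plasma_amplitude Subject's plasma label plateau p_bar.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, arm, seed,
                            body_weight_kg = 75,
                            baseline_eos_count = 0.45,
                            baseline_baso_count = 0.04,
                            plasma_amplitude = 0.05) {
  stopifnot(baseline_eos_count > 0, baseline_baso_count > 0,
            plasma_amplitude > 0, plasma_amplitude <= 1)
  if (baseline_eos_count < 0.25)
    stop("baseline eosinophil count below the 0.25e6/mL inclusion floor")
  structure(list(subject_id = subject_id, arm = arm,
                 seed = as.integer(seed),
                 body_weight_kg = body_weight_kg,
                 baseline_eos_count = baseline_eos_count,
                 baseline_baso_count = baseline_baso_count,
                 plasma_amplitude = plasma_amplitude),
            class = "subject_profile")
}

# draw a baseline count: lognormal around the arm median with ~0.4 log-sd
# (matching the reported interquartile spread), truncated at the inclusion
# floor for eosinophils
draw_baseline_count <- function(rng, median_count, floor = 0) {
  repeat {
    v <- median_count * exp(norm_rng(rng, 1) * 0.45)
    if (v >= floor) return(v)
  }
}

# natural-abundance TTR offsets used when synthesizing peak areas; the
# pipeline removes them via its baseline correction, so their values are
# arbitrary plumbing constants
DNA_BACKGROUND_TTR <- 0.002
GLUCOSE_BACKGROUND_TTR <- 0.003

#' Construct a GC-MS peak-area pair encoding a true enrichment
#'
#' Inverse of the enrichment pipeline under identity calibration: the
#' noise-free TTR is the natural-background TTR plus the (raw) enrichment;
#' areas are split so that area_m2/area_m0 equals that TTR at the requested
#' total area. Multiplicative Gaussian noise with `noise_cv` is applied per
#' area.
#'
#' @param true_enrichment Raw net DNA enrichment to encode (>= 0), i.e.
#'   normalized enrichment times b * p_bar for DNA channels, or the plasma
#'   glucose enrichment itself for glucose channels.
#' @param background_ttr Natural-abundance TTR of the channel.
#' @param total_area Total ion area (arbitrary units, default 1e6).
#' @param noise_cv Multiplicative noise CV per area (default 0).
#' @param rng Internal RNG state (from `make_rng`); required when
#'   `noise_cv > 0`.
#' @return List with `area_m0`, `area_m2`.
#' @export
emit_ms_areas <- function(true_enrichment, background_ttr = DNA_BACKGROUND_TTR,
                          total_area = 1e6, noise_cv = 0, rng = NULL) {
  if (!is.finite(true_enrichment) || true_enrichment < 0)
    stop("true enrichment must be a nonnegative finite fraction")
  ttr <- background_ttr + true_enrichment
  area_m0 <- total_area / (1 + ttr)
  area_m2 <- area_m0 * ttr
  if (noise_cv > 0) {
    if (is.null(rng)) stop("noisy emission requires an rng state")
    area_m0 <- area_m0 * (1 + norm_rng(rng, 1) * noise_cv)
    area_m2 <- area_m2 * (1 + norm_rng(rng, 1) * noise_cv)
    area_m0 <- max(area_m0, total_area * 1e-6)
    area_m2 <- max(area_m2, 0)
  }
  list(area_m0 = area_m0, area_m2 = area_m2)
}

# look up curve value at a phase-local day (exact grid match)
curve_at <- function(curve, day) {
  i <- which(abs(curve$t_days - day) < 1e-9)
  if (length(i) == 0L) stop("day not on simulation grid: ", day)
  curve[i[1], ]
}

#' Generate one subject's truth curves and noisy measurements
#'
#' Runs the forward model for both cell types and both phases with the
#' subject's effective (arm- and phase-dependent) parameters, then samples
#' the design's schedule: DNA readings for blood eosinophils/basophils and
#' sputum eosinophils, plasma glucose readings, and cell counts (lognormal
#' noise). Reproducible from `profile$seed`.
#'
#' @param profile A `subject_profile`.
#' @param design A `trial_design` (supplies this subject's sampling days via
#'   its index in `design$subjects`).
#' @param base_params Named list with `eosinophil` and `basophil`
#'   `kinetic_parameters`.
#' @param scenario A `treatment_scenario`.
#' @param grid A `simulation_grid`.
#' @param constants A `correction_constants`.
#' @param curve_cache Optional environment used to share truth curves
#'   between subjects with identical arm/phase/cell type (pure speed-up).
#' @return List with `readings` (MassSpecReading rows), `counts`, `truth`
#'   (sidecar rows of true normalized enrichment).
#' @export
generate_subject <- function(profile, design, base_params, scenario,
                             grid = simulation_grid(),
                             constants = correction_constants(),
                             curve_cache = NULL) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(design, "trial_design"))
  rng <- make_rng(profile$seed)
  i_subj <- match(profile$subject_id, design$subjects$subject_id)
  if (is.na(i_subj)) stop("subject not in design: ", profile$subject_id)
  blood_days <- design$blood_sampling_days[[i_subj]]
  sputum_days <- design$sputum_sampling_days[[i_subj]]

  get_curves <- function(cell_type, phase) {
    key <- paste(profile$arm, phase, cell_type, sep = "|")
    if (!is.null(curve_cache) && exists(key, envir = curve_cache))
      return(get(key, envir = curve_cache))
    base <- base_params[[cell_type]]
    prod <- NULL
    if (cell_type != "eosinophil") {
      # anti-IL-5 leaves basophil numbers and kinetics unchanged: both arms
      # use the base parameters
      eff <- base
    } else {
      eff <- effective_params(base, scenario, profile$arm, phase,
                              t = if (phase == 1) 0 else 80)
      if (profile$arm == "mepolizumab" && phase == 1) {
        # suppression unfolds during phase 1: full-production history,
        # marrow release collapsing from the first dose onward
        eff$production_scale <- base$production_scale
        prod <- release_trajectory(grid, scenario, profile$arm, phase)
      }
      # in phase 2, after ~80 days of dosing, history and current release
      # both sit at the suppressed floor (effective_params applied it), so
      # the pool is at its suppressed steady state and no gating is needed
    }
    blood <- simulate_blood_curve(eff, label_availability(), grid,
                                  constants, release = prod)
    airway <- simulate_airway_curve(eff, blood, grid)
    val <- list(blood = blood, airway = airway)
    if (!is.null(curve_cache)) assign(key, val, envir = curve_cache)
    val
  }

  b <- constants$de_novo_fraction_b
  p_bar <- profile$plasma_amplitude
  sid <- profile$subject_id
  curve_vals <- function(curve, days, col) {
    i <- match(round(days / grid$dt), round(curve$t_days / grid$dt))
    if (anyNA(i)) stop("sampling day not on simulation grid")
    curve[[col]][i]
  }
  readings <- list(); counts <- list(); truth <- list()
  for (phase in 1:2) {
    curves_eos <- get_curves("eosinophil", phase)
    curves_baso <- get_curves("basophil", phase)
    eos_bl <- curve_vals(curves_eos$blood, blood_days, "enrichment")
    baso_bl <- curve_vals(curves_baso$blood, blood_days, "enrichment")
    eos_sp <- curve_vals(curves_eos$airway, sputum_days, "enrichment")
    nb <- length(blood_days); ns <- length(sputum_days)
    nbl <- length(design$baseline_days)
    ids <- c(
      sprintf("%s-P%d-PLA-base", sid, phase),
      sprintf("%s-P%d-PLA-%d", sid, phase, design$plasma_times_min),
      sprintf("%s-P%d-B-eos-d%g", sid, phase,
              c(design$baseline_days, blood_days)),
      sprintf("%s-P%d-B-bas-d%g", sid, phase,
              c(design$baseline_days, blood_days)),
      sprintf("%s-P%d-S-eos-base", sid, phase),
      sprintf("%s-P%d-S-eos-d%g", sid, phase, sputum_days))
    days <- c(0, design$plasma_times_min / 1440,
              design$baseline_days, blood_days,
              design$baseline_days, blood_days,
              0, sputum_days)
    npl <- 1L + length(design$plasma_times_min)
    compartment <- c(rep("plasma", npl), rep("blood", 2 * (nbl + nb)),
                     rep("sputum", 1L + ns))
    cell_type <- c(rep("none", npl), rep("eosinophil", nbl + nb),
                   rep("basophil", nbl + nb), rep("eosinophil", 1L + ns))
    channel <- c(rep("glucose_328_330", npl),
                 rep("dna_adenosine_435_437", 2 * (nbl + nb) + 1L + ns))
    true_raw <- c(0, rep(p_bar, npl - 1L),
                  numeric(nbl), eos_bl * b * p_bar,
                  numeric(nbl), baso_bl * b * p_bar,
                  0, eos_sp * b * p_bar)
    bk_ttr <- ifelse(channel == "glucose_328_330",
                     GLUCOSE_BACKGROUND_TTR, DNA_BACKGROUND_TTR)
    ttr <- bk_ttr + true_raw
    area_m0 <- 1e6 / (1 + ttr)
    area_m2 <- area_m0 * ttr
    if (scenario$ms_area_noise_cv > 0) {
      nn <- length(area_m0)
      eps <- norm_rng(rng, 2L * nn) * scenario$ms_area_noise_cv
      area_m0 <- pmax(area_m0 * (1 + eps[seq_len(nn)]), 1)
      area_m2 <- pmax(area_m2 * (1 + eps[nn + seq_len(nn)]), 0)
    }
    readings[[phase]] <- data.frame(
      sample_id = ids, subject_id = sid, phase = phase, study_day = days,
      compartment = compartment, cell_type = cell_type,
      channel_set = channel, area_m0 = area_m0, area_m2 = area_m2,
      stringsAsFactors = FALSE)
    truth[[phase]] <- data.frame(
      subject_id = sid, arm = profile$arm, phase = phase,
      study_day = c(blood_days, blood_days, sputum_days),
      compartment = rep(c("blood", "sputum"), c(2 * nb, ns)),
      cell_type = rep(c("eosinophil", "basophil", "eosinophil"),
                      c(nb, nb, ns)),
      true_normalized_enrichment = c(eos_bl, baso_bl, eos_sp),
      true_count_relative = c(
        curve_vals(curves_eos$blood, blood_days, "count_relative"),
        curve_vals(curves_baso$blood, blood_days, "count_relative"),
        curve_vals(curves_eos$airway, sputum_days, "count_relative")),
      stringsAsFactors = FALSE)
    cdays <- c(0, blood_days)
    rel <- c(curve_vals(curves_eos$blood, cdays, "count_relative"),
             curve_vals(curves_baso$blood, cdays, "count_relative"))
    base_count <- rep(c(profile$baseline_eos_count,
                        profile$baseline_baso_count), each = length(cdays))
    noise <- if (scenario$count_noise_cv > 0) {
      s2 <- log(1 + scenario$count_noise_cv^2)
      exp(norm_rng(rng, length(rel)) * sqrt(s2) - s2 / 2)
    } else 1
    counts[[phase]] <- data.frame(
      subject_id = sid, arm = profile$arm, phase = phase,
      study_day = rep(cdays, 2L),
      cell_type = rep(c("eosinophil", "basophil"), each = length(cdays)),
      count = base_count * rel * noise, stringsAsFactors = FALSE)
  }
  list(readings = do.call(rbind, readings),
       counts = do.call(rbind, counts),
       truth = do.call(rbind, truth))
}

#' Generate a complete synthetic trial
#'
#' @param design A `trial_design`.
#' @param base_params Named list of `kinetic_parameters` for `eosinophil`
#'   and `basophil` (defaults from [default_kinetic_parameters()]).
#' @param scenario A `treatment_scenario`.
#' @param master_seed Integer master seed; subject seeds and profiles derive
#'   deterministically from it.
#' @param grid,constants Forward-model settings.
#' @return List of class `measurement_table` with data frames `readings`,
#'   `counts`, `truth` (sidecar; never consumed by the analysis path) and
#'   `profiles`.
#' @export
generate_trial <- function(design = default_design(),
                           base_params = list(
                             eosinophil = default_kinetic_parameters("eosinophil"),
                             basophil = default_kinetic_parameters("basophil")),
                           scenario = treatment_scenario(),
                           master_seed = 1L,
                           grid = simulation_grid(),
                           constants = correction_constants()) {
  rng <- make_rng(master_seed)
  cache <- new.env(parent = emptyenv())
  out_r <- list(); out_c <- list(); out_t <- list(); profs <- list()
  med_eos <- c(placebo = 0.49, mepolizumab = 0.40)
  med_baso <- c(placebo = 0.035, mepolizumab = 0.046)
  for (i in seq_len(nrow(design$subjects))) {
    sid <- design$subjects$subject_id[i]
    arm <- design$subjects$arm[i]
    prof <- subject_profile(
      subject_id = sid, arm = arm,
      seed = int_rng(rng),
      body_weight_kg = 60 + 40 * unif_rng(rng, 1),
      baseline_eos_count = draw_baseline_count(rng, med_eos[[arm]],
                                               floor = 0.25),
      baseline_baso_count = draw_baseline_count(rng, med_baso[[arm]]),
      plasma_amplitude = 0.05 * exp(norm_rng(rng, 1) * 0.1))
    res <- generate_subject(prof, design, base_params, scenario, grid,
                            constants, curve_cache = cache)
    out_r[[i]] <- res$readings; out_c[[i]] <- res$counts
    out_t[[i]] <- res$truth
    profs[[i]] <- data.frame(subject_id = sid, arm = arm, seed = prof$seed,
                             body_weight_kg = prof$body_weight_kg,
                             baseline_eos_count = prof$baseline_eos_count,
                             baseline_baso_count = prof$baseline_baso_count,
                             plasma_amplitude = prof$plasma_amplitude,
                             stringsAsFactors = FALSE)
  }
  structure(list(readings = do.call(rbind, out_r),
                 counts = do.call(rbind, out_c),
                 truth = do.call(rbind, out_t),
                 profiles = do.call(rbind, profs),
                 design = design, master_seed = master_seed),
            class = "measurement_table")
}
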