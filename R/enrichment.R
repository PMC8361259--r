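# Conversion of raw GC-MS isotopomer peak areas into calibrated,
# background-corrected and precursor-normalized DNA deuterium enrichment.
#
# The measured quantity is the tracer-to-tracee ratio TTR = (m+2)/m of the
# derivatized analyte (DNA deoxyadenosine at m/z 435/437, plasma glucose at
# m/z 328/330). A calibration line against standards of known enrichment maps
# TTR to enrichment; the pre-label baseline sample of the same subject and
# phase supplies the natural-abundance background; division by b * p_bar
# (de novo synthesis fraction times mean plasma precursor enrichment) turns
# net enrichment into the fraction of cells whose DNA was synthesized during
# the labeling window.

#' Correction constants for the enrichment pipeline
#'
#' @param de_novo_fraction_b Fraction of DNA adenosine synthesized de novo
#'   (as opposed to obtained by base salvage); scales the precursor
#'   enrichment available to DNA. Default 0.65.
#' @param detection_threshold Minimum normalized enrichment considered
#'   distinguishable from background. Default 5e-4 (0.05%).
#' @return An object of class `correction_constants`.
#' @export
correction_constants <- function(de_novo_fraction_b = 0.65,
                                 detection_threshold = 5e-4) {
  stopifnot(is.numeric(de_novo_fraction_b), length(de_novo_fraction_b) == 1L,
            is.finite(de_novo_fraction_b),
            de_novo_fraction_b > 0, de_novo_fraction_b <= 1,
            is.numeric(detection_threshold), length(detection_threshold) == 1L,
            is.finite(detection_threshold), detection_threshold >= 0)
  structure(list(de_novo_fraction_b = de_novo_fraction_b,
                 detection_threshold = detection_threshold),
            class = "correction_constants")
}

#' Tracer-to-tracee ratio of one isotopomer peak-area pair
#'
#' TTR = (m+2)/m, the ratio of the labeled (M+2) to the unlabeled (M+0) ion
#' peak area.
#'
#' @param area_m0 Peak area of the unlabeled ion (must be > 0).
#' @param area_m2 Peak area of the labeled ion (>= 0).
#' @return Nonnegative numeric TTR, vectorized over its arguments.
#' @export
compute_ttr <- function(area_m0, area_m2) {
  if (length(area_m0) != length(area_m2))
    stop("area_m0 and area_m2 must have the same length")
  if (any(!is.finite(area_m0)) || any(!is.finite(area_m2)))
    stop("unusable reading: missing or non-finite peak area")
  if (any(area_m0 <= 0))
    stop("unusable reading: zero unlabeled peak")
  if (any(area_m2 < 0))
    stop("unusable reading: negative labeled peak area")
  area_m2 / area_m0
}

#' Fit a calibration line from enrichment standards
#'
#' Ordinary least squares of measured TTR on known enrichment, computed from
#' closed-form sums of squares.
#'
#' @param known_enrichment Numeric vector of true enrichment fractions of the
#'   standards.
#' @param measured_ttr Numeric vector of measured TTR values, same length.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `n_standards`, `residual_sd`.
#' @export
fit_calibration <- function(known_enrichment, measured_ttr) {
  x <- as.numeric(known_enrichment)
  y <- as.numeric(measured_ttr)
  if (length(x) != length(y)) stop("standards must pair enrichment with TTR")
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("degenerate calibration design: need >= 2 distinct known enrichments")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite calibration standard")
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  residual_sd <- if (n > 2L) sqrt(sum(resid^2) / (n - 2L)) else 0
  if (slope <= 0)
    stop("invalid calibration: fitted slope is not positive")
  structure(list(slope = slope, intercept = intercept,
                 n_standards = n, residual_sd = residual_sd),
            class = "calibration_curve")
}

#' Identity calibration curve
#'
#' Convenience constructor for a curve with unit slope, used when the
#' instrument response is taken at face value (e.g. on synthetic data).
#'
#' @param intercept Natural-abundance TTR offset (default 0).
#' @return A `calibration_curve`.
#' @export
identity_calibration <- function(intercept = 0) {
  structure(list(slope = 1, intercept = intercept,
                 n_standards = 2L, residual_sd = 0),
            class = "calibration_curve")
}

#' Invert a calibration curve
#'
#' Maps a measured TTR back to an enrichment fraction. Values slightly below
#' the intercept yield small negative enrichments, which are preserved (never
#' clipped) so that downstream background subtraction stays unbiased.
#'
#' @param ttr Measured TTR (vectorized).
#' @param curve A `calibration_curve`.
#' @return Enrichment fraction(s).
#' @export
ttr_to_enrichment <- function(ttr, curve) {
  if (!inherits(curve, "calibration_curve"))
    stop("curve must be a calibration_curve")
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("invalid calibration curve: slope must be > 0")
  (ttr - curve$intercept) / curve$slope
}

#' Subtract the natural-abundance background enrichment
#'
#' The baseline is the same subject's pre-label sample of the same phase.
#' Negative net enrichments are preserved and flagged downstream.
#'
#' @param enrichment Calibrated enrichment fraction(s).
#' @param baseline_enrichment Baseline enrichment of the matching pre-label
#'   sample.
#' @return Net enrichment (may be negative).
#' @export
subtract_background <- function(enrichment, baseline_enrichment) {
  if (any(!is.finite(enrichment)) || any(!is.finite(baseline_enrichment)))
    stop("non-finite enrichment in background subtraction")
  enrichment - baseline_enrichment
}

#' Summarize a subject's plasma precursor exposure
#'
#' The mean plasma glucose deuterium enrichment over the finger-prick samples
#' taken during label intake (default schedule: 35, 185 and 305 minutes after
#' the first dose) measures the label available to dividing cells.
#'
#' @param enrichments Plasma glucose enrichment fractions.
#' @param sample_times_min Minutes after first dose (metadata only).
#' @return An object of class `precursor_exposure` with `mean_enrichment`.
#' @export
summarize_precursor <- function(enrichments,
                                sample_times_min = c(35, 185, 305)) {
  e <- as.numeric(enrichments)
  if (length(e) == 0L)
    stop("missing precursor: no plasma enrichment values")
  if (any(!is.finite(e)))
    stop("non-finite plasma enrichment value")
  structure(list(enrichments = e,
                 sample_times_min = sample_times_min,
                 mean_enrichment = mean(e)),
            class = "precursor_exposure")
}

#' Precursor-product normalization of net DNA enrichment
#'
#' Divides net enrichment by b * p_bar, where b is the de novo synthesis
#' fraction and p_bar the subject's mean plasma precursor enrichment for the
#' phase. The result estimates the fraction of cells whose DNA was
#' synthesized during the labeling window.
#'
#' @param net Net (background-subtracted) DNA enrichment.
#' @param exposure A `precursor_exposure`, or a single numeric p_bar.
#' @param constants A `correction_constants` object.
#' @return Normalized enrichment fraction(s).
#' @export
normalize_enrichment <- function(net, exposure,
                                 constants = correction_constants()) {
  p_bar <- if (inherits(exposure, "precursor_exposure"))
    exposure$mean_enrichment else as.numeric(exposure)
  if (length(p_bar) != 1L || !is.finite(p_bar))
    stop("precursor exposure must be a single finite value")
  if (p_bar <= 0)
    stop("cannot normalize: mean precursor enrichment is not positive")
  b <- constants$de_novo_fraction_b
  net / (b * p_bar)
}

# Baseline rows are pre-label samples: phase-local study_day <= 0.
is_baseline_row <- function(study_day) study_day <= 0

#' Full enrichment pipeline: raw readings to enrichment points
#'
#' For every DNA reading (channel set `dna_adenosine_435_437`): compute
#' TTR, calibrate, subtract the subject/phase/cell-type baseline (the mean
#' over that subject's pre-label samples, study_day <= 0), and normalize by
#' b times the subject/phase mean plasma glucose
#' enrichment. Rows that cannot be processed are collected and reported, not
#' fatal.
#'
#' @param readings Data frame with columns `sample_id`, `subject_id`,
#'   `phase`, `study_day`, `compartment`, `cell_type`, `channel_set`,
#'   `area_m0`, `area_m2`.
#' @param calibration A `calibration_curve` (applied to both channel sets),
#'   or a named list with elements `dna` and `glucose`.
#' @param constants A `correction_constants` object.
#' @return A data frame of class `enrichment_points` with one row per
#'   post-baseline DNA reading: `subject_id`, `phase`, `study_day`,
#'   `compartment`, `cell_type`, `raw_enrichment`, `net_enrichment`,
#'   `normalized_enrichment`, `below_detection`; failed rows are attached as
#'   attribute `errors` (data frame `sample_id`, `reason`).
#' @export
enrichment_pipeline <- function(readings,
                                calibration = identity_calibration(),
                                constants = correction_constants()) {
  required <- c("sample_id", "subject_id", "phase", "study_day",
                "compartment", "cell_type", "channel_set",
                "area_m0", "area_m2")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0L)
    stop("readings table missing columns: ",
         paste(missing_cols, collapse = ", "))
  cal_dna <- if (inherits(calibration, "calibration_curve")) calibration
             else calibration$dna
  cal_glu <- if (inherits(calibration, "calibration_curve")) calibration
             else calibration$glucose
  readings$study_day <- as.numeric(readings$study_day)
  readings$area_m0 <- as.numeric(readings$area_m0)
  readings$area_m2 <- as.numeric(readings$area_m2)

  errors <- list()
  note_error <- function(sample_id, reason) {
    errors[[length(errors) + 1L]] <<- data.frame(
      sample_id = as.character(sample_id), reason = reason,
      stringsAsFactors = FALSE)
  }

  ok_area <- is.finite(readings$area_m0) & readings$area_m0 > 0 &
    is.finite(readings$area_m2) & readings$area_m2 >= 0
  for (i in which(!ok_area))
    note_error(readings$sample_id[i],
               "unusable reading: invalid peak area (m0 must be > 0, m2 >= 0)")
  rd <- readings[ok_area, , drop = FALSE]
  rd$ttr <- rd$area_m2 / rd$area_m0

  is_glu <- rd$channel_set == "glucose_328_330"
  is_dna <- rd$channel_set == "dna_adenosine_435_437"
  for (i in which(!is_glu & !is_dna))
    note_error(rd$sample_id[i], "unknown channel_set")

  rd$enrichment <- NA_real_
  rd$enrichment[is_dna] <- ttr_to_enrichment(rd$ttr[is_dna], cal_dna)
  rd$enrichment[is_glu] <- ttr_to_enrichment(rd$ttr[is_glu], cal_glu)

  key_sp <- paste(rd$subject_id, rd$phase, sep = "\r")

  # plasma precursor means per subject/phase (baseline-corrected against the
  # subject's pre-label plasma sample when present)
  glu <- rd[is_glu, , drop = FALSE]
  glu_key <- key_sp[is_glu]
  glu_base <- is_baseline_row(glu$study_day)
  base_mean <- tapply(glu$enrichment[glu_base], glu_key[glu_base], mean)
  post_mean <- tapply(glu$enrichment[!glu_base], glu_key[!glu_base], mean)
  all_mean <- tapply(glu$enrichment, glu_key, mean)
  p_bar_keys <- names(all_mean)
  p_bar <- vapply(p_bar_keys, function(k) {
    pm <- post_mean[k]
    if (is.na(pm)) pm <- all_mean[k]      # only baseline samples present
    bm <- base_mean[k]
    unname(pm - (if (is.na(bm)) 0 else bm))
  }, numeric(1))

  # DNA baselines per subject/phase/cell_type (pre-label rows, study_day <= 0)
  dna <- rd[is_dna, , drop = FALSE]
  dna_key <- paste(dna$subject_id, dna$phase, dna$cell_type, sep = "\r")
  dna_base <- is_baseline_row(dna$study_day)
  baselines <- tapply(dna$enrichment[dna_base], dna_key[dna_base], mean)

  post <- dna[!dna_base, , drop = FALSE]
  post_bkey <- dna_key[!dna_base]
  post_pkey <- paste(post$subject_id, post$phase, sep = "\r")
  bl_val <- unname(baselines[post_bkey])
  pb_val <- unname(p_bar[match(post_pkey, p_bar_keys)])

  no_base <- is.na(bl_val)
  no_plasma <- is.na(pb_val)
  bad_plasma <- !no_plasma & pb_val <= 0
  for (i in which(no_base))
    note_error(post$sample_id[i],
               sprintf("missing pre-label baseline for subject %s phase %s cell type %s",
                       post$subject_id[i], post$phase[i], post$cell_type[i]))
  for (i in which(no_plasma & !no_base))
    note_error(post$sample_id[i],
               sprintf("missing plasma precursor samples for subject %s phase %s",
                       post$subject_id[i], post$phase[i]))
  for (i in which(bad_plasma & !no_base))
    note_error(post$sample_id[i],
               sprintf("non-positive mean precursor enrichment for subject %s phase %s",
                       post$subject_id[i], post$phase[i]))
  keep <- !no_base & !no_plasma & !bad_plasma
  post <- post[keep, , drop = FALSE]
  net <- subtract_background(post$enrichment, bl_val[keep])
  norm <- net / (constants$de_novo_fraction_b * pb_val[keep])
  result <- data.frame(
    subject_id = post$subject_id, phase = post$phase,
    study_day = post$study_day, compartment = post$compartment,
    cell_type = post$cell_type,
    raw_enrichment = post$enrichment, net_enrichment = net,
    normalized_enrichment = norm,
    below_detection = norm < constants$detection_threshold,
    stringsAsFactors = FALSE)
  rownames(result) <- NULL
  err_df <- if (length(errors) > 0L) do.call(rbind, errors) else
    data.frame(sample_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  attr(result, "errors") <- err_df
  class(result) <- c("enrichment_points", class(result))
  result
}

#' Read a raw GC-MS readings table from CSV
#'
#' @param path Path to a CSV file with the reading schema (see
#'   [enrichment_pipeline()]).
#' @return A data frame.
#' @export
read_readings_csv <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write enrichment points to CSV
#'
#' Floats are written with full precision (15 significant digits).
#'
#' @param points An `enrichment_points` data frame.
#' @param path Output path.
#' @export
write_enrichment_csv <- function(points, path) {
  df <- as.data.frame(points)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
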