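# Raw peak areas -> calibrated, corrected, normalized enrichment.

test_that("TTR is the labeled-to-unlabeled area ratio with guarded inputs", {
  expect_equal(compute_ttr(1000, 0), 0)
  expect_equal(compute_ttr(1000, 20), 0.02)
  expect_error(compute_ttr(0, 5), "zero unlabeled peak")
  expect_error(compute_ttr(NA_real_, 5), "unusable")
  # homogeneity of degree zero: scaling both areas leaves TTR unchanged
  for (c_scale in c(1e-3, 1, 7.5, 1e6)) {
    expect_equal(compute_ttr(123 * c_scale, 4.56 * c_scale),
                 compute_ttr(123, 4.56))
  }
})

test_that("calibration is exact OLS and rejects degenerate designs", {
  f <- fit_calibration(c(0, 0.10), c(0, 0.10))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  f2 <- fit_calibration(c(0, 0.05, 0.10), c(0.002, 0.052, 0.102))
  expect_equal(f2$slope, 1, tolerance = 1e-12)
  expect_equal(f2$intercept, 0.002, tolerance = 1e-12)
  expect_equal(f2$residual_sd, 0, tolerance = 1e-12)

  # agrees with lm() on noisy standards
  set.seed(11)
  x <- seq(0, 0.1, length.out = 8)
  y <- 0.003 + 0.97 * x + rnorm(8, sd = 1e-4)
  f3 <- fit_calibration(x, y)
  ref <- lm(y ~ x)
  expect_equal(f3$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(f3$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(f3$residual_sd, summary(ref)$sigma, tolerance = 1e-10)

  expect_error(fit_calibration(0.05, 0.05), "degenerate")
  expect_error(fit_calibration(c(0.05, 0.05), c(0.04, 0.06)), "degenerate")
})

test_that("calibration inversion preserves negatives and checks the curve", {
  curve <- fit_calibration(c(0, 0.05, 0.10), c(0.002, 0.052, 0.102))
  expect_equal(ttr_to_enrichment(0.052, curve), 0.05, tolerance = 1e-12)
  expect_equal(ttr_to_enrichment(curve$intercept, curve), 0)
  expect_equal(ttr_to_enrichment(0, identity_calibration(0.002)), -0.002)
  bad <- identity_calibration()
  bad$slope <- -1
  expect_error(ttr_to_enrichment(0.05, bad), "slope")
})

test_that("background subtraction and precursor summaries behave", {
  expect_equal(subtract_background(0.020, 0.005), 0.015)
  expect_equal(subtract_background(0.005, 0.005), 0)
  expect_equal(subtract_background(0.004, 0.005), -0.001)

  pe <- summarize_precursor(c(0.04, 0.05, 0.06))
  expect_equal(pe$mean_enrichment, 0.05)
  expect_equal(summarize_precursor(0.05)$mean_enrichment, 0.05)
  expect_error(summarize_precursor(numeric(0)), "missing precursor")
})

test_that("precursor-product normalization divides by b times p_bar", {
  expect_equal(normalize_enrichment(0.013, 0.04), 0.5)
  expect_equal(normalize_enrichment(0, 0.03), 0)
  expect_error(normalize_enrichment(0.01, 0), "not positive")
  # b enters as a pure divisor
  cst <- correction_constants(de_novo_fraction_b = 0.5)
  expect_equal(normalize_enrichment(0.01, 0.05, cst), 0.01 / (0.5 * 0.05))
})

make_readings <- function(net_by_day, p_bar = 0.04, subject = "S01",
                          phase = 1) {
  days <- as.numeric(names(net_by_day))
  base <- data.frame(
    sample_id = c("bl", "pl0", "pl1", "pl2", "pl3"),
    subject_id = subject, phase = phase,
    study_day = c(0, 0, 0.02, 0.13, 0.21),
    compartment = c("blood", rep("plasma", 4)),
    cell_type = c("eosinophil", rep("none", 4)),
    channel_set = c("dna_adenosine_435_437", rep("glucose_328_330", 4)),
    area_m0 = 1e6,
    area_m2 = 1e6 * c(0.002, 0.003, 0.003 + p_bar, 0.003 + p_bar,
                      0.003 + p_bar),
    stringsAsFactors = FALSE)
  post <- data.frame(
    sample_id = paste0("d", days), subject_id = subject, phase = phase,
    study_day = days, compartment = "blood", cell_type = "eosinophil",
    channel_set = "dna_adenosine_435_437",
    area_m0 = 1e6, area_m2 = 1e6 * (0.002 + unname(net_by_day)),
    stringsAsFactors = FALSE)
  rbind(base, post)
}

test_that("pipeline composes calibration, background and normalization", {
  rd <- make_readings(c("5" = 0.013, "8" = 0.0065))
  pts <- enrichment_pipeline(rd)
  expect_equal(nrow(pts), 2L)
  expect_equal(pts$net_enrichment, c(0.013, 0.0065), tolerance = 1e-12)
  expect_equal(pts$normalized_enrichment, c(0.5, 0.25), tolerance = 1e-12)
  expect_false(any(pts$below_detection))
  expect_equal(nrow(attr(pts, "errors")), 0L)
})

test_that("pipeline is linear in area_m2 at fixed area_m0", {
  nets <- c(0.001, 0.002, 0.004, 0.008)
  rd <- make_readings(stats::setNames(nets, 5:8))
  pts <- enrichment_pipeline(rd)
  # normalized enrichment doubles as the m2 increment doubles
  expect_equal(pts$normalized_enrichment / pts$normalized_enrichment[1],
               nets / nets[1], tolerance = 1e-9)
})

test_that("a table of pure-baseline DNA readings yields zero net enrichment", {
  rd <- make_readings(c("5" = 0, "12" = 0))
  pts <- enrichment_pipeline(rd)
  expect_equal(pts$net_enrichment, c(0, 0))
  expect_true(all(pts$below_detection))
})

test_that("full-turnover window at full availability gives enrichment ~ 1", {
  # every strand newly synthesized during the window: net = b * p_bar
  p_bar <- 0.05
  rd <- make_readings(c("5" = 0.65 * 0.05), p_bar = p_bar)
  rd$area_m2[rd$sample_id %in% c("pl1", "pl2", "pl3")] <-
    1e6 * (0.003 + p_bar)
  pts <- enrichment_pipeline(rd)
  expect_equal(pts$normalized_enrichment, 1, tolerance = 1e-9)
})

test_that("per-row failures are collected without aborting the pipeline", {
  rd <- make_readings(c("5" = 0.013))
  rd2 <- make_readings(c("5" = 0.013), subject = "S02")
  rd2 <- rd2[rd2$channel_set != "glucose_328_330", ]  # no plasma for S02
  bad <- make_readings(c("5" = 0.01), subject = "S03")
  bad$area_m0[bad$sample_id == "d5"] <- 0             # unusable area
  pts <- enrichment_pipeline(rbind(rd, rd2, bad))
  errs <- attr(pts, "errors")
  expect_true(any(grepl("missing plasma precursor samples for subject S02",
                        errs$reason)))
  expect_true(any(grepl("invalid peak area", errs$reason)))
  # the good subject is still processed
  expect_true("S01" %in% pts$subject_id)
  expect_false("S02" %in% pts$subject_id)
})

test_that("missing baseline is a named configuration error", {
  rd <- make_readings(c("5" = 0.013))
  rd <- rd[rd$sample_id != "bl", ]
  pts <- enrichment_pipeline(rd)
  errs <- attr(pts, "errors")
  expect_true(any(grepl("missing pre-label baseline for subject S01",
                        errs$reason)))
  expect_equal(nrow(pts), 0L)
})

test_that("enrichment CSV round-trips with full precision", {
  rd <- make_readings(c("5" = 0.0131234567))
  pts <- enrichment_pipeline(rd)
  path <- tempfile(fileext = ".csv")
  write_enrichment_csv(pts, path)
  back <- read.csv(path)
  expect_equal(back$normalized_enrichment, pts$normalized_enrichment,
               tolerance = 1e-12)
})
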