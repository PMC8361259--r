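# Conveyor-belt forward model: label availability, blood and airway curves,
# detection landmarks, closed-form oracle, parameter recovery.

test_that("label availability integrates to amplitude * window_length", {
  grid <- simulation_grid(dt = 0.1, horizon = 60)
  av <- label_availability(amplitude = 0.05, window_length = 0.42)
  u <- label_availability_curve(av, grid)
  expect_equal(sum(u) * grid$dt, 0.05 * 0.42, tolerance = 1e-12)
  expect_equal(u[grid$times == 0.2], 0.05)   # cell fully inside the window
  expect_equal(u[grid$times == 1.0], 0)
  expect_true(all(label_availability_curve(
    label_availability(amplitude = 0), grid) == 0))
  # invariant under refinement
  g2 <- simulation_grid(dt = 0.05, horizon = 60)
  expect_equal(sum(label_availability_curve(av, g2)) * g2$dt, 0.05 * 0.42,
               tolerance = 1e-12)
})

test_that("no label in means no label out", {
  cv <- simulate_blood_curve(default_kinetic_parameters("eosinophil"),
                             label_availability(amplitude = 0))
  expect_true(all(cv$enrichment == 0))
  aw <- simulate_airway_curve(default_kinetic_parameters("eosinophil"), cv)
  expect_true(all(aw$enrichment == 0))
})

test_that("mass is conserved in both compartments", {
  params <- default_kinetic_parameters("eosinophil")
  cv <- simulate_blood_curve(params)
  audit <- attr(cv, "mass_audit")
  total <- audit[["initial_transit"]] + audit[["initial_blood"]] +
    audit[["produced"]]
  expect_lt(abs(audit[["imbalance"]]) / total, 1e-6)
  aw <- simulate_airway_curve(params, cv)
  audit_a <- attr(aw, "mass_audit")
  total_a <- audit_a[["initial_pool"]] + audit_a[["influx"]]
  expect_lt(abs(audit_a[["imbalance"]]) / total_a, 1e-6)
  # and with time-varying production
  grid <- simulation_grid()
  prod <- ifelse(grid$times < 4, 1, 0.1 + 0.9 * exp(-(grid$times - 4)))
  cv2 <- simulate_blood_curve(params, grid = grid, release = prod)
  expect_lt(abs(attr(cv2, "mass_audit")[["imbalance"]]), 1e-9)
})

test_that("enrichment respects its bounds in both compartments", {
  av <- label_availability(amplitude = 0.05)
  b <- correction_constants()$de_novo_fraction_b
  for (ct in c("eosinophil", "basophil")) {
    params <- default_kinetic_parameters(ct)
    cv <- simulate_blood_curve(params, av)
    expect_true(all(cv$raw_enrichment >= 0))
    expect_true(all(cv$raw_enrichment <= b * av$amplitude + 1e-12))
    expect_true(all(cv$enrichment >= 0 & cv$enrichment <= 1))
    aw <- simulate_airway_curve(params, cv)
    expect_true(all(aw$raw_enrichment >= 0 &
                      aw$raw_enrichment <= b * av$amplitude + 1e-12))
  }
})

test_that("increasing the transit shift translates the blood curve exactly", {
  grid <- simulation_grid(dt = 0.1, horizon = 60)
  p1 <- default_kinetic_parameters("eosinophil")
  p2 <- p1; p2$delay_shift <- p1$delay_shift + 2.0
  c1 <- simulate_blood_curve(p1, grid = grid)
  c2 <- simulate_blood_curve(p2, grid = grid)
  k <- round(2.0 / grid$dt)
  n <- nrow(c1)
  expect_equal(c2$enrichment[(k + 1):n], c1$enrichment[1:(n - k)],
               tolerance = 1e-10)
})

test_that("airway pool dilutes: airway max below and later than blood max", {
  params <- default_kinetic_parameters("eosinophil")
  cv <- simulate_blood_curve(params)
  for (P in c(0.5, 2, 10, 50)) {
    p <- params; p$airway_pool_relative <- P
    aw <- simulate_airway_curve(p, cv)
    expect_lt(max(aw$enrichment), max(cv$enrichment))
  }
  aw10 <- simulate_airway_curve(params, cv)
  expect_gt(aw10$t_days[which.max(aw10$enrichment)],
            cv$t_days[which.max(cv$enrichment)])
})

test_that("a vanishing fast-draining pool tracks the blood curve", {
  params <- default_kinetic_parameters("eosinophil")
  grid <- simulation_grid(dt = 0.1, horizon = 60)
  cv <- simulate_blood_curve(params, grid = grid)
  p <- params
  p$airway_pool_relative <- 1e-9
  p$airway_residence_mean <- 0.1
  aw <- simulate_airway_curve(p, cv)
  # one-step lag: the pool is essentially the last step's egress
  n <- nrow(cv)
  lag <- 1L
  err <- abs(aw$enrichment[(lag + 1):n] - cv$enrichment[1:(n - lag)])
  expect_lt(max(err), 0.02 * max(cv$enrichment))
})

test_that("simulation matches the closed-form degenerate-limit oracle", {
  dt <- 0.02
  grid <- simulation_grid(dt = dt, horizon = 30)
  delta0 <- 3.6; t_half <- 2.5
  p <- kinetic_parameters(delay_shift = delta0, delay_mean_extra = 0.005,
                          blood_half_life = t_half)
  av <- label_availability(amplitude = 0.05, window_length = dt)
  cv <- simulate_blood_curve(p, av, grid)
  # labeled cohort share of the steady blood pool; the discrete scheme
  # registers the cohort (born mid-cell, delayed delta0) one grid cell after
  # its arrival cell, hence the dt timing offset
  M0 <- attr(cv, "mass_audit")[["initial_blood"]]
  oracle <- closed_form_blood_curve(delta0 + dt, t_half, grid,
                                    cohort_share = av$window_length / M0)
  sel <- grid$times > delta0 + 0.5
  rel_err <- abs(cv$enrichment[sel] - oracle$enrichment[sel]) /
    oracle$enrichment[sel]
  expect_lt(max(rel_err), 0.01)
  # trivial closed-form properties
  expect_equal(closed_form_blood_curve(5, 2, grid)$enrichment[
    grid$times < 5], rep(0, sum(grid$times < 5)))
  cf_inf <- closed_form_blood_curve(5, 1e9, grid)
  vals <- cf_inf$enrichment[grid$times >= 5]
  expect_equal(vals, rep(vals[1], length(vals)), tolerance = 1e-6)
})

test_that("near-infinite blood half-life preserves the arrived label", {
  p <- kinetic_parameters(delay_shift = 3.6, delay_mean_extra = 0.01,
                          blood_half_life = 1e6)
  cv <- simulate_blood_curve(p, label_availability(window_length = 0.1),
                             simulation_grid(dt = 0.1, horizon = 60))
  post <- cv$enrichment[cv$t_days >= 5]
  expect_equal(post, rep(post[1], length(post)), tolerance = 1e-4)
})

test_that("halving the grid step changes the curves by less than 0.5%", {
  params <- default_kinetic_parameters("eosinophil")
  c1 <- simulate_blood_curve(params, grid = simulation_grid(dt = 0.1))
  c2 <- simulate_blood_curve(params, grid = simulation_grid(dt = 0.05))
  common <- c1$t_days
  v2 <- c2$enrichment[match(round(common / 0.05), round(c2$t_days / 0.05))]
  peak <- max(c1$enrichment)
  sel <- c1$enrichment > 1e-3 * peak
  rel <- abs(c1$enrichment[sel] - v2[sel]) /
    pmax(abs(v2[sel]), 1e-3 * peak)
  expect_lt(max(rel), 0.005)
})

test_that("detection windows follow the default parameter sets", {
  thr <- correction_constants()$detection_threshold
  cv_eos <- simulate_blood_curve(default_kinetic_parameters("eosinophil"))
  dd <- detection_days(cv_eos, thr, 1:60)
  expect_equal(dd$first_day, 4)
  expect_lte(dd$last_day, 32)
  cv_baso <- simulate_blood_curve(default_kinetic_parameters("basophil"))
  expect_equal(detection_days(cv_baso, thr, 1:60)$first_day, 6)
  aw <- simulate_airway_curve(default_kinetic_parameters("eosinophil"),
                              cv_eos)
  dd_aw <- detection_days(aw, thr, 1:60)
  expect_lte(dd_aw$last_day, 40)
  expect_gt(dd_aw$last_day, dd$last_day)  # airway label outlives blood label
})

test_that("detection-day edge cases: never detected, boundary inclusive", {
  cv <- simulate_blood_curve(default_kinetic_parameters("eosinophil"),
                             label_availability(amplitude = 0))
  dd <- detection_days(cv, 5e-4, 1:60)
  expect_true(is.na(dd$first_day) && is.na(dd$last_day))
  cv2 <- simulate_blood_curve(default_kinetic_parameters("eosinophil"))
  v10 <- cv2$enrichment[cv2$t_days == 10]
  dd2 <- detection_days(cv2, v10, 1:60)     # threshold met exactly at day 10
  expect_lte(dd2$first_day, 10)
  expect_gte(dd2$last_day, 10)
  expect_error(detection_days(cv2, 5e-4, numeric(0)), "empty")
  expect_error(detection_days(cv2, 5e-4, 1:100), "horizon")
})

test_that("a horizon shorter than the transit delay warns and returns zeros", {
  p <- kinetic_parameters(delay_shift = 40)
  expect_warning(cv <- simulate_blood_curve(p, grid = simulation_grid(
    dt = 0.1, horizon = 30)), "horizon")
  expect_true(all(cv$enrichment == 0))
})

test_that("kinetic parameters are recovered from noise-free observations", {
  truth <- default_kinetic_parameters("eosinophil")
  grid <- simulation_grid(dt = 0.1, horizon = 60)
  cv <- simulate_blood_curve(truth, grid = grid)
  obs <- cv[cv$t_days %in% c(2, 4, 5, 6, 7, 8, 10, 12, 14, 18, 22, 27, 32),
            c("t_days", "enrichment")]
  init <- truth
  init$delay_shift <- truth$delay_shift * 1.3
  init$delay_mean_extra <- truth$delay_mean_extra * 0.7
  init$blood_half_life <- truth$blood_half_life * 1.25
  fit <- fit_kinetics(obs, init, grid = grid)
  for (f in c("delay_shift", "delay_mean_extra", "blood_half_life")) {
    expect_lt(abs(fit$params[[f]] - truth[[f]]) / truth[[f]], 0.15)
  }
})

test_that("kinetic fitting enforces its preconditions and degenerate flags", {
  grid <- simulation_grid()
  cv <- simulate_blood_curve(default_kinetic_parameters("eosinophil"),
                             grid = grid)
  obs3 <- cv[cv$t_days %in% c(5, 10, 15), c("t_days", "enrichment")]
  expect_error(fit_kinetics(obs3), "at least 4")
  # label-free observations carry no kinetic information
  obs0 <- data.frame(t_days = c(5, 10, 15, 20), enrichment = 0)
  expect_error(fit_kinetics(obs0), "not identifiable")
})
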