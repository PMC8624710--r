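test_that("dilution correction reproduces the hand mass balance", {
  cell <- cell_config(area = 1, V_receptor = 8, V_sample = 0.5,
                      C_donor = 50000)
  raw <- data.frame(cell_id = "c1", compound = "[IBU]", membrane = "skin",
                    time_h = c(1, 2, 3), conc_ug_per_ml = c(1, 2, 3))
  prof <- cumulative_amount(raw, cell)
  expect_equal(prof$Q_ug_per_cm2, c(8.0, 16.5, 25.5))
  rates <- interval_flux(prof)
  expect_equal(rates$rate_ug_per_cm2_h, c(8.0, 8.5, 9.0))
  zero <- raw; zero$conc_ug_per_ml <- c(0, 0, 0)
  expect_equal(cumulative_amount(zero, cell)$Q_ug_per_cm2, c(0, 0, 0))
  bad <- raw; bad$conc_ug_per_ml <- c(1, -2, 3)
  expect_error(cumulative_amount(bad, cell), ">= 0")
})

test_that("dilution correction inverts the sampling model at zero noise", {
  m <- ibu_skin_model(); cell <- default_cell(); sch <- sampling_schedule()
  raw <- simulate_sampling(m, cell, sch, noise_cv = 0, seed = 3)
  prof <- cumulative_amount(raw, cell)
  q <- cumulative_permeation(m, cell$C_donor, as.numeric(sch))
  expect_lt(max(abs(prof$Q_ug_per_cm2 - q) / q), 1e-10)
})

test_that("interval flux is constant on a line and rises toward kp*C on lag curves", {
  t <- c(1, 2, 4, 7)
  prof <- data.frame(cell_id = "c", compound = "x", membrane = "m",
                     time_h = t, Q_ug_per_cm2 = 5 * t)
  class(prof) <- c("permeation_profile", "data.frame")
  expect_equal(interval_flux(prof)$rate_ug_per_cm2_h, rep(5, 4))
  m <- ibu_skin_model(); cell <- default_cell()
  raw <- simulate_sampling(m, cell, sampling_schedule(), noise_cv = 0)
  r <- interval_flux(cumulative_amount(raw, cell))$rate_ug_per_cm2_h
  expect_true(all(diff(r) > 0))
  expect_lt(max(r), steady_state_flux(m, cell$C_donor))
  dup <- prof; dup$time_h <- c(1, 1, 4, 7)
  expect_error(interval_flux(dup), "duplicate|non-increasing")
})

test_that("steady-state fit is exact on an exact line", {
  t <- c(2, 3, 4, 5)
  prof <- data.frame(cell_id = "c", compound = "x", membrane = "m",
                     time_h = t, Q_ug_per_cm2 = 5 * (t - 1))
  class(prof) <- c("permeation_profile", "data.frame")
  fit <- fit_steady_state(prof, cell_config(C_donor = 50000))
  expect_equal(fit$J_ss, 5)
  expect_equal(fit$L_T, 1)
  expect_equal(fit$r2_fit, 1)
  expect_equal(fit$K_p, 5 / 50000)
  expect_equal(fit$K_p * 50000, fit$J_ss)   # K_p * C_donor == J_ss
})

test_that("fit recovers simulator ground truth on a noiseless profile", {
  m <- ibu_skin_model()   # kp = 0.74e-3 cm/h, lt = 1.17 h
  cell <- default_cell()  # C_donor = 50,000 ug/cm^3
  raw <- simulate_sampling(m, cell, sampling_schedule(), noise_cv = 0)
  fit <- fit_steady_state(cumulative_amount(raw, cell), cell)
  expect_equal(fit$J_ss, 37.0, tolerance = 0.02)
  expect_equal(fit$L_T, 1.17, tolerance = 0.10)
  # window never reaches into the pre-lag regime on noiseless data
  expect_gte(raw$time_h[fit$window["start"]], m$lt / 2)
})

test_that("chosen window equals exhaustive lm() search on noisy profiles", {
  cell <- default_cell()
  set.seed(99)
  for (i in 1:12) {
    m <- random_model()
    raw <- simulate_sampling(m, cell, sampling_schedule(), noise_cv = 0.08)
    prof <- cumulative_amount(raw, cell)
    fit <- suppressWarnings(fit_steady_state(prof, cell))
    oracle <- brute_force_window(prof$time_h, prof$Q_ug_per_cm2)
    expect_identical(unname(fit$window), c(oracle$s, oracle$e))
    expect_equal(fit$J_ss, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$r2_fit, oracle$r2, tolerance = 1e-10)
  }
})

test_that("degenerate fits error out; negative lag warns", {
  cell <- default_cell()
  t <- c(1, 2, 3, 4)
  down <- data.frame(cell_id = "c", compound = "x", membrane = "m",
                     time_h = t, Q_ug_per_cm2 = -2 * t + 10)
  class(down) <- c("permeation_profile", "data.frame")
  expect_error(fit_steady_state(down, cell), "no steady state")
  neg <- down; neg$Q_ug_per_cm2 <- 2 * t + 1   # x-intercept below zero
  expect_warning(fit_steady_state(neg, cell), "negative fitted lag")
})

test_that("replicate aggregation gives mean and n-1 SD", {
  mk <- function(j) structure(list(cell_id = "c", compound = "[IBU]",
    membrane = "skin", J_ss = j, intercept = 0, L_T = 1,
    K_p = j / 50000, r2_fit = 1, window = c(start = 1, end = 4)),
    class = "steady_state_fit")
  summ <- aggregate_cells(list(mk(36), mk(37), mk(38)))
  expect_equal(summ$Jss_mean, 37)
  expect_equal(summ$Jss_sd, 1)
  single <- aggregate_cells(list(mk(36)))
  expect_true(is.na(single$Jss_sd))
  other <- mk(40); other$membrane <- "strat-m"
  expect_error(aggregate_cells(list(mk(36), other)), "mixed")
})

test_that("permeation ratio worked examples and reciprocal identity hold", {
  expect_equal(round(permeation_ratio(163.45, 36.98), 2), 4.42)
  expect_equal(round(permeation_ratio(205.81, 56.56), 2), 3.64)
  expect_equal(permeation_ratio(50, 50), 1)
  expect_equal(permeation_ratio(163.45, 36.98) *
               permeation_ratio(36.98, 163.45), 1, tolerance = 1e-12)
  expect_error(permeation_ratio(10, 0), "zero denominator")
})

test_that("noiseless study analysis recovers every ground-truth parameter", {
  reg <- default_compound_registry()
  study <- generate_study(reg, n_cells = 2, noise_cv = 0, seed = 1)
  res <- analyze_study(study$data, default_cell())
  truth <- study$truth
  for (r in seq_len(nrow(truth))) {
    s <- res$summaries[res$summaries$compound == truth$acronym[r] &
                       res$summaries$membrane == truth$membrane[r], ]
    expect_equal(s$Kp_e3_mean, 1e3 * truth$kp[r], tolerance = 0.005)
    expect_equal(s$Jss_mean, truth$kp[r] * 50000, tolerance = 0.005)
  }
  # profiles from noiseless simulation are strictly increasing
  expect_true(all(vapply(res$profiles,
    function(p) all(diff(p$Q_ug_per_cm2) > 0), logical(1))))
})
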