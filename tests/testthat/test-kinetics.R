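test_that("bleach correction cancels shared decay and is anchored at 1", {
  t <- seq(0, 60, 2)
  ctrl <- 800 * exp(-0.01 * t)
  samp <- 800 * (1 - 0.02 * t) * exp(-0.01 * t)
  out <- bleach_correct(t, samp, ctrl)
  expect_equal(out$corrected, 1 - 0.02 * t, tolerance = 1e-12)
  expect_equal(out$corrected[1], 1)
  # sample identical to control: flat at 1
  same <- bleach_correct(t, ctrl, ctrl)
  expect_true(all(same$corrected == 1))
})

test_that("bleach correction guards its inputs", {
  t <- 0:5
  expect_error(bleach_correct(t, c(0, rep(1, 5)), rep(1, 6)), "F_0")
  expect_error(bleach_correct(t, rep(1, 6), rep(1, 5)), "time grid")
  expect_warning(out <- bleach_correct(t, rep(2, 6), c(4, 3, 2, 1, 0, -1)),
                 "truncating")
  expect_equal(nrow(out), 4)
})

test_that("degradation fits recover the generating line exactly", {
  t <- seq(0, 100, 5)
  fit <- fit_degradation(t, 1 - 0.02 * t, window = c(0, 100))
  expect_equal(fit$k_per_min, 0.02, tolerance = 1e-12)
  expect_equal(fit$B, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  flat <- fit_degradation(t, rep(1, length(t)))
  expect_equal(flat$k_per_min, 0, tolerance = 1e-12)
  conv <- fit_degradation(t, 1 - 0.02 * t, window = c(0, 100),
                          substrate_conc = 1, enzyme_conc = 0.1)
  expect_equal(conv$rate_per_enzyme, 0.2, tolerance = 1e-12)
  expect_error(fit_degradation(t, 1 - 0.02 * t, window = c(200, 300)),
               "outside")
})

test_that("pathlength calibration inverts the Beer-Lambert slope", {
  conc <- seq(0, 1.2, 0.1)
  cal <- calibrate_pathlength(conc, 6.22 * 0.3 * conc)
  expect_equal(cal$lightpath_cm, 0.3, tolerance = 1e-12)
  expect_equal(cal$r2, 1)
  single <- calibrate_pathlength(1.0, 1.866)
  expect_equal(single$lightpath_cm, 0.3, tolerance = 1e-9)
  expect_error(calibrate_pathlength(rep(0, 4), rep(0, 4)), "positive")
  expect_error(calibrate_pathlength(conc, rep(0, length(conc))), "zero")
})

test_that("ATPase rates convert slopes through 6.22 * lightpath", {
  t <- seq(0, 30, 1)
  abs_s <- 1.8 - 0.01866 * t
  fit <- fit_atpase(t, abs_s, lightpath_cm = 0.3)
  expect_equal(fit$rate_mM_min, 0.01, tolerance = 1e-9)
  per <- fit_atpase(t, abs_s, lightpath_cm = 0.3, enzyme_mM = 1e-4)
  expect_equal(per$rate_per_enzyme, 100, tolerance = 1e-6)
  # background-only signal: net rate zero
  zero <- fit_atpase(t, abs_s, abs_background = abs_s, lightpath_cm = 0.3)
  expect_equal(zero$rate_mM_min, 0)
  expect_warning(
    clip <- fit_atpase(t, 1.8 - 0.001 * t, abs_background = 1.8 - 0.002 * t,
                       lightpath_cm = 0.3),
    "clipped")
  expect_equal(clip$rate_mM_min, 0)
})

test_that("ATP cost is a guarded, scale-invariant quotient", {
  expect_equal(atp_cost(150, 0.3), 500)
  expect_equal(atp_cost(7, 7), 1)
  expect_equal(atp_cost(150 * 3.7, 0.3 * 3.7), 500, tolerance = 1e-12)
  expect_error(atp_cost(150, 0), "positive")
  expect_error(atp_cost(150, -1), "positive")
})

test_that("noise-free plate round trips recover generating values to 1e-6", {
  # degradation branch
  p <- plate_sim_params("degradation", k_deg_per_min = 0.015,
                        k_bleach_per_min = 0.02, noise_sd = 0,
                        n_replicates = 1)
  tab <- simulate_plate(p)
  s <- tab[tab$role == "sample", ]
  ctl <- tab[tab$role == "bleach_control", ]
  corr <- bleach_correct(s$time_min, s$value, ctl$value)
  fit <- fit_degradation(corr$time_min, corr$corrected,
                         window = range(corr$time_min))
  expect_lt(abs(fit$k_per_min / 0.015 - 1), 1e-6)
  # pathlength branch
  ps <- plate_sim_params("nadh_standard", lightpath_cm = 0.42, noise_sd = 0)
  std <- simulate_plate(ps)
  cal <- calibrate_pathlength(std$nadh_mM, std$value)
  expect_lt(abs(cal$lightpath_cm / 0.42 - 1), 1e-6)
  # ATPase branch, with background subtraction
  pa <- plate_sim_params("atpase", nadh_rate_mM_min = 0.008,
                         background_rate_mM_min = 0.003,
                         lightpath_cm = 0.42, noise_sd = 0, n_replicates = 1)
  at <- simulate_plate(pa)
  sa <- at[at$role == "sample", ]
  ba <- at[at$role == "background", ]
  fa <- fit_atpase(sa$time_min, sa$value, ba$value, lightpath_cm = 0.42)
  expect_lt(abs(fa$rate_mM_min / 0.008 - 1), 1e-6)
})

test_that("1% measurement noise leaves rate estimates unbiased", {
  ks <- numeric(200)
  rates <- numeric(200)
  for (s in 1:200) {
    p <- plate_sim_params("degradation", k_deg_per_min = 0.02,
                          k_bleach_per_min = 0.01, f0 = 1000,
                          t_points_min = seq(0, 40, 2),
                          noise_sd = 10, n_replicates = 1, seed = s)
    tab <- simulate_plate(p)
    sm <- tab[tab$role == "sample", ]
    ctl <- tab[tab$role == "bleach_control", ]
    corr <- bleach_correct(sm$time_min, sm$value, ctl$value)
    ks[s] <- fit_degradation(corr$time_min, corr$corrected,
                             window = range(corr$time_min))$k_per_min
    pa <- plate_sim_params("atpase", nadh_rate_mM_min = 0.01,
                           background_rate_mM_min = 0, lightpath_cm = 0.3,
                           noise_sd = 0.018, n_replicates = 1, seed = s)
    at <- simulate_plate(pa)
    sa <- at[at$role == "sample", ]
    rates[s] <- fit_atpase(sa$time_min, sa$value,
                           lightpath_cm = 0.3)$rate_mM_min
  }
  expect_lt(abs(mean(ks) - 0.02), 2 * sd(ks) / sqrt(200))
  expect_lt(abs(mean(rates) - 0.01), 2 * sd(rates) / sqrt(200))
})
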