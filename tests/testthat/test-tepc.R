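test_that("mean dose from charge follows the W/e unit chain", {
  # one electron of collected charge, unit gain, W/e = 28 eV, 1 kg of gas:
  # 28 eV deposited in 1 kg = 28 x 1.602176634e-19 Gy
  cfg <- tepc_config(m_det = 1, gas_gain = 1, w_over_e = 28)
  q <- rep(1.602176634e-19, 4)
  expect_equal(mean_dose_from_charge(charge_series(q), cfg),
               28 * 1.602176634e-19, tolerance = 1e-12)
  # zero charge means zero dose
  expect_equal(mean_dose_from_charge(charge_series(c(0, 0)), cfg), 0)
  # dose is inversely proportional to the gas gain
  cfg2 <- tepc_config(m_det = 1, gas_gain = 2, w_over_e = 28)
  expect_equal(mean_dose_from_charge(charge_series(q), cfg2),
               mean_dose_from_charge(charge_series(q), cfg) / 2)
})

test_that("variance-method dose-mean lineal energy behaves and scales", {
  cfg <- tepc_config()
  # constant non-zero series: zero relative variance, zero y_D
  est <- dose_mean_lineal_energy(charge_series(rep(2e-12, 10)), cfg)
  expect_equal(est$v_rel, 0)
  expect_equal(est$y_d_keV_um, 0)
  # all-zero series is rejected
  expect_error(dose_mean_lineal_energy(charge_series(rep(0, 10)), cfg),
               class = "neutrondose_invalid_argument")
  # doubling every charge leaves v_rel unchanged and doubles y_D
  q <- c(1, 2, 3, 5, 8) * 1e-13
  e1 <- dose_mean_lineal_energy(charge_series(q), cfg)
  e2 <- dose_mean_lineal_energy(charge_series(2 * q), cfg)
  expect_equal(e2$v_rel, e1$v_rel, tolerance = 1e-12)
  expect_equal(e2$d_mean_Gy, 2 * e1$d_mean_Gy, tolerance = 1e-12)
  expect_equal(e2$y_d_keV_um, 2 * e1$y_d_keV_um, tolerance = 1e-12)
})

test_that("variance method recovers the generator's dose-mean lineal energy", {
  sim <- simulate_tepc_intervals(photon_fraction = 0, n_intervals = 1e5,
                                 event_rate = 50, seed = 1)
  expect_equal(sim$truth$y_d_keV_um, 96, tolerance = 1e-12)
  est <- dose_mean_lineal_energy(sim$series)
  # standard error of the estimator from 20 blocks of the same series
  q <- sim$series$charge_C
  blocks <- split(q, rep(1:20, each = length(q) / 20))
  block_est <- vapply(blocks, function(b) {
    dose_mean_lineal_energy(charge_series(b))$y_d_keV_um
  }, numeric(1))
  se <- stats::sd(block_est) / sqrt(20)
  expect_lt(abs(est$y_d_keV_um - 96), 3 * se)
  expect_equal(est$d_mean_Gy, sim$truth$d_mean_Gy, tolerance = 0.02)
})

test_that("estimator bias shrinks with the number of intervals", {
  err_at <- function(n) {
    errs <- vapply(1:5, function(s) {
      sim <- simulate_tepc_intervals(0.3, n, event_rate = 50, seed = s)
      est <- dose_mean_lineal_energy(sim$series)
      abs(est$y_d_keV_um - sim$truth$y_d_keV_um) / sim$truth$y_d_keV_um
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(1e4), err_at(1e3))
})

test_that("simulated series are reproducible and validated", {
  a <- simulate_tepc_intervals(0.5, 100, seed = 42)
  b <- simulate_tepc_intervals(0.5, 100, seed = 42)
  expect_identical(a$series$charge_C, b$series$charge_C)
  expect_error(simulate_tepc_intervals(0.5, 1, seed = 1),
               class = "neutrondose_invalid_argument")
  expect_error(simulate_tepc_intervals(1.5, 100, seed = 1),
               class = "neutrondose_invalid_argument")
  # a pure-photon stream has the photon component's dose-mean y
  p <- simulate_tepc_intervals(1, 10, seed = 1)
  expect_equal(p$truth$y_d_keV_um, 1.4, tolerance = 1e-12)
})

test_that("dose equivalent from the printed constants is reproduced", {
  cfg <- tepc_config()
  # D = 1 Gy, y_D = 96 keV/um -> 0.88 + 0.09 * 96 = 9.52 Sv
  expect_equal(dose_equivalent_variance(1, 96, cfg), 9.52)
  expect_equal(dose_equivalent_variance(0, 96, cfg), 0)
  expect_equal(dose_equivalent_variance(1, 0, cfg), 0.88)
  # H/D never falls below a
  expect_gte(dose_equivalent_variance(2, 0.01, cfg) / 2, cfg$a)
})

test_that("mixed-field split interpolates between the photon and neutron endpoints", {
  cfg <- tepc_config()
  expect_equal(mixed_field_split(96, cfg)$d_n, 1)
  expect_equal(mixed_field_split(1.4, cfg)$d_gamma, 1)
  mid <- mixed_field_split(48.7, cfg)
  expect_equal(mid$d_gamma, 0.5)
  expect_equal(mid$d_n, 0.5)
  # out-of-range estimates are clamped with a warning, not rejected
  expect_warning(hi <- mixed_field_split(120, cfg), "clamped")
  expect_equal(hi$d_n, 1)
})

test_that("component dose equivalents match the printed-constant arithmetic", {
  cfg <- tepc_config()
  pure_n <- component_dose_equivalents(1, 1, cfg)
  expect_equal(pure_n$h_n_Sv, 9.52)
  expect_equal(pure_n$h_gamma_Sv, 0)
  pure_g <- component_dose_equivalents(1, 0, cfg)
  expect_equal(pure_g$h_gamma_Sv, 0.88 + 0.09 * 1.4)
  zero <- component_dose_equivalents(0, 0.5, cfg)
  expect_equal(unlist(zero), c(h_n_Sv = 0, h_gamma_Sv = 0))
  expect_error(component_dose_equivalents(1, 1.2, cfg),
               class = "neutrondose_invalid_argument")
})

test_that("split then recombine reproduces the direct dose equivalent at the endpoints", {
  cfg <- tepc_config()
  for (y in c(1.4, 96)) {
    d <- 0.37
    split <- mixed_field_split(y, cfg)
    comp <- component_dose_equivalents(d, split$d_n, cfg)
    expect_equal(comp$h_n_Sv + comp$h_gamma_Sv,
                 dose_equivalent_variance(d, y, cfg), tolerance = 1e-12)
  }
})

test_that("quality factor matches an independent piecewise oracle", {
  expect_equal(quality_factor(5), 1)
  expect_equal(quality_factor(96), 28.52)
  expect_equal(quality_factor(400), 15)
  # continuity at the 10 keV/um branch point
  expect_equal(quality_factor(10), 1, tolerance = 1e-9)
  expect_error(quality_factor(-1), class = "neutrondose_invalid_argument")
  withr::with_seed(99, {
    y <- stats::runif(1000, 0.01, 1000)
    expect_equal(quality_factor(y), vapply(y, oracle_q, numeric(1)))
  })
})

test_that("single-event dose equivalent splits at 10 keV/um with calibration factors", {
  cfg <- hawk_config()
  # single bin with geometric-mean y = 96 carrying 1 Gy:
  # H_high = 0.8 * Q(96) * 1 = 0.8 * 28.52
  spec <- lineal_energy_spectrum(96 / 1.001, 96 * 1.001, 1)
  h <- hawk_dose_equivalent(spec, cfg)
  expect_equal(h$h_low_Sv, 0)
  expect_equal(h$h_high_Sv, 0.8 * quality_factor(96), tolerance = 1e-6)
  # all dose below 10 keV/um leaves the high-LET component empty
  low <- lineal_energy_spectrum(c(1, 2), c(2, 4), c(0.3, 0.2))
  expect_equal(hawk_dose_equivalent(low, cfg)$h_high_Sv, 0)
  # empty spectrum
  empty <- lineal_energy_spectrum(numeric(0), numeric(0), numeric(0))
  expect_equal(unlist(hawk_dose_equivalent(empty, cfg)),
               c(h_low_Sv = 0, h_high_Sv = 0, h_total_Sv = 0))
  # dose below the electronic threshold is excluded
  sub <- lineal_energy_spectrum(0.1, 0.3, 5)
  expect_equal(hawk_dose_equivalent(sub, cfg)$h_total_Sv, 0)
  # bins above y_max are an error
  expect_error(hawk_dose_equivalent(lineal_energy_spectrum(2000, 3000, 1), cfg),
               class = "neutrondose_invalid_argument")
})

test_that("single-event method is additive and homogeneous in dose", {
  cfg <- hawk_config()
  y_lo <- c(1, 5, 20, 100)
  y_hi <- c(5, 20, 100, 500)
  d1 <- c(0.1, 0.2, 0.3, 0.4)
  d2 <- c(0.4, 0.1, 0.0, 0.2)
  h1 <- hawk_dose_equivalent(lineal_energy_spectrum(y_lo, y_hi, d1), cfg)
  h2 <- hawk_dose_equivalent(lineal_energy_spectrum(y_lo, y_hi, d2), cfg)
  hsum <- hawk_dose_equivalent(lineal_energy_spectrum(y_lo, y_hi, d1 + d2), cfg)
  expect_equal(hsum$h_total_Sv, h1$h_total_Sv + h2$h_total_Sv,
               tolerance = 1e-12)
  h3 <- hawk_dose_equivalent(lineal_energy_spectrum(y_lo, y_hi, 3 * d1), cfg)
  expect_equal(h3$h_total_Sv, 3 * h1$h_total_Sv, tolerance = 1e-12)
})
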