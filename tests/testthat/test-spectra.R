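test_that("lethargy grid has constant log-width edges covering the span", {
  edges <- lethargy_grid(1e-9, 240, 0.26)
  expect_equal(diff(log(edges)), rep(0.26, length(edges) - 1), tolerance = 1e-12)
  expect_equal(edges[1], 1e-9)
  expect_gte(max(edges), 240)
  expect_equal(length(edges) - 1, ceiling(log(240 / 1e-9) / 0.26))
  # consecutive edge ratio is exp(0.26)
  expect_equal(unique(round(edges[-1] / edges[-length(edges)], 10)),
               round(exp(0.26), 10))
  # a span of exactly one lethargy width gives exactly one bin
  expect_length(lethargy_grid(1, exp(0.26), 0.26), 2)
})

test_that("degenerate grid requests error", {
  expect_error(lethargy_grid(1, 1, 0.26), class = "neutrondose_invalid_argument")
  expect_error(lethargy_grid(-1, 10, 0.26), class = "neutrondose_invalid_argument")
  expect_error(lethargy_grid(1, 10, 0), class = "neutrondose_invalid_argument")
})

test_that("per-lethargy view divides by bin lethargy width and round-trips", {
  edges <- lethargy_grid(1e-3, 10, 0.26)
  n <- length(edges) - 1
  # constant fluence on a uniform-lethargy grid -> constant per-lethargy values
  sp <- neutron_spectrum(edges, rep(2, n))
  pl <- per_lethargy(sp)
  expect_equal(pl$fluence_per_lethargy, rep(2 / 0.26, n), tolerance = 1e-12)
  # single bin: fluence / 0.26
  sp1 <- neutron_spectrum(c(1, exp(0.26)), 5)
  expect_equal(per_lethargy(sp1)$fluence_per_lethargy, 5 / 0.26)
  # round trip is the identity at double precision
  sp2 <- neutron_spectrum(edges, stats::runif(n))
  back <- from_per_lethargy(per_lethargy(sp2))
  expect_equal(back$fluence_per_cm2_per_Gy, sp2$fluence_per_cm2_per_Gy,
               tolerance = 1e-15)
})

test_that("band fractions partition unity and handle degenerate spectra", {
  sp <- two_delta_spectrum(1, 1)
  fr <- band_fractions(sp)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_equal(fr$fraction[fr$band == "thermal"], 0.5)
  expect_equal(fr$fraction[fr$band == "high_energy"], 0.5)
  # spectrum entirely inside one band
  edges <- lethargy_grid(1e-9, 240)
  fl <- rep(0, length(edges) - 1)
  fl[2] <- 3
  one <- band_fractions(neutron_spectrum(edges, fl))
  expect_equal(one$fraction[one$band == "thermal"], 1)
  expect_equal(sum(one$fraction), 1)
  # all-zero spectrum: NaN fractions plus a warning, not an error
  expect_warning(
    z <- band_fractions(neutron_spectrum(edges, rep(0, length(edges) - 1))),
    "zero total fluence"
  )
  expect_true(all(is.nan(z$fraction)))
  # band outside the grid span is rejected
  expect_error(
    band_fractions(sp, tibble::tibble(band = "x", e_low_MeV = 1e-12,
                                      e_high_MeV = 1)),
    class = "neutrondose_invalid_argument"
  )
})

test_that("source energy bounds ignore zero-weight layers", {
  expect_equal(source_energy_bounds(proton_source(c(100, 212), c(1, 2))),
               c(min = 100, max = 212))
  expect_equal(source_energy_bounds(proton_source(146)),
               c(min = 146, max = 146))
  src <- proton_source(c(65, 103), c(0, 1))
  expect_equal(source_energy_bounds(src), c(min = 103, max = 103))
  expect_error(source_energy_bounds(proton_source(c(65, 103), c(0, 0))),
               class = "neutrondose_invalid_argument")
})

test_that("synthesized cascade peak sits at the requested centre", {
  src <- proton_source(c(100, 212), c(1, 2))
  sp <- synthesize_spectrum(src, spectrum_shape(0, 0, 0, 1))
  e_rep <- sqrt(sp$e_low_MeV * sp$e_high_MeV)
  mean_e <- sum(sp$fluence_per_cm2_per_Gy * e_rep) /
    sum(sp$fluence_per_cm2_per_Gy)
  # oracle: the component is a Gaussian at 0.6 x 212 = 127.2 MeV; binning and
  # truncation move the fluence-weighted mean by well under 1 %
  expect_equal(mean_e, 127.2, tolerance = 0.01)
  # no fluence above E_max + 3 peak widths
  expect_true(all(sp$fluence_per_cm2_per_Gy[e_rep > 212 + 3 * 0.15 * 212] == 0))
})

test_that("synthesized spectrum totals the amplitudes and scales linearly", {
  src <- proton_source(c(100, 212), c(1, 2))
  sh1 <- spectrum_shape(1, 0.5, 2, 3)
  sp1 <- synthesize_spectrum(src, sh1)
  expect_equal(sum(sp1$fluence_per_cm2_per_Gy), 1 + 0.5 + 2 + 3,
               tolerance = 1e-12)
  # homogeneity of degree 1: doubling all amplitudes doubles every bin exactly
  sh2 <- spectrum_shape(2, 1, 4, 6)
  sp2 <- synthesize_spectrum(src, sh2)
  expect_identical(sp2$fluence_per_cm2_per_Gy, 2 * sp1$fluence_per_cm2_per_Gy)
})

high_part <- function(sp) {
  # fluence restricted to energies above 20 MeV, where only the cascade
  # component lives
  e_rep <- sqrt(sp$e_low_MeV * sp$e_high_MeV)
  ifelse(e_rep > 20, sp$fluence_per_cm2_per_Gy, 0)
}

test_that("cascade peak position is non-decreasing in max proton energy", {
  sh <- spectrum_shape(0.5, 0.2, 1, 2)
  withr::with_seed(101, {
    for (i in 1:10) {
      e1 <- stats::runif(1, 80, 150)
      e2 <- stats::runif(1, e1 + 10, 230)
      am1 <- which.max(high_part(synthesize_spectrum(proton_source(e1), sh)))
      am2 <- which.max(high_part(synthesize_spectrum(proton_source(e2), sh)))
      expect_gte(am2, am1)
    }
  })
  # the shift is strict between 103 and 212 MeV sources
  am_low <- which.max(high_part(synthesize_spectrum(proton_source(103), sh)))
  am_high <- which.max(high_part(synthesize_spectrum(proton_source(212), sh)))
  expect_gt(am_high, am_low)
})

test_that("shape and amplitude validation rejects impossible requests", {
  expect_error(spectrum_shape(0, 0, 0, 0), class = "neutrondose_invalid_argument")
  expect_error(spectrum_shape(1, 1, 1, 1, highenergy_center_fraction = 1.5),
               class = "neutrondose_invalid_argument")
  # grid stopping below the cascade peak is rejected
  expect_error(
    synthesize_spectrum(proton_source(212), spectrum_shape(0, 0, 0, 1),
                        grid = lethargy_grid(1e-9, 50)),
    class = "neutrondose_invalid_argument"
  )
})
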