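#' Configuration of a variance-method TEPC
#'
#' Constants of the variance-method dose-equivalent algorithm for a
#' tissue-equivalent proportional counter read out by repeated charge
#' integrations.
#'
#' @param m_det Detector gas mass, kg. The default corresponds to about
#'   1.2 dm^3 of propane-based TE gas at 1.37 kPa.
#' @param l_bar Mean chord length of the simulated tissue site, um
#'   (default 1.88).
#' @param w_over_e Mean energy per ion pair W/e, eV (default 28).
#' @param gas_gain Gas multiplication factor M (dimensionless).
#' @param a,b Dose-equivalent constants in `H* = D (a + b yD)`:
#'   `a` dimensionless (0.88), `b` in um/keV (0.09), chosen for the
#'   high-energy neutron fields of proton therapy rooms.
#' @param y_d_gamma,y_d_neutron Dose-mean lineal energies of the photon and
#'   neutron field components, keV/um (1.4 and 96).
#' @return A list of class `tepc_config`.
#' @export
tepc_config <- function(m_det = 3e-5, l_bar = 1.88, w_over_e = 28,
                        gas_gain = 1, a = 0.88, b = 0.09,
                        y_d_gamma = 1.4, y_d_neutron = 96) {
  vals <- c(m_det = m_det, l_bar = l_bar, w_over_e = w_over_e,
            gas_gain = gas_gain, a = a, b = b,
            y_d_gamma = y_d_gamma, y_d_neutron = y_d_neutron)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_invalid("All TEPC configuration values must be positive and finite.")
  }
  if (y_d_gamma >= y_d_neutron) {
    abort_invalid("`y_d_gamma` must be smaller than `y_d_neutron`.")
  }
  structure(as.list(vals), class = "tepc_config")
}

#' Charge series from repeated integrations
#'
#' @param charge_C Non-negative collected charges per integration interval,
#'   coulomb; at least 2 intervals are needed for variance estimation.
#' @param interval_s Integration time per interval, s (default 0.1).
#' @return A tibble of class `charge_series` with column `charge_C`;
#'   `interval_s` is stored as an attribute.
#' @export
charge_series <- function(charge_C, interval_s = 0.1) {
  if (!is.numeric(charge_C) || length(charge_C) < 2 ||
      any(!is.finite(charge_C)) || any(charge_C < 0)) {
    abort_invalid("`charge_C` must be >= 2 finite non-negative charges.")
  }
  out <- tibble(charge_C = as.double(charge_C))
  attr(out, "interval_s") <- interval_s
  class(out) <- c("charge_series", class(out))
  out
}

charges_of <- function(series) {
  if (is.data.frame(series)) {
    if (!"charge_C" %in% names(series)) {
      abort_invalid("A charge series needs a `charge_C` column.")
    }
    series$charge_C
  } else if (is.numeric(series)) {
    series
  } else {
    abort_invalid("`series` must be a charge_series tibble or numeric vector.")
  }
}

#' Mean absorbed detector dose from a charge series
#'
#' `D = qbar (W/e) / (M m_det)`: the mean collected charge divided by the
#' elementary charge and the gas gain gives the number of ion pairs; times
#' W/e gives the deposited energy; divided by the gas mass gives the dose.
#' Numerically the elementary charge cancels, so with W/e in eV and charge
#' in coulomb the dose in Gy is `mean(q) * w_over_e / (gas_gain * m_det)`.
#'
#' @param series A [charge_series()] (or bare numeric vector of charges, C).
#' @param cfg A [tepc_config()].
#' @return Mean absorbed dose in the detector gas, Gy.
#' @export
mean_dose_from_charge <- function(series, cfg = tepc_config()) {
  q <- charges_of(series)
  mean(q) * cfg$w_over_e / (cfg$gas_gain * cfg$m_det)
}

#' Dose-mean lineal energy by the variance method
#'
#' From repeated charge integrations: the relative variance of the absorbed
#' dose over intervals, `V = var(D) / Dbar^2` (unbiased sample variance),
#' yields the dose-mean lineal energy `yD = m_det V Dbar / l_bar`. The
#' product `m_det V Dbar` is an energy (J); division by the mean chord
#' length and conversion J -> keV gives keV/um. A constant series has zero
#' variance and hence `yD = 0`.
#'
#' @inheritParams mean_dose_from_charge
#' @return A one-row tibble with `d_mean_Gy`, `v_rel`, `y_d_keV_um`.
#' @export
dose_mean_lineal_energy <- function(series, cfg = tepc_config()) {
  q <- charges_of(series)
  if (length(q) < 2) {
    abort_invalid("Need at least 2 intervals for variance estimation.")
  }
  if (all(q == 0)) {
    abort_invalid("All charges are zero; the relative variance is undefined.")
  }
  d_mean <- mean_dose_from_charge(q, cfg)
  v_rel <- stats::var(q) / mean(q)^2
  y_d <- cfg$m_det * v_rel * d_mean / (cfg$l_bar * .j_per_kev)
  tibble(d_mean_Gy = d_mean, v_rel = v_rel, y_d_keV_um = y_d)
}

#' Dose equivalent from mean dose and dose-mean lineal energy
#'
#' `H* = D (a + b yD)` with the constants of the configuration; the
#' dose-equivalent-to-dose ratio is therefore never below `a`.
#'
#' @param d_mean Mean absorbed detector dose, Gy.
#' @param y_d Dose-mean lineal energy, keV/um.
#' @param cfg A [tepc_config()].
#' @return Dose equivalent H*, Sv.
#' @export
dose_equivalent_variance <- function(d_mean, y_d, cfg = tepc_config()) {
  if (any(d_mean < 0) || any(y_d < 0)) {
    abort_invalid("`d_mean` and `y_d` must be non-negative.")
  }
  d_mean * (cfg$a + cfg$b * y_d)
}

#' Photon/neutron dose split of a mixed field
#'
#' In a mixed photon/neutron field the measured dose-mean lineal energy is
#' the dose-weighted mean of the component values,
#' `yD = yD_gamma d_gamma + yD_n (1 - d_gamma)`, which inverts to the photon
#' dose fraction `d_gamma = (yD_n - yD) / (yD_n - yD_gamma)`. Measurement
#' noise can push the estimate past the endpoints, so out-of-range values
#' are clamped to \[0, 1\] with a warning rather than rejected.
#'
#' @param y_d Measured dose-mean lineal energy, keV/um.
#' @param cfg A [tepc_config()].
#' @return A one-row tibble with `d_gamma` and `d_n` (fractions summing
#'   to 1).
#' @export
mixed_field_split <- function(y_d, cfg = tepc_config()) {
  d_gamma <- (cfg$y_d_neutron - y_d) / (cfg$y_d_neutron - cfg$y_d_gamma)
  if (any(d_gamma < 0) || any(d_gamma > 1)) {
    warn(paste0(
      "Measured y_d outside [y_d_gamma, y_d_neutron]; ",
      "dose fractions clamped to [0, 1]."
    ))
    d_gamma <- pmin(pmax(d_gamma, 0), 1)
  }
  tibble(d_gamma = d_gamma, d_n = 1 - d_gamma)
}

#' Component dose equivalents of a mixed field
#'
#' `H*_n = d_n D (a + b yD_n)` and `H*_gamma = (1 - d_n) D (a + b yD_gamma)`.
#'
#' @param d_mean Mean absorbed detector dose, Gy.
#' @param d_n Neutron dose fraction in \[0, 1\].
#' @param cfg A [tepc_config()].
#' @return A one-row tibble with `h_n_Sv` and `h_gamma_Sv`.
#' @export
component_dose_equivalents <- function(d_mean, d_n, cfg = tepc_config()) {
  if (any(d_n < 0) || any(d_n > 1)) {
    abort_invalid("`d_n` must lie in [0, 1].")
  }
  if (any(d_mean < 0)) abort_invalid("`d_mean` must be non-negative.")
  tibble(
    h_n_Sv = d_n * d_mean * (cfg$a + cfg$b * cfg$y_d_neutron),
    h_gamma_Sv = (1 - d_n) * d_mean * (cfg$a + cfg$b * cfg$y_d_gamma)
  )
}

#' Quality factor as a function of lineal energy
#'
#' The ICRP 60 quality factor Q(L) with lineal energy y substituted for
#' unrestricted LET, the standard surrogate in TEPC dosimetry:
#' `Q = 1` below 10 keV/um, `0.32 y - 2.2` between 10 and 100 keV/um, and
#' `300 / sqrt(y)` above 100 keV/um. The function is continuous at
#' 10 keV/um; at 100 keV/um it has the well-known small step
#' (29.8 vs 30.0) inherited from the ICRP formulation.
#'
#' @param y Lineal energy, keV/um; strictly positive (vectorised).
#' @return Dimensionless quality factor(s).
#' @export
quality_factor <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y <= 0)) {
    abort_invalid("`y` must be positive and finite (keV/um).")
  }
  dplyr::case_when(
    y < 10 ~ 1,
    y <= 100 ~ 0.32 * y - 2.2,
    TRUE ~ 300 / sqrt(y)
  )
}

#' Configuration of the single-event (lineal-energy spectrum) method
#'
#' @param n_low,n_high Low- and high-LET H*(10) calibration correction
#'   factors (defaults 1.1 and 0.8). `n_low` compensates the electronic
#'   threshold that hides events below `y_min`; `n_high` compensates the
#'   proton-edge calibration of the y scale.
#' @param y_split Boundary between the low- and high-LET components, keV/um
#'   (default 10); the high-LET component approximates the neutron H*(10).
#' @param y_min,y_max Integration bounds, keV/um (defaults 0.5 and 1024).
#' @param quality_function Function `Q(y)`; defaults to [quality_factor()].
#' @return A list of class `hawk_config`.
#' @export
hawk_config <- function(n_low = 1.1, n_high = 0.8, y_split = 10,
                        y_min = 0.5, y_max = 1024,
                        quality_function = quality_factor) {
  if (n_low <= 0 || n_high <= 0) {
    abort_invalid("Calibration factors must be positive.")
  }
  if (!(y_min < y_split && y_split < y_max)) {
    abort_invalid("Need y_min < y_split < y_max.")
  }
  if (!is.function(quality_function)) {
    abort_invalid("`quality_function` must be a function of y.")
  }
  structure(
    list(n_low = n_low, n_high = n_high, y_split = y_split,
         y_min = y_min, y_max = y_max, quality_function = quality_function),
    class = "hawk_config"
  )
}

#' Construct a lineal-energy dose spectrum d(y)
#'
#' Absorbed dose per lineal-energy bin, stored as absolute dose in Gy (not
#' normalised) so that quality-weighted sums yield Sv directly.
#'
#' @param y_low,y_high Bin edges, keV/um, strictly increasing and positive.
#' @param dose_Gy Non-negative absorbed dose per bin, Gy.
#' @return A tibble of class `lineal_energy_spectrum` with columns
#'   `y_low_keV_um`, `y_high_keV_um`, `dose_Gy`.
#' @export
lineal_energy_spectrum <- function(y_low, y_high, dose_Gy) {
  if (length(y_low) != length(y_high) || length(y_low) != length(dose_Gy)) {
    abort_invalid("`y_low`, `y_high`, `dose_Gy` must have equal lengths.")
  }
  if (length(y_low) > 0) {
    if (any(y_low <= 0) || any(y_high <= y_low)) {
      abort_invalid("Bin edges must be positive with y_low < y_high.")
    }
    if (any(diff(y_low) <= 0)) {
      abort_invalid("Bins must be ascending in lineal energy.")
    }
    if (any(!is.finite(dose_Gy)) || any(dose_Gy < 0)) {
      abort_invalid("Doses must be finite and non-negative.")
    }
  }
  out <- tibble(y_low_keV_um = as.double(y_low),
                y_high_keV_um = as.double(y_high),
                dose_Gy = as.double(dose_Gy))
  class(out) <- c("lineal_energy_spectrum", class(out))
  out
}

#' Dose equivalent by the single-event method
#'
#' Quality-weighted sums over a measured d(y) distribution:
#' `H*_low = N_low * sum(Q(y_i) d_i)` over bins with representative lineal
#' energy (geometric mean of the bin edges) between `y_min` and `y_split`,
#' `H*_high = N_high * sum(Q(y_i) d_i)` between `y_split` and `y_max`, and
#' `H* = H*_low + H*_high`. Dose below `y_min` is excluded (electronic
#' threshold); bins above `y_max` are an error. The high-LET component is
#' the conventional approximation of the neutron H*(10).
#'
#' @param spec A [lineal_energy_spectrum()].
#' @param cfg A [hawk_config()].
#' @return A one-row tibble with `h_low_Sv`, `h_high_Sv`, `h_total_Sv`.
#' @export
hawk_dose_equivalent <- function(spec, cfg = hawk_config()) {
  req <- c("y_low_keV_um", "y_high_keV_um", "dose_Gy")
  if (!is.data.frame(spec) || !all(req %in% names(spec))) {
    abort_invalid(paste0("`spec` needs columns ", paste(req, collapse = ", "), "."))
  }
  if (nrow(spec) == 0) {
    return(tibble(h_low_Sv = 0, h_high_Sv = 0, h_total_Sv = 0))
  }
  y_rep <- geomean(spec$y_low_keV_um, spec$y_high_keV_um)
  if (any(y_rep > cfg$y_max)) {
    abort_invalid(sprintf("Spectrum bins above y_max = %g keV/um.", cfg$y_max))
  }
  q <- cfg$quality_function(y_rep)
  low <- y_rep >= cfg$y_min & y_rep < cfg$y_split
  high <- y_rep >= cfg$y_split & y_rep <= cfg$y_max
  h_low <- cfg$n_low * sum(q[low] * spec$dose_Gy[low])
  h_high <- cfg$n_high * sum(q[high] * spec$dose_Gy[high])
  tibble(h_low_Sv = h_low, h_high_Sv = h_high, h_total_Sv = h_low + h_high)
}

# raw moments of a lognormal: E[y^k] = exp(k mu + k^2 sigma^2 / 2)
lnorm_moment <- function(mu, sigma, k) exp(k * mu + k^2 * sigma^2 / 2)

#' Simulate TEPC charge-integration intervals
#'
#' Generates a synthetic mixed photon/neutron event stream and the resulting
#' charge series: events arrive Poisson-distributed per interval, each with
#' a lineal energy drawn from a two-component lognormal mixture (photon-like
#' component with dose-mean lineal energy near 1.4 keV/um, neutron-like near
#' 96 keV/um). Event energy is `y * l_bar`; charge follows from W/e and the
#' gas gain. The returned truth is analytic: for this compound-Poisson
#' process the variance method recovers exactly the dose-weighted mean
#' lineal energy `E[y^2]/E[y]` of the mixture.
#'
#' @param photon_fraction Dose fraction carried by the photon-like
#'   component, in \[0, 1\].
#' @param n_intervals Number of integration intervals (>= 2).
#' @param event_rate Mean number of events per interval.
#' @param cfg A [tepc_config()].
#' @param seed Integer seed; the simulation is reproducible for a fixed seed.
#' @param photon_meanlog,photon_sdlog,neutron_meanlog,neutron_sdlog
#'   Lognormal parameters of the two components. Defaults place the
#'   dose-mean lineal energies `exp(mu + 1.5 sigma^2)` at 1.4 and
#'   96 keV/um.
#' @return A list with elements `series` (a [charge_series()]) and `truth`
#'   (one-row tibble with `d_mean_Gy`, `y_d_keV_um`, `d_gamma`).
#' @export
simulate_tepc_intervals <- function(photon_fraction, n_intervals,
                                    event_rate = 50, cfg = tepc_config(),
                                    seed = 1L,
                                    photon_sdlog = 0.5,
                                    photon_meanlog = log(1.4) - 1.5 * photon_sdlog^2,
                                    neutron_sdlog = 0.7,
                                    neutron_meanlog = log(96) - 1.5 * neutron_sdlog^2) {
  if (!is.numeric(photon_fraction) || length(photon_fraction) != 1 ||
      photon_fraction < 0 || photon_fraction > 1) {
    abort_invalid("`photon_fraction` must be a single value in [0, 1].")
  }
  if (n_intervals < 2) abort_invalid("Need at least 2 intervals.")
  if (event_rate <= 0) abort_invalid("`event_rate` must be positive.")

  mean_g <- lnorm_moment(photon_meanlog, photon_sdlog, 1)
  mean_n <- lnorm_moment(neutron_meanlog, neutron_sdlog, 1)
  # convert the requested dose fraction into an event-number weight
  w_g <- if (photon_fraction %in% c(0, 1)) photon_fraction else
    photon_fraction * mean_n /
      (photon_fraction * mean_n + (1 - photon_fraction) * mean_g)

  m1 <- w_g * mean_g + (1 - w_g) * mean_n
  m2 <- w_g * lnorm_moment(photon_meanlog, photon_sdlog, 2) +
    (1 - w_g) * lnorm_moment(neutron_meanlog, neutron_sdlog, 2)
  true_y_d <- m2 / m1
  # mean event energy in keV and true mean dose per interval
  mean_event_kev <- m1 * cfg$l_bar
  true_d_mean <- event_rate * mean_event_kev * .j_per_kev / cfg$m_det

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n_events <- stats::rpois(n_intervals, event_rate)
  total <- sum(n_events)
  is_gamma <- stats::runif(total) < w_g
  y <- numeric(total)
  y[is_gamma] <- stats::rlnorm(sum(is_gamma), photon_meanlog, photon_sdlog)
  y[!is_gamma] <- stats::rlnorm(sum(!is_gamma), neutron_meanlog, neutron_sdlog)
  energy_kev <- y * cfg$l_bar
  # charge per event: ion pairs = energy / (W/e), charge = pairs * e * gain
  q_event <- energy_kev * 1e3 / cfg$w_over_e * .e_charge * cfg$gas_gain
  idx <- rep(seq_len(n_intervals), n_events)
  q <- numeric(n_intervals)
  if (total > 0) {
    sums <- tapply(q_event, factor(idx, levels = seq_len(n_intervals)), sum)
    q <- as.double(ifelse(is.na(sums), 0, sums))
  }
  list(
    series = charge_series(q),
    truth = tibble(d_mean_Gy = true_d_mean, y_d_keV_um = true_y_d,
                   d_gamma = photon_fraction)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
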