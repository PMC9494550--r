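#' Build a lethargy-spaced energy grid
#'
#' Energy bin edges with constant logarithmic (lethargy) width
#' `ln(E_i / E_{i-1}) = lethargy_width`. Bins are half-open
#' `[E_{i-1}, E_i)`. The last edge is the first edge at or above `e_max`,
#' so the grid always covers `[e_min, e_max]`.
#'
#' @param e_min,e_max Grid span in MeV; both must be positive with
#'   `e_min < e_max`.
#' @param lethargy_width Constant bin width in lethargy (dimensionless),
#'   default 0.26.
#' @return Numeric vector of bin edges (length `n_bins + 1`), in MeV.
#' @examples
#' edges <- lethargy_grid(1e-9, 240)
#' diff(log(edges)) # all equal to 0.26
#' @export
lethargy_grid <- function(e_min, e_max, lethargy_width = 0.26) {
  if (!is.numeric(e_min) || !is.numeric(e_max) || length(e_min) != 1 ||
      length(e_max) != 1 || !is.finite(e_min) || !is.finite(e_max)) {
    abort_invalid("`e_min` and `e_max` must be single finite numbers.")
  }
  if (e_min <= 0 || e_max <= 0) {
    abort_invalid("Energies must be strictly positive (MeV).")
  }
  if (e_min >= e_max) {
    abort_invalid("`e_min` must be smaller than `e_max`.")
  }
  if (!is.numeric(lethargy_width) || length(lethargy_width) != 1 ||
      !is.finite(lethargy_width) || lethargy_width <= 0) {
    abort_invalid("`lethargy_width` must be a single positive number.")
  }
  # tolerate floating-point noise so an exact integer span stays exact
  n_bins <- ceiling(log(e_max / e_min) / lethargy_width - 1e-9)
  e_min * exp(lethargy_width * (0:n_bins))
}

check_edges <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2 || any(!is.finite(edges))) {
    abort_invalid("Energy bin edges must be a numeric vector of length >= 2.")
  }
  if (any(edges <= 0)) abort_invalid("Energy bin edges must be positive.")
  if (any(diff(edges) <= 0)) {
    abort_invalid("Energy bin edges must be strictly increasing.")
  }
  invisible(edges)
}

#' Construct a lethargy-binned neutron fluence spectrum
#'
#' The central data structure of the package: per-bin neutron fluence
#' (n/cm^2, integrated over the bin, not a density) per Gy of absorbed dose
#' in the target, on an energy grid of bin edges in MeV.
#'
#' @param edges Bin edges in MeV (length `n + 1`), strictly increasing and
#'   positive, e.g. from [lethargy_grid()].
#' @param fluence Per-bin fluence, n/cm^2 per Gy target dose (length `n`),
#'   non-negative and finite.
#' @param label Optional identifier (position or plan), stored as a column.
#' @return A tibble of class `neutron_spectrum` with columns `e_low_MeV`,
#'   `e_high_MeV`, `fluence_per_cm2_per_Gy` and, if given, `label`.
#' @export
neutron_spectrum <- function(edges, fluence, label = NULL) {
  check_edges(edges)
  n <- length(edges) - 1
  if (!is.numeric(fluence) || length(fluence) != n) {
    abort_invalid(sprintf(
      "`fluence` must be numeric with one value per bin (%d bins).", n
    ))
  }
  if (any(!is.finite(fluence))) abort_invalid("Fluence values must be finite.")
  if (any(fluence < 0)) abort_invalid("Fluence values must be non-negative.")
  out <- tibble(
    e_low_MeV = edges[-length(edges)],
    e_high_MeV = edges[-1],
    fluence_per_cm2_per_Gy = as.double(fluence)
  )
  if (!is.null(label)) out$label <- label
  class(out) <- c("neutron_spectrum", class(out))
  out
}

check_spectrum <- function(spectrum) {
  req <- c("e_low_MeV", "e_high_MeV", "fluence_per_cm2_per_Gy")
  if (!is.data.frame(spectrum) || !all(req %in% names(spectrum))) {
    abort_invalid(paste0(
      "A neutron spectrum needs columns ", paste(req, collapse = ", "), "."
    ))
  }
  if (nrow(spectrum) == 0) abort_invalid("Spectrum has no bins.")
  edges <- c(spectrum$e_low_MeV[1], spectrum$e_high_MeV)
  if (any(abs(spectrum$e_low_MeV[-1] - spectrum$e_high_MeV[-nrow(spectrum)]) >
          1e-12 * spectrum$e_high_MeV[-nrow(spectrum)])) {
    abort_invalid("Spectrum bins must be contiguous and ascending in energy.")
  }
  check_edges(edges)
  if (any(!is.finite(spectrum$fluence_per_cm2_per_Gy)) ||
      any(spectrum$fluence_per_cm2_per_Gy < 0)) {
    abort_invalid("Fluence values must be finite and non-negative.")
  }
  invisible(spectrum)
}

#' Per-lethargy view of a spectrum
#'
#' Divides each bin's fluence by its lethargy width `ln(E_hi/E_lo)`, the
#' conventional presentation for log-energy plots (equal areas then represent
#' equal fluence). [from_per_lethargy()] inverts the transformation.
#'
#' @param spectrum A `neutron_spectrum` tibble.
#' @return The input tibble with an added `fluence_per_lethargy` column.
#' @export
per_lethargy <- function(spectrum) {
  check_spectrum(spectrum)
  dplyr::mutate(
    spectrum,
    fluence_per_lethargy = .data$fluence_per_cm2_per_Gy /
      log(.data$e_high_MeV / .data$e_low_MeV)
  )
}

#' @rdname per_lethargy
#' @param x A tibble with `e_low_MeV`, `e_high_MeV` and
#'   `fluence_per_lethargy` columns.
#' @export
from_per_lethargy <- function(x) {
  req <- c("e_low_MeV", "e_high_MeV", "fluence_per_lethargy")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    abort_invalid(paste0("Need columns ", paste(req, collapse = ", "), "."))
  }
  neutron_spectrum(
    edges = c(x$e_low_MeV[1], x$e_high_MeV),
    fluence = x$fluence_per_lethargy * log(x$e_high_MeV / x$e_low_MeV),
    label = if ("label" %in% names(x)) x$label[1] else NULL
  )
}

#' Default neutron energy bands
#'
#' Conventional boundaries between the thermal, epithermal, evaporation and
#' high-energy (cascade) regions of a proton-therapy neutron spectrum. The
#' boundaries are a package choice (0.5 eV, 10 keV, 20 MeV) consistent with
#' the physics of moderated spectra; they are configurable because no
#' universal convention exists.
#'
#' @param e_min,e_max Outer limits of the banded region, MeV.
#' @return Tibble with columns `band`, `e_low_MeV`, `e_high_MeV`.
#' @export
default_neutron_bands <- function(e_min = 1e-9, e_max = 240) {
  tibble(
    band = c("thermal", "epithermal", "evaporation", "high_energy"),
    e_low_MeV = c(e_min, 5e-7, 1e-2, 20),
    e_high_MeV = c(5e-7, 1e-2, 20, e_max)
  )
}

#' Fluence fractions per energy band
#'
#' Assigns each spectrum bin to the band containing its geometric-mean
#' energy and reports the fluence fraction in each band. Over a full
#' partition of the grid span the fractions sum to one.
#'
#' @param spectrum A `neutron_spectrum` tibble.
#' @param bands Tibble with columns `band`, `e_low_MeV`, `e_high_MeV`
#'   describing disjoint intervals inside the grid span.
#' @return Tibble with columns `band` and `fraction`. For an all-zero
#'   spectrum the fractions are `NaN` and a warning is raised.
#' @export
band_fractions <- function(spectrum, bands = default_neutron_bands(
                             min(spectrum$e_low_MeV), max(spectrum$e_high_MeV)
                           )) {
  check_spectrum(spectrum)
  req <- c("band", "e_low_MeV", "e_high_MeV")
  if (!is.data.frame(bands) || !all(req %in% names(bands))) {
    abort_invalid("`bands` needs columns band, e_low_MeV, e_high_MeV.")
  }
  span <- c(min(spectrum$e_low_MeV), max(spectrum$e_high_MeV))
  if (any(bands$e_low_MeV < span[1] * (1 - 1e-12)) ||
      any(bands$e_high_MeV > span[2] * (1 + 1e-12))) {
    abort_invalid("All bands must lie inside the spectrum's energy span.")
  }
  if (any(bands$e_high_MeV <= bands$e_low_MeV)) {
    abort_invalid("Band intervals must have positive width.")
  }
  ord <- order(bands$e_low_MeV)
  if (any(bands$e_low_MeV[ord][-1] < bands$e_high_MeV[ord][-nrow(bands)] *
          (1 - 1e-12))) {
    abort_invalid("Band intervals must be disjoint.")
  }
  total <- sum(spectrum$fluence_per_cm2_per_Gy)
  e_rep <- geomean(spectrum$e_low_MeV, spectrum$e_high_MeV)
  in_band <- function(lo, hi) e_rep >= lo & e_rep < hi
  amount <- purrr::map2_dbl(bands$e_low_MeV, bands$e_high_MeV, function(lo, hi) {
    sum(spectrum$fluence_per_cm2_per_Gy[in_band(lo, hi)])
  })
  if (total == 0) {
    warn("Spectrum has zero total fluence; band fractions are NaN.")
    return(tibble(band = bands$band, fraction = NaN))
  }
  tibble(band = bands$band, fraction = amount / total)
}

#' Proton source as a set of energy layers
#'
#' A pencil-beam-scanning field is delivered as energy layers; each layer is
#' modelled as a Gaussian energy distribution with relative full width
#' `2 sigma = two_sigma_fraction` around the layer energy, weighted by the
#' layer weight.
#'
#' @param energy_MeV Layer energies, MeV; clinical PBS layers lie between
#'   60 and 250 MeV.
#' @param weight Non-negative layer weights with positive sum.
#' @param two_sigma_fraction Relative `2 sigma` of each layer's Gaussian
#'   energy spread (default 0.015, i.e. 1.5 %).
#' @return A tibble of class `proton_source` with columns `energy_MeV`,
#'   `weight`; `two_sigma_fraction` is kept as an attribute.
#' @export
proton_source <- function(energy_MeV, weight = rep(1, length(energy_MeV)),
                          two_sigma_fraction = 0.015) {
  if (length(energy_MeV) == 0) abort_invalid("A source needs at least one layer.")
  if (!is.numeric(energy_MeV) || any(!is.finite(energy_MeV))) {
    abort_invalid("Layer energies must be finite numbers (MeV).")
  }
  if (any(energy_MeV < 60) || any(energy_MeV > 250)) {
    abort_invalid("Layer energies must lie within 60-250 MeV.")
  }
  if (!is.numeric(weight) || length(weight) != length(energy_MeV) ||
      any(!is.finite(weight)) || any(weight < 0)) {
    abort_invalid("Layer weights must be non-negative and match the energies.")
  }
  if (sum(weight) <= 0) abort_invalid("Layer weights must have a positive sum.")
  if (!is.numeric(two_sigma_fraction) || length(two_sigma_fraction) != 1 ||
      two_sigma_fraction <= 0 || two_sigma_fraction > 1) {
    abort_invalid("`two_sigma_fraction` must be in (0, 1].")
  }
  out <- tibble(energy_MeV = as.double(energy_MeV), weight = as.double(weight))
  attr(out, "two_sigma_fraction") <- two_sigma_fraction
  class(out) <- c("proton_source", class(out))
  out
}

#' Minimum and maximum proton energy of a source
#'
#' Zero-weight layers are ignored.
#'
#' @param source A `proton_source` tibble.
#' @return Named numeric vector `c(min = ..., max = ...)`, MeV.
#' @export
source_energy_bounds <- function(source) {
  if (!is.data.frame(source) ||
      !all(c("energy_MeV", "weight") %in% names(source))) {
    abort_invalid("`source` needs columns energy_MeV and weight.")
  }
  active <- source$energy_MeV[source$weight > 0]
  if (length(active) == 0) {
    abort_invalid("All layer weights are zero; no active layers.")
  }
  c(min = min(active), max = max(active))
}

#' Shape parameters for the parametric neutron spectrum
#'
#' Parameterises the characteristic three-peak structure of neutron spectra
#' in proton therapy rooms: a thermal Maxwellian, a 1/E epithermal tail, an
#' evaporation Maxwellian (around 1 MeV) and a Gaussian cascade
#' ("high-energy") peak tied to the maximum proton energy. Amplitudes are
#' total fluences of each component (each component is normalised to unit
#' fluence on the grid before weighting).
#'
#' @param thermal_amplitude,epithermal_amplitude,evaporation_amplitude,highenergy_amplitude
#'   Relative component fluences, all >= 0, at least one > 0.
#' @param thermal_kT Thermal Maxwellian temperature, MeV (default
#'   2.585e-8 MeV = 0.02585 eV, room temperature).
#' @param evaporation_kT Evaporation Maxwellian temperature, MeV.
#' @param highenergy_center_fraction,highenergy_width_fraction Centre and
#'   standard deviation of the cascade Gaussian as fractions of the maximum
#'   proton energy, both in (0, 1].
#' @return A list of class `spectrum_shape`.
#' @export
spectrum_shape <- function(thermal_amplitude = 1,
                           epithermal_amplitude = 0.5,
                           evaporation_amplitude = 2,
                           highenergy_amplitude = 3,
                           thermal_kT = 2.585e-8,
                           evaporation_kT = 1,
                           highenergy_center_fraction = 0.6,
                           highenergy_width_fraction = 0.15) {
  amps <- c(thermal_amplitude, epithermal_amplitude,
            evaporation_amplitude, highenergy_amplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    abort_invalid("Component amplitudes must be finite and non-negative.")
  }
  if (sum(amps) <= 0) abort_invalid("At least one amplitude must be positive.")
  fr <- c(highenergy_center_fraction, highenergy_width_fraction)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr > 1)) {
    abort_invalid("Centre/width fractions must lie in (0, 1].")
  }
  if (thermal_kT <= 0 || evaporation_kT <= 0) {
    abort_invalid("Maxwellian temperatures must be positive.")
  }
  structure(
    list(
      thermal_amplitude = thermal_amplitude,
      epithermal_amplitude = epithermal_amplitude,
      evaporation_amplitude = evaporation_amplitude,
      highenergy_amplitude = highenergy_amplitude,
      thermal_kT = thermal_kT,
      evaporation_kT = evaporation_kT,
      highenergy_center_fraction = highenergy_center_fraction,
      highenergy_width_fraction = highenergy_width_fraction
    ),
    class = "spectrum_shape"
  )
}

# per-bin integral of a Maxwellian fluence density phi(E) ~ E exp(-E/kT):
# int_0^E phi dE = kT^2 * (1 - (1 + x) exp(-x)), x = E/kT
maxwellian_bin_fluence <- function(edges, kT) {
  cdf <- function(e) {
    x <- e / kT
    1 - (1 + x) * exp(-x)
  }
  diff(cdf(edges))
}

# per-bin integral of a 1/E density restricted to [lo, hi]
one_over_e_bin_fluence <- function(edges, lo, hi) {
  a <- pmin(pmax(edges[-length(edges)], lo), hi)
  b <- pmin(pmax(edges[-1], lo), hi)
  out <- log(b / a)
  out[b <= a] <- 0
  out
}

#' Synthesize a three-peak neutron fluence spectrum
#'
#' Deterministic parametric stand-in for a simulated or unfolded neutron
#' spectrum in a proton therapy room: thermal Maxwellian + 1/E epithermal
#' tail + evaporation Maxwellian + Gaussian cascade peak centred at
#' `highenergy_center_fraction` times the maximum proton energy. Each
#' component is normalised to unit fluence on the grid before weighting, so
#' the total fluence equals the sum of the amplitudes exactly. Fluence is
#' forced to zero above `E_max + 3` cascade-peak widths.
#'
#' @param source A [proton_source()]; only the maximum active layer energy
#'   enters the spectral shape.
#' @param shape A [spectrum_shape()].
#' @param grid Energy bin edges in MeV, e.g. [lethargy_grid()]. Must reach at
#'   least one peak width above the cascade-peak centre when the cascade
#'   amplitude is positive.
#' @return A `neutron_spectrum` tibble.
#' @export
synthesize_spectrum <- function(source, shape = spectrum_shape(),
                                grid = lethargy_grid(1e-9, 240)) {
  if (!inherits(shape, "spectrum_shape")) {
    abort_invalid("`shape` must be a spectrum_shape object.")
  }
  check_edges(grid)
  e_max <- source_energy_bounds(source)[["max"]]
  center <- shape$highenergy_center_fraction * e_max
  width <- shape$highenergy_width_fraction * e_max
  if (shape$highenergy_amplitude > 0 && max(grid) < center + width) {
    abort_invalid(paste0(
      "Grid does not cover the high-energy neutron peak (needs to reach ",
      signif(center + width, 4), " MeV)."
    ))
  }
  e_cut <- e_max + 3 * width
  components <- list(
    thermal = maxwellian_bin_fluence(grid, shape$thermal_kT),
    epithermal = one_over_e_bin_fluence(grid, 5e-7, 1e-2),
    evaporation = maxwellian_bin_fluence(grid, shape$evaporation_kT),
    highenergy = diff(stats::pnorm(grid, mean = center, sd = width))
  )
  amps <- c(shape$thermal_amplitude, shape$epithermal_amplitude,
            shape$evaporation_amplitude, shape$highenergy_amplitude)
  zero_above <- geomean(grid[-length(grid)], grid[-1]) > e_cut
  fluence <- rep(0, length(grid) - 1)
  for (k in seq_along(components)) {
    if (amps[k] == 0) next
    comp <- components[[k]]
    comp[zero_above] <- 0
    tot <- sum(comp)
    if (tot <= 0) {
      abort_invalid("A requested spectral component has no support on the grid.")
    }
    fluence <- fluence + amps[k] * comp / tot
  }
  neutron_spectrum(grid, fluence)
}
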