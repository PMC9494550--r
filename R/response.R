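#' Fluence-to-H*(10) conversion coefficient table
#'
#' Tabulated coefficients h*(E) in pSv cm^2 mapping neutron fluence to
#' ambient dose equivalent H*(10), evaluated between tabulated points by
#' log-log linear interpolation (both quantities vary over decades of
#' energy).
#'
#' @param energy_MeV Strictly increasing energies, MeV.
#' @param h10_pSv_cm2 Positive coefficients, pSv cm^2.
#' @return A tibble of class `conversion_table`.
#' @export
conversion_table <- function(energy_MeV, h10_pSv_cm2) {
  if (!is.numeric(energy_MeV) || !is.numeric(h10_pSv_cm2) ||
      length(energy_MeV) != length(h10_pSv_cm2) || length(energy_MeV) < 2) {
    abort_invalid("Need matching numeric energies and coefficients (>= 2 points).")
  }
  if (any(diff(energy_MeV) <= 0) || any(energy_MeV <= 0)) {
    abort_invalid("Energies must be positive and strictly increasing.")
  }
  if (any(!is.finite(h10_pSv_cm2)) || any(h10_pSv_cm2 <= 0)) {
    abort_invalid("Conversion coefficients must be positive and finite.")
  }
  out <- tibble(energy_MeV = as.double(energy_MeV),
                h10_pSv_cm2 = as.double(h10_pSv_cm2))
  class(out) <- c("conversion_table", class(out))
  out
}

#' The bundled fluence-to-H*(10) conversion table
#'
#' ICRP 74 neutron fluence to ambient dose equivalent coefficients, shipped
#' as a user-editable CSV and extended above 201 MeV to the 240 MeV
#' transport cutoff by explicitly flagged synthetic rows (the extension is a
#' data file, never hardcoded).
#'
#' @return A `conversion_table` tibble spanning 1e-9 to 240 MeV.
#' @export
default_conversion_table <- function() {
  path <- system.file("extdata", "icrp74_h10_conversion_extended.csv",
                      package = "neutrondose", mustWork = TRUE)
  read_conversion_csv(path)
}

# log-log linear interpolation with a linear-in-value fallback wherever a
# tabulated value is zero or negative (log undefined); x must be positive.
loglog_interp <- function(x, xp, yp) {
  if (any(x <= 0)) abort_invalid("Interpolation energies must be positive.")
  lx <- log(x)
  lxp <- log(xp)
  out <- numeric(length(x))
  idx <- findInterval(lx, lxp, rightmost.closed = TRUE, all.inside = TRUE)
  lo <- idx
  hi <- idx + 1L
  t <- (lx - lxp[lo]) / (lxp[hi] - lxp[lo])
  pos <- yp[lo] > 0 & yp[hi] > 0
  out[pos] <- exp((1 - t[pos]) * log(yp[lo[pos]]) + t[pos] * log(yp[hi[pos]]))
  out[!pos] <- (1 - t[!pos]) * yp[lo[!pos]] + t[!pos] * yp[hi[!pos]]
  out
}

#' Ambient-neutron-monitor H*(10) energy response function
#'
#' A monitor's reading per unit true H*(10) as a function of neutron energy
#' (ideal is unity). Within `valid_range` but outside the tabulated span the
#' response extends as a constant at the edge value; evaluating non-zero
#' fluence outside `valid_range` is an error (a silent zero would fabricate
#' cutoff behaviour).
#'
#' @param monitor_id Monitor name, e.g. `"wendi2"`.
#' @param energy_MeV Strictly increasing tabulated energies, MeV.
#' @param response Non-negative dimensionless responses.
#' @param valid_range Length-2 numeric range (MeV) within the tabulated span.
#' @return A list of class `response_function`.
#' @export
response_function <- function(monitor_id, energy_MeV, response,
                              valid_range = range(energy_MeV)) {
  if (!is.character(monitor_id) || length(monitor_id) != 1) {
    abort_invalid("`monitor_id` must be a single string.")
  }
  if (!is.numeric(energy_MeV) || !is.numeric(response) ||
      length(energy_MeV) != length(response) || length(energy_MeV) < 2) {
    abort_invalid("Need matching numeric energies and responses (>= 2 points).")
  }
  if (any(diff(energy_MeV) <= 0) || any(energy_MeV <= 0)) {
    abort_invalid("Energies must be positive and strictly increasing.")
  }
  if (any(!is.finite(response)) || any(response < 0)) {
    abort_invalid("Responses must be finite and non-negative.")
  }
  if (length(valid_range) != 2 || valid_range[1] >= valid_range[2] ||
      valid_range[1] < min(energy_MeV) * (1 - 1e-9) ||
      valid_range[2] > max(energy_MeV) * (1 + 1e-9)) {
    abort_invalid("`valid_range` must be an increasing range within the tabulated span.")
  }
  structure(
    list(
      monitor_id = monitor_id,
      table = tibble(energy_MeV = as.double(energy_MeV),
                     response = as.double(response)),
      valid_range = as.double(valid_range)
    ),
    class = "response_function"
  )
}

# evaluate R(E); caller has already checked E against valid_range
response_at <- function(rf, energy) {
  e <- pmin(pmax(energy, min(rf$table$energy_MeV)), max(rf$table$energy_MeV))
  loglog_interp(e, rf$table$energy_MeV, rf$table$response)
}

spectrum_rep_energies <- function(spectrum) {
  geomean(spectrum$e_low_MeV, spectrum$e_high_MeV)
}

check_span <- function(e_rep, fluence, lo, hi, what) {
  active <- fluence > 0
  if (any(active & (e_rep < lo | e_rep > hi))) {
    abort_invalid(sprintf(
      "Non-zero fluence outside the %s span (%g-%g MeV).", what, lo, hi
    ))
  }
}

#' Ambient dose equivalent of a neutron spectrum
#'
#' Folds a fluence spectrum with fluence-to-H*(10) conversion coefficients:
#' `H = sum_i fluence_i h*(E_i)` with `E_i` the geometric-mean bin energy,
#' converted from pSv to uSv.
#'
#' @param spectrum A `neutron_spectrum` tibble.
#' @param table A [conversion_table()]; must span all bins carrying fluence.
#' @return H*(10) in uSv per Gy target dose (single number).
#' @export
h10_from_spectrum <- function(spectrum, table = default_conversion_table()) {
  check_spectrum(spectrum)
  e_rep <- spectrum_rep_energies(spectrum)
  fl <- spectrum$fluence_per_cm2_per_Gy
  check_span(e_rep, fl, min(table$energy_MeV), max(table$energy_MeV),
             "conversion-table")
  active <- fl > 0
  if (!any(active)) return(0)
  h <- loglog_interp(e_rep[active], table$energy_MeV, table$h10_pSv_cm2)
  sum(fl[active] * h) * 1e-6
}

#' Expected monitor response to a neutron spectrum
#'
#' The H*(10)-weighted mean of the monitor's energy response over the
#' spectrum: `sum(fluence h* R) / sum(fluence h*)`. This is the factor by
#' which the monitor's reading deviates from the true H*(10) in that field;
#' it is invariant under uniform rescaling of the spectrum.
#'
#' @param spectrum A non-zero `neutron_spectrum`.
#' @param rf A [response_function()] whose `valid_range` covers all bins
#'   carrying fluence.
#' @param table A [conversion_table()].
#' @return Dimensionless expected response (single number).
#' @export
expected_monitor_response <- function(spectrum, rf,
                                      table = default_conversion_table()) {
  check_spectrum(spectrum)
  if (!inherits(rf, "response_function")) {
    abort_invalid("`rf` must be a response_function.")
  }
  fl <- spectrum$fluence_per_cm2_per_Gy
  if (sum(fl) == 0) {
    abort_invalid("Cannot compute an expected response for an all-zero spectrum.")
  }
  e_rep <- spectrum_rep_energies(spectrum)
  check_span(e_rep, fl, min(table$energy_MeV), max(table$energy_MeV),
             "conversion-table")
  check_span(e_rep, fl, rf$valid_range[1], rf$valid_range[2],
             paste0("monitor '", rf$monitor_id, "' valid"))
  active <- fl > 0
  h <- loglog_interp(e_rep[active], table$energy_MeV, table$h10_pSv_cm2)
  w <- fl[active] * h
  r <- response_at(rf, e_rep[active])
  sum(w * r) / sum(w)
}

#' Predicted monitor reading for a neutron spectrum
#'
#' The H*(10) a monitor would report in the given field: the true H*(10)
#' of the spectrum times the expected monitor response, i.e. the convolution
#' of the H*(10) energy spectrum with the monitor response function.
#'
#' @inheritParams expected_monitor_response
#' @return Predicted reading in uSv per Gy target dose.
#' @export
predict_reading <- function(spectrum, rf, table = default_conversion_table()) {
  h10_from_spectrum(spectrum, table) *
    expected_monitor_response(spectrum, rf, table)
}

#' Simulated-over-measured H*(10) ratio summary
#'
#' Joins a simulated and a measured campaign table on
#' `(irradiation_id, position)`, forms per-irradiation ratios, averages them
#' per position (arithmetic mean) and reports the grand average as the mean
#' of the position averages. Rows present in only one table are skipped and
#' counted.
#'
#' @param sim,meas Campaign tibbles with columns `irradiation_id`,
#'   `position`, `h10_uSv_per_Gy` (measured values must be positive).
#' @param case Comparison label, one of `"no_room"`, `"with_room"`,
#'   `"no_room_energy_corrected"`.
#' @return A tibble with one row per position (`position`, `n`,
#'   `mean_ratio`, `case`) plus attributes `grand_average` and `n_skipped`.
#' @export
ratio_summary <- function(sim, meas,
                          case = c("no_room", "with_room",
                                   "no_room_energy_corrected")) {
  case <- match.arg(case)
  req <- c("irradiation_id", "position", "h10_uSv_per_Gy")
  for (nm in list(sim = sim, meas = meas)) {
    if (!is.data.frame(nm) || !all(req %in% names(nm))) {
      abort_invalid(paste0(
        "Campaign tables need columns ", paste(req, collapse = ", "), "."
      ))
    }
  }
  if (any(meas$h10_uSv_per_Gy <= 0) || any(sim$h10_uSv_per_Gy <= 0)) {
    abort_invalid("H*(10) values must be strictly positive.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(sim, "irradiation_id", "position", sim = "h10_uSv_per_Gy"),
    dplyr::select(meas, "irradiation_id", "position", meas = "h10_uSv_per_Gy"),
    by = c("irradiation_id", "position")
  )
  if (nrow(joined) == 0) {
    abort_invalid("No overlapping (irradiation_id, position) keys.")
  }
  n_skipped <- nrow(sim) + nrow(meas) - 2 * nrow(joined)
  out <- joined |>
    dplyr::mutate(ratio = sim / meas) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(n = dplyr::n(), mean_ratio = mean(.data$ratio),
                     .groups = "drop") |>
    dplyr::arrange(.data$position) |>
    dplyr::mutate(case = case)
  attr(out, "grand_average") <- mean(out$mean_ratio)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Load a bundled monitor response function
#'
#' The package ships stylized synthetic response curves for the monitor
#' types commonly deployed around proton therapy rooms (moderated counters
#' with and without high-energy extension, and TEPC-based instruments),
#' registered in `inst/extdata/monitors.yaml`. They reproduce the
#' qualitative features of published curves (thermal under-response,
#' epithermal over-response of moderated counters, high-energy cutoff of
#' conventional counters) and are fixtures for testing and demonstration,
#' not metrological data.
#'
#' @param monitor_id One of the ids in [list_monitors()].
#' @param registry Path to a YAML registry mapping monitor ids to response
#'   CSV files and valid ranges; defaults to the bundled registry.
#' @return A [response_function()].
#' @export
load_monitor <- function(monitor_id, registry = NULL) {
  reg_path <- registry %||% system.file("extdata", "monitors.yaml",
                                        package = "neutrondose", mustWork = TRUE)
  reg <- yaml::read_yaml(reg_path)
  if (!monitor_id %in% names(reg)) {
    abort_invalid(sprintf(
      "Unknown monitor '%s'; available: %s.", monitor_id,
      paste(names(reg), collapse = ", ")
    ))
  }
  entry <- reg[[monitor_id]]
  path <- entry$file
  if (!file.exists(path)) {
    path <- system.file("extdata", entry$file, package = "neutrondose",
                        mustWork = TRUE)
  }
  tab <- read_response_csv(path)
  response_function(monitor_id, tab$energy_MeV, tab$response,
                    valid_range = as.double(unlist(entry$valid_range)))
}

#' @rdname load_monitor
#' @export
list_monitors <- function(registry = NULL) {
  reg_path <- registry %||% system.file("extdata", "monitors.yaml",
                                        package = "neutrondose", mustWork = TRUE)
  names(yaml::read_yaml(reg_path))
}
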