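# line-by-line CSV reading so parse errors can name the offending line;
# '#' lines and blank lines are ignored, the header is mandatory
read_dialect_csv <- function(path, columns) {
  if (!file.exists(path)) abort_parse(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) abort_parse(sprintf("%s: no content lines.", path))
  header <- strsplit(trimws(lines[idx[1]]), ",")[[1]]
  if (!identical(trimws(header), columns)) {
    abort_parse(sprintf(
      "%s line %d: header must be exactly '%s'.",
      path, idx[1], paste(columns, collapse = ",")
    ))
  }
  body_idx <- idx[-1]
  if (length(body_idx) == 0) {
    abort_parse(sprintf("%s: no data rows.", path))
  }
  fields <- strsplit(trimws(lines[body_idx]), ",")
  bad <- which(lengths(fields) != length(columns))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "%s line %d: expected %d comma-separated fields.",
      path, body_idx[bad[1]], length(columns)
    ))
  }
  mat <- do.call(rbind, fields)
  out <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                            columns))
  attr(out, "line_numbers") <- body_idx
  out
}

parse_numeric_col <- function(x, path, lines, col) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) & !(trimws(x) %in% c("NA", "")))
  nas <- trimws(x) %in% c("NA", "")
  val[nas] <- NA_real_
  bad <- which(is.na(val) & !nas)
  if (length(bad) > 0) {
    abort_parse(sprintf("%s line %d: '%s' is not a number (column %s).",
                        path, lines[bad[1]], x[bad[1]], col))
  }
  val
}

fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Read and write neutron spectrum CSV files
#'
#' Dialect: mandatory header
#' `e_low_MeV,e_high_MeV,fluence_per_cm2_per_Gy`, `#` comment lines allowed,
#' rows ascending in energy. Reading then writing round-trips exactly
#' (values are serialised with 17 significant digits).
#'
#' @param path File path.
#' @return `read_spectrum_csv()` returns a `neutron_spectrum` tibble;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  cols <- c("e_low_MeV", "e_high_MeV", "fluence_per_cm2_per_Gy")
  raw <- read_dialect_csv(path, cols)
  lines <- attr(raw, "line_numbers")
  e_lo <- parse_numeric_col(raw$e_low_MeV, path, lines, "e_low_MeV")
  e_hi <- parse_numeric_col(raw$e_high_MeV, path, lines, "e_high_MeV")
  fl <- parse_numeric_col(raw$fluence_per_cm2_per_Gy, path, lines,
                          "fluence_per_cm2_per_Gy")
  bad <- which(e_hi <= e_lo)
  if (length(bad) > 0) {
    abort_parse(sprintf("%s line %d: e_high_MeV must exceed e_low_MeV.",
                        path, lines[bad[1]]))
  }
  if (length(e_lo) > 1) {
    bad <- which(abs(e_lo[-1] - e_hi[-length(e_hi)]) >
                   1e-12 * e_hi[-length(e_hi)])
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "%s line %d: bins must be contiguous and ascending in energy.",
        path, lines[bad[1] + 1]
      ))
    }
  }
  bad <- which(fl < 0)
  if (length(bad) > 0) {
    abort_parse(sprintf("%s line %d: negative fluence.", path, lines[bad[1]]))
  }
  neutron_spectrum(c(e_lo[1], e_hi), fl)
}

#' @rdname read_spectrum_csv
#' @param spectrum A `neutron_spectrum` tibble.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  check_spectrum(spectrum)
  writeLines(c(
    "e_low_MeV,e_high_MeV,fluence_per_cm2_per_Gy",
    sprintf("%s,%s,%s", fmt(spectrum$e_low_MeV), fmt(spectrum$e_high_MeV),
            fmt(spectrum$fluence_per_cm2_per_Gy))
  ), path)
  invisible(path)
}

#' Read a proton-layer list
#'
#' Minimal surrogate for a TPS layer export: header `energy_MeV,weight`,
#' `#` comments allowed.
#'
#' @param path File path.
#' @param two_sigma_fraction Relative Gaussian energy spread per layer.
#' @return A [proton_source()].
#' @export
read_layer_csv <- function(path, two_sigma_fraction = 0.015) {
  raw <- read_dialect_csv(path, c("energy_MeV", "weight"))
  lines <- attr(raw, "line_numbers")
  e <- parse_numeric_col(raw$energy_MeV, path, lines, "energy_MeV")
  w <- parse_numeric_col(raw$weight, path, lines, "weight")
  proton_source(e, w, two_sigma_fraction = two_sigma_fraction)
}

#' Read a fluence-to-H*(10) conversion table CSV
#'
#' Dialect: header `energy_MeV,h10_pSv_cm2`, `#` comments allowed.
#'
#' @param path File path.
#' @return A [conversion_table()].
#' @export
read_conversion_csv <- function(path) {
  raw <- read_dialect_csv(path, c("energy_MeV", "h10_pSv_cm2"))
  lines <- attr(raw, "line_numbers")
  e <- parse_numeric_col(raw$energy_MeV, path, lines, "energy_MeV")
  h <- parse_numeric_col(raw$h10_pSv_cm2, path, lines, "h10_pSv_cm2")
  conversion_table(e, h)
}

#' Read a monitor response CSV
#'
#' Dialect: header `energy_MeV,response`, `#` comments allowed.
#'
#' @param path File path.
#' @return A tibble with columns `energy_MeV`, `response`.
#' @export
read_response_csv <- function(path) {
  raw <- read_dialect_csv(path, c("energy_MeV", "response"))
  lines <- attr(raw, "line_numbers")
  tibble(
    energy_MeV = parse_numeric_col(raw$energy_MeV, path, lines, "energy_MeV"),
    response = parse_numeric_col(raw$response, path, lines, "response")
  )
}

#' Read a lineal-energy dose spectrum CSV
#'
#' Dialect: header `y_low_keV_um,y_high_keV_um,dose_Gy`, `#` comments
#' allowed.
#'
#' @param path File path.
#' @return A [lineal_energy_spectrum()].
#' @export
read_lineal_csv <- function(path) {
  cols <- c("y_low_keV_um", "y_high_keV_um", "dose_Gy")
  raw <- read_dialect_csv(path, cols)
  lines <- attr(raw, "line_numbers")
  lineal_energy_spectrum(
    parse_numeric_col(raw$y_low_keV_um, path, lines, cols[1]),
    parse_numeric_col(raw$y_high_keV_um, path, lines, cols[2]),
    parse_numeric_col(raw$dose_Gy, path, lines, cols[3])
  )
}

campaign_cols <- c("irradiation_id", "field_size_cm2", "range_cm",
                   "modulation_cm", "range_shifter", "air_gap_cm",
                   "position", "h10_uSv_per_Gy", "rel_uncertainty")

#' Read and write campaign CSV files
#'
#' Dialect: mandatory header `irradiation_id,field_size_cm2,range_cm,`
#' `modulation_cm,range_shifter,air_gap_cm,position,h10_uSv_per_Gy,`
#' `rel_uncertainty`; `#` comments allowed; `range_shifter` accepts
#' 0/1/true/false/yes/no (canonicalised to logical); duplicate
#' `(irradiation_id, position)` keys are an error.
#'
#' @param path File path.
#' @return `read_campaign_csv()` returns a campaign tibble;
#'   `write_campaign_csv()` returns `path` invisibly.
#' @export
read_campaign_csv <- function(path) {
  raw <- read_dialect_csv(path, campaign_cols)
  lines <- attr(raw, "line_numbers")
  rs_raw <- tolower(trimws(raw$range_shifter))
  valid <- rs_raw %in% c("0", "1", "true", "false", "yes", "no")
  if (any(!valid)) {
    abort_parse(sprintf(
      "%s line %d: range_shifter must be one of 0,1,true,false,yes,no.",
      path, lines[which(!valid)[1]]
    ))
  }
  out <- tibble(
    irradiation_id = trimws(raw$irradiation_id),
    field_size_cm2 = parse_numeric_col(raw$field_size_cm2, path, lines,
                                       "field_size_cm2"),
    range_cm = parse_numeric_col(raw$range_cm, path, lines, "range_cm"),
    modulation_cm = parse_numeric_col(raw$modulation_cm, path, lines,
                                      "modulation_cm"),
    range_shifter = rs_raw %in% c("1", "true", "yes"),
    air_gap_cm = parse_numeric_col(raw$air_gap_cm, path, lines, "air_gap_cm"),
    position = trimws(raw$position),
    h10_uSv_per_Gy = parse_numeric_col(raw$h10_uSv_per_Gy, path, lines,
                                       "h10_uSv_per_Gy"),
    rel_uncertainty = parse_numeric_col(raw$rel_uncertainty, path, lines,
                                        "rel_uncertainty")
  )
  key <- paste(out$irradiation_id, out$position, sep = "/")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort_parse(sprintf("%s line %d: duplicate key (%s).",
                        path, lines[dup[1]], key[dup[1]]))
  }
  if (any(out$h10_uSv_per_Gy <= 0)) {
    bad <- which(out$h10_uSv_per_Gy <= 0)[1]
    abort_parse(sprintf("%s line %d: H*(10) must be positive.",
                        path, lines[bad]))
  }
  out
}

#' @rdname read_campaign_csv
#' @param campaign A campaign tibble (see [read_campaign_csv()] for
#'   columns).
#' @export
write_campaign_csv <- function(campaign, path) {
  missing_cols <- setdiff(campaign_cols, names(campaign))
  if ("rel_uncertainty" %in% missing_cols) campaign$rel_uncertainty <- 0
  if ("air_gap_cm" %in% missing_cols) campaign$air_gap_cm <- NA_real_
  missing_cols <- setdiff(campaign_cols, names(campaign))
  if (length(missing_cols) > 0) {
    abort_invalid(paste0("Campaign is missing columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  writeLines(c(
    paste(campaign_cols, collapse = ","),
    sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s",
            campaign$irradiation_id,
            fmt(campaign$field_size_cm2), fmt(campaign$range_cm),
            fmt(campaign$modulation_cm),
            ifelse(campaign$range_shifter, "true", "false"),
            fmt(campaign$air_gap_cm), campaign$position,
            fmt(campaign$h10_uSv_per_Gy), fmt(campaign$rel_uncertainty))
  ), path)
  invisible(path)
}

#' Write and read a scaling model as YAML
#'
#' The file stores all coefficients, the reference plan, the range-shifter
#' mode and a provenance block (package version); it is the exchange format
#' between fitting and prediction.
#'
#' @param model A [scaling_model()].
#' @param path File path.
#' @return `write_model_yaml()` returns `path` invisibly;
#'   `read_model_yaml()` returns a [scaling_model()].
#' @export
write_model_yaml <- function(model, path) {
  if (!inherits(model, "scaling_model")) {
    abort_invalid("`model` must be a scaling_model.")
  }
  obj <- list(
    provenance = list(
      package = "neutrondose",
      version = as.character(utils::packageVersion("neutrondose"))
    ),
    reference_plan = list(
      field_size_cm2 = model$ref_area,
      range_cm = model$ref_range,
      modulation_cm = model$ref_modulation
    ),
    range_shifter = list(mode = model$rs_mode, flat_factor = model$rs_factor),
    coefficients = purrr::pmap(model$coefficients, function(position, a0,
                                                            c_r, c_m1, c_m2) {
      list(position = position, a0 = a0, c_r = c_r, c_m1 = c_m1, c_m2 = c_m2)
    })
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("File not found: %s", path))
  obj <- yaml::read_yaml(path)
  co <- dplyr::bind_rows(purrr::map(obj$coefficients, as_tibble))
  scaling_model(
    co,
    ref_area = obj$reference_plan$field_size_cm2,
    ref_range = obj$reference_plan$range_cm,
    ref_modulation = obj$reference_plan$modulation_cm,
    rs_mode = obj$range_shifter$mode,
    rs_factor = obj$range_shifter$flat_factor
  )
}
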