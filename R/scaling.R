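#' Construct a treatment-plan table
#'
#' One row per irradiation plan. Validation follows the domain covered by
#' typical PBS measurement campaigns: field size 9-625 cm^2, range 8-25 cm,
#' modulation 3-25 cm (and never exceeding the range), air gap 5.5-23 cm
#' when a range shifter is used. Values outside the domain raise a warning
#' (the model extrapolates) unless `strict = TRUE`; a modulation larger than
#' the range is always an error.
#'
#' @param field_size_cm2 Field size, cm^2.
#' @param range_cm Proton range in water, cm.
#' @param modulation_cm SOBP modulation width, cm.
#' @param range_shifter Logical, range shifter in the beam.
#' @param air_gap_cm Air gap between range shifter and phantom, cm
#'   (only meaningful with `range_shifter = TRUE`).
#' @param rs_wet_cm Water-equivalent thickness of the range shifter, cm
#'   (default 3.1).
#' @param strict Error instead of warning outside the plan domain.
#' @return A tibble of class `treatment_plan`, one row per plan.
#' @export
treatment_plan <- function(field_size_cm2, range_cm, modulation_cm,
                           range_shifter = FALSE, air_gap_cm = NA_real_,
                           rs_wet_cm = 3.1, strict = FALSE) {
  plans <- tibble(
    field_size_cm2 = as.double(field_size_cm2),
    range_cm = as.double(range_cm),
    modulation_cm = as.double(modulation_cm),
    range_shifter = as.logical(range_shifter),
    air_gap_cm = as.double(air_gap_cm),
    rs_wet_cm = as.double(rs_wet_cm)
  )
  validate_plans(plans, strict = strict)
  class(plans) <- c("treatment_plan", class(plans))
  plans
}

validate_plans <- function(plans, strict = FALSE) {
  req <- c("field_size_cm2", "range_cm", "modulation_cm", "range_shifter")
  if (!is.data.frame(plans) || !all(req %in% names(plans))) {
    abort_invalid(paste0("Plans need columns ", paste(req, collapse = ", "), "."))
  }
  with(plans, {
    if (any(!is.finite(field_size_cm2)) || any(field_size_cm2 <= 0) ||
        any(!is.finite(range_cm)) || any(range_cm <= 0) ||
        any(!is.finite(modulation_cm)) || any(modulation_cm <= 0)) {
      abort_invalid("Field size, range and modulation must be positive.")
    }
    if (any(modulation_cm > range_cm)) {
      abort_invalid("Modulation width cannot exceed the range.")
    }
    outside <- field_size_cm2 < 9 | field_size_cm2 > 625 |
      range_cm < 8 | range_cm > 25 | modulation_cm < 3 | modulation_cm > 25
    gap <- if ("air_gap_cm" %in% names(plans)) plans$air_gap_cm else NA_real_
    gap_bad <- range_shifter & !is.na(gap) & (gap < 5.5 | gap > 23)
    if (any(outside | gap_bad)) {
      msg <- sprintf(
        "%d plan(s) outside the supported domain (field 9-625 cm^2, range 8-25 cm, modulation 3-25 cm, air gap 5.5-23 cm).",
        sum(outside | gap_bad)
      )
      if (strict) abort_invalid(msg) else warn(msg)
    }
  })
  invisible(plans)
}

#' Measurement positions around the phantom
#'
#' Positions are labelled A-F, ordered by distance from the isocenter and,
#' at equal distance, by angle to the beam direction. Published distances:
#' B at 1 m in the beam direction, F at 1.5 m perpendicular, D and E at
#' 2.25 m (perpendicular and backward). Distances and angles for A and C
#' are placeholders (`NA`) requiring user input.
#'
#' @return A tibble with columns `position`, `distance_m`, `angle_deg`.
#' @export
default_positions <- function() {
  tibble(
    position = c("A", "B", "C", "D", "E", "F"),
    distance_m = c(NA, 1.0, NA, 2.25, 2.25, 1.5),
    angle_deg = c(NA, 0, NA, 90, 180, 90)
  )
}

#' Per-position multiplicative scaling-law model of out-of-field H*(10)
#'
#' Encodes the empirical dependence of out-of-field neutron H*(10) on
#' treatment-plan parameters: exactly linear in field-size area, linear in
#' (effective) range, quadratic in modulation width, all normalised to a
#' reference plan so that the baseline `a0` is the prediction at the
#' reference plan:
#'
#' `H = a0 * (FS / ref_area) * (1 + c_r (R_eff - ref_range)) *
#'      m(M) / m(ref_mod)` with `m(M) = 1 + c_m1 M + c_m2 M^2`.
#'
#' A range shifter either increases the effective range by its
#' water-equivalent thickness (`rs_mode = "effective_range"`, the physical
#' first approximation) or multiplies the prediction by a flat factor
#' (`rs_mode = "flat_factor"`, the empirical average of about two).
#'
#' @param coefficients Tibble with columns `position`, `a0` (uSv/Gy at the
#'   reference plan), `c_r` (per cm), `c_m1` (per cm), `c_m2` (per cm^2).
#' @param ref_area Reference field size, cm^2 (default 100).
#' @param ref_range,ref_modulation Reference range and modulation, cm
#'   (defaults 15 and 10).
#' @param rs_mode `"effective_range"` or `"flat_factor"`.
#' @param rs_factor Flat range-shifter factor (default 2), used only in
#'   `"flat_factor"` mode.
#' @return A list of class `scaling_model`.
#' @export
scaling_model <- function(coefficients, ref_area = 100, ref_range = 15,
                          ref_modulation = 10,
                          rs_mode = c("effective_range", "flat_factor"),
                          rs_factor = 2) {
  rs_mode <- match.arg(rs_mode)
  req <- c("position", "a0", "c_r", "c_m1", "c_m2")
  if (!is.data.frame(coefficients) || !all(req %in% names(coefficients))) {
    abort_invalid(paste0(
      "`coefficients` needs columns ", paste(req, collapse = ", "), "."
    ))
  }
  if (any(coefficients$a0 <= 0)) {
    abort_invalid("Baselines `a0` must be strictly positive.")
  }
  if (anyDuplicated(coefficients$position)) {
    abort_invalid("Duplicate position labels in `coefficients`.")
  }
  structure(
    list(
      coefficients = as_tibble(coefficients[req]),
      ref_area = ref_area, ref_range = ref_range,
      ref_modulation = ref_modulation,
      rs_mode = rs_mode, rs_factor = rs_factor
    ),
    class = "scaling_model"
  )
}

#' Default scaling-law model
#'
#' A fixture model whose per-position coefficients echo the qualitative
#' behaviour reported for PBS treatment rooms: doses from ~1 uSv/Gy
#' (position D, distant and perpendicular) to ~66 uSv/Gy (position B, 1 m in
#' the beam direction) at the reference plan; range factors of 2-8 over
#' 10-25 cm; a 35-60 % modulation effect over 3-20 cm; and a range-shifter
#' ratio bounded by about 2.5 except at position D. The numbers are
#' synthetic defaults for simulation and testing, not facility
#' characterisations.
#'
#' @return A [scaling_model()].
#' @export
default_scaling_model <- function() {
  scaling_model(
    tibble(
      position = c("A", "B", "C", "D", "E", "F"),
      a0 = c(12, 66, 25, 1, 3, 8),
      c_r = c(0.08, 0.055, 0.07, 0.12, 0.10, 0.09),
      c_m1 = c(0.040, 0.038, 0.042, 0.045, 0.040, 0.036),
      c_m2 = c(-7e-4, -6e-4, -8e-4, -9e-4, -7e-4, -6e-4)
    )
  )
}

#' Effective proton range of a plan
#'
#' With a range shifter in the beam the protons start with the energy of a
#' deeper-range plan; to first approximation the effective range is the
#' nominal range plus the water-equivalent thickness of the range shifter.
#'
#' @param plans Treatment-plan tibble (needs `range_cm`, `range_shifter`,
#'   and optionally `rs_wet_cm`, default 3.1).
#' @return Numeric vector of effective ranges, cm.
#' @export
effective_range <- function(plans) {
  if (!is.data.frame(plans) ||
      !all(c("range_cm", "range_shifter") %in% names(plans))) {
    abort_invalid("`plans` needs columns range_cm and range_shifter.")
  }
  wet <- if ("rs_wet_cm" %in% names(plans)) plans$rs_wet_cm else 3.1
  wet[is.na(wet)] <- 3.1
  plans$range_cm + ifelse(plans$range_shifter, wet, 0)
}

model_coefs_at <- function(model, position) {
  co <- model$coefficients[model$coefficients$position == position, ]
  if (nrow(co) != 1) {
    abort_invalid(sprintf("Model has no coefficients for position '%s'.", position))
  }
  co
}

mod_term <- function(m, c_m1, c_m2) 1 + c_m1 * m + c_m2 * m^2

#' Predict out-of-field neutron H*(10) for treatment plans
#'
#' Applies the multiplicative scaling law of a [scaling_model()] at one
#' position. Predictions are exactly linear in field-size area. The air gap
#' between range shifter and phantom has no significant effect on H*(10)
#' at the modelled positions and is deliberately ignored (a message is
#' emitted when non-missing air gaps are present).
#'
#' @param plans Treatment-plan tibble (see [treatment_plan()]); may carry a
#'   `position` column if `position` is not given.
#' @param model A [scaling_model()].
#' @param position Position label; overrides any `position` column.
#' @param quiet Suppress the air-gap message.
#' @return The input tibble with an added `h10_uSv_per_Gy` column.
#' @export
predict_h10 <- function(plans, model, position = NULL, quiet = FALSE) {
  if (!inherits(model, "scaling_model")) {
    abort_invalid("`model` must be a scaling_model.")
  }
  validate_plans(plans)
  pos <- position %||%
    (if ("position" %in% names(plans)) plans$position else
       abort_invalid("Provide `position` or a position column."))
  if (!quiet && "air_gap_cm" %in% names(plans) &&
      any(!is.na(plans$air_gap_cm))) {
    inform(paste0(
      "Air gap has no significant effect on out-of-field neutron H*(10) ",
      "at the modelled positions and is ignored by the scaling law."
    ))
  }
  pos <- rep_len(pos, nrow(plans))
  co <- model$coefficients[match(pos, model$coefficients$position), ]
  if (any(is.na(co$a0))) {
    abort_invalid(sprintf(
      "Model has no coefficients for position(s): %s.",
      paste(unique(pos[is.na(co$a0)]), collapse = ", ")
    ))
  }
  r_eff <- if (model$rs_mode == "effective_range") effective_range(plans) else
    plans$range_cm
  r_term <- 1 + co$c_r * (r_eff - model$ref_range)
  m_ratio <- mod_term(plans$modulation_cm, co$c_m1, co$c_m2) /
    mod_term(model$ref_modulation, co$c_m1, co$c_m2)
  h <- co$a0 * (plans$field_size_cm2 / model$ref_area) * r_term * m_ratio
  if (model$rs_mode == "flat_factor") {
    h <- h * ifelse(plans$range_shifter, model$rs_factor, 1)
  }
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort(
      "Scaling law yields non-positive H*(10) for some plans; the model is not valid there.",
      class = "neutrondose_model_validity_error"
    )
  }
  dplyr::mutate(as_tibble(plans), h10_uSv_per_Gy = h)
}

check_design_axes <- function(campaign) {
  axes <- list(field_size_cm2 = 2L, range_cm = 2L, modulation_cm = 3L)
  for (ax in names(axes)) {
    if (length(unique(campaign[[ax]])) < axes[[ax]]) {
      abort_invalid(sprintf(
        "Campaign has too little variation in `%s` (need >= %d distinct values) to identify the scaling law.",
        ax, axes[[ax]]
      ))
    }
  }
}

#' Fit the scaling-law model to a measurement campaign
#'
#' Fits the multiplicative law position by position, by least squares in log
#' space (doses span orders of magnitude, so relative errors are what
#' matters): `log H - log(FS/ref_area)` is regressed on
#' `log a0 + log(1 + c_r (R_eff - ref_range)) + log(m(M)/m(ref_mod))` with
#' [minpack.lm::nlsLM]. Rows are sorted by irradiation id first, so the fit
#' is deterministic under row permutation.
#'
#' @param campaign Campaign tibble with columns `irradiation_id`,
#'   `field_size_cm2`, `range_cm`, `modulation_cm`, `range_shifter`,
#'   `position`, `h10_uSv_per_Gy` (positive).
#' @param ref_area,ref_range,ref_modulation Reference plan of the fitted
#'   model (defaults 100 cm^2, 15 cm, 10 cm).
#' @param rs_mode Range-shifter handling of the fitted model; default
#'   `"effective_range"`.
#' @return A list of class `scaling_fit` with elements `model` (a
#'   [scaling_model()]), `coefficients` (tidy per-position estimates with
#'   standard errors), `residuals` (per-row log residuals) and `positions`.
#' @export
fit_scaling_model <- function(campaign, ref_area = 100, ref_range = 15,
                              ref_modulation = 10,
                              rs_mode = "effective_range") {
  req <- c("irradiation_id", "field_size_cm2", "range_cm", "modulation_cm",
           "range_shifter", "position", "h10_uSv_per_Gy")
  if (!is.data.frame(campaign) || !all(req %in% names(campaign))) {
    abort_invalid(paste0(
      "`campaign` needs columns ", paste(req, collapse = ", "), "."
    ))
  }
  if (any(campaign$h10_uSv_per_Gy <= 0)) {
    abort_invalid("H*(10) values must be strictly positive.")
  }
  check_design_axes(campaign)
  campaign <- dplyr::arrange(as_tibble(campaign), .data$position,
                             .data$irradiation_id)
  r_eff <- if (rs_mode == "effective_range") effective_range(campaign) else
    campaign$range_cm
  campaign$.dr <- r_eff - ref_range
  campaign$.lhs <- log(campaign$h10_uSv_per_Gy) -
    log(campaign$field_size_cm2 / ref_area)

  fit_one <- function(df) {
    start <- list(log_a0 = mean(df$.lhs), c_r = 0.05, c_m1 = 0.02, c_m2 = -5e-4)
    fit <- minpack.lm::nlsLM(
      .lhs ~ log_a0 + log(1 + c_r * .dr) +
        log((1 + c_m1 * modulation_cm + c_m2 * modulation_cm^2) /
              (1 + c_m1 * ref_modulation + c_m2 * ref_modulation^2)),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    )
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
    tibble(
      term = c("a0", "c_r", "c_m1", "c_m2"),
      estimate = c(exp(est[["log_a0"]]), est[["c_r"]], est[["c_m1"]],
                   est[["c_m2"]]),
      std.error = c(exp(est[["log_a0"]]) * se[[1]], se[[2]], se[[3]], se[[4]]),
      sigma_log = sqrt(mean(stats::resid(fit)^2)),
      n = nrow(df),
      resid = list(stats::resid(fit))
    )
  }

  by_pos <- dplyr::group_split(dplyr::group_by(campaign, .data$position))
  labels <- vapply(by_pos, function(d) d$position[1], character(1))
  fits <- purrr::map(by_pos, fit_one)
  coefs <- dplyr::bind_rows(purrr::map2(labels, fits, function(p, f) {
    dplyr::mutate(dplyr::select(f, -"resid"), position = p, .before = 1)
  }))
  residuals <- dplyr::bind_rows(purrr::map2(labels, by_pos, function(p, d) {
    tibble(position = p, irradiation_id = d$irradiation_id)
  }))
  residuals$log_residual <- unlist(purrr::map(fits, function(f) f$resid[[1]]))

  wide <- coefs |>
    dplyr::select("position", "term", "estimate") |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
  model <- scaling_model(wide, ref_area = ref_area, ref_range = ref_range,
                         ref_modulation = ref_modulation, rs_mode = rs_mode)
  structure(
    list(model = model, coefficients = coefs, residuals = residuals,
         positions = labels,
         ref = list(area = ref_area, range = ref_range,
                    modulation = ref_modulation)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Out-of-field neutron H*(10) scaling-law fit\n")
  cat(sprintf("Positions: %s\n", paste(x$positions, collapse = ", ")))
  cat(sprintf("Reference plan: %g cm^2, range %g cm, modulation %g cm\n",
              x$ref$area, x$ref$range, x$ref$modulation))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted scaling-law model
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return Tibble with columns `position`, `term`, `estimate`, `std.error`.
#' @method tidy scaling_fit
#' @export
tidy.scaling_fit <- function(x, ...) {
  dplyr::select(x$coefficients, "position", "term", "estimate", "std.error")
}

#' One-row-per-position fit summary
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return Tibble with `position`, `n`, `sigma_log` (residual standard
#'   deviation in log space, i.e. roughly the relative scatter).
#' @method glance scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  dplyr::distinct(x$coefficients, .data$position, .data$n, .data$sigma_log)
}

#' Inverse-square distance extrapolation
#'
#' Rescales an H*(10) value measured or predicted at `d_ref` to `d_target`
#' assuming a point-like neutron source at the isocenter:
#' `h10 * (d_ref / d_target)^2`. A rough model, adequate for order-of-
#' magnitude organ-dose estimates.
#'
#' @param h10 H*(10), uSv per Gy.
#' @param d_ref,d_target Distances from the isocenter, m; both positive.
#' @return Rescaled H*(10), uSv per Gy.
#' @export
extrapolate_inverse_square <- function(h10, d_ref, d_target) {
  if (any(d_ref <= 0) || any(d_target <= 0)) {
    abort_invalid("Distances must be strictly positive.")
  }
  h10 * (d_ref / d_target)^2
}

#' Estimate an organ-level out-of-field neutron dose
#'
#' The worked-example estimator: starting from a reference H*(10) for a
#' known plan at a known position, apply (1) the linear field-size
#' correction, (2) the model's range law between the two effective ranges,
#' (3) the modulation law, and (4) the inverse-square distance law to the
#' target distance. Each factor is returned separately; their product times
#' the reference value is the estimate. Accuracy is no better than a factor
#' of about three: the plan parameters have interdependencies that a
#' separable scaling law cannot capture.
#'
#' @param reference_h10 Reference H*(10), uSv per Gy.
#' @param reference_plan,target_plan One-row treatment-plan tibbles.
#' @param position One row of a positions table (needs `position`,
#'   `distance_m`), the location where `reference_h10` applies.
#' @param target_distance_m Distance of the organ from the isocenter, m.
#' @param model A [scaling_model()] supplying the range/modulation laws.
#' @return A one-row tibble: `h10_uSv_per_Gy`, `field_size_factor`,
#'   `range_factor`, `modulation_factor`, `inverse_square_factor`.
#' @export
estimate_organ_dose <- function(reference_h10, reference_plan, target_plan,
                                position, target_distance_m,
                                model = default_scaling_model()) {
  if (reference_h10 <= 0) abort_invalid("`reference_h10` must be positive.")
  if (!is.data.frame(position) || nrow(position) != 1 ||
      !all(c("position", "distance_m") %in% names(position))) {
    abort_invalid("`position` must be a one-row tibble with position and distance_m.")
  }
  if (is.na(position$distance_m)) {
    abort_invalid(sprintf(
      "Distance for position '%s' is a placeholder; supply it explicitly.",
      position$position
    ))
  }
  validate_plans(reference_plan)
  validate_plans(target_plan)
  co <- model_coefs_at(model, position$position)
  f_fs <- target_plan$field_size_cm2 / reference_plan$field_size_cm2
  r_ref <- effective_range(reference_plan)
  r_tgt <- effective_range(target_plan)
  f_r <- (1 + co$c_r * (r_tgt - model$ref_range)) /
    (1 + co$c_r * (r_ref - model$ref_range))
  f_m <- mod_term(target_plan$modulation_cm, co$c_m1, co$c_m2) /
    mod_term(reference_plan$modulation_cm, co$c_m1, co$c_m2)
  f_d <- (position$distance_m / target_distance_m)^2
  if (f_r <= 0 || !is.finite(f_r)) {
    abort("Range law is not valid between these plans.",
          class = "neutrondose_model_validity_error")
  }
  tibble(
    h10_uSv_per_Gy = reference_h10 * f_fs * f_r * f_m * f_d,
    field_size_factor = f_fs,
    range_factor = f_r,
    modulation_factor = f_m,
    inverse_square_factor = f_d
  )
}
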