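#' Design of a synthetic measurement campaign
#'
#' Describes the plan-parameter axes, the measurement positions, the
#' per-position relative measurement noise and (optionally) the monitors
#' assigned to the positions. The defaults mimic a realistic campaign:
#' plan axes inside the supported domain, six positions A-F, and
#' multiplicative noise between 15 % and 30 % (the typical combined
#' measurement uncertainty).
#'
#' @param field_sizes_cm2,ranges_cm,modulations_cm Plan axes; the full
#'   factorial is formed and combinations with modulation > range dropped.
#' @param range_shifter Logical values to cross with the other axes.
#' @param air_gaps_cm Air gaps, cm, used for plans with a range shifter.
#' @param positions Positions tibble, see [default_positions()].
#' @param noise_sd Relative measurement noise per position: a single value
#'   or a vector named by position label (default 0.2 everywhere).
#' @param monitors Optional named character vector mapping position labels
#'   to monitor ids (see [list_monitors()]); when set,
#'   [generate_campaign()] folds the monitor's imperfect energy response
#'   into the measured values.
#' @param seed Integer seed (mandatory; all randomness is derived from it).
#' @return A list of class `campaign_design`.
#' @export
campaign_design <- function(field_sizes_cm2 = c(9, 100, 400, 625),
                            ranges_cm = c(10, 15, 20, 25),
                            modulations_cm = c(3, 5, 10, 15, 20),
                            range_shifter = FALSE,
                            air_gaps_cm = NA_real_,
                            positions = default_positions(),
                            noise_sd = 0.2,
                            monitors = NULL,
                            seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    abort_invalid("A single integer `seed` is mandatory.")
  }
  if (length(field_sizes_cm2) == 0 || length(ranges_cm) == 0 ||
      length(modulations_cm) == 0) {
    abort_invalid("All plan axes must be non-empty.")
  }
  if (!is.data.frame(positions) || !"position" %in% names(positions)) {
    abort_invalid("`positions` must be a tibble with a position column.")
  }
  if (is.null(names(noise_sd))) {
    noise_sd <- setNames(rep_len(noise_sd, nrow(positions)),
                         positions$position)
  }
  if (any(noise_sd < 0)) abort_invalid("Noise levels must be non-negative.")
  structure(
    list(
      field_sizes_cm2 = field_sizes_cm2, ranges_cm = ranges_cm,
      modulations_cm = modulations_cm, range_shifter = range_shifter,
      air_gaps_cm = air_gaps_cm, positions = positions,
      noise_sd = noise_sd, monitors = monitors, seed = as.integer(seed)
    ),
    class = "campaign_design"
  )
}

#' Expand a campaign design into a treatment-plan grid
#'
#' Full factorial over the design's plan axes; combinations with modulation
#' width exceeding the range are dropped (their count is reported in the
#' `n_dropped` attribute). Plans are labelled `irr001`, `irr002`, ... in a
#' deterministic order.
#'
#' @param design A [campaign_design()].
#' @return A tibble of plans with an `irradiation_id` column.
#' @export
generate_plan_grid <- function(design) {
  if (!inherits(design, "campaign_design")) {
    abort_invalid("`design` must be a campaign_design.")
  }
  grid <- tidyr::expand_grid(
    field_size_cm2 = design$field_sizes_cm2,
    range_cm = design$ranges_cm,
    modulation_cm = design$modulations_cm,
    range_shifter = design$range_shifter
  )
  n_all <- nrow(grid)
  grid <- dplyr::filter(grid, .data$modulation_cm <= .data$range_cm)
  n_dropped <- n_all - nrow(grid)
  if (nrow(grid) == 0) {
    abort_invalid("No valid plans remain after enforcing modulation <= range.")
  }
  gap <- design$air_gaps_cm[1]
  grid <- grid |>
    dplyr::mutate(
      air_gap_cm = ifelse(.data$range_shifter, gap, NA_real_),
      rs_wet_cm = 3.1,
      irradiation_id = sprintf("irr%03d", dplyr::row_number()),
      .before = 1
    )
  validate_plans(grid)
  attr(grid, "n_dropped") <- n_dropped
  grid
}

# approximate proton energy (MeV) for a range in water (cm); inverse of the
# Bragg-Kleeman rule R = 0.0022 E^1.77
range_to_energy <- function(range_cm) (range_cm / 0.0022)^(1 / 1.77)

#' Generate a synthetic measurement campaign
#'
#' Simulates the campaign a set of fixed monitors would record: the ground
#' truth is the scaling-law prediction of `truth_model` for every plan and
#' position; the "measured" value multiplies the truth by the monitor's
#' expected energy response (only when monitors are attached to the design)
#' and by multiplicative lognormal noise with the design's per-position
#' relative sigma (noise is lognormal because doses are positive and
#' uncertainties are quoted relatively). Reproducible for a fixed design
#' seed.
#'
#' @param design A [campaign_design()].
#' @param truth_model The generating [scaling_model()].
#' @return A list with `measured` and `truth` campaign tibbles (sharing
#'   keys), the plan grid `plans`, and `truth_model`.
#' @export
generate_campaign <- function(design, truth_model = default_scaling_model()) {
  if (!inherits(design, "campaign_design")) {
    abort_invalid("`design` must be a campaign_design.")
  }
  plans <- generate_plan_grid(design)
  positions <- design$positions$position

  monitor_factor <- function(pos, plan_rows) {
    if (is.null(design$monitors) || !pos %in% names(design$monitors)) {
      return(rep(1, nrow(plan_rows)))
    }
    rf <- load_monitor(design$monitors[[pos]])
    tab <- default_conversion_table()
    vapply(seq_len(nrow(plan_rows)), function(i) {
      e_max <- min(range_to_energy(effective_range(plan_rows[i, ])), 230)
      src <- proton_source(e_max)
      spec <- synthesize_spectrum(src)
      expected_monitor_response(spec, rf, tab)
    }, numeric(1))
  }

  truth <- purrr::map(positions, function(pos) {
    predicted <- predict_h10(plans, truth_model, position = pos, quiet = TRUE)
    dplyr::mutate(predicted, position = pos)
  }) |> dplyr::bind_rows()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)
  measured <- purrr::map(positions, function(pos) {
    rows <- truth[truth$position == pos, ]
    sd_rel <- unname(design$noise_sd[[pos]])
    # lognormal with unit mean and relative sd sd_rel
    sdlog <- sqrt(log(1 + sd_rel^2))
    noise <- if (sd_rel == 0) rep(1, nrow(rows)) else
      stats::rlnorm(nrow(rows), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mf <- monitor_factor(pos, rows)
    dplyr::mutate(rows,
                  h10_uSv_per_Gy = .data$h10_uSv_per_Gy * mf * noise,
                  rel_uncertainty = sd_rel)
  }) |> dplyr::bind_rows()

  list(
    measured = measured,
    truth = dplyr::mutate(truth, rel_uncertainty = 0),
    plans = plans,
    truth_model = truth_model
  )
}
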