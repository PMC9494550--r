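#' Counting-statistics uncertainty
#'
#' Relative k = 1 uncertainty of a Poisson count: the inverse square root of
#' the number of counts.
#'
#' @param counts Number of counts, >= 1 (vectorised).
#' @return Relative uncertainty (fraction).
#' @export
counting_uncertainty <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 1)) {
    abort_invalid("`counts` must be >= 1.")
  }
  1 / sqrt(counts)
}

#' A 3-D dose mesh around a detector position
#'
#' Simulated H*(10) values on a regular lattice, used to propagate detector
#' positioning uncertainty.
#'
#' @param values 3-D numeric array of positive H*(10) values, uSv per Gy.
#' @param spacing Lattice spacing, cm.
#' @param origin Coordinates (cm) of the `[1, 1, 1]` lattice point.
#' @return A list of class `dose_mesh`.
#' @export
dose_mesh <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    abort_invalid("`values` must be a 3-D array.")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort_invalid("Mesh values must be positive and finite.")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    abort_invalid("`spacing` must be a single positive number (cm).")
  }
  if (length(origin) != 3) abort_invalid("`origin` must have 3 coordinates.")
  structure(list(values = values, spacing = spacing, origin = as.double(origin)),
            class = "dose_mesh")
}

mesh_axis <- function(mesh, k) {
  mesh$origin[k] + (seq_len(dim(mesh$values)[k]) - 1) * mesh$spacing
}

# detector-volume average: mean of lattice values within `radius` of `center`
mesh_volume_average <- function(mesh, center, radius) {
  ax <- lapply(1:3, mesh_axis, mesh = mesh)
  lo <- center - radius
  hi <- center + radius
  for (k in 1:3) {
    if (lo[k] < min(ax[[k]]) - 1e-9 || hi[k] > max(ax[[k]]) + 1e-9) {
      abort_invalid("Mesh does not cover the detector volume at this position.")
    }
  }
  dx <- outer(ax[[1]] - center[1], rep(1, length(ax[[2]])))
  inside_xy <- outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`)
  vals <- 0
  n <- 0
  for (k in seq_along(ax[[3]])) {
    d2 <- inside_xy + (ax[[3]][k] - center[3])^2
    sel <- d2 <= radius^2 + 1e-9
    if (any(sel)) {
      vals <- vals + sum(mesh$values[, , k][sel])
      n <- n + sum(sel)
    }
  }
  if (n == 0) {
    # detector smaller than the lattice spacing: fall back to nearest point
    idx <- vapply(1:3, function(k) which.min(abs(ax[[k]] - center[k])), 1L)
    return(mesh$values[idx[1], idx[2], idx[3]])
  }
  vals / n
}

#' Positioning uncertainty from a dose mesh
#'
#' Detectors are placed with a finite precision (about 5 cm). The
#' H*(10) is averaged over the detector volume at the nominal position and
#' at the six positions shifted by `shift` in the positive and negative
#' x, y and z directions; the relative uncertainty is the k = 1 standard
#' deviation of a uniform distribution between the lowest and highest of the
#' seven values: `(max - min) / (sqrt(12) * nominal)`.
#'
#' @param mesh A [dose_mesh()] covering nominal position +/- shift + radius.
#' @param nominal Nominal detector position, cm (length 3).
#' @param shift Positioning precision, cm (default 5).
#' @param detector_radius Radius of the detector volume, cm (default 10,
#'   i.e. a 20-cm-diameter spherical tally cell).
#' @return Relative uncertainty (fraction, k = 1).
#' @export
positioning_uncertainty <- function(mesh, nominal, shift = 5,
                                    detector_radius = 10) {
  if (!inherits(mesh, "dose_mesh")) abort_invalid("`mesh` must be a dose_mesh.")
  if (length(nominal) != 3) abort_invalid("`nominal` must have 3 coordinates.")
  if (shift < 0) abort_invalid("`shift` must be non-negative.")
  if (shift == 0) return(0)
  shifts <- rbind(
    c(0, 0, 0),
    diag(3) * shift,
    -diag(3) * shift
  )
  avgs <- apply(shifts, 1, function(s) {
    mesh_volume_average(mesh, nominal + s, detector_radius)
  })
  (max(avgs) - min(avgs)) / (sqrt(12) * avgs[1])
}

#' Energy-response uncertainty component
#'
#' When a monitor's reading is not corrected for its imperfect H*(10)
#' energy response, the deviation of the expected response from unity
#' enters the uncertainty budget as a one-sided component `|1 - R|`, tagged
#' with its direction (an expected response above 1 means the monitor
#' over-estimates the true H*(10)).
#'
#' @param expected_response Expected monitor response (dimensionless, > 0),
#'   e.g. from [expected_monitor_response()].
#' @return A one-row tibble with `fraction` and `direction`
#'   (`"over"`, `"under"` or `"none"`).
#' @export
energy_response_component <- function(expected_response) {
  if (!is.numeric(expected_response) || length(expected_response) != 1 ||
      !is.finite(expected_response) || expected_response <= 0) {
    abort_invalid("`expected_response` must be a single positive number.")
  }
  tibble(
    fraction = abs(1 - expected_response),
    direction = if (expected_response > 1) "over" else
      if (expected_response < 1) "under" else "none"
  )
}

#' Combine an uncertainty budget
#'
#' Combines independent relative k = 1 components in quadrature
#' (root-sum-square), the GUM rule for independent contributions. Typical
#' components: positioning, calibration, counting statistics, energy
#' response, target dose.
#'
#' @param components Named numeric vector or list of non-negative relative
#'   uncertainties (fractions).
#' @return A list of class `uncertainty_budget` with elements `components`
#'   (tibble `component`, `fraction`, `percent`) and `combined` (fraction).
#' @export
combine_budget <- function(components) {
  comp <- unlist(components)
  if (length(comp) == 0) abort_invalid("Need at least one component.")
  if (!is.numeric(comp) || any(!is.finite(comp))) {
    abort_invalid("Components must be finite numbers.")
  }
  if (any(comp < 0)) abort_invalid("Components must be non-negative.")
  if (is.null(names(comp)) || any(names(comp) == "")) {
    names(comp) <- paste0("component_", seq_along(comp))
  }
  combined <- sqrt(sum(comp^2))
  structure(
    list(
      components = tibble(component = names(comp), fraction = as.double(comp),
                          percent = 100 * as.double(comp)),
      combined = combined
    ),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Measurement uncertainty budget (relative, k = 1)\n")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-16s %6.2f %%\n", x$components$component[i],
                x$components$percent[i]))
  }
  cat(sprintf("  %-16s %6.2f %%  (quadrature)\n", "combined", 100 * x$combined))
  invisible(x)
}

#' Tidy an uncertainty budget
#'
#' @param x An `uncertainty_budget`.
#' @param ... Unused.
#' @return The component tibble with the combined value appended as a row.
#' @method tidy uncertainty_budget
#' @export
tidy.uncertainty_budget <- function(x, ...) {
  dplyr::bind_rows(
    x$components,
    tibble(component = "combined", fraction = x$combined,
           percent = 100 * x$combined)
  )
}
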