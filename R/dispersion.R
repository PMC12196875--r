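STABILITY_CLASSES <- c("A", "B", "C", "D", "E", "F")

#' Validate a Pasquill stability class label
#'
#' The Pasquill scheme grades atmospheric turbulence from very unstable (A)
#' through unstable (B), weakly unstable (C), neutral (D) and moderately
#' stable (E) to stable (F).
#' @param label One of `"A"`..`"F"`.
#' @return The validated label, class `stability_class`.
#' @export
stability_class <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% STABILITY_CLASSES) {
    stop_validation("unknown stability class '", paste(label, collapse = ","),
                    "'; must be one of ", paste(STABILITY_CLASSES, collapse = ", "))
  }
  structure(label, class = "stability_class")
}

#' Power-law dispersion coefficient parameters
#'
#' Gaussian plume spread is modeled as sigma_y = gamma1 * x^alpha1 and
#' sigma_z = gamma2 * x^alpha2 with class- and distance-regime-specific
#' regression constants.
#'
#' @param gamma1,alpha1 Lateral regression coefficient/exponent; gamma1 > 0,
#'   alpha1 in (0, 2).
#' @param gamma2,alpha2 Vertical regression coefficient/exponent; same
#'   constraints.
#' @param valid_range Length-2 numeric, the downwind-distance interval (m)
#'   over which the regression holds.
#' @return Object of class `dispersion_params`.
#' @export
dispersion_params <- function(gamma1, alpha1, gamma2, alpha2,
                              valid_range = c(10, 10000)) {
  check_number(gamma1, "gamma1", 0, strict = TRUE)
  check_number(gamma2, "gamma2", 0, strict = TRUE)
  check_number(alpha1, "alpha1", 0, strict = TRUE)
  check_number(alpha2, "alpha2", 0, strict = TRUE)
  if (alpha1 >= 2 || alpha2 >= 2) stop_validation("alpha exponents must be < 2")
  check_number(valid_range, "valid_range", 0, len = 2L)
  if (valid_range[1] >= valid_range[2]) {
    stop_validation("valid_range must be an increasing interval")
  }
  structure(list(gamma1 = gamma1, alpha1 = alpha1, gamma2 = gamma2,
                 alpha2 = alpha2, valid_range = valid_range),
            class = "dispersion_params")
}

#' Load a stability-class dispersion coefficient table
#'
#' Reads a YAML table mapping each Pasquill class to a list of distance
#' regimes `(x_min, x_max, gamma1, alpha1, gamma2, alpha2)`. The packaged
#' default (`dispersion_briggs_fit.yaml`) carries power-law fits to the
#' Briggs open-country curves; users holding an exact national-standard
#' regression table can substitute their own file.
#'
#' @param path Path to a YAML table; `NULL` loads the packaged default.
#' @return A named list (classes A-F) of lists of `dispersion_params`,
#'   class `dispersion_table`.
#' @export
load_dispersion_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dispersion_briggs_fit.yaml",
                                package = "odorisk", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(STABILITY_CLASSES, names(raw))
  if (length(missing)) {
    stop_validation("dispersion table lacks class(es): ",
                    paste(missing, collapse = ", "))
  }
  tab <- lapply(raw[STABILITY_CLASSES], function(regimes) {
    lapply(regimes, function(r) {
      dispersion_params(gamma1 = r$gamma1, alpha1 = r$alpha1,
                        gamma2 = r$gamma2, alpha2 = r$alpha2,
                        valid_range = c(r$x_min, r$x_max))
    })
  })
  structure(tab, class = "dispersion_table")
}

# memoised default table (read once per session)
the <- new.env(parent = emptyenv())
default_dispersion_table <- function() {
  if (is.null(the$disp_table)) the$disp_table <- load_dispersion_table()
  the$disp_table
}

#' Look up dispersion parameters for a stability class and distance
#'
#' @param stability A class label `"A"`..`"F"` or [stability_class()].
#' @param x Downwind distance, m; must fall in one of the table's regimes.
#' @param table A `dispersion_table`; default is the packaged table.
#' @return The matching [dispersion_params()].
#' @export
stability_param_table <- function(stability, x, table = default_dispersion_table()) {
  lab <- as.character(stability_class(as.character(stability)))
  check_number(x, "x", 0, strict = TRUE)
  regimes <- table[[lab]]
  for (p in regimes) {
    if (x >= p$valid_range[1] && x <= p$valid_range[2]) return(p)
  }
  spans <- vapply(regimes, function(p)
    paste0("[", p$valid_range[1], ", ", p$valid_range[2], "] m"), "")
  stop_validation("x = ", x, " m is outside every distance regime of class ",
                  lab, " (table covers ", paste(spans, collapse = "; "), ")")
}

#' Lateral and vertical dispersion coefficients
#'
#' Evaluates the power laws sigma_y = gamma1*x^alpha1, sigma_z =
#' gamma2*x^alpha2; both strictly increasing in x.
#'
#' @param params A [dispersion_params()].
#' @param x Downwind distance, m, within `params$valid_range`.
#' @return Named numeric `c(sigma_y = , sigma_z = )`, metres.
#' @export
dispersion_coefficients <- function(params, x) {
  stopifnot(inherits(params, "dispersion_params"))
  check_number(x, "x", 0, strict = TRUE)
  if (x < params$valid_range[1] || x > params$valid_range[2]) {
    stop_validation("x = ", x, " m outside the regression's valid range [",
                    params$valid_range[1], ", ", params$valid_range[2], "] m")
  }
  c(sigma_y = params$gamma1 * x^params$alpha1,
    sigma_z = params$gamma2 * x^params$alpha2)
}

#' Meteorological scenario
#' @param stability Pasquill class label `"A"`..`"F"`.
#' @param wind_speed Mean wind speed Uair at plume height, m/s, > 0.
#' @return Object of class `meteo_scenario`.
#' @export
meteo_scenario <- function(stability, wind_speed) {
  check_number(wind_speed, "wind_speed", 0, strict = TRUE)
  structure(list(stability = stability_class(stability),
                 wind_speed = wind_speed),
            class = "meteo_scenario")
}

#' Downwind receptor geometry
#'
#' Coordinates follow the standard plume convention: x strictly downwind
#' along the mean wind, y lateral, z vertical, all in metres. Receptors at
#' or upwind of the source (`downwind <= 0`) are rejected. The default
#' geometry treats the excavation face as a ground-level release
#' (`release_height = 0`) evaluated at breathing-zone height 1.5 m.
#'
#' @param downwind Distance x from source to receptor, m, > 0.
#' @param lateral Lateral offset y from the plume centerline, m.
#' @param receptor_height Evaluation height z, m, >= 0; default 1.5
#'   (breathing zone).
#' @param release_height Effective release height of the source, m, >= 0;
#'   default 0 (excavation emits at grade).
#' @return Object of class `receptor`.
#' @export
receptor <- function(downwind, lateral = 0, receptor_height = 1.5,
                     release_height = 0) {
  check_number(downwind, "downwind", 0, strict = TRUE)
  check_number(lateral, "lateral")
  check_number(receptor_height, "receptor_height", 0)
  check_number(release_height, "release_height", 0)
  structure(list(downwind = downwind, lateral = lateral,
                 receptor_height = receptor_height,
                 release_height = release_height),
            class = "receptor")
}

# vectorized plume kernel shared by the scalar API and the Monte Carlo layer
gaussian_plume_epc <- function(er, u, sigma_y, sigma_z, y, z, h) {
  er / (2 * pi * u * sigma_y * sigma_z) *
    exp(-y^2 / (2 * sigma_y^2)) *
    (exp(-(z - h)^2 / (2 * sigma_z^2)) + exp(-(z + h)^2 / (2 * sigma_z^2)))
}

#' Gaussian plume exposure-point concentration
#'
#' Continuous ground-reflecting point-source plume:
#' \deqn{EPC = \frac{ER}{2\pi U \sigma_y \sigma_z}
#'   e^{-y^2/2\sigma_y^2}\left[e^{-(z-h)^2/2\sigma_z^2} +
#'   e^{-(z+h)^2/2\sigma_z^2}\right]}
#' Zero iff the emission rate is zero; symmetric in the lateral offset;
#' linear in `er` and inversely proportional to wind speed.
#'
#' @param er Emission rate, mg/s, >= 0 (vectorized).
#' @param meteo A [meteo_scenario()].
#' @param receptor A [receptor()].
#' @param params A [dispersion_params()]; `NULL` looks the parameters up
#'   from the default table by `meteo$stability` and `receptor$downwind`.
#' @return Exposure-point concentration, mg/m3.
#' @export
plume_concentration <- function(er, meteo, receptor, params = NULL) {
  stopifnot(inherits(meteo, "meteo_scenario"), inherits(receptor, "receptor"))
  if (any(er < 0) || anyNA(er)) stop_validation("'er' must be >= 0")
  params <- params %||% stability_param_table(meteo$stability, receptor$downwind)
  sig <- dispersion_coefficients(params, receptor$downwind)
  gaussian_plume_epc(er, meteo$wind_speed, sig[["sigma_y"]], sig[["sigma_z"]],
                     receptor$lateral, receptor$receptor_height,
                     receptor$release_height)
}

#' Crosswind-integrated advected mass flux (conservation oracle)
#'
#' Numerically integrates `EPC * Uair` over the crosswind plane (y over the
#' real line, z over the ground half-space) at downwind distance `x`. For a
#' conservative plume with full ground reflection the result equals the
#' emission rate at every distance; this function exists as a numerical
#' mass-conservation check and is used by the test-suite, not the pipeline.
#'
#' @param er Emission rate, mg/s, > 0.
#' @param meteo A [meteo_scenario()].
#' @param params A [dispersion_params()]; `NULL` for table lookup at `x`.
#' @param x Downwind distance, m.
#' @param release_height Source height h, m; default 0.
#' @param rel_tol Quadrature relative tolerance.
#' @return Advected mass flux through the plane, mg/s.
#' @export
crosswind_integrated_flux <- function(er, meteo, params = NULL, x,
                                      release_height = 0, rel_tol = 1e-8) {
  stopifnot(inherits(meteo, "meteo_scenario"))
  check_number(er, "er", 0, strict = TRUE)
  params <- params %||% stability_param_table(meteo$stability, x)
  sig <- dispersion_coefficients(params, x)
  sy <- sig[["sigma_y"]]; sz <- sig[["sigma_z"]]
  u <- meteo$wind_speed
  inner <- function(z) {
    vapply(z, function(zi) {
      iy <- stats::integrate(function(y) {
        u * gaussian_plume_epc(er, u, sy, sz, y, zi, release_height)
      }, -Inf, Inf, rel.tol = rel_tol)
      if (iy$message != "OK") {
        stop("non-convergent lateral quadrature at z = ", zi, ": ", iy$message)
      }
      iy$value
    }, numeric(1))
  }
  iz <- stats::integrate(inner, 0, Inf, rel.tol = rel_tol)
  if (iz$message != "OK") {
    stop("non-convergent vertical quadrature (sigma_z = ", signif(sz, 4),
         " m): ", iz$message)
  }
  iz$value
}
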