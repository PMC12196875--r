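#' Full odor-assessment scenario bundle
#'
#' Binds everything one source-to-receptor assessment needs: the pollutant
#' registry, per-pollutant mean solid-phase contents (and optionally their
#' distributions), the waste matrix, the excavation operation, the
#' meteorology, and the receptor geometry. Every pollutant named in
#' `cs_mean` must resolve in the registry before any computation starts.
#'
#' @param registry A `pollutant_registry`.
#' @param cs_mean Named numeric vector: mean solid-phase content per
#'   pollutant, mg/kg.
#' @param matrix A [waste_matrix()].
#' @param excavation An [excavation_scenario()].
#' @param stability Pasquill class label `"A"`..`"F"`, or a discrete
#'   [dist_discrete()] over class labels for pooled-meteorology runs.
#' @param wind_speed Wind speed, m/s (numeric), or a [param_dist] for
#'   probabilistic runs.
#' @param receptor A [receptor()].
#' @param cs_dist Optional named list of [param_dist] objects, one per
#'   pollutant, describing solid-phase content uncertainty. Required when
#'   the Monte Carlo config randomizes `cs`.
#' @param matrix_dist Optional named list of [param_dist] for
#'   `theta_air`, `theta_w`, `foc`.
#' @param dispersion_table A `dispersion_table`; `NULL` for the packaged
#'   default.
#' @return An object of class `odor_scenario`.
#' @export
odor_scenario <- function(registry, cs_mean, matrix, excavation,
                          stability, wind_speed, receptor,
                          cs_dist = NULL, matrix_dist = NULL,
                          dispersion_table = NULL) {
  stopifnot(inherits(registry, "pollutant_registry"),
            inherits(matrix, "waste_matrix"),
            inherits(excavation, "excavation_scenario"),
            inherits(receptor, "receptor"))
  if (!is.numeric(cs_mean) || is.null(names(cs_mean)) ||
      any(!nzchar(names(cs_mean)))) {
    stop_validation("'cs_mean' must be a named numeric vector (mg/kg)")
  }
  if (any(cs_mean < 0) || anyNA(cs_mean)) stop_validation("'cs_mean' must be >= 0")
  resolve_pollutants(registry, names(cs_mean))
  if (!inherits(stability, "param_dist")) stability <- stability_class(stability)
  if (!inherits(wind_speed, "param_dist")) {
    check_number(wind_speed, "wind_speed", 0, strict = TRUE)
  }
  if (!is.null(cs_dist)) {
    stopifnot(is.list(cs_dist))
    extra <- setdiff(names(cs_dist), names(cs_mean))
    if (length(extra)) {
      stop_validation("cs_dist for unknown pollutant(s): ",
                      paste(extra, collapse = ", "))
    }
  }
  structure(list(registry = registry, cs_mean = cs_mean, matrix = matrix,
                 excavation = excavation, stability = stability,
                 wind_speed = wind_speed, receptor = receptor,
                 cs_dist = cs_dist, matrix_dist = matrix_dist,
                 dispersion_table = dispersion_table),
            class = "odor_scenario")
}

# Weber-Fechner with the zero-OAV sentinel used by the probabilistic layer:
# OAV = 0 maps to -Inf ("below every level") rather than erroring.
wf_intensity_sentinel <- function(oav, k, b) {
  ifelse(oav > 0, k * log10(oav) + b, -Inf)
}

#' Deterministic source-to-receptor assessment of one scenario
#'
#' Runs the partitioning -> emission -> plume -> odor chain once per
#' pollutant using mean inputs (the mean of any parameter distribution),
#' a fixed stability class (the highest-frequency class if pooled) and
#' the scenario receptor.
#'
#' @param scenario An [odor_scenario()].
#' @return A data.frame with one row per pollutant: `cs` (mg/kg), `cair`
#'   (pore gas, mg/m3), `er` (mg/s), `epc` (mg/m3), `oav`, `oi`, `band`,
#'   `descriptor`, plus attributes `total_oav` and `stability`.
#' @export
assess_deterministic <- function(scenario) {
  stopifnot(inherits(scenario, "odor_scenario"))
  stab <- if (inherits(scenario$stability, "param_dist")) {
    stability_class(mean(scenario$stability))
  } else scenario$stability
  u <- if (inherits(scenario$wind_speed, "param_dist")) {
    mean(scenario$wind_speed)
  } else scenario$wind_speed
  met <- meteo_scenario(as.character(stab), u)
  params <- stability_param_table(stab, scenario$receptor$downwind,
    scenario$dispersion_table %||% default_dispersion_table())
  rows <- lapply(names(scenario$cs_mean), function(nm) {
    p <- scenario$registry[[nm]]
    cs <- scenario$cs_mean[[nm]]
    cair <- pore_gas_concentration(cs, p, scenario$matrix)
    er <- emission_rate(cair, scenario$excavation, scenario$matrix)
    epc <- plume_concentration(er, met, scenario$receptor, params)
    oav <- odor_activity_value(epc, p$odor_threshold)
    oi <- wf_intensity_sentinel(oav, p$wf_slope, p$wf_intercept)
    data.frame(pollutant = nm, cs = cs, cair = cair, er = er, epc = epc,
               oav = oav, oi = oi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cls <- classify_intensity(out$oi)
  out$band <- cls$band
  out$descriptor <- cls$descriptor
  attr(out, "total_oav") <- total_odor_activity(out$oav)
  attr(out, "stability") <- as.character(stab)
  rownames(out) <- NULL
  out
}
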