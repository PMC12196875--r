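#' Physical properties of the waste matrix
#'
#' Bulk physical properties of the excavated solid waste governing
#' three-phase (solid / pore water / pore gas) partitioning. Inputs use the
#' field-customary units (bulk density in g/cm3, organic carbon in g/kg);
#' storage is SI (kg/m3, kg/kg).
#'
#' @param bulk_density Bulk density rho in g/cm3, > 0. Stored as kg/m3.
#' @param theta_w Volumetric pore-water fraction, >= 0.
#' @param theta_air Volumetric pore-gas fraction, > 0. `theta_w + theta_air`
#'   must be < 1.
#' @param foc Organic-carbon content in g/kg, >= 0. Stored as kg/kg.
#' @return Object of class `waste_matrix` with SI fields `bulk_density`
#'   (kg/m3), `theta_w`, `theta_air`, `foc` (kg/kg).
#' @examples
#' waste_matrix(bulk_density = 1.5, theta_w = 0.2, theta_air = 0.3, foc = 10)
#' @export
waste_matrix <- function(bulk_density, theta_w, theta_air, foc) {
  check_number(bulk_density, "bulk_density", 0, strict = TRUE)
  check_number(theta_w, "theta_w", 0)
  check_number(theta_air, "theta_air", 0, strict = TRUE)
  check_number(foc, "foc", 0)
  if (theta_w + theta_air >= 1) {
    stop_validation("theta_w + theta_air must be < 1 (got ",
                    theta_w + theta_air, ")")
  }
  structure(list(bulk_density = bulk_density * 1000, theta_w = theta_w,
                 theta_air = theta_air, foc = foc * 1e-3),
            class = "waste_matrix")
}

#' Excavation operating scenario
#'
#' @param dig_rate Digging rate V of a single excavator, m3/h, > 0.
#'   150 m3/h is a typical large-excavator rate for emergency cleanup.
#' @param n_excavators Number N of excavators operating simultaneously,
#'   integer >= 1.
#' @return Object of class `excavation_scenario`.
#' @export
excavation_scenario <- function(dig_rate = 150, n_excavators = 1) {
  check_number(dig_rate, "dig_rate", 0, strict = TRUE)
  check_number(n_excavators, "n_excavators", 1)
  if (n_excavators != round(n_excavators)) {
    stop_validation("'n_excavators' must be a whole number")
  }
  structure(list(dig_rate = dig_rate, n_excavators = as.integer(n_excavators)),
            class = "excavation_scenario")
}

#' Pore-gas VOC concentration by three-phase equilibrium partitioning
#'
#' Linear equilibrium partitioning of a VOC among the sorbed, dissolved and
#' vapor phases of the waste, as in vapor-intrusion screening guidance:
#' \deqn{C_{air} = \frac{C_s \, H \, \rho}{\theta_w + \rho \, K_{oc} \,
#'   f_{oc} + H \, \theta_{air}}}
#' with all terms SI-normalized (rho in kg/m3, Koc in m3/kg, foc in kg/kg)
#' so the result is mg/m3. The model assumes full reversible equilibrium
#' and instantaneous balance; no kinetics, no temperature dependence.
#'
#' Vectorized over `cs` (and over equal-length numeric overrides in
#' `matrix` fields when called internally by the Monte Carlo layer).
#'
#' @param cs Solid-phase VOC content, mg/kg, >= 0.
#' @param pollutant A [pollutant_properties()] object.
#' @param matrix A [waste_matrix()] object.
#' @return Pore-gas concentration, mg/m3. Zero iff `cs` is zero; strictly
#'   increasing in `cs`; decreasing in `foc` (organic carbon retains VOCs).
#' @export
pore_gas_concentration <- function(cs, pollutant, matrix) {
  stopifnot(inherits(pollutant, "pollutant_properties"))
  if (any(cs < 0) || anyNA(cs)) stop_validation("'cs' must be >= 0")
  denom <- matrix$theta_w + matrix$bulk_density * pollutant$koc * matrix$foc +
    pollutant$henry * matrix$theta_air
  if (any(denom <= 0)) {
    stop("internal consistency error: non-positive partitioning denominator")
  }
  cs * pollutant$henry * matrix$bulk_density / denom
}

#' Excavation-driven VOC emission rate
#'
#' Conservative source term: every excavated pore volume releases its full
#' pore-gas VOC inventory to ambient air, so the emission rate is the
#' excavated gas-phase volume flux times the pore-gas concentration:
#' \deqn{ER = V \, N \, \theta_{air} \, C_{air}}
#' with V converted from m3/h to m3/s. Linear in each factor.
#'
#' @param cair Pore-gas concentration, mg/m3, >= 0 (vectorized).
#' @param excavation An [excavation_scenario()].
#' @param matrix A [waste_matrix()].
#' @return Emission rate, mg/s.
#' @export
emission_rate <- function(cair, excavation, matrix) {
  stopifnot(inherits(excavation, "excavation_scenario"),
            inherits(matrix, "waste_matrix"))
  if (any(cair < 0) || anyNA(cair)) stop_validation("'cair' must be >= 0")
  (excavation$dig_rate / 3600) * excavation$n_excavators *
    matrix$theta_air * cair
}
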