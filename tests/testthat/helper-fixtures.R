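# shared fixtures, built in code

# a minimal single-pollutant registry with round-number constants so hand
# arithmetic in the tests stays transparent
toy_pollutant <- function(henry = 0.25, koc = 100, ct = 0.1, k = 1.4, b = 1,
                          screening = 50, name = "toyene") {
  pollutant_properties(name, henry = henry, koc = koc, odor_threshold = ct,
                       wf_slope = k, wf_intercept = b, screening_value = screening)
}

toy_registry <- function(...) {
  p <- toy_pollutant(...)
  structure(setNames(list(p), p$name), class = "pollutant_registry")
}

toy_matrix <- function() waste_matrix(bulk_density = 1.5, theta_w = 0.2,
                                      theta_air = 0.3, foc = 10)

# single-regime dispersion table with hand-checkable power laws
toy_dispersion_table <- function(gamma1 = 0.2, alpha1 = 0.9,
                                 gamma2 = 0.1, alpha2 = 0.8) {
  structure(
    setNames(lapply(c("A", "B", "C", "D", "E", "F"), function(cl) {
      list(dispersion_params(gamma1, alpha1, gamma2, alpha2,
                             valid_range = c(1, 10000)))
    }), c("A", "B", "C", "D", "E", "F")),
    class = "dispersion_table")
}

toy_scenario <- function(cs = 100, stability = "D", wind = 3,
                         cs_dist = NULL, x = 50, z = 0,
                         table = toy_dispersion_table(), ...) {
  reg <- toy_registry(...)
  odor_scenario(registry = reg,
                cs_mean = setNames(cs, names(reg)),
                matrix = toy_matrix(),
                excavation = excavation_scenario(150, 1),
                stability = stability, wind_speed = wind,
                receptor = receptor(downwind = x, receptor_height = z),
                cs_dist = cs_dist, dispersion_table = table)
}
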