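#' Pollutant physicochemical and sensory properties
#'
#' Container for the per-chemical constants used throughout the assessment
#' chain: the dimensionless Henry's Law constant, the organic-carbon
#' partition coefficient, the olfactory threshold, the Weber-Fechner
#' intensity coefficients, and the soil risk screening value.
#'
#' Units on input follow the conventions of the Chinese risk-assessment
#' guidance the model mirrors (Koc in cm3/g); storage is SI-normalized
#' (Koc in m3/kg) so that downstream partitioning arithmetic closes
#' dimensionally. The conversion happens exactly once, here.
#'
#' @param name Chemical identifier (non-empty string).
#' @param henry Dimensionless air/water Henry's Law constant, > 0.
#' @param koc Organic-carbon partition coefficient in cm3/g, >= 0.
#'   Stored as m3/kg (multiplied by 1e-3).
#' @param odor_threshold Olfactory threshold concentration, mg/m3, > 0.
#' @param wf_slope Weber-Fechner slope k (> 0) in `OI = k*log10(OAV) + B`.
#' @param wf_intercept Weber-Fechner intercept B.
#' @param screening_value Soil risk screening value, mg/kg, > 0.
#'
#' @return An object of class `pollutant_properties`: a list with fields
#'   `name`, `henry`, `koc` (m3/kg), `odor_threshold`, `wf_slope`,
#'   `wf_intercept`, `screening_value`.
#' @examples
#' pollutant_properties("toluene", henry = 0.272, koc = 234,
#'                      odor_threshold = 0.403, wf_slope = 1.38,
#'                      wf_intercept = 1, screening_value = 1200)
#' @export
pollutant_properties <- function(name, henry, koc, odor_threshold,
                                 wf_slope, wf_intercept, screening_value) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("'name' must be a non-empty string")
  }
  check_number(henry, paste0(name, ": henry"), 0, strict = TRUE)
  check_number(koc, paste0(name, ": koc"), 0)
  check_number(odor_threshold, paste0(name, ": odor_threshold"), 0, strict = TRUE)
  check_number(wf_slope, paste0(name, ": wf_slope"), 0, strict = TRUE)
  check_number(wf_intercept, paste0(name, ": wf_intercept"))
  check_number(screening_value, paste0(name, ": screening_value"), 0, strict = TRUE)
  structure(
    list(name = name, henry = henry, koc = koc * 1e-3,
         odor_threshold = odor_threshold, wf_slope = wf_slope,
         wf_intercept = wf_intercept, screening_value = screening_value),
    class = "pollutant_properties")
}

REGISTRY_FIELDS <- c("henry", "koc", "odor_threshold", "wf_slope",
                     "wf_intercept", "screening_value")

#' Load a pollutant property registry from a YAML file or list
#'
#' Reads one record per pollutant (fields as in [pollutant_properties()],
#' Koc in cm3/g) and returns a registry keyed by pollutant name. Duplicate
#' names and missing fields are rejected with an error naming the record
#' and field.
#'
#' @param source Path to a YAML registry file, or an already-parsed named
#'   list of records.
#' @return A named list of `pollutant_properties`, class
#'   `pollutant_registry`.
#' @seealso [builtin_default_registry()], [write_registry()]
#' @export
load_registry <- function(source) {
  records <- if (is.character(source)) yaml::read_yaml(source) else source
  if (is.null(records)) records <- list()
  if (!is.list(records)) stop_validation("registry source must parse to a named list")
  nm <- names(records)
  if (length(records) && (is.null(nm) || any(!nzchar(nm)))) {
    stop_validation("every registry record must be named by its pollutant")
  }
  if (anyDuplicated(nm)) {
    stop_validation("duplicate pollutant record(s): ",
                    paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  reg <- lapply(nm, function(n) {
    rec <- records[[n]]
    missing <- setdiff(REGISTRY_FIELDS, names(rec))
    if (length(missing)) {
      stop_validation("registry record '", n, "' is missing field(s): ",
                      paste(missing, collapse = ", "))
    }
    pollutant_properties(n, henry = rec$henry, koc = rec$koc,
                         odor_threshold = rec$odor_threshold,
                         wf_slope = rec$wf_slope,
                         wf_intercept = rec$wf_intercept,
                         screening_value = rec$screening_value)
  })
  names(reg) <- nm
  structure(reg, class = "pollutant_registry")
}

#' Built-in registry of the four priority pollutants
#'
#' Returns the packaged default registry covering ethylbenzene, toluene,
#' styrene and m/p-xylene — the priority odorants for aromatic-solvent
#' waste — with olfactory thresholds 0.085, 0.403, 0.158 and 0.431 mg/m3
#' respectively and the GB 36600-2018 first-category screening values
#' (ethylbenzene 28 mg/kg). Henry constants, Koc and Weber-Fechner
#' coefficients are documented, overridable defaults; see the comments in
#' `system.file("extdata", "pollutants_default.yaml", package = "odorisk")`.
#'
#' @return A `pollutant_registry` with four entries.
#' @examples
#' reg <- builtin_default_registry()
#' reg[["ethylbenzene"]]$screening_value  # 28 mg/kg
#' @export
builtin_default_registry <- function() {
  load_registry(system.file("extdata", "pollutants_default.yaml",
                            package = "odorisk", mustWork = TRUE))
}

#' Serialize a registry back to YAML
#'
#' Inverse of [load_registry()]: writes one record per pollutant with Koc
#' converted back to cm3/g, so that a load/write/load round trip reproduces
#' every field exactly.
#'
#' @param registry A `pollutant_registry`.
#' @param path Output file path; if `NULL`, the YAML text is returned
#'   invisibly instead of written.
#' @return The YAML text, invisibly.
#' @export
write_registry <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "pollutant_registry"))
  records <- lapply(registry, function(p) {
    list(henry = p$henry, koc = p$koc * 1e3,
         odor_threshold = p$odor_threshold, wf_slope = p$wf_slope,
         wf_intercept = p$wf_intercept, screening_value = p$screening_value)
  })
  txt <- yaml::as.yaml(records, precision = 15)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Resolve pollutant names against a registry
#'
#' Fails before any computation starts if a scenario references a pollutant
#' the registry does not carry.
#' @param registry A `pollutant_registry`.
#' @param pollutants Character vector of names to resolve.
#' @return The matching list of `pollutant_properties`, invisibly.
#' @export
resolve_pollutants <- function(registry, pollutants) {
  stopifnot(inherits(registry, "pollutant_registry"))
  missing <- setdiff(pollutants, names(registry))
  if (length(missing)) {
    stop_validation("pollutant(s) not in registry: ",
                    paste(missing, collapse = ", "))
  }
  invisible(registry[pollutants])
}

#' @export
print.pollutant_registry <- function(x, ...) {
  cat("<pollutant_registry> ", length(x), " pollutant(s): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
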