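# cheap stable polynomial rolling hash of the run configuration, for report
# metadata only (not cryptographic)
config_hash <- function(...) {
  txt <- paste(utils::capture.output(utils::str(list(...), digits.d = 15)),
               collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

scenario_at <- function(scenario, distance, stability) {
  scenario$receptor$downwind <- distance
  scenario$stability <- stability_class(stability)
  if (inherits(scenario$wind_speed, "param_dist") &&
      scenario$wind_speed$kind == "uniform") {
    scenario$wind_speed <- wind_speed_dist(stability)
  }
  scenario
}

#' End-to-end odor-risk assessment over distances and stability classes
#'
#' Runs the deterministic source-to-receptor chain, and optionally the
#' Monte Carlo propagation, for every receptor distance x stability class
#' combination, and assembles the result tables. When the scenario's wind
#' speed is a class-conditional uniform distribution it is re-conditioned
#' on each swept stability class.
#'
#' @param bundle A `case_study_bundle` from [make_case_study_scenario()],
#'   or a bare [odor_scenario()].
#' @param distances Receptor downwind distances, m; defaults to the
#'   bundle's distances (or the scenario receptor's distance).
#' @param stabilities Stability classes to sweep; default the scenario's
#'   own class.
#' @param config An [mc_config()]; its seed governs every random draw.
#' @param monte_carlo Run the Monte Carlo layer? (deterministic-only runs
#'   are much faster).
#' @param out_dir If non-`NULL`, report tables are written there as CSV
#'   with a JSON metadata sidecar (see [write_report()]).
#' @return Object of class `assessment_report`: list with data.frames
#'   `deterministic` (pollutant x distance x stability: epc, oav, oi,
#'   band), `mc_percentiles`, `mc_exceedance` (empty if `monte_carlo =
#'   FALSE`), and `meta`.
#' @export
assess <- function(bundle, distances = NULL, stabilities = NULL,
                   config = mc_config(), monte_carlo = TRUE,
                   out_dir = NULL) {
  scenario <- if (inherits(bundle, "case_study_bundle")) bundle$scenario else bundle
  stopifnot(inherits(scenario, "odor_scenario"))
  distances <- distances %||%
    (if (inherits(bundle, "case_study_bundle")) bundle$distances
     else scenario$receptor$downwind)
  stabilities <- stabilities %||%
    (if (inherits(scenario$stability, "param_dist")) "D"
     else as.character(scenario$stability))
  det <- list(); pct <- list(); exc <- list()
  for (st in stabilities) {
    for (x in distances) {
      sc <- scenario_at(scenario, x, st)
      d <- assess_deterministic(sc)
      d$distance <- x; d$stability <- st
      det[[length(det) + 1L]] <- d
      if (monte_carlo) {
        mc <- run_monte_carlo(sc, config)
        p <- mc$percentiles; p$distance <- x; p$stability <- st
        e <- mc$exceedance; e$distance <- x; e$stability <- st
        pct[[length(pct) + 1L]] <- p
        exc[[length(exc) + 1L]] <- e
      }
    }
  }
  meta <- list(
    seed = config$seed, n_iterations = config$n_iterations,
    randomized = config$randomized,
    distances = distances, stabilities = stabilities,
    pollutants = names(scenario$cs_mean),
    tool = paste0("odorisk ", as.character(utils::packageVersion("odorisk"))),
    config_hash = config_hash(scenario[c("cs_mean", "matrix", "excavation")],
                              distances, stabilities, config))
  report <- structure(
    list(deterministic = do.call(rbind, det),
         mc_percentiles = if (length(pct)) do.call(rbind, pct) else NULL,
         mc_exceedance = if (length(exc)) do.call(rbind, exc) else NULL,
         meta = meta),
    class = "assessment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an assessment report to disk
#'
#' Numeric tables are written at full precision (15 significant digits);
#' any display rounding is left to human-readable summaries. Identical
#' report objects produce byte-identical files.
#'
#' @param report An `assessment_report`.
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` (tables + JSON sidecar) or `"json"` (everything
#'   in one JSON file).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, format = c("csv", "json")) {
  stopifnot(inherits(report, "assessment_report"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (format == "json") {
    path <- file.path(out_dir, "assessment_report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(path))
  }
  tabs <- c("deterministic", "mc_percentiles", "mc_exceedance")
  for (t in tabs) {
    if (is.null(report[[t]])) next
    path <- file.path(out_dir, paste0(t, ".csv"))
    df <- report[[t]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(report$meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}

#' Read back a CSV assessment report
#'
#' Inverse of [write_report()] for the CSV format; numeric columns round
#' trip at full double precision.
#' @param out_dir Directory written by [write_report()].
#' @return An `assessment_report` (metadata list re-read from the JSON
#'   sidecar).
#' @export
read_report <- function(out_dir) {
  read_tab <- function(name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  structure(list(deterministic = read_tab("deterministic"),
                 mc_percentiles = read_tab("mc_percentiles"),
                 mc_exceedance = read_tab("mc_exceedance"),
                 meta = jsonlite::read_json(file.path(out_dir, "run_metadata.json"),
                                            simplifyVector = TRUE)),
            class = "assessment_report")
}

#' Minimum buffer distance meeting an odor exceedance criterion
#'
#' Finds the smallest receptor setback such that the Monte Carlo
#' probability of the odor intensity exceeding `level` is at most
#' `max_prob` at that distance and everywhere beyond it (a buffer protects
#' every resident at or past the setback, so the criterion is applied to
#' the whole tail, not a single point; for stable classes and an elevated
#' breathing-zone receptor the exceedance curve can rise before it decays,
#' which makes the two readings differ). A coarse log-spaced scan brackets
#' the last criterion crossing, then bisection refines it to 1 m. Every
#' evaluation reuses the same seed (common random numbers), so the
#' estimated curve is deterministic and the search well-posed.
#'
#' @param bundle A `case_study_bundle` or [odor_scenario()].
#' @param pollutant Pollutant to assess.
#' @param level Odor-intensity criterion (e.g. 2.5).
#' @param max_prob Largest acceptable exceedance probability.
#' @param bracket Length-2 search interval for the distance, m.
#' @param stability Stability class for the search; default the scenario's.
#' @param config An [mc_config()].
#' @return The buffer distance in metres (within 1 m), the lower bracket
#'   endpoint if it already qualifies, or `NA` with a warning if even the
#'   upper endpoint fails the criterion ("not attainable in bracket").
#' @export
buffer_distance <- function(bundle, pollutant, level, max_prob,
                            bracket = c(20, 1000), stability = NULL,
                            config = mc_config()) {
  scenario <- if (inherits(bundle, "case_study_bundle")) bundle$scenario else bundle
  stopifnot(inherits(scenario, "odor_scenario"))
  check_number(level, "level")
  check_number(max_prob, "max_prob", 0)
  if (max_prob > 1) stop_validation("'max_prob' must be <= 1")
  check_number(bracket, "bracket", 0, strict = TRUE, len = 2L)
  if (bracket[1] >= bracket[2]) stop_validation("'bracket' must be increasing")
  stability <- stability %||% (if (inherits(scenario$stability, "param_dist"))
    "D" else as.character(scenario$stability))
  p_at <- function(x) {
    mc <- run_monte_carlo(scenario_at(scenario, x, stability), config)
    exceedance_probability(mc, pollutant, level)
  }
  if (p_at(bracket[2]) > max_prob) {
    warning("criterion not attainable in bracket [", bracket[1], ", ",
            bracket[2], "] m")
    return(NA_real_)
  }
  # bracket the last crossing of max_prob on a log-spaced scan
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 16))
  pg <- vapply(grid, p_at, numeric(1))
  failing <- which(pg > max_prob)
  if (!length(failing)) return(bracket[1])  # whole bracket qualifies
  lo <- grid[max(failing)]; hi <- grid[max(failing) + 1L]
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (p_at(mid) <= max_prob) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report> ", length(x$meta$pollutants), " pollutant(s), ",
      length(x$meta$distances), " distance(s), stabilities ",
      paste(x$meta$stabilities, collapse = ""), "\n", sep = "")
  d <- x$deterministic
  d$oi <- round(d$oi, 2)  # display rounding only
  print(d[, c("pollutant", "distance", "stability", "oi", "band", "descriptor")],
        row.names = FALSE)
  invisible(x)
}
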