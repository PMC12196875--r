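#' Monte Carlo run configuration
#'
#' @param n_iterations Number of Monte Carlo iterations, >= 1. Default
#'   10 000, enough for stable percentile and exceedance estimates at the
#'   probabilities of interest.
#' @param seed Integer RNG seed; every source of randomness in a run flows
#'   through it.
#' @param randomized Character subset of
#'   `c("cs", "wind_speed", "stability", "theta_air", "theta_w", "foc")`
#'   naming which parameters are drawn from distributions; all others are
#'   held at their scenario (point/mean) values.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000, seed = 0,
                      randomized = c("cs", "wind_speed")) {
  check_number(n_iterations, "n_iterations", 1)
  check_number(seed, "seed")
  allowed <- c("cs", "wind_speed", "stability", "theta_air", "theta_w", "foc")
  bad <- setdiff(randomized, allowed)
  if (length(bad)) {
    stop_validation("unknown randomized parameter(s): ",
                    paste(bad, collapse = ", "))
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), randomized = randomized),
            class = "mc_config")
}

mc_require_dist <- function(obj, what) {
  if (!inherits(obj, "param_dist")) {
    stop_validation("'", what, "' is randomized but the scenario supplies no ",
                    "distribution for it")
  }
  obj
}

#' Monte Carlo propagation through the source-plume-odor chain
#'
#' Draws `n_iterations` parameter vectors with the configured seed, runs
#' the deterministic chain (partitioning, emission, Gaussian plume,
#' odor activity, Weber-Fechner intensity) for every draw and pollutant,
#' and returns the sampled distributions with percentile and exceedance
#' summaries. Identical seed and config give bit-identical results. Draws
#' with zero odor activity are carried as `OI = -Inf` (below every level).
#'
#' @param scenario An [odor_scenario()]. Each randomized parameter must
#'   carry a distribution (`cs_dist`, a `param_dist` wind speed, a
#'   discrete stability table, `matrix_dist` entries).
#' @param config An [mc_config()].
#' @param levels Odor-intensity levels for the exceedance summary. The
#'   defaults bracket the perception threshold (Level 1) and the nuisance
#'   criterion (Level 2.5).
#' @param percentile_qs Percentiles for the summary table.
#' @return Object of class `mc_result`: list with `pollutants`, `samples`
#'   (matrices `epc`, `oav`, `oi` of dim n x n_pollutants), `percentiles`
#'   and `exceedance` data.frames, `total_oav` (per-draw mixture OAV),
#'   `n`, `seed`, `randomized`.
#' @export
run_monte_carlo <- function(scenario, config = mc_config(),
                            levels = c(1, 2, 2.5, 3),
                            percentile_qs = c(5, 25, 50, 75, 90, 95, 99)) {
  stopifnot(inherits(scenario, "odor_scenario"), inherits(config, "mc_config"))
  n <- config$n_iterations
  pollutants <- names(scenario$cs_mean)
  rnd <- config$randomized

  # preserve the caller's RNG state; all run randomness comes from the seed
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  # --- parameter draws (fixed order: cs by pollutant, wind, stability, matrix)
  cs <- sapply(pollutants, function(nm) {
    if ("cs" %in% rnd) {
      d <- mc_require_dist(scenario$cs_dist[[nm]], paste0("cs[", nm, "]"))
      draw_samples(d, n)
    } else rep(scenario$cs_mean[[nm]], n)
  })
  cs <- matrix(cs, nrow = n, dimnames = list(NULL, pollutants))
  if (all(cs == 0)) {
    warning("all-zero solid-phase contents: every odor intensity is -Inf")
  }
  u <- if ("wind_speed" %in% rnd) {
    draw_samples(mc_require_dist(scenario$wind_speed, "wind_speed"), n)
  } else {
    rep(if (inherits(scenario$wind_speed, "param_dist"))
      mean(scenario$wind_speed) else scenario$wind_speed, n)
  }
  stab <- if ("stability" %in% rnd) {
    as.character(draw_samples(mc_require_dist(scenario$stability, "stability"), n))
  } else {
    lab <- if (inherits(scenario$stability, "param_dist")) {
      mean(scenario$stability)
    } else as.character(scenario$stability)
    rep(lab, n)
  }
  mat <- scenario$matrix
  draw_matrix_field <- function(field, default) {
    if (field %in% rnd) {
      draw_samples(mc_require_dist(scenario$matrix_dist[[field]], field), n)
    } else default
  }
  theta_air <- draw_matrix_field("theta_air", mat$theta_air)
  theta_w <- draw_matrix_field("theta_w", mat$theta_w)
  foc <- draw_matrix_field("foc", mat$foc)  # already kg/kg in matrix_dist

  # --- dispersion coefficients per draw (grouped by stability class)
  tab <- scenario$dispersion_table %||% default_dispersion_table()
  x <- scenario$receptor$downwind
  sy <- numeric(n); sz <- numeric(n)
  for (cl in unique(stab)) {
    sig <- dispersion_coefficients(stability_param_table(cl, x, tab), x)
    idx <- stab == cl
    sy[idx] <- sig[["sigma_y"]]
    sz[idx] <- sig[["sigma_z"]]
  }

  # --- vectorized chain per pollutant
  epc <- oav <- oi <- matrix(NA_real_, n, length(pollutants),
                             dimnames = list(NULL, pollutants))
  v_si <- scenario$excavation$dig_rate / 3600 * scenario$excavation$n_excavators
  rec <- scenario$receptor
  for (nm in pollutants) {
    p <- scenario$registry[[nm]]
    denom <- theta_w + mat$bulk_density * p$koc * foc + p$henry * theta_air
    cair <- cs[, nm] * p$henry * mat$bulk_density / denom
    er <- v_si * theta_air * cair
    epc[, nm] <- gaussian_plume_epc(er, u, sy, sz, rec$lateral,
                                    rec$receptor_height, rec$release_height)
    oav[, nm] <- epc[, nm] / p$odor_threshold
    oi[, nm] <- wf_intensity_sentinel(oav[, nm], p$wf_slope, p$wf_intercept)
  }

  pct <- do.call(rbind, lapply(pollutants, function(nm) {
    data.frame(pollutant = nm, q = percentile_qs,
               epc = stats::quantile(epc[, nm], percentile_qs / 100,
                                     type = 7, names = FALSE),
               oav = stats::quantile(oav[, nm], percentile_qs / 100,
                                     type = 7, names = FALSE),
               oi = stats::quantile(oi[, nm], percentile_qs / 100,
                                    type = 7, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  exc <- do.call(rbind, lapply(pollutants, function(nm) {
    data.frame(pollutant = nm, level = levels,
               probability = vapply(levels, function(L) mean(oi[, nm] > L),
                                    numeric(1)),
               stringsAsFactors = FALSE)
  }))
  structure(list(pollutants = pollutants,
                 samples = list(epc = epc, oav = oav, oi = oi),
                 total_oav = rowSums(oav),
                 percentiles = pct, exceedance = exc,
                 n = n, seed = config$seed, randomized = rnd),
            class = "mc_result")
}

mc_samples <- function(result, pollutant, what = "oi") {
  stopifnot(inherits(result, "mc_result"))
  if (!pollutant %in% result$pollutants) {
    stop_validation("pollutant '", pollutant, "' not present in this result")
  }
  what <- match.arg(what, c("oi", "oav", "epc"))
  result$samples[[what]][, pollutant]
}

#' Exceedance probability of an odor-intensity level
#'
#' Fraction of Monte Carlo draws whose continuous odor intensity strictly
#' exceeds `level`; non-increasing in `level`. Ties are measure-zero under
#' continuous input distributions; the strict inequality is the documented
#' convention.
#'
#' @param result An `mc_result` from [run_monte_carlo()].
#' @param pollutant Pollutant name present in the result.
#' @param level Odor-intensity threshold (e.g. 2.5, the nuisance criterion).
#' @return Probability in [0, 1].
#' @export
exceedance_probability <- function(result, pollutant, level) {
  check_number(level, "level")
  mean(mc_samples(result, pollutant, "oi") > level)
}

#' Empirical percentile of a Monte Carlo sample vector
#'
#' Linear interpolation between order statistics (the common empirical
#' quantile definition, R's `type = 7`), so e.g. the median of samples
#' `1..100` is 50.5 and printed percentile ratios are reproducible.
#'
#' @param result An `mc_result`.
#' @param pollutant Pollutant name.
#' @param q Percentile in (0, 100).
#' @param what Which sampled quantity: `"oi"` (default), `"oav"` or
#'   `"epc"`.
#' @return The empirical percentile value.
#' @export
percentile_value <- function(result, pollutant, q, what = "oi") {
  if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q >= 100)) {
    stop_validation("'q' must lie strictly within (0, 100)")
  }
  stats::quantile(mc_samples(result, pollutant, what), q / 100,
                  type = 7, names = FALSE)
}

#' Empirical CDF of a Monte Carlo sample vector
#' @inheritParams percentile_value
#' @return A `stats::ecdf` step function.
#' @export
mc_ecdf <- function(result, pollutant, what = "oi") {
  stats::ecdf(mc_samples(result, pollutant, what))
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> ", x$n, " iterations, seed ", x$seed, ", randomized: ",
      paste(x$randomized, collapse = ", "), "\n", sep = "")
  cat("exceedance summary (P[OI > level]):\n")
  print(x$exceedance, row.names = FALSE)
  invisible(x)
}
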