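#' Parameter distributions for uncertainty propagation
#'
#' Lightweight distribution objects describing the uncertainty of a scalar
#' model parameter; every kind is seedable through R's RNG via
#' [draw_samples()]. Supported kinds: point (degenerate), uniform,
#' triangular, lognormal, and discrete (finite support with weights).
#'
#' @param value Point value (kind `point`).
#' @return An object of class `param_dist`.
#' @name param_dist
NULL

new_param_dist <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_point <- function(value) {
  check_number(value, "value")
  new_param_dist("point", list(value = value))
}

#' @rdname param_dist
#' @param min,max Lower/upper bounds (kind `uniform` and `triangular`);
#'   `min < max`.
#' @export
dist_uniform <- function(min, max) {
  check_number(min, "min"); check_number(max, "max")
  if (min >= max) stop_validation("uniform: 'min' must be < 'max'")
  new_param_dist("uniform", list(min = min, max = max))
}

#' @rdname param_dist
#' @param mode Mode of the triangular density, in `[min, max]`.
#' @export
dist_triangular <- function(min, mode, max) {
  check_number(min, "min"); check_number(mode, "mode"); check_number(max, "max")
  if (min >= max || mode < min || mode > max) {
    stop_validation("triangular: need min < max and mode within [min, max]")
  }
  new_param_dist("triangular", list(min = min, mode = mode, max = max))
}

#' @rdname param_dist
#' @param meanlog,sdlog Natural-log-space mean and standard deviation (kind
#'   `lognormal`); `sdlog >= 0` (zero gives a degenerate lognormal).
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  check_number(meanlog, "meanlog"); check_number(sdlog, "sdlog", 0)
  new_param_dist("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname param_dist
#' @param values Support values (kind `discrete`); numeric or character.
#' @param probs Weights, same length as `values`, summing to 1 within 1e-9.
#' @export
dist_discrete <- function(values, probs) {
  if (length(values) != length(probs) || !length(values)) {
    stop_validation("discrete: 'values' and 'probs' must be equal, positive length")
  }
  check_number(probs, "probs", 0, len = length(probs))
  if (abs(sum(probs) - 1) > 1e-9) {
    stop_validation("discrete: weights must sum to 1 (got ", sum(probs), ")")
  }
  new_param_dist("discrete", list(values = values, probs = probs))
}

#' Draw seeded samples from a parameter distribution
#'
#' Uses the current RNG state; callers seed once per run (see
#' [run_monte_carlo()]) so identical seeds give identical draws.
#'
#' @param dist A `param_dist`.
#' @param n Number of draws.
#' @return Length-`n` vector (numeric, or the support's type for
#'   `discrete`).
#' @export
draw_samples <- function(dist, n) {
  stopifnot(inherits(dist, "param_dist"))
  check_number(n, "n", 1)
  p <- dist$params
  switch(dist$kind,
    point     = rep(p$value, n),
    uniform   = stats::runif(n, p$min, p$max),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    triangular = {
      # inverse-CDF of the triangular distribution
      u <- stats::runif(n)
      fc <- (p$mode - p$min) / (p$max - p$min)
      lo <- p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min))
      hi <- p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode))
      ifelse(u < fc, lo, hi)
    },
    discrete  = p$values[sample.int(length(p$values), n, replace = TRUE,
                                    prob = p$probs)],
    stop_validation("unknown distribution kind '", dist$kind, "'"))
}

#' Mean of a parameter distribution
#'
#' Arithmetic expectation used by the deterministic assessment path when a
#' parameter is described by a distribution.
#' @param x A `param_dist`.
#' @param ... Unused.
#' @return The distribution mean (for `discrete` over characters, the
#'   highest-weight value).
#' @export
mean.param_dist <- function(x, ...) {
  p <- x$params
  switch(x$kind,
    point = p$value,
    uniform = (p$min + p$max) / 2,
    triangular = (p$min + p$mode + p$max) / 3,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    discrete = if (is.numeric(p$values)) sum(p$values * p$probs)
               else p$values[which.max(p$probs)])
}

#' Fit a lognormal distribution to positive concentration samples
#'
#' Moment fit in natural-log space: `meanlog = mean(log x)`,
#' `sdlog = sd(log x)` (0 for constant samples). This is the standard way
#' measured solid-phase concentration tables enter the Monte Carlo source
#' term.
#'
#' @param samples Numeric vector of at least 3 strictly positive values.
#' @return A `dist_lognormal` `param_dist`.
#' @export
fit_lognormal <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 3L) {
    stop_validation("need at least 3 numeric samples")
  }
  bad <- which(is.na(samples) | samples <= 0)
  if (length(bad)) {
    stop_validation("all samples must be > 0; offending index(es): ",
                    paste(utils::head(bad, 10), collapse = ", "))
  }
  lx <- log(samples)
  s <- stats::sd(lx)
  dist_lognormal(mean(lx), if (is.na(s)) 0 else s)
}
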