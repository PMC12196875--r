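#' Odor activity value
#'
#' Ratio of an odorant's air concentration to its olfactory threshold;
#' values above 1 indicate perceptible odor potential.
#'
#' @param ci Pollutant air concentration, mg/m3, >= 0 (vectorized).
#' @param ct Olfactory threshold, mg/m3, > 0; alternatively pass a
#'   [pollutant_properties()] object and its threshold is used.
#' @return Dimensionless OAV, `ci / ct`.
#' @examples
#' odor_activity_value(0.85, 0.085)  # ethylbenzene at 10x threshold -> 10
#' @export
odor_activity_value <- function(ci, ct) {
  if (inherits(ct, "pollutant_properties")) ct <- ct$odor_threshold
  if (!is.numeric(ct) || length(ct) != 1L || is.na(ct) || ct <= 0) {
    stop_validation("'ct' (olfactory threshold) must be > 0")
  }
  if (any(ci < 0) || anyNA(ci)) stop_validation("'ci' must be >= 0")
  ci / ct
}

#' Total odor activity value of a gas mixture
#'
#' Component OAVs add; the sum is the mixture's total odor activity, used
#' here as the model's odor concentration (dilutions-to-threshold) measure.
#'
#' @param oavs Numeric vector of component OAVs, all >= 0; an empty vector
#'   sums to 0.
#' @return The arithmetic sum.
#' @export
total_odor_activity <- function(oavs) {
  if (length(oavs) && (any(oavs < 0) || anyNA(oavs))) {
    stop_validation("component OAVs must be >= 0")
  }
  sum(oavs)
}

#' Weber-Fechner odor intensity
#'
#' Perceived odor intensity grows with the logarithm of the stimulus:
#' `OI = k * log10(OAV) + B` with pollutant-specific coefficients k, B.
#' Strictly increasing in OAV. `oav <= 0` is a domain error here (the log
#' is undefined); the Monte Carlo layer maps zero-OAV draws to a `-Inf`
#' sentinel instead, counted below every level, so that legitimately
#' negative intensities near the threshold are preserved rather than
#' floored at zero.
#'
#' @param oav Dimensionless odor activity value, > 0 (vectorized).
#' @param pollutant A [pollutant_properties()] carrying `wf_slope` (k) and
#'   `wf_intercept` (B).
#' @return Dimensionless odor intensity OI (may be negative).
#' @export
odor_intensity <- function(oav, pollutant) {
  stopifnot(inherits(pollutant, "pollutant_properties"))
  if (any(oav <= 0) || anyNA(oav)) {
    stop_validation("'oav' must be > 0: log10 is undefined at or below zero")
  }
  pollutant$wf_slope * log10(oav) + pollutant$wf_intercept
}

INTENSITY_DESCRIPTORS <- c("none", "slight", "weak", "noticeable",
                           "strong", "unbearable")

#' Classify continuous odor intensity on the six-level scale
#'
#' China's six-level odor intensity scale: Level 0 no odor, 1 slight
#' perception, 2 weak, 3 noticeable, 4 strong, 5 unbearable. The band is
#' the nearest level, clamped to [0, 5]: `clamp(floor(oi + 0.5), 0, 5)`.
#' The continuous intensity is reported alongside the band; exceedance
#' tests (OI > 1, OI > 2.5, ...) always use the continuous value, never
#' the band.
#'
#' @param oi Continuous odor intensity (vectorized; `-Inf` allowed and
#'   classified as band 0).
#' @return A data.frame with columns `oi` (the continuous value), `band`
#'   (integer 0-5) and `descriptor`.
#' @examples
#' classify_intensity(2.2)   # band 2, "weak"
#' @export
classify_intensity <- function(oi) {
  if (!is.numeric(oi) || anyNA(oi)) stop_validation("'oi' must be numeric")
  band <- pmin(pmax(floor(oi + 0.5), 0), 5)
  band[!is.finite(band)] <- 0  # -Inf sentinel: below every level
  band <- as.integer(band)
  data.frame(oi = oi, band = band,
             descriptor = INTENSITY_DESCRIPTORS[band + 1L],
             stringsAsFactors = FALSE)
}

#' Health-risk Potential Hazard Index
#'
#' Ratio of the mean solid-phase pollutant content to its soil risk
#' screening value; > 1 flags a potential short-term health hazard.
#'
#' @param cs_mean Mean solid-phase content, mg/kg, >= 0.
#' @param screening Soil risk screening value, mg/kg, > 0.
#' @return Dimensionless PHI.
#' @examples
#' phi_health(18, 28)  # ethylbenzene: 0.64
#' @export
phi_health <- function(cs_mean, screening) {
  if (!is.numeric(screening) || length(screening) != 1L || is.na(screening) ||
      screening <= 0) {
    stop_validation("'screening' must be > 0")
  }
  if (any(cs_mean < 0) || anyNA(cs_mean)) stop_validation("'cs_mean' must be >= 0")
  cs_mean / screening
}

#' Odor Potential Hazard Index
#'
#' Ratio of the mean pore-gas concentration to the olfactory threshold;
#' quantifies the odor nuisance potential of the source itself. Note the
#' deliberately different numerator from [phi_health()]: health screening
#' compares solid-phase content to soil limits, odor screening compares
#' the pore-gas concentration driving emissions to the nose's threshold.
#'
#' @param cair_mean Mean pore-gas concentration, mg/m3, >= 0.
#' @param ct Olfactory threshold, mg/m3, > 0.
#' @return Dimensionless PHI.
#' @export
phi_odor <- function(cair_mean, ct) {
  if (!is.numeric(ct) || length(ct) != 1L || is.na(ct) || ct <= 0) {
    stop_validation("'ct' must be > 0")
  }
  if (any(cair_mean < 0) || anyNA(cair_mean)) {
    stop_validation("'cair_mean' must be >= 0")
  }
  cair_mean / ct
}
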