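#' Acoustic target strength of a single fish
#'
#' Species-calibrated log-linear target-strength model:
#' `TS = 19.1 * log10(L) - 0.9 * log10(f) - 62` (dB), with body length `L`
#' in cm and transducer frequency `f` in kHz.  The three constants are
#' configurable (they come from a species-specific gill-net calibration).
#'
#' @param length_cm body length, cm; positive.
#' @param frequency_khz transducer frequency, kHz (default 210).
#' @param b_length,b_freq,b0 model constants.
#' @return Target strength, dB (vectorised over `length_cm`).
#' @examples
#' target_strength(10)  # about -45 dB at 210 kHz
#' @export
target_strength <- function(length_cm, frequency_khz = 210,
                            b_length = 19.1, b_freq = -0.9, b0 = -62) {
  if (any(length_cm <= 0)) stop("'length_cm' must be positive")
  if (any(frequency_khz <= 0)) stop("'frequency_khz' must be positive")
  b_length * log10(length_cm) + b_freq * log10(frequency_khz) + b0
}

#' Mean individual weight from a gill-net sample
#'
#' @param sample a data.frame with a `weight_g` column (e.g. the `gillnet`
#'   component of [generate_survey()]), or a numeric vector of weights.
#' @return Arithmetic mean weight, g.
#' @export
mean_weight <- function(sample) {
  w <- if (is.data.frame(sample)) sample$weight_g else as.numeric(sample)
  if (length(w) == 0) stop("empty gill-net sample")
  if (any(w <= 0)) stop("weights must be positive")
  mean(w)
}

#' Volume-weighted mean acoustic density
#'
#' Pools transect-segment densities into a single lake-wide density,
#' weighting each segment by its insonified volume (equal-volume segments
#' reduce to the plain mean).
#'
#' @param acoustic data.frame with `density_ind_per_m3` and optionally
#'   `segment_volume_m3`.
#' @return Mean density, individuals per m3.
#' @export
volume_weighted_density <- function(acoustic) {
  d <- acoustic$density_ind_per_m3
  if (length(d) == 0) stop("no acoustic segments")
  v <- acoustic$segment_volume_m3 %||% rep(1, length(d))
  sum(d * v) / sum(v)
}

#' Lake-wide fish population biomass
#'
#' `FP = mean density (ind/m3) x mean weight (g) x lake volume (m3) x 1e-6`,
#' in tonnes.
#'
#' @param mean_density individuals per m3.
#' @param mean_weight_g grams.
#' @param lake_volume_m3 m3.
#' @param year optional survey year carried into the record.
#' @return An object of class `fp_estimate`: `year`, `mean_density`,
#'   `mean_weight`, `lake_volume`, `fp` (tonnes).
#' @examples
#' fish_population(0.001, 250, 9e10)$fp  # 22,500 t
#' @export
fish_population <- function(mean_density, mean_weight_g, lake_volume_m3,
                            year = NA_integer_) {
  if (mean_density < 0 || mean_weight_g < 0 || lake_volume_m3 < 0)
    stop("density, weight and volume must all be >= 0")
  structure(list(year = year,
                 mean_density = mean_density,
                 mean_weight = mean_weight_g,
                 lake_volume = lake_volume_m3,
                 fp = mean_density * mean_weight_g * lake_volume_m3 * 1e-6),
            class = "fp_estimate")
}

#' @export
print.fp_estimate <- function(x, ...) {
  cat(sprintf(
    "Fish population estimate%s: %.1f t (%.3g ind/m3 x %.1f g x %.3g m3)\n",
    if (is.na(x$year)) "" else paste0(" (", x$year, ")"),
    x$fp, x$mean_density, x$mean_weight, x$lake_volume))
  invisible(x)
}

#' Estimate the stock from a survey object
#'
#' Convenience wrapper chaining [volume_weighted_density()],
#' [mean_weight()] and [fish_population()] over a [generate_survey()]
#' result (or any list with the same components).
#'
#' @param survey a `lake_survey`.
#' @return An `fp_estimate`.
#' @export
survey_fp <- function(survey) {
  fish_population(volume_weighted_density(survey$acoustic),
                  mean_weight(survey$gillnet),
                  survey$lake_volume_m3,
                  year = survey$year %||% NA_integer_)
}
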