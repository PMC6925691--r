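#' @keywords internal
"_PACKAGE"

#' Monitored vital signs
#'
#' The four bedside-monitor signals the pipeline works with: mean arterial
#' pressure (`MAP`, mmHg), heart rate (`HR`, bpm), respiratory rate
#' (`RR`, breaths/min) and core temperature (`TEMP`, degrees Celsius).
#'
#' @export
VITAL_SIGNS <- c("MAP", "HR", "RR", "TEMP")

#' Variability feature names
#'
#' `f1` counts trend changes (interior local extrema); `f2`--`f5` are the
#' mean, median, minimum and maximum absolute swing between consecutive
#' points of the endpoint-augmented extrema sequence, in sign units.
#'
#' @export
VARIABILITY_FEATURES <- c("f1", "f2", "f3", "f4", "f5")

match_sign <- function(sign) {
  match.arg(sign, VITAL_SIGNS)
}

#' Per-sign generator parameters
#'
#' Describes the instability process of one vital sign for one patient group:
#' how many turning points a reference 8-hour window contains on average, how
#' large the swings between turning points are, the physiologic baseline the
#' path oscillates around, measurement noise, and hard physiologic bounds.
#'
#' @param extrema_count_mean Expected number of turning points per reference
#'   8-hour window (48 samples); dimensionless, must be >= 0.
#' @param swing_magnitude_mean Mean absolute swing between consecutive turning
#'   points, in sign units; must be > 0.
#' @param swing_magnitude_sd Standard deviation of swing magnitudes (gamma
#'   distributed); defaults to 80% of the mean.
#' @param baseline_level Physiologic baseline the path starts from, sign units.
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise
#'   added to the piecewise-linear skeleton; defaults to 5% of
#'   `swing_magnitude_mean`, small enough that nominal turning points survive
#'   extraction instead of being swamped by noise-induced reversals.
#' @param bounds Length-2 numeric `(low, high)` physiologic bounds; generated
#'   values are folded/clipped into this range.
#' @param resolution Instrument recording resolution in sign units (e.g.
#'   1 mmHg, 0.1 degrees C); generated values are rounded to this quantum,
#'   as bedside monitors record them. `0` disables rounding.
#' @param dispersion Between-patient heterogeneity: the log-sd of a
#'   mean-one lognormal multiplier drawn per window and applied to the
#'   turning-point rate and (independently) to the swing-magnitude mean.
#'   Without it every patient shares one instability level and the
#'   between-patient feature spread collapses to counting noise.
#' @return A list of class `sign_params`.
#' @export
sign_params <- function(extrema_count_mean,
                        swing_magnitude_mean,
                        swing_magnitude_sd = 0.8 * swing_magnitude_mean,
                        baseline_level,
                        noise_sd = 0.05 * swing_magnitude_mean,
                        bounds,
                        resolution = 0,
                        dispersion = 0.3) {
  stopifnot(
    is.numeric(extrema_count_mean), length(extrema_count_mean) == 1L,
    extrema_count_mean >= 0,
    is.numeric(swing_magnitude_mean), swing_magnitude_mean > 0,
    is.numeric(swing_magnitude_sd), swing_magnitude_sd > 0,
    is.numeric(noise_sd), noise_sd >= 0,
    is.numeric(bounds), length(bounds) == 2L, bounds[1] < bounds[2],
    is.numeric(resolution), resolution >= 0,
    is.numeric(dispersion), dispersion >= 0
  )
  if (!(bounds[1] < baseline_level && baseline_level < bounds[2])) {
    stop("baseline_level must lie strictly inside the physiologic bounds")
  }
  structure(
    list(
      extrema_count_mean = extrema_count_mean,
      swing_magnitude_mean = swing_magnitude_mean,
      swing_magnitude_sd = swing_magnitude_sd,
      baseline_level = baseline_level,
      noise_sd = noise_sd,
      bounds = as.numeric(bounds),
      resolution = resolution,
      dispersion = dispersion
    ),
    class = "sign_params"
  )
}

#' Group-level generator parameters
#'
#' Bundles one [sign_params()] per vital sign for one patient group.
#'
#' @param group `"septic"` or `"control"`.
#' @param signs Named list with one `sign_params` entry per element of
#'   [VITAL_SIGNS].
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(group = c("septic", "control"), signs) {
  group <- match.arg(group)
  if (!setequal(names(signs), VITAL_SIGNS)) {
    stop("signs must be a named list with exactly the entries ",
         paste(VITAL_SIGNS, collapse = ", "))
  }
  for (s in VITAL_SIGNS) {
    if (!inherits(signs[[s]], "sign_params")) {
      stop("signs[['", s, "']] is not a sign_params object")
    }
  }
  structure(list(group = group, signs = signs[VITAL_SIGNS]),
            class = "generator_params")
}

#' Published per-group feature statistics used as calibration targets
#'
#' Group means and standard deviations of the five variability features per
#' vital sign, as reported for a 300 septic / 300 control adult ICU cohort
#' (8-hour collection window, 4-hour prediction horizon, 6 samples/hour).
#' These printed statistics are the moment-matching targets for the synthetic
#' cohort generator; the real records themselves are not publicly available.
#'
#' @return A data.frame with columns `sign`, `feature`, `septic_mean`,
#'   `septic_sd`, `control_mean`, `control_sd`. Features are `f1` (trend-change
#'   count) and `f2`--`f5` (mean/median/min/max swing intensity, sign units).
#' @export
reference_group_stats <- function() {
  tab <- rbind(
    c("MAP",  "f1", 21.71,  8.48, 11.17, 10.94),
    c("MAP",  "f2", 12.48,  8.60, 22.44, 14.58),
    c("MAP",  "f3", 10.15,  9.27, 21.14, 15.16),
    c("MAP",  "f4",  3.35,  7.08, 13.64, 14.53),
    c("MAP",  "f5", 35.15, 17.60, 37.62, 18.49),
    c("HR",   "f1", 23.56,  6.32, 22.96,  5.88),
    c("HR",   "f2",  9.17,  5.79,  8.591,  4.89),
    c("HR",   "f3",  6.90,  5.32,  6.117,  3.98),
    c("HR",   "f4",  1.31,  0.88,  1.231,  0.75),
    c("HR",   "f5", 30.18, 21.19, 28.87, 19.40),
    c("RR",   "f1", 15.76, 10.02, 11.53, 11.30),
    c("RR",   "f2",  5.39,  3.69,  7.176,  4.86),
    c("RR",   "f3",  4.933,  4.252,  7.033,  5.57),
    c("RR",   "f4",  1.83,  2.86,  4.086,  5.22),
    c("RR",   "f5", 11.61,  6.46, 12.00,  6.29),
    c("TEMP", "f1",  7.76,  5.64,  8.73,  5.02),
    c("TEMP", "f2",  0.75,  0.91,  0.63,  0.67),
    c("TEMP", "f3",  0.56,  0.93,  0.42,  0.67),
    c("TEMP", "f4",  0.33,  0.91,  0.11,  0.41),
    c("TEMP", "f5",  1.68,  1.50,  1.72,  1.46)
  )
  out <- data.frame(
    sign = tab[, 1],
    feature = tab[, 2],
    septic_mean = as.numeric(tab[, 3]),
    septic_sd = as.numeric(tab[, 4]),
    control_mean = as.numeric(tab[, 5]),
    control_sd = as.numeric(tab[, 6]),
    stringsAsFactors = FALSE
  )
  out
}

# Clinically typical baselines, hard bounds and recording resolution per sign.
.sign_physio <- list(
  MAP  = list(baseline = 75,  bounds = c(40, 140), resolution = 1),
  HR   = list(baseline = 80,  bounds = c(30, 190), resolution = 1),
  RR   = list(baseline = 16,  bounds = c(4, 50),   resolution = 1),
  TEMP = list(baseline = 37.0, bounds = c(34, 41), resolution = 0.1)
)

# Gamma shape giving median/mean ratio r (Wilson-Hilferty approximation
# median ~ mean * (1 - 1/(9k))^3), clamped to a sane range.
.shape_from_median_ratio <- function(r) {
  r <- min(max(r, 0.4), 0.98)
  k <- 1 / (9 * (1 - r^(1/3)))
  min(max(k, 0.6), 30)
}

#' Default generator parameters for one group
#'
#' Starting parameters derived from the published group statistics
#' ([reference_group_stats()]): the turning-point rate starts at the printed
#' trend-change count, swing magnitudes at the printed mean intensity, and the
#' swing-magnitude spread is chosen so the gamma median/mean ratio matches the
#' printed median/mean intensity ratio. Septic parameters describe the
#' *full-instability* state reached near sepsis onset; because septic windows
#' ramp up from control-level instability (see [instability_ramp()]), the
#' septic rates are inflated by the default window's mean ramp factor so that
#' a default cohort lands near the printed septic means. [calibrate_generator()]
#' refines these starting points by simulation-based moment matching.
#'
#' @param group `"septic"` or `"control"`.
#' @return A [generator_params()] object.
#' @export
default_generator_params <- function(group = c("septic", "control")) {
  group <- match.arg(group)
  ref <- reference_group_stats()
  get_ref <- function(sign, feature, col) {
    ref[ref$sign == sign & ref$feature == feature, col]
  }
  # mean ramp factor of the default 8 h window at 4 h horizon
  g_bar <- mean(instability_ramp(seq(12, 4, length.out = 49)))
  signs <- list()
  for (s in VITAL_SIGNS) {
    if (group == "control") {
      cm <- get_ref(s, "f1", "control_mean")
      sm <- get_ref(s, "f2", "control_mean")
      ratio <- get_ref(s, "f3", "control_mean") / sm
    } else {
      # invert the ramp dilution: window mean = control + g_bar*(full - control)
      cm_c <- get_ref(s, "f1", "control_mean")
      sm_c <- get_ref(s, "f2", "control_mean")
      cm <- max(cm_c + (get_ref(s, "f1", "septic_mean") - cm_c) / g_bar, 0.5)
      sm <- max(sm_c + (get_ref(s, "f2", "septic_mean") - sm_c) / g_bar,
                0.05 * sm_c)
      ratio <- get_ref(s, "f3", "septic_mean") / get_ref(s, "f2", "septic_mean")
    }
    shape <- .shape_from_median_ratio(ratio)
    ssd <- sm / sqrt(shape)
    phys <- .sign_physio[[s]]
    # between-patient spread: printed f1 sd in excess of the counting noise
    t_f1m <- get_ref(s, "f1", paste0(group, "_mean"))
    t_f1s <- get_ref(s, "f1", paste0(group, "_sd"))
    disp <- sqrt(max(t_f1s^2 - t_f1m, 0.01)) / max(t_f1m, 1)
    disp <- min(max(disp, 0.05), 0.5)
    signs[[s]] <- sign_params(
      extrema_count_mean = cm,
      swing_magnitude_mean = sm,
      swing_magnitude_sd = ssd,
      baseline_level = phys$baseline,
      noise_sd = 0.05 * sm,
      bounds = phys$bounds,
      resolution = phys$resolution,
      dispersion = disp
    )
  }
  generator_params(group, signs)
}

#' Cohort layout specification
#'
#' Describes the simulated study design: group sizes, the collection interval
#' `T_hours` (features are extracted from this window), the prediction horizon
#' (gap between the prediction moment and sepsis detection `T0`), the monitor
#' sampling rate and the master seed.
#'
#' @param n_septic,n_control Patients per group.
#' @param T_hours Data-collection interval in hours (default 8).
#' @param sampling_per_hour Monitor samples per hour (default 6, i.e. every
#'   10 minutes).
#' @param horizon_hours Hours between the prediction moment and `T0`
#'   (default 4).
#' @param seed Master RNG seed for cohort simulation.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_septic = 300, n_control = 300, T_hours = 8,
                        sampling_per_hour = 6, horizon_hours = 4, seed = 1L) {
  stopifnot(
    n_septic >= 0, n_control >= 0,
    T_hours >= 1, sampling_per_hour >= 1, horizon_hours >= 0,
    is.numeric(seed), length(seed) == 1L
  )
  if (T_hours + horizon_hours > 24) {
    stop("T_hours + horizon_hours must not exceed 24 hours of records")
  }
  structure(
    list(
      n_septic = as.integer(n_septic),
      n_control = as.integer(n_control),
      T_hours = T_hours,
      sampling_per_hour = as.integer(sampling_per_hour),
      horizon_hours = horizon_hours,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: %d septic + %d control, T = %g h at %d samples/h, horizon = %g h, seed = %d\n",
    x$n_septic, x$n_control, x$T_hours, x$sampling_per_hour,
    x$horizon_hours, x$seed
  ))
  invisible(x)
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf("Generator parameters (%s group):\n", x$group))
  for (s in VITAL_SIGNS) {
    p <- x$signs[[s]]
    cat(sprintf(
      "  %-4s extrema/8h %6.2f | swing %5.2f +/- %-5.2f | baseline %5.1f | noise %4.2f | disp %4.2f | bounds [%g, %g]\n",
      s, p$extrema_count_mean, p$swing_magnitude_mean, p$swing_magnitude_sd,
      p$baseline_level, p$noise_sd, p$dispersion, p$bounds[1], p$bounds[2]
    ))
  }
  invisible(x)
}
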