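#' Septic instability ramp
#'
#' Fraction of full septic instability as a function of hours before sepsis
#' detection (`T0`). Instability is at control level 12 h or more before `T0`,
#' interpolates linearly between 12 h and 9 h before `T0`, and is at full
#' septic level within the final 9 h. Control patients are unramped
#' (factor 0 throughout). The shape makes longer prediction horizons dilute
#' the septic signal (windows pushed away from `T0` overlap the ramp), while
#' the default 8-hour window at a 4-hour horizon carries most of it.
#'
#' @param hours_before_t0 Numeric vector of times, in hours before `T0`.
#' @return Numeric vector of ramp factors in `[0, 1]`.
#' @export
instability_ramp <- function(hours_before_t0) {
  pmin(pmax((12 - hours_before_t0) / 3, 0), 1)
}

# Reflect values into [lo, hi] (triangle fold); keeps swings physiologic
# without flattening them at the boundary.
.fold <- function(x, lo, hi) {
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  ifelse(y > (hi - lo), period - y, y) + lo
}

# Number of samples in the reference 8-hour window; extrema_count_mean is
# expressed per this window so rates transfer across window lengths.
.REF_SAMPLES <- 48

# Core series engine. Generates one sign's sampled series of length n under
# parameters that interpolate between a low-instability state (par_lo) and a
# high-instability state (par_hi) according to the per-sample ramp factor g.
# Construction: inhomogeneous Poisson turning points, gamma swing magnitudes,
# alternating up/down piecewise-linear path folded into the physiologic
# bounds, linear resampling on the grid, additive Gaussian noise, clipping,
# and rounding to the instrument recording resolution (sub-quantum noise
# collapses into plateaus, as on a real monitor).
# Uses the current RNG stream (callers manage seeding).
.sim_series <- function(par_hi, par_lo, g, n) {
  stopifnot(n >= 2, length(g) == n)
  mix <- function(field) (1 - g) * par_lo[[field]] + g * par_hi[[field]]
  # between-patient heterogeneity: one mean-one lognormal multiplier per
  # window for the turning-point rate and one for the swing scale
  g_bar <- mean(g)
  d_lo <- if (is.null(par_lo$dispersion)) 0 else par_lo$dispersion
  d_hi <- if (is.null(par_hi$dispersion)) 0 else par_hi$dispersion
  disp <- (1 - g_bar) * d_lo + g_bar * d_hi
  m_rate <- if (disp > 0) stats::rlnorm(1, -disp^2 / 2, disp) else 1
  m_swing <- if (disp > 0) stats::rlnorm(1, -disp^2 / 2, disp) else 1
  rate <- m_rate * mix("extrema_count_mean") / .REF_SAMPLES  # per sample
  lambda <- sum(rate)
  lo <- par_lo$bounds[1]
  hi <- par_lo$bounds[2]
  k <- stats::rpois(1L, lambda)
  k <- min(k, n - 2L)

  quantize <- function(x) {
    res <- par_lo$resolution
    if (is.null(res) || res <= 0) return(x)
    round(x / res) * res
  }

  base <- (1 - g[1]) * par_lo$baseline_level + g[1] * par_hi$baseline_level
  if (k == 0L) {
    skeleton <- rep(base, n)
    noise_sd <- mix("noise_sd")
    out <- skeleton + stats::rnorm(n, 0, noise_sd)
    return(quantize(pmin(pmax(out, lo), hi)))
  }

  # turning positions with density proportional to the local rate, placed by
  # stratified inverse-CDF sampling (one jittered point per equal-mass
  # stratum): spreads points out so that neighbouring turning points rarely
  # fall inside one sampling gap and cancel on the grid
  cum <- cumsum(rate)
  u <- (seq_len(k) - stats::runif(k)) / k
  pos <- stats::approx(x = c(0, cum), y = c(1, seq_len(n)),
                       xout = u * cum[n], ties = "ordered")$y
  pos <- pmin(pmax(pos, 1.01), n - 0.01)
  # hard-core thinning: turning points closer than ~one sampling gap produce
  # partially sampled swings (spurious tiny intensities) on the grid
  if (k > 1L) {
    keep <- logical(k)
    last <- -Inf
    for (j in seq_len(k)) {
      if (pos[j] - last >= 1.2) { keep[j] <- TRUE; last <- pos[j] }
    }
    pos <- pos[keep]
    k <- length(pos)
    if (k == 0L) { pos <- numeric(0) }
  }
  if (k == 0L) {
    skeleton <- rep(base, n)
    out <- skeleton + stats::rnorm(n, 0, mix("noise_sd"))
    return(quantize(pmin(pmax(out, lo), hi)))
  }

  # swing magnitudes drawn with locally interpolated gamma parameters;
  # one extra swing carries the path from the last turning point to the edge
  knot_x <- c(pos, n)
  gi <- stats::approx(seq_len(n), g, xout = knot_x)$y
  m <- m_swing *
    ((1 - gi) * par_lo$swing_magnitude_mean + gi * par_hi$swing_magnitude_mean)
  s <- m_swing *
    ((1 - gi) * par_lo$swing_magnitude_sd + gi * par_hi$swing_magnitude_sd)
  shape <- (m / s)^2
  mags <- stats::rgamma(k + 1L, shape = shape, rate = shape / m)

  dir <- sample(c(-1, 1), 1L)
  v <- numeric(k + 2L)
  v[1] <- base
  for (j in seq_len(k + 1L)) {
    v[j + 1L] <- .fold(v[j] + dir * mags[j], lo, hi)
    dir <- -dir
  }
  skeleton <- stats::approx(c(1, knot_x), v, xout = seq_len(n),
                            ties = "ordered")$y
  out <- skeleton + stats::rnorm(n, 0, mix("noise_sd"))
  quantize(pmin(pmax(out, lo), hi))
}

#' Construct a vital-sign window object
#'
#' @param values Numeric measurement vector (no missing values).
#' @param sign One of [VITAL_SIGNS].
#' @param T_hours Window length in hours.
#' @param sampling_per_hour Samples per hour.
#' @param patient_id Optional patient identifier.
#' @return A list of class `vital_window`.
#' @export
vital_window <- function(values, sign, T_hours, sampling_per_hour = 6,
                         patient_id = NA_character_) {
  sign <- match_sign(sign)
  values <- as.numeric(values)
  if (anyNA(values)) stop("window contains missing values")
  structure(
    list(values = values, sign = sign, T_hours = T_hours,
         sampling_per_hour = sampling_per_hour, patient_id = patient_id),
    class = "vital_window"
  )
}

#' @export
print.vital_window <- function(x, ...) {
  cat(sprintf("<vital_window> %s, %d samples (%g h at %d/h), range [%.2f, %.2f]\n",
              x$sign, length(x$values), x$T_hours, x$sampling_per_hour,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Simulate a single vital-sign window at constant instability
#'
#' Draws one sampled series under a fixed (unramped) instability state: a
#' Poisson number of interior turning points, gamma-distributed swing
#' magnitudes alternating up and down from the baseline, linear interpolation
#' onto the sampling grid, additive Gaussian noise, and folding/clipping into
#' the physiologic bounds. With `extrema_count_mean = 0` and `noise_sd = 0`
#' the window is flat at the baseline level.
#'
#' @param params A [generator_params()] object (the group whose instability
#'   state to simulate at full strength).
#' @param sign One of [VITAL_SIGNS].
#' @param n_samples Number of samples (>= 2).
#' @param rng_seed Optional integer seed for reproducibility.
#' @return A [vital_window()] with `n_samples` values.
#' @export
simulate_window <- function(params, sign, n_samples, rng_seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  sign <- match_sign(sign)
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be at least 2")
  }
  n_samples <- as.integer(n_samples)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p <- params$signs[[sign]]
  vals <- .sim_series(p, p, rep(1, n_samples), n_samples)
  vital_window(vals, sign, T_hours = n_samples / 6)
}

#' Simulate one patient's full multi-sign record
#'
#' Generates, for each of the four vital signs, a sampled series covering the
#' `T_hours + horizon_hours` span ending at the patient's reference moment
#' `T0` (plus the sample at `T0` itself). Control series are generated at
#' constant control-level instability; septic series ramp from control level
#' up to full septic level approaching `T0` (see [instability_ramp()]), so
#' the closer the analysis window sits to `T0`, the stronger the instability
#' signal it contains. `T0` is placed `T_hours + horizon_hours` after the
#' start of the simulated record.
#'
#' @param spec A [cohort_spec()].
#' @param group `"septic"` or `"control"`; the label is 1 iff septic.
#' @param septic_params,control_params [generator_params()] for each group.
#' @param rng_seed Optional integer seed.
#' @param patient_id Identifier stored with the record.
#' @return A list of class `vital_patient` with elements `patient_id`,
#'   `group`, `label`, `T0_min`, `time_offset_min` and `series` (named list of
#'   numeric vectors, one per sign).
#' @export
simulate_patient <- function(spec, group = c("septic", "control"),
                             septic_params, control_params,
                             rng_seed = NULL, patient_id = "P001") {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  stopifnot(inherits(septic_params, "generator_params"),
            inherits(control_params, "generator_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)

  span_h <- spec$T_hours + spec$horizon_hours
  step_min <- 60 / spec$sampling_per_hour
  offsets <- seq(0, span_h * 60, by = step_min)
  n <- length(offsets)
  hours_before_t0 <- span_h - offsets / 60
  g <- if (group == "septic") instability_ramp(hours_before_t0) else rep(0, n)

  series <- list()
  for (s in VITAL_SIGNS) {
    series[[s]] <- .sim_series(septic_params$signs[[s]],
                               control_params$signs[[s]], g, n)
  }
  structure(
    list(
      patient_id = patient_id,
      group = group,
      label = as.integer(group == "septic"),
      T0_min = span_h * 60,
      time_offset_min = offsets,
      series = series
    ),
    class = "vital_patient"
  )
}

#' Simulate a labeled cohort
#'
#' Draws `n_septic + n_control` patients via [simulate_patient()], fully
#' reproducible from `spec$seed` (per-patient seeds are derived from the
#' master seed).
#'
#' @param spec A [cohort_spec()].
#' @param septic_params,control_params [generator_params()] per group;
#'   defaults come from [default_generator_params()].
#' @return A list of class `vital_cohort` with `patients` (data.frame:
#'   `patient_id`, `group`, `label`, `T0_min`), `samples` (long data.frame:
#'   `patient_id`, `group`, `vital_sign`, `time_offset_min`, `value`) and the
#'   `spec` / parameter sets used.
#' @export
simulate_cohort <- function(spec,
                            septic_params = default_generator_params("septic"),
                            control_params = default_generator_params("control")) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_septic + spec$n_control
  if (n_tot == 0L) stop("cohort must contain at least one patient")
  set.seed(spec$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  groups <- rep(c("septic", "control"), c(spec$n_septic, spec$n_control))
  ids <- sprintf("P%04d", seq_len(n_tot))

  pats <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    pats[[i]] <- simulate_patient(spec, groups[i], septic_params,
                                  control_params, rng_seed = patient_seeds[i],
                                  patient_id = ids[i])
  }

  n_off <- length(pats[[1]]$time_offset_min)
  n_row <- n_tot * length(VITAL_SIGNS) * n_off
  samples <- data.frame(
    patient_id = rep(ids, each = length(VITAL_SIGNS) * n_off),
    group = rep(groups, each = length(VITAL_SIGNS) * n_off),
    vital_sign = rep(rep(VITAL_SIGNS, each = n_off), times = n_tot),
    time_offset_min = rep(pats[[1]]$time_offset_min,
                          times = n_tot * length(VITAL_SIGNS)),
    value = unlist(lapply(pats, function(p) unlist(p$series, use.names = FALSE)),
                   use.names = FALSE),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(samples) == n_row)

  structure(
    list(
      patients = data.frame(
        patient_id = ids, group = groups,
        label = as.integer(groups == "septic"),
        T0_min = rep(pats[[1]]$T0_min, n_tot),
        stringsAsFactors = FALSE
      ),
      samples = samples,
      spec = spec,
      septic_params = septic_params,
      control_params = control_params
    ),
    class = "vital_cohort"
  )
}

#' @export
print.vital_cohort <- function(x, ...) {
  cat(sprintf("<vital_cohort> %d septic + %d control patients, %d samples\n",
              sum(x$patients$label == 1L), sum(x$patients$label == 0L),
              nrow(x$samples)))
  print(x$spec)
  invisible(x)
}
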