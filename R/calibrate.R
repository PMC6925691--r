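# Simulate n_sim single-sign analysis windows through the same path the
# feature pipeline uses (full span ending at T0, ramp profile for septic,
# slice of the first T hours) and return the n_sim x 5 feature matrix.
.sim_sign_features <- function(par_hi_sign, par_lo_sign, group, spec, n_sim) {
  span_h <- spec$T_hours + spec$horizon_hours
  step_min <- 60 / spec$sampling_per_hour
  offsets <- seq(0, span_h * 60, by = step_min)
  n <- length(offsets)
  hours_before_t0 <- span_h - offsets / 60
  g <- if (group == "septic") instability_ramp(hours_before_t0) else rep(0, n)
  n_win <- round(spec$sampling_per_hour * spec$T_hours)
  out <- matrix(NA_real_, n_sim, 5,
                dimnames = list(NULL, VARIABILITY_FEATURES))
  for (i in seq_len(n_sim)) {
    v <- .sim_series(par_hi_sign, par_lo_sign, g, n)
    out[i, ] <- compute_features(v[seq_len(n_win)])
  }
  out
}

.target_row <- function(targets, sign, feature, group, stat = "mean") {
  col <- paste0(group, "_", stat)
  val <- targets[targets$sign == sign & targets$feature == feature, col]
  if (length(val) != 1L || is.na(val)) {
    stop("no ", group, " ", stat, " target for ", sign, " ", feature)
  }
  val
}

# One sign, one group: damped multiplicative moment matching of
# extrema_count_mean (-> f1), swing_magnitude_mean (-> the intensity-level
# moment, f2 or f4) and swing_magnitude_sd (-> the shape moment, f3).
.calibrate_sign <- function(par_sign, par_lo_sign, group, sign, targets, spec,
                            n_sim, max_iter, tol, seed, intensity_target,
                            shape_target) {
  t_f1 <- .target_row(targets, sign, "f1", group)
  t_int <- .target_row(targets, sign, intensity_target, group)
  t_f2 <- .target_row(targets, sign, "f2", group)
  t_shape <- if (shape_target == "none") NA_real_ else
    .target_row(targets, sign, shape_target, group)
  t_f1_sd <- .target_row(targets, sign, "f1", group, stat = "sd")
  span_samples <- round(spec$sampling_per_hour *
                          (spec$T_hours + spec$horizon_hours)) + 1L
  eps <- 1e-8
  damp <- 0.7
  # noise stays at its initial absolute level: tying it to the evolving swing
  # mean couples the f2 and f1 updates into a runaway (larger swings -> more
  # noise -> more spurious extrema -> ever lower count)
  noise0 <- par_sign$noise_sd
  step_cap <- function(f) min(max(f, 0.6), 1.6)
  achieved <- NULL
  converged <- FALSE
  iter <- 0L
  history <- list()
  for (iter in seq_len(max_iter)) {
    set.seed(seed)  # common random numbers keep the moment map smooth
    lo <- if (group == "septic") par_lo_sign else par_sign
    sim <- .sim_sign_features(par_sign, lo, group, spec, n_sim)
    achieved <- colMeans(sim)
    achieved_f1_sd <- stats::sd(sim[, "f1"])
    rel <- c(
      f1 = achieved[["f1"]] / t_f1 - 1,
      intensity = achieved[[intensity_target]] / t_int - 1,
      shape = if (shape_target == "none") 0 else
        achieved[[shape_target]] / t_shape - 1,
      f1_sd = achieved_f1_sd / t_f1_sd - 1
    )
    history[[iter]] <- c(iter = iter, rel)
    # only the three mean moments are matched; the between-patient spread
    # (dispersion) stays at its preset value -- the extraction's response to
    # the patient multiplier is non-monotone (near-flat windows gain noise
    # extrema), so the printed spreads are not a stable control target
    if (max(abs(rel[1:3])) < tol) { converged <- TRUE; break }

    cm <- par_sign$extrema_count_mean *
      step_cap((t_f1 / max(achieved[["f1"]], eps))^damp)
    cm <- min(max(cm, 0.1), 2 * (span_samples - 2L))
    sm <- par_sign$swing_magnitude_mean *
      step_cap((t_int / max(achieved[[intensity_target]], eps))^damp)
    # beyond ~1/3 of the physiologic range the boundary fold compresses
    # swings and the intensity moments stop responding (non-monotone region)
    sm <- min(max(sm, eps), diff(par_sign$bounds) / 3)
    ssd <- par_sign$swing_magnitude_sd
    if (shape_target == "none") {
      # maximally concentrated swings: highest attainable minimum intensity
      ssd <- 0.15 * sm
    } else if (shape_target == "f4") {
      # the minimum swing shrinks as the gamma grows more skewed
      ssd <- ssd * step_cap((max(achieved[["f4"]], eps) / t_shape)^0.5)
    } else if (intensity_target == "f2") {
      # the median/mean ratio falls as the gamma grows more skewed
      ratio_sim <- achieved[[shape_target]] / max(achieved[["f2"]], eps)
      ratio_tgt <- t_shape / t_f2
      ssd <- ssd * step_cap((ratio_sim / max(ratio_tgt, eps))^0.5)
    } else {
      # intensity anchored on f4: drive the spread by the median directly
      ssd <- ssd * step_cap((achieved[[shape_target]] / t_shape)^0.4)
    }
    ssd <- min(max(ssd, 0.15 * sm), 3 * sm)
    par_sign <- sign_params(
      extrema_count_mean = cm,
      swing_magnitude_mean = sm,
      swing_magnitude_sd = ssd,
      baseline_level = par_sign$baseline_level,
      noise_sd = noise0,
      bounds = par_sign$bounds,
      resolution = par_sign$resolution,
      dispersion = par_sign$dispersion
    )
  }
  list(params = par_sign, achieved = achieved,
       achieved_f1_sd = achieved_f1_sd, converged = converged,
       iterations = iter,
       targets = c(f1 = t_f1, intensity = t_int, shape = t_shape,
                   f1_sd = t_f1_sd),
       intensity_target = intensity_target, shape_target = shape_target,
       history = do.call(rbind, history))
}

#' Calibrate generator parameters against published group statistics
#'
#' Iterative simulation-based moment matching: for each vital sign and group,
#' windows are simulated through the same path the feature pipeline uses
#' (full record, septic ramp, window slicing, feature extraction) and the
#' turning-point rate, swing-magnitude mean and swing-magnitude spread are
#' adjusted multiplicatively (damped) until the simulated feature means match
#' the targets -- `f1` via the rate, one intensity-level moment (`f2` by
#' default; `f4` for respiratory rate, whose minimum swing is the feature the
#' downstream models select) via the swing mean, and the median intensity
#' `f3` via the swing spread. Control
#' parameters are calibrated first; septic windows interpolate from the
#' calibrated control state along [instability_ramp()]. The noise level is
#' held at its initial absolute value throughout (adapting it to the evolving
#' swing mean couples the updates into a runaway). Common random numbers are
#' reused across iterations so the moment map is smooth.
#'
#' @param septic_init,control_init Starting [generator_params()]; defaults
#'   from [default_generator_params()].
#' @param targets Calibration targets as returned by
#'   [reference_group_stats()] (columns `sign`, `feature`, `septic_mean`,
#'   `control_mean`; sds are unused).
#' @param spec The [cohort_spec()] defining the window layout the targets
#'   refer to (defaults to 8 h window, 4 h horizon).
#' @param signs Signs to calibrate (default all four).
#' @param n_sim Simulated windows per iteration (default 400).
#' @param max_iter Maximum iterations per sign and group (default 15).
#' @param tol Relative tolerance on each matched moment (default 0.02).
#' @param seed Master seed; per-sign streams are derived from it.
#' @param intensity_targets Moment the swing mean is matched to (`"f2"` or
#'   `"f4"`): either a named character vector over signs (applied to both
#'   groups) or a list with `septic` and `control` vectors.
#' @param shape_targets Moment the swing spread is matched to (`"f3"`,
#'   `"f4"`, or `"none"` to pin the spread at maximal concentration, used
#'   where the minimum-intensity target is binding), same shape as
#'   `intensity_targets`.
#' @return A list of class `calibration_result` with `septic_params`,
#'   `control_params` and a `diagnostics` data.frame (group, sign, iterations,
#'   converged flag, achieved and target moments). Non-convergence of any
#'   sign raises a warning and returns the partial result.
#' @export
calibrate_generator <- function(septic_init = default_generator_params("septic"),
                                control_init = default_generator_params("control"),
                                targets = reference_group_stats(),
                                spec = cohort_spec(),
                                signs = VITAL_SIGNS,
                                n_sim = 400,
                                max_iter = 25,
                                tol = 0.02,
                                seed = 1L,
                                intensity_targets = list(
                                  septic = c(MAP = "f2", HR = "f2",
                                             RR = "f2", TEMP = "f2"),
                                  control = c(MAP = "f2", HR = "f2",
                                              RR = "f4", TEMP = "f2")
                                ),
                                shape_targets = list(
                                  septic = c(MAP = "f3", HR = "f3",
                                             RR = "f4", TEMP = "f3"),
                                  control = c(MAP = "f3", HR = "f3",
                                              RR = "none", TEMP = "f3")
                                )) {
  stopifnot(all(signs %in% VITAL_SIGNS))
  plan_for <- function(plan, grp, s) {
    if (is.list(plan)) unname(plan[[grp]][s]) else unname(plan[s])
  }
  set.seed(seed)
  sign_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * length(signs)),
                       nrow = 2L,
                       dimnames = list(c("control", "septic"), signs))
  septic <- septic_init
  control <- control_init
  diag_rows <- list()
  for (s in signs) {
    for (grp in c("control", "septic")) {
      init <- if (grp == "control") control$signs[[s]] else septic$signs[[s]]
      res <- .calibrate_sign(
        par_sign = init,
        par_lo_sign = control$signs[[s]],
        group = grp, sign = s, targets = targets, spec = spec,
        n_sim = n_sim, max_iter = max_iter, tol = tol,
        seed = sign_seeds[grp, s],
        intensity_target = plan_for(intensity_targets, grp, s),
        shape_target = plan_for(shape_targets, grp, s)
      )
      if (grp == "control") control$signs[[s]] <- res$params
      else septic$signs[[s]] <- res$params
      if (!res$converged) {
        warning("calibration did not converge for ", grp, " ", s,
                " within ", max_iter, " iterations (worst rel. error ",
                sprintf("%.3f", max(abs(res$history[nrow(res$history),
                                                    -1]))), ")")
      }
      diag_rows[[paste(grp, s)]] <- data.frame(
        group = grp, sign = s, iterations = res$iterations,
        converged = res$converged,
        intensity_target = res$intensity_target,
        shape_target = res$shape_target,
        target_f1 = res$targets[["f1"]], achieved_f1 = res$achieved[["f1"]],
        target_intensity = res$targets[["intensity"]],
        achieved_intensity = res$achieved[[res$intensity_target]],
        target_shape = res$targets[["shape"]],
        achieved_shape = res$achieved[[
          if (res$shape_target == "none") "f3" else res$shape_target]],
        target_f1_sd = res$targets[["f1_sd"]],
        achieved_f1_sd = res$achieved_f1_sd,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(septic_params = septic, control_params = control,
         diagnostics = do.call(rbind, c(diag_rows, make.row.names = FALSE))),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  print(x$diagnostics, digits = 4)
  invisible(x)
}
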