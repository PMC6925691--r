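#' Slice the analysis window out of a full time series
#'
#' Cuts the `T_hours` collection interval ending `horizon_hours` before the
#' reference moment `T0` out of one patient's one-sign series. The convention
#' is half-open `[T0 - (T + horizon), T0 - horizon)`: the sample at the
#' prediction moment itself is excluded. Patients whose series do not cover
#' the window completely on the regular sampling grid are rejected, mirroring
#' the study's inclusion criterion of continuous documented measurements.
#'
#' @param time_offset_min Sample times in minutes (relative to any origin).
#' @param values Measurements at those times.
#' @param T0_min The reference moment `T0` on the same time axis, minutes.
#' @param T_hours Collection interval length in hours.
#' @param horizon_hours Gap between the prediction moment and `T0`, hours.
#' @param sign Vital sign name, one of [VITAL_SIGNS].
#' @param sampling_per_hour Expected sampling rate (default 6).
#' @param patient_id Identifier carried into the window.
#' @return A [vital_window()] with exactly `sampling_per_hour * T_hours`
#'   samples.
#' @export
slice_window <- function(time_offset_min, values, T0_min, T_hours,
                         horizon_hours, sign, sampling_per_hour = 6,
                         patient_id = NA_character_) {
  stopifnot(length(time_offset_min) == length(values))
  start <- T0_min - (T_hours + horizon_hours) * 60
  end <- T0_min - horizon_hours * 60
  keep <- time_offset_min >= start & time_offset_min < end
  t_in <- time_offset_min[keep]
  ord <- order(t_in)
  t_in <- t_in[ord]
  v_in <- values[keep][ord]
  step <- 60 / sampling_per_hour
  n_expected <- round(sampling_per_hour * T_hours)
  expected_times <- start + step * (seq_len(n_expected) - 1)
  if (length(t_in) != n_expected || !isTRUE(all.equal(t_in, expected_times))) {
    stop(sprintf(
      "incomplete coverage for patient %s (%s): expected %d samples on a %g-min grid in [%g, %g), found %d",
      patient_id, sign, n_expected, step, start, end, length(t_in)
    ))
  }
  vital_window(v_in, sign, T_hours = T_hours,
               sampling_per_hour = sampling_per_hour, patient_id = patient_id)
}

#' Extract the local-extrema (trend-change) sequence of a window
#'
#' Scans the series for interior local extrema: points strictly greater than
#' both neighbours (local maxima) or strictly smaller (local minima), in
#' order of appearance. Runs of equal consecutive values (plateaus) are first
#' collapsed to a single representative, so a flat summit or valley counts as
#' one extremum. The augmented sequence prepends the window's first sample
#' and appends its last; swing intensities are computed over it.
#'
#' @param window A [vital_window()] or a numeric vector of length >= 2.
#' @return A list of class `extrema_seq` with `interior` and `augmented`
#'   numeric vectors.
#' @export
extract_extrema <- function(window) {
  x <- if (inherits(window, "vital_window")) window$values else as.numeric(window)
  if (length(x) < 2L) stop("window must contain at least 2 samples")
  collapsed <- rle(x)$values
  m <- length(collapsed)
  interior <- numeric(0)
  if (m >= 3L) {
    s <- sign(diff(collapsed))           # nonzero by construction
    turn <- which(s[-1] != s[-(m - 1L)]) # direction change between steps
    interior <- collapsed[turn + 1L]
  }
  structure(
    list(interior = interior, augmented = c(x[1L], interior, x[length(x)])),
    class = "extrema_seq"
  )
}

#' Number of trend changes (feature f1)
#'
#' The count of interior local extrema of the window; each extremum marks a
#' reversal of the series' direction.
#'
#' @param e An `extrema_seq` from [extract_extrema()].
#' @return Non-negative integer count.
#' @export
compute_f1 <- function(e) {
  stopifnot(inherits(e, "extrema_seq"))
  length(e$interior)
}

#' Absolute swing intensities between consecutive trend-change points
#'
#' Absolute differences of consecutive values of the endpoint-augmented
#' extrema sequence. This is the shared kernel of features f2--f5. A constant
#' window yields the single intensity 0.
#'
#' @param e An `extrema_seq` from [extract_extrema()].
#' @return Numeric vector of non-negative swing magnitudes.
#' @export
intensity_diffs <- function(e) {
  stopifnot(inherits(e, "extrema_seq"))
  abs(diff(e$augmented))
}

#' Variability features f1--f5 of one window
#'
#' `f1` is the trend-change count ([compute_f1()]); `f2`--`f5` are the mean,
#' median, minimum and maximum of the swing intensities
#' ([intensity_diffs()]), in sign units. The median of an even-length
#' intensity sequence is the usual midpoint average.
#'
#' @param window A [vital_window()] or numeric vector (length >= 2).
#' @return Named numeric vector `c(f1, f2, f3, f4, f5)`.
#' @export
compute_features <- function(window) {
  e <- extract_extrema(window)
  d <- intensity_diffs(e)
  c(f1 = compute_f1(e), f2 = mean(d), f3 = stats::median(d),
    f4 = min(d), f5 = max(d))
}

#' Descriptive baseline features of one window
#'
#' The comparator feature set from earlier severe-sepsis prediction work:
#' mean, median, minimum, maximum and sample standard deviation (n-1
#' denominator) of the raw samples.
#'
#' @param window A [vital_window()] or numeric vector.
#' @return Named numeric vector `c(mean, median, min, max, sd)`.
#' @export
compute_baseline <- function(window) {
  x <- if (inherits(window, "vital_window")) window$values else as.numeric(window)
  c(mean = mean(x), median = stats::median(x), min = min(x), max = max(x),
    sd = stats::sd(x))
}

#' Build one patient's 20-feature record
#'
#' Applies the chosen extractor to exactly one window per vital sign and
#' names the result `sign_feature` (e.g. `RR_f1`, `MAP_sd`), yielding the
#' 20-dimensional per-patient feature vector (5 features x 4 signs).
#'
#' @param windows Named list with one [vital_window()] per element of
#'   [VITAL_SIGNS] (names must match the signs exactly).
#' @param feature_set `"variability"` (f1--f5) or `"baseline"`
#'   (descriptive statistics).
#' @param label Optional class label (1 = septic) stored as an attribute.
#' @return Named numeric vector of length 20 with attributes `patient_id`,
#'   `label` and `feature_set`.
#' @export
featurize_patient <- function(windows, feature_set = c("variability", "baseline"),
                              label = NA_integer_) {
  feature_set <- match.arg(feature_set)
  if (!setequal(names(windows), VITAL_SIGNS) ||
      length(windows) != length(VITAL_SIGNS)) {
    stop("windows must contain exactly one window per sign: ",
         paste(VITAL_SIGNS, collapse = ", "))
  }
  fun <- if (feature_set == "variability") compute_features else compute_baseline
  out <- numeric(0)
  for (s in VITAL_SIGNS) {
    w <- windows[[s]]
    if (inherits(w, "vital_window") && w$sign != s) {
      stop("window listed under ", s, " is for sign ", w$sign)
    }
    f <- fun(w)
    names(f) <- paste(s, names(f), sep = "_")
    out <- c(out, f)
  }
  stopifnot(length(out) == 20L)
  attr(out, "patient_id") <- if (inherits(windows[[1]], "vital_window")) {
    windows[[1]]$patient_id
  } else NA_character_
  attr(out, "label") <- label
  attr(out, "feature_set") <- feature_set
  out
}

#' Extract the per-patient feature table from a cohort
#'
#' Slices each patient's analysis window per sign ([slice_window()]) and
#' extracts either the variability features f1--f5 or the descriptive
#' baseline features, producing the modeling table with one row per patient.
#' Patients with incomplete coverage are dropped with a warning (mirroring
#' the study's inclusion criteria).
#'
#' @param cohort A `vital_cohort` from [simulate_cohort()] or
#'   [read_timeseries_csv()].
#' @param T_hours,horizon_hours Window layout; defaults come from the cohort's
#'   spec when present, else 8 and 4.
#' @param feature_set `"variability"` or `"baseline"`.
#' @return A data.frame: `patient_id`, `label`, then 20 feature columns.
#' @export
featurize_cohort <- function(cohort, T_hours = NULL, horizon_hours = NULL,
                             feature_set = c("variability", "baseline")) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(cohort, "vital_cohort"))
  spp <- if (!is.null(cohort$spec)) cohort$spec$sampling_per_hour else 6L
  if (is.null(T_hours)) {
    T_hours <- if (!is.null(cohort$spec)) cohort$spec$T_hours else 8
  }
  if (is.null(horizon_hours)) {
    horizon_hours <- if (!is.null(cohort$spec)) cohort$spec$horizon_hours else 4
  }

  ids <- cohort$patients$patient_id
  rows <- vector("list", length(ids))
  kept <- logical(length(ids))
  samp <- cohort$samples
  split_pat <- split(seq_len(nrow(samp)), samp$patient_id)
  for (i in seq_along(ids)) {
    pid <- ids[i]
    pidx <- split_pat[[pid]]
    psamp <- samp[pidx, ]
    t0 <- cohort$patients$T0_min[i]
    windows <- list()
    ok <- TRUE
    for (s in VITAL_SIGNS) {
      sel <- psamp$vital_sign == s
      w <- try(slice_window(psamp$time_offset_min[sel], psamp$value[sel],
                            T0_min = t0, T_hours = T_hours,
                            horizon_hours = horizon_hours, sign = s,
                            sampling_per_hour = spp, patient_id = pid),
               silent = TRUE)
      if (inherits(w, "try-error")) { ok <- FALSE; break }
      windows[[s]] <- w
    }
    if (!ok) next
    kept[i] <- TRUE
    rows[[i]] <- featurize_patient(windows, feature_set,
                                   label = cohort$patients$label[i])
  }
  if (!any(kept)) stop("no patient had complete coverage of the window")
  if (any(!kept)) {
    warning(sum(!kept), " patient(s) dropped for incomplete window coverage")
  }
  feat <- do.call(rbind, rows[kept])
  out <- data.frame(
    patient_id = ids[kept],
    label = cohort$patients$label[kept],
    feat,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Names of the feature columns in a feature table
#'
#' @param features A feature data.frame from [featurize_cohort()].
#' @return Character vector of the 20 feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features), c("patient_id", "label"))
}
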