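#' Write a cohort's sample table to long-format CSV
#'
#' Columns `patient_id`, `group`, `vital_sign`, `time_offset_min`, `value`;
#' UTF-8, header row, `.` decimal separator. Identical cohorts produce
#' byte-identical files.
#'
#' @param cohort A `vital_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "vital_cohort"))
  utils::write.csv(cohort$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format vital-sign time-series CSV
#'
#' Expects the schema written by [write_cohort_csv()] (or any conforming
#' EMR export): header `patient_id`, `group`, `vital_sign`,
#' `time_offset_min`, `value`. Rows are validated (known signs, numeric
#' times/values, no duplicate patient/sign/time triples; offending row
#' numbers are reported) and sorted by patient, sign and time. Each
#' patient's reference moment `T0` is taken as their last recorded sample
#' time, the convention used by the simulator (records end at `T0`).
#'
#' @param path CSV file path.
#' @return A `vital_cohort` (without a generator spec).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "group", "vital_sign", "time_offset_min", "value")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("malformed time-series CSV, missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty cohort: the time-series file has no rows")
  bad_sign <- which(!df$vital_sign %in% VITAL_SIGNS)
  if (length(bad_sign)) {
    stop("unknown vital_sign at row(s) ",
         paste(utils::head(bad_sign, 5L), collapse = ", "))
  }
  if (!is.numeric(df$time_offset_min) || anyNA(df$time_offset_min)) {
    stop("time_offset_min must be numeric and complete")
  }
  if (!is.numeric(df$value) || anyNA(df$value)) {
    stop("value must be numeric and complete")
  }
  bad_group <- which(!df$group %in% c("septic", "control"))
  if (length(bad_group)) {
    stop("group must be 'septic' or 'control'; offending row(s) ",
         paste(utils::head(bad_group, 5L), collapse = ", "))
  }
  key <- paste(df$patient_id, df$vital_sign, df$time_offset_min)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (patient, sign, time) row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  df <- df[order(df$patient_id, df$vital_sign, df$time_offset_min), ]
  rownames(df) <- NULL

  t0 <- tapply(df$time_offset_min, df$patient_id, max)
  first <- !duplicated(df$patient_id)
  patients <- data.frame(
    patient_id = df$patient_id[first],
    group = df$group[first],
    stringsAsFactors = FALSE
  )
  patients <- patients[order(patients$patient_id), ]
  patients$label <- as.integer(patients$group == "septic")
  patients$T0_min <- as.numeric(t0[patients$patient_id])
  rownames(patients) <- NULL

  structure(
    list(patients = patients, samples = df, spec = NULL,
         septic_params = NULL, control_params = NULL),
    class = "vital_cohort"
  )
}

#' Write / read a per-patient feature table CSV
#'
#' @param features Feature data.frame (`patient_id`, `label`, 20 feature
#'   columns).
#' @param path File path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("patient_id", "label") %in% colnames(df))) {
    stop("feature CSV must contain patient_id and label columns")
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  df
}

# generator_params <-> plain list (for JSON round-tripping)
.params_to_list <- function(params) {
  list(group = params$group,
       signs = lapply(params$signs, function(p) {
         list(extrema_count_mean = p$extrema_count_mean,
              swing_magnitude_mean = p$swing_magnitude_mean,
              swing_magnitude_sd = p$swing_magnitude_sd,
              baseline_level = p$baseline_level,
              noise_sd = p$noise_sd,
              bounds = p$bounds,
              resolution = p$resolution)
       }))
}

.params_from_list <- function(x) {
  signs <- lapply(x$signs, function(p) {
    sign_params(extrema_count_mean = p$extrema_count_mean,
                swing_magnitude_mean = p$swing_magnitude_mean,
                swing_magnitude_sd = p$swing_magnitude_sd,
                baseline_level = p$baseline_level,
                noise_sd = p$noise_sd,
                bounds = unlist(p$bounds),
                resolution = if (is.null(p$resolution)) 0 else p$resolution)
  })
  generator_params(x$group, signs)
}

#' Default end-to-end pipeline configuration
#'
#' A plain list describing every stage of [run_pipeline()]: cohort layout,
#' generator parameters (defaults when omitted), feature set, model families,
#' selection and tuning settings, and the master seed all stages derive
#' their randomness from.
#'
#' @param seed Master seed.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(
    list(
      n_septic = 300L, n_control = 300L,
      T_hours = 8, horizon_hours = 4, sampling_per_hour = 6L,
      seed = as.integer(seed),
      feature_set = "variability",
      families = MODEL_FAMILIES,
      train_frac = 0.75,
      select_k = 2L, n_repeats = 20L,
      tune = FALSE, cv_folds = 10L,
      calibrate = FALSE,
      septic_params = NULL, control_params = NULL
    ),
    class = "pipeline_config"
  )
}

.validate_config <- function(config) {
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(
    config$feature_set %in% c("variability", "baseline"),
    all(config$families %in% MODEL_FAMILIES),
    config$train_frac > 0, config$train_frac < 1,
    config$select_k >= 1
  )
  config
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A pipeline configuration list (see
#'   [default_pipeline_config()]).
#' @param path JSON file path.
#' @return `path` (write) or the validated configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  config <- .validate_config(config)
  out <- unclass(config)
  if (!is.null(out$septic_params)) {
    out$septic_params <- .params_to_list(out$septic_params)
  }
  if (!is.null(out$control_params)) {
    out$control_params <- .params_to_list(out$control_params)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(x$septic_params)) {
    x$septic_params <- .params_from_list(x$septic_params)
  }
  if (!is.null(x$control_params)) {
    x$control_params <- .params_from_list(x$control_params)
  }
  structure(.validate_config(x), class = "pipeline_config")
}

.md5_of_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate, extract, split, select, train and evaluate in
#' sequence, writes every intermediate artifact (cohort CSV, feature CSV,
#' selection JSON, evaluation report JSON) under `out_dir`, and returns a
#' manifest with the configuration hash and per-file checksums. Fully
#' deterministic under the configuration's master seed: running twice yields
#' identical file checksums.
#'
#' @param config Pipeline configuration (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if absent).
#' @param verbose Emit stage progress messages (default FALSE).
#' @return A list of class `run_manifest`: `config_hash`, `files` (named md5
#'   vector), `selected_features`, `reports` (per-family metric rows),
#'   `timestamp`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = ".",
                         verbose = FALSE) {
  config <- .validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  params <- .stage("parameters", verbose, {
    if (isTRUE(config$calibrate)) {
      cal <- calibrate_generator(seed = config$seed)
      list(septic = cal$septic_params, control = cal$control_params)
    } else {
      list(
        septic = if (is.null(config$septic_params))
          default_generator_params("septic") else config$septic_params,
        control = if (is.null(config$control_params))
          default_generator_params("control") else config$control_params
      )
    }
  })

  cohort <- .stage("simulate", verbose, {
    spec <- cohort_spec(n_septic = config$n_septic,
                        n_control = config$n_control,
                        T_hours = config$T_hours,
                        sampling_per_hour = config$sampling_per_hour,
                        horizon_hours = config$horizon_hours,
                        seed = config$seed)
    co <- simulate_cohort(spec, params$septic, params$control)
    write_cohort_csv(co, file.path(out_dir, "cohort.csv"))
    co
  })

  features <- .stage("extract", verbose, {
    ft <- featurize_cohort(cohort, feature_set = config$feature_set)
    write_features_csv(ft, file.path(out_dir, "features.csv"))
    ft
  })

  split <- .stage("split", verbose, {
    stratified_split(features, train_frac = config$train_frac,
                     seed = config$seed)
  })
  train <- features[split$train_idx, ]
  test <- features[split$test_idx, ]

  selection <- .stage("select", verbose, {
    sel <- select_features(train, families = config$families,
                           k = config$select_k,
                           n_repeats = config$n_repeats,
                           seed = config$seed, tune = FALSE)
    jsonlite::write_json(
      list(features = sel$features, provenance = sel$provenance),
      file.path(out_dir, "selected.json"), auto_unbox = FALSE, pretty = TRUE
    )
    sel
  })

  reports <- .stage("train_evaluate", verbose, {
    rows <- list()
    for (fam in config$families) {
      cfg <- model_config(fam, cv_folds = config$cv_folds, seed = config$seed)
      hyper <- if (isTRUE(config$tune)) {
        tune_model(cfg, train, feature_names = selection$features)$hyper
      } else default_hyper(fam)
      fit <- fit_model(cfg, train, feature_names = selection$features,
                       hyper = hyper)
      ev <- evaluate_model(fit, test)
      rows[[fam]] <- data.frame(
        family = fam, auc = ev$auc, auc_pr = ev$auc_pr,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        ppv = ev$ppv, npv = ev$npv, accuracy = ev$accuracy,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    jsonlite::write_json(out, file.path(out_dir, "reports.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    out
  })

  files <- c("cohort.csv", "features.csv", "selected.json", "reports.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- structure(
    list(
      config_hash = .md5_of_object(unclass(.validate_config(config))[
        setdiff(names(config), c("septic_params", "control_params"))]),
      files = checksums,
      selected_features = selection$features,
      reports = reports,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(config_hash = manifest$config_hash,
         files = as.list(manifest$files),
         selected_features = manifest$selected_features,
         timestamp = manifest$timestamp),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$timestamp, "\n  config", x$config_hash, "\n")
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  print(x$reports, digits = 4)
  invisible(x)
}
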