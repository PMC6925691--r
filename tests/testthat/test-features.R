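test_that("slice_window returns the half-open collection interval", {
  # 13 h of records ending at T0, every 10 min
  times <- seq(0, 780, by = 10)
  values <- seq_along(times)
  w <- slice_window(times, values, T0_min = 780, T_hours = 8,
                    horizon_hours = 4, sign = "MAP")
  expect_s3_class(w, "vital_window")
  expect_length(w$values, 48)
  # window = [T0-12h, T0-4h): first sample at offset 60, last at offset 530
  expect_equal(w$values[1], values[times == 60])
  expect_equal(w$values[48], values[times == 530])
  # the prediction-moment sample itself (offset 540) is excluded
  expect_false(values[times == 540] %in% w$values)

  w1 <- slice_window(times, values, T0_min = 780, T_hours = 1,
                     horizon_hours = 4, sign = "HR")
  expect_length(w1$values, 6)
})

test_that("slice_window rejects series with gaps or short coverage", {
  times <- seq(0, 720, by = 10)
  values <- rnorm(length(times))
  keep <- times != 300  # one missing sample inside the window
  expect_error(
    slice_window(times[keep], values[keep], T0_min = 720, T_hours = 8,
                 horizon_hours = 4, sign = "RR", patient_id = "P1"),
    "incomplete coverage"
  )
  expect_error(
    slice_window(times[times >= 300], values[times >= 300], T0_min = 720,
                 T_hours = 8, horizon_hours = 4, sign = "RR"),
    "incomplete coverage"
  )
})

test_that("extract_extrema matches hand-worked examples", {
  e <- extract_extrema(c(1, 2, 3, 4))
  expect_identical(e$interior, numeric(0))
  expect_identical(e$augmented, c(1, 4))

  e <- extract_extrema(c(2, 5, 3, 6, 1))
  expect_identical(e$interior, c(5, 3, 6))
  expect_identical(e$augmented, c(2, 5, 3, 6, 1))

  e <- extract_extrema(c(7, 7, 7, 7))
  expect_identical(e$interior, numeric(0))
  expect_identical(e$augmented, c(7, 7))

  # a plateau summit counts as one extremum
  e <- extract_extrema(c(1, 4, 4, 4, 2, 2, 5, 0))
  expect_identical(e$interior, c(4, 2, 5))

  expect_error(extract_extrema(3), "at least 2")
})

test_that("f1 and intensity kernels follow their definitions", {
  e <- extract_extrema(c(2, 5, 3, 6, 1))
  expect_identical(compute_f1(e), 3L)
  expect_equal(intensity_diffs(e), c(3, 2, 3, 5))

  expect_identical(compute_f1(extract_extrema(1:10)), 0L)
  expect_equal(intensity_diffs(extract_extrema(rep(4, 6))), 0)

  tri <- extract_extrema(c(60, 95, 60))
  expect_identical(compute_f1(tri), 1L)
  expect_equal(intensity_diffs(tri), c(35, 35))
})

test_that("compute_features and compute_baseline match worked examples", {
  f <- compute_features(c(2, 5, 3, 6, 1))
  expect_equal(unname(f), c(3, 3.25, 3, 2, 5))

  f <- compute_features(c(60, 95, 60))
  expect_equal(unname(f), c(1, 35, 35, 35, 35))

  f <- compute_features(rep(7, 20))
  expect_equal(unname(f), c(0, 0, 0, 0, 0))

  b <- compute_baseline(c(2, 5, 3, 6, 1))
  expect_equal(unname(b[c("min", "max", "mean", "median")]), c(1, 6, 3.4, 3))
  b7 <- compute_baseline(rep(7, 5))
  expect_equal(unname(b7[c("sd", "min", "max")]), c(0, 7, 7))
})

test_that("featurize_patient builds a named 20-feature record", {
  set.seed(1)
  windows <- lapply(VITAL_SIGNS, function(s) {
    vital_window(rnorm(48, 50, 5), s, T_hours = 8, patient_id = "P7")
  })
  names(windows) <- VITAL_SIGNS
  rec <- featurize_patient(windows, "variability", label = 1L)
  expect_length(rec, 20)
  expect_identical(names(rec)[1:5], paste0("MAP_", VARIABILITY_FEATURES))
  expect_identical(attr(rec, "label"), 1L)

  recb <- featurize_patient(windows, "baseline")
  expect_length(recb, 20)
  expect_true("TEMP_sd" %in% names(recb))

  # constant windows: all intensities zero
  flat <- lapply(VITAL_SIGNS, function(s) vital_window(rep(10, 48), s, 8))
  names(flat) <- VITAL_SIGNS
  recf <- featurize_patient(flat, "variability")
  expect_true(all(recf[grep("_f[2-5]$", names(recf))] == 0))

  expect_error(featurize_patient(windows[1:3]), "exactly one window per sign")
  wrong <- windows
  names(wrong) <- c("MAP", "MAP", "RR", "TEMP")
  expect_error(featurize_patient(wrong), "exactly one window per sign")
})

test_that("extrema extraction agrees with an independent naive scan", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    x <- random_window(n, quantize = i %% 2 == 0)  # half with plateaus
    got <- extract_extrema(x)
    want <- naive_extrema(x)
    expect_identical(got$interior, want$interior)
    expect_identical(got$augmented, want$augmented)
  }
})

test_that("features are translation invariant and scale covariant", {
  set.seed(202)
  for (i in 1:50) {
    x <- random_window(sample(10:60, 1), quantize = i %% 3 == 0)
    f <- compute_features(x)
    expect_equal(compute_features(x + 17.3), f)
    a <- runif(1, 0.5, 4)
    fa <- compute_features(a * x)
    expect_equal(fa[["f1"]], f[["f1"]])
    expect_equal(unname(fa[2:5]), a * unname(f[2:5]))
  }
})

test_that("intensity ordering, telescoping and reflection hold", {
  set.seed(303)
  for (i in 1:200) {
    x <- random_window(sample(5:60, 1), quantize = i %% 2 == 0)
    f <- compute_features(x)
    expect_true(f[["f4"]] <= f[["f2"]] && f[["f2"]] <= f[["f5"]])
    expect_true(f[["f4"]] <= f[["f3"]] && f[["f3"]] <= f[["f5"]])
    # signed swings over the augmented sequence telescope to last - first
    aug <- extract_extrema(x)$augmented
    expect_equal(sum(diff(aug)), x[length(x)] - x[1])
    # reflection: same trend-change count, same multiset of intensities
    fr <- compute_features(rev(x))
    expect_equal(fr[["f1"]], f[["f1"]])
    expect_equal(sort(intensity_diffs(extract_extrema(rev(x)))),
                 sort(intensity_diffs(extract_extrema(x))))
  }
})
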