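# Independent naive extrema scan: explicit index-by-index loop over the
# plateau-collapsed series. Deliberately written in a different style from
# the package implementation so the two can cross-check each other.
naive_extrema <- function(x) {
  # collapse runs of equal consecutive values
  collapsed <- x[1]
  for (i in seq_along(x)[-1]) {
    if (x[i] != collapsed[length(collapsed)]) collapsed <- c(collapsed, x[i])
  }
  interior <- numeric(0)
  if (length(collapsed) >= 3) {
    for (j in 2:(length(collapsed) - 1)) {
      lo <- collapsed[j - 1]; mid <- collapsed[j]; hi <- collapsed[j + 1]
      if ((mid > lo && mid > hi) || (mid < lo && mid < hi)) {
        interior <- c(interior, mid)
      }
    }
  }
  list(interior = interior,
       augmented = c(x[1], interior, x[length(x)]))
}

# random test windows, some with plateaus, some quantized
random_window <- function(n, quantize = FALSE) {
  x <- cumsum(stats::rnorm(n))
  if (quantize) x <- round(x)
  x
}

# Gaussian feature table with group signal confined to `informative` columns
make_gaussian_features <- function(n_per_group, feature_names, informative,
                                   delta = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  label <- rep(c(1L, 0L), each = n_per_group)
  m <- matrix(stats::rnorm(n * length(feature_names)), nrow = n,
              dimnames = list(NULL, feature_names))
  for (f in informative) m[label == 1L, f] <- m[label == 1L, f] + delta
  data.frame(patient_id = sprintf("P%04d", seq_len(n)), label = label, m,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# small calibrated-free cohort for structural tests
small_cohort <- function(n = 20, seed = 42, T_hours = 8, horizon_hours = 4) {
  simulate_cohort(cohort_spec(n_septic = n, n_control = n, T_hours = T_hours,
                              horizon_hours = horizon_hours, seed = seed))
}
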