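# Shared fixtures and independent oracles used across the suite.

# Noiseless noise configuration (wander/mains amplitudes zero).
no_noise <- function() noise_config(white_sd_uv = 0, wander_amp_uv = 0,
                                    mains_amp_uv = 0)

# A small, fast patient: default morphology at a configurable rate.
quick_template <- function(fs = 500, ...) {
  make_patient_template(build_morphology(...), fs = fs)
}

# A reduced cohort configuration for pipeline tests: calibration populations,
# small n, short records at 500 Hz (8 beats averaged instead of 20).
small_cohort_config <- function(n_success = 4, n_fail = 3, seed = 1,
                                duration_s = 20, fs = 500) {
  cal <- calibration_config()
  cohort_config(n_success = n_success, n_fail = n_fail, arms = cal$arms,
                fs = fs, duration_s = duration_s, noise = cal$noise,
                seed = seed, min_beats = 9L)
}

# ---- independent K2 oracle ------------------------------------------------
# Re-derivation of the D'Agostino-Pearson omnibus test, written directly from
# the published transformations in a different style (explicit intermediate
# moments, no shared code with the package implementation).
oracle_k2 <- function(x) {
  n <- length(x)
  stopifnot(n >= 8)
  xc <- x - sum(x) / n
  s2 <- sum(xc^2) / n
  g1 <- (sum(xc^3) / n) / s2^(3 / 2)
  g2 <- (sum(xc^4) / n) / s2^2 - 3
  # D'Agostino skewness transform
  Y <- g1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  b2g1 <- (3 * (n * n + 27 * n - 70) * (n + 1) * (n + 3)) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- sqrt(2 * (b2g1 - 1)) - 1
  W <- sqrt(W2)
  d <- 1 / sqrt(log(W))
  a <- sqrt(2 / (W2 - 1))
  Zg1 <- d * asinh(Y / a)
  # Anscombe-Glynn kurtosis transform (on non-excess kurtosis b2)
  b2 <- g2 + 3
  Eb2 <- (3 * (n - 1)) / (n + 1)
  Vb2 <- (24 * n * (n - 2) * (n - 3)) / ((n + 1)^2 * (n + 3) * (n + 5))
  stdb2 <- (b2 - Eb2) / sqrt(Vb2)
  rootb1 <- (6 * (n * n - 5 * n + 2)) / ((n + 7) * (n + 9)) *
    sqrt((6 * (n + 3) * (n + 5)) / (n * (n - 2) * (n - 3)))
  A <- 6 + (8 / rootb1) * (2 / rootb1 + sqrt(1 + 4 / rootb1^2))
  term <- (1 - 2 / A) / (1 + stdb2 * sqrt(2 / (A - 4)))
  Zg2 <- ((1 - 2 / (9 * A)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2, p_value = stats::pchisq(K2, 2, lower.tail = FALSE))
}

# Fixed vectors with statistics frozen from an independent reference
# implementation (scipy.stats.normaltest).
frozen_normaltest_cases <- function() {
  list(
    normal30 = list(
      x = c(1.028857, 1.64192, 1.14672, -0.97318, -1.3928, 0.067196,
            0.861351, 0.509187, 1.810286, 0.750843, 0.63976, -0.731323,
            -1.107717, 1.484406, 0.048912, 0.81152, -1.376423, -0.436371,
            -1.291092, -0.775679, 0.903063, -1.480581, -0.534093, 0.163789,
            -0.66847, -0.25229, -0.221862, 0.418139, -0.431255, 0.272261),
      k2 = 2.903943386769, p = 0.234108243064),
    expo40 = list(
      x = c(0.809409, 0.222616, 1.768771, 0.400942, 0.785837, 0.060554,
            0.071239, 0.120815, 4.128727, 1.477388, 2.037766, 0.158406,
            0.263372, 0.786251, 0.119173, 0.014494, 1.74444, 0.021509,
            0.199105, 0.100843, 0.707185, 1.086718, 1.346614, 0.291276,
            2.092544, 0.096664, 1.533757, 0.658858, 4.028033, 0.037997,
            0.451697, 3.994275, 1.809664, 0.037912, 0.418281, 0.094067,
            0.004035, 1.396115, 0.996821, 0.44839),
      k2 = 20.975828272609, p = 0.000027871270))
}

# ---- independent delineation oracles -------------------------------------
# Threshold-crossing delineation of a noiseless single-lead beat: first/last
# sample where the waveform departs from zero by more than `thr` mV inside
# a window. Used against the generator's closed-form ground truth.
oracle_threshold_delineate <- function(y, window, thr = 1e-6) {
  idx <- window[abs(y[window]) > thr]
  if (!length(idx)) return(NULL)
  list(onset = min(idx), offset = max(idx))
}

# Brute-force perpendicular-distance scan used against chord_knee-based
# results: literal distance-to-line computation for every interior sample.
oracle_chord_scan <- function(y, i1, i2) {
  t1 <- i1; t2 <- i2
  num <- abs((y[i1:i2] - y[i1]) * (t2 - t1) -
               ((i1:i2) - t1) * (y[i2] - y[i1]))
  d <- num / sqrt((t2 - t1)^2 + (y[i2] - y[i1])^2)
  (i1:i2)[which.max(d)]
}

# Brute-force width-at-half-prominence scan: for every local extremum in the
# window, measure the contiguous run above half its prominence.
oracle_widest_lobe <- function(y, fs, window, baseline, min_width_ms = 15) {
  dev <- y - baseline
  best <- NULL
  for (i in window[-c(1, length(window))]) {
    s <- sign(dev[i])
    if (s == 0) next
    z <- s * dev
    if (!(z[i] >= z[i - 1] && z[i] >= z[i + 1])) next
    run <- which(z > z[i] / 2)
    run <- run[run %in% window]
    blocks <- split(run, cumsum(c(1, diff(run) != 1)))
    blk <- Filter(function(b) i %in% b, blocks)[[1]]
    w_ms <- length(blk) / fs * 1000
    if (w_ms >= min_width_ms && (is.null(best) || w_ms > best$w))
      best <- list(idx = i, w = w_ms)
  }
  best
}
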