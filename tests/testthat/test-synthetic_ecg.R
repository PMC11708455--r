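test_that("analytic PTFV1 follows directly from the lobe parameters", {
  m <- build_morphology(ptf_depth_mv = 0.08, ptf_width_ms = 40)
  gt <- make_patient_template(m, fs = 1000)$ground_truth
  expect_equal(gt$ptfv1, -3.2)
  m0 <- build_morphology(ptf_depth_mv = 0)
  expect_identical(make_patient_template(m0, fs = 1000)$ground_truth$ptfv1, 0)
})

test_that("ground truth is internally consistent and satisfies invariants", {
  set.seed(7)
  for (k in 1:12) {
    m <- build_morphology(pwd_ms = runif(1, 118, 150),
                          pwdisp_ms = runif(1, 24, 34),
                          ptf_depth_mv = runif(1, 0, 0.12),
                          hr_bpm = runif(1, 60, 95))
    gt <- make_patient_template(m, fs = 500)$ground_truth
    expect_true(all(gt$lead$onset_ms < gt$lead$peak_ms))
    expect_true(all(gt$lead$peak_ms < gt$lead$offset_ms))
    expect_equal(gt$pwdisp_ms, max(gt$lead$pwd_ms) - min(gt$lead$pwd_ms))
    expect_gte(gt$pwdisp_ms, 0)
    expect_lte(gt$ptfv1, 0)
  }
})

test_that("threshold-crossing oracle on the noiseless beat matches ground truth", {
  tpl <- make_patient_template(build_morphology(), fs = 1000)
  gt <- tpl$ground_truth
  for (ld in c("II", "aVR", "V1", "V5")) {
    y <- tpl$beat[, ld]
    # search only the P region: end clear of the QRS foot, whose corner
    # smoothing starts ~8 ms before nominal QRS onset
    win <- 40:(round(gt$qrs_onset_ms) - 12)
    oc <- oracle_threshold_delineate(y, win, thr = 1e-9)
    i <- match(ld, gt$lead$lead)
    expect_lte(abs((oc$onset - 1) - gt$lead$onset_ms[i]), 1.0)
    expect_lte(abs((oc$offset - 1) - gt$lead$offset_ms[i]), 1.0)
  }
})

test_that("morphology invariants are enforced", {
  expect_error(build_morphology(pwd_ms = 40, pwdisp_ms = 30), "P widths")
  expect_error(pwave_morphology(
    p_amp = setNames(rep(0.1, 12), ECG_LEADS),
    p_center = setNames(rep(240, 12), ECG_LEADS),
    p_width = setNames(rep(60, 12), ECG_LEADS),
    v1_neg_amp = 0.05, v1_neg_center = 240, v1_neg_width = 30),
    "end before QRS onset")
  m <- build_morphology()
  m$hr_bpm <- 200
  expect_error(do.call(pwave_morphology, m[setdiff(names(m), "pr_ms")]),
               "30, 180")
  expect_error(make_patient_template(build_morphology(), fs = 100),
               "fs >= 250")
})

test_that("noiseless tiling is exact and seeded generation reproducible", {
  tpl <- quick_template(fs = 500, hr_bpm = 75)
  rec0 <- generate_record(tpl, duration_s = 6, noise = no_noise(), seed = 1)
  nb <- nrow(tpl$beat)
  expect_identical(rec0$samples[seq_len(nb), ], tpl$beat)
  expect_identical(rec0$samples[nb + seq_len(nb), ], tpl$beat)
  r1 <- generate_record(tpl, duration_s = 6, seed = 99)
  r2 <- generate_record(tpl, duration_s = 6, seed = 99)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_record(tpl, duration_s = 6, seed = 100)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(generate_record(tpl, duration_s = 0.2), "too short")
  expect_error(noise_config(white_sd_uv = -3), ">= 0")
  expect_error(noise_config(mains_hz = 55), "50 or 60")
})

test_that("white-noise level in the TP segment matches the configuration", {
  tpl <- quick_template(fs = 500, hr_bpm = 60)
  noise <- noise_config(white_sd_uv = 20, wander_amp_uv = 0, mains_amp_uv = 0)
  rec <- generate_record(tpl, duration_s = 60, noise = noise, seed = 5)
  clean <- generate_record(tpl, duration_s = 60, noise = no_noise(), seed = 5)
  resid <- rec$samples - clean$samples
  # TP segment of each beat: between T support end and next P onset
  gt <- tpl$ground_truth
  nb <- nrow(tpl$beat)
  tp_lo <- round((gt$t_peak_ms + 90) / 1000 * 500)
  tp_hi <- nb - 5
  tp_idx <- as.vector(outer(tp_lo:tp_hi, (0:58) * nb, `+`))
  sd_uv <- sd(resid[tp_idx, "II"]) * 1000
  expect_equal(sd_uv, 20, tolerance = 0.10 * 20)
})

test_that("cohort generation: counts, determinism, degenerate SDs", {
  cfg <- small_cohort_config(n_success = 3, n_fail = 2, seed = 42)
  coh <- generate_cohort(cfg)
  expect_length(coh$patients, 5)
  expect_identical(vapply(coh$patients, `[[`, "", "arm"),
                   rep(c("success", "fail"), c(3, 2)))
  coh2 <- generate_cohort(cfg)
  expect_identical(patient_record(coh, 2, "pre")$samples,
                   patient_record(coh2, 2, "pre")$samples)
  # zero between-patient SDs: identical ground truth within an arm/phase
  cal <- calibration_config()
  pop0 <- cal$arms$success$pre
  pop0$pwd_sd <- pop0$pwv_sd <- pop0$ptf_sd <- 0
  pop0$width_jitter_sd <- pop0$hr_sd <- 0
  cfg0 <- cohort_config(n_success = 3, n_fail = 1,
                        arms = list(success = list(pre = pop0, post = pop0),
                                    fail = list(pre = pop0, post = pop0)),
                        fs = 500, duration_s = 20, noise = no_noise(),
                        seed = 3, min_beats = 9L)
  coh0 <- generate_cohort(cfg0)
  gts <- lapply(coh0$patients[1:3], function(p) p$pre$ground_truth)
  expect_equal(gts[[1]], gts[[2]])
  expect_equal(gts[[2]], gts[[3]])
})

test_that("config text round-trip preserves every field", {
  cfg <- calibration_config()
  path <- withr::local_tempfile(fileext = ".txt")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back, cfg)
  expect_error(read_cohort_config(file.path(tempdir(), "nope.txt")),
               "unreadable")
})

test_that("ground-truth export has one row per patient x phase x lead", {
  coh <- generate_cohort(small_cohort_config(n_success = 2, n_fail = 1))
  gt <- cohort_ground_truth(coh)
  expect_equal(nrow(gt), 3 * 2 * 12)
  expect_true(all(gt$ptfv1 <= 0))
})
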