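# Shared fixtures: one clean noiseless record measured once per file run.
fixt <- local({
  tpl <- make_patient_template(build_morphology(), fs = 1000)
  rec <- generate_record(tpl, duration_s = 60, noise = no_noise(), seed = 1)
  recf <- preprocess_record(rec)
  beats <- detect_beats(recf)
  template <- average_pwave(recf, beats)
  list(tpl = tpl, rec = rec, recf = recf, beats = beats,
       template = template, delin = delineate_template(template))
})

test_that("beat detection finds every beat within 10 ms on synthetic records", {
  tpl60 <- quick_template(fs = 500, hr_bpm = 60)
  rec <- generate_record(tpl60, duration_s = 60, seed = 2)
  beats <- detect_beats(preprocess_record(rec))
  expect_gte(length(beats$r_peaks), 58)
  expect_lte(length(beats$r_peaks), 61)
  # true R times: template r_peak_ms plus the beat grid
  gt <- tpl60$ground_truth
  nb <- nrow(tpl60$beat)
  true_r <- round(gt$r_peak_ms / 1000 * 500) + (0:59) * nb
  err_ms <- sapply(beats$r_peaks, function(r) min(abs(r - true_r))) / 500 * 1000
  expect_lt(max(err_ms), 10)
  # QRS onsets precede their R peaks
  expect_true(all(beats$qrs_onsets < beats$r_peaks))
})

test_that("degenerate records raise the documented errors", {
  flat <- ecg_record(matrix(0, 6000, 12, dimnames = list(NULL, ECG_LEADS)),
                     fs = 500)
  expect_error(detect_beats(flat), "flat signal")
  short <- generate_record(quick_template(fs = 500), duration_s = 11,
                           noise = no_noise(), seed = 1)
  expect_error(detect_beats(short), "insufficient beats")
  expect_error(detect_beats(short, min_beats = 5L), NA)
})

test_that("20-beat averaging: noiseless template equals a single beat segment", {
  template <- fixt$template
  # the 20-beat mean reproduces a single-beat segment to sub-uV level (R-peak
  # detection may quantize individual beats by one sample)
  one <- average_pwave(fixt$recf, fixt$beats, n_beats = 1L)
  expect_lt(max(abs(template$samples - one$samples)), 2e-3)
  expect_error(average_pwave(fixt$recf, fixt$beats, n_beats = 100L),
               "insufficient beats")
})

test_that("averaging suppresses white noise by ~ 1/sqrt(n_beats)", {
  tpl <- quick_template(fs = 500, hr_bpm = 72)
  sigma <- 25
  rec <- generate_record(tpl, duration_s = 40,
                         noise = noise_config(white_sd_uv = sigma,
                                              wander_amp_uv = 0,
                                              mains_amp_uv = 0), seed = 8)
  clean <- generate_record(tpl, duration_s = 40, noise = no_noise(), seed = 8)
  beats <- detect_beats(clean)  # identical beat grid, noise-free detection
  t_noisy <- average_pwave(rec, beats, n_beats = 20L)
  t_clean <- average_pwave(clean, beats, n_beats = 20L)
  resid_sd <- sd(t_noisy$samples - t_clean$samples) * 1000
  expect_equal(resid_sd, sigma / sqrt(20), tolerance = 0.15)
})

test_that("P-peak: widest width-qualified lobe wins, spikes are ignored", {
  fs <- 1000
  t <- 1:600
  # single 60 ms Gaussian lobe centred at 400
  y <- 0.15 * exp(-((t - 400)^2) / (2 * 15^2))
  pk <- detect_p_peak(y, fs, window = 100:550)
  expect_lte(abs(pk - 400), 1)
  # a narrow 5 ms spike near the lobe must not win even though it is taller
  y2 <- y; y2[300:304] <- y2[300:304] + 0.3
  pk2 <- detect_p_peak(y2, fs, window = 100:550)
  expect_lte(abs(pk2 - 400), 1)
  # agreement with the brute-force width-scan oracle
  oc <- oracle_widest_lobe(y2, fs, 100:550, baseline = 0)
  expect_lte(abs(pk2 - oc$idx), 1)
  # flat window
  expect_error(detect_p_peak(rep(0, 600), fs, window = 100:550), "no P-wave")
})

test_that("chord rule: noiseless onset/offset within 5 ms of ground truth", {
  gt <- fixt$tpl$ground_truth
  fid <- fixt$delin$fiducials
  qa <- fixt$template$qrs_onset_idx
  on_err <- (fid$onset - qa) - (gt$lead$onset_ms - gt$qrs_onset_ms)
  off_err <- (fid$offset - qa) - (gt$lead$offset_ms - gt$qrs_onset_ms)
  expect_true(all(fid$measurable))
  expect_lt(max(abs(on_err)), 5)
  expect_lt(max(abs(off_err)), 5)
})

test_that("symmetric lobe with symmetric flanking chords delineates symmetrically", {
  fs <- 1000
  t <- 1:801
  # compact-support symmetric lobe with symmetric anchors; the de-biasing tie
  # window compensates band-limited corner smear on each side, so mirror
  # symmetry holds to the tie-window width (a few samples), not exactly
  y <- pwavekit:::trunc_gauss_lobe(t, 0.2, 401, 130)
  res <- locate_onset_offset(y, fs, t_peak = 251L, p_peak = 401L,
                             qrs_onset = 551L, baseline = 0)
  expect_lte(abs((401 - res$onset) - (res$offset - 401)), 4)
  expect_error(locate_onset_offset(y, fs, 401L, 401L, 551L),
               "degenerate chord")
})

test_that("V1 terminal negative phase: duration, trough, and edge cases", {
  gt <- fixt$tpl$ground_truth
  neg <- fixt$delin$v1_neg
  qa <- fixt$template$qrs_onset_idx
  expect_false(is.null(neg))
  dur_ms <- (neg$end - neg$start)
  true_dur <- gt$v1_neg[["end"]] - gt$v1_neg[["start"]]
  expect_lte(abs(dur_ms - true_dur), 4)
  expect_lte(abs((neg$trough - qa) -
                   (gt$v1_neg[["trough"]] - gt$qrs_onset_ms)), 4)
  # monophasic positive V1: no negative phase
  y <- 0.1 * exp(-((1:500 - 300)^2) / (2 * 25^2))
  expect_null(locate_v1_negative_phase(y, p_peak = 300L, onset = 250L,
                                       offset = 350L, baseline = 0))
  # entirely negative P: the negative phase spans onset..offset
  res <- locate_v1_negative_phase(-y, p_peak = 300L, onset = 250L,
                                  offset = 350L, baseline = 0)
  expect_identical(res$start, 250L)
  expect_identical(res$end, 350L)
  expect_lte(abs(res$trough - 300L), 1)
})

test_that("noiseless sweep: per-lead PWD within 5 ms, PTFV1 within 10%", {
  set.seed(11)
  for (k in 1:6) {
    m <- build_morphology(pwd_ms = runif(1, 120, 148),
                          pwdisp_ms = runif(1, 25, 33),
                          pwv_mv = runif(1, 1.0, 1.4),
                          ptf_depth_mv = runif(1, 0.04, 0.11),
                          ptf_width_ms = runif(1, 38, 52),
                          hr_bpm = runif(1, 63, 90))
    tpl <- make_patient_template(m, fs = 1000)
    rec <- generate_record(tpl, duration_s = 60, noise = no_noise(), seed = k)
    p <- measure_record(rec)
    gt <- tpl$ground_truth
    err <- p$pwd_per_lead - gt$lead$pwd_ms[match(names(p$pwd_per_lead),
                                                 gt$lead$lead)]
    expect_lt(max(abs(err), na.rm = TRUE), 5)
    expect_lt(abs(p$ptfv1 - gt$ptfv1), 0.1 * abs(gt$ptfv1))
  }
})

test_that("delineation stays within 10 ms under 10 uV noise in >= 95% of trials", {
  tpl <- quick_template(fs = 500, hr_bpm = 72)
  gt <- tpl$ground_truth
  noise <- noise_config(white_sd_uv = 10, wander_amp_uv = 0, mains_amp_uv = 0)
  ok <- 0L; total <- 0L
  for (s in 1:25) {
    rec <- generate_record(tpl, duration_s = 30, noise = noise, seed = s)
    d <- delineate_template(average_pwave(
      preprocess_record(rec), detect_beats(preprocess_record(rec))))
    fid <- d$fiducials
    qa <- d$template$qrs_onset_idx
    on_err <- abs((fid$onset - qa) / 500 * 1000 -
                    (gt$lead$onset_ms - gt$qrs_onset_ms))
    off_err <- abs((fid$offset - qa) / 500 * 1000 -
                     (gt$lead$offset_ms - gt$qrs_onset_ms))
    ok <- ok + sum(c(on_err, off_err) <= 10, na.rm = TRUE)
    total <- total + sum(!is.na(c(on_err, off_err)))
  }
  expect_gte(ok / total, 0.95)
})

test_that("annotation overrides are honored verbatim, invalid ones rejected", {
  ov <- data.frame(lead = "II", onset = 10L, peak = NA_integer_,
                   offset = NA_integer_)
  d <- delineate_template(fixt$template, overrides = ov)
  expect_identical(d$fiducials$onset[d$fiducials$lead == "II"], 10L)
  p <- params_from_delineation(d)
  i2 <- match("II", names(p$pwd_per_lead))
  expect_equal(p$pwd_per_lead[[i2]],
               (d$fiducials$offset[d$fiducials$lead == "II"] - 10) /
                 1000 * 1000)
  bad <- data.frame(lead = "II", onset = 5000L)
  expect_error(delineate_template(fixt$template, overrides = bad),
               "outside|ordering")
  bad2 <- data.frame(lead = "II",
                     onset = d$fiducials$peak[d$fiducials$lead == "II"] + 5L)
  expect_error(delineate_template(fixt$template, overrides = bad2),
               "ordering")
})
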