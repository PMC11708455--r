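#' Additive noise configuration for synthetic records
#'
#' White (broadband) noise, sinusoidal baseline wander, and sinusoidal mains
#' interference. Amplitudes are in microvolts; `mains_hz` must be a supported
#' power-line frequency (50 or 60 Hz).
#'
#' @param white_sd_uv standard deviation of white noise, uV.
#' @param wander_amp_uv,wander_hz baseline-wander amplitude (uV) and
#'   frequency (Hz).
#' @param mains_amp_uv,mains_hz mains amplitude (uV) and frequency (Hz).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(white_sd_uv = 15, wander_amp_uv = 100,
                         wander_hz = 0.25, mains_amp_uv = 30, mains_hz = 50) {
  if (white_sd_uv < 0 || wander_amp_uv < 0 || mains_amp_uv < 0)
    stop("noise amplitudes must be >= 0")
  if (!mains_hz %in% c(50, 60)) stop("mains frequency must be 50 or 60 Hz")
  structure(list(white_sd_uv = white_sd_uv, wander_amp_uv = wander_amp_uv,
                 wander_hz = wander_hz, mains_amp_uv = mains_amp_uv,
                 mains_hz = mains_hz),
            class = "noise_config")
}

# Fraction of the RR interval after QRS onset at which the T wave peaks
# (rate-adaptive QT surrogate); documented constant of the beat model.
T_PEAK_FRAC_RR <- 0.43

#' Render one noiseless beat per lead with closed-form ground truth
#'
#' Samples the parametric beat of a [pwave_morphology()] at `fs` and returns
#' both the waveform and the analytic values every later measurement stage
#' is supposed to recover: per-lead P onset/peak/offset (at the exact lobe
#' support boundaries), per-lead and global P-wave duration, P-wave voltage
#' (12-lead sum of absolute peak amplitudes), P-wave dispersion, and PTFV1
#' (minus V1 negative-lobe depth in mV times its duration in ms). Lobes that
#' would spill over a beat boundary wrap around, so a tiled record is exactly
#' periodic.
#'
#' @param morph a [pwave_morphology()].
#' @param fs sampling rate in Hz (>= 250).
#' @return A list of class `patient_template`: `beat` (samples x 12 matrix,
#'   mV), `fs`, `rr_ms`, and `ground_truth`.
#' @export
make_patient_template <- function(morph, fs = 1000) {
  stopifnot(inherits(morph, "pwave_morphology"))
  if (fs < 250) stop("unsupported sampling rate: need fs >= 250 Hz")
  rr_ms <- 60000 / morph$hr_bpm
  n <- round(rr_ms / 1000 * fs)
  t <- (seq_len(n) - 1L) / fs * 1000
  qrs_center <- morph$qrs_onset_ms + morph$qrs_width / 2
  t_center <- morph$qrs_onset_ms + T_PEAK_FRAC_RR * rr_ms
  wrap <- function(f, amp, center, width) {
    f(t, amp, center, width) + f(t, amp, center - rr_ms, width) +
      f(t, amp, center + rr_ms, width)
  }
  # The QRS triangle's corners are rounded with a short Hann kernel (16 ms):
  # a corner discontinuity rings under the 50 Hz low-pass and the resulting
  # pre-QRS undershoot would contaminate the P-offset search. Physiological
  # QRS upstrokes are not perfect corners either.
  kw <- max(3L, as.integer(round(0.016 * fs)))
  if (kw %% 2L == 0L) kw <- kw + 1L
  kern <- 0.5 * (1 - cos(2 * pi * seq_len(kw) / (kw + 1)))
  kern <- kern / sum(kern)
  beat <- matrix(0, n, 12L, dimnames = list(NULL, ECG_LEADS))
  qrs_unit <- as.numeric(stats::filter(
    wrap(triangle_lobe, 1, qrs_center, morph$qrs_width), kern,
    method = "convolution", sides = 2L, circular = TRUE))
  for (ld in ECG_LEADS) {
    s <- morph$lead_scale[[ld]]
    x <- wrap(trunc_gauss_lobe, morph$p_amp[[ld]], morph$p_center[[ld]],
              morph$p_width[[ld]]) +
      morph$qrs_amp * s * qrs_unit +
      wrap(trunc_gauss_lobe, morph$t_amp * s, t_center, morph$t_width)
    if (ld == "V1" && morph$v1_neg_amp > 0)
      x <- x + wrap(trunc_gauss_lobe, -morph$v1_neg_amp,
                    morph$v1_neg_center, morph$v1_neg_width)
    beat[, ld] <- x
  }
  onset <- morph$p_center - morph$p_width / 2
  offset <- morph$p_center + morph$p_width / 2
  peak <- morph$p_center
  neg <- NULL
  if (morph$v1_neg_amp > 0) {
    neg <- c(start = morph$v1_neg_center - morph$v1_neg_width / 2,
             trough = morph$v1_neg_center,
             end = morph$v1_neg_center + morph$v1_neg_width / 2)
    offset["V1"] <- neg[["end"]]
  }
  pwd_lead <- offset - onset
  gt <- list(
    lead = data.frame(lead = ECG_LEADS, onset_ms = unname(onset),
                      peak_ms = unname(peak), offset_ms = unname(offset),
                      pwd_ms = unname(pwd_lead), row.names = NULL),
    pwd_ms = max(pwd_lead),
    pwv_mv = sum(abs(morph$p_amp)),
    pwdisp_ms = max(pwd_lead) - min(pwd_lead),
    ptfv1 = -morph$v1_neg_amp * (if (morph$v1_neg_amp > 0) morph$v1_neg_width else 0),
    v1_neg = neg,
    qrs_onset_ms = morph$qrs_onset_ms,
    r_peak_ms = qrs_center,
    t_peak_ms = t_center,
    rr_ms = rr_ms)
  structure(list(beat = beat, fs = fs, rr_ms = rr_ms, ground_truth = gt),
            class = "patient_template")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Tile a beat template into a noisy 60-second style recording
#'
#' Beats are tiled at the template's RR interval; white noise, baseline
#' wander and mains interference are added per [noise_config()], each with
#' phases/realisations drawn reproducibly from `seed`.
#'
#' @param template a [make_patient_template()] result.
#' @param duration_s recording duration in seconds (>= 1 beat).
#' @param noise a [noise_config()].
#' @param seed integer seed; the same seed yields a bit-identical record.
#' @return An [ecg_record()].
#' @export
generate_record <- function(template, duration_s = 60,
                            noise = noise_config(), seed = 1) {
  stopifnot(inherits(template, "patient_template"),
            inherits(noise, "noise_config"))
  fs <- template$fs
  n_beat <- nrow(template$beat)
  n_total <- round(duration_s * fs)
  if (n_total < n_beat) stop("duration too short for a single beat")
  idx <- ((seq_len(n_total) - 1L) %% n_beat) + 1L
  x <- template$beat[idx, , drop = FALSE]
  with_seed(seed, {
    if (noise$white_sd_uv > 0)
      x <- x + matrix(stats::rnorm(n_total * 12L, sd = noise$white_sd_uv / 1000),
                      n_total, 12L)
    tt <- (seq_len(n_total) - 1L) / fs
    if (noise$wander_amp_uv > 0) {
      ph <- stats::runif(12L, 0, 2 * pi)
      x <- x + (noise$wander_amp_uv / 1000) *
        sin(outer(2 * pi * noise$wander_hz * tt, ph, `+`))
    }
    if (noise$mains_amp_uv > 0) {
      ph <- stats::runif(12L, 0, 2 * pi)
      x <- x + (noise$mains_amp_uv / 1000) *
        sin(outer(2 * pi * noise$mains_hz * tt, ph, `+`))
    }
  })
  ecg_record(x, fs = fs)
}

#' Arm/phase population specification
#'
#' Population means and between-patient SDs of the interpretable morphology
#' summaries consumed by [build_morphology()]. `ptf_mean`/`ptf_sd` describe
#' the *magnitude* of PTFV1 (mV x ms); draws clipped at zero yield a
#' monophasic V1 P wave (PTFV1 = 0).
#'
#' @param pwd_mean,pwd_sd global P-wave duration, ms.
#' @param pwdisp_mean P-wave dispersion, ms (between-patient spread enters
#'   through `width_jitter_sd`).
#' @param pwv_mean,pwv_sd 12-lead P-wave voltage sum, mV.
#' @param ptf_mean,ptf_sd PTFV1 magnitude, mV.ms.
#' @param ptf_width_ms V1 negative-phase duration, ms.
#' @param width_jitter_sd per-lead additive width jitter SD, ms.
#' @param hr_mean,hr_sd heart rate, bpm.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(pwd_mean = 136.7, pwd_sd = 23,
                            pwdisp_mean = 29.7,
                            pwv_mean = 1.2, pwv_sd = 0.35,
                            ptf_mean = 3.1, ptf_sd = 2.0,
                            ptf_width_ms = 45, width_jitter_sd = 1.5,
                            hr_mean = 72, hr_sd = 5) {
  if (any(c(pwd_sd, pwv_sd, ptf_sd, width_jitter_sd, hr_sd) < 0))
    stop("population SDs must be >= 0")
  structure(list(pwd_mean = pwd_mean, pwd_sd = pwd_sd,
                 pwdisp_mean = pwdisp_mean, pwv_mean = pwv_mean,
                 pwv_sd = pwv_sd, ptf_mean = ptf_mean, ptf_sd = ptf_sd,
                 ptf_width_ms = ptf_width_ms,
                 width_jitter_sd = width_jitter_sd,
                 hr_mean = hr_mean, hr_sd = hr_sd),
            class = "population_spec")
}

#' Two-arm pre/post cohort configuration
#'
#' @param n_success,n_fail patients per arm (>= 1).
#' @param arms nested list `arms$success$pre`, `arms$success$post`,
#'   `arms$fail$pre`, `arms$fail$post`, each a [population_spec()].
#' @param fs sampling rate, Hz.
#' @param duration_s record duration, s; must allow at least 21 beats at the
#'   slowest plausible heart rate of the populations.
#' @param noise a [noise_config()].
#' @param seed integer master seed.
#' @param min_beats beats the recordings must accommodate; the default 21
#'   supports 20-beat template averaging. Reduced-scale runs (shorter
#'   records averaged over fewer beats) may lower it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_success = 43, n_fail = 29,
                          arms = list(
                            success = list(pre = population_spec(),
                                           post = population_spec()),
                            fail = list(pre = population_spec(),
                                        post = population_spec())),
                          fs = 1000, duration_s = 60,
                          noise = noise_config(), seed = 1,
                          min_beats = 21L) {
  if (n_success < 1 || n_fail < 1) stop("need at least one patient per arm")
  for (arm in c("success", "fail")) for (ph in c("pre", "post"))
    stopifnot(inherits(arms[[arm]][[ph]], "population_spec"))
  slow_hr <- min(vapply(c("success", "fail"), function(a)
    min(arms[[a]]$pre$hr_mean, arms[[a]]$post$hr_mean), numeric(1))) - 15
  if (duration_s < min_beats * 60 / max(slow_hr, 30))
    stop(sprintf("duration too short for %d beats at the configured heart rate",
                 min_beats))
  structure(list(n_success = n_success, n_fail = n_fail, arms = arms,
                 fs = fs, duration_s = duration_s, noise = noise,
                 seed = seed, min_beats = as.integer(min_beats)),
            class = "cohort_config")
}

draw_morphology <- function(pop, max_retry = 25L) {
  for (k in seq_len(max_retry)) {
    m <- try({
      jit <- stats::setNames(stats::rnorm(12L, sd = pop$width_jitter_sd),
                             ECG_LEADS)
      depth <- max(pop$ptf_mean + stats::rnorm(1L, sd = pop$ptf_sd), 0) /
        pop$ptf_width_ms
      build_morphology(
        pwd_ms = pop$pwd_mean + stats::rnorm(1L, sd = pop$pwd_sd),
        pwdisp_ms = pop$pwdisp_mean,
        pwv_mv = max(pop$pwv_mean + stats::rnorm(1L, sd = pop$pwv_sd),
                     0.3 * pop$pwv_mean),
        ptf_depth_mv = depth, ptf_width_ms = pop$ptf_width_ms,
        hr_bpm = min(max(pop$hr_mean + stats::rnorm(1L, sd = pop$hr_sd), 40),
                     150),
        width_jitter_ms = jit)
    }, silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
  }
  stop("could not draw a feasible morphology after ", max_retry, " attempts")
}

#' Generate a two-arm pre/post synthetic cohort
#'
#' Draws one morphology per patient and phase from the arm-specific
#' populations, attaches the closed-form ground truth, and stores a
#' deterministic per-record seed so that recordings can be materialised
#' lazily with [patient_record()] (full 60 s x 12 lead cohorts are large;
#' keeping only the recipe makes a 72-patient study fit comfortably in
#' memory).
#'
#' @param cfg a [cohort_config()].
#' @param keep_records if `TRUE`, also materialise and store every
#'   [ecg_record()] (only advisable for small configurations).
#' @return A list of class `cohort`: `patients` (list), `cfg`.
#'   Each patient has `id`, `arm`, and per-phase entries `pre`/`post` with
#'   `morph`, `template`, `ground_truth`, `seed` (and `record` when kept).
#' @export
generate_cohort <- function(cfg, keep_records = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_success + cfg$n_fail
  arms <- rep(c("success", "fail"), c(cfg$n_success, cfg$n_fail))
  patients <- with_seed(cfg$seed, {
    rec_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                        n, 2L, dimnames = list(NULL, c("pre", "post")))
    lapply(seq_len(n), function(i) {
      p <- list(id = sprintf("P%03d", i), arm = arms[i])
      for (ph in c("pre", "post")) {
        morph <- draw_morphology(cfg$arms[[arms[i]]][[ph]])
        tpl <- make_patient_template(morph, fs = cfg$fs)
        p[[ph]] <- list(morph = morph, template = tpl,
                        ground_truth = tpl$ground_truth,
                        seed = rec_seeds[i, ph])
      }
      p
    })
  })
  if (keep_records) {
    for (i in seq_along(patients)) for (ph in c("pre", "post"))
      patients[[i]][[ph]]$record <- generate_record(
        patients[[i]][[ph]]$template, duration_s = cfg$duration_s,
        noise = cfg$noise, seed = patients[[i]][[ph]]$seed)
  }
  structure(list(patients = patients, cfg = cfg), class = "cohort")
}

#' Materialise one patient-phase recording of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param i patient index.
#' @param phase `"pre"` or `"post"`.
#' @return An [ecg_record()].
#' @export
patient_record <- function(cohort, i, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  p <- cohort$patients[[i]][[phase]]
  if (!is.null(p$record)) return(p$record)
  generate_record(p$template, duration_s = cohort$cfg$duration_s,
                  noise = cohort$cfg$noise, seed = p$seed)
}

#' Ground-truth table of a cohort
#'
#' One row per patient x phase x lead with analytic fiducials, plus the
#' per-recording analytic global parameters, suitable for CSV export.
#'
#' @param cohort a [generate_cohort()] result.
#' @return A data.frame.
#' @export
cohort_ground_truth <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(c("pre", "post"), function(ph) {
      gt <- p[[ph]]$ground_truth
      cbind(data.frame(id = p$id, arm = p$arm, phase = ph), gt$lead,
            data.frame(pwd_global_ms = gt$pwd_ms, pwv_mv = gt$pwv_mv,
                       pwdisp_ms = gt$pwdisp_ms, ptfv1 = gt$ptfv1))
    }))
  })
  do.call(rbind, rows)
}
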