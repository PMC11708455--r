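#' Per-patient P-wave / beat morphology
#'
#' Parametric description of one sinus beat across the 12 leads. P and T
#' waves are truncated, baseline-shifted Gaussian lobes: a lobe of amplitude
#' `a`, center `c` and width `w` (ms) is
#' `a * (exp(-(t-c)^2 / (2*sigma^2)) - exp(-2)) / (1 - exp(-2))` with
#' `sigma = w/4`, identically zero outside `[c - w/2, c + w/2]`. The compact
#' support makes analytic onset/offset (and hence PWD, PWDisp, PTFV1) exact,
#' and the non-zero slope at the support edge keeps the chord-distance
#' delineation rule sharp. The QRS complex is a triangle. Lead V1 carries a
#' biphasic P wave: its positive lobe is followed by a negative lobe of depth
#' `v1_neg_amp` (stored >= 0) whose support begins where the positive lobe's
#' support ends.
#'
#' All times are ms from the beat start; QRS onset sits at `qrs_onset_ms`
#' and the T wave of the *same* beat peaks at `qrs_onset_ms + 0.43 * RR`
#' (rate-adaptive QT), so the P wave of the following beat is flanked by
#' this beat's T wave.
#'
#' @param p_amp named numeric vector (mV), signed P-lobe amplitude per lead
#'   (V1 entry = positive lobe).
#' @param p_center named numeric vector (ms), P-lobe centers per lead.
#' @param p_width named numeric vector (ms), P-lobe support widths per lead.
#' @param v1_neg_amp depth of the V1 negative lobe in mV (>= 0; 0 =
#'   monophasic V1).
#' @param v1_neg_center,v1_neg_width center and support width (ms) of the V1
#'   negative lobe.
#' @param qrs_amp,qrs_width QRS triangle amplitude (mV, lead II reference)
#'   and base width (ms).
#' @param t_amp,t_width T-wave lobe amplitude (mV, lead II reference) and
#'   support width (ms).
#' @param pr_ms PR interval: lead-II P onset to QRS onset (ms).
#' @param hr_bpm heart rate in beats per minute (30--180).
#' @param qrs_onset_ms QRS onset position within the beat (ms).
#' @param lead_scale named numeric vector scaling QRS and T per lead.
#' @return An object of class `pwave_morphology`.
#' @export
pwave_morphology <- function(p_amp, p_center, p_width,
                             v1_neg_amp, v1_neg_center, v1_neg_width,
                             qrs_amp = 0.9, qrs_width = 80,
                             t_amp = 0.25, t_width = 140,
                             pr_ms = NULL, hr_bpm = 72,
                             qrs_onset_ms = 250,
                             lead_scale = default_lead_scale()) {
  for (v in list(p_amp, p_center, p_width, lead_scale)) {
    if (!all(ECG_LEADS %in% names(v)))
      stop("per-lead vectors must be named with all 12 standard leads")
  }
  p_amp <- p_amp[ECG_LEADS]; p_center <- p_center[ECG_LEADS]
  p_width <- p_width[ECG_LEADS]; lead_scale <- lead_scale[ECG_LEADS]
  if (any(p_width <= 0) || v1_neg_width <= 0 || qrs_width <= 0 || t_width <= 0)
    stop("all widths must be > 0")
  if (v1_neg_amp < 0) stop("V1 negative-lobe depth is stored as >= 0")
  if (hr_bpm < 30 || hr_bpm > 180) stop("heart rate outside [30, 180] bpm")
  if (any(p_center + p_width / 2 > qrs_onset_ms))
    stop("P lobes must end before QRS onset")
  if (v1_neg_amp > 0) {
    if (v1_neg_center - v1_neg_width / 2 < p_center["V1"] - 1e-9)
      stop("V1 negative lobe must begin at or after the V1 positive-lobe center")
    if (v1_neg_center + v1_neg_width / 2 > qrs_onset_ms)
      stop("P lobes must end before QRS onset")
  }
  if (is.null(pr_ms))
    pr_ms <- qrs_onset_ms - (p_center["II"] - p_width["II"] / 2)
  structure(list(p_amp = p_amp, p_center = p_center, p_width = p_width,
                 v1_neg_amp = v1_neg_amp, v1_neg_center = v1_neg_center,
                 v1_neg_width = v1_neg_width,
                 qrs_amp = qrs_amp, qrs_width = qrs_width,
                 t_amp = t_amp, t_width = t_width,
                 pr_ms = as.numeric(pr_ms), hr_bpm = hr_bpm,
                 qrs_onset_ms = qrs_onset_ms, lead_scale = lead_scale),
            class = "pwave_morphology")
}

#' Default per-lead QRS/T projection factors
#'
#' Rough frontal/precordial projections of a normal sinus beat; aVR is
#' inverted, V1 predominantly negative (rS pattern).
#' @return Named numeric vector over [ECG_LEADS].
#' @export
default_lead_scale <- function() {
  c(I = 0.7, II = 1.0, III = 0.5, aVR = -0.8, aVL = 0.4, aVF = 0.8,
    V1 = -0.5, V2 = 0.7, V3 = 0.9, V4 = 1.0, V5 = 0.9, V6 = 0.8)
}

#' Build a morphology from interpretable summary parameters
#'
#' Convenience layer used by the cohort generator: per-lead P widths are a
#' fixed ranking pattern rescaled so that the longest lead equals `pwd_ms`
#' and the max-min spread equals `pwdisp_ms`; per-lead P amplitudes are a
#' fixed pattern rescaled so the 12-lead absolute sum equals `pwv_mv`; the
#' V1 terminal force follows from `ptf_depth_mv` and `ptf_width_ms`
#' (analytic PTFV1 = -depth x width). Every lobe's support ends `p_gap_ms`
#' before QRS onset.
#'
#' @param pwd_ms analytic global (longest-lead) P-wave duration, ms.
#' @param pwdisp_ms analytic P-wave dispersion (max - min per-lead PWD), ms.
#' @param pwv_mv analytic P-wave voltage (12-lead sum of |peak|), mV.
#' @param ptf_depth_mv V1 negative-lobe depth, mV (0 = monophasic V1).
#' @param ptf_width_ms V1 negative-lobe support width, ms.
#' @param hr_bpm heart rate, bpm.
#' @param p_gap_ms gap between P offset and QRS onset, ms.
#' @param width_jitter_ms optional named per-lead additive width jitter (ms).
#' @param ... passed on to [pwave_morphology()] (e.g. `qrs_amp`, `t_amp`).
#' @return A `pwave_morphology`.
#' @export
build_morphology <- function(pwd_ms = 136.7, pwdisp_ms = 29.7, pwv_mv = 1.2,
                             ptf_depth_mv = 0.069, ptf_width_ms = 45,
                             hr_bpm = 72, p_gap_ms = 30,
                             width_jitter_ms = NULL, ...) {
  # Fixed ranking pattern in [0, 1]: 1 = longest lead (II), 0 = shortest (V1).
  rank_pat <- c(II = 1.00, aVF = 0.78, I = 0.67, V5 = 0.61, V6 = 0.54,
                V4 = 0.47, V3 = 0.40, aVL = 0.34, V2 = 0.27, III = 0.17,
                aVR = 0.10, V1 = 0.00)[ECG_LEADS]
  amp_pat <- c(I = 0.08, II = 0.15, III = 0.08, aVR = -0.12, aVL = 0.05,
               aVF = 0.11, V1 = 0.06, V2 = 0.10, V3 = 0.12, V4 = 0.12,
               V5 = 0.10, V6 = 0.09)[ECG_LEADS]
  widths <- pwd_ms - (1 - rank_pat) * pwdisp_ms
  if (!is.null(width_jitter_ms)) widths <- widths + width_jitter_ms[ECG_LEADS]
  if (any(widths <= 15)) stop("infeasible P widths (<= 15 ms)")
  amps <- amp_pat * (pwv_mv / sum(abs(amp_pat)))
  qrs_onset_ms <- 250
  # V1: positive support + negative support are contiguous; total = widths["V1"]
  has_neg <- ptf_depth_mv > 0
  w_neg <- if (has_neg) ptf_width_ms else 0
  if (widths["V1"] - w_neg <= 15)
    stop("infeasible V1 positive-lobe width")
  centers <- qrs_onset_ms - p_gap_ms - widths / 2
  w_pos_v1 <- widths[["V1"]] - w_neg
  centers["V1"] <- qrs_onset_ms - p_gap_ms - w_neg - w_pos_v1 / 2
  v1_neg_center <- qrs_onset_ms - p_gap_ms - w_neg / 2
  pwave_morphology(p_amp = amps, p_center = centers, p_width =
                     replace(widths, "V1", w_pos_v1),
                   v1_neg_amp = ptf_depth_mv,
                   v1_neg_center = if (has_neg) v1_neg_center else centers[["V1"]] + 1,
                   v1_neg_width = max(w_neg, 1),
                   hr_bpm = hr_bpm, qrs_onset_ms = qrs_onset_ms, ...)
}

# Truncated, baseline-shifted Gaussian lobe evaluated at times t (ms).
trunc_gauss_lobe <- function(t, amp, center, width) {
  sigma <- width / 4
  out <- numeric(length(t))
  inside <- abs(t - center) <= width / 2
  if (any(inside)) {
    e <- exp(-((t[inside] - center)^2) / (2 * sigma^2))
    out[inside] <- amp * (e - exp(-2)) / (1 - exp(-2))
  }
  out
}

triangle_lobe <- function(t, amp, center, width) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= width / 2
  out[inside] <- amp * (1 - abs(t[inside] - center) / (width / 2))
  out
}
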