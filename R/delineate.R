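#' Detect beats (R peaks and QRS onsets)
#'
#' A derivative-energy detector on one reference lead: the squared first
#' difference is smoothed (60 ms window), thresholded, and each
#' supra-threshold region is refined to the local extremum of the raw
#' amplitude. The QRS onset of every beat is the last sample before the
#' sustained upstroke (amplitude within 6% of the local baseline-to-R
#' excursion).
#'
#' @param record an [ecg_record()] (filtered or raw).
#' @param lead reference lead used for detection, default `"II"`.
#' @param min_beats minimum number of beats required; the default 21 is what
#'   a 20-beat averaged template (which also needs the preceding T wave)
#'   consumes.
#' @return An object of class `beat_set`: list with integer vectors
#'   `r_peaks` and `qrs_onsets` (sample indices, ascending), `fs`,
#'   `rr_median` (samples).
#' @export
detect_beats <- function(record, lead = "II", min_beats = 21L) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  x <- record$samples[, lead]
  if (length(x) < 10 * fs) stop("record must be at least 10 s long")
  if (diff(range(x)) < 0.05) stop("flat signal: no QRS activity detected")
  w <- max(3L, as.integer(round(0.06 * fs)))
  e <- c(0, diff(x))^2
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  thr <- 0.25 * stats::quantile(e, 0.995, names = FALSE)
  if (!is.finite(thr) || thr <= 0) stop("flat signal: no QRS activity detected")
  above <- e > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  if (nrow(regions) == 0L) stop("flat signal: no QRS activity detected")
  # merge regions separated by < 200 ms
  gap <- as.integer(round(0.2 * fs))
  keep <- list(regions[1L, ])
  if (nrow(regions) > 1L) for (k in 2L:nrow(regions)) {
    last <- keep[[length(keep)]]
    if (regions[k, 1L] - last[2L] < gap)
      keep[[length(keep)]] <- c(last[1L], regions[k, 2L])
    else keep[[length(keep) + 1L]] <- regions[k, ]
  }
  med <- stats::median(x)
  half <- as.integer(round(0.08 * fs))
  n <- length(x)
  r_peaks <- vapply(keep, function(rg) {
    lo <- max(1L, rg[1L] - half); hi <- min(n, rg[2L] + half)
    lo + which.max(abs(x[lo:hi] - med)) - 1L
  }, integer(1L))
  r_peaks <- sort(unique(r_peaks))
  # drop beats too close to the edges for onset estimation
  r_peaks <- r_peaks[r_peaks > 0.3 * fs & r_peaks < n - 0.1 * fs]
  if (length(r_peaks) < min_beats)
    stop(sprintf("insufficient beats for %d-beat averaging: detected %d, need %d",
                 min_beats - 1L, length(r_peaks), min_beats))
  qrs_onsets <- vapply(r_peaks, function(rp) {
    base_win <- x[max(1L, rp - as.integer(0.24 * fs)):(rp - as.integer(0.14 * fs))]
    base <- stats::median(base_win)
    amp <- x[rp] - base
    js <- max(1L, rp - as.integer(0.12 * fs)):(rp - 1L)
    small <- abs(x[js] - base) < 0.06 * abs(amp)
    if (!any(small)) js[1L] else js[max(which(small))]
  }, integer(1L))
  structure(list(r_peaks = r_peaks, qrs_onsets = qrs_onsets, fs = fs,
                 rr_median = stats::median(diff(r_peaks))),
            class = "beat_set")
}

#' Average consecutive P waves into a per-lead template
#'
#' Aligns beats on the R peak and averages `n_beats` consecutive pre-QRS
#' segments per lead. Each segment spans the last 60% of the median RR
#' interval before QRS onset, so it contains the preceding T peak, the TP
#' baseline and the P wave, and ends exactly at QRS onset. Beats whose
#' preceding RR interval deviates more than 20% from the record median are
#' excluded before the consecutive run is chosen (ectopy guard).
#'
#' @param record an [ecg_record()].
#' @param beats a [detect_beats()] result.
#' @param n_beats number of beats to average (default 20).
#' @return An object of class `pwave_template`: `samples` (segment x 12
#'   matrix, mV), `fs`, `qrs_onset_idx` (last sample of the segment),
#'   `rr_ms`, `n_beats`.
#' @export
average_pwave <- function(record, beats, n_beats = 20L) {
  stopifnot(inherits(record, "ecg_record"), inherits(beats, "beat_set"))
  fs <- record$fs
  rp <- beats$r_peaks
  if (length(rp) < n_beats + 1L)
    stop(sprintf("insufficient beats: have %d, need %d for %d-beat averaging",
                 length(rp), n_beats + 1L, n_beats))
  rr <- diff(rp)
  med_rr <- stats::median(rr)
  ok <- c(FALSE, abs(rr - med_rr) <= 0.2 * med_rr)  # beat needs a clean preceding RR
  delta <- as.integer(round(stats::median(rp - beats$qrs_onsets)))
  L <- as.integer(round(0.6 * med_rr))
  starts <- rp - delta - L
  usable <- ok & starts >= 1L & (rp - delta) <= n_samples(record)
  # first run of n_beats consecutive usable beats
  run <- rle(usable)
  ends <- cumsum(run$lengths)
  cand <- which(run$values & run$lengths >= n_beats)
  if (!length(cand))
    stop("segment misalignment: no run of ", n_beats, " consecutive clean beats")
  first <- ends[cand[1L]] - run$lengths[cand[1L]] + 1L
  sel <- seq(first, length.out = n_beats)
  seg_idx <- outer(0:L, starts[sel], `+`)  # (L+1) x n_beats
  acc <- matrix(0, L + 1L, 12L, dimnames = list(NULL, ECG_LEADS))
  for (ld in ECG_LEADS) {
    v <- record$samples[, ld]
    acc[, ld] <- rowMeans(matrix(v[seg_idx], L + 1L, n_beats))
  }
  structure(list(samples = acc, fs = fs, qrs_onset_idx = L + 1L,
                 rr_ms = med_rr / fs * 1000, n_beats = n_beats,
                 beats_used = rp[sel]),
            class = "pwave_template")
}

# last argmax (ties break to the later sample, i.e. toward the P wave)
last_argmax <- function(d) {
  m <- max(d)
  max(which(d >= m - 1e-12))
}

# Interior sample of maximal perpendicular distance to the chord joining
# (i1, y[i1]) and (i2, y[i2]). Vertical and perpendicular distances share
# their argmax along a fixed chord. Samples whose distance is within
# `tie_tol` (mV, the template's effective amplitude resolution) of the
# maximum count as ties; ties break toward the P wave (`tie = "later"` on
# the onset side, `"earlier"` on the offset side). `exclude_end` interior
# samples adjacent to i2 are skipped (used to keep the pre-QRS foot of the
# filtered QRS out of the offset search).
chord_knee <- function(y, i1, i2, tie = c("later", "earlier"),
                       tie_tol = 0, exclude_end = 0L) {
  tie <- match.arg(tie)
  hi <- i2 - 1L - as.integer(exclude_end)
  if (hi - i1 < 1L) stop("degenerate chord: fewer than one interior sample")
  ii <- (i1 + 1L):hi
  chord <- y[i1] + (y[i2] - y[i1]) * (ii - i1) / (i2 - i1)
  d <- abs(y[ii] - chord)
  cand <- which(d >= max(d) - tie_tol)
  ii[if (tie == "later") max(cand) else min(cand)]
}

# Refine a knee to the point of maximal signed curvature in a small
# neighborhood. Band-limited acquisition smears the wave-foot corner over
# roughly the filter transition width, which biases the raw knee outward on
# narrow lobes; the curvature maximum of the smeared corner stays put.
# `s` is +1 for a corner that curls upward (foot of a positive lobe).
refine_corner <- function(y, i, s, fs, win_ms = 6, h_ms = 5) {
  h <- max(2L, as.integer(round(h_ms / 1000 * fs)))
  w <- as.integer(round(win_ms / 1000 * fs))
  ii <- max(h + 1L, i - w):min(length(y) - h, i + w)
  if (length(ii) < 3L) return(i)
  curv <- (y[ii - h] - 2 * y[ii] + y[ii + h]) * s
  ii[which.max(curv)]
}

#' Detect the P-wave peak in a template window
#'
#' Returns the extremum of the widest deflection whose width at
#' half-prominence (relative to the provisional baseline) is at least
#' `min_width_ms`; narrower spikes are ignored. Both polarities are
#' considered, so inverted P waves (e.g. aVR) are found.
#'
#' @param y numeric vector, one lead of a [average_pwave()] template (mV).
#' @param fs sampling rate, Hz.
#' @param window integer vector of candidate indices (the search window:
#'   after the T peak, before QRS onset).
#' @param baseline provisional baseline level (mV); default median of the
#'   window.
#' @param min_width_ms minimum lobe width at half-prominence, ms.
#' @param prefer_positive when `TRUE` and any positive lobe qualifies, only
#'   positive lobes are considered. Used for lead V1, where the P peak of a
#'   biphasic (positive-then-negative) P wave is the initial positive
#'   deflection even when the terminal negative phase is wider; a V1 P wave
#'   with no qualifying positive lobe (entirely negative) still falls back
#'   to the negative extremum.
#' @return The peak sample index.
#' @export
detect_p_peak <- function(y, fs, window = seq_along(y),
                          baseline = stats::median(y[window]),
                          min_width_ms = 15, prefer_positive = FALSE) {
  dev <- y - baseline
  # candidates must be substantial relative to the dominant deflection (the
  # residual low-frequency trend forms broad shallow humps) and no wider
  # than 60% of the window (such humps are not P waves)
  floor_amp <- max(0.015, 0.30 * max(abs(dev[window])))
  max_width_ms <- 0.6 * length(window) / fs * 1000
  cands <- list()
  for (s in c(1, -1)) {
    z <- s * dev
    cand <- window[-c(1L, length(window))]
    is_max <- z[cand] >= z[cand - 1L] & z[cand] >= z[cand + 1L] &
      z[cand] > floor_amp
    for (i in cand[is_max]) {
      half <- z[i] / 2
      lo <- i; while (lo > window[1L] && z[lo - 1L] > half) lo <- lo - 1L
      hi <- i; while (hi < window[length(window)] && z[hi + 1L] > half) hi <- hi + 1L
      w_ms <- (hi - lo + 1L) / fs * 1000
      if (w_ms >= min_width_ms && w_ms <= max_width_ms)
        cands[[length(cands) + 1L]] <- list(idx = i, w = w_ms, amp = z[i],
                                            sign = s)
    }
  }
  if (!length(cands))
    stop(sprintf("no P-wave lobe of at least %g ms width in the search window",
                 min_width_ms))
  if (prefer_positive && any(vapply(cands, `[[`, numeric(1L), "sign") > 0))
    cands <- Filter(function(cc) cc$sign > 0, cands)
  best <- cands[[1L]]
  for (cc in cands[-1L]) {
    if (cc$w > best$w || (abs(cc$w - best$w) < 1e-9 && cc$amp > best$amp))
      best <- cc
  }
  best$idx
}

#' Locate P-wave onset and offset by the chord-distance rule
#'
#' Onset: the interior sample at maximal perpendicular distance from the
#' chord joining the T peak to the P peak. Because a T wave taller than the
#' P wave makes that knee land at the end of the T wave rather than at P
#' onset, the rule is applied in two stages: the first knee is re-used as
#' the chord anchor and the knee is recomputed; the second knee is accepted
#' only when the segment between the two knees is flat (mean absolute slope
#' below 0.4% of the P prominence per ms), i.e. when the first knee was a
#' T-end corner and the chord traversed TP baseline. Ties break to the later
#' sample.
#'
#' Offset mirrors the rule on the chord joining the P peak to QRS onset.
#' When that knee is itself a sub-baseline trough (terminal negative phase,
#' as in a biphasic V1 P wave), the chord is re-anchored at the trough and
#' the knee recomputed, so the offset lands at the return to baseline after
#' the negative phase.
#'
#' @param y numeric vector, one lead of a template (mV).
#' @param fs sampling rate, Hz.
#' @param t_peak,p_peak,qrs_onset sample indices with
#'   `t_peak < p_peak < qrs_onset`.
#' @param baseline provisional baseline level (mV).
#' @param win_lo first sample index that could plausibly be the P onset
#'   (the start of the P search window); a first knee earlier than this is
#'   necessarily a T-end corner, so the re-anchored knee is accepted
#'   unconditionally.
#' @return A list with integer elements `onset` and `offset` (and the
#'   intermediate `t_end` anchor).
#' @export
locate_onset_offset <- function(y, fs, t_peak, p_peak, qrs_onset,
                                baseline = stats::median(y[t_peak:qrs_onset]),
                                win_lo = t_peak + 1L) {
  if (t_peak == p_peak) stop("degenerate chord: T peak equals P peak")
  if (!(t_peak < p_peak && p_peak < qrs_onset))
    stop("need t_peak < p_peak < qrs_onset")
  amp <- abs(y[p_peak] - baseline)
  k1 <- chord_knee(y, t_peak, p_peak)
  onset <- k1
  t_end <- t_peak
  if (p_peak - k1 > 2L) {
    k2 <- chord_knee(y, k1, p_peak, tie = "later", tie_tol = 1e-3)
    seg_ms <- (k2 - k1) / fs * 1000
    seg_slope <- abs(y[k2] - y[k1]) / max(seg_ms, 1e-9)
    # accept the re-anchored knee when the first knee was a T-end-type
    # corner: either it precedes the plausible-onset window outright, or the
    # k1->k2 segment is flat relative to the P upstroke (slope comparison is
    # insensitive to the residual low-frequency trend)
    up_slope <- abs(y[p_peak] - y[k2]) / max((p_peak - k2) / fs * 1000, 1e-9)
    if (k1 < win_lo || (seg_ms >= 10 && seg_slope < 0.25 * up_slope)) {
      onset <- k2
      t_end <- k1
    }
  }
  onset <- refine_corner(y, onset, sign(y[p_peak] - baseline), fs)
  if (onset >= p_peak) onset <- p_peak - 1L
  guard <- as.integer(round(0.015 * fs))
  # late-PQ isoelectric level right before QRS onset; it shares any slow
  # baseline trend with the P-offset region
  pq_win <- max(p_peak + 1L, qrs_onset - guard - as.integer(round(0.008 * fs))):
    max(p_peak + 2L, qrs_onset - max(guard - 2L, 1L))
  pq_base <- stats::median(y[pq_win])
  # the offset chord is anchored at QRS onset *at the isoelectric level*:
  # the amplitude actually sampled there sits on the (filter-smoothed) QRS
  # foot, which would tilt the chord and drag the knee toward the QRS
  y2 <- y
  y2[qrs_onset] <- pq_base
  k1o <- chord_knee(y2, p_peak, qrs_onset, tie = "later", tie_tol = 3e-3,
                    exclude_end = min(guard, qrs_onset - p_peak - 2L))
  offset <- k1o
  is_trough <- y[k1o] < pq_base - max(0.25 * amp, 0.012) &&
    (qrs_onset - k1o) > as.integer(round(0.02 * fs))
  if (is_trough && qrs_onset - k1o > 3L) {
    offset <- chord_knee(y2, k1o, qrs_onset, tie = "later", tie_tol = 3e-3,
                         exclude_end = min(guard, qrs_onset - k1o - 2L))
  }
  list(onset = onset, offset = offset, t_end = t_end)
}

#' Locate the terminal negative phase of the V1 P wave
#'
#' Finds the contiguous sub-baseline run of the P wave after its positive
#' phase (the whole P wave when it is entirely negative). Returns `NULL`
#' when no sample between the P peak and the offset dips below the baseline
#' by at least 10 uV -- the absence of a negative phase is a valid outcome,
#' not an error.
#'
#' @param y numeric vector, the V1 template (mV).
#' @param p_peak,onset,offset sample indices from delineation.
#' @param baseline baseline level, either a scalar or a vector over
#'   `seq_along(y)` (a linear TP--PQ baseline).
#' @return `NULL`, or a list with indices `start`, `trough`, `end`.
#' @export
locate_v1_negative_phase <- function(y, p_peak, onset, offset,
                                     baseline = stats::median(y[onset:offset])) {
  b <- if (length(baseline) == 1L) rep(baseline, length(y)) else baseline
  if (y[p_peak] < b[p_peak]) {
    # entirely negative P wave: the negative phase is the whole wave
    tr <- onset + last_argmax(-(y[onset:offset] - b[onset:offset])) - 1L
    return(list(start = onset, trough = tr, end = offset))
  }
  ii <- (p_peak + 1L):offset
  if (length(ii) < 2L) return(NULL)
  below <- y[ii] < b[ii]
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  depth <- apply(runs, 1L, function(rg)
    max(b[ii[rg[1L]:rg[2L]]] - y[ii[rg[1L]:rg[2L]]]))
  best <- which.max(depth)
  if (depth[best] < 0.010) return(NULL)
  rg <- runs[best, ]
  seg <- ii[rg[1L]:rg[2L]]
  list(start = seg[1L],
       trough = seg[last_argmax(b[seg] - y[seg])],
       end = seg[length(seg)])
}

# Linear TP->PQ baseline: anchored on the median of a window before P onset
# and the median of the PQ gap after P offset; falls back to the left anchor
# alone when the PQ gap is too short.
linear_baseline <- function(y, fs, onset, offset, qrs_onset, t_end) {
  lw <- max(t_end, onset - as.integer(round(0.04 * fs))):max(t_end, onset - 2L)
  left <- stats::median(y[lw])
  lx <- stats::median(lw)
  rw_lo <- offset + 2L
  rw_hi <- qrs_onset - 2L
  if (rw_hi - rw_lo >= as.integer(round(0.008 * fs))) {
    right <- stats::median(y[rw_lo:rw_hi])
    rx <- stats::median(rw_lo:rw_hi)
    left + (right - left) * (seq_along(y) - lx) / (rx - lx)
  } else rep(left, length(y))
}

#' Delineate every lead of an averaged P-wave template
#'
#' Runs T-peak search, width-qualified P-peak detection, chord-rule
#' onset/offset location and (for V1) terminal-negative-phase detection on
#' each lead, then applies any annotation overrides. Leads where any stage
#' fails are flagged unmeasurable rather than aborting the record.
#'
#' @param template a [average_pwave()] result.
#' @param overrides optional annotation override: a data.frame with a `lead`
#'   column and any of `onset`, `peak`, `offset`, `trough` (sample indices;
#'   `NA` keeps the computed value). Overridden indices must satisfy
#'   `onset < peak < offset`; violations are an error. Valid overrides are
#'   honored verbatim downstream.
#' @param min_width_ms minimum P-lobe width at half-prominence, ms.
#' @return An object of class `pwave_delineation`: `fiducials` (data.frame,
#'   one row per lead: indices and ms of T peak, onset, peak, offset, the
#'   measurable flag), `v1_neg` (list or NULL), `baseline` (per-lead list of
#'   baseline vectors), plus `fs` and the template.
#' @export
delineate_template <- function(template, overrides = NULL, min_width_ms = 15) {
  stopifnot(inherits(template, "pwave_template"))
  fs <- template$fs
  Ln <- nrow(template$samples)
  qrs_onset <- template$qrs_onset_idx
  rr_ms <- template$rr_ms
  rows <- vector("list", 12L)
  baselines <- vector("list", 12L)
  v1_neg <- NULL
  for (k in seq_along(ECG_LEADS)) {
    ld <- ECG_LEADS[k]
    y <- template$samples[, ld]
    res <- try({
      tw <- 1L:max(3L, as.integer(round(0.35 * Ln)))
      t_peak <- tw[which.max(abs(y[tw] - stats::median(y)))]
      sw_lo <- t_peak + as.integer(round(0.12 * rr_ms / 1000 * fs))
      sw_hi <- qrs_onset - as.integer(round(0.010 * fs))
      if (sw_hi - sw_lo < 0.03 * fs) stop("search window too short")
      window <- sw_lo:sw_hi
      b0 <- stats::median(y[window])
      p_peak <- detect_p_peak(y, fs, window, baseline = b0,
                              min_width_ms = min_width_ms,
                              prefer_positive = (ld == "V1"))
      oo <- locate_onset_offset(y, fs, t_peak, p_peak, qrs_onset,
                                baseline = b0, win_lo = sw_lo)
      pwd_ms <- (oo$offset - oo$onset) / fs * 1000
      if (pwd_ms > 220 || pwd_ms < 30)
        stop(sprintf("implausible P-wave duration (%.0f ms)", pwd_ms))
      bl <- linear_baseline(y, fs, oo$onset, oo$offset, qrs_onset, oo$t_end)
      list(t_peak = t_peak, p_peak = p_peak, onset = oo$onset,
           offset = oo$offset, baseline = bl)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[k]] <- data.frame(lead = ld, t_peak = NA_integer_,
                              onset = NA_integer_, peak = NA_integer_,
                              offset = NA_integer_, measurable = FALSE)
      next
    }
    rows[[k]] <- data.frame(lead = ld, t_peak = res$t_peak, onset = res$onset,
                            peak = res$p_peak, offset = res$offset,
                            measurable = TRUE)
    baselines[[k]] <- res$baseline
  }
  fid <- do.call(rbind, rows)
  # annotation overrides replace computed indices after ordering checks
  if (!is.null(overrides)) {
    for (j in seq_len(nrow(overrides))) {
      ld <- overrides$lead[j]
      i <- match(ld, fid$lead)
      if (is.na(i)) stop("override references unknown lead: ", ld)
      for (fld in intersect(c("onset", "peak", "offset"), names(overrides))) {
        v <- overrides[[fld]][j]
        if (!is.na(v)) fid[[fld]][i] <- as.integer(v)
      }
      if (isTRUE(fid$measurable[i]) &&
          !(fid$onset[i] < fid$peak[i] && fid$peak[i] < fid$offset[i]))
        stop("override violates onset < peak < offset ordering for lead ", ld)
      if (any(c(fid$onset[i], fid$offset[i]) < 1L) ||
          any(c(fid$onset[i], fid$offset[i]) > Ln))
        stop("override index outside the template for lead ", ld)
    }
  }
  iv1 <- match("V1", fid$lead)
  if (isTRUE(fid$measurable[iv1])) {
    v1_neg <- locate_v1_negative_phase(
      template$samples[, "V1"], p_peak = fid$peak[iv1],
      onset = fid$onset[iv1], offset = fid$offset[iv1],
      baseline = baselines[[iv1]])
    if (!is.null(v1_neg) && !is.null(overrides) &&
        "trough" %in% names(overrides)) {
      j <- which(overrides$lead == "V1")
      if (length(j) && !is.na(overrides$trough[j])) {
        tr <- as.integer(overrides$trough[j])
        if (tr < v1_neg$start || tr > v1_neg$end)
          stop("trough override outside the negative phase")
        v1_neg$trough <- tr
      }
    }
  }
  fid$t_peak_ms <- (fid$t_peak - 1L) / fs * 1000
  fid$onset_ms <- (fid$onset - 1L) / fs * 1000
  fid$peak_ms <- (fid$peak - 1L) / fs * 1000
  fid$offset_ms <- (fid$offset - 1L) / fs * 1000
  structure(list(fiducials = fid, v1_neg = v1_neg, baseline = baselines,
                 fs = fs, template = template),
            class = "pwave_delineation")
}
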