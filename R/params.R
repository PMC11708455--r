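#' P-wave duration per lead and globally
#'
#' Per-lead PWD is `(offset - onset) / fs * 1000` ms. The global PWD is by
#' default the maximum over measurable leads (the convention consistent with
#' dispersion = max - min); the across-lead mean is selectable.
#'
#' @param delin a [delineate_template()] result, or a data.frame of
#'   fiducials with `onset`, `offset`, `measurable` columns.
#' @param fs sampling rate, Hz (taken from `delin` when available).
#' @param combine `"max"` (default) or `"mean"`.
#' @return A list with `per_lead` (named numeric, ms; NA where not
#'   measurable) and `global` (ms).
#' @export
compute_pwd <- function(delin, fs = NULL, combine = c("max", "mean")) {
  combine <- match.arg(combine)
  fid <- if (inherits(delin, "pwave_delineation")) delin$fiducials else delin
  if (is.null(fs)) fs <- delin$fs
  pwd <- ifelse(fid$measurable, (fid$offset - fid$onset) / fs * 1000, NA_real_)
  names(pwd) <- fid$lead
  ok <- !is.na(pwd)
  if (!any(ok)) stop("no measurable lead for PWD")
  g <- if (combine == "max") max(pwd[ok]) else mean(pwd[ok])
  list(per_lead = pwd, global = g)
}

#' P-wave voltage
#'
#' Per-lead voltage is the absolute distance from the isoelectric line
#' (the per-lead baseline estimated during delineation) to the P peak. The
#' reported PWV combines the 12 leads; the default is the sum, which
#' reproduces the conventional 12-lead combined magnitude (about 12 x a
#' single-lead P amplitude); `"max"` and `"mean"` are selectable.
#'
#' @param delin a [delineate_template()] result.
#' @param combine `"sum"` (default), `"max"` or `"mean"`.
#' @return A list with `per_lead` (named numeric, mV) and `value` (mV).
#' @export
compute_pwv <- function(delin, combine = c("sum", "max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(delin, "pwave_delineation"))
  fid <- delin$fiducials
  tplm <- delin$template$samples
  amp <- rep(NA_real_, 12L); names(amp) <- fid$lead
  for (i in seq_len(nrow(fid))) {
    if (!fid$measurable[i]) next
    bl <- delin$baseline[[i]]
    b <- if (is.null(bl)) stats::median(tplm[, i]) else bl[fid$peak[i]]
    amp[i] <- abs(tplm[fid$peak[i], i] - b)
  }
  ok <- !is.na(amp)
  if (!any(ok)) stop("no measurable lead for PWV")
  v <- switch(combine, sum = sum(amp[ok]), max = max(amp[ok]),
              mean = mean(amp[ok]))
  list(per_lead = amp, value = v)
}

#' P-wave dispersion
#'
#' The maximum difference between per-lead P-wave durations,
#' `max(PWD) - min(PWD)` in ms.
#'
#' @param pwd_per_lead named numeric vector of per-lead PWDs (ms), NA for
#'   unmeasurable leads (e.g. `compute_pwd(...)$per_lead`).
#' @return Dispersion in ms (>= 0).
#' @export
compute_pwdisp <- function(pwd_per_lead) {
  v <- pwd_per_lead[!is.na(pwd_per_lead)]
  if (length(v) < 2L) stop("PWDisp needs at least 2 measurable leads")
  max(v) - min(v)
}

#' P-wave terminal force in V1
#'
#' The product of the maximum absolute amplitude of the negative (terminal)
#' phase of the V1 P wave and its duration, reported as a non-positive
#' number. The default unit is mV.ms ("paper units": depth in mV times
#' duration in ms, matching the printed -3-ish magnitudes); `unit = "mm.s"`
#' applies the classical display conversion 10 mm/mV x 10^-3 s/ms.
#'
#' @param delin a [delineate_template()] result (its `v1_neg` element), or
#'   `NULL`/a list with `start`, `trough`, `end` indices.
#' @param unit `"paper"` (mV.ms) or `"mm.s"`.
#' @return PTFV1 (<= 0); 0 when there is no negative phase.
#' @export
compute_ptfv1 <- function(delin, unit = c("paper", "mm.s")) {
  unit <- match.arg(unit)
  if (inherits(delin, "pwave_delineation")) {
    neg <- delin$v1_neg
    if (is.null(neg)) return(0)
    iv1 <- match("V1", delin$fiducials$lead)
    y <- delin$template$samples[, "V1"]
    bl <- delin$baseline[[iv1]]
    depth <- bl[neg$trough] - y[neg$trough]
    dur_ms <- (neg$end - neg$start) / delin$fs * 1000
  } else {
    if (is.null(delin)) return(0)
    depth <- delin$depth_mv
    dur_ms <- delin$duration_ms
  }
  v <- -abs(depth) * dur_ms
  if (unit == "mm.s") v <- v * 10 * 1e-3
  v
}

#' Full P-wave parameter set for one recording
#'
#' Runs preprocessing, beat detection, 20-beat template averaging,
#' delineation and parameter computation on one [ecg_record()]. A record
#' must yield at least `min_leads` measurable leads (default 9) to emit
#' global parameters.
#'
#' @param record an [ecg_record()].
#' @param spec a [filter_spec()]; `NULL` skips filtering.
#' @param n_beats beats averaged per template.
#' @param overrides optional annotation override (see
#'   [delineate_template()]).
#' @param pwd_combine,pwv_combine lead-combination rules.
#' @param min_leads minimum measurable leads required.
#' @return An object of class `pwave_params`: `pwd_ms`, `pwv_mv`,
#'   `pwdisp_ms`, `ptfv1` (paper units), `pwd_per_lead`, `n_leads`,
#'   plus the `delineation` it was measured from.
#' @export
measure_record <- function(record, spec = filter_spec(), n_beats = 20L,
                           overrides = NULL, pwd_combine = "max",
                           pwv_combine = "sum", min_leads = 9L) {
  if (!is.null(spec)) record <- preprocess_record(record, spec)
  beats <- detect_beats(record, min_beats = n_beats + 1L)
  tpl <- average_pwave(record, beats, n_beats = n_beats)
  delin <- delineate_template(tpl, overrides = overrides)
  params_from_delineation(delin, pwd_combine = pwd_combine,
                          pwv_combine = pwv_combine, min_leads = min_leads)
}

#' Compute the parameter set from an existing delineation
#'
#' Used both by [measure_record()] and by re-measurement passes that modify
#' fiducials (annotation overrides, intraobserver jitter) without re-running
#' detection.
#'
#' @param delin a [delineate_template()] result.
#' @inheritParams measure_record
#' @return A `pwave_params` object.
#' @export
params_from_delineation <- function(delin, pwd_combine = "max",
                                    pwv_combine = "sum", min_leads = 9L) {
  stopifnot(inherits(delin, "pwave_delineation"))
  n_ok <- sum(delin$fiducials$measurable)
  if (n_ok < min_leads)
    stop(sprintf("only %d of 12 leads measurable (need >= %d)", n_ok, min_leads))
  pwd <- compute_pwd(delin, combine = pwd_combine)
  pwv <- compute_pwv(delin, combine = pwv_combine)
  structure(list(pwd_ms = pwd$global,
                 pwv_mv = pwv$value,
                 pwdisp_ms = compute_pwdisp(pwd$per_lead),
                 ptfv1 = compute_ptfv1(delin),
                 pwd_per_lead = pwd$per_lead,
                 pwv_per_lead = pwv$per_lead,
                 n_leads = n_ok,
                 delineation = delin),
            class = "pwave_params")
}

#' @export
print.pwave_params <- function(x, ...) {
  cat(sprintf(paste0("<pwave_params> PWD %.1f ms | PWV %.3f mV | ",
                     "PWDisp %.1f ms | PTFV1 %.2f mV.ms (%d leads)\n"),
              x$pwd_ms, x$pwv_mv, x$pwdisp_ms, x$ptfv1, x$n_leads))
  invisible(x)
}
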