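PARAM_NAMES <- c("pwd_ms", "pwv_mv", "pwdisp_ms", "ptfv1")

# Polynomial rolling hash (mod 2^31 - 1) over the serialized configuration;
# a stable short fingerprint for report provenance without external digest
# dependencies.
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full two-arm pre/post simulated study
#'
#' Generates the cohort, measures every patient's pre- and post-ablation
#' recording end-to-end (filter, beat detection, 20-beat P-wave averaging,
#' delineation, parameter computation), and assembles the study report:
#' per-arm/phase mean +- SEM for PWD, PWV, PWDisp and PTFV1, within-arm
#' paired comparisons, and between-arm comparisons of the per-patient
#' pre-to-post changes. Patients failing quality guards in either phase are
#' excluded and counted.
#'
#' @param config a [cohort_config()] or the path of a config text file.
#' @param seed integer; overrides the config seed (all randomness derives
#'   from it).
#' @param out_dir optional output directory: writes `measurements.csv`,
#'   `summary.csv`, `comparisons.csv` and `report.txt`.
#' @param n_beats beats averaged per template (default 20).
#' @param progress emit per-record progress messages to stderr.
#' @return An object of class `study_report`: `measurements` (data.frame),
#'   `summary` (data.frame), `within` and `between` (named lists of
#'   `pwave_comparison`), `n_excluded`, `meta`.
#' @export
run_study <- function(config, seed = NULL, out_dir = NULL, n_beats = 20L,
                      progress = FALSE) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  rows <- list()
  n_excluded <- 0L
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    meas <- list()
    for (ph in c("pre", "post")) {
      res <- tryCatch(
        measure_record(patient_record(cohort, i, ph), n_beats = n_beats),
        error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("excluding %s (%s %s): %s", p$id, p$arm, ph,
                        conditionMessage(res)))
        meas <- NULL
        break
      }
      meas[[ph]] <- res
    }
    if (is.null(meas)) {
      n_excluded <- n_excluded + 1L
      next
    }
    if (progress) message(sprintf("measured %s (%s)", p$id, p$arm))
    for (ph in c("pre", "post"))
      rows[[length(rows) + 1L]] <- data.frame(
        id = p$id, arm = p$arm, phase = ph,
        pwd_ms = meas[[ph]]$pwd_ms, pwv_mv = meas[[ph]]$pwv_mv,
        pwdisp_ms = meas[[ph]]$pwdisp_ms, ptfv1 = meas[[ph]]$ptfv1,
        n_leads = meas[[ph]]$n_leads)
  }
  if (!length(rows)) stop("no patient could be measured")
  meas_df <- do.call(rbind, rows)
  report <- build_study_report(meas_df, config, n_excluded)
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Assemble a study report from a measurement table
#'
#' @param meas_df data.frame with columns `id`, `arm`, `phase` and the four
#'   parameters (as written by [run_study()] to `measurements.csv`).
#' @param config the generating [cohort_config()] (optional, metadata only).
#' @param n_excluded excluded-patient count (metadata).
#' @return A `study_report`.
#' @export
build_study_report <- function(meas_df, config = NULL, n_excluded = 0L) {
  summ <- do.call(rbind, lapply(split(
    meas_df, list(meas_df$arm, meas_df$phase), sep = "."), function(g) {
      out <- data.frame(arm = g$arm[1L], phase = g$phase[1L], n = nrow(g))
      for (pn in PARAM_NAMES) {
        out[[paste0(pn, "_mean")]] <- mean(g[[pn]])
        out[[paste0(pn, "_sem")]] <- sem(g[[pn]])
      }
      out
    }))
  rownames(summ) <- NULL
  within <- list()
  deltas <- list()
  for (arm in unique(meas_df$arm)) {
    sub <- meas_df[meas_df$arm == arm, ]
    pre <- sub[sub$phase == "pre", ]
    post <- sub[sub$phase == "post", ]
    post <- post[match(pre$id, post$id), ]
    within[[arm]] <- list()
    deltas[[arm]] <- list()
    for (pn in PARAM_NAMES) {
      within[[arm]][[pn]] <- paired_compare(pre[[pn]], post[[pn]])
      deltas[[arm]][[pn]] <- post[[pn]] - pre[[pn]]
    }
  }
  between <- NULL
  if (all(c("success", "fail") %in% names(deltas))) {
    between <- list()
    for (pn in PARAM_NAMES)
      between[[pn]] <- unpaired_compare(deltas$success[[pn]],
                                        deltas$fail[[pn]])
  }
  meta <- list(
    n_success = sum(meas_df$arm == "success" & meas_df$phase == "pre"),
    n_fail = sum(meas_df$arm == "fail" & meas_df$phase == "pre"),
    n_excluded = n_excluded,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config_hash = if (!is.null(config)) config_hash(config) else NA_character_)
  structure(list(measurements = meas_df, summary = summ, within = within,
                 between = between, n_excluded = n_excluded, meta = meta),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n = %d (success %d / fail %d), %d excluded\n",
              x$meta$n_success + x$meta$n_fail, x$meta$n_success,
              x$meta$n_fail, x$n_excluded))
  for (ln in report_lines(x)) cat(ln, "\n")
  invisible(x)
}

param_label <- function(pn) {
  c(pwd_ms = "PWD (ms)", pwv_mv = "PWV (mV)", pwdisp_ms = "PWDisp (ms)",
    ptfv1 = "PTFV1 (mV.ms)")[[pn]]
}

report_lines <- function(report) {
  s <- report$summary
  lines <- character(0)
  for (pn in PARAM_NAMES) {
    for (arm in names(report$within)) {
      pre <- s[s$arm == arm & s$phase == "pre", ]
      post <- s[s$arm == arm & s$phase == "post", ]
      w <- report$within[[arm]][[pn]]
      lines <- c(lines, sprintf(
        "%s, %s arm: %.1f +- %.1f to %.1f +- %.1f (%s, p = %.3g)",
        param_label(pn), arm,
        pre[[paste0(pn, "_mean")]], pre[[paste0(pn, "_sem")]],
        post[[paste0(pn, "_mean")]], post[[paste0(pn, "_sem")]],
        w$test, w$p_value))
    }
    if (!is.null(report$between)) {
      b <- report$between[[pn]]
      lines <- c(lines, sprintf(
        "%s, between-arm change: %.2f vs %.2f (%s, p = %.3g)",
        param_label(pn), b$means[[1L]], b$means[[2L]], b$test, b$p_value))
    }
  }
  lines
}

#' Persist a study report as CSV + text
#'
#' @param report a `study_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measurements,
                   file.path(out_dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  comp <- list()
  for (arm in names(report$within)) for (pn in PARAM_NAMES) {
    w <- report$within[[arm]][[pn]]
    comp[[length(comp) + 1L]] <- data.frame(
      comparison = paste0("within-", arm), parameter = pn, test = w$test,
      statistic = w$statistic, p_value = w$p_value, mean_diff = w$mean_diff)
  }
  if (!is.null(report$between)) for (pn in PARAM_NAMES) {
    b <- report$between[[pn]]
    comp[[length(comp) + 1L]] <- data.frame(
      comparison = "between-arm", parameter = pn, test = b$test,
      statistic = b$statistic, p_value = b$p_value, mean_diff = b$mean_diff)
  }
  utils::write.csv(do.call(rbind, comp), file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("n = %d (success %d, fail %d), excluded %d, seed %s, config %s",
                       report$meta$n_success + report$meta$n_fail,
                       report$meta$n_success, report$meta$n_fail,
                       report$n_excluded, report$meta$seed,
                       report$meta$config_hash),
               report_lines(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# Apply seeded annotation jitter to a delineation (emulating a human
# re-measurement pass): onset/offset (and the V1 trough) move by rounded
# N(0, jitter_ms) samples, clamped so ordering invariants keep holding.
jitter_delineation <- function(delin, jitter_ms) {
  fid <- delin$fiducials
  fs <- delin$fs
  Ln <- nrow(delin$template$samples)
  j <- function(n) as.integer(round(stats::rnorm(n, sd = jitter_ms) / 1000 * fs))
  for (i in seq_len(nrow(fid))) {
    if (!fid$measurable[i]) next
    fid$onset[i] <- min(max(fid$onset[i] + j(1L), 1L), fid$peak[i] - 1L)
    fid$offset[i] <- max(min(fid$offset[i] + j(1L), Ln), fid$peak[i] + 1L)
  }
  delin$fiducials <- fid
  if (!is.null(delin$v1_neg)) {
    iv1 <- match("V1", fid$lead)
    neg <- delin$v1_neg
    neg$start <- min(max(neg$start + j(1L), 1L), neg$trough - 1L)
    neg$end <- max(min(neg$end + j(1L), fid$offset[iv1]), neg$trough + 1L)
    neg$trough <- min(max(neg$trough + j(1L), neg$start), neg$end)
    delin$v1_neg <- neg
  }
  delin
}

#' Intraobserver variability study on synthetic recordings
#'
#' Generates `n_ecgs` recordings (drawn from the success-arm pre-ablation
#' population of `config`), delineates each once, then re-measures with
#' seeded annotation jitter emulating a human's second pass on a later day,
#' and reports per-parameter variability. The report header counts the
#' number of P waves analysed: `n_ecgs x 12 leads x n_beats`.
#'
#' @param config a [cohort_config()] or config file path.
#' @param n_ecgs number of recordings (default 22).
#' @param jitter_ms SD of the annotation jitter in ms (0 = identical runs).
#' @param seed integer seed.
#' @param n_beats beats averaged per template.
#' @return A list of class `intraobserver_report`: `variability` (named list
#'   of `variability_result` per parameter), `n_pwaves`, `n_ecgs`,
#'   `runs` (the two measurement data.frames).
#' @export
run_intraobserver <- function(config, n_ecgs = 22L, jitter_ms = 2,
                              seed = 1L, n_beats = 20L) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  cfg <- cohort_config(n_success = n_ecgs, n_fail = 1L, arms = config$arms,
                       fs = config$fs, duration_s = config$duration_s,
                       noise = config$noise, seed = as.integer(seed),
                       min_beats = config$min_beats)
  cohort <- generate_cohort(cfg)
  run1 <- run2 <- list()
  with_seed(seed + 1L, {
    for (i in seq_len(n_ecgs)) {
      rec <- preprocess_record(patient_record(cohort, i, "pre"))
      beats <- detect_beats(rec, min_beats = n_beats + 1L)
      tpl <- average_pwave(rec, beats, n_beats = n_beats)
      delin <- delineate_template(tpl)
      p1 <- params_from_delineation(delin)
      p2 <- params_from_delineation(
        if (jitter_ms > 0) jitter_delineation(delin, jitter_ms) else delin)
      run1[[i]] <- data.frame(pwd_ms = p1$pwd_ms, pwv_mv = p1$pwv_mv,
                              pwdisp_ms = p1$pwdisp_ms, ptfv1 = p1$ptfv1)
      run2[[i]] <- data.frame(pwd_ms = p2$pwd_ms, pwv_mv = p2$pwv_mv,
                              pwdisp_ms = p2$pwdisp_ms, ptfv1 = p2$ptfv1)
    }
  })
  r1 <- do.call(rbind, run1)
  r2 <- do.call(rbind, run2)
  variability <- lapply(stats::setNames(PARAM_NAMES, PARAM_NAMES), function(pn)
    intraobserver_variability(r1[[pn]], r2[[pn]]))
  structure(list(variability = variability,
                 n_pwaves = n_ecgs * 12L * n_beats,
                 n_ecgs = n_ecgs, n_beats = n_beats,
                 runs = list(r1, r2)),
            class = "intraobserver_report")
}

#' @export
print.intraobserver_report <- function(x, ...) {
  cat(sprintf("<intraobserver_report> %d ECGs, %d P-waves analysed twice\n",
              x$n_ecgs, x$n_pwaves))
  for (pn in names(x$variability)) {
    v <- x$variability[[pn]]
    cat(sprintf("  %-13s %.3g +- %.2g (%.1f%%)\n", param_label(pn),
                v$mean_abs_diff, v$sem, v$percent))
  }
  invisible(x)
}
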