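# Flat "key: value" text dialect for cohort configurations. Keys are dotted
# paths: top-level scalars (n_success, fs, ...), noise.<field>, and
# <arm>.<phase>.<population field>.

POP_FIELDS <- c("pwd_mean", "pwd_sd", "pwdisp_mean", "pwv_mean", "pwv_sd",
                "ptf_mean", "ptf_sd", "ptf_width_ms", "width_jitter_sd",
                "hr_mean", "hr_sd")
NOISE_FIELDS <- c("white_sd_uv", "wander_amp_uv", "wander_hz",
                  "mains_amp_uv", "mains_hz")

#' Write a cohort configuration as a flat key/value text file
#'
#' @param cfg a [cohort_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  lines <- c(
    sprintf("n_success: %d", cfg$n_success),
    sprintf("n_fail: %d", cfg$n_fail),
    sprintf("fs: %g", cfg$fs),
    sprintf("duration_s: %g", cfg$duration_s),
    sprintf("seed: %d", cfg$seed),
    sprintf("min_beats: %d", cfg$min_beats),
    vapply(NOISE_FIELDS, function(f)
      sprintf("noise.%s: %g", f, cfg$noise[[f]]), character(1L)))
  for (arm in c("success", "fail")) for (ph in c("pre", "post"))
    lines <- c(lines, vapply(POP_FIELDS, function(f)
      sprintf("%s.%s.%s: %g", arm, ph, f, cfg$arms[[arm]][[ph]][[f]]),
      character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort configuration from a flat key/value text file
#'
#' @param path path to a file written by [write_cohort_config()] (or edited
#'   by hand; `#` comments and blank lines are ignored).
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- regmatches(ln, regexec("^\\s*([A-Za-z0-9._]+)\\s*:\\s*(\\S+)\\s*$", ln))
  bad <- vapply(kv, length, integer(1L)) != 3L
  if (any(bad)) stop("unparsable config line(s): ",
                     paste(ln[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- as.numeric(vapply(kv, `[`, character(1L), 3L))
  if (anyNA(vals)) stop("non-numeric config value")
  val <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("missing config key: ", k)
      default
    } else vals[i]
  }
  noise_args <- lapply(NOISE_FIELDS, function(f)
    val(paste0("noise.", f), formals(noise_config)[[f]]))
  names(noise_args) <- NOISE_FIELDS
  arms <- list()
  for (arm in c("success", "fail")) {
    arms[[arm]] <- list()
    for (ph in c("pre", "post")) {
      pa <- lapply(POP_FIELDS, function(f) val(paste(arm, ph, f, sep = ".")))
      names(pa) <- POP_FIELDS
      arms[[arm]][[ph]] <- do.call(population_spec, pa)
    }
  }
  cohort_config(n_success = as.integer(val("n_success")),
                n_fail = as.integer(val("n_fail")),
                arms = arms, fs = val("fs", 1000),
                duration_s = val("duration_s", 60),
                noise = do.call(noise_config, noise_args),
                seed = as.integer(val("seed", 1)),
                min_beats = as.integer(val("min_beats", 21)))
}

#' The packaged calibration configuration
#'
#' The cohort configuration whose population analytic means reproduce the
#' reference repeat-ablation study arms: success arm (n = 43) PWD
#' 136.7 -> 123.5 ms and PTFV1 -3.1 -> -4.4 mV.ms, failed arm (n = 29) PWD
#' 135.4 -> 125.3 ms and PTFV1 -2.9 -> -2.7 mV.ms, with PWV about
#' 1.2--1.3 mV and PWDisp about 28--30 ms in both arms. Between-patient SDs
#' are solved from the corresponding paired-test significance levels (see
#' the methods vignette). Shipped as a plain-text fixture in
#' `inst/extdata/calibration_cohort.txt`.
#'
#' @param ... overrides passed to [cohort_config()] (e.g. `fs`,
#'   `duration_s`, `seed`).
#' @return A [cohort_config()].
#' @export
calibration_config <- function(...) {
  path <- system.file("extdata", "calibration_cohort.txt",
                      package = "pwavekit", mustWork = TRUE)
  cfg <- read_cohort_config(path)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  do.call(cohort_config, cfg[c("n_success", "n_fail", "arms", "fs",
                               "duration_s", "noise", "seed", "min_beats")])
}
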