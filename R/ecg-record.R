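#' Standard 12-lead names, in conventional order
#'
#' Limb leads I, II, III, augmented leads aVR, aVL, aVF, then the precordial
#' leads V1--V6. Every [ecg_record()] carries its sample matrix in this order.
#'
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

# Acquisition contract: +-5 mV dynamic range digitised at 16 bit, so one
# quantization step is 10 mV / 2^16.
ECG_RANGE_MV <- 5
ECG_QUANT_STEP <- (2 * ECG_RANGE_MV) / 2^16

#' 12-lead ECG recording
#'
#' Container for a multichannel ECG: a numeric sample matrix in millivolts
#' with one column per lead, the sampling rate, and a display-gain note.
#' The acquisition contract is enforced at construction: exactly 12 leads,
#' equal-length non-empty series, and every sample within the +-5 mV
#' digitiser range.
#'
#' @param samples numeric matrix, one column per lead, values in mV.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param leads character vector of lead names; defaults to the column names
#'   of `samples` or [ECG_LEADS]. Columns are reordered to standard order.
#' @param gain display gain in mm/mV (metadata only), default 10.
#'
#' @return An object of class `ecg_record`: a list with elements `samples`
#'   (matrix, columns named by lead), `fs`, and `gain`.
#' @export
ecg_record <- function(samples, fs, leads = NULL, gain = 10) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (one column per lead)")
  if (is.null(leads)) leads <- colnames(samples)
  if (is.null(leads) && ncol(samples) == 12L) leads <- ECG_LEADS
  if (length(leads) != ncol(samples))
    stop("lead names do not match the number of sample columns")
  if (ncol(samples) != 12L)
    stop(sprintf("expected 12 leads, got %d", ncol(samples)))
  unknown <- setdiff(leads, ECG_LEADS)
  if (length(unknown))
    stop("unknown lead name(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(leads)) stop("duplicated lead names")
  if (nrow(samples) < 1L) stop("record has zero-length series")
  if (anyNA(samples)) stop("record contains missing samples")
  rng <- range(samples)
  if (rng[1] < -ECG_RANGE_MV || rng[2] > ECG_RANGE_MV)
    stop(sprintf(paste0("sample outside the +-%g mV acquisition range ",
                        "(observed %.4g mV): clipped or range-violating ",
                        "acquisition"),
                 ECG_RANGE_MV, rng[which.max(abs(rng))]))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("missing or invalid sampling rate")
  colnames(samples) <- leads
  samples <- samples[, ECG_LEADS, drop = FALSE]
  structure(list(samples = samples, fs = as.numeric(fs),
                 gain = as.numeric(gain)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> 12 leads x %d samples @ %g Hz (%.1f s), gain %g mm/mV\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs, x$gain))
  invisible(x)
}

#' Number of samples in a record
#' @param record an [ecg_record()].
#' @return integer sample count per lead.
#' @export
n_samples <- function(record) nrow(record$samples)

#' Read a 12-lead ECG recording from a text file
#'
#' The repository dialect is two header lines `fs=<Hz>` and
#' `leads=<comma-separated names>`, followed by a tab-delimited numeric body
#' (one row per sample, values in mV). A permissive CSV fallback accepts a
#' delimited file whose first row is the 12 lead names, with the sampling
#' rate supplied via `fs`.
#'
#' @param path path to the file.
#' @param fs sampling rate in Hz; only used (and then required) when the file
#'   carries no `fs=` header.
#' @return An [ecg_record()].
#' @export
read_ecg_record <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 2L)
  skip <- 0L
  leads <- NULL
  for (ln in head_lines) {
    if (grepl("^fs=", ln)) {
      fs <- as.numeric(sub("^fs=", "", ln)); skip <- skip + 1L
    } else if (grepl("^leads=", ln)) {
      leads <- trimws(strsplit(sub("^leads=", "", ln), ",")[[1]])
      skip <- skip + 1L
    }
  }
  if (is.null(fs) || is.na(fs))
    stop("missing sampling rate: no fs= header and no `fs` argument")
  dt <- withCallingHandlers(
    data.table::fread(path, skip = skip, header = (skip == 0L),
                      sep = "auto", fill = FALSE, data.table = FALSE),
    warning = function(w) stop("ragged or malformed sample rows in ", path,
                               ": ", conditionMessage(w)))
  if (skip == 0L) leads <- names(dt)
  if (!all(vapply(dt, is.numeric, logical(1L))))
    stop("non-numeric or ragged sample rows in ", path)
  m <- as.matrix(dt)
  ecg_record(m, fs = fs, leads = leads)
}

#' Write a 12-lead ECG recording to a text file
#'
#' Writes the repository dialect (see [read_ecg_record()]). Samples are
#' quantized to the 16-bit grid over the 10 mV range before writing, so a
#' read-back record equals the original within one quantization step
#' (10 mV / 2^16, about 0.15 uV).
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  if (nrow(record$samples) < 1L) stop("empty record")
  q <- round(record$samples / ECG_QUANT_STEP) * ECG_QUANT_STEP
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fs=%g", record$fs),
               paste0("leads=", paste(colnames(record$samples), collapse = ","))),
             con)
  close(con); on.exit(NULL)
  data.table::fwrite(data.table::as.data.table(q), path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}
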