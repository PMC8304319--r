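#' Read an SpO2 trace from CSV
#'
#' Expects columns `time_s`, `spo2` and optionally `valid` (0/1 or
#' logical). Rows violating the schema (non-numeric, SpO2 outside
#' \[0, 100\], non-increasing time) are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return an [spo2_trace()].
#' @export
read_spo2_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "spo2")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$spo2) |
                 df$spo2 < 0 | df$spo2 > 100)
  if (length(bad)) {
    stop("invalid spo2/time values at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono)) {
    stop("time_s not strictly increasing at data row(s): ",
         paste(utils::head(nonmono + 1, 5), collapse = ", "), call. = FALSE)
  }
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
  spo2_trace(df$time_s, df$spo2, valid)
}

#' Write an SpO2 trace to CSV
#'
#' @param trace an [spo2_trace()].
#' @param path output path.
#' @export
write_spo2_csv <- function(trace, path) {
  stopifnot(inherits(trace, "spo2_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, spo2 = trace$spo2,
               valid = as.integer(trace$valid)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a PCM-16 mono WAV file
#'
#' Minimal RIFF/WAVE reader for the recordings this analysis consumes:
#' uncompressed PCM, 16-bit, single channel. Samples are normalized to
#' \[-1, 1\] by 32768.
#'
#' @param path WAV file path.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  sample_hz <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      sample_hz <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (fmt != 1) stop("only uncompressed PCM WAV is supported", call. = FALSE)
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2, 2, endian = "little", signed = TRUE)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(data) && !is.null(sample_hz)) break
  }
  if (is.null(data) || is.null(sample_hz)) stop("malformed WAV file", call. = FALSE)
  if (n_channels != 1) {
    stop("stereo input not supported: recordings must be mono", call. = FALSE)
  }
  if (bits != 16) stop("only 16-bit PCM is supported", call. = FALSE)
  audio_signal(data / 32768, sample_hz)
}

#' Write an audio signal as PCM-16 mono WAV
#'
#' Samples are clipped to \[-1, 1\] and quantized by 32767.
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  pcm <- as.integer(round(pmin(1, pmax(-1, signal$samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                       # PCM
  writeBin(1L, con, size = 2, endian = "little")                       # mono
  writeBin(as.integer(signal$sample_hz), con, size = 4, endian = "little")
  writeBin(as.integer(signal$sample_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                       # block align
  writeBin(16L, con, size = 2, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a per-patient feature table from CSV
#'
#' @param path CSV with at least `patient_id` and `severe` columns.
#' @return a tibble.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "severe")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  df$severe <- as.logical(df$severe)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("female", "male"))
  tibble::as_tibble(df)
}

#' Write a per-patient feature table to CSV
#'
#' @param cohort tibble of patient records.
#' @param path output path.
#' @export
write_features_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  if ("severe" %in% names(df)) df$severe <- as.integer(df$severe)
  if ("sex" %in% names(df)) df$sex <- as.character(df$sex)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics/report object as JSON
#'
#' @param x a list (e.g. a pipeline report).
#' @param path output path.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
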