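#' SpO2 trace container
#'
#' A timestamped pulse-oximetry trace with per-sample validity flags. Home
#' oximeters in pediatric sleep studies record SpO2 at a nominal 0.5 Hz
#' (some report 1 Hz); both rates are accepted and up to 10% timestamp
#' jitter is tolerated.
#'
#' @param times sample times in seconds, strictly increasing.
#' @param spo2 saturation in percent; must lie in \[0, 100\] where valid.
#' @param valid logical validity flags (default all `TRUE`).
#' @param sample_hz nominal sampling rate; inferred from `times` if `NULL`.
#' @return an object of class `spo2_trace`.
#' @export
spo2_trace <- function(times, spo2, valid = NULL, sample_hz = NULL) {
  if (length(times) == 0) stop("empty trace", call. = FALSE)
  if (length(times) != length(spo2)) {
    stop("times and spo2 must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  valid <- valid %||% rep(TRUE, length(times))
  if (length(valid) != length(times)) {
    stop("valid flags must match trace length", call. = FALSE)
  }
  if (any(spo2[valid] < 0 | spo2[valid] > 100)) {
    stop("spo2 outside [0, 100] on valid samples", call. = FALSE)
  }
  if (is.null(sample_hz)) {
    sample_hz <- 1 / stats::median(diff(times))
    # snap to the two rates seen in practice when within jitter tolerance
    for (hz in c(0.5, 1)) if (abs(sample_hz - hz) / hz < 0.1) sample_hz <- hz
  }
  structure(
    list(times = as.numeric(times), spo2 = as.numeric(spo2),
         valid = as.logical(valid), sample_hz = sample_hz),
    class = "spo2_trace"
  )
}

#' @export
print.spo2_trace <- function(x, ...) {
  cat(sprintf(
    "<spo2_trace> %d samples @ %.2g Hz, %.1f min, %.1f%% valid\n",
    length(x$times), x$sample_hz,
    (x$times[length(x$times)] - x$times[1]) / 60,
    100 * mean(x$valid)
  ))
  invisible(x)
}

#' Flag motion artifacts and dropouts in an SpO2 trace
#'
#' Marks as invalid any sample that is 0 (sensor dropout), below 50%
#' (non-physiological), or whose change from the previous valid sample
#' exceeds 4 percentage points per sampling step (motion artifact).
#' Existing invalid flags are preserved. True desaturations descend at
#' most ~2 points per sampling interval at these rates, so the jump rule
#' does not clip real events.
#'
#' @param trace an [spo2_trace()].
#' @return the trace with updated `valid` flags.
#' @export
clean_trace <- function(trace) {
  stopifnot(inherits(trace, "spo2_trace"))
  n <- length(trace$spo2)
  valid <- trace$valid
  valid[trace$spo2 == 0 | trace$spo2 < 50] <- FALSE
  step_s <- 1 / trace$sample_hz
  last_i <- NA_integer_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(last_i)) {
      steps <- max(1, (trace$times[i] - trace$times[last_i]) / step_s)
      if (abs(trace$spo2[i] - trace$spo2[last_i]) / steps > 4) {
        valid[i] <- FALSE
        next
      }
    }
    last_i <- i
  }
  trace$valid <- valid
  trace
}

#' Select the analysis window after the first snore
#'
#' Home oximetry is analyzed over a consecutive 90-minute window starting
#' at the first snoring signal, which covers at least one sleep cycle and
#' the part of the night a caregiver can supervise. The window is taken on
#' wall-clock time and clipped to the end of the trace; validity flags are
#' carried over.
#'
#' @param trace an [spo2_trace()].
#' @param first_snore_s time of the first snore, seconds from trace start.
#' @param window_min window length in minutes (default 90).
#' @return the sub-trace covering `[first_snore_s, first_snore_s + window)`.
#' @export
select_window <- function(trace, first_snore_s, window_min = 90) {
  stopifnot(inherits(trace, "spo2_trace"))
  t_end <- trace$times[length(trace$times)]
  if (first_snore_s > t_end) {
    stop("first_snore_s lies after the end of the trace", call. = FALSE)
  }
  keep <- trace$times >= first_snore_s &
    trace$times < first_snore_s + window_min * 60
  if (!any(keep)) stop("empty analysis window", call. = FALSE)
  spo2_trace(trace$times[keep], trace$spo2[keep], trace$valid[keep],
             sample_hz = trace$sample_hz)
}

#' Compute the 3% oxygen desaturation index (ODI3)
#'
#' A desaturation event is a maximal episode in which SpO2 falls at least
#' `min_drop` percentage points below the running baseline - the maximum
#' valid SpO2 over the preceding 30 s - lasts at least `min_duration_s`,
#' and ends when SpO2 recovers to within 1 point of the baseline frozen at
#' event onset. ODI3 is the event count per hour of *valid* recording
#' (artifact samples are excluded from the denominator). Quality control
#' fails when fewer than 75 valid minutes remain.
#'
#' @param trace a cleaned, windowed [spo2_trace()].
#' @param min_drop event depth threshold in percentage points (default 3).
#' @param min_duration_s minimum episode duration in seconds (default 4).
#' @param qc_min_valid_minutes QC threshold in minutes (default 75).
#' @return an `odi_result` list: `odi3` (events/h, `NA` if no valid data),
#'   `n_events`, `valid_minutes`, `window_start_s`, `window_end_s`,
#'   `qc_pass`, and `events` (tibble of detected episodes).
#' @export
compute_odi3 <- function(trace, min_drop = 3, min_duration_s = 4,
                         qc_min_valid_minutes = 75) {
  stopifnot(inherits(trace, "spo2_trace"))
  times <- trace$times[trace$valid]
  spo2 <- trace$spo2[trace$valid]
  valid_minutes <- length(times) / trace$sample_hz / 60
  res <- list(
    odi3 = NA_real_, n_events = 0L, valid_minutes = valid_minutes,
    window_start_s = trace$times[1],
    window_end_s = trace$times[length(trace$times)],
    qc_pass = valid_minutes >= qc_min_valid_minutes,
    events = tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                            nadir = numeric(0))
  )
  class(res) <- "odi_result"
  if (length(times) == 0) {
    res$qc_pass <- FALSE
    return(res)
  }

  n <- length(times)
  ev_start <- numeric(0); ev_end <- numeric(0); ev_nadir <- numeric(0)
  in_event <- FALSE
  ref <- NA_real_
  start_t <- NA_real_
  nadir <- NA_real_
  j0 <- 1L  # left edge of the trailing 30-s baseline window
  for (i in seq_len(n)) {
    while (times[j0] < times[i] - 30) j0 <- j0 + 1L
    base_idx <- j0:i
    base_idx <- base_idx[base_idx < i]
    baseline <- if (length(base_idx)) max(spo2[base_idx]) else spo2[i]
    if (!in_event) {
      if (spo2[i] <= baseline - min_drop) {
        in_event <- TRUE
        ref <- baseline
        start_t <- times[i]
        nadir <- spo2[i]
      }
    } else {
      nadir <- min(nadir, spo2[i])
      if (spo2[i] >= ref - 1) {
        if (times[i] - start_t >= min_duration_s) {
          ev_start <- c(ev_start, start_t)
          ev_end <- c(ev_end, times[i])
          ev_nadir <- c(ev_nadir, nadir)
        }
        in_event <- FALSE
      }
    }
  }
  if (in_event && times[n] - start_t >= min_duration_s) {
    ev_start <- c(ev_start, start_t)
    ev_end <- c(ev_end, times[n])
    ev_nadir <- c(ev_nadir, nadir)
  }

  res$n_events <- length(ev_start)
  res$events <- tibble::tibble(start_s = ev_start, end_s = ev_end,
                               nadir = ev_nadir)
  res$odi3 <- if (valid_minutes > 0) res$n_events / (valid_minutes / 60) else NA_real_
  res
}

#' @export
print.odi_result <- function(x, ...) {
  cat(sprintf(
    "<odi_result> ODI3 = %s events/h (%d events / %.1f valid min), QC %s\n",
    ifelse(is.na(x$odi3), "NA", sprintf("%.2f", x$odi3)),
    x$n_events, x$valid_minutes, ifelse(x$qc_pass, "pass", "FAIL")
  ))
  invisible(x)
}
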