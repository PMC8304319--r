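#' Oximetry trace simulation specification
#'
#' Describes a planted-event SpO2 trace: a flat baseline with square
#' desaturation dips (1-sample entry/exit ramps at half depth) and an
#' optional fraction of artifact-corrupted samples (dropouts to 0 or
#' downward spikes > 4 points). Desaturations of depth >= 3 points are the
#' events the ODI3 detector must count.
#'
#' @param duration_min trace length in minutes.
#' @param sample_hz sampling rate in Hz (0.5 nominal; 1 Hz also accepted).
#' @param baseline_spo2 baseline saturation in percent.
#' @param event_rate_per_h planted desaturation events per hour.
#' @param event_depth dip depth in percentage points (>= 3 for countable
#'   events).
#' @param event_duration_s dip duration in seconds.
#' @param artifact_frac fraction of samples corrupted, in \[0, 1).
#' @param first_snore_offset_min minutes from recording start to the first
#'   snore (events are planted after this offset).
#' @param seed integer seed.
#' @export
trace_sim_spec <- function(duration_min = 100,
                           sample_hz = 0.5,
                           baseline_spo2 = 98,
                           event_rate_per_h = 6,
                           event_depth = 3.5,
                           event_duration_s = 20,
                           artifact_frac = 0,
                           first_snore_offset_min = 10,
                           seed = 1) {
  if (artifact_frac < 0 || artifact_frac >= 1) {
    stop("artifact_frac must be in [0, 1)", call. = FALSE)
  }
  if (duration_min <= 0 || sample_hz <= 0) {
    stop("duration_min and sample_hz must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "trace_sim_spec")
}

#' Simulate an SpO2 trace with planted desaturation events
#'
#' Events are placed on the sampling grid after `first_snore_offset_min`
#' (plus a 60-s lead so the running-baseline detector has history), with at
#' least 30 s separation between consecutive events so they cannot merge.
#' Each event is a square dip of `event_depth` points with one ramp sample
#' at half depth on each side. Afterwards `artifact_frac` of the non-event
#' samples are corrupted (half set to 0, half spiked downward by 8-20
#' points), isolated from each other and from events. Deterministic given
#' the spec's seed.
#'
#' @param spec a [trace_sim_spec()].
#' @return an [spo2_trace()] with attributes `ground_truth` (tibble of
#'   planted event intervals) and `artifact_idx` (corrupted sample indices).
#' @export
simulate_spo2_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  set.seed(as.integer(spec$seed))
  hz <- spec$sample_hz
  n <- round(spec$duration_min * 60 * hz)
  times <- (seq_len(n) - 1) / hz
  spo2 <- rep(spec$baseline_spo2, n)

  dur_smp <- max(1L, round(spec$event_duration_s * hz))
  t0 <- spec$first_snore_offset_min * 60 + 60
  t1 <- spec$duration_min * 60 - spec$event_duration_s - 2 / hz
  # rate is relative to the plantable span (after the first snore plus a
  # 60-s lead for the running baseline), so a windowed analysis of that
  # span measures the requested rate back
  n_events <- round(spec$event_rate_per_h * max(0, t1 - t0) / 3600)
  gt <- NULL
  if (n_events > 0) {
    min_gap_s <- 30 + spec$event_duration_s
    span <- t1 - t0
    if (span < n_events * min_gap_s) {
      stop("event_rate_per_h too high to place non-overlapping events",
           call. = FALSE)
    }
    # jittered regular placement: guarantees >= 30 s separation
    slot <- span / n_events
    starts <- t0 + (seq_len(n_events) - 1) * slot +
      stats::runif(n_events, 0, max(0, slot - min_gap_s))
    start_idx <- round(starts * hz) + 1L
    for (k in seq_len(n_events)) {
      i0 <- start_idx[k]
      idx <- i0:(i0 + dur_smp - 1L)
      spo2[idx] <- spec$baseline_spo2 - spec$event_depth
      # half-depth ramps so cleaning's 4-point jump rule tolerates real events
      spo2[i0 - 1L] <- spec$baseline_spo2 - spec$event_depth / 2
      spo2[i0 + dur_smp] <- spec$baseline_spo2 - spec$event_depth / 2
    }
    gt <- tibble::tibble(
      start_s = times[start_idx],
      end_s = times[start_idx] + spec$event_duration_s,
      depth = spec$event_depth
    )
  }

  artifact_idx <- integer(0)
  if (spec$artifact_frac > 0) {
    event_smp <- if (n_events > 0) {
      unlist(lapply(seq_len(n_events),
                    function(k) (round(gt$start_s[k] * hz) - 1L):(round(gt$end_s[k] * hz) + 2L)))
    } else integer(0)
    candidates <- setdiff(seq(3L, n - 2L), event_smp)
    n_art <- min(round(spec$artifact_frac * n), length(candidates))
    pool <- candidates
    sel <- integer(0)
    last <- -10L
    for (i in sample(seq_along(pool))) {
      if (length(sel) >= n_art) break
      if (all(abs(pool[i] - sel) > 2)) sel <- c(sel, pool[i])
    }
    artifact_idx <- sort(sel)
    is_zero <- stats::runif(length(artifact_idx)) < 0.5
    spo2[artifact_idx[is_zero]] <- 0
    spikes <- artifact_idx[!is_zero]
    spo2[spikes] <- pmax(spo2[spikes] - stats::runif(length(spikes), 8, 20), 51)
  }

  tr <- spo2_trace(times, spo2, sample_hz = hz)
  attr(tr, "ground_truth") <- gt %||% tibble::tibble(start_s = numeric(0),
                                                     end_s = numeric(0),
                                                     depth = numeric(0))
  attr(tr, "artifact_idx") <- artifact_idx
  tr
}

#' Snore audio simulation specification
#'
#' Describes planted-snore audio: a Gaussian noise floor plus snore bursts
#' built from band-shaped noise whose power in each snoring-sound-energy
#' (SSE) band sits `band_gains_db` decibels above the noise floor's power
#' in that band. The first 60 s are guaranteed burst-free to serve as the
#' background-noise baseline.
#'
#' @param duration_min audio length in minutes.
#' @param sample_hz sampling rate (44100 Hz, PCM-style).
#' @param noise_rms noise-floor RMS amplitude (full scale = 1).
#' @param snore_rate_per_h planted snore bursts per hour of post-baseline
#'   time.
#' @param snore_duration_s burst duration in seconds, within \[0.5, 3\];
#'   snapped to the 0.25-s analysis grid.
#' @param band_gains_db length-5 vector of dB over noise for the bands
#'   21-200, 201-400, 401-600, 601-800, 801-1000 Hz.
#' @param seed integer seed.
#' @export
audio_sim_spec <- function(duration_min = 2.5,
                           sample_hz = 44100,
                           noise_rms = 0.005,
                           snore_rate_per_h = 600,
                           snore_duration_s = 1.0,
                           band_gains_db = c(18, 15, 12, 12, 12),
                           seed = 1) {
  if (snore_duration_s < 0.5 || snore_duration_s > 3) {
    stop("snore_duration_s must lie in [0.5, 3] for countable snores",
         call. = FALSE)
  }
  if (length(band_gains_db) != 5 || any(!is.finite(band_gains_db))) {
    stop("band_gains_db must be 5 finite values", call. = FALSE)
  }
  if (noise_rms <= 0) stop("noise_rms must be positive", call. = FALSE)
  structure(as.list(environment()), class = "audio_sim_spec")
}

sse_band_edges <- function() {
  list(lo = c(20, 200, 400, 600, 800), hi = c(200, 400, 600, 800, 1000))
}

#' Simulate snore audio with planted bursts
#'
#' The background is white Gaussian noise at `noise_rms`. Bursts start on
#' the 0.25-s analysis grid, last `snore_duration_s` (grid-snapped), are
#' separated by at least 0.5 s of clean noise, and are synthesized in the
#' frequency domain: per SSE band, noise bins are scaled so the burst adds
#' `10^(g/10) - 1` times the expected noise band power (total in-band power
#' during the burst is then `g` dB over baseline); bins outside 20-1000 Hz
#' are zeroed. Deterministic given the spec's seed.
#'
#' @param spec an [audio_sim_spec()].
#' @return an [audio_signal()] with attribute `ground_truth` (tibble of
#'   burst intervals).
#' @export
simulate_snore_audio <- function(spec) {
  stopifnot(inherits(spec, "audio_sim_spec"))
  set.seed(as.integer(spec$seed))
  fs <- spec$sample_hz
  n <- round(spec$duration_min * 60 * fs)
  x <- stats::rnorm(n, sd = spec$noise_rms)

  dur_s <- round(spec$snore_duration_s / 0.25) * 0.25
  dur_s <- min(max(dur_s, 0.5), 3)
  active_s <- spec$duration_min * 60 - 60
  n_bursts <- round(spec$snore_rate_per_h * active_s / 3600)
  gt <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  if (n_bursts > 0) {
    min_gap_s <- 0.5
    slot_s <- active_s / n_bursts
    if (slot_s < dur_s + min_gap_s) {
      stop("snore_rate_per_h too high for the requested burst duration",
           call. = FALSE)
    }
    # implied post-lowpass RMS ratio of burst windows over baseline; the
    # detector needs >= 2x, so refuse gains too weak to ever be detected
    edges0 <- sse_band_edges()
    band_frac <- (edges0$hi - edges0$lo) / (fs / 2)
    lp_frac <- 1000 / (fs / 2)
    ratio <- sqrt((lp_frac + sum((10^(spec$band_gains_db / 10) - 1) * band_frac)) / lp_frac)
    if (ratio < 2) {
      warning(sprintf(
        "band_gains_db imply a burst/baseline RMS ratio of %.2f (< 2); planted snores will not be detectable",
        ratio
      ), call. = FALSE)
    }
    jitter_slots <- floor((slot_s - dur_s - min_gap_s) / 0.25)
    starts <- 60 + (seq_len(n_bursts) - 1) * slot_s
    starts <- round(starts / 0.25) * 0.25 +
      0.25 * sample.int(max(1L, jitter_slots), n_bursts, replace = TRUE) - 0.25
    # synthesize each burst as a train of 0.25-s pieces whose FFT bins
    # coincide with the analysis grid, so planted band powers land in the
    # intended SSE bands without leakage across band edges
    Lw <- round(0.25 * fs)
    n_sub <- round(dur_s / 0.25)
    edges <- sse_band_edges()
    freq <- (0:(Lw - 1)) * fs / Lw
    fpos <- pmin(freq, fs - freq)  # two-sided bin frequencies
    noise_bin_power <- spec$noise_rms^2 / Lw  # expected per two-sided bin
    band_idx <- lapply(1:5, function(b) which(fpos > edges$lo[b] & fpos <= edges$hi[b]))
    x_noise <- x  # pre-burst noise floor, used to taper burst edges only
    for (k in seq_len(n_bursts)) {
      # one 0.25-s in-band piece, tiled over the burst: every frequency on
      # the 4-Hz analysis grid is periodic in 0.25 s, so the tiling is
      # continuous at block boundaries and each analysis window sees the
      # calibrated band powers exactly (snores are quasi-periodic anyway)
      seg <- stats::rnorm(Lw)
      X <- stats::fft(seg)
      scale <- numeric(Lw)
      for (b in 1:5) {
        in_band <- band_idx[[b]]
        if (!length(in_band)) next
        target <- (10^(spec$band_gains_db[b] / 10) - 1) *
          noise_bin_power * length(in_band)
        cur <- sum(Mod(X[in_band])^2) / Lw^2
        if (cur > 0 && target > 0) scale[in_band] <- sqrt(target / cur)
      }
      piece <- Re(stats::fft(X * scale, inverse = TRUE)) / Lw
      i0 <- round(starts[k] * fs) + 1L
      x[i0:(i0 + n_sub * Lw - 1L)] <- x[i0:(i0 + n_sub * Lw - 1L)] +
        rep(piece, n_sub)
      # 50-ms raised-cosine edges: an abrupt in-band burst has wideband
      # spectral splatter that the 1-kHz brick-wall would turn into ringing
      # tails long enough to bridge snores at high planted gains
      nt <- round(0.05 * fs)
      ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 0.5) / nt))
      b0 <- round(starts[k] * fs) + 1L
      b1 <- b0 + n_sub * Lw - 1L
      noise_head <- x_noise[b0:(b0 + nt - 1L)]
      noise_tail <- x_noise[(b1 - nt + 1L):b1]
      x[b0:(b0 + nt - 1L)] <- noise_head + (x[b0:(b0 + nt - 1L)] - noise_head) * ramp
      x[(b1 - nt + 1L):b1] <- noise_tail + (x[(b1 - nt + 1L):b1] - noise_tail) * rev(ramp)
    }
    gt <- tibble::tibble(start_s = starts, end_s = starts + dur_s)
  }

  sig <- audio_signal(x, sample_hz = fs)
  attr(sig, "ground_truth") <- gt
  sig
}
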