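test_that("the 1 kHz low-pass keeps the passband and kills the stopband", {
  s500 <- sine_signal(500)
  out <- lowpass_1k(s500)
  rms_in <- sqrt(mean(s500$samples^2))
  rms_out <- sqrt(mean(out$samples^2))
  expect_lt(abs(rms_out - rms_in) / rms_in, 0.01)

  s2k <- sine_signal(2000)
  out2 <- lowpass_1k(s2k)
  expect_lt(sqrt(mean(out2$samples^2)), 0.01 * sqrt(mean(s2k$samples^2)))

  set.seed(3)
  noise <- audio_signal(rnorm(44100, sd = 0.05), 44100)
  lp <- lowpass_1k(noise)
  X <- abs(fft(lp$samples))^2
  freq <- (seq_along(X) - 1) * 44100 / length(X)
  fpos <- pmin(freq, 44100 - freq)
  # residual above 1 kHz at least 40 dB below the passband
  p_stop <- sum(X[fpos > 1000])
  p_pass <- sum(X[fpos <= 1000])
  expect_lt(p_stop / p_pass, 1e-4)
})

test_that("window energies have exact counts, sine RMS, and Parseval", {
  s <- sine_signal(900, duration_s = 60, amp = 1)
  we <- window_energies(s)
  expect_equal(we$n_windows, 240L)
  expect_lt(max(abs(we$rms - 1 / sqrt(2))), 0.01 / sqrt(2))
  # spectral power concentrated in the 900-Hz bin
  i900 <- which(we$freq == 900)
  expect_gt(sum(we$power[1, i900]) / sum(we$power[1, ]), 0.999)

  set.seed(4)
  noise <- audio_signal(rnorm(44100 * 2, sd = 0.03), 44100)
  weN <- window_energies(noise, max_hz = 22050)
  # Parseval: per-window spectral power sums equal the time-domain mean square
  expect_lt(max(abs(weN$total_power - weN$rms^2) / weN$rms^2), 1e-6)
})

test_that("baseline estimation falls back to the first minute for pure noise", {
  set.seed(5)
  noise <- audio_signal(rnorm(44100 * 130, sd = 0.02), 44100)
  bl <- find_baseline(noise)
  expect_equal(bl$segment, c(0, 60))
  expect_lt(abs(bl$rms - 0.02) / 0.02, 0.02)
  expect_error(find_baseline(audio_signal(rep(0, 44100 * 130), 44100)),
               "all-zero")
})

test_that("baseline re-anchors to the minute before the first snore", {
  aud <- simulate_snore_audio(audio_sim_spec(duration_min = 3,
                                             snore_rate_per_h = 60, seed = 12))
  gt <- attr(aud, "ground_truth")
  lp <- lowpass_1k(aud)
  bl <- find_baseline(lp)
  expect_equal(bl$segment[2], gt$start_s[1], tolerance = 0.26)
  expect_equal(bl$segment[1], gt$start_s[1] - 60, tolerance = 0.26)
})

test_that("snore detection needs 6 dB over baseline and 0.5-3 s duration", {
  set.seed(6)
  fs <- 44100
  sigma <- 0.02
  x <- rnorm(fs * 150, sd = sigma)
  add_burst <- function(x, start_s, dur_s, amp) {
    idx <- (round(start_s * fs) + 1):(round((start_s + dur_s) * fs))
    x[idx] <- x[idx] + rnorm(length(idx), sd = amp)
    x
  }
  # three valid 1-s bursts, one too-short (0.25 s), one too-long (4 s)
  x <- add_burst(x, 70, 1, 4 * sigma)
  x <- add_burst(x, 80, 1, 4 * sigma)
  x <- add_burst(x, 90, 1, 4 * sigma)
  x <- add_burst(x, 100, 0.25, 4 * sigma)
  x <- add_burst(x, 110, 4, 4 * sigma)
  sig <- audio_signal(x, fs)
  bl <- find_baseline(sig)
  ev <- detect_snores(sig, bl)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$duration_s, rep(1.0, 3))
  expect_true(all(ev$start_s < 95))

  # silence after the baseline minute: nothing detected
  quiet <- audio_signal(rnorm(fs * 130, sd = sigma), fs)
  expect_equal(nrow(detect_snores(quiet, find_baseline(quiet))), 0)
})

test_that("snore index uses events per hour of analyzed time", {
  events <- tibble::tibble(start_s = seq_len(929), end_s = seq_len(929) + 0.5,
                           duration_s = 0.5, win_from = 1L, win_to = 1L)
  s <- sine_signal(500, duration_s = 2)
  we <- window_energies(s)
  bl <- structure(list(rms = 0.01, band_power = rep(1, 5), segment = c(0, 60)),
                  class = "noise_baseline")
  feats <- acoustic_features(events, we, bl, analyzed_minutes = 60,
                             qc_min_minutes = 300)
  expect_equal(feats$si, 929)
  expect_false(feats$qc_pass)
  feats6h <- acoustic_features(events, we, bl, analyzed_minutes = 360)
  expect_equal(feats6h$si, 929 / 6)
  expect_true(feats6h$qc_pass)

  none <- events[0, ]
  f0 <- acoustic_features(none, we, bl, analyzed_minutes = 360)
  expect_equal(f0$si, 0)
  expect_equal(f0$sse_db, rep(0, 5))
})

test_that("events and SSE are invariant to joint amplitude scaling", {
  aud <- simulate_snore_audio(audio_sim_spec(duration_min = 2.5,
                                             snore_rate_per_h = 120, seed = 13))
  res1 <- analyze_audio(aud)
  scaled <- audio_signal(aud$samples * 0.35, aud$sample_hz)
  res2 <- analyze_audio(scaled)
  expect_equal(res1$events$start_s, res2$events$start_s)
  expect_equal(res1$features$sse_db, res2$features$sse_db, tolerance = 1e-9)
})

test_that("planted SI and band gains are recovered", {
  gains <- c(18, 15, 12, 9, 14)
  for (seed in 1:5) {
    aud <- simulate_snore_audio(audio_sim_spec(
      duration_min = 2.5, snore_rate_per_h = 400, snore_duration_s = 1.0,
      band_gains_db = gains, seed = seed
    ))
    gt <- attr(aud, "ground_truth")
    res <- analyze_audio(aud)
    si_true <- nrow(gt) / ((aud$duration_s - gt$start_s[1]) / 3600)
    expect_lt(abs(res$features$si - si_true) / si_true, 0.02)
    expect_lt(max(abs(res$features$sse_db - gains)), 1)
  }
})
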