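test_that("quantile-matched distributions hit the requested median and IQR", {
  targets <- list(
    list(m = 22.2, q25 = 16.7, q75 = 33.9, tr = "lognormal"),
    list(m = 929, q25 = 348, q75 = 1261, tr = "lognormal"),
    list(m = 0.84, q25 = 0.80, q75 = 0.92, tr = "logitnormal"),
    list(m = 1.4, q25 = 0.8, q75 = 2.0, tr = "normal")
  )
  set.seed(42)
  for (tg in targets) {
    d <- qdist(tg$m, tg$q25, tg$q75, tg$tr)
    expect_equal(unname(qdist_quantile(d, c(0.25, 0.5, 0.75))),
                 c(tg$q25, tg$m, tg$q75), tolerance = 1e-12)
    x <- qdist_sample(5000, d)
    emp <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    expect_lt(max(abs(emp - c(tg$q25, tg$m, tg$q75)) / abs(c(tg$q25, tg$m, tg$q75))),
              0.05)
  }
  expect_error(qdist(5, 6, 7, "lognormal"), "inverted")
  expect_error(qdist(0.5, 0.2, 1.1, "logitnormal"), "inside")
})

test_that("severe-group ODI3 draws match the target median within 5%", {
  set.seed(7)
  d <- qdist(22.2, 16.7, 33.9, "lognormal")
  x <- qdist_sample(10000, d)
  expect_lt(abs(median(x) - 22.2) / 22.2, 0.05)
})

test_that("quota cohorts have exact group sizes and consistent labels", {
  coh <- generate_cohort(cohort_params_study1(39), seed = 1)
  expect_equal(nrow(coh), 39)
  expect_equal(sum(coh$severe), 21)
  expect_equal(sum(!coh$severe), 18)
  # severity label is defined by the AHI threshold
  expect_equal(coh$severe, coh$obstructive_ahi >= 10)
  expect_true(all(coh$tonsil %in% 1:4))
  expect_true(all(coh$anr > 0 & coh$anr < 1))
  expect_true(all(coh$osa18 >= 18 & coh$osa18 <= 126))
  expect_true(all(coh$age >= 5 & coh$age <= 12))
})

test_that("degenerate prevalence yields a single-class cohort", {
  coh <- generate_cohort(cohort_params(10, prevalence_severe = 0), seed = 3)
  expect_false(any(coh$severe))
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_params_study1(), seed = 99)
  b <- generate_cohort(cohort_params_study1(), seed = 99)
  expect_identical(a, b)
  c <- generate_cohort(cohort_params_study1(), seed = 100)
  expect_false(identical(a, c))
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(1, 0.5), "n_patients")
  expect_error(cohort_params(10, 1.5), "prevalence")
  bad <- default_feature_targets()
  bad$odi3$severe <- c(5, 10, 20)  # q25 > median
  expect_error(cohort_params(10, 0.5, features = bad), "q25 <= median")
})

test_that("simulated SpO2 traces carry exhaustive planted truth", {
  spec <- trace_sim_spec(duration_min = 100, event_rate_per_h = 6,
                         first_snore_offset_min = 10, seed = 5)
  tr <- simulate_spo2_trace(spec)
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(gt), 9)  # 6/h over the ~89-min plantable span
  expect_true(all(gt$start_s >= 660))
  expect_true(all(gt$end_s <= 6000))
  expect_true(all(diff(gt$start_s) >= 30 + spec$event_duration_s))
  # bit-for-bit determinism
  expect_identical(tr, simulate_spo2_trace(spec))
})

test_that("a null SpO2 simulation is a flat trace at baseline", {
  tr <- simulate_spo2_trace(trace_sim_spec(duration_min = 30,
                                           event_rate_per_h = 0,
                                           artifact_frac = 0, seed = 1))
  expect_true(all(tr$spo2 == 98))
  expect_true(all(tr$valid))
  expect_equal(nrow(attr(tr, "ground_truth")), 0)
})

test_that("infeasible desaturation rates are refused", {
  expect_error(
    simulate_spo2_trace(trace_sim_spec(duration_min = 95, event_rate_per_h = 200,
                                       first_snore_offset_min = 0)),
    "too high"
  )
})

test_that("null audio simulation yields no bursts and SI 0", {
  aud <- simulate_snore_audio(audio_sim_spec(duration_min = 2.5,
                                             snore_rate_per_h = 0, seed = 2))
  expect_equal(nrow(attr(aud, "ground_truth")), 0)
  res <- analyze_audio(aud)
  expect_equal(res$features$si, 0)
})

test_that("planted snore bursts are book-kept exactly and are deterministic", {
  spec <- audio_sim_spec(duration_min = 2.5, snore_rate_per_h = 80,
                         snore_duration_s = 1.0, seed = 6)
  aud <- simulate_snore_audio(spec)
  gt <- attr(aud, "ground_truth")
  expect_equal(nrow(gt), 2)  # 80/h over 1.5 active minutes
  expect_equal(gt$end_s - gt$start_s, rep(1.0, 2))
  expect_true(all(gt$start_s >= 60))
  expect_true(all(gt$end_s <= aud$duration_s))
  expect_identical(aud$samples, simulate_snore_audio(spec)$samples)
})

test_that("burst energy placed in one band stays in that band", {
  aud <- simulate_snore_audio(audio_sim_spec(duration_min = 2.5,
                                             snore_rate_per_h = 120,
                                             band_gains_db = c(0, 0, 0, 0, 22),
                                             seed = 8))
  gt <- attr(aud, "ground_truth")
  noise_rms <- 0.005  # simulator default noise floor
  # Parseval-based check on the raw waveform: burst-minus-noise power above
  # 800 Hz must dominate the planted excess energy
  fs <- aud$sample_hz
  i0 <- round(gt$start_s[1] * fs) + 1
  seg <- aud$samples[i0:(i0 + fs - 1)]
  X <- abs(fft(seg))^2 / length(seg)^2
  freq <- (seq_along(X) - 1) * fs / length(seg)
  fpos <- pmin(freq, fs - freq)
  excess <- sum(X) - noise_rms^2
  in_band <- sum(X[fpos > 800 & fpos <= 1000]) - noise_rms^2 * 200 / (fs / 2)
  expect_gt(in_band / excess, 0.9)
})

test_that("audio simulation validates its parameters", {
  expect_error(audio_sim_spec(snore_duration_s = 0.3), "0.5")
  expect_error(audio_sim_spec(band_gains_db = c(1, 2, 3)), "5 finite")
  expect_warning(
    simulate_snore_audio(audio_sim_spec(duration_min = 2.5, snore_rate_per_h = 40,
                                        band_gains_db = rep(3, 5), seed = 1)),
    "not be detectable"
  )
})
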