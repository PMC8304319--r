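test_that("trace cleaning flags dropouts and jumps but keeps clean data", {
  n <- 120
  times <- (seq_len(n) - 1) * 2
  tr <- clean_trace(spo2_trace(times, rep(98, n)))
  expect_true(all(tr$valid))

  spo2 <- rep(98, n)
  spo2[50] <- 0
  tr <- clean_trace(spo2_trace(times, spo2))
  expect_false(tr$valid[50])
  expect_true(all(tr$valid[-50]))

  spo2 <- rep(98, n)
  spo2[70] <- 88  # 10-point jump, motion artifact
  tr <- clean_trace(spo2_trace(times, spo2))
  expect_false(tr$valid[70])
  expect_true(tr$valid[71])  # compared against the last *valid* sample
})

test_that("cleaning recovers at least 95% of simulated artifacts", {
  tr <- simulate_spo2_trace(trace_sim_spec(duration_min = 100,
                                           event_rate_per_h = 6,
                                           artifact_frac = 0.1, seed = 11))
  art <- attr(tr, "artifact_idx")
  expect_gt(length(art), 100)
  cleaned <- clean_trace(tr)
  expect_gte(mean(!cleaned$valid[art]), 0.95)
  # planted desaturations must survive cleaning
  gt <- attr(tr, "ground_truth")
  ev_idx <- unlist(Map(function(a, b) seq(round(a * 0.5) + 1, round(b * 0.5) + 1),
                       gt$start_s, gt$end_s))
  expect_true(all(cleaned$valid[ev_idx]))
})

test_that("the analysis window starts at the first snore and clips", {
  hz <- 0.5
  n <- 8 * 3600 * hz
  tr <- spo2_trace((seq_len(n) - 1) / hz, rep(97, n))
  w <- select_window(tr, first_snore_s = 30 * 60)
  expect_equal(w$times[1], 1800)
  expect_equal(w$times[length(w$times)], 120 * 60 - 2)

  tr90 <- spo2_trace((seq_len(90 * 60 * hz) - 1) / hz, rep(97, 90 * 60 * hz))
  w0 <- select_window(tr90, 0)
  expect_identical(w0$spo2, tr90$spo2)

  tr100 <- spo2_trace((seq_len(100 * 60 * hz) - 1) / hz, rep(97, 100 * 60 * hz))
  wclip <- select_window(tr100, 30 * 60)
  expect_equal(length(wclip$times) / hz / 60, 70)
  expect_false(compute_odi3(wclip)$qc_pass)  # 70 valid min < 75

  expect_error(select_window(tr100, 7000 * 60), "after the end")
})

test_that("ODI3 is zero on a flat trace and QC depends on valid minutes", {
  tr <- flat_trace_with_dips(90)
  res <- compute_odi3(tr)
  expect_equal(res$odi3, 0)
  expect_equal(res$n_events, 0L)
  expect_true(res$qc_pass)
  expect_false(compute_odi3(flat_trace_with_dips(74))$qc_pass)
  expect_true(compute_odi3(flat_trace_with_dips(75))$qc_pass)
})

test_that("planted 3.5-point dips are counted and shallow dips are not", {
  starts <- 60 + (0:8) * 560  # 9 dips across 90 min
  tr <- flat_trace_with_dips(90, dip_starts_s = starts, depth = 3.5)
  res <- compute_odi3(tr)
  expect_equal(res$n_events, 9L)
  expect_equal(res$odi3, 6.0)

  tr2 <- flat_trace_with_dips(90, dip_starts_s = starts, depth = 2)
  expect_equal(compute_odi3(tr2)$n_events, 0L)
})

test_that("ODI3 is invariant to time shifts and invalid padding", {
  starts <- 60 + (0:5) * 700
  tr <- flat_trace_with_dips(90, dip_starts_s = starts)
  base <- compute_odi3(tr)

  shifted <- spo2_trace(tr$times + 12345, tr$spo2, tr$valid, tr$sample_hz)
  res_sh <- compute_odi3(shifted)
  expect_equal(res_sh$n_events, base$n_events)
  expect_equal(res_sh$odi3, base$odi3)

  extra <- 100
  padded <- spo2_trace(
    c(tr$times, max(tr$times) + (1:extra) * 2),
    c(tr$spo2, rep(0, extra)),
    c(tr$valid, rep(FALSE, extra)),
    tr$sample_hz
  )
  res_pad <- compute_odi3(padded)
  expect_equal(res_pad$n_events, base$n_events)
  expect_equal(res_pad$odi3, base$odi3)
})

test_that("halving valid time at fixed event count doubles ODI3", {
  starts <- 60 + (0:3) * 600
  tr45 <- flat_trace_with_dips(45, dip_starts_s = starts)
  tr90 <- flat_trace_with_dips(90, dip_starts_s = starts)
  r45 <- compute_odi3(tr45)
  r90 <- compute_odi3(tr90)
  expect_equal(r45$n_events, r90$n_events)
  expect_equal(r45$odi3, 2 * r90$odi3)
})

test_that("adding a qualifying event never decreases the count", {
  starts <- 60 + (0:4) * 800
  for (k in 1:5) {
    a <- compute_odi3(flat_trace_with_dips(90, dip_starts_s = starts[seq_len(k - 1)]))
    b <- compute_odi3(flat_trace_with_dips(90, dip_starts_s = starts[seq_len(k)]))
    expect_gte(b$n_events, a$n_events)
  }
})

test_that("the detector recovers planted events exactly across seeds", {
  for (seed in 1:10) {
    spec <- trace_sim_spec(duration_min = 100, event_rate_per_h = sample(3:20, 1),
                           event_depth = 3.5, event_duration_s = 20, seed = seed)
    tr <- clean_trace(simulate_spo2_trace(spec))
    w <- select_window(tr, 600)
    gt <- attr(tr, "ground_truth")
    planted <- sum(gt$start_s >= 600 & gt$end_s < 600 + 90 * 60)
    expect_equal(compute_odi3(w)$n_events, planted)
  }
})

test_that("degenerate traces are flagged rather than raising", {
  tr <- spo2_trace(c(0, 2, 4), c(0, 0, 0), valid = rep(FALSE, 3))
  res <- compute_odi3(tr)
  expect_false(res$qc_pass)
  expect_true(is.na(res$odi3))
  expect_error(spo2_trace(numeric(0), numeric(0)), "empty")
})
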