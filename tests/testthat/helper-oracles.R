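# Independent brute-force oracles the implementation is checked against.

# AUC as the fraction of concordant (severe, non-severe) pairs, ties = 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# AUC as the trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(cuts, function(ct) mean(scores[labels] >= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(scores[!labels] >= ct), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# Hodges-Lehmann estimate by explicit enumeration of pairwise differences.
oracle_hl <- function(x, y) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  median(d)
}

# Best Youden J over an exhaustive sweep of ">= threshold" rules at every
# observed value and midpoint; returns max J and the (sens, spec) attaining
# it with the highest specificity.
oracle_youden <- function(values, labels) {
  u <- sort(unique(values))
  cand <- sort(unique(c(-Inf, u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)))
  best <- list(j = -Inf, sens = NA, spec = NA)
  for (ct in cand) {
    pred <- values >= ct
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 || (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Direct recount of classification metrics from raw prediction vectors.
oracle_metrics <- function(predicted, truth) {
  list(
    sens = mean(predicted[truth]),
    spec = mean(!predicted[!truth]),
    ppv = mean(truth[predicted]),
    npv = mean(!truth[!predicted]),
    acc = mean(predicted == truth)
  )
}

# A designed LASSO-selection problem: three informative dichotomized
# predictors with the discovery study's sensitivity/specificity margins
# plus two label-independent noise predictors.
make_lasso_sim <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- stats::runif(n) < 21 / 39
  mk <- function(sens, spec) ifelse(y, stats::runif(n) < sens, stats::runif(n) < 1 - spec)
  x <- cbind(
    odi3_high = mk(0.90, 0.83),
    tonsil4 = mk(0.52, 0.83),
    anr_high = mk(0.86, 0.67),
    noise1 = stats::runif(n) < 0.45,
    noise2 = stats::runif(n) < 0.45
  )
  list(x = x, y = y)
}

# Unit-amplitude sine as an audio_signal.
sine_signal <- function(freq_hz, duration_s = 2, fs = 44100, amp = 0.5) {
  t <- seq_len(duration_s * fs) / fs
  audio_signal(amp * sin(2 * pi * freq_hz * t), fs)
}

# Flat oximetry trace with hand-planted square desaturation dips.
flat_trace_with_dips <- function(duration_min = 90, hz = 0.5, baseline = 98,
                                 dip_starts_s = numeric(0), depth = 3.5,
                                 dip_duration_s = 20) {
  n <- duration_min * 60 * hz
  times <- (seq_len(n) - 1) / hz
  spo2 <- rep(baseline, n)
  for (s in dip_starts_s) {
    i0 <- round(s * hz) + 1
    idx <- i0:(i0 + dip_duration_s * hz - 1)
    spo2[idx] <- baseline - depth
    spo2[i0 - 1] <- baseline - depth / 2
    spo2[max(idx) + 1] <- baseline - depth / 2
  }
  spo2_trace(times, spo2, sample_hz = hz)
}
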