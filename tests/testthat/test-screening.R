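test_that("Youden dichotomization handles separation and constant features", {
  vals <- c(8, 9, 10, 1, 2, 3)
  labs <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- youden_dichotomize(vals, labs)
  expect_equal(d$youden_j, 1)
  expect_equal(d$auc, 1)
  expect_true(d$cutoff > 3 && d$cutoff <= 8)

  d0 <- youden_dichotomize(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(d0$auc, 0.5)
  expect_equal(d0$youden_j, 0)

  expect_error(youden_dichotomize(1:5, rep(TRUE, 5)), "both classes")
  expect_error(youden_dichotomize(c(1, NA, 3), c(TRUE, FALSE, TRUE)), "missing")
})

test_that("Youden cut-off matches an exhaustive threshold sweep", {
  vals <- c(8, 9, 10, 1, 2, 9)
  labs <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- youden_dichotomize(vals, labs)
  o <- oracle_youden(vals, labs)
  expect_equal(d$youden_j, o$j)
  expect_equal(c(d$sens, d$spec), c(o$sens, o$spec))
  expect_equal(d$auc, oracle_auc_pairs(vals, labs))

  set.seed(21)
  for (i in 1:20) {
    v <- round(rexp(30, 0.2), 1)
    l <- runif(30) < plogis((v - 5) / 3)
    if (length(unique(l)) < 2) next
    d <- youden_dichotomize(v, l)
    o <- oracle_youden(v, l)
    expect_equal(d$youden_j, o$j)
    expect_equal(d$spec, o$spec)
  }
})

test_that("univariate logistic OR equals the 2x2 cross-product", {
  # counts (19, 2; 3, 15): exposed/unexposed among severe and non-severe
  x <- rep(c(TRUE, FALSE, TRUE, FALSE), c(19, 2, 3, 15))
  y <- rep(c(TRUE, TRUE, FALSE, FALSE), c(19, 2, 3, 15))
  fit <- fit_univariate_logistic(x, y)
  expect_equal(fit$or, 47.5, tolerance = 1e-6)
  expect_false(fit$corrected)

  # exhaustive over all 2x2 tables with cells 1..6
  for (a in 1:6) for (b in 1:6) for (c_ in 1:6) for (d in 1:6) {
    x <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d))
    y <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c_, d))
    fit <- fit_univariate_logistic(x, y)
    expect_equal(fit$or, (a * d) / (b * c_), tolerance = 1e-6)
  }
})

test_that("independent balanced predictors give OR near 1 and zero cells flag", {
  x <- rep(c(TRUE, FALSE), 50)
  y <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  expect_equal(fit_univariate_logistic(x, y)$or, 1, tolerance = 1e-6)

  xs <- rep(c(TRUE, FALSE), c(10, 10))
  ys <- rep(c(TRUE, FALSE), c(10, 10))
  sep <- fit_univariate_logistic(xs, ys)
  expect_true(sep$corrected)
  expect_true(sep$separation)
  expect_true(is.finite(sep$or))
  expect_error(fit_univariate_logistic(xs, rep(TRUE, 20)), "both outcome")
})

test_that("the LASSO path starts empty and ranks a dominant feature first", {
  sim <- make_lasso_sim(seed = 3)
  lp <- lasso_bootstrap(sim$x, sim$y, seed = 3)
  expect_equal(unname(lp$active[1]), 0)  # all coefficients zero at lambda_max
  expect_true(all(diff(lp$active) >= 0))  # active set grows along this path
  expect_equal(length(lp$ref_features), 3)
  expect_true(all(lp$selection_freq >= 0 & lp$selection_freq <= 1))

  # a perfectly predictive feature dominates the selection frequencies
  set.seed(9)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(
    perfect = y,
    n1 = runif(n) < 0.5, n2 = runif(n) < 0.5,
    n3 = runif(n) < 0.5, n4 = runif(n) < 0.5
  )
  lp2 <- lasso_bootstrap(x, y, seed = 9)
  expect_equal(names(which.max(lp2$selection_freq)), "perfect")
  expect_equal(lp2$selection_order[1], "perfect")
})

test_that("constant features are dropped with a warning", {
  sim <- make_lasso_sim(seed = 4)
  x <- cbind(sim$x, flat = 1)
  expect_warning(lp <- lasso_bootstrap(x, sim$y, seed = 4), "constant")
  expect_false("flat" %in% names(lp$selection_freq))
})

test_that("model scoring applies the weighted rules", {
  rec <- list(patient_id = "P001", odi3_high = TRUE, tonsil4 = TRUE, anr_high = TRUE)
  combined <- model_spec("combined")
  s <- score_patient(rec, combined)
  expect_equal(s$score, 6L)
  expect_true(s$predicted_severe)

  s3 <- score_patient(list(odi3_high = TRUE, tonsil4 = FALSE, anr_high = FALSE), combined)
  expect_equal(s3$score, 3L)
  expect_false(s3$predicted_severe)  # 3 < 4

  s0 <- score_patient(list(odi3_high = FALSE, tonsil4 = FALSE, anr_high = FALSE), combined)
  expect_equal(s0$score, 0L)
  expect_false(s0$predicted_severe)

  anat <- model_spec("anatomical")
  sa <- score_patient(list(anr_high = TRUE, tonsil4 = FALSE), anat)
  expect_equal(sa$score, 1L)
  expect_true(sa$predicted_severe)

  expect_error(score_patient(list(odi3_high = TRUE), combined), "tonsil4")
})

test_that("flipping a component positive never decreases the score", {
  combined <- model_spec("combined")
  combos <- expand.grid(odi3_high = c(FALSE, TRUE), tonsil4 = c(FALSE, TRUE),
                        anr_high = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    base <- score_patient(as.list(combos[i, ]), combined)$score
    for (comp in names(combos)) {
      if (!combos[i, comp]) {
        up <- combos[i, ]
        up[[comp]] <- TRUE
        expect_gte(score_patient(as.list(up), combined)$score, base)
      }
    }
  }
})

test_that("dichotomization uses >= for continuous features and = for tonsil", {
  coh <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    odi3 = c(6.0, 5.99, 7), anr = c(0.78, 0.5, 0.9),
    tonsil = c(4L, 3L, 2L), sse_801_1000 = c(22, 10, 30), osa18 = c(77, 60, 90)
  )
  d <- dichotomize_cohort(coh)
  expect_equal(d$odi3_high, c(TRUE, FALSE, TRUE))
  expect_equal(d$anr_high, c(TRUE, FALSE, TRUE))
  expect_equal(d$tonsil4, c(TRUE, FALSE, FALSE))
  expect_equal(d$sse_high, c(TRUE, FALSE, TRUE))
  expect_equal(d$osa18_high, c(TRUE, FALSE, TRUE))
})

test_that("Youden recovers a known severity threshold on synthetic cohorts", {
  # discovery-structure cohorts: non-severe ODI3 quartiles top out at 5.3,
  # severe start at 7.5; a recovered cut-off should sit in that gap
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_params_study1(500), seed = seed)
    d <- youden_dichotomize(coh$odi3, coh$severe)
    expect_gte(d$cutoff, 5.3)
    expect_lte(d$cutoff, 7.5)
  }
})
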