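#' Dichotomize a predictor at the Youden-optimal cut-off
#'
#' Builds the empirical ROC of `values` against `labels` (positive class =
#' severe OSA, direction: higher values predict severe), evaluating every
#' candidate cut-off at the midpoints between consecutive sorted unique
#' values plus the two infinities, and picks the cut-off maximizing
#' Youden's J = sensitivity + specificity - 1. Ties in J are broken toward
#' higher specificity (screening follow-up is costly, so fewer false
#' positives win). The AUC is the tie-corrected Mann-Whitney statistic.
#'
#' @param values numeric predictor, no missing values.
#' @param labels logical, `TRUE` = severe.
#' @param feature_name label carried into the result.
#' @return a `dichotomizer` list: `feature_name`, `cutoff`, `direction`
#'   (`">="`), `auc`, `sens`, `spec`, `youden_j`.
#' @export
youden_dichotomize <- function(values, labels, feature_name = "feature") {
  if (anyNA(values) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  u <- sort(unique(values))
  candidates <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  best <- NULL
  for (cut in candidates) {
    pred <- values >= cut
    sens <- sum(pred & labels) / n_pos
    spec <- sum(!pred & !labels) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && spec > best$spec)) {
      best <- list(cutoff = cut, sens = sens, spec = spec, youden_j = j)
    }
  }
  structure(
    list(
      feature_name = feature_name,
      cutoff = best$cutoff,
      direction = ">=",
      auc = auc_rank(values, labels),
      sens = best$sens,
      spec = best$spec,
      youden_j = best$youden_j
    ),
    class = "dichotomizer"
  )
}

#' @export
print.dichotomizer <- function(x, ...) {
  cat(sprintf("<dichotomizer> %s %s %.4g  (AUC %.2f, sens %.0f%%, spec %.0f%%)\n",
              x$feature_name, x$direction, x$cutoff, x$auc,
              100 * x$sens, 100 * x$spec))
  invisible(x)
}

#' Univariate logistic regression of severity on a binary predictor
#'
#' Maximum-likelihood logistic fit (intercept + slope) of `y` on `x`; the
#' odds ratio is `exp(slope)` with a Wald 95% CI, and for a single binary
#' predictor it equals the 2x2 cross-product ratio. Complete separation
#' (a zero cell in the implied 2x2 table) makes the MLE infinite, so the
#' fit falls back to the Haldane-Anscombe correction (+0.5 to every cell)
#' with a Woolf log-scale CI and is flagged.
#'
#' @param x logical predictor.
#' @param y logical outcome (`TRUE` = severe).
#' @return a list: `or`, `ci95` (length 2), `p` (Wald), `separation`
#'   (logical flag), `corrected` (Haldane flag).
#' @export
fit_univariate_logistic <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(unique(y)) < 2) stop("both outcome classes must be present", call. = FALSE)
  a <- sum(x & y); b <- sum(!x & y)     # exposed/unexposed among severe
  c_ <- sum(x & !y); d <- sum(!x & !y)  # exposed/unexposed among non-severe
  if (min(a, b, c_, d) == 0) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c_ + 0.5; dd <- d + 0.5
    log_or <- log(aa * dd / (bb * cc))
    se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
    return(list(
      or = exp(log_or),
      ci95 = exp(log_or + c(-1, 1) * stats::qnorm(0.975) * se),
      p = 2 * stats::pnorm(-abs(log_or / se)),
      # any zero cell makes the unpenalized MLE infinite (quasi-/complete
      # separation for a binary predictor)
      separation = TRUE,
      corrected = TRUE
    ))
  }
  fit <- stats::glm(y ~ x, family = stats::binomial())
  co <- summary(fit)$coefficients
  est <- co["xTRUE", "Estimate"]
  se <- co["xTRUE", "Std. Error"]
  list(
    or = exp(est),
    ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
    p = co["xTRUE", "Pr(>|z|)"],
    separation = FALSE,
    corrected = FALSE
  )
}

#' Logistic LASSO path with bootstrap selection frequencies
#'
#' Fits an L1-penalized logistic regression of severity on standardized
#' dichotomized predictors over a 50-point log-spaced penalty grid from
#' the smallest all-zero penalty down to 0.001 of it (via glmnet), then
#' refits the same grid on bootstrap resamples (size `n_boot`, with
#' replacement, `n_runs` runs) and records how often each predictor is
#' active at the reference penalty - the largest penalty at which the
#' full-data path carries exactly `n_ref` (default 3) predictors, the
#' size of the combined screening model.
#'
#' @param features numeric/logical matrix (patients x predictors) with
#'   column names.
#' @param labels logical outcome.
#' @param n_boot bootstrap sample size (default 50).
#' @param n_runs bootstrap runs (default 100).
#' @param seed integer seed.
#' @param n_ref reference active-set size (default 3).
#' @return a `lasso_path` list: `lambda_grid`, `coef_paths` (predictors x
#'   lambdas), `active` (active-set size per lambda), `lambda_ref`,
#'   `ref_features` (active at the reference penalty), `selection_freq`,
#'   `selection_order` (penalty-entry order), `n_boot_samples`, `n_runs`,
#'   `dropped` (constant columns removed).
#' @export
lasso_bootstrap <- function(features, labels, n_boot = 50, n_runs = 100,
                            seed = 1, n_ref = 3) {
  x <- as.matrix(features) * 1.0
  y <- as.logical(labels)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("need at least 2 features", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  set.seed(as.integer(seed))
  full <- glmnet::glmnet(x, y, family = "binomial", nlambda = 50,
                         lambda.min.ratio = 0.001, standardize = TRUE)
  lambda_grid <- full$lambda
  beta <- as.matrix(full$beta)
  active <- colSums(beta != 0)
  # largest penalty with exactly n_ref active; if the path never pauses at
  # n_ref, the largest penalty with at least n_ref active
  at_ref <- which(active == n_ref)
  idx_ref <- if (length(at_ref)) at_ref[1] else which(active >= n_ref)[1]
  if (is.na(idx_ref)) idx_ref <- length(lambda_grid)
  lambda_ref <- lambda_grid[idx_ref]
  ref_features <- rownames(beta)[beta[, idx_ref] != 0]

  # penalty-entry order: feature rank by the first lambda at which it is active
  entry <- apply(beta != 0, 1, function(row) {
    i <- which(row)[1]
    if (is.na(i)) Inf else i
  })
  selection_order <- names(sort(entry))

  sel <- matrix(FALSE, nrow = n_runs, ncol = ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (r in seq_len(n_runs)) {
    repeat {
      idx <- sample.int(length(y), n_boot, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    bfit <- tryCatch(
      glmnet::glmnet(x[idx, , drop = FALSE], y[idx], family = "binomial",
                     lambda = lambda_grid, standardize = TRUE),
      error = function(e) NULL
    )
    if (is.null(bfit)) next
    bcoef <- stats::coef(bfit, s = lambda_ref)[-1, 1]
    sel[r, names(bcoef)] <- bcoef != 0
  }
  structure(
    list(
      lambda_grid = lambda_grid,
      coef_paths = beta,
      active = active,
      lambda_ref = lambda_ref,
      ref_features = ref_features,
      selection_freq = colMeans(sel),
      selection_order = selection_order,
      n_boot_samples = n_boot,
      n_runs = n_runs,
      dropped = names(const)[const]
    ),
    class = "lasso_path"
  )
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> %d lambdas, reference lambda %.4g (%d active)\n",
              length(x$lambda_grid), x$lambda_ref, length(x$ref_features)))
  cat("selection frequency:\n")
  print(round(sort(x$selection_freq, decreasing = TRUE), 2))
  invisible(x)
}

#' Screening model specifications
#'
#' Three screening models for severe pediatric OSA over dichotomized
#' predictors:
#' * `"anatomical"`: ANR >= 0.78 or tonsil grade = 4; positive with >= 1
#'   risk factor.
#' * `"hsat"` (home sleep apnea test): ODI3 >= 6.0 events/h or SSE of
#'   801-1000 Hz >= 22.0 dB; positive with >= 1 risk factor.
#' * `"combined"`: weighted score 3 x (ODI3 >= 6.0) + 2 x (tonsil = 4) +
#'   1 x (ANR >= 0.78); positive when the score is >= 4.
#'
#' Components refer to indicator column names produced by
#' [dichotomize_cohort()].
#'
#' @param name model name.
#' @return a `model_spec` list: `name`, `components` (named integer
#'   weights), `threshold`.
#' @export
model_spec <- function(name = c("combined", "anatomical", "hsat")) {
  name <- match.arg(name)
  spec <- switch(name,
    anatomical = list(components = c(anr_high = 1L, tonsil4 = 1L), threshold = 1L),
    hsat = list(components = c(odi3_high = 1L, sse_high = 1L), threshold = 1L),
    combined = list(components = c(odi3_high = 3L, tonsil4 = 2L, anr_high = 1L),
                    threshold = 4L)
  )
  structure(c(list(name = name), spec), class = "model_spec")
}

#' Apply the study cut-offs to a cohort's features
#'
#' Adds the indicator columns the screening models consume: `odi3_high`
#' (ODI3 >= cut-off), `anr_high`, `tonsil4` (grade equality, not >=),
#' `sse_high` (SSE of 801-1000 Hz), `osa18_high`.
#'
#' @param cohort tibble with columns `odi3`, `anr`, `tonsil`,
#'   `sse_801_1000`, `osa18`.
#' @param cutoffs named list of cut-off values; defaults are the
#'   discovery-study values.
#' @return the cohort with indicator columns appended.
#' @export
dichotomize_cohort <- function(cohort,
                               cutoffs = list(odi3 = 6.0, anr = 0.78,
                                              tonsil = 4L, sse = 22.0,
                                              osa18 = 77)) {
  cohort$odi3_high <- cohort$odi3 >= cutoffs$odi3
  cohort$anr_high <- cohort$anr >= cutoffs$anr
  cohort$tonsil4 <- cohort$tonsil == cutoffs$tonsil
  if ("sse_801_1000" %in% names(cohort)) {
    cohort$sse_high <- cohort$sse_801_1000 >= cutoffs$sse
  }
  if ("osa18" %in% names(cohort)) {
    cohort$osa18_high <- cohort$osa18 >= cutoffs$osa18
  }
  cohort
}

#' Score one patient with a screening model
#'
#' @param record one-row data frame or named list holding the model's
#'   indicator components.
#' @param model a [model_spec()].
#' @return a list: `patient_id` (if present), `score`,
#'   `predicted_severe` (`score >= threshold`).
#' @export
score_patient <- function(record, model) {
  stopifnot(inherits(model, "model_spec"))
  comp <- names(model$components)
  missing <- comp[!comp %in% names(record)]
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(comp, function(nm) as.logical(record[[nm]][1]), logical(1))
  if (anyNA(vals)) {
    stop("missing feature value(s): ",
         paste(comp[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  score <- sum(model$components * vals)
  list(
    patient_id = if ("patient_id" %in% names(record)) record[["patient_id"]][1] else NA_character_,
    score = as.integer(score),
    predicted_severe = score >= model$threshold
  )
}

#' Score a whole cohort with a screening model
#'
#' @param cohort dichotomized cohort tibble (see [dichotomize_cohort()]).
#' @param model a [model_spec()].
#' @return tibble with `patient_id`, `score`, `predicted_severe`.
#' @export
score_cohort <- function(cohort, model) {
  stopifnot(inherits(model, "model_spec"))
  comp <- names(model$components)
  missing <- comp[!comp %in% names(cohort)]
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ind <- sapply(comp, function(nm) as.logical(cohort[[nm]]))
  ind <- matrix(ind, ncol = length(comp))
  score <- as.integer(ind %*% model$components)
  tibble::tibble(
    patient_id = if ("patient_id" %in% names(cohort)) cohort$patient_id else sprintf("P%03d", seq_len(nrow(cohort))),
    score = score,
    predicted_severe = score >= model$threshold
  )
}
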