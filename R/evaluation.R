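#' 2x2 confusion matrix (positive class = severe OSA)
#'
#' @param tp,fn,fp,tn non-negative counts; `tp` = severe predicted severe,
#'   `tn` = non-severe predicted non-severe.
#' @return a `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(cells), class = "confusion_matrix")
}

#' Build a confusion matrix from predictions and truth
#'
#' @param predicted,truth logical vectors (`TRUE` = severe).
#' @export
confusion_from_predictions <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(
    tp = sum(predicted & truth), fn = sum(!predicted & truth),
    fp = sum(predicted & !truth), tn = sum(!predicted & !truth)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Diagnostic-accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive/negative predictive value and
#' accuracy as fractions; ratios with a zero denominator are reported as
#' `NA` (missing), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metric_report` list with `sens`, `spec`, `ppv`, `npv`,
#'   `acc`, and the source counts.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  structure(
    list(
      sens = frac(cm$tp, cm$tp + cm$fn),
      spec = frac(cm$tn, cm$tn + cm$fp),
      ppv = frac(cm$tp, cm$tp + cm$fp),
      npv = frac(cm$tn, cm$tn + cm$fn),
      acc = (cm$tp + cm$tn) / n,
      cm = cm
    ),
    class = "metric_report"
  )
}

#' Round half away from zero
#'
#' Display rounding used throughout the screening tables (R's `round()`
#' rounds half to even, which clinical tables do not use).
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format metrics as whole-number percentages
#'
#' @param m a `metric_report` from [confusion_metrics()].
#' @return named numeric vector of percentages rounded half away from zero.
#' @export
metrics_pct <- function(m) {
  stopifnot(inherits(m, "metric_report"))
  vapply(c(sens = "sens", spec = "spec", ppv = "ppv", npv = "npv", acc = "acc"),
         function(k) round_half_up(100 * m[[k]]), numeric(1))
}

#' @export
print.metric_report <- function(x, ...) {
  p <- metrics_pct(x)
  cat(sprintf("<metric_report> sens %g%% spec %g%% ppv %g%% npv %g%% acc %g%%\n",
              p["sens"], p["spec"], p["ppv"], p["npv"], p["acc"]))
  invisible(x)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Cross-product odds ratio `(tp*tn)/(fn*fp)` with a log-scale (Woolf)
#' interval; a zero cell triggers the Haldane-Anscombe +0.5 correction to
#' all cells, flagged in the result.
#'
#' @param cm a [confusion_matrix()].
#' @return a list: `or`, `ci95`, `corrected`.
#' @export
odds_ratio <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cells <- c(cm$tp, cm$fn, cm$fp, cm$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  list(
    or = exp(log_or),
    ci95 = exp(log_or + c(-1, 1) * stats::qnorm(0.975) * se),
    corrected = corrected
  )
}

#' Cohen's kappa for predicted vs true severity
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with
#' `po` the observed agreement and `pe` the agreement expected from the
#' marginal prediction and truth rates.
#'
#' @param cm a [confusion_matrix()].
#' @return kappa (numeric scalar; `NA` with a warning when `pe = 1`).
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("chance agreement is 1; kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' AUC by the rank (Mann-Whitney) formula with tie correction
#'
#' The area under the empirical ROC equals the probability that a random
#' severe patient scores above a random non-severe one, ties counting
#' one half: `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` with `R1` the rank sum of
#' the severe scores (midranks for ties).
#'
#' @param scores numeric scores (higher = more likely severe).
#' @param labels logical, `TRUE` = severe.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hodges-Lehmann effect size for two groups
#'
#' The location shift reported alongside Mann-Whitney tests: the median of
#' all pairwise differences `x_i - y_j` (severe minus non-severe), with a
#' distribution-free 95% CI from the ordered pairwise differences at the
#' Mann-Whitney critical ranks (normal approximation).
#'
#' @param x numeric values in the severe group.
#' @param y numeric values in the non-severe group.
#' @param conf_level confidence level (default 0.95).
#' @return a list: `estimate`, `ci95`.
#' @export
hodges_lehmann <- function(x, y, conf_level = 0.95) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  d <- sort(as.vector(outer(x, y, "-")))
  mn <- length(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  k <- mn / 2 - z * sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  k <- max(1, floor(k))
  list(
    estimate = stats::median(d),
    ci95 = c(d[k], d[mn + 1 - k])
  )
}

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' Published screening tables report sensitivity and specificity as whole
#' percentages together with the group sizes; because the underlying
#' counts are integers, the table row determines the 2x2 exactly:
#' `tp = round(sens/100 * n_pos)`, `tn = round(spec/100 * n_neg)`
#' (half away from zero), with `fn`, `fp` as complements. This is the
#' bridge from a printed table row back to the counts its other columns
#' (predictive values, accuracy, odds ratio, kappa) derive from.
#'
#' @param sens_pct,spec_pct printed percentages in \[0, 100\].
#' @param n_pos,n_neg group sizes (severe / non-severe).
#' @return a [confusion_matrix()].
#' @examples
#' reconstruct_cm(90, 83, 21, 18)  # tp=19 fn=2 fp=3 tn=15
#' @export
reconstruct_cm <- function(sens_pct, spec_pct, n_pos, n_neg) {
  if (sens_pct < 0 || sens_pct > 100 || spec_pct < 0 || spec_pct > 100) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  tp <- round_half_up(sens_pct / 100 * n_pos)
  tn <- round_half_up(spec_pct / 100 * n_neg)
  confusion_matrix(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}
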