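#!/usr/bin/env Rscript

# Step 3: discovery-cohort model building.
#
# Dichotomizes each candidate predictor at its Youden-optimal cut-off,
# fits univariate logistic regressions for the dichotomized predictors,
# runs the bootstrapped logistic LASSO (50-sample resamples, 100 runs) to
# rank predictors by selection frequency, and evaluates the three
# screening models - anatomical, home sleep apnea test, and the weighted
# combined score 3x(ODI3>=6) + 2x(tonsil=4) + 1x(ANR>=0.78) with
# threshold >= 4 - against polysomnography severity.

library(pedosa)

seed <- 20210626 %% 10000
dir.create("results", showWarnings = FALSE)

cohort <- read_features_csv("results/cohort_discovery.csv")

## Youden cut-offs for the continuous predictors -----------------------------
cands <- c("odi3", "anr", "sse_801_1000", "osa18", "si")
cuts <- lapply(cands, function(f) youden_dichotomize(cohort[[f]], cohort$severe, f))
cut_tab <- do.call(rbind, lapply(cuts, function(d) data.frame(
  feature = d$feature_name, cutoff = signif(d$cutoff, 3), auc = round(d$auc, 2),
  sens_pct = round_half_up(100 * d$sens), spec_pct = round_half_up(100 * d$spec)
)))
write.csv(cut_tab, "results/table_youden_cutoffs.csv", row.names = FALSE)
cat("Youden-optimal cut-offs on this synthetic discovery cohort:\n")
print(cut_tab, row.names = FALSE)

## Univariate logistic models at the study's operating cut-offs --------------
feat <- dichotomize_cohort(cohort)
preds <- c("odi3_high", "anr_high", "tonsil4", "sse_high", "osa18_high")
uni <- do.call(rbind, lapply(preds, function(p) {
  f <- fit_univariate_logistic(feat[[p]], feat$severe)
  data.frame(predictor = p, or = round_half_up(f$or, 1),
             ci_lo = signif(f$ci95[1], 3), ci_hi = signif(f$ci95[2], 3),
             p = signif(f$p, 2), corrected = f$corrected)
}))
write.csv(uni, "results/table_univariate_logistic.csv", row.names = FALSE)
cat("\nUnivariate logistic odds ratios (operating cut-offs):\n")
print(uni, row.names = FALSE)

## LASSO bootstrap variable selection -----------------------------------------
x <- as.matrix(feat[, preds]) * 1
lp <- lasso_bootstrap(x, feat$severe, n_boot = 50, n_runs = 100, seed = seed)
sel <- data.frame(predictor = names(lp$selection_freq),
                  selection_freq = unname(lp$selection_freq))
sel <- sel[order(-sel$selection_freq), ]
write.csv(sel, "results/table_lasso_selection.csv", row.names = FALSE)
cat(sprintf("\nLASSO reference penalty %.4f carries %d active predictors: %s\n",
            lp$lambda_ref, length(lp$ref_features),
            paste(lp$ref_features, collapse = ", ")))
print(sel, row.names = FALSE)

## The three screening models --------------------------------------------------
models <- do.call(rbind, lapply(c("anatomical", "hsat", "combined"), function(nm) {
  ms <- model_spec(nm)
  sc <- score_cohort(feat, ms)
  cm <- confusion_from_predictions(sc$predicted_severe, feat$severe)
  p <- metrics_pct(confusion_metrics(cm))
  data.frame(model = nm, threshold = ms$threshold,
             auc = round(auc_rank(sc$score, feat$severe), 2),
             sens_pct = p["sens"], spec_pct = p["spec"], ppv_pct = p["ppv"],
             npv_pct = p["npv"], acc_pct = p["acc"])
}))
write.csv(models, "results/table_discovery_models.csv", row.names = FALSE)
cat("\nScreening-model performance on the synthetic discovery cohort:\n")
print(models, row.names = FALSE)
cat("\nWrote cut-off, logistic, LASSO and model tables under results/.\n")
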