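#!/usr/bin/env Rscript

# Step 1: generate the two synthetic study cohorts.
#
# The discovery cohort mirrors a case-matched design: 39 habitually snoring
# children, 21 with severe OSA (obstructive AHI >= 10 events/h) and 18
# non-severe, with severity-conditional distributions for the anatomical,
# questionnaire, polysomnography and home-sleep-apnea-test features. The
# validation cohort is 100 children (47 severe / 53 non-severe) with its
# own demographic and oximetry structure. Writes per-patient feature tables
# and a median/IQR group-summary table with Hodges-Lehmann effect sizes and
# Mann-Whitney / Fisher p-values.

library(pedosa)
suppressPackageStartupMessages(library(dplyr))

seed <- 20210626 %% 10000  # master seed for the analysis workflow
dir.create("results", showWarnings = FALSE)

discovery <- generate_cohort(cohort_params_study1(39), seed = seed)
validation <- generate_cohort(cohort_params_study2(100), seed = seed + 1)

write_features_csv(discovery, "results/cohort_discovery.csv")
write_features_csv(validation, "results/cohort_validation.csv")

summarize_cohort <- function(coh, features) {
  rows <- lapply(features, function(f) {
    x <- coh[[f]][coh$severe]
    y <- coh[[f]][!coh$severe]
    hl <- hodges_lehmann(x, y)
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    q <- function(v) sprintf("%.2f (%.2f-%.2f)", median(v),
                             quantile(v, 0.25), quantile(v, 0.75))
    tibble(
      feature = f, severe = q(x), non_severe = q(y),
      effect_size = sprintf("%.2f (%.2f-%.2f)", hl$estimate, hl$ci95[1], hl$ci95[2]),
      p_value = signif(p, 2)
    )
  })
  bind_rows(rows)
}

feat1 <- c("age", "bmi_z", "osa18", "tonsil", "anr", "obstructive_ahi",
           "obstructive_ai", "odi3", "si", "sse_801_1000")
tab1 <- summarize_cohort(discovery, feat1)
sex_p <- fisher.test(table(discovery$sex, discovery$severe))$p.value
write.csv(tab1, "results/table_discovery_characteristics.csv", row.names = FALSE)

feat2 <- c("age", "bmi_z", "tonsil", "anr", "obstructive_ahi",
           "obstructive_ai", "odi3")
tab2 <- summarize_cohort(validation, feat2)
write.csv(tab2, "results/table_validation_characteristics.csv", row.names = FALSE)

cat(sprintf(
  "Discovery cohort: %d children (%d severe / %d non-severe), Fisher p (sex) = %.2f\n",
  nrow(discovery), sum(discovery$severe), sum(!discovery$severe), sex_p
))
print(as.data.frame(tab1), right = FALSE)
cat(sprintf(
  "\nValidation cohort: %d children (%d severe / %d non-severe)\n",
  nrow(validation), sum(validation$severe), sum(!validation$severe)
))
print(as.data.frame(tab2), right = FALSE)
cat("\nWrote results/cohort_discovery.csv, results/cohort_validation.csv and summary tables.\n")
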