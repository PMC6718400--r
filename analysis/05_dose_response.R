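#!/usr/bin/env Rscript
# Step 5: dose-response analysis.
#
# Pools both batches' predicted viability percentages (per-batch controls
# averaged into the zero-dose anchor), fits the four-parameter log-logistic,
# and compares per-condition predictions against the reference viability
# assay used to parameterize the generator. Also fits the published
# viability table itself for comparison.

suppressMessages(library(ramanviability))
dir.create("results", showWarnings = FALSE)

st <- readRDS("scratch/classifier.rds")
pred <- st$pred

pooled <- pool_dose_response(pred$per_condition)
fit_syn <- fit_ic50(pooled$dose, pooled$percent_viable)

tab <- dox_viability_table()
fit_tab <- fit_ic50(pool_dose_response(
  data.frame(dose = tab$dose, batch = tab$batch,
             percent_viable = tab$raman_percent))$dose,
  pool_dose_response(
    data.frame(dose = tab$dose, batch = tab$batch,
               percent_viable = tab$raman_percent))$percent_viable)

cmp <- compare_assays(pred,
                      data.frame(condition_label = tab$condition_label,
                                 batch = tab$batch,
                                 reference_percent = tab$reference_percent))

write.csv(cmp$rows, "results/05_assay_comparison.csv", row.names = FALSE)
write.csv(data.frame(
  dataset = c("synthetic_pipeline", "published_table"),
  ic50_um = c(fit_syn$ic50, fit_tab$ic50),
  slope = c(fit_syn$slope, fit_tab$slope),
  lower = c(fit_syn$lower, fit_tab$lower),
  upper = c(fit_syn$upper, fit_tab$upper),
  rss = c(fit_syn$rss, fit_tab$rss)),
  "results/05_dose_response.csv", row.names = FALSE)

cat("IC50 of the synthetic pipeline run:", format(fit_syn$ic50, digits = 3),
    "uM\n")
cat("IC50 of the published viability table:", format(fit_tab$ic50, digits = 3),
    "uM\n")
cat("Max |Raman - assay| deviation:", round(cmp$max_abs_deviation, 1),
    "points; mean:", round(mean(abs(cmp$rows$deviation)), 1), "points\n")
cat("Wrote results/05_dose_response.csv and results/05_assay_comparison.csv\n")
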