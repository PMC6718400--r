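#!/usr/bin/env Rscript
# Step 4: PCA-SVM viability classification.
#
# PCA on the batch-2 training conditions (control + 1 uM), linear SVM on the
# first two PC scores with condition-level labels, 10-fold cross-validated
# cost, then prediction of per-condition viable percentages for both
# batches. Also reconstructs the decision-threshold spectrum along a line
# parallel to PC1 through the median PC2 score.

suppressMessages(library(ramanviability))
dir.create("results", showWarnings = FALSE)

pp <- readRDS("scratch/preprocessed.rds")
cls <- train_classifier(pp, train_batch = 2L, control_label = "control",
                        highdose_label = "1 uM", n_components = 2,
                        folds = 10, seed = 7L)
pred <- predict_viability(pp, cls$pca, cls$svm)

write.csv(pred$per_condition, "results/04_viability_predictions.csv",
          row.names = FALSE)
model_summary <- data.frame(
  quantity = c("explained_variance_pc1_percent", "explained_variance_pc2_percent",
               "explained_variance_first_two_percent", "cv_cost_percent",
               "svm_weight_pc1", "svm_weight_pc2", "svm_bias"),
  value = c(100 * cls$pca$explained_variance_ratio[1],
            100 * cls$pca$explained_variance_ratio[2],
            100 * sum(cls$pca$explained_variance_ratio),
            100 * cls$svm$cv_cost,
            cls$svm$weights, cls$svm$bias))
write.csv(model_summary, "results/04_model_summary.csv", row.names = FALSE)

bnd <- boundary_spectra(cls$pca, cls$svm,
                        pc2_value = median(pred$scores[, 2]),
                        pc1_range = range(pred$scores[, 1]), n_points = 7)
saveRDS(list(cls = cls, pred = pred, boundary = bnd), "scratch/classifier.rds")

cat("First two PCs explain",
    round(100 * sum(cls$pca$explained_variance_ratio), 2),
    "% of the spectral variance (PC1",
    round(100 * cls$pca$explained_variance_ratio[1], 2), "%, PC2",
    round(100 * cls$pca$explained_variance_ratio[2], 2), "%).\n")
cat("10-fold CV cost:", round(100 * cls$svm$cv_cost, 2), "%\n")
print(pred$per_condition)
cat("Decision-threshold spectrum crosses at PC1 =",
    format(bnd$crossing["PC1"], digits = 4), "\n")
cat("Wrote results/04_viability_predictions.csv and results/04_model_summary.csv\n")
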