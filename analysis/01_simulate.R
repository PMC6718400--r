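#!/usr/bin/env Rscript
# Step 1: synthesize the study dataset.
#
# Two biological replicates of a doxorubicin dose ladder on THP-1-like cells
# (0, 0.05, 0.1, 0.5, 1 uM plus a trailing control per batch), 1000 cells per
# well. Ground-truth viable fractions follow the reference-assay column of
# the published viability table, so the downstream chain can be judged
# against known truth. Raw spectra go to scratch/ (they are large and fully
# reproducible from the seed); the per-well accounting table goes to results/.

suppressMessages(library(ramanviability))
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

tab <- dox_viability_table()
labels <- c("control", "0.05 uM", "0.1 uM", "0.5 uM", "1 uM", "control (end)")
doses <- c(0, 0.05, 0.1, 0.5, 1, 0)

batches <- lapply(1:2, function(b) {
  simulate_dose_ladder(doses,
                       viable_fractions = tab$reference_percent[tab$batch == b] / 100,
                       n_cells = 1000, labels = labels, batch = b,
                       seed = 5000L + 100L * b)$spectra
})
s <- batches[[1]]
s$intensities <- do.call(rbind, lapply(batches, `[[`, "intensities"))
s$meta <- do.call(rbind, lapply(batches, `[[`, "meta"))
rownames(s$meta) <- NULL
s$provenance <- list()

write_spectra(s, "scratch/data/raw_spectra.tsv", "scratch/data/raw_spectra.json")

counts <- aggregate(list(n_cells = s$meta$dose),
                    by = list(condition_label = s$meta$condition_label,
                              batch = s$meta$batch), FUN = length)
counts <- counts[order(counts$batch), ]
write.csv(counts, "results/01_cell_counts.csv", row.names = FALSE)

cat("Simulated", n_spectra(s), "spectra x", n_channels(s), "channels,",
    length(unique(s$meta$condition_label)), "conditions x 2 batches.\n")
cat("True empty-detection fraction:",
    round(mean(s$meta$ground_truth_label == "empty"), 4), "\n")
cat("Wrote scratch/data/raw_spectra.{tsv,json} and results/01_cell_counts.csv\n")
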