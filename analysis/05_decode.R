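#!/usr/bin/env Rscript
# Step 5: edge vs surface decoding — train the L1-regularized logistic
# decoder on per-site gamma-power triplets and on MUA-rate time-bin
# triplets, and trace accuracy against the number of sites. Reads
# results/data/edge_surface_*.csv; writes accuracy tables.

suppressPackageStartupMessages(library(gammatrio))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

load_ds <- function(kind) {
  tab <- utils::read.csv(sprintf("results/data/edge_surface_%s.csv",
                                 kind))
  decode_dataset(as.matrix(tab[, -(1:2)]), tab$label, kind)
}
pools <- list(gamma = load_ds("gamma"), mua = load_ds("mua"))

single <- lapply(pools, function(ds)
  train_decoder(subset_sites(ds, 1), lambda = 0.1, seed = seed))
cat(sprintf("single-site test accuracy: gamma %.1f%%, MUA %.1f%%\n",
            100 * single$gamma$test_accuracy,
            100 * single$mua$test_accuracy))

curve <- accuracy_vs_nsites(pools, counts = c(1, 2, 4, 8), repeats = 10,
                            seed = seed)
utils::write.csv(curve, "results/decoding_accuracy.csv",
                 row.names = FALSE)
print(curve, row.names = FALSE)
cat("gamma-power features should outperform MUA rates at every count\n")

sel <- train_decoder(pools$gamma, seed = seed)  # lambda selected on grid
cat(sprintf("all-site gamma decoder: lambda %.3g, accuracy %.1f%%\n",
            sel$lambda, 100 * sel$test_accuracy))
jsonlite::write_json(list(lambda = sel$lambda, w0 = sel$w0, W = sel$W,
                          test_accuracy = sel$test_accuracy),
                     "results/decoder_model.json", auto_unbox = TRUE,
                     digits = NA)
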