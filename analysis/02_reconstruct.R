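#!/usr/bin/env Rscript
# Step 2: reconstruct one relevance network per recording.
#
# Whole-series Pearson correlation, coefficient histograms, r > 0.8
# thresholding with a 0.75-0.85 robustness sweep, and a shuffle
# permutation null for link significance. Also fits the shrinkage partial
# correlation as the conditional-independence view of the same recording.

suppressPackageStartupMessages(library(brainplex))

seed <- 20260930L
indir <- "results/data"
out <- "results/reconstruction"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (nm in c("sleepA", "sleepB", "dream")) {
  ts <- read_feature_timeseries(file.path(indir, paste0(nm, ".tsv")),
                                state_label = nm)
  sim <- compute_similarity(ts)
  write_similarity_csv(sim, file.path(out, paste0("similarity_", nm, ".csv")))
  h <- summarize_coefficients(sim, bins = 40)
  utils::write.csv(h, file.path(out, paste0("coefficient_hist_", nm, ".csv")),
                   row.names = FALSE)
  message(nm, ": ", sum(h$count), " unordered pairs; ",
          sum(h$count[h$lower >= 0.75]), " with r > 0.75")

  net <- threshold_network(sim, 0.8, state_label = nm)
  write_adjacency_csv(net, file.path(out, paste0("network_", nm, "_adjacency.csv")))
  write_edge_list(net, file.path(out, paste0("network_", nm, "_edges.tsv")))
  write_layer_graphml(net, file.path(out, paste0("network_", nm, ".graphml")))

  sw <- as.data.frame(threshold_sweep(sim, 0.75, 0.85, 0.05))
  utils::write.csv(sw, file.path(out, paste0("sweep_", nm, ".csv")), row.names = FALSE)
  message(nm, ": ", network_edge_count(net), " links at r > 0.8; sweep Jaccard ",
          paste(round(sw$jaccard_prev[-1], 3), collapse = ", "))

  # 999 permutations so the smallest attainable p (1/1000) can survive BH
  # across all 7260 pairs
  ls <- adjust_link_significance(
    permutation_null(ts, n_permutations = 999, null_mode = "shuffle",
                     seed = seed + match(nm, c("sleepA", "sleepB", "dream"))))
  sig <- ls$q_values[upper.tri(ls$q_values)] <= 0.05
  message(nm, ": ", sum(sig), " links significant at FDR 0.05 (of ",
          length(sig), " pairs)")

  pc <- compute_partial_correlation(ts, shrinkage = "auto")
  write_similarity_csv(pc, file.path(out, paste0("partial_", nm, ".csv")))
  message(nm, ": partial correlation at auto shrinkage ",
          signif(attr(pc, "shrinkage"), 3))
}
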