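#!/usr/bin/env Rscript
# Step 3: assemble the three thresholded layers into a multiplex and
# quantify how much network structure the brain states share.

suppressPackageStartupMessages(library(brainplex))

indir <- "results/reconstruction"
out <- "results/multiplex"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

names <- c("sleepA", "sleepB", "dream")
layers <- lapply(names, function(nm) {
  read_adjacency_csv(file.path(indir, paste0("network_", nm, "_adjacency.csv")),
                     threshold = 0.8, state_label = nm)
})
mx <- build_multiplex(layers, layer_names = names)

pairs <- utils::combn(names, 2)
report <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(ci) {
  ov <- layer_overlap(mx, pairs[1, ci], pairs[2, ci])
  data.frame(layer_a = pairs[1, ci], layer_b = pairs[2, ci],
             shared_ordered_pairs = ov$shared_ordered_pairs,
             possible_ordered_pairs = ov$possible_ordered_pairs,
             overlap_pct = 100 * ov$overlap_fraction,
             jaccard = ov$jaccard)
}))
utils::write.csv(report, file.path(out, "overlap_report.csv"), row.names = FALSE)
message("pairwise layer overlap (% of N(N-1) ordered pairs):")
print(report, row.names = FALSE)

utils::write.csv(as.data.frame(degree_vectors(mx)),
                 file.path(out, "degree_vectors.csv"))
for (metric in c("overlap_fraction", "jaccard")) {
  utils::write.csv(layer_similarity_matrix(mx, metric),
                   file.path(out, paste0("layer_similarity_", metric, ".csv")))
}

# map a held-out recording (same state as sleepA/B) onto the library
tpl_sleep <- generate_state_template(121, 11, rho_within = 0.9, layout = "contiguous")
held_out <- simulate_feature_timeseries(tpl_sleep, 500, seed = 20269999L,
                                        state_label = "held_out")
query <- threshold_network(compute_similarity(held_out), 0.8)
ranking <- match_state(query, mx, metric = "jaccard")
utils::write.csv(ranking, file.path(out, "match_state_ranking.csv"), row.names = FALSE)
message("held-out sleep recording maps to: ",
        paste(sprintf("%s (%.3f)", ranking$layer_name, ranking$similarity),
              collapse = ", "))
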