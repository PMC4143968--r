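#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Three 121-feature recordings (T = 500, ~1 Hz): two from the same
# "sleep-like" state (contiguous co-activation blocks, rho = 0.9) and one
# from a "dream-like" state whose blocks cut across the first partition so
# the two states share no planted feature pair. Also a synthetic gene
# universe with six overlapping pathways and a DE excess planted in the
# S1-S2 intersection for the pathway-crosstalk step.

suppressPackageStartupMessages(library(brainplex))

seed <- 20260930L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tpl_sleep <- generate_state_template(121, 11, rho_within = 0.9, layout = "contiguous")
tpl_dream <- generate_state_template(121, 11, rho_within = 0.9, layout = "interleaved")
message("states share a fraction ",
        template_coblock_fraction(tpl_sleep, tpl_dream),
        " of co-blocked feature pairs (0 = fully distinct co-activation)")

recs <- list(sleepA = list(tpl = tpl_sleep, seed = seed + 1L),
             sleepB = list(tpl = tpl_sleep, seed = seed + 2L),
             dream  = list(tpl = tpl_dream, seed = seed + 3L))
for (nm in names(recs)) {
  ts <- simulate_feature_timeseries(recs[[nm]]$tpl, 500,
                                    seed = recs[[nm]]$seed, state_label = nm)
  write_feature_timeseries(ts, file.path(out, paste0(nm, ".tsv")))
  message("wrote ", nm, ".tsv  (", nrow(ts$values), " x ", ncol(ts$values), ")")
}

ov <- matrix(0, 6, 6)
for (i in 1:5) ov[i, i + 1] <- ov[i + 1, i] <- 0.3
gu <- generate_gene_universe(
  1000, c(S1 = 100, S2 = 100, S3 = 100, S4 = 100, S5 = 100, S6 = 100),
  overlap_fractions = ov, n_de = 100,
  enrichment_plan = list(list(sets = c("S1", "S2"), odds_ratio = 10)),
  seed = seed + 4L
)
write_gmt(gu, file.path(out, "pathways.gmt"))
write_de_list(gu$de_genes, file.path(out, "de_genes.txt"))
message("wrote pathways.gmt (", length(gu$sets), " sets) and de_genes.txt (",
        length(gu$de_genes), " genes; excess planted in S1 ∩ S2)")
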