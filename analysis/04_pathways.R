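#!/usr/bin/env Rscript
# Step 4: pathway over-representation and the intersection (crosstalk)
# network on the synthetic gene universe from step 1.

suppressPackageStartupMessages(library(brainplex))

indir <- "results/data"
out <- "results/pathways"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gsc <- read_gmt(file.path(indir, "pathways.gmt"))
# the GMT only lists genes that belong to some set; restore the full
# simulated universe as the background
universe <- sprintf("g%05d", 1:1000)
gsc <- gene_set_collection(universe, gsc$sets)
de <- read_de_list(file.path(indir, "de_genes.txt"))

enr <- enrich_sets(gsc, de)
utils::write.csv(enr, file.path(out, "set_enrichment.csv"), row.names = FALSE)
message("per-set enrichment (one-sided Fisher, BH):")
print(enr, row.names = FALSE, digits = 3)

pn <- intersection_network(gsc, de, alpha = 0.05, min_intersection = 1)
utils::write.csv(pn$tests, file.path(out, "intersection_tests.csv"), row.names = FALSE)
write_pathway_graphml(pn, file.path(out, "pathway_network.graphml"))
message(nrow(pn$tests), " pathway pairs tested; ", nrow(pn$edges),
        " significant intersection(s) at FDR 0.05")

if (nrow(pn$edges)) {
  for (i in seq_len(nrow(pn$edges))) {
    a <- pn$edges$set_a[i]; b <- pn$edges$set_b[i]
    ig <- interface_genes(gsc, a, b, de_genes = de)
    utils::write.table(ig, file.path(out, paste0("interface_", a, "_", b, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    message("interface ", a, " ~ ", b, ": ", nrow(ig), " genes, ",
            sum(ig$de), " DE")
  }
}
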