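#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the three-species pangenome design (barley 2x/20 lines, wild
# emmer 4x/20 lines, bread wheat 6x/15 lines) under the logistic dosage
# loss model, plus a genome layout with planted duplication events and a
# GO annotation set with one planted enriched term. Everything downstream
# (02-06) reads the files written here.

suppressMessages(library(panretain))

seed <- 7
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sim <- gen_pangenome(n_ogs = 300, seed = seed)
write_hog_table(sim$hogs, file.path(outdir, "hogs.tsv"))
for (sp in names(sim$pavs)) {
  write_pav_matrix(sim$pavs[[sp]], file.path(outdir, paste0("pav_", sp, ".csv")))
}
utils::write.table(sim$truth, file.path(outdir, "truth_retention.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

lay <- gen_genome_layout(n_chrom = 4, genes_per_chrom = 80,
                         events = c(tandem = 2, proximal = 2,
                                    dispersed = 2, wgd = 1),
                         seed = seed + 1)
utils::write.table(lay$loci, file.path(outdir, "loci.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(lay$hits, file.path(outdir, "hits.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(lay$truth, file.path(outdir, "truth_dup.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

go <- gen_go(n_genes = 20000, n_terms = 25, query = 300, fold = 5,
             base_prob_range = c(0.01, 0.02), seed = seed + 2)
utils::write.table(go$annotation, file.path(outdir, "go_annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(go$query, file.path(outdir, "go_query.txt"))
writeLines(go$truth$planted_term, file.path(outdir, "go_planted_term.txt"))

cat("Synthetic study written to", outdir, "\n")
cat("  HOGs:", nrow(sim$hogs), "in", length(unique(sim$hogs$og_id)), "OGs\n")
cat("  Planted duplication events:", nrow(lay$hits), "hit pairs\n")
cat("  GO terms:", length(unique(go$annotation$term_id)),
    "(planted:", go$truth$planted_term, ")\n")
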