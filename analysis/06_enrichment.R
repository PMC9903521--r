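#!/usr/bin/env Rscript
# Stage 6: GO over-representation of the planted query set and the
# term-overlap network.

suppressMessages(library(panretain))

indir <- "results/synthetic"
annot <- read_annotation(file.path(indir, "go_annotation.tsv"))
query <- readLines(file.path(indir, "go_query.txt"))
planted <- readLines(file.path(indir, "go_planted_term.txt"))

res <- enrich(query, annot)
utils::write.table(res, "results/go_enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Top 5 terms by raw p:\n")
print(res[1:5, c("term_id", "K", "k", "p_value", "p_adjust", "score",
                 "significant")], row.names = FALSE)
rank_planted <- which(res$term_id == planted)
cat(sprintf("\nPlanted term %s ranked %d of %d (score %.2f, significant: %s)\n",
            planted, rank_planted, nrow(res), res$score[rank_planted],
            res$significant[rank_planted]))

# overlap network over the significant terms
sig <- res$term_id[res$significant]
sets <- lapply(sig, function(tm) unique(annot$gene_id[annot$term_id == tm]))
names(sets) <- sig
edges <- term_overlap(sets)
utils::write.table(edges, "results/go_term_network.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Term-overlap network: %d nodes, %d edges\n",
            length(sets), nrow(edges)))
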