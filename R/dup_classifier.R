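# Duplication-type classification: filter homology hits, chain collinear
# anchors into blocks, and assign every gene one of
# singleton / dispersed / proximal / tandem / wgd_segmental.

#' Filter raw homology hits
#'
#' Removes self-hits, applies the E-value cutoff, and keeps the top-n best
#' hits per query (ranked by E-value, ties broken by bit score then subject
#' id, so the result is deterministic).
#'
#' @param hits data.frame with columns `query`, `subject`, `e_value`,
#'   `bit_score` (a BLAST outfmt-6 table reduced to these columns).
#' @param e_cutoff Maximum E-value retained; default `1e-5`.
#' @param top_n Hits kept per query; default 5.
#' @return Filtered data.frame (possibly empty).
#' @export
filter_hits <- function(hits, e_cutoff = 1e-5, top_n = 5L) {
  hits <- hits[hits$query != hits$subject & hits$e_value <= e_cutoff, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$e_value, -hits$bit_score, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along) <= top_n
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tabular BLAST hit file (outfmt 6)
#'
#' @param path 12-column tab-separated BLAST output.
#' @return data.frame with `query`, `subject`, `pident`, `length`,
#'   `e_value`, `bit_score` (other columns dropped).
#' @export
read_blast_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "e_value", "bit_score")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L) stop("expected 12 columns of BLAST outfmt 6, got ", ncol(df))
  names(df) <- cols
  df[, c("query", "subject", "pident", "length", "e_value", "bit_score")]
}

#' Chain collinear anchors into blocks
#'
#' Dynamic-programming chaining of anchor pairs (gene ranks in two genomic
#' regions) into maximal collinear blocks. A chain must be strictly
#' increasing in the first genome's rank and strictly monotone in the
#' second (increasing for same orientation, decreasing for inverted), with
#' consecutive anchors at most `max_gap_genes` ranks apart in both genomes.
#' Chain length is the score; the best chain is extracted first and its
#' anchors removed before searching again, so each anchor belongs to at
#' most one block. Chains shorter than `min_block_size` are dropped.
#'
#' @param anchors data.frame with columns `chrom_a`, `rank_a`, `chrom_b`,
#'   `rank_b` (and optionally `gene_a`, `gene_b`).
#' @param min_block_size Minimum anchors per reported block; default 5.
#' @param max_gap_genes Maximum rank gap between consecutive anchors;
#'   default 25.
#' @return List of blocks; each block is a list with `anchors` (the rows of
#'   `anchors` in chain order), `chrom_a`, `chrom_b`, `orientation`
#'   (`"same"` or `"inverted"`), and `n_anchors`.
#' @export
detect_collinear_blocks <- function(anchors, min_block_size = 5L,
                                    max_gap_genes = 25L) {
  blocks <- list()
  if (is.null(anchors) || nrow(anchors) == 0L) return(blocks)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (k in unique(key)) {
    sub <- anchors[key == k, , drop = FALSE]
    repeat {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- .best_chain(sub$rank_a, sub$rank_b, orient, max_gap_genes)
        if (length(ch) > length(best$idx %||% integer(0))) {
          best <- list(idx = ch, orientation = orient)
        }
      }
      if (is.null(best) || length(best$idx) < min_block_size) break
      blk <- sub[best$idx, , drop = FALSE]
      rownames(blk) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        anchors = blk, chrom_a = blk$chrom_a[1], chrom_b = blk$chrom_b[1],
        orientation = best$orientation, n_anchors = nrow(blk))
      sub <- sub[-best$idx, , drop = FALSE]
      if (nrow(sub) == 0L) break
    }
  }
  blocks
}

# O(n^2) longest-chain DP over anchors for one chromosome pair and
# orientation; returns row indices of the best chain in chain order.
.best_chain <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  if (n == 0L) return(integer(0))
  ord <- order(ra, if (orientation == "same") rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  len <- rep(1L, n); prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- if (orientation == "same") rb[j] - rb[i] else rb[i] - rb[j]
      if (da >= 1L && db >= 1L && da <= max_gap && db <= max_gap &&
          len[i] + 1L > len[j]) {
        len[j] <- len[i] + 1L
        prev[j] <- i
      }
    }
  }
  j <- which.max(len)
  chain <- integer(0)
  while (j != 0L) { chain <- c(j, chain); j <- prev[j] }
  ord[chain]
}

#' Classify gene duplication types
#'
#' Assigns each gene in `loci` one of `singleton`, `dispersed`, `proximal`,
#' `tandem`, `wgd_segmental`. A gene with no retained (filtered) hit is a
#' singleton. Otherwise the gene gets the highest-precedence class over its
#' hits, with precedence `wgd_segmental > tandem > proximal > dispersed`:
#' anchor of a collinear block is WGD/segmental; a hit partner at adjacent
#' rank on the same chromosome is tandem; within `proximal_window` ranks is
#' proximal; anything else is dispersed. Hits are symmetrized, so the two
#' genes of a pair see the same evidence regardless of hit direction.
#'
#' @param loci data.frame from [gene_ranks()]/[read_gff_gene_loci()].
#' @param hits Filtered hit table ([filter_hits()]).
#' @param blocks Output of [detect_collinear_blocks()]; the anchors'
#'   `gene_a`/`gene_b` columns identify block member genes.
#' @param proximal_window Maximum rank separation counted as proximal;
#'   default 10.
#' @return data.frame `gene_id`, `class` (factor over the five classes).
#' @export
classify_duplicates <- function(loci, hits, blocks = list(),
                                proximal_window = 10L) {
  genes <- loci$gene_id
  unknown <- setdiff(unique(c(hits$query, hits$subject)), genes)
  if (length(unknown) > 0L) {
    stop("hit references unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  chrom <- stats::setNames(loci$chrom, genes)
  rank <- stats::setNames(loci$rank, genes)
  anchor_genes <- unique(unlist(lapply(blocks, function(b) {
    c(b$anchors$gene_a, b$anchors$gene_b)
  })))
  # symmetric hit pairs
  pairs <- unique(rbind(data.frame(a = hits$query, b = hits$subject,
                                   stringsAsFactors = FALSE),
                        data.frame(a = hits$subject, b = hits$query,
                                   stringsAsFactors = FALSE)))
  cls <- rep("singleton", length(genes))
  names(cls) <- genes
  prec <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3,
            wgd_segmental = 4)
  if (nrow(pairs) > 0L) {
    same <- chrom[pairs$a] == chrom[pairs$b]
    dr <- abs(rank[pairs$a] - rank[pairs$b])
    pair_cls <- ifelse(same & dr == 1L, "tandem",
                ifelse(same & dr >= 2L & dr <= proximal_window, "proximal",
                       "dispersed"))
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$a[i]
      if (prec[pair_cls[i]] > prec[cls[g]]) cls[g] <- pair_cls[i]
    }
  }
  hit_genes <- unique(pairs$a)
  is_anchor <- genes %in% anchor_genes & genes %in% hit_genes
  cls[is_anchor] <- "wgd_segmental"
  data.frame(gene_id = genes,
             class = factor(cls, levels = names(prec)),
             stringsAsFactors = FALSE)
}

#' Duplication-class composition
#'
#' @param table Output of [classify_duplicates()].
#' @return Named numeric vector of percentages (summing to 100) over the
#'   classes present.
#' @export
class_composition <- function(table) {
  if (nrow(table) == 0L) stop("empty classification table")
  tab <- base::table(droplevels(table$class))
  stats::setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}
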