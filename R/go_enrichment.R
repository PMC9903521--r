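# Hypergeometric over-representation tests with Benjamini-Hochberg
# control, enrichment scores, and term-overlap network edges.

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a universe of `N` genes of which `K`
#' carry the term: `P[X >= k]`.
#'
#' @param k Observed overlap (query genes with the term).
#' @param K Genes in the universe carrying the term.
#' @param n Query size.
#' @param N Universe size.
#' @return The exact tail probability.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || any(c(k, K, n, N) < 0)) {
    stop("invalid hypergeometric bounds (need k <= min(K, n), K <= N, n <= N)")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' Tests every term with at least one annotated gene in the universe for
#' over-representation in the query set. The enrichment score is
#' `-log10(raw p)`; significance is called on the BH-adjusted p at
#' `threshold`.
#'
#' @param query Character vector of query gene ids.
#' @param annotation data.frame with columns `gene_id`, `term_id`, and
#'   optionally `term_name`, `namespace`.
#' @param universe Character vector of universe gene ids; defaults to all
#'   genes in the annotation table.
#' @param threshold Adjusted-p significance threshold; default 0.05.
#' @return data.frame with one row per term: `term_id`, `term_name`,
#'   `namespace`, `K`, `k`, `p_value`, `p_adjust`, `score`, `significant`,
#'   sorted by `p_value`.
#' @export
enrich <- function(query, annotation, universe = NULL, threshold = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  universe <- unique(universe)
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  query <- unique(intersect(query, universe))
  N <- length(universe)
  n <- length(query)
  terms <- unique(annotation$term_id)
  res <- lapply(terms, function(tm) {
    sub <- annotation[annotation$term_id == tm, , drop = FALSE]
    genes <- unique(sub$gene_id)
    K <- length(genes)
    k <- length(intersect(genes, query))
    data.frame(term_id = tm,
               term_name = if ("term_name" %in% names(sub)) sub$term_name[1] else tm,
               namespace = if ("namespace" %in% names(sub)) sub$namespace[1] else NA,
               K = K, k = k,
               p_value = hypergeom_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjust <- bh_adjust(out$p_value)
  out$score <- -log10(out$p_value)
  out$significant <- out$p_adjust < threshold
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Term-overlap network edges
#'
#' For every pair of terms, the number of shared genes; pairs with zero
#' overlap are omitted. These edges drive the enriched-term network view.
#'
#' @param term_genes Named list of character vectors (term -> gene set).
#' @return data.frame `term_a`, `term_b`, `overlap` (term_a < term_b).
#' @export
term_overlap <- function(term_genes) {
  terms <- names(term_genes)
  out <- list()
  if (length(terms) >= 2L) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in seq(i + 1L, length(terms))) {
        ov <- length(intersect(term_genes[[i]], term_genes[[j]]))
        if (ov > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            term_a = terms[i], term_b = terms[j], overlap = ov,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(term_a = character(0), term_b = character(0),
                      overlap = integer(0)))
  }
  do.call(rbind, out)
}

#' Read a gene-to-GO annotation table
#'
#' @param path Tab-separated file with columns `gene_id`, `term_id`,
#'   `term_name`, `namespace`.
#' @return data.frame of the annotation.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns gene_id, term_id")
  }
  df
}
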