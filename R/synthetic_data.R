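# Seeded generators emulating every input the pipeline consumes, each with
# ground truth attached: pangenome presence/absence under a dosage-and-
# family-size loss model, genome layouts with planted duplication events,
# codon alignments evolved under branch- or site-specific omega, and GO
# annotation sets with a planted enriched term.

#' Default species panel
#'
#' Three-species panel mirroring a diploid/tetraploid/hexaploid pangenome
#' study design: 20, 20 and 15 lines at ploidy 2, 4 and 6.
#'
#' @return data.frame with columns `name`, `ploidy`, `n_lines`.
#' @export
default_panel <- function() {
  data.frame(name = c("barley", "emmer", "wheat"),
             ploidy = c(2L, 4L, 6L),
             n_lines = c(20L, 20L, 15L),
             stringsAsFactors = FALSE)
}

#' Logistic gene-loss model
#'
#' Retention probability of a gene in one pangenome line:
#' `p = logistic(beta0 - beta_family * (f - 1) - beta_ploidy * (ploidy/2 - 1)
#' - beta_interact * (f - 1) * (ploidy/2 - 1))`
#' where `f` is the gene-family size (HOGs under the parent OG). Positive
#' `beta_family` and `beta_ploidy` encode the dosage-constraint hypothesis:
#' more redundant copies (larger families, higher ploidy) mean weaker
#' constraint on each copy and a higher loss probability.
#'
#' @param beta0 Baseline logit of retention.
#' @param beta_family Penalty per extra HOG in the OG (>= 0).
#' @param beta_ploidy Penalty per extra genome copy set (>= 0).
#' @param beta_interact Optional family-by-ploidy interaction (>= 0).
#' @return A `loss_model` list.
#' @export
loss_model <- function(beta0 = 2.5, beta_family = 0.35, beta_ploidy = 0.9,
                       beta_interact = 0) {
  if (beta_family < 0 || beta_ploidy < 0 || beta_interact < 0) {
    stop("penalty coefficients must be >= 0")
  }
  structure(list(beta0 = beta0, beta_family = beta_family,
                 beta_ploidy = beta_ploidy, beta_interact = beta_interact),
            class = "loss_model")
}

#' Retention probability under a loss model
#' @param loss A [loss_model()].
#' @param family_size Gene-family size (>= 1).
#' @param ploidy Genome ploidy (2, 4, 6, ...).
#' @return Retention probability in (0, 1).
#' @export
retention_prob <- function(loss, family_size, ploidy) {
  stats::plogis(loss$beta0 -
                  loss$beta_family * (family_size - 1) -
                  loss$beta_ploidy * (ploidy / 2 - 1) -
                  loss$beta_interact * (family_size - 1) * (ploidy / 2 - 1))
}

#' Generate a synthetic pangenome
#'
#' Draws orthogroup family sizes (number of HOGs per OG) from a truncated
#' geometric distribution, builds a HOG table with one gene per species per
#' HOG, and samples per-line presence calls independently with the
#' retention probability given by the loss model. Fully reproducible under
#' the seed.
#'
#' @param panel Species panel ([default_panel()] layout).
#' @param n_ogs Number of parent orthogroups; default 300.
#' @param loss A [loss_model()].
#' @param family_geom_prob Success probability of the geometric family-size
#'   distribution (default 0.5, mean 2).
#' @param family_max Truncation point of family size; default 12.
#' @param seed Integer seed.
#' @return List with `hogs` (a `hog_table`), `pavs` (named list of
#'   `pav_matrix`), and `truth` (data.frame of per-HOG family size and true
#'   retention probability per species).
#' @export
gen_pangenome <- function(panel = default_panel(), n_ogs = 300L,
                          loss = loss_model(), family_geom_prob = 0.5,
                          family_max = 12L, seed = 1L) {
  stopifnot(all(panel$n_lines >= 1L))
  set.seed(seed)
  fam <- stats::rgeom(n_ogs, prob = family_geom_prob) + 1L
  while (any(fam > family_max)) {            # re-draw beyond truncation
    idx <- fam > family_max
    fam[idx] <- stats::rgeom(sum(idx), prob = family_geom_prob) + 1L
  }
  og_ids <- sprintf("OG%06d", seq_len(n_ogs))
  hog_og <- rep(og_ids, fam)
  hog_fam <- rep(fam, fam)
  n_hogs <- length(hog_og)
  hog_ids <- sprintf("N1.HOG%06d", seq_len(n_hogs))

  hogs <- data.frame(hog_id = hog_ids, og_id = hog_og,
                     stringsAsFactors = FALSE)
  truth <- data.frame(hog_id = hog_ids, og_id = hog_og,
                      family_size = hog_fam, stringsAsFactors = FALSE)
  pavs <- list()
  for (s in seq_len(nrow(panel))) {
    sp <- panel$name[s]
    genes <- sprintf("%s_g%06d", sp, seq_len(n_hogs))
    hogs[[sp]] <- as.list(genes)
    p <- retention_prob(loss, hog_fam, panel$ploidy[s])
    truth[[paste0(sp, "_p")]] <- p
    calls <- matrix(stats::runif(panel$n_lines[s] * n_hogs) <
                      rep(p, each = panel$n_lines[s]),
                    nrow = panel$n_lines[s])
    pavs[[sp]] <- pav_matrix(calls,
                             line_ids = sprintf("%s_line%02d", sp,
                                                seq_len(panel$n_lines[s])),
                             gene_ids = genes, species = sp)
  }
  attr(hogs, "species") <- panel$name
  class(hogs) <- c("hog_table", class(hogs))
  validate_hog_table(hogs)
  list(hogs = hogs, pavs = pavs, truth = truth)
}

#' Generate a genome layout with planted duplication events
#'
#' Lays out genes on chromosomes at regular spacing and plants
#' non-overlapping duplication events of each requested class: tandem pairs
#' at adjacent ranks, proximal pairs within the window, dispersed pairs on
#' different chromosomes, and WGD/segmental events as two runs of
#' `block_size` collinear anchor pairs on two chromosomes. Every planted
#' duplicate pair emits a homology hit with E-value 1e-30. All other genes
#' are singletons.
#'
#' @param n_chrom Number of chromosomes; default 3.
#' @param genes_per_chrom Genes per chromosome; default 100.
#' @param events Named integer vector of event counts with names among
#'   `tandem`, `proximal`, `dispersed`, `wgd`.
#' @param proximal_window Rank window used for the proximal events
#'   (pairs planted at rank distance `min(5, proximal_window)`).
#' @param block_size Anchors per planted segmental block; default 6.
#' @param max_gap_genes Chaining gap the downstream block detector will
#'   use; successive planted events are separated by more than this many
#'   ranks so distinct events can never chain into one block.
#' @param seed Integer seed (layouts differ across seeds via shuffled
#'   event placement order).
#' @return List with `loci` (ranked gene table), `hits` (hit table),
#'   `truth` (data.frame `gene_id`, `class`).
#' @export
gen_genome_layout <- function(n_chrom = 3L, genes_per_chrom = 100L,
                              events = c(tandem = 1L, proximal = 1L,
                                         dispersed = 1L, wgd = 1L),
                              proximal_window = 10L, block_size = 6L,
                              max_gap_genes = 25L, seed = 1L) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  loci <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    data.frame(gene_id = sprintf("%s_g%03d", chroms[c], seq_len(genes_per_chrom)),
               chrom = chroms[c],
               start = seq_len(genes_per_chrom) * 10000L,
               end = seq_len(genes_per_chrom) * 10000L + 999L,
               strand = "+", stringsAsFactors = FALSE)
  }))
  loci <- gene_ranks(loci)
  gene_at <- function(chrom, rank) loci$gene_id[loci$chrom == chrom & loci$rank == rank]

  cursor <- stats::setNames(rep(0L, n_chrom), chroms)
  pad <- max(proximal_window + 2L, max_gap_genes + 1L)
  take <- function(chrom, len) {
    r0 <- cursor[[chrom]]
    if (r0 + len > genes_per_chrom) stop("chromosome ", chrom, " too short for planted events")
    cursor[[chrom]] <<- r0 + len + pad
    seq(r0, r0 + len - 1L)
  }
  next_chrom_pair <- function() {
    ord <- order(cursor)
    chroms[ord[1:2]]
  }

  hits <- list(); truth_cls <- stats::setNames(rep("singleton", nrow(loci)),
                                               loci$gene_id)
  add_hit <- function(a, b) {
    hits[[length(hits) + 1L]] <<- data.frame(
      query = a, subject = b, pident = 98, length = 300,
      e_value = 1e-30, bit_score = 500, stringsAsFactors = FALSE)
  }
  plan <- rep(names(events), events)
  plan <- sample(plan)                      # seed-dependent placement order
  for (ev in plan) {
    if (ev == "tandem") {
      ch <- chroms[which.min(cursor)]
      r <- take(ch, 2L)
      g <- c(gene_at(ch, r[1]), gene_at(ch, r[2]))
      add_hit(g[1], g[2])
      truth_cls[g] <- "tandem"
    } else if (ev == "proximal") {
      d <- min(5L, proximal_window)
      ch <- chroms[which.min(cursor)]
      r <- take(ch, d + 1L)
      g <- c(gene_at(ch, r[1]), gene_at(ch, r[length(r)]))
      add_hit(g[1], g[2])
      truth_cls[g] <- "proximal"
    } else if (ev == "dispersed") {
      cp <- next_chrom_pair()
      g <- c(gene_at(cp[1], take(cp[1], 1L)), gene_at(cp[2], take(cp[2], 1L)))
      add_hit(g[1], g[2])
      truth_cls[g] <- "dispersed"
    } else if (ev == "wgd") {
      cp <- next_chrom_pair()
      ra <- take(cp[1], block_size)
      rb <- take(cp[2], block_size)
      for (i in seq_len(block_size)) {
        ga <- gene_at(cp[1], ra[i]); gb <- gene_at(cp[2], rb[i])
        add_hit(ga, gb)
        truth_cls[c(ga, gb)] <- "wgd_segmental"
      }
    } else stop("unknown event type: ", ev)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query = character(0), subject = character(0), pident = numeric(0),
               length = integer(0), e_value = numeric(0), bit_score = numeric(0))
  list(loci = loci, hits = hits,
       truth = data.frame(gene_id = loci$gene_id,
                          class = unname(truth_cls[loci$gene_id]),
                          stringsAsFactors = FALSE))
}

#' Anchor pairs from a hit table
#'
#' Converts filtered homology hits into the rank-pair anchors consumed by
#' [detect_collinear_blocks()], one row per unordered gene pair.
#'
#' @param hits Hit table with `query`, `subject`.
#' @param loci Ranked locus table.
#' @return data.frame `gene_a`, `gene_b`, `chrom_a`, `rank_a`, `chrom_b`,
#'   `rank_b`.
#' @export
anchors_from_hits <- function(hits, loci) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), rank_a = integer(0),
                      chrom_b = character(0), rank_b = integer(0)))
  }
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  keep <- !duplicated(paste(a, b)) & a != b
  a <- a[keep]; b <- b[keep]
  ia <- match(a, loci$gene_id); ib <- match(b, loci$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("hit references gene absent from loci")
  data.frame(gene_a = a, gene_b = b,
             chrom_a = loci$chrom[ia], rank_a = loci$rank[ia],
             chrom_b = loci$chrom[ib], rank_b = loci$rank[ib],
             stringsAsFactors = FALSE)
}

#' Evolve a codon alignment along a labeled tree
#'
#' Samples root codons from `pi` and propagates them down the tree with
#' transition matrices `exp(Q * t)` of the branch's scaled GY94 rate matrix
#' (branch-specific omega from the edge labels, or a Model-A site-class
#' mixture). States are confined to the 61 sense codons, so no stop codon
#' is ever generated.
#'
#' @param labeled Labeled tree (see [read_newick_labeled()]).
#' @param kappa Transition/transversion ratio.
#' @param omega_by_label Named label -> omega map (branch-wise evolution).
#' @param mix Model-A style mixture (`p0, p1, p2a, p2b, omega0, omega2`);
#'   per-site classes are drawn from the proportions.
#' @param pi Codon frequencies (default uniform over the 61 sense codons).
#' @param n_codons Alignment length in codons.
#' @param seed Integer seed.
#' @param foreground Foreground edge label for `mix`; default `"1"`.
#' @return List with `alignment` (named codon strings, tips only) and
#'   `site_classes` (for `mix`: integer vector 1..4 of true classes,
#'   otherwise `NULL`).
#' @export
evolve_codons <- function(labeled, kappa, omega_by_label = NULL, mix = NULL,
                          pi = NULL, n_codons = 300L, seed = 1L,
                          foreground = "1") {
  set.seed(seed)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  tree <- labeled$tree
  edge_labels <- labeled$edge_labels
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  site_classes <- NULL
  if (!is.null(mix)) {
    props <- c(mix$p0, mix$p1, mix$p2a, mix$p2b)
    site_classes <- sample.int(4L, n_codons, replace = TRUE, prob = props)
    # per (edge, class) omega
    class_om <- rbind(c(mix$omega0, mix$omega0), c(1, 1),
                      c(mix$omega0, mix$omega2), c(1, mix$omega2))
  } else if (is.null(omega_by_label)) {
    stop("supply omega_by_label or mix")
  }

  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  edge_order <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  # branch-wise evolution uses per-matrix rate-1 scaling; site-class
  # mixtures share the neutral (omega = 1) scale so positive-selection
  # classes evolve faster, matching the likelihood convention
  mix_scale <- if (is.null(mix)) NULL else .q_raw(pi, kappa, 1)$rate
  dec_cache <- list()
  get_dec <- function(w) {
    key <- sprintf("%.17g", w)
    if (is.null(dec_cache[[key]])) {
      dec_cache[[key]] <<- .q_eigen(pi, kappa, w, scale = mix_scale)
    }
    dec_cache[[key]]
  }
  for (k in seq_len(nrow(pre$edge))) {
    eidx <- edge_order[k]
    parent <- tree$edge[eidx, 1]; child <- tree$edge[eidx, 2]
    t <- tree$edge.length[eidx]
    is_fg <- edge_labels[eidx] == foreground
    if (is.null(mix)) {
      w <- .edge_omegas(edge_labels[eidx], omega_by_label)
      P <- .p_matrix(get_dec(w), t)
      states[child, ] <- .sample_transitions(states[parent, ], P)
    } else {
      out <- integer(n_codons)
      for (cl in 1:4) {
        idx <- which(site_classes == cl)
        if (!length(idx)) next
        w <- class_om[cl, if (is_fg) 2 else 1]
        P <- .p_matrix(get_dec(w), t)
        out[idx] <- .sample_transitions(states[parent, idx], P)
      }
      states[child, ] <- out
    }
  }
  codons <- sense_codons()
  aln <- vapply(seq_len(ntip), function(i) {
    paste(codons[states[i, ]], collapse = "")
  }, "")
  names(aln) <- tree$tip.label
  list(alignment = aln, site_classes = site_classes)
}

# draw child states given parent states and a transition matrix
.sample_transitions <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    pr <- P[s, ]
    pr[pr < 0] <- 0
    out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Generate a GO annotation set with one planted enriched term
#'
#' Unplanted terms annotate genes uniformly at random (per-term background
#' probability drawn once); the planted term annotates designated query
#' genes with `fold` times its background probability (capped at 1), so
#' the query set is over-represented for that term by the stated fold.
#'
#' @param n_genes Universe size; default 20000.
#' @param n_terms Number of terms; default 50.
#' @param query Character vector of query gene ids, or an integer size (a
#'   random query of that size is drawn); default 300.
#' @param fold Fold enrichment of the planted term in the query; `1` plants
#'   no signal.
#' @param base_prob_range Range the per-term background annotation
#'   probability is drawn from.
#' @param seed Integer seed.
#' @return List with `annotation` (data.frame `gene_id`, `term_id`,
#'   `term_name`, `namespace`), `universe`, `query`, and `truth` (planted
#'   term id and fold).
#' @export
gen_go <- function(n_genes = 20000L, n_terms = 50L, query = 300L, fold = 5,
                   base_prob_range = c(0.005, 0.02), seed = 1L) {
  set.seed(seed)
  universe <- sprintf("gene%05d", seq_len(n_genes))
  if (is.numeric(query) && length(query) == 1L) {
    query <- sample(universe, query)
  }
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  base_p <- stats::runif(n_terms, base_prob_range[1], base_prob_range[2])
  planted <- term_ids[1]
  ns <- sample(c("MF", "BP", "CC"), n_terms, replace = TRUE)
  rows <- list()
  in_query <- universe %in% query
  for (t in seq_len(n_terms)) {
    p <- rep(base_p[t], n_genes)
    if (term_ids[t] == planted) p[in_query] <- pmin(1, fold * base_p[t])
    hit <- stats::runif(n_genes) < p
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = universe[hit], term_id = term_ids[t],
        term_name = paste0("term_", t), namespace = ns[t],
        stringsAsFactors = FALSE)
    }
  }
  list(annotation = do.call(rbind, rows), universe = universe, query = query,
       truth = list(planted_term = planted, fold = fold))
}
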