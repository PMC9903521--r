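# Independent oracle implementations used to cross-check the package:
# deliberately written from first principles (enumeration, closed forms,
# textbook formulas), not by calling the code paths they verify.

# --- genetic code, written out via Biostrings but used only through
#     enumeration helpers below
.oracle_gc <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(.oracle_gc[[toupper(codon)]])

# NG86 synonymous site count of one codon: at each position, the fraction
# of the possible single-nucleotide changes (stop-codon targets excluded)
# that preserve the amino acid.
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  cod <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    nsyn <- 0; nvalid <- 0
    for (nt in setdiff(nts, cod[pos])) {
      mut <- cod; mut[pos] <- nt
      aa <- oracle_translate(paste(mut, collapse = ""))
      if (aa == "*") next
      nvalid <- nvalid + 1
      if (aa == oracle_translate(codon)) nsyn <- nsyn + 1
    }
    if (nvalid > 0) s <- s + nsyn / nvalid
  }
  s
}

# all permutations of a vector (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# NG86 pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair; pathways passing through stop codons are discarded.
oracle_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  tot <- c(0, 0); np <- 0
  for (path in oracle_perms(pos)) {
    cur <- s1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in path) {
      nxt <- cur; nxt[p] <- s2[p]
      if (oracle_translate(paste(nxt, collapse = "")) == "*") { ok <- FALSE; break }
      if (oracle_translate(paste(cur, collapse = "")) ==
          oracle_translate(paste(nxt, collapse = ""))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); np <- np + 1 }
  }
  if (np == 0) return(c(NA, NA))
  tot / np
}

# full NG86 on two aligned codon vectors (no gaps/stops), from scratch
oracle_ng86 <- function(cod1, cod2) {
  S <- (sum(vapply(cod1, oracle_syn_sites, 0)) +
          sum(vapply(cod2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(cod1) - S
  d <- rowSums(vapply(seq_along(cod1), function(k) {
    v <- oracle_pair_diffs(cod1[k], cod2[k])
    if (anyNA(v)) c(0, 0) else v
  }, c(0, 0)))
  pS <- d[1] / S; pN <- d[2] / N
  jc <- function(p) if (p >= 3 / 4) NA else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# upper-tail hypergeometric probability by explicit pmf summation
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Benjamini-Hochberg by the rank formula with step-up monotonicity
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# Welch two-sample t statistic from the textbook formula
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

# exhaustive longest collinear chain by recursive search (memo-free DFS)
oracle_best_chain_len <- function(ra, rb, orientation, max_gap) {
  n <- length(ra)
  succ <- function(i, j) {
    da <- ra[j] - ra[i]
    db <- if (orientation == "same") rb[j] - rb[i] else rb[i] - rb[j]
    da >= 1 && db >= 1 && da <= max_gap && db <= max_gap
  }
  extend <- function(i) {
    best <- 1
    for (j in seq_len(n)) {
      if (j != i && succ(i, j)) best <- max(best, 1 + extend(j))
    }
    best
  }
  if (n == 0) return(0)
  max(vapply(seq_len(n), extend, 0))
}

# exhaustive pruning likelihood: sum the joint probability over every
# assignment of ancestral states (root + internal nodes)
oracle_tree_loglik <- function(aln, labeled, kappa, omega_by_label, pi) {
  tree <- labeled$tree
  codons <- sense_codons()
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    w <- unname(unlist(omega_by_label)[labeled$edge_labels[e]])
    Q <- build_q(pi, kappa, w)
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  nsite <- nchar(aln[[1]]) / 3
  tipstate <- sapply(tree$tip.label, function(tl) {
    match(substring(aln[[tl]], 3 * (1:nsite) - 2, 3 * (1:nsite)), codons)
  })
  tipstate <- matrix(tipstate, nrow = nsite)
  total <- 0
  nint <- length(internal)
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  for (site in seq_len(nsite)) {
    lik_per_assign <- rep(1, nrow(grid))
    state_of <- function(node, g) {
      if (node <= ntip) tipstate[site, node] else g[match(node, internal)]
    }
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- grid[, match(par, internal)]
      cs <- if (ch <= ntip) rep(tipstate[site, ch], nrow(grid)) else
        grid[, match(ch, internal)]
      lik_per_assign <- lik_per_assign * P[[e]][cbind(ps, cs)]
    }
    lik_per_assign <- lik_per_assign * pi[grid[, match(root, internal)]]
    total <- total + log(sum(lik_per_assign))
  }
  total
}

# a small labeled tree used across selection tests
make_labeled_tree <- function(nwk = "((A:0.2,B:0.2):0.15,(C:0.2,D:0.2)#1:0.15);") {
  read_newick_labeled(nwk)
}
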