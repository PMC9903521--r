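# Codon substitution likelihood machinery: GY94-style rate matrices with
# F1X4 equilibrium frequencies, Felsenstein pruning on labeled trees,
# one-ratio / n-ratio branch models, branch-site Model A with its null,
# naive empirical Bayes site posteriors, and chi-square likelihood-ratio
# tests.

#' F1X4 codon equilibrium frequencies
#'
#' Codon frequency = product of observed nucleotide frequencies pooled over
#' the three codon positions of all sequences, with stop codons removed and
#' the 61 sense-codon frequencies renormalized to sum to 1.
#'
#' @param seqs Named character vector of (possibly gapped) CDS sequences.
#' @return Numeric vector of 61 frequencies in [sense_codons()] order.
#' @export
f1x4_frequencies <- function(seqs) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0L) stop("no nucleotides in input")
  ntfreq <- table(factor(chars, levels = c("A", "C", "G", "T")))
  ntfreq <- as.numeric(ntfreq) / sum(ntfreq)
  tab <- .codon_tables()
  pi <- ntfreq[tab$ntidx[, 1]] * ntfreq[tab$ntidx[, 2]] * ntfreq[tab$ntidx[, 3]]
  pi / sum(pi)
}

#' Build a scaled GY94 codon rate matrix
#'
#' Off-diagonal rate for a single-nucleotide change i -> j is
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`; multi-nucleotide
#' changes have rate 0. The diagonal makes rows sum to zero and the matrix
#' is rescaled so that the expected substitution rate at equilibrium,
#' `-sum(pi_i q_ii)`, is 1 (branch lengths are then expected substitutions
#' per codon).
#'
#' @param pi 61 sense-codon equilibrium frequencies.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @return 61 x 61 rate matrix.
#' @export
build_q <- function(pi, kappa, omega) {
  raw <- .q_raw(pi, kappa, omega)
  if (raw$rate <= 0) stop("degenerate rate matrix (zero expected rate)")
  raw$Q / raw$rate
}

# unnormalized GY94 generator and its equilibrium substitution rate
.q_raw <- function(pi, kappa, omega) {
  tab <- .codon_tables()
  single <- tab$single_pos > 0L
  Q <- matrix(0, 61, 61)
  jidx <- col(Q)[single]
  Q[single] <- pi[jidx] *
    ifelse(tab$single_ts[single], kappa, 1) *
    ifelse(tab$single_syn[single], 1, omega)
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

# symmetric eigendecomposition of a reversible Q; `scale` overrides the
# matrix's own equilibrium rate as the normalization (used by site-class
# mixtures, where all classes share the neutral omega = 1 scale so that
# high-omega classes genuinely evolve faster)
.q_eigen <- function(pi, kappa, omega, scale = NULL) {
  raw <- .q_raw(pi, kappa, omega)
  if (is.null(scale)) scale <- raw$rate
  if (scale <= 0) stop("degenerate rate matrix (zero expected rate)")
  Q <- raw$Q / scale
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)          # rows scaled by sqrt(pi)
  B <- (B + t(B)) / 2                      # symmetrize numeric noise
  e <- eigen(B, symmetric = TRUE)
  left <- (1 / sq) * e$vectors             # D^{-1/2} U
  right <- t(e$vectors * sq)               # U^T D^{1/2}
  list(values = e$values, left = left, right = right)
}

# transition probability matrix from a .q_eigen decomposition
.p_matrix <- function(dec, t) {
  P <- dec$left %*% (exp(dec$values * t) * dec$right)
  P[P < 0] <- 0
  P
}

# encode a codon alignment (named equal-length strings) as an integer
# matrix tips x sites of sense-codon indices; gap/stop/ambiguous -> NA
.encode_codon_alignment <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  if (lens[1] %% 3L != 0L) stop("alignment length not divisible by 3")
  nsite <- lens[1] / 3L
  m <- matrix(NA_integer_, length(aln), nsite,
              dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) m[i, ] <- codon_index(split_codons(aln[[i]]))
  m
}

# collapse identical site patterns; returns list(states, weights)
.compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  list(states = states[, first, drop = FALSE], weights = w)
}

# Precompute everything pruning needs that does not depend on parameters:
# postorder edge traversal, per-tip partial-likelihood matrices, root node.
.make_prune_ctx <- function(tree, states) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  npat <- ncol(states)
  tipmap <- match(tree$tip.label, rownames(states))
  if (anyNA(tipmap)) {
    stop("alignment lacks tip(s): ",
         paste(tree$tip.label[is.na(tipmap)], collapse = ", "))
  }
  tip_partials <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    L <- matrix(0, 61, npat)
    st <- states[tipmap[i], ]
    known <- !is.na(st)
    L[cbind(st[known], which(known))] <- 1
    L[, !known] <- 1                       # missing data: uninformative tip
    tip_partials[[i]] <- L
  }
  edge_order <- match(paste(po$edge[, 1], po$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  list(po_edge = po$edge, edge_order = edge_order, ntip = ntip,
       nnode = ntip + tree$Nnode, npat = npat, tip_partials = tip_partials,
       root = po$edge[nrow(po$edge), 1])
}

# Felsenstein pruning for one set of per-edge P matrices (tree$edge order).
# Scaling-free for speed; falls back to a per-edge rescaled pass on
# underflow. Returns per-pattern log-likelihoods.
.prune_loglik_ctx <- function(ctx, Plist, pi, rescale = FALSE) {
  partial <- vector("list", ctx$nnode)
  partial[seq_len(ctx$ntip)] <- ctx$tip_partials
  logscale <- if (rescale) numeric(ctx$npat) else NULL
  for (k in seq_len(nrow(ctx$po_edge))) {
    parent <- ctx$po_edge[k, 1]; child <- ctx$po_edge[k, 2]
    contrib <- Plist[[ctx$edge_order[k]]] %*% partial[[child]]
    if (rescale) {
      sc <- apply(contrib, 2L, max)
      sc[sc <= 0] <- 1
      contrib <- sweep(contrib, 2L, sc, "/")
      logscale <- logscale + log(sc)
    }
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib else
      partial[[parent]] * contrib
  }
  ll <- log(colSums(pi * partial[[ctx$root]]))
  if (rescale) ll <- ll + logscale
  if (!rescale && any(!is.finite(ll))) {
    return(.prune_loglik_ctx(ctx, Plist, pi, rescale = TRUE))
  }
  ll
}

# convenience wrapper used by public entry points
.prune_loglik <- function(tree, states, Plist, pi) {
  .prune_loglik_ctx(.make_prune_ctx(tree, states), Plist, pi)
}

# per-edge omega vector from labels and a label -> omega map
.edge_omegas <- function(edge_labels, omega_by_label) {
  miss <- setdiff(unique(edge_labels), names(omega_by_label))
  if (length(miss) > 0L) {
    stop("no omega for branch label(s): ", paste(miss, collapse = ", "))
  }
  unname(unlist(omega_by_label)[edge_labels])
}

# build per-edge P matrices for a per-edge omega assignment, caching the
# eigendecomposition per distinct omega
.edge_p_matrices <- function(tree, edge_omega, pi, kappa) {
  uo <- unique(edge_omega)
  decs <- lapply(uo, function(w) .q_eigen(pi, kappa, w))
  names(decs) <- as.character(uo)
  lapply(seq_along(edge_omega), function(k) {
    .p_matrix(decs[[as.character(edge_omega[k])]], tree$edge.length[k])
  })
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Felsenstein-pruned log-likelihood under the GY94-style model. For a
#' branch model, supply `omega_by_label` mapping each branch label to its
#' omega. For branch-site Model A, supply `mix` (see [fit_model_a()]); the
#' site likelihood is the proportion-weighted sum over the four site
#' classes.
#'
#' @param aln Named character vector: codon alignment.
#' @param labeled List with `tree` ([ape::phylo], branch lengths in expected
#'   substitutions per codon) and `edge_labels` (see
#'   [read_newick_labeled()]).
#' @param kappa Transition/transversion ratio.
#' @param omega_by_label Named list/vector label -> omega (branch models).
#' @param mix List `p0, p1, p2a, p2b, omega0, omega2` (Model A);
#'   `omega1 = 1` is implied.
#' @param pi Codon frequencies; default F1X4 from the alignment.
#' @param foreground Label of the foreground branches for `mix` models.
#' @return The log-likelihood (a scalar).
#' @export
tree_loglik <- function(aln, labeled, kappa, omega_by_label = NULL,
                        mix = NULL, pi = NULL, foreground = "1") {
  states <- .encode_codon_alignment(aln)
  if (ncol(states) == 0L) stop("zero-length alignment")
  if (is.null(pi)) pi <- f1x4_frequencies(aln)
  cp <- .compress_patterns(states)
  ll <- .site_logliks(cp$states, labeled, kappa, omega_by_label, mix, pi,
                      foreground)
  sum(ll * cp$weights)
}

# per-class per-pattern log-likelihood matrix (npat x 4) for the Model A
# site classes, sharing eigendecompositions and per-edge P matrices across
# classes:
#   class 0: (bg w0, fg w0); class 1: (1, 1);
#   class 2a: (w0, w2);      class 2b: (1, w2)
.class_site_logliks <- function(ctx, labeled, kappa, omega0, omega2, pi,
                                foreground = "1") {
  tree <- labeled$tree
  fg <- labeled$edge_labels == foreground
  uo <- unique(c(omega0, 1, omega2))
  nscale <- .q_raw(pi, kappa, 1)$rate      # shared neutral-rate scaling
  decs <- lapply(uo, function(w) .q_eigen(pi, kappa, w, scale = nscale))
  names(decs) <- sprintf("%.17g", uo)
  pmat <- function(w, k) .p_matrix(decs[[sprintf("%.17g", w)]],
                                   tree$edge.length[k])
  nedge <- nrow(tree$edge)
  # per-edge P matrices for each needed omega, computed once and shared
  P_w0 <- lapply(seq_len(nedge), function(k) pmat(omega0, k))
  P_1 <- lapply(seq_len(nedge), function(k) pmat(1, k))
  P_w2_fg <- lapply(seq_len(nedge), function(k) if (fg[k]) pmat(omega2, k))
  pick <- function(bg_list, fg_list) {
    lapply(seq_len(nedge), function(k) if (fg[k]) fg_list[[k]] else bg_list[[k]])
  }
  cbind(.prune_loglik_ctx(ctx, P_w0, pi),
        .prune_loglik_ctx(ctx, P_1, pi),
        .prune_loglik_ctx(ctx, pick(P_w0, P_w2_fg), pi),
        .prune_loglik_ctx(ctx, pick(P_1, P_w2_fg), pi))
}

# per-pattern log-likelihoods for either model family
.site_logliks <- function(states, labeled, kappa, omega_by_label = NULL,
                          mix = NULL, pi, foreground = "1", ctx = NULL) {
  tree <- labeled$tree
  edge_labels <- labeled$edge_labels
  if (is.null(ctx)) ctx <- .make_prune_ctx(tree, states)
  if (!is.null(omega_by_label)) {
    ew <- .edge_omegas(edge_labels, omega_by_label)
    Plist <- .edge_p_matrices(tree, ew, pi, kappa)
    return(.prune_loglik_ctx(ctx, Plist, pi))
  }
  if (is.null(mix)) stop("supply omega_by_label or mix")
  M <- .class_site_logliks(ctx, labeled, kappa, mix$omega0, mix$omega2, pi,
                           foreground)
  props <- c(mix$p0, mix$p1, mix$p2a, mix$p2b)
  mx <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
  mx + log(as.vector(exp(M - mx) %*% props))
}

#' Fit branch-specific codon models
#'
#' Maximizes the log-likelihood over kappa and one omega per branch-ratio
#' group, with branch lengths fixed from the input tree. `ratio_spec` maps
#' every branch label occurring in the tree to a group name; labels sharing
#' a group share an omega. Multi-start bounded quasi-Newton optimization
#' (`L-BFGS-B` on log-transformed parameters, omega in `[1e-4, 50]`, kappa
#' in `[0.1, 20]`); restart points are seed-controlled.
#'
#' @param aln Codon alignment (named character vector).
#' @param labeled Labeled tree (see [tree_loglik()]).
#' @param ratio_spec Named character vector, e.g.
#'   `c("0" = "bg", "1" = "fg")` for a two-ratio model or
#'   `c("0" = "w", "1" = "w")` for one ratio.
#' @param pi Codon frequencies; default F1X4 from `aln`.
#' @param n_starts Number of optimizer starts; default 5.
#' @param seed Seed for the random restart points.
#' @return List of class `codon_fit`: `lnL`, `np` (free selection
#'   parameters, i.e. number of distinct omegas), `kappa`,
#'   `omega_by_group`, `omega_by_label`, `converged`.
#' @export
fit_branch_model <- function(aln, labeled, ratio_spec, pi = NULL,
                             n_starts = 5L, seed = 1L) {
  states <- .encode_codon_alignment(aln)
  if (is.null(pi)) pi <- f1x4_frequencies(aln)
  cp <- .compress_patterns(states)
  labs <- unique(labeled$edge_labels)
  miss <- setdiff(labs, names(ratio_spec))
  if (length(miss) > 0L) {
    stop("ratio_spec lacks branch label(s): ", paste(miss, collapse = ", "))
  }
  groups <- unique(unname(ratio_spec[labs]))
  ng <- length(groups)
  lab2grp <- match(unname(ratio_spec[labeled$edge_labels]), groups)
  ctx <- .make_prune_ctx(labeled$tree, cp$states)

  negll <- function(par) {
    kappa <- exp(par[1])
    omg <- exp(par[-1])
    ew <- omg[lab2grp]
    Plist <- .edge_p_matrices(labeled$tree, ew, pi, kappa)
    ll <- sum(.prune_loglik_ctx(ctx, Plist, pi) * cp$weights)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- c(log(0.1), rep(log(1e-4), ng))
  upper <- c(log(20), rep(log(50), ng))
  starts <- list(c(log(2), rep(log(0.3), ng)))
  if (n_starts > 1L) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- c(log(stats::runif(1, 0.5, 8)),
                            log(stats::runif(ng, 0.02, 3)))
    }
  }
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    fit <- try(stats::optim(st, negll, method = "L-BFGS-B", lower = lower,
                            upper = upper, control = list(factr = 1e8)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")
  omg <- stats::setNames(exp(best$par[-1]), groups)
  structure(list(lnL = -best$value, np = ng, kappa = exp(best$par[1]),
                 omega_by_group = omg,
                 omega_by_label = stats::setNames(
                   omg[unname(ratio_spec[labs])], labs),
                 converged = conv && best$convergence == 0),
            class = "codon_fit")
}

# shared machinery for Model A and its null (omega2 fixed at 1). The class
# proportions enter the likelihood only through the cached per-class site
# likelihood matrix, so they are profiled out in an inner optimization that
# requires no new pruning passes; the outer bounded quasi-Newton search runs
# over (kappa, omega0[, omega2]) only.
.fit_model_a_impl <- function(aln, labeled, null = FALSE, pi = NULL,
                              foreground = "1", n_starts = 5L, seed = 1L,
                              factr = 1e8) {
  states <- .encode_codon_alignment(aln)
  if (is.null(pi)) pi <- f1x4_frequencies(aln)
  cp <- .compress_patterns(states)
  ctx <- .make_prune_ctx(labeled$tree, cp$states)
  w <- cp$weights

  props_of <- function(ab) {
    ex <- exp(c(ab, 0))
    pr <- ex / sum(ex)
    p0 <- pr[1]; p1 <- pr[2]; p2 <- pr[3]
    c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  }
  prop_start <- c(log(0.6 / 0.15), log(0.25 / 0.15))
  last_inner <- NULL
  negll_outer <- function(par) {
    kappa <- exp(par[1])
    w0 <- stats::plogis(par[2])
    w2 <- if (null) 1 else 1 + exp(par[3])
    M <- .class_site_logliks(ctx, labeled, kappa, w0, w2, pi, foreground)
    mx <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
    E <- exp(M - mx)
    f_inner <- function(ab) {
      v <- -sum(w * (mx + log(as.vector(E %*% props_of(ab)))))
      if (!is.finite(v)) 1e10 else v
    }
    inner <- stats::optim(prop_start, f_inner, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 500))
    prop_start <<- inner$par
    last_inner <<- inner$par
    if (!is.finite(inner$value)) 1e10 else inner$value
  }
  npar <- if (null) 2L else 3L
  lower <- c(log(0.1), stats::qlogis(1e-4), if (!null) log(1e-6))
  upper <- c(log(20), stats::qlogis(1 - 1e-6), if (!null) log(49))
  starts <- list(c(log(2), stats::qlogis(0.1), if (!null) log(1.5)))
  if (n_starts > 1L) {
    set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- c(log(stats::runif(1, 0.5, 8)),
                            stats::qlogis(stats::runif(1, 0.02, 0.6)),
                            if (!null) log(stats::runif(1, 0.05, 8)))
    }
  }
  best <- NULL
  best_props <- NULL
  conv <- FALSE
  for (st in starts) {
    prop_start <- c(log(0.6 / 0.15), log(0.25 / 0.15))
    fit <- try(stats::optim(st, negll_outer, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = factr)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      # re-evaluate at the optimum so the stored proportions match it
      prop_start <- last_inner
      val <- negll_outer(fit$par)
      best <- fit
      best$value <- min(best$value, val)
      best_props <- props_of(last_inner)
    }
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")
  mix <- list(p0 = best_props[1], p1 = best_props[2],
              p2a = best_props[3], p2b = best_props[4],
              omega0 = stats::plogis(best$par[2]),
              omega2 = if (null) 1 else 1 + exp(best$par[3]))
  structure(list(lnL = -best$value, np = if (null) 3L else 4L,
                 kappa = exp(best$par[1]), mix = mix,
                 converged = conv && best$convergence == 0,
                 aln = aln, labeled = labeled, pi = pi,
                 foreground = foreground),
            class = c("model_a_fit", "codon_fit"))
}

#' Fit branch-site Model A (and its null)
#'
#' Model A mixes four site classes over a labeled tree: class 0 (omega0 on
#' all branches), class 1 (neutral, omega = 1), and classes 2a/2b where
#' background branches keep omega0 / 1 while foreground branches get
#' omega2 >= 1. Class proportions satisfy `p2a/p2b = p0/p1`. The null model
#' is Model A with omega2 fixed at 1 (1 df against the alternative).
#' Reported `np` counts the free selection parameters (4 for Model A, 3 for
#' the null), excluding kappa and the fixed branch lengths.
#'
#' @inheritParams fit_branch_model
#' @param foreground Branch label treated as foreground; default `"1"`.
#' @return A `model_a_fit`: `lnL`, `np`, `kappa`, `mix`
#'   (`p0, p1, p2a, p2b, omega0, omega2`), `converged`.
#' @export
fit_model_a <- function(aln, labeled, pi = NULL, foreground = "1",
                        n_starts = 5L, seed = 1L, factr = 1e8) {
  .fit_model_a_impl(aln, labeled, null = FALSE, pi = pi,
                    foreground = foreground, n_starts = n_starts, seed = seed,
                    factr = factr)
}

#' @rdname fit_model_a
#' @param factr `L-BFGS-B` convergence tolerance factor (see
#'   [stats::optim()]); larger is looser/faster.
#' @export
fit_model_a_null <- function(aln, labeled, pi = NULL, foreground = "1",
                             n_starts = 5L, seed = 1L, factr = 1e8) {
  .fit_model_a_impl(aln, labeled, null = TRUE, pi = pi,
                    foreground = foreground, n_starts = n_starts, seed = seed,
                    factr = factr)
}

#' Naive empirical Bayes site posteriors for Model A
#'
#' Per-site posterior probability that the site belongs to a foreground
#' positive-selection class (2a or 2b), evaluated at the fitted parameter
#' values (naive empirical Bayes: estimation uncertainty is ignored).
#'
#' @param fit A `model_a_fit` from [fit_model_a()].
#' @param threshold Sites with posterior above this value are listed;
#'   default 0.6.
#' @return List with `posterior` (per-site vector) and `selected_sites`
#'   (1-based site indices above the threshold).
#' @export
neb_site_posteriors <- function(fit, threshold = 0.6) {
  states <- .encode_codon_alignment(fit$aln)
  mix <- fit$mix
  ctx <- .make_prune_ctx(fit$labeled$tree, states)
  props <- c(mix$p0, mix$p1, mix$p2a, mix$p2b)
  M <- .class_site_logliks(ctx, fit$labeled, fit$kappa, mix$omega0,
                           mix$omega2, fit$pi, fit$foreground)
  mx <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
  w <- exp(M - mx) * rep(props, each = nrow(M))
  post <- (w[, 3] + w[, 4]) / rowSums(w)
  list(posterior = post, selected_sites = which(post > threshold))
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnL0 Log-likelihood of the restricted (null) model.
#' @param lnL1 Log-likelihood of the more general model.
#' @param df Difference in free parameters (>= 1).
#' @return List with `stat` (`2 * (lnL1 - lnL0)`, clamped at 0 with a
#'   warning if slightly negative from optimizer noise), `df`, `p_value`
#'   (upper-tail chi-square).
#' @export
lrt <- function(lnL0, lnL1, df) {
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnL1 - lnL0)
  if (stat < 0) {
    warning("negative LRT statistic (", format(stat), ") clamped to 0")
    stat <- 0
  }
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
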