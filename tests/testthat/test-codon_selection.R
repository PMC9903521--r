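# Codon substitution models: F1X4 frequencies, rate-matrix construction,
# pruning likelihood (against exhaustive enumeration), branch and
# branch-site fits, NEB posteriors and the chi-square LRT.

test_that("F1X4 frequencies pool positions, drop stops and sum to 1", {
  # uniform nucleotide composition -> all 61 frequencies equal
  uni <- c(u = paste(rep(c("A", "C", "G", "T"), 30), collapse = ""))
  pi <- f1x4_frequencies(uni)
  expect_equal(pi, rep(1 / 61, 61))
  expect_equal(sum(pi), 1)

  # arbitrary sequences against an independent counting computation
  set.seed(4)
  seqs <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
  }, "")
  pi <- f1x4_frequencies(seqs)
  chars <- unlist(strsplit(seqs, ""))
  f <- vapply(c("A", "C", "G", "T"), function(n) mean(chars == n), 0)
  expected <- vapply(sense_codons(), function(cod) {
    prod(f[strsplit(cod, "")[[1]]])
  }, 0)
  expect_equal(pi, unname(expected / sum(expected)), tolerance = 1e-13)
})

test_that("rate matrix obeys GY94 structure, scaling and detailed balance", {
  set.seed(10)
  pi <- as.vector(stats::rgamma(61, 2)); pi <- pi / sum(pi)
  Q <- build_q(pi, kappa = 3, omega = 0.4)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # reversibility: pi_i q_ij = pi_j q_ji for all pairs
  F <- pi * Q
  expect_lt(max(abs(F - t(F))), 1e-15)
  # omega = 0 kills every nonsynonymous rate
  Q0 <- build_q(pi, kappa = 3, omega = 0)
  tabs <- panretain:::.codon_tables()
  nonsyn <- tabs$single_pos > 0 & !tabs$single_syn
  expect_true(all(Q0[nonsyn] == 0))
  # multi-nucleotide changes always have rate 0
  multi <- tabs$diff_count > 1
  expect_true(all(Q[multi] == 0))
})

test_that("pruning equals exhaustive ancestral-state enumeration (3 taxa)", {
  lt <- read_newick_labeled("((A:0.3,B:0.2):0.1,C:0.4);")
  set.seed(6)
  pi <- as.vector(stats::rgamma(61, 2)); pi <- pi / sum(pi)
  sense <- sense_codons()
  aln <- vapply(1:3, function(i) {
    paste(sample(sense, 2, replace = TRUE), collapse = "")
  }, "")
  names(aln) <- c("A", "B", "C")
  ll <- tree_loglik(aln, lt, kappa = 2.5, omega_by_label = c("0" = 0.6),
                    pi = pi)
  oracle <- oracle_tree_loglik(aln, lt, 2.5, c("0" = 0.6), pi)
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("degenerate limits behave: zero branch lengths give ln pi_c", {
  lt <- read_newick_labeled("((A:0,B:0):0,C:0);")
  pi <- rep(1 / 61, 61)
  aln <- c(A = "ATG", B = "ATG", C = "ATG")
  ll <- tree_loglik(aln, lt, kappa = 2, omega_by_label = c("0" = 0.5), pi = pi)
  expect_equal(ll, log(pi[match("ATG", sense_codons())]), tolerance = 1e-10)
  expect_error(tree_loglik(c(A = "", B = "", C = ""), lt, 2,
                           omega_by_label = c("0" = 1)), "zero-length")
  expect_error(tree_loglik(c(X = "ATG", B = "ATG", C = "ATG"), lt, 2,
                           omega_by_label = c("0" = 1), pi = pi), "lacks tip")
})

test_that("likelihood is invariant to root placement and column order", {
  set.seed(12)
  pi <- as.vector(stats::rgamma(61, 2)); pi <- pi / sum(pi)
  sense <- sense_codons()
  aln <- vapply(1:4, function(i) paste(sample(sense, 20, TRUE), collapse = ""), "")
  names(aln) <- c("A", "B", "C", "D")
  lt1 <- read_newick_labeled("((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.2);")
  t2 <- ape::unroot(lt1$tree)
  lt2 <- list(tree = t2, edge_labels = rep("0", nrow(t2$edge)))
  ll1 <- tree_loglik(aln, lt1, kappa = 2, omega_by_label = c("0" = 0.5), pi = pi)
  ll2 <- tree_loglik(aln, lt2, kappa = 2, omega_by_label = c("0" = 0.5), pi = pi)
  expect_equal(ll1, ll2, tolerance = 1e-9)

  # permute codon columns
  perm <- sample(20)
  aln_p <- vapply(aln, function(s) {
    cs <- substring(s, 3 * (1:20) - 2, 3 * (1:20))
    paste(cs[perm], collapse = "")
  }, "")
  ll3 <- tree_loglik(aln_p, lt1, kappa = 2, omega_by_label = c("0" = 0.5),
                     pi = pi)
  expect_equal(ll1, ll3, tolerance = 1e-10)
})

test_that("nested branch models satisfy lnL ordering and two-ratio recovery", {
  lt <- read_newick_labeled(
    "((A:0.15,B:0.15):0.1,((C:0.1,D:0.1):0.1,(E#1:0.1,F#1:0.1)#1:0.15):0.1);")
  pi <- rep(1 / 61, 61)
  sim <- evolve_codons(lt, kappa = 2, omega_by_label = c("0" = 0.28, "1" = 0.8),
                       pi = pi, n_codons = 300, seed = 17)
  one <- fit_branch_model(sim$alignment, lt, c("0" = "w", "1" = "w"),
                          pi = pi, n_starts = 2, seed = 1)
  two <- fit_branch_model(sim$alignment, lt, c("0" = "bg", "1" = "fg"),
                          pi = pi, n_starts = 2, seed = 1)
  expect_true(one$converged)
  expect_true(two$converged)
  expect_gte(two$lnL, one$lnL - 1e-6)
  # at 300 codons the point estimates are noisy; the ordering and rough
  # location must still hold (tight recovery is exercised at 500 codons in
  # the acceptance suite)
  expect_lt(abs(two$omega_by_group["bg"] - 0.28), 0.2)
  expect_lt(abs(two$omega_by_group["fg"] - 0.8), 0.6)
  expect_lt(two$omega_by_group["bg"], two$omega_by_group["fg"])
})

test_that("Model A nests its null and returns a valid mixture", {
  lt <- make_labeled_tree()
  pi <- rep(1 / 61, 61)
  mix <- list(p0 = 0.55, p1 = 0.3, p2a = 0.55 * 0.15 / 0.85,
              p2b = 0.3 * 0.15 / 0.85, omega0 = 0.1, omega2 = 4)
  sim <- evolve_codons(lt, kappa = 2, mix = mix, pi = pi,
                       n_codons = 150, seed = 23)
  f0 <- fit_model_a_null(sim$alignment, lt, pi = pi, n_starts = 1)
  f1 <- fit_model_a(sim$alignment, lt, pi = pi, n_starts = 1)
  expect_gte(f1$lnL, f0$lnL - 1e-4)
  with(f1$mix, {
    expect_equal(p0 + p1 + p2a + p2b, 1, tolerance = 1e-8)
    expect_gte(omega2, 1)
    expect_true(omega0 >= 0 && omega0 <= 1)
    # the Model A constraint p2a/p2b = p0/p1
    expect_equal(p2a / p2b, p0 / p1, tolerance = 1e-6)
  })
  expect_identical(f0$mix$omega2, 1)
  expect_equal(f0$np, 3L)
  expect_equal(f1$np, 4L)
})

test_that("NEB posteriors concentrate on truly selected sites", {
  # 8 taxa; the foreground clade carries enough branch length for per-site
  # evidence, and the planted selected sites are conserved on the
  # background (the canonical positive-selection signature)
  lt <- read_newick_labeled(paste0(
    "(((A:0.3,B:0.3):0.15,(C:0.3,D:0.3):0.15):0.1,",
    "((E:0.3,F:0.3):0.15,(G#1:0.6,H#1:0.6)#1:0.5):0.1);"))
  pi <- rep(1 / 61, 61)
  p0 <- 0.85; p1 <- 0.05; p2 <- 0.10
  mix <- list(p0 = p0, p1 = p1, p2a = p2 * p0 / (p0 + p1),
              p2b = p2 * p1 / (p0 + p1), omega0 = 0.02, omega2 = 4)
  sim <- evolve_codons(lt, kappa = 2, mix = mix, pi = pi,
                       n_codons = 500, seed = 31)
  fit <- fit_model_a(sim$alignment, lt, pi = pi, n_starts = 2, seed = 31)
  neb <- neb_site_posteriors(fit, threshold = 0.6)
  truth_fg <- which(sim$site_classes %in% c(3L, 4L))
  called <- neb$selected_sites
  expect_gt(length(truth_fg), 0)
  recall <- length(intersect(called, truth_fg)) / length(truth_fg)
  expect_gte(recall, 0.5)
})

test_that("chi-square LRT has the closed-form behaviour", {
  expect_equal(lrt(-10, -10, 1)$stat, 0)
  expect_equal(lrt(-10, -10, 1)$p_value, 1)
  # df = 2 closed form: p = exp(-stat / 2)
  expect_equal(lrt(0, 0.51, 2)$p_value, exp(-0.51), tolerance = 1e-12)
  # p strictly decreasing in the statistic for fixed df
  stats_seq <- seq(0.1, 20, length.out = 30)
  ps <- vapply(stats_seq, function(s) lrt(0, s / 2, 1)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(lrt(0, 1, 0), "df")
  expect_warning(out <- lrt(-5, -5.01, 1), "clamped")
  expect_equal(out$stat, 0)
})
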