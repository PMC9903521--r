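# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method, with codon
# back-translation of protein alignments, relative Ka/Ks against orthogroup
# means, histogram binning and plain t-test utilities.

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each aligned residue by its source codon and each alignment gap
#' by `---`, after verifying that every ungapped protein translates exactly
#' from its CDS under the standard genetic code.
#'
#' @param protein_alignment Named character vector of aligned protein
#'   sequences (equal lengths, `-` gaps).
#' @param cds_by_id Named character vector of unaligned CDS sequences; must
#'   cover every alignment id.
#' @return Named character vector: the codon alignment.
#' @export
backtranslate <- function(protein_alignment, cds_by_id) {
  lens <- nchar(protein_alignment)
  if (length(unique(lens)) != 1L) stop("protein alignment rows differ in length")
  out <- character(length(protein_alignment))
  names(out) <- names(protein_alignment)
  for (id in names(protein_alignment)) {
    if (!id %in% names(cds_by_id)) stop("no CDS for sequence '", id, "'")
    aa <- strsplit(protein_alignment[[id]], "")[[1]]
    cds <- gsub("-", "", cds_by_id[[id]])
    codons <- split_codons(cds)
    # a trailing stop codon on the CDS is tolerated and dropped
    if (length(codons) > 0L && translate_codons(codons[length(codons)]) == "*" &&
        sum(aa != "-") == length(codons) - 1L) {
      codons <- codons[-length(codons)]
    }
    if (sum(aa != "-") != length(codons)) {
      stop(sprintf("CDS of '%s' has %d codons but alignment has %d residues",
                   id, length(codons), sum(aa != "-")))
    }
    trans <- translate_codons(codons)
    bad <- which(trans != aa[aa != "-"])
    if (length(bad) > 0L) {
      stop(sprintf("translation mismatch for '%s' at residue %d ('%s' vs codon '%s')",
                   id, bad[1], aa[aa != "-"][bad[1]], codons[bad[1]]))
    }
    cells <- rep("---", length(aa))
    cells[aa != "-"] <- codons
    out[[id]] <- paste(cells, collapse = "")
  }
  out
}

# NG86 per-codon synonymous site fraction at each of the 3 positions:
# fraction of the 3 possible nucleotide changes that are synonymous,
# changes producing stop codons excluded from the possibility set.
.ng86_site_table <- function() {
  tab <- .codon_tables()
  if (!is.null(.codon_env$ng86_sites)) return(.codon_env$ng86_sites)
  nt <- tab$nt
  syn_sites <- matrix(0, 61, 3)
  for (i in seq_len(61)) {
    cod <- strsplit(tab$codons[i], "")[[1]]
    for (pos in 1:3) {
      alts <- setdiff(nt, cod[pos])
      n_valid <- 0L; n_syn <- 0L
      for (a in alts) {
        mut <- cod; mut[pos] <- a
        mut_aa <- tab$gc[paste(mut, collapse = "")]
        if (mut_aa == "*") next    # stop-codon-adjacent change: excluded
        n_valid <- n_valid + 1L
        if (mut_aa == tab$aa[i]) n_syn <- n_syn + 1L
      }
      # each position contributes 1 site split by the synonymous fraction
      syn_sites[i, pos] <- if (n_valid > 0L) n_syn / n_valid else 0
    }
  }
  .codon_env$ng86_sites <- syn_sites
  syn_sites
}

# pathway-averaged (Sd, Nd) for one codon pair; paths through stop codons
# are discarded before averaging; returns c(NA, NA) if every path is blocked
.ng86_pair_diffs <- function(c1, c2) {
  tab <- .codon_tables()
  if (c1 == c2) return(c(0, 0))
  s1 <- strsplit(tab$codons[c1], "")[[1]]
  s2 <- strsplit(tab$codons[c2], "")[[1]]
  pos <- which(s1 != s2)
  paths <- .permutations(pos)
  tot <- c(0, 0); np <- 0L
  for (p in seq_len(nrow(paths))) {
    cur <- s1; sd <- 0; nd <- 0; ok <- TRUE
    for (step in paths[p, ]) {
      nxt <- cur; nxt[step] <- s2[step]
      a1 <- tab$gc[paste(cur, collapse = "")]
      a2 <- tab$gc[paste(nxt, collapse = "")]
      if (a2 == "*") { ok <- FALSE; break }
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); np <- np + 1L }
  }
  if (np == 0L) return(c(NA_real_, NA_real_))
  tot / np
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Pairwise Ka/Ks by NG86 counting
#'
#' Nei-Gojobori (1986) estimator: per-codon synonymous/nonsynonymous site
#' fractions (changes to stop codons excluded from the possibility set),
#' pathway-averaged difference counts for codon pairs differing at more
#' than one position (pathways through stops discarded), and Jukes-Cantor
#' correction `d = -3/4 * log(1 - 4/3 * p)`. Symmetric in sequence order.
#'
#' @param seq1,seq2 Aligned in-frame CDS strings over `A,C,G,T,-` of equal
#'   length; gaps must come in whole-codon units. Codons that are gapped or
#'   contain a stop/ambiguity in either sequence are skipped.
#' @param inf_omega If `TRUE`, report `omega = Inf` when `Ks = 0` and
#'   `Ka > 0`; otherwise report `NA`.
#' @return List with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`,
#'   `n_codons` (compared codons), and `saturated` flag.
#' @export
ng86 <- function(seq1, seq2, inf_omega = FALSE) {
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  if (length(cod1) != length(cod2)) stop("aligned sequences differ in length")
  i1 <- codon_index(cod1)
  i2 <- codon_index(cod2)
  use <- !is.na(i1) & !is.na(i2)
  if (!any(use)) stop("no shared ungapped sense codon")
  i1 <- i1[use]; i2 <- i2[use]
  sites <- .ng86_site_table()
  s1 <- sum(sites[i1, ]); s2 <- sum(sites[i2, ])
  S <- (s1 + s2) / 2
  N <- 3 * length(i1) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(i1)) {
    d <- .ng86_pair_diffs(i1[k], i2[k])
    if (anyNA(d)) next    # all pathways blocked by stops: pair uninformative
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)   # saturated
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)
  omega <- if (is.na(Ka) || is.na(Ks)) {
    NA_real_
  } else if (Ks == 0) {
    if (Ka == 0) NA_real_ else if (inf_omega) Inf else NA_real_
  } else Ka / Ks
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, omega = omega, n_codons = length(i1),
       saturated = saturated)
}

#' Relative Ka/Ks against the orthogroup mean
#'
#' @param omega_values Numeric vector of omega values for the genes of one
#'   orthogroup (NAs dropped).
#' @param gene_omega Omega of the focal gene.
#' @return `gene_omega` divided by the group mean; values above 1 indicate
#'   elevated Ka/Ks relative to the group.
#' @export
relative_kaks <- function(omega_values, gene_omega) {
  vals <- omega_values[!is.na(omega_values) & is.finite(omega_values)]
  m <- mean(vals)
  if (!length(vals) || !is.finite(m) || m <= 0) {
    stop("orthogroup mean omega undefined or non-positive")
  }
  gene_omega / m
}

#' Histogram of omega values
#'
#' @param omegas Numeric vector (NAs and infinities dropped).
#' @param edges Increasing break points; values outside are collected in
#'   open-ended flanking bins.
#' @return Named integer vector of counts per bin.
#' @export
kaks_bins <- function(omegas, edges = c(0.5, 1.0, 2.2)) {
  om <- omegas[!is.na(omegas) & is.finite(omegas)]
  if (length(om) == 0L) return(stats::setNames(integer(0), character(0)))
  breaks <- c(-Inf, edges, Inf)
  tab <- table(cut(om, breaks = breaks, right = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Two-sample / one-sample two-tailed t-test utility
#'
#' @param x,y Numeric samples; when `y` is `NULL` a one-sample test of
#'   `mean(x) == mu` is performed.
#' @param mu Null mean for the one-sample case.
#' @param var_equal Pool variances in the two-sample case.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
t_test2 <- function(x, y = NULL, mu = 0, var_equal = FALSE) {
  tt <- if (is.null(y)) {
    stats::t.test(x, mu = mu)
  } else {
    stats::t.test(x, y, var.equal = var_equal)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
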