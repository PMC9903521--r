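# Shared genetic-code machinery used by the Ka/Ks counter, the codon
# substitution models and the sequence simulator. Built once at load time
# from the standard genetic code shipped with Biostrings.

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  all_codons <- names(gc)
  sense <- all_codons[gc != "*"]            # 61 sense codons, alphabetical
  stopifnot(length(sense) == 61L)
  aa <- gc[sense]
  # per-codon nucleotide index matrix (61 x 3), letters in ACGT order
  nt <- c("A", "C", "G", "T")
  ntidx <- matrix(match(unlist(strsplit(sense, "")), nt), ncol = 3, byrow = TRUE)
  # transition pairs among nucleotides: A<->G, C<->T
  is_transition <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  # pairwise structure over the 61 sense codons
  n <- length(sense)
  diff_count <- matrix(0L, n, n)
  single_pos <- matrix(0L, n, n)     # position of the single difference (0 if not single)
  single_ts <- matrix(FALSE, n, n)   # that single change is a transition
  single_syn <- matrix(FALSE, n, n)  # that single change is synonymous
  sp <- strsplit(sense, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(sp[[i]] != sp[[j]])
      diff_count[i, j] <- length(d)
      if (length(d) == 1L) {
        single_pos[i, j] <- d
        single_ts[i, j] <- is_transition(sp[[i]][d], sp[[j]][d])
        single_syn[i, j] <- aa[i] == aa[j]
      }
    }
  }
  tab <- list(codons = sense, aa = aa, ntidx = ntidx, nt = nt,
              all_codons = all_codons, gc = gc,
              diff_count = diff_count, single_pos = single_pos,
              single_ts = single_ts, single_syn = single_syn)
  .codon_env$tab <- tab
  tab
}

#' Indices of sense codons
#'
#' Returns the 61 sense codons of the standard genetic code in the fixed
#' (alphabetical) order used throughout the package for rate matrices,
#' equilibrium frequency vectors and simulated alignments.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .codon_tables()$codons

# codon string -> index in 1..61 (NA for stops/gaps/ambiguous)
codon_index <- function(codons) {
  match(toupper(codons), .codon_tables()$codons)
}

# split an in-frame DNA string into codons
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# translate a vector of codons ("-"-free) to amino acids; stops become "*"
translate_codons <- function(codons) {
  unname(.codon_tables()$gc[toupper(codons)])
}
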