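# Readers, writers and validators for the external formats the pipeline
# consumes: hierarchical-orthogroup (HOG) tables, presence/absence matrices,
# GFF3 gene coordinates, FASTA sequence sets, labeled Newick trees, and
# pre-tabulated genotype-missingness counts.

#' Read a hierarchical orthogroup table
#'
#' Parses a tab-separated orthogroup table in the `N0.tsv` dialect: columns
#' `HOG`, `OG`, `Gene Tree Parent Clade`, then one column per species whose
#' cells hold comma-separated gene identifiers (empty cells allowed --- a
#' species may have lost the group entirely, as with genes absent from a
#' reference genome).
#'
#' @param path Path to the tab-separated file.
#' @return A data.frame of class `hog_table` with columns `hog_id`, `og_id`
#'   and one list-column of gene-id character vectors per species.
#' @export
read_hog_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  need <- c("HOG", "OG", "Gene Tree Parent Clade")
  if (!all(need %in% names(df))) {
    stop("HOG table must have columns: ", paste(need, collapse = ", "))
  }
  species <- setdiff(names(df), need)
  if (anyDuplicated(df$HOG)) {
    stop("duplicated hog_id in HOG table: ",
         paste(unique(df$HOG[duplicated(df$HOG)]), collapse = ", "))
  }
  out <- data.frame(hog_id = df$HOG, og_id = df$OG, stringsAsFactors = FALSE)
  for (sp in species) {
    out[[sp]] <- lapply(df[[sp]], .split_gene_list)
  }
  attr(out, "species") <- species
  class(out) <- c("hog_table", class(out))
  validate_hog_table(out)
  out
}

# gene-list cells are ", "-separated with fallback to ","; whitespace stripped
.split_gene_list <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  ids <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  ids[nzchar(ids)]
}

#' Validate a HOG table
#'
#' Checks that `hog_id`s are unique and that no gene identifier occurs in
#' more than one HOG (across all species columns).
#'
#' @param hogs A `hog_table`.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending records.
#' @export
validate_hog_table <- function(hogs) {
  species <- hog_species(hogs)
  if (anyDuplicated(hogs$hog_id)) stop("duplicated hog_id")
  all_genes <- character(0)
  all_hogs <- character(0)
  for (sp in species) {
    ln <- lengths(hogs[[sp]])
    all_genes <- c(all_genes, unlist(hogs[[sp]], use.names = FALSE))
    all_hogs <- c(all_hogs, rep(hogs$hog_id, ln))
  }
  dup <- duplicated(all_genes)
  if (any(dup)) {
    g <- all_genes[dup][1]
    in_hogs <- unique(all_hogs[all_genes == g])
    stop(sprintf("gene id '%s' appears in more than one HOG (%s)",
                 g, paste(in_hogs, collapse = ", ")))
  }
  invisible(hogs)
}

#' @rdname read_hog_table
#' @param hogs A `hog_table` to serialize.
#' @export
write_hog_table <- function(hogs, path) {
  species <- hog_species(hogs)
  df <- data.frame(HOG = hogs$hog_id, OG = hogs$og_id,
                   `Gene Tree Parent Clade` = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (sp in species) {
    df[[sp]] <- vapply(hogs[[sp]], paste, "", collapse = ", ")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Species columns of a HOG table
#' @param hogs A `hog_table`.
#' @return Character vector of species names.
#' @export
hog_species <- function(hogs) {
  sp <- attr(hogs, "species")
  if (is.null(sp)) sp <- setdiff(names(hogs), c("hog_id", "og_id"))
  sp
}

#' Read a presence/absence matrix
#'
#' First column holds the pangenome line identifier; remaining columns are
#' genes; cells are `0`/`1` (or `absent`/`present`). Comma- and tab-separated
#' files are both accepted.
#'
#' @param path Path to the delimited file.
#' @param species Species name to attach (defaults to the file base name).
#' @return A `pav_matrix`: logical matrix lines x genes with `dimnames`,
#'   plus a `species` attribute.
#' @export
read_pav_matrix <- function(path, species = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 2L)
  if (length(first) >= 1L && !grepl(sep, first[1], fixed = TRUE) &&
      grepl(",", first[1], fixed = TRUE)) sep <- ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty presence/absence matrix: ", path)
  line_ids <- df[[1]]
  gene_ids <- names(df)[-1]
  if (anyDuplicated(line_ids)) stop("duplicated line ids in ", path)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  calls <- matrix(NA, nrow(m), ncol(m))
  calls[m %in% c("1", "present")] <- TRUE
  calls[m %in% c("0", "absent")] <- FALSE
  if (anyNA(calls)) {
    bad <- which(is.na(calls), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell '%s' at row %d (line '%s'), column '%s' in %s",
                 m[bad[1], bad[2]], bad[1], line_ids[bad[1]],
                 gene_ids[bad[2]], path))
  }
  pav_matrix(calls, line_ids, gene_ids,
             species = if (is.null(species)) sub("\\.[^.]*$", "", basename(path)) else species)
}

#' Construct a presence/absence matrix
#'
#' @param calls Logical matrix, lines x genes.
#' @param line_ids,gene_ids Row/column identifiers (unique).
#' @param species Species label.
#' @return A `pav_matrix` object.
#' @export
pav_matrix <- function(calls, line_ids, gene_ids, species = "species") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "logical"
  if (nrow(calls) != length(line_ids) || ncol(calls) != length(gene_ids)) {
    stop("matrix dimensions do not match id lists")
  }
  if (anyDuplicated(line_ids)) stop("duplicated line ids")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  dimnames(calls) <- list(line_ids, gene_ids)
  attr(calls, "species") <- species
  class(calls) <- c("pav_matrix", class(calls))
  calls
}

#' @rdname read_pav_matrix
#' @param pav A `pav_matrix` to serialize.
#' @export
write_pav_matrix <- function(pav, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(line_id = rownames(pav), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (g in colnames(pav)) df[[g]] <- as.integer(pav[, g])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call presence/absence from genotype missingness
#'
#' Infers gene presence per pangenome line from pre-tabulated SNP genotype
#' counts: a gene is called absent in a line when the fraction of missing
#' genotype calls over its SNPs exceeds `max_missing_fraction`. Lines with
#' no genotyped SNPs for a gene (`total == 0`) are flagged "no-data" and
#' returned as `NA` so retention-rate denominators can exclude them.
#'
#' @param missing Integer matrix (lines x genes) of missing-call counts.
#' @param total Integer matrix of total genotype calls, same shape.
#' @param max_missing_fraction Absence threshold on missing/total; default 0.8.
#' @param species Species label for the resulting matrix.
#' @return A `pav_matrix` whose cells may be `NA` for no-data calls.
#' @export
pav_from_missingness <- function(missing, total, max_missing_fraction = 0.8,
                                 species = "species") {
  missing <- as.matrix(missing); total <- as.matrix(total)
  if (!identical(dim(missing), dim(total))) stop("missing/total shape mismatch")
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in [0, 1]")
  }
  if (any(missing > total)) stop("missing count exceeds total")
  frac <- missing / total                 # NaN where total == 0
  calls <- frac <= max_missing_fraction   # present iff missing fraction <= threshold
  calls[total == 0] <- NA                 # no-data
  pav_matrix(calls,
             line_ids = rownames(missing) %||% paste0("line", seq_len(nrow(missing))),
             gene_ids = colnames(missing) %||% paste0("gene", seq_len(ncol(missing))),
             species = species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene loci from a GFF3 file
#'
#' Extracts records of type `gene` and assigns each gene a 0-based rank
#' along its chromosome, ordering by start coordinate with ties broken on
#' gene id. Internally the package keeps GFF3's 1-based inclusive
#' coordinates as parsed by rtracklayer.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
read_gff_gene_loci <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  if ("type" %in% names(g)) g <- g[g$type == "gene", , drop = FALSE]
  id <- if ("ID" %in% names(g)) as.character(g$ID) else as.character(g$Name)
  loci <- data.frame(gene_id = id, chrom = as.character(g$seqid),
                     start = as.integer(g$start), end = as.integer(g$end),
                     strand = as.character(g$strand), stringsAsFactors = FALSE)
  gene_ranks(loci)
}

#' Assign per-chromosome gene ranks
#'
#' @param loci data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return Same frame, sorted by (chrom, start, gene_id), with 0-based `rank`.
#' @export
gene_ranks <- function(loci) {
  if (any(loci$start > loci$end)) stop("locus with start > end")
  if (anyDuplicated(loci$gene_id)) stop("duplicated gene ids in loci")
  ord <- order(loci$chrom, loci$start, loci$gene_id)
  loci <- loci[ord, , drop = FALSE]
  loci$rank <- stats::ave(seq_len(nrow(loci)), loci$chrom,
                          FUN = seq_along) - 1L
  rownames(loci) <- NULL
  loci
}

#' Read or write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is the representation the codon machinery works with.
#'
#' @param path FASTA file path.
#' @param validate_cds Check that sequences are in frame (length divisible
#'   by 3) and free of internal stop codons.
#' @param allow_internal_stops Skip the internal-stop check.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, validate_cds = FALSE, allow_internal_stops = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  if (validate_cds) {
    for (id in names(seqs)) {
      s <- gsub("-", "", seqs[[id]])
      if (nchar(s) %% 3L != 0L) {
        stop(sprintf("CDS length of '%s' (%d) not divisible by 3", id, nchar(s)))
      }
      if (!allow_internal_stops) {
        aa <- translate_codons(split_codons(s))
        if (any(aa[-length(aa)] == "*")) {
          stop(sprintf("internal stop codon in '%s'", id))
        }
      }
    }
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a Newick tree with foreground branch labels
#'
#' Parses a Newick string/file where branches of interest carry the `#k`
#' suffix convention on the subtending node or tip (e.g. `(A,(B,C)#1);`
#' marks the branch above the `(B,C)` clade as foreground group 1). The
#' labels are stripped from the tree and returned as a per-edge label
#' vector (`"0"` for unlabeled background edges).
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param resolve_polytomies Resolve multifurcations arbitrarily (zero-length
#'   branches) so downstream code can assume a binary tree.
#' @return List with `tree` (an [ape::phylo]) and `edge_labels` (character
#'   vector along `tree$edge` rows).
#' @export
read_newick_labeled <- function(path, resolve_polytomies = TRUE) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick input")
  lab_of <- function(x) {
    m <- regmatches(x, regexpr("#[0-9]+$", x))
    ifelse(lengths(regmatches(x, gregexpr("#[0-9]+$", x))) > 0, sub("^#", "", m), NA)
  }
  ntip <- length(tree$tip.label)
  tip_grp <- rep(NA_character_, ntip)
  has <- grepl("#[0-9]+$", tree$tip.label)
  tip_grp[has] <- sub("^.*#", "", tree$tip.label[has])
  tree$tip.label <- sub("#[0-9]+$", "", tree$tip.label)
  node_grp <- rep(NA_character_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    hasn <- grepl("#[0-9]+$", tree$node.label)
    node_grp[hasn] <- sub("^.*#", "", tree$node.label[hasn])
    tree$node.label <- sub("#[0-9]+$", "", tree$node.label)
  }
  if (resolve_polytomies && !ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    # labels indexed by node number survive multi2di for tips; node groups
    # are re-derived conservatively (polytomy resolution keeps node order
    # for pre-existing internal nodes in ape >= 5)
  }
  grp_of_node <- c(tip_grp, node_grp)
  edge_labels <- rep("0", nrow(tree$edge))
  child <- tree$edge[, 2]
  ok <- child <= length(grp_of_node) & !is.na(grp_of_node[child])
  edge_labels[ok] <- grp_of_node[child[ok]]
  list(tree = tree, edge_labels = edge_labels)
}
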