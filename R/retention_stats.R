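# Core retention-rate statistics: per-HOG gene retention rates (GRR) over
# pangenome panels, the monotone dosage-pattern filter, the R_bw
# barley/wheat preference categorisation, and GRR-vs-family-size
# correlation.

#' Gene retention rate
#'
#' The fraction of pangenome lines carrying a gene, as a percentage. No-data
#' calls (`NA`) are excluded from the denominator when `exclude_nodata` is
#' set; by default they are counted as absences, matching the convention of
#' treating unassembled regions as gene losses.
#'
#' @param presence Logical vector of per-line presence calls (may contain
#'   `NA` no-data calls).
#' @param exclude_nodata Drop `NA` calls from the denominator instead of
#'   counting them as absent.
#' @return Percentage in \[0, 100\], or `NA` if no line is countable.
#' @examples
#' grr(c(rep(TRUE, 13), rep(FALSE, 7)))  # 65
#' @export
grr <- function(presence, exclude_nodata = FALSE) {
  presence <- as.logical(presence)
  if (exclude_nodata) presence <- presence[!is.na(presence)]
  n <- length(presence)
  if (n == 0L) return(NA_real_)
  100 * sum(presence, na.rm = TRUE) / n
}

#' Retention table over a HOG table and per-species PAV matrices
#'
#' For every HOG and species, counts the pangenome lines in which at least
#' one of the HOG's genes for that species is present, and derives the gene
#' retention rate. HOGs with no gene in a species get `NA` retention there
#' (the group does not exist in that species' reference annotation); HOGs
#' whose genes are all absent from the PAV matrix columns are treated the
#' same way.
#'
#' @param hogs A `hog_table` (see [read_hog_table()]).
#' @param pavs Named list of `pav_matrix` objects, one per species; names
#'   must match the HOG table's species columns.
#' @param exclude_nodata Passed to [grr()].
#' @return data.frame keyed by `hog_id` with, per species, columns
#'   `<sp>_n_present`, `<sp>_n_lines`, `<sp>_grr`.
#' @export
retention_table <- function(hogs, pavs, exclude_nodata = FALSE) {
  species <- names(pavs)
  if (!all(species %in% hog_species(hogs))) {
    stop("PAV species not all present in HOG table: ",
         paste(setdiff(species, hog_species(hogs)), collapse = ", "))
  }
  out <- data.frame(hog_id = hogs$hog_id, og_id = hogs$og_id,
                    stringsAsFactors = FALSE)
  for (sp in species) {
    pav <- pavs[[sp]]
    npres <- nlines <- rep(NA_integer_, nrow(hogs))
    gvals <- rep(NA_real_, nrow(hogs))
    for (i in seq_len(nrow(hogs))) {
      genes <- intersect(hogs[[sp]][[i]], colnames(pav))
      if (length(genes) == 0L) next
      # a line retains the HOG if any member gene is present in it
      sub <- pav[, genes, drop = FALSE]
      pres <- apply(sub, 1L, function(x) {
        if (all(is.na(x))) NA else any(x, na.rm = TRUE)
      })
      if (exclude_nodata) pres <- pres[!is.na(pres)]
      if (length(pres) == 0L) next
      npres[i] <- sum(pres, na.rm = TRUE)
      nlines[i] <- length(pres)
      gvals[i] <- 100 * npres[i] / nlines[i]
    }
    out[[paste0(sp, "_n_present")]] <- npres
    out[[paste0(sp, "_n_lines")]] <- nlines
    out[[paste0(sp, "_grr")]] <- gvals
  }
  attr(out, "species") <- species
  out
}

#' Monotone dosage-pattern filter
#'
#' Keeps HOGs whose retention rates decrease along a given species order
#' (e.g. barley > emmer > bread wheat), the retention signature of a gene
#' duplicate under increasing dosage constraint. Strict decrease is the
#' default; `strict = FALSE` allows ties provided at least one step is
#' strict.
#'
#' @param retention A retention table from [retention_table()].
#' @param species_order Character vector of species, highest expected
#'   retention first.
#' @param hogs The originating `hog_table`, used to collect reference gene
#'   ids from the first species of `species_order`.
#' @param strict Require every step strictly decreasing.
#' @return List with `hog_ids` (passing HOGs), `genes` (reference-species
#'   gene ids of passing HOGs), `reference_species`, and `n_skipped` (HOGs
#'   lacking a retention value in some species).
#' @export
pattern_filter <- function(retention, species_order, hogs = NULL, strict = TRUE) {
  cols <- paste0(species_order, "_grr")
  if (!all(cols %in% names(retention))) {
    stop("retention table lacks species: ",
         paste(species_order[!cols %in% names(retention)], collapse = ", "))
  }
  g <- as.matrix(retention[, cols, drop = FALSE])
  complete <- stats::complete.cases(g)
  d <- g[, -ncol(g), drop = FALSE] - g[, -1, drop = FALSE]
  pass <- complete & if (strict) {
    apply(d > 0, 1L, all)
  } else {
    apply(d >= 0, 1L, all) & apply(d > 0, 1L, any)
  }
  pass[is.na(pass)] <- FALSE
  hog_ids <- retention$hog_id[pass]
  genes <- character(0)
  if (!is.null(hogs)) {
    ref <- species_order[1]
    idx <- match(hog_ids, hogs$hog_id)
    genes <- unlist(hogs[[ref]][idx], use.names = FALSE)
  }
  list(hog_ids = hog_ids, genes = genes,
       reference_species = species_order[1],
       n_skipped = sum(!complete))
}

#' Categorize retention preference between two species
#'
#' Computes `R_bw = GRR_a / GRR_b` and bins it with the cutoffs:
#' `R_bw >= 1.2` preferential to species a (barley), `0.9 < R_bw < 1.1`
#' neutral, `R_bw <= 0.8` preferential to species b (wheat). Ratios falling
#' in the deliberate gaps `(0.8, 0.9]` and `[1.1, 1.2)` are `unassigned`.
#' A gene fully lost in b but retained in a has infinite ratio and is the
#' extreme a-preferential case; both rates zero is `undefined`.
#'
#' @param grr_a,grr_b Retention-rate percentages (vectorized).
#' @return data.frame with `r_bw` and `category` (factor with levels
#'   `barley_preferential`, `neutral`, `wheat_preferential`, `unassigned`,
#'   `undefined`).
#' @export
rbw_categorize <- function(grr_a, grr_b) {
  if (length(grr_a) != length(grr_b)) stop("length mismatch")
  if (any(grr_a < 0, na.rm = TRUE) || any(grr_b < 0, na.rm = TRUE)) {
    stop("negative retention rate")
  }
  r <- ifelse(grr_b == 0, ifelse(grr_a > 0, Inf, NaN), grr_a / grr_b)
  cat <- rep(NA_character_, length(r))
  cat[!is.na(r) & r >= 1.2] <- "barley_preferential"   # includes +Inf
  cat[!is.na(r) & r > 0.9 & r < 1.1] <- "neutral"
  cat[!is.na(r) & r <= 0.8] <- "wheat_preferential"
  cat[!is.na(r) & ((r > 0.8 & r <= 0.9) | (r >= 1.1 & r < 1.2))] <- "unassigned"
  cat[is.nan(r)] <- "undefined"
  cat[is.na(grr_a) | is.na(grr_b)] <- NA
  data.frame(r_bw = r,
             category = factor(cat, levels = c("barley_preferential", "neutral",
                                               "wheat_preferential", "unassigned",
                                               "undefined")))
}

#' Family-size vs retention correlation
#'
#' Groups HOGs by their parent orthogroup (OG), defines family size as the
#' number of HOGs under the OG, averages the species' retention rate over
#' member HOGs (unweighted), and correlates mean retention with family
#' size (Pearson), also returning the least-squares slope.
#'
#' @param retention A retention table carrying an `og_id` column.
#' @param species Species whose retention rates to use.
#' @return List with `r`, `slope`, and the per-OG data.frame `og_table`
#'   (`og_id`, `family_size`, `mean_grr`).
#' @export
family_size_correlation <- function(retention, species) {
  col <- paste0(species, "_grr")
  if (!col %in% names(retention)) stop("no retention column for ", species)
  keep <- !is.na(retention[[col]])
  ret <- retention[keep, , drop = FALSE]
  if (nrow(ret) == 0L) stop("no HOGs with defined retention for ", species)
  fam <- as.data.frame(table(og_id = ret$og_id), stringsAsFactors = FALSE)
  names(fam)[2] <- "family_size"
  mg <- tapply(ret[[col]], ret$og_id, mean)
  fam$mean_grr <- as.numeric(mg[fam$og_id])
  if (nrow(fam) < 2L || length(unique(fam$family_size)) < 2L) {
    stop("need >= 2 orthogroups with distinct family sizes")
  }
  fit <- stats::lm(mean_grr ~ family_size, data = fam)
  list(r = stats::cor(fam$family_size, fam$mean_grr),
       slope = unname(stats::coef(fit)[2]),
       og_table = fam)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  stats::cor(x, y)
}

#' Log-transform a TPM expression matrix
#'
#' Elementwise `log10(TPM + 0.01)`, the transform used for expression
#' heatmaps of transcripts-per-million values.
#'
#' @param tpm Non-negative numeric matrix or vector.
#' @return Transformed matrix/vector.
#' @export
tpm_log_transform <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM value")
  log10(tpm + 0.01)
}
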