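# End-to-end "retention study" orchestration: validated configuration,
# staged execution with in/out counts, and a study report bundling the
# retention table, pattern gene set, preference categories, duplication
# classes and enrichment tables.

.config_defaults <- function() {
  list(
    preset = NULL,              # "dosage" generates a synthetic study
    hog_table = NULL,           # path or hog_table object
    pav = NULL,                 # named list of paths or pav_matrix objects
    species_order = NULL,       # required: retention-decreasing order
    rbw_species = NULL,         # pair for R_bw; default first/last of order
    exclude_nodata = FALSE,
    strict_pattern = TRUE,
    proximal_window = 10L,
    e_cutoff = 1e-5,
    top_n = 5L,
    min_block_size = 5L,
    max_gap_genes = 25L,
    enrichment_threshold = 0.05,
    annotation = NULL,          # path or data.frame gene_id/term_id
    loci = NULL,                # path (GFF3) or ranked locus data.frame
    hits = NULL,                # path (outfmt 6) or hit data.frame
    n_ogs = 300L,               # synthetic preset size
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Merges a user configuration (an R list or the path of a YAML file) with
#' the documented defaults, rejecting unknown keys and missing required
#' fields. The validated configuration is echoed into the study report's
#' provenance block.
#'
#' @param config Named list, or path to a YAML file.
#' @return The completed configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  full <- utils::modifyList(defaults, config)
  if (is.null(full$species_order) || length(full$species_order) < 2L) {
    stop("config must set species_order (>= 2 species)")
  }
  if (is.null(full$rbw_species)) {
    full$rbw_species <- c(full$species_order[1],
                          full$species_order[length(full$species_order)])
  }
  if (is.null(full$preset) && (is.null(full$hog_table) || is.null(full$pav))) {
    stop("config needs either preset = 'dosage' or hog_table + pav inputs")
  }
  class(full) <- c("pipeline_config", "list")
  full
}

.load_inputs <- function(config) {
  if (identical(config$preset, "dosage")) {
    sim <- gen_pangenome(n_ogs = config$n_ogs, seed = config$seed)
    return(list(hogs = sim$hogs, pavs = sim$pavs, truth = sim$truth))
  }
  hogs <- config$hog_table
  if (is.character(hogs)) hogs <- read_hog_table(hogs)
  pavs <- config$pav
  pavs <- stats::setNames(lapply(names(pavs), function(sp) {
    x <- pavs[[sp]]
    if (is.character(x)) read_pav_matrix(x, species = sp) else x
  }), names(pavs))
  list(hogs = hogs, pavs = pavs, truth = NULL)
}

#' Run the comparative retention study
#'
#' Strings the pipeline stages together: read (or generate) the HOG table
#' and presence/absence matrices, compute per-HOG retention rates, apply
#' the monotone dosage-pattern filter, categorize the two-species
#' preference ratio, optionally classify duplication types and run
#' per-category GO enrichment. Deterministic given the configuration and
#' its seed.
#'
#' @param config A validated configuration ([validate_config()] is applied
#'   if the input is a plain list or path).
#' @return A `study_report` list: `retention`, `pattern` (gene set),
#'   `rbw` (per-HOG categories), `category_counts`, `dup_classes` and
#'   `dup_composition` (when loci/hits supplied), `enrichment` (per
#'   category, when an annotation is supplied), `log` (stage in/out
#'   counts), and `provenance` (config echo, seed, config hash, package
#'   version).
#' @export
run_study <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  log <- list()
  inputs <- .load_inputs(config)
  log$hogs_read <- nrow(inputs$hogs)

  retention <- retention_table(inputs$hogs, inputs$pavs,
                               exclude_nodata = config$exclude_nodata)
  log$grr_computed <- sum(stats::complete.cases(
    retention[, paste0(config$species_order, "_grr")]))

  pattern <- pattern_filter(retention, config$species_order,
                            hogs = inputs$hogs, strict = config$strict_pattern)
  log$pattern_passing <- length(pattern$hog_ids)
  log$pattern_skipped <- pattern$n_skipped

  ga <- retention[[paste0(config$rbw_species[1], "_grr")]]
  gb <- retention[[paste0(config$rbw_species[2], "_grr")]]
  rbw <- cbind(retention[, c("hog_id", "og_id")], rbw_categorize(ga, gb))
  category_counts <- table(rbw$category)
  log$rbw_categorized <- sum(!is.na(rbw$category))

  dup_classes <- NULL
  dup_composition <- NULL
  if (!is.null(config$loci) && !is.null(config$hits)) {
    loci <- config$loci
    if (is.character(loci)) loci <- read_gff_gene_loci(loci)
    hits <- config$hits
    if (is.character(hits)) hits <- read_blast_hits(hits)
    hits <- filter_hits(hits, e_cutoff = config$e_cutoff, top_n = config$top_n)
    blocks <- detect_collinear_blocks(anchors_from_hits(hits, loci),
                                      min_block_size = config$min_block_size,
                                      max_gap_genes = config$max_gap_genes)
    dup_classes <- classify_duplicates(loci, hits, blocks,
                                       proximal_window = config$proximal_window)
    dup_composition <- class_composition(dup_classes)
    log$genes_classified <- nrow(dup_classes)
  }

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    annot <- config$annotation
    if (is.character(annot)) annot <- read_annotation(annot)
    ref <- config$rbw_species[1]
    gene_of_hog <- function(ids) {
      unlist(inputs$hogs[[ref]][match(ids, inputs$hogs$hog_id)], use.names = FALSE)
    }
    enrichment <- lapply(
      stats::setNames(nm = c("barley_preferential", "neutral",
                             "wheat_preferential")),
      function(cat) {
        q <- gene_of_hog(rbw$hog_id[!is.na(rbw$category) & rbw$category == cat])
        enrich(q, annot, threshold = config$enrichment_threshold)
      })
    log$enrichment_categories <- length(enrichment)
  }

  cfg_plain <- unclass(config)
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_plain, tmp)
  structure(list(
    retention = retention,
    pattern = pattern,
    rbw = rbw,
    category_counts = category_counts,
    dup_classes = dup_classes,
    dup_composition = dup_composition,
    enrichment = enrichment,
    truth = inputs$truth,
    log = log,
    provenance = list(config = cfg_plain, seed = config$seed,
                      config_md5 = unname(tools::md5sum(tmp)),
                      package_version = as.character(
                        utils::packageVersion("panretain")))),
    class = "study_report")
}
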