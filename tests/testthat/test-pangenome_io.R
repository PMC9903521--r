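# I/O layer: HOG tables, presence/absence matrices, missingness calls,
# GFF3 ranks, FASTA, labeled Newick.

make_hog_file <- function(path,
                          rows = list(
                            c("N1.HOG0000001", "OG0000001", "n1",
                              "b1, b2", "e1", "w1"),
                            c("N1.HOG0000002", "OG0000002", "n1",
                              "b3", "e2, e3", ""))) {
  header <- c("HOG", "OG", "Gene Tree Parent Clade", "barley", "emmer", "wheat")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

test_that("HOG table parsing splits gene lists and keeps empty cells empty", {
  f <- make_hog_file(withr::local_tempfile(fileext = ".tsv"))
  hogs <- read_hog_table(f)
  expect_equal(nrow(hogs), 2L)
  expect_equal(hog_species(hogs), c("barley", "emmer", "wheat"))
  expect_equal(hogs$barley[[1]], c("b1", "b2"))
  expect_equal(hogs$emmer[[2]], c("e2", "e3"))
  # the reference-absence situation: empty cell -> empty gene list
  expect_identical(hogs$wheat[[2]], character(0))
})

test_that("HOG table round-trips through write and read", {
  f <- make_hog_file(withr::local_tempfile(fileext = ".tsv"))
  hogs <- read_hog_table(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_hog_table(hogs, f2)
  hogs2 <- read_hog_table(f2)
  expect_equal(hogs2, hogs, ignore_attr = TRUE)
})

test_that("HOG validation rejects duplicate HOG ids and shared genes", {
  f <- make_hog_file(withr::local_tempfile(fileext = ".tsv"),
                     rows = list(c("H1", "O1", "n", "a1", "", ""),
                                 c("H1", "O2", "n", "a2", "", "")))
  expect_error(read_hog_table(f), "duplicated hog_id")
  f <- make_hog_file(withr::local_tempfile(fileext = ".tsv"),
                     rows = list(c("H1", "O1", "n", "a1", "", ""),
                                 c("H2", "O2", "n", "a1", "", "")))
  expect_error(read_hog_table(f), "more than one HOG")
})

test_that("PAV matrices parse, count, reject non-binary cells and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  calls <- c(rep(1L, 13), rep(0L, 7))
  writeLines(c("line_id,hpt2",
               paste(paste0("L", 1:20), calls, sep = ",")), f)
  pav <- read_pav_matrix(f, species = "barley")
  expect_equal(dim(pav), c(20L, 1L))
  expect_equal(sum(pav[, "hpt2"]), 13L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pav_matrix(pav, f2)
  expect_equal(unclass(read_pav_matrix(f2, species = "barley")),
               unclass(pav), ignore_attr = TRUE)

  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,g1,g2", "L1,1,0", "L2,2,1"), fbad)
  expect_error(read_pav_matrix(fbad), "non-binary cell '2'.*row 2.*'g1'")

  fempty <- withr::local_tempfile(fileext = ".csv")
  writeLines("line_id,g1", fempty)
  expect_error(read_pav_matrix(fempty), "empty")
})

test_that("missingness calls follow the threshold rule and flag no-data", {
  miss <- matrix(c(100, 0, 90, 70, 0), ncol = 1)
  tot <- matrix(c(100, 100, 100, 100, 0), ncol = 1)
  pav <- pav_from_missingness(miss, tot, max_missing_fraction = 0.8)
  expect_identical(as.vector(unclass(pav)), c(FALSE, TRUE, FALSE, TRUE, NA))
  expect_error(pav_from_missingness(tot, miss), "exceeds total")
  expect_error(pav_from_missingness(miss, tot, max_missing_fraction = 2),
               "must be in")
})

test_that("missingness calls are monotone in the threshold", {
  set.seed(42)
  tot <- matrix(sample(5:50, 60, replace = TRUE), nrow = 6)
  miss <- matrix(stats::rbinom(60, as.vector(tot), 0.5), nrow = 6)
  thresholds <- seq(0, 1, by = 0.1)
  prev <- NULL
  for (th in thresholds) {
    cur <- unclass(pav_from_missingness(miss, tot, th))
    if (!is.null(prev)) {
      # raising the threshold can only convert absent -> present
      expect_true(all(cur[prev]))
    }
    prev <- cur
  }
})

test_that("gene ranks order by start with deterministic tie-break on id", {
  loci <- data.frame(
    gene_id = c("g3", "g1", "g2", "gB", "gA"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(500L, 100L, 300L, 50L, 50L),
    end = c(600L, 200L, 400L, 80L, 80L),
    strand = "+")
  r <- gene_ranks(loci)
  expect_equal(r$gene_id[r$chrom == "chr1"], c("g1", "g2", "g3"))
  expect_equal(r$rank[r$chrom == "chr1"], 0:2)
  # tied starts resolved on gene_id
  expect_equal(r$gene_id[r$chrom == "chr2"], c("gA", "gB"))
  expect_equal(r$rank[r$chrom == "chr2"], 0:1)
})

test_that("GFF3 gene records parse into ranked loci", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t3001\t4000\t.\t+\t.\tID=gene2",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=t1;Parent=gene1",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gene3"), f)
  loci <- read_gff_gene_loci(f)
  expect_equal(loci$gene_id, c("gene1", "gene2", "gene3"))
  expect_equal(loci$rank, 0:2)
  expect_equal(loci$start[1], 1001L)
})

test_that("FASTA round-trips and CDS validation catches frame and stops", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(s1 = "ATGAAATTT", s2 = "ATGCCC")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)

  fbad <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(bad = "ATGAA"), fbad)
  expect_error(read_fasta(fbad, validate_cds = TRUE), "not divisible by 3")

  fstop <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(stopper = "ATGTAAAAA"), fstop)
  expect_error(read_fasta(fstop, validate_cds = TRUE), "internal stop")
  expect_silent(read_fasta(fstop, validate_cds = TRUE,
                           allow_internal_stops = TRUE))
})

test_that("Newick '#k' suffixes become foreground edge labels", {
  lt <- read_newick_labeled("(A,(B,C)#1);", resolve_polytomies = FALSE)
  expect_equal(sort(lt$tree$tip.label), c("A", "B", "C"))
  ntip <- 3L
  bc_node <- lt$tree$edge[lt$tree$edge[, 2] > ntip, 2]
  fg_edges <- which(lt$edge_labels == "1")
  expect_length(fg_edges, 1L)
  expect_equal(lt$tree$edge[fg_edges, 2], bc_node[length(bc_node)])
  # tip labels can be foreground too
  lt2 <- read_newick_labeled("(A#1:1,(B:1,C:1):1);")
  fg2 <- which(lt2$edge_labels == "1")
  expect_equal(lt2$tree$tip.label[lt2$tree$edge[fg2, 2]], "A")
})
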