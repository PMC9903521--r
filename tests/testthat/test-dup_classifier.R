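# Duplicate classification: hit filtering, collinear-block chaining, class
# assignment and composition.

test_that("hit filtering applies E-value cutoff, top-n and tie rules", {
  hits <- data.frame(query = "q",
                     subject = c("q", paste0("s", 1:7)),
                     e_value = c(0, rep(1e-10, 8))[1:8],
                     bit_score = c(999, 7:1))
  out <- filter_hits(hits)
  expect_equal(nrow(out), 5L)
  expect_false("q" %in% out$subject)          # self-hit removed
  expect_equal(out$subject, paste0("s", 1:5)) # best bit scores kept

  only_self <- data.frame(query = "q", subject = "q",
                          e_value = 0, bit_score = 100)
  expect_equal(nrow(filter_hits(only_self)), 0L)

  # E-value cutoff
  weak <- data.frame(query = "q", subject = c("a", "b"),
                     e_value = c(1e-6, 1e-3), bit_score = c(50, 60))
  expect_equal(filter_hits(weak)$subject, "a")

  # tie at the cut rank resolved deterministically by subject id
  tie <- data.frame(query = "q", subject = c("z", "y", "x", "w", "v", "u"),
                    e_value = 1e-10, bit_score = 100)
  expect_equal(sort(filter_hits(tie)$subject), c("u", "v", "w", "x", "y"))
})

test_that("collinear chaining finds diagonals above the size threshold", {
  diag6 <- data.frame(chrom_a = "c1", rank_a = 0:5,
                      chrom_b = "c2", rank_b = 10:15,
                      gene_a = paste0("a", 0:5), gene_b = paste0("b", 0:5))
  blocks <- detect_collinear_blocks(diag6)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$n_anchors, 6L)
  expect_equal(blocks[[1]]$orientation, "same")

  expect_length(detect_collinear_blocks(diag6[1:4, ]), 0L)

  inv <- data.frame(chrom_a = "c1", rank_a = 0:5,
                    chrom_b = "c2", rank_b = 15:10,
                    gene_a = paste0("a", 0:5), gene_b = paste0("b", 0:5))
  binv <- detect_collinear_blocks(inv)
  expect_length(binv, 1L)
  expect_equal(binv[[1]]$orientation, "inverted")

  # a rank gap beyond max_gap_genes breaks the chain
  gapped <- diag6
  gapped$rank_a[4:6] <- gapped$rank_a[4:6] + 30L
  gapped$rank_b[4:6] <- gapped$rank_b[4:6] + 30L
  expect_length(detect_collinear_blocks(gapped), 0L)
  expect_length(detect_collinear_blocks(gapped, min_block_size = 3), 2L)
})

test_that("best chain length equals exhaustive recursive search", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(10:25, 1)
    anchors <- data.frame(chrom_a = "c1",
                          rank_a = sample(0:29, n),
                          chrom_b = "c2",
                          rank_b = sample(0:29, n))
    anchors$gene_a <- paste0("a", seq_len(n))
    anchors$gene_b <- paste0("b", seq_len(n))
    gap <- sample(c(5L, 10L, 25L), 1)
    blocks <- detect_collinear_blocks(anchors, min_block_size = 2,
                                      max_gap_genes = gap)
    best_len <- if (length(blocks)) max(vapply(blocks, `[[`, 0, "n_anchors")) else 1
    oracle <- max(oracle_best_chain_len(anchors$rank_a, anchors$rank_b,
                                        "same", gap),
                  oracle_best_chain_len(anchors$rank_a, anchors$rank_b,
                                        "inverted", gap))
    if (oracle >= 2) {
      expect_equal(best_len, oracle,
                   info = sprintf("rep %d (n=%d gap=%d)", rep, n, gap))
    } else {
      expect_length(blocks, 0L)
    }
  }
})

make_linear_loci <- function(n = 30, chrom = "chr1") {
  gene_ranks(data.frame(gene_id = sprintf("%s_g%02d", chrom, 1:n),
                        chrom = chrom, start = (1:n) * 1000L,
                        end = (1:n) * 1000L + 500L, strand = "+"))
}

test_that("classifier applies the rank-window rules and precedence", {
  loci <- make_linear_loci(30)
  g <- loci$gene_id
  hit <- function(a, b) data.frame(query = a, subject = b,
                                   e_value = 1e-30, bit_score = 500)
  # adjacent pair -> both tandem
  out <- classify_duplicates(loci, hit(g[1], g[2]))
  expect_equal(as.character(out$class[1:2]), c("tandem", "tandem"))
  expect_equal(as.character(out$class[3]), "singleton")
  # rank distance 5 -> proximal; 11 -> dispersed (window 10)
  out <- classify_duplicates(loci, hit(g[10], g[15]))
  expect_equal(as.character(out$class[c(10, 15)]), rep("proximal", 2))
  out <- classify_duplicates(loci, hit(g[10], g[21]))
  expect_equal(as.character(out$class[c(10, 21)]), rep("dispersed", 2))
  # widening the window flips dispersed to proximal but never steals tandem
  out <- classify_duplicates(loci, hit(g[10], g[21]), proximal_window = 11)
  expect_equal(as.character(out$class[c(10, 21)]), rep("proximal", 2))
  out <- classify_duplicates(loci, hit(g[1], g[2]), proximal_window = 11)
  expect_equal(as.character(out$class[1:2]), c("tandem", "tandem"))
  # unknown gene in hits is an error
  expect_error(classify_duplicates(loci, hit(g[1], "nope")), "unknown gene")
})

test_that("classification is invariant to hit direction", {
  loci <- make_linear_loci(30)
  g <- loci$gene_id
  fwd <- data.frame(query = g[3], subject = g[8], e_value = 1e-30,
                    bit_score = 500)
  rev <- data.frame(query = g[8], subject = g[3], e_value = 1e-30,
                    bit_score = 500)
  expect_equal(classify_duplicates(loci, fwd), classify_duplicates(loci, rev))
})

test_that("classifier recovers all planted event labels exactly", {
  lay <- gen_genome_layout(n_chrom = 4, genes_per_chrom = 80,
                           events = c(tandem = 2, proximal = 2,
                                      dispersed = 2, wgd = 1),
                           seed = 5)
  hits <- filter_hits(lay$hits)
  blocks <- detect_collinear_blocks(anchors_from_hits(hits, lay$loci))
  out <- classify_duplicates(lay$loci, hits, blocks)
  expect_equal(as.character(out$class), lay$truth$class)
})

test_that("class composition percentages sum to 100 and match planted shares", {
  tab <- data.frame(gene_id = paste0("g", 1:4),
                    class = factor(c("tandem", "tandem", "dispersed",
                                     "dispersed"),
                                   levels = c("singleton", "dispersed",
                                              "proximal", "tandem",
                                              "wgd_segmental")))
  comp <- class_composition(tab)
  expect_equal(unname(comp), c(50, 50))
  allsing <- data.frame(gene_id = "g", class = factor("singleton"))
  expect_equal(unname(class_composition(allsing)), 100)

  lay <- gen_genome_layout(n_chrom = 4, genes_per_chrom = 80,
                           events = c(tandem = 3, proximal = 1,
                                      dispersed = 2, wgd = 1), seed = 9)
  hits <- filter_hits(lay$hits)
  blocks <- detect_collinear_blocks(anchors_from_hits(hits, lay$loci))
  out <- classify_duplicates(lay$loci, hits, blocks)
  comp <- class_composition(out)
  truth_comp <- 100 * table(lay$truth$class) / nrow(lay$truth)
  expect_equal(comp[names(truth_comp)], c(truth_comp), tolerance = 1e-12)
  expect_equal(sum(comp), 100, tolerance = 1e-9)
})
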