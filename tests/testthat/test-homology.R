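# Hit-table filtering, collinear chaining, paralog classification.

test_that("build_hit_table drops self-hits, enforces strict E < ceiling and truncates", {
  mk <- function(q, s, e, b) data.frame(qseqid = q, sseqid = s, evalue = e,
                                        bitscore = b)
  expect_equal(nrow(build_hit_table(mk("qA", "qA", 1e-40, 100))), 0)
  # E exactly at the ceiling is dropped (the published filter is strict)
  ht <- build_hit_table(mk("q1", c("s1", "s2"), c(1e-5, 0.9e-5),
                           c(50, 40)))
  expect_equal(ht$sseqid, "s2")
  seven <- mk("q1", paste0("s", 1:7), 1e-20, c(10, 70, 30, 60, 50, 40, 20))
  top <- build_hit_table(seven)
  expect_equal(nrow(top), 5)
  expect_equal(top$bitscore, c(70, 60, 50, 40, 30))
  bad <- mk("q1", "s1", "xx", 10)
  expect_error(build_hit_table(bad), "non-numeric evalue at row 1")
})

test_that("chaining finds same and inverted diagonals", {
  ann_a <- toy_annotation(c(A = 10))
  ann_b <- toy_annotation(c(B = 10))
  anchors <- data.frame(gene_a = sprintf("A_g%03d", 1:10),
                        gene_b = sprintf("B_g%03d", 1:10))
  bl <- chain_collinear_blocks(anchors, ann_a, ann_b)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$orientation, "same")
  expect_equal(bl[[1]]$n_anchors, 10)

  anchors_inv <- data.frame(gene_a = sprintf("A_g%03d", 1:10),
                            gene_b = sprintf("B_g%03d", 10:1))
  bl2 <- chain_collinear_blocks(anchors_inv, ann_a, ann_b)
  expect_length(bl2, 1)
  expect_equal(bl2[[1]]$orientation, "inverted")

  expect_error(chain_collinear_blocks(
    data.frame(gene_a = "nope", gene_b = "B_g001"), ann_a, ann_b),
    "unknown gene")
})

test_that("every emitted block is monotone with bounded gaps", {
  set.seed(31)
  ann_a <- toy_annotation(c(A = 100))
  ann_b <- toy_annotation(c(B = 100))
  ra <- sample(100, 200, replace = TRUE)
  rb <- sample(100, 200, replace = TRUE)
  anchors <- data.frame(gene_a = sprintf("A_g%03d", ra),
                        gene_b = sprintf("B_g%03d", rb))
  anchors <- anchors[!duplicated(anchors), ]
  bl <- chain_collinear_blocks(anchors, ann_a, ann_b, min_block_size = 5,
                               max_rank_gap = 25)
  for (b in bl) {
    da <- diff(b$anchors$rank_a)
    db <- diff(b$anchors$rank_b)
    expect_true(all(da > 0 & da <= 25))
    if (b$orientation == "same") expect_true(all(db > 0 & db <= 25))
    else expect_true(all(db < 0 & -db <= 25))
    expect_gte(b$n_anchors, 5)
  }
})

test_that("greedy chaining peels exhaustive-longest chains", {
  # each successive block must have the length of the exhaustive longest
  # remaining chain (memoized-recursion oracle), for small anchor sets
  set.seed(77)
  ann_a <- toy_annotation(c(A = 15))
  ann_b <- toy_annotation(c(B = 15))
  for (rep in 1:25) {
    n <- sample(8:25, 1)
    pts <- unique(data.frame(ra = sample(15, n, replace = TRUE),
                             rb = sample(15, n, replace = TRUE)))
    anchors <- data.frame(gene_a = sprintf("A_g%03d", pts$ra),
                          gene_b = sprintf("B_g%03d", pts$rb))
    anchors <- anchors[!duplicated(anchors), ]
    bl <- chain_collinear_blocks(anchors, ann_a, ann_b,
                                 min_block_size = 3, max_rank_gap = 6)
    remaining <- data.frame(ra = pts$ra - 1, rb = pts$rb - 1)  # ranks
    for (b in bl) {
      expect_equal(b$n_anchors,
                   oracle_longest_chain_len(remaining$ra, remaining$rb, 6))
      used <- paste(b$anchors$rank_a, b$anchors$rank_b)
      keep <- !(paste(remaining$ra, remaining$rb) %in% used)
      remaining <- remaining[keep, , drop = FALSE]
    }
    # nothing chainable above the size threshold is left behind
    expect_lt(oracle_longest_chain_len(remaining$ra, remaining$rb, 6), 3)
  }
})

test_that("implanted inversions are recovered as inverted blocks", {
  gp <- simulate_genome_pair(n_chromosomes = 2, genes_per_chromosome = 120,
                             n_inversions = 2, inversion_genes = 20,
                             specific_segments = numeric(0), seed = 12)
  anchors <- best_hits(build_hit_table(gp$hits_cross))
  bl <- chain_collinear_blocks(
    data.frame(gene_a = anchors$qseqid, gene_b = anchors$sseqid),
    gp$ref_annotation, gp$qry_annotation)
  inv_blocks <- Filter(function(b) b$orientation == "inverted", bl)
  for (i in seq_len(nrow(gp$truth$inversions))) {
    tr <- gp$truth$inversions[i, ]
    tr_genes <- sprintf("refG%02dg%04d",
                        as.integer(sub("chr", "", tr$chrom)),
                        tr$first_gene:tr$last_gene)
    cover <- vapply(inv_blocks, function(b)
      mean(tr_genes %in% b$anchors$gene_a), numeric(1))
    expect_gte(max(cover, 0), 0.8)
  }
})

test_that("paralog classes follow the block/Ks and rank-gap rules", {
  ann <- toy_annotation(c(chr1 = 20, chr2 = 20))
  blocks <- list(list(chrom_a = "chr1", chrom_b = "chr2",
                      orientation = "same", n_anchors = 5,
                      anchors = data.frame(
                        gene_a = sprintf("chr1_g%03d", 1:5),
                        gene_b = sprintf("chr2_g%03d", 1:5),
                        rank_a = 0:4, rank_b = 0:4)))
  peak <- data.frame(mu = 1.25, sigma = 0.135, weight = 1)
  pairs <- data.frame(
    gene_a = c("chr1_g001", "chr1_g010", "chr1_g006"),
    gene_b = c("chr2_g001", "chr1_g011", "chr2_g015"))
  cls <- classify_paralogs(pairs, blocks, c(1.25, 0.02, 0.025), ann, peak)
  expect_equal(cls$class, c("ech", "tandem", "other"))
  # ECH window is mu +/- 2 sigma
  cls2 <- classify_paralogs(pairs[1, ], blocks, 1.25 + 2.1 * 0.135, ann,
                            peak)
  expect_equal(cls2$class, "other")
  # both labels satisfied -> reported under both, with a warning
  both <- data.frame(gene_a = "chr1_g001", gene_b = "chr2_g001")
  blocks_same_chrom <- list(list(
    chrom_a = "chr1", chrom_b = "chr1", orientation = "same",
    n_anchors = 5,
    anchors = data.frame(gene_a = sprintf("chr1_g%03d", 1:5),
                         gene_b = sprintf("chr1_g%03d", 2:6),
                         rank_a = 0:4, rank_b = 1:5)))
  tandem_pair <- data.frame(gene_a = "chr1_g001", gene_b = "chr1_g002")
  expect_warning(
    res <- classify_paralogs(tandem_pair, blocks_same_chrom, 1.3, ann,
                             peak),
    "both")
  expect_equal(res$class, "ech|tandem")
})

test_that("retained-duplicate counting recovers the simulated retention", {
  ann <- toy_annotation(c(chr1 = 10))
  expect_equal(count_retained_duplicates(list(), ann)$n_genes, 0)
  expect_error(count_retained_duplicates(
    list(), genome_annotation(data.frame(name = "c", length = 10),
                              data.frame(gene_id = character(),
                                         chrom = character(),
                                         start = numeric(), end = numeric(),
                                         strand = character()))),
    "zero genes")

  gp <- simulate_genome_pair(n_chromosomes = 2, genes_per_chromosome = 250,
                             wgd_retention = 0.2, n_inversions = 0,
                             specific_segments = numeric(0), seed = 17)
  sht <- build_hit_table(gp$hits_self_ref)
  sbl <- chain_collinear_blocks(
    data.frame(gene_a = sht$qseqid, gene_b = sht$sseqid),
    gp$ref_annotation, gp$ref_annotation)
  dup <- count_retained_duplicates(sbl, gp$ref_annotation)
  expect_lt(abs(dup$percent - 20), 1)
})
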