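# Synthetic-data generators: determinism, truth completeness, and
# calibration of the implanted signals.

test_that("simulators are deterministic given a seed", {
  a <- simulate_codon_pair_set(20, 60, 0.5, seed = 9)
  b <- simulate_codon_pair_set(20, 60, 0.5, seed = 9)
  expect_identical(a, b)
  g1 <- simulate_genome_pair(seed = 4, genes_per_chromosome = 40,
                             n_inversions = 1, inversion_genes = 8)
  g2 <- simulate_genome_pair(seed = 4, genes_per_chromosome = 40,
                             n_inversions = 1, inversion_genes = 8)
  expect_identical(g1, g2)
  p1 <- simulate_population(n_sites = 2000, chrom_length = 100000,
                            sweep_interval = interval("chr2", 40001, 50000),
                            seed = 2)
  p2 <- simulate_population(n_sites = 2000, chrom_length = 100000,
                            sweep_interval = interval("chr2", 40001, 50000),
                            seed = 2)
  expect_identical(p1, p2)
  n1 <- simulate_network(30, 4, seed = 5)
  n2 <- simulate_network(30, 4, seed = 5)
  expect_identical(igraph::as_edgelist(n1), igraph::as_edgelist(n2))
})

test_that("codon pairs hit the target Ks and respect the JC ceiling", {
  z <- simulate_codon_pair_set(10, 60, 0, seed = 1)
  expect_true(all(z$pairs$seq_a == z$pairs$seq_b))
  expect_true(all(z$truth$n_syn == 0))

  cs <- simulate_codon_pair_set(400, 300, 1.25, seed = 7)
  ks <- estimate_ka_ks_set(cs$pairs)$Ks
  expect_lt(abs(mean(ks, na.rm = TRUE) - 1.25), 0.05)

  cs2 <- simulate_codon_pair_set(400, 300, 0.026, seed = 7)
  expect_lt(abs(mean(estimate_ka_ks_set(cs2$pairs)$Ks) - 0.026), 0.005)

  expect_error(simulate_codon_pair_set(5, 60, Inf, seed = 1),
               "Jukes-Cantor ceiling")
  expect_error(simulate_codon_pair_set(5, 10, 0.1, seed = 1), ">= 50")
})

test_that("genome pair construction matches its truth table", {
  # no inversions, no implants: alignment covers the query end to end
  gp0 <- simulate_genome_pair(n_chromosomes = 2, genes_per_chromosome = 30,
                              n_inversions = 0,
                              specific_segments = numeric(0), seed = 3)
  for (ch in gp0$qry_annotation$chromosomes$name) {
    aln <- gp0$alignments[gp0$alignments$qchrom == ch, ]
    len <- gp0$qry_annotation$chromosomes$length[
      gp0$qry_annotation$chromosomes$name == ch]
    expect_equal(sum(aln$qend - aln$qstart + 1), len)
  }
  expect_null(gp0$truth$specific_segments)

  # one 5-kb implant: exactly one 5-kb gap in query coverage
  gp1 <- simulate_genome_pair(n_chromosomes = 2, genes_per_chromosome = 30,
                              n_inversions = 0, specific_segments = 5000,
                              seed = 3)
  expect_equal(nrow(gp1$truth$specific_segments), 1)
  expect_equal(gp1$truth$specific_segments$end -
                 gp1$truth$specific_segments$start + 1, 5000)
  covered <- sum(gp1$alignments$qend - gp1$alignments$qstart + 1)
  total <- sum(gp1$qry_annotation$chromosomes$length)
  expect_equal(total - covered, 5000)
  # no alignment intersects the implant
  seg <- gp1$truth$specific_segments
  aln <- gp1$alignments[gp1$alignments$qchrom == seg$chrom, ]
  expect_true(all(aln$qend < seg$start | aln$qstart > seg$end))

  # paralog retention: fraction of genes in pairs equals the retention knob
  gp2 <- simulate_genome_pair(n_chromosomes = 2,
                              genes_per_chromosome = 500,
                              wgd_retention = 0.2, n_inversions = 0,
                              specific_segments = numeric(0), seed = 8)
  expect_equal(nrow(gp2$truth$paralog_pairs), round(0.2 * 500))
  expect_equal(2 * nrow(gp2$truth$paralog_pairs) /
                 nrow(gp2$ref_annotation$genes), 0.2)

  # every implanted feature appears in the truth exactly once
  gp3 <- simulate_genome_pair(n_chromosomes = 4, genes_per_chromosome = 50,
                              n_inversions = 2, inversion_genes = 10,
                              specific_segments = c(4000, 6000), seed = 5)
  expect_equal(nrow(gp3$truth$inversions), 2)
  expect_equal(nrow(gp3$truth$specific_segments), 2)
  expect_false(any(duplicated(gp3$truth$specific_segments[c("chrom",
                                                            "start")])))
  expect_error(simulate_genome_pair(specific_segments = 1e9, seed = 1),
               "longer than the chromosome")
})

test_that("implanted sweep raises FST in-sweep; permutation destroys it", {
  pop <- simulate_population(seed = 1)
  win <- make_genome_windows(c(chr2 = 500000), 5000)
  fst <- window_fst(pop$gt, pop$groups$female, pop$groups$male, win)
  sw <- pop$truth$sweep_interval
  inside <- fst$start >= sw$start & fst$end <= sw$end
  expect_gt(min(fst$fst[inside], na.rm = TRUE),
            median(fst$fst[!inside], na.rm = TRUE))

  # label permutation: sweep-interval coverage by selected regions
  # collapses relative to the true labels (mixed groups still inflate
  # in-sweep FST variance, so sporadic window hits remain possible)
  sw_len <- sw$end - sw$start + 1
  sc_true <- sweep_scan(pop$gt, pop$groups, candidate = "male",
                        reference = "female",
                        chrom_lengths = c(chr2 = 500000))
  cov_true <- overlap_regions(sc_true$regions, sw)$overlap_bp / sw_len
  expect_gte(cov_true, 0.5)
  set.seed(123)
  cov_perm <- vapply(1:20, function(k) {
    shuffled <- sample(pop$gt$samples)
    sc <- sweep_scan(pop$gt,
                     list(male = shuffled[1:5], female = shuffled[6:15]),
                     candidate = "male", reference = "female",
                     chrom_lengths = c(chr2 = 500000))
    overlap_regions(sc$regions, sw)$overlap_bp / sw_len
  }, numeric(1))
  expect_lt(mean(cov_perm), cov_true / 2)
})

test_that("null sweep spec produces no distinguishable window", {
  pop <- simulate_population(sweep_pi_reduction = 1, sweep_fst_boost = 0,
                             n_sites = 4000, chrom_length = 200000,
                             sweep_interval = interval("chr2", 80001,
                                                       100000),
                             seed = 6)
  win <- make_genome_windows(c(chr2 = 200000), 5000)
  fst <- window_fst(pop$gt, pop$groups$female, pop$groups$male, win)
  sw <- pop$truth$sweep_interval
  inside <- fst$start >= sw$start & fst$end <= sw$end
  # in-sweep windows indistinguishable from background
  expect_lt(mean(fst$fst[inside], na.rm = TRUE),
            quantile(fst$fst[!inside], 0.95, na.rm = TRUE))
})

test_that("population simulator enforces its preconditions", {
  expect_error(simulate_population(sweep_pi_reduction = 0), "\\(0, 1\\]")
  expect_error(simulate_population(
    sweep_interval = interval("chr2", 1, 600000)), "within the chromosome")
  expect_error(simulate_population(
    n_sites = 400, chrom_length = 20000,
    sweep_interval = interval("chr2", 1000, 2000)),
    "fewer than 50 SNPs")
  expect_error(simulate_population(n_sites = 100, chrom_length = 500000),
               "background_pi too high")
})

test_that("network generator hits saturation, edge count and heavy tails", {
  k10 <- simulate_network(10, 9, "erdos_renyi", seed = 1)
  expect_equal(igraph::ecount(k10), choose(10, 2))  # complete graph

  edges <- vapply(1:100, function(s)
    igraph::ecount(simulate_network(84, 4, "erdos_renyi", seed = s)),
    numeric(1))
  expect_lt(abs(mean(edges) - 84 * 4 / 2), 8)

  sf <- simulate_network(100, 4, "scale_free", seed = 3)
  expect_gt(max(igraph::degree(sf)), 3 * 4)
  expect_equal(sum(igraph::which_loop(sf)), 0)

  expect_error(simulate_network(10, 10, seed = 1), "mean_degree")
  expect_error(simulate_network(1, 0, seed = 1), "n_nodes")
})
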