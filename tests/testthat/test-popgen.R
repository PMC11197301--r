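# Diversity, FST, LD pruning, sweep scanning and SNP trees.

test_that("window_pi matches the unbiased per-site formula", {
  # one site, two diploids 0/0 and 1/1 in a 1-kb window
  gt <- toy_gt(matrix(c(0L, 2L), 1, 2), pos = 500)
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  expect_equal(window_pi(gt, gt$samples, win)$pi, 2 * 0.25 * (4 / 3) / 1000)
  # monomorphic window
  gt0 <- toy_gt(matrix(0L, 5, 3))
  expect_equal(window_pi(gt0, gt0$samples, win)$pi, 0)
  expect_error(window_pi(gt0, character(0), win), "empty group")
})

test_that("window_fst matches the Hudson formula on hand cases", {
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  # fixed difference at large n -> FST ~ 1
  gt <- toy_gt(cbind(matrix(2L, 1, 20), matrix(0L, 1, 20)), pos = 10)
  f <- window_fst(gt, sprintf("s%02d", 1:20), sprintf("s%02d", 21:40), win)
  expect_equal(f$fst, 1)
  # p1 = 0.8 (10 alleles), p2 = 0.2 (10 alleles):
  # num = 0.36 - 2*(0.16/9), den = 0.68 -> 0.47712
  g <- matrix(c(2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L, 1L), 1, 10)
  gt2 <- toy_gt(g, pos = 10)
  f2 <- window_fst(gt2, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10), win)
  expect_equal(f2$fst, (0.36 - 2 * (0.16 / 9)) / 0.68, tolerance = 1e-10)
  expect_equal(f2$fst, 0.47712, tolerance = 1e-4)
  # swapping labels leaves FST unchanged
  f3 <- window_fst(gt2, sprintf("s%02d", 6:10), sprintf("s%02d", 1:5), win)
  expect_equal(f2$fst, f3$fst)
  # two groups drawn from the same allele frequencies: FST ~ 0
  set.seed(4)
  big <- toy_gt(matrix(rbinom(50 * 80, 2, 0.4), 50, 80),
                pos = seq_len(50) * 10)
  same <- window_fst(big, big$samples[1:40], big$samples[41:80], win)
  expect_lt(abs(same$fst), 0.05)
  expect_error(window_fst(gt2, character(0), "s01", win), "empty group")
})

test_that("pi and FST equal brute-force oracles on random toy tables", {
  set.seed(55)
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  for (rep in 1:40) {
    ns <- sample(2:5, 1)
    nsite <- sample(1:10, 1)
    g <- matrix(sample(c(0:2, NA), ns * 2 * nsite, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), nsite, ns * 2)
    gt <- toy_gt(g, pos = sort(sample(1000, nsite)))
    sa <- gt$samples[1:ns]
    sb <- gt$samples[(ns + 1):(2 * ns)]
    pi_pkg <- window_pi(gt, sa, win)$pi
    pi_or <- oracle_window_pi(g[, 1:ns, drop = FALSE], 1000)
    if (!is.na(pi_pkg)) expect_equal(pi_pkg, pi_or, tolerance = 1e-12)
    f_pkg <- window_fst(gt, sa, sb, win)$fst
    f_or <- oracle_window_fst(g[, 1:ns, drop = FALSE],
                              g[, (ns + 1):(2 * ns), drop = FALSE])
    expect_equal(f_pkg, f_or, tolerance = 1e-12)
  }
})

test_that("ld_prune removes duplicated columns and keeps independent ones", {
  set.seed(8)
  base <- matrix(sample(0:2, 30 * 40, replace = TRUE), 30, 40)
  dup <- rbind(base[1, ], base)  # site 2 duplicates site 1
  gt <- toy_gt(dup)
  pruned <- ld_prune(gt)
  expect_equal(attr(pruned, "n_removed") >= 1, TRUE)
  # the later duplicate is removed, the first kept
  expect_true(10 %in% pruned$sites$pos)   # site 1 at pos 10
  expect_false(identical(nrow(pruned$sites), nrow(gt$sites)))

  # mutually independent columns: almost everything is retained
  big <- matrix(rbinom(60 * 200, 2, 0.5), 60, 200)
  gt2 <- toy_gt(big)
  pruned2 <- ld_prune(gt2)
  expect_gte(nrow(pruned2$sites) / 60, 0.95)

  # monomorphic sites have undefined r2 and are always retained
  mono <- rbind(matrix(1L, 1, 10), matrix(rbinom(20 * 10, 2, 0.5), 20, 10))
  mono[1, ] <- 0L
  gt3 <- toy_gt(mono)
  expect_true(10 %in% ld_prune(gt3)$sites$pos)
})

test_that("scan_sweeps requires both top-quantile criteria, strictly", {
  win <- make_genome_windows(c(chr1 = 150000), 5000)
  # degenerate: all windows identical -> strict > selects nothing
  st <- cbind(win, fst = 0.2, pi_ratio = 1.5)
  sc <- scan_sweeps(st)
  expect_equal(sum(sc$windows$selected), 0)
  expect_equal(nrow(sc$regions), 0)
  # one window on top of both criteria; a second high on only one
  st2 <- st
  st2$fst[5] <- 0.9; st2$pi_ratio[5] <- 9
  st2$fst[10] <- 0.95                       # ratio stays at baseline
  sc2 <- scan_sweeps(st2)
  expect_equal(which(sc2$windows$selected), 5)
  # adjacent selected windows merge into one region
  st3 <- st
  st3$fst[7:8] <- 0.9; st3$pi_ratio[7:8] <- 9
  sc3 <- scan_sweeps(st3)
  expect_equal(nrow(sc3$regions), 1)
  expect_equal(sc3$regions$start, st3$start[7])
  expect_equal(sc3$regions$end, st3$end[8])
  expect_error(scan_sweeps(st[1:10, ]), "at least 20")
})

test_that("overlap_regions computes inclusive overlap and containment", {
  sdr <- interval("chr2", 5055465, 5198824)
  expect_equal(overlap_regions(data.frame(chrom = "chr3", start = 1,
                                          end = 10), sdr),
               list(overlap_bp = 0, fully_contains = FALSE))
  ov <- overlap_regions(data.frame(chrom = "chr2", start = 5000001,
                                   end = 5300000), sdr)
  expect_equal(ov$overlap_bp, 143360)
  expect_true(ov$fully_contains)
  half <- overlap_regions(data.frame(chrom = "chr2", start = 5100000,
                                     end = 5300000), sdr)
  expect_equal(half$overlap_bp, 5198824 - 5100000 + 1)
  expect_false(half$fully_contains)
})

test_that("allele-sharing distances match hand computation", {
  g <- matrix(c(0L, 0L, 0L,
                2L, 2L, 2L,
                0L, 1L, 2L,
                1L, 1L, 0L), nrow = 4, byrow = TRUE)
  gt <- toy_gt(g)
  d <- snp_distance_matrix(gt)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # pair (1,2): |0-0|+|2-2|+|0-1|+|1-1| = 1 over 4 sites -> 0.125
  expect_equal(d[1, 2], (0 + 0 + 1 + 0) / 4 / 2)
  expect_equal(d[1, 3], (0 + 0 + 2 + 1) / 4 / 2)

  opp <- toy_gt(matrix(c(0L, 2L, 1L), 10, 3, byrow = TRUE))
  expect_equal(snp_distance_matrix(opp)[1, 2], 1)

  miss <- toy_gt(matrix(c(0L, NA, 1L, NA, 2L, NA), 2, 3, byrow = TRUE))
  expect_error(snp_distance_matrix(miss), "no shared non-missing")
})

test_that("nj_tree recovers an additive 4-leaf tree", {
  # ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(dm)
  expect_true(tree_separates_group(tr, c("A", "B")))
  expect_true(tree_separates_group(tr, c("C", "D")))
  expect_false(tree_separates_group(tr, c("A", "C")))
  # branch lengths reproduce the generating tree (sum = 11)
  expect_equal(sum(tr$edge.length), 11)
  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "not symmetric")
})

test_that("SDR-restricted tree groups by sex while genome-wide does not", {
  pop <- simulate_population(seed = 3)
  males <- pop$groups$male
  region_tree <- nj_tree(snp_distance_matrix(
    pop$gt, restrict = pop$truth$sweep_interval))
  genome_tree <- nj_tree(snp_distance_matrix(pop$gt))
  expect_true(tree_separates_group(region_tree, males))
  expect_false(tree_separates_group(genome_tree, males))
  # the genome-wide tree instead follows the simulated ancestry clusters
  origin1 <- names(pop$origins)[pop$origins == 1]
  expect_true(tree_separates_group(genome_tree, origin1))
})
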