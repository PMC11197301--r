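# Windowed nucleotide diversity and Hudson FST, PLINK-style LD pruning,
# joint top-5% sweep calling, candidate-region overlap, and region-restricted
# neighbor-joining SNP phylogenies.

# per-site ALT allele frequency and non-missing allele count for a sample set
.site_allele_stats <- function(gt, samples) {
  missing <- setdiff(samples, gt$samples)
  if (length(missing) > 0)
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  g <- gt$geno[, samples, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  list(p = p, n = n)
}

# map sites to windows (possibly overlapping); returns Hits-like index pairs
.site_window_hits <- function(sites, windows) {
  out_site <- integer(0); out_win <- integer(0)
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    ssel <- which(sites$chrom == ch)
    if (length(ssel) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[ssel], width = 1),
      IRanges::IRanges(windows$start[wsel], windows$end[wsel]))
    out_site <- c(out_site, ssel[S4Vectors::queryHits(ov)])
    out_win <- c(out_win, wsel[S4Vectors::subjectHits(ov)])
  }
  list(site = out_site, window = out_win)
}

#' Non-overlapping genome windows
#'
#' Tiles each chromosome with fixed-size windows (the final window is
#' truncated at the chromosome end). The default 5-kb geometry matches the
#' resolution at which selective-sweep regions are conventionally reported.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param size window size in bp (default 5000).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_genome_windows <- function(chrom_lengths, size = 5000) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per SNP site the unbiased heterozygosity `2*p*(1-p)*n/(n-1)` is computed
#' with `n` the number of non-missing alleles in the group (sites with
#' `n < 2` are skipped); window pi is the sum over the window's SNPs divided
#' by the window length in bp.
#'
#' @param gt [genotype_table()].
#' @param samples sample ids of the group (non-empty).
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @return `windows` with `pi` and `n_snps` columns; windows whose group data
#'   are entirely missing get `pi = NA`.
#' @export
window_pi <- function(gt, samples, windows) {
  if (length(samples) == 0) stop("empty group")
  st <- .site_allele_stats(gt, samples)
  het <- ifelse(st$n >= 2, 2 * st$p * (1 - st$p) * st$n / (st$n - 1),
                NA_real_)
  hits <- .site_window_hits(gt$sites, windows)
  pi_sum <- rep(0, nrow(windows))
  n_used <- rep(0L, nrow(windows))
  n_tot <- rep(0L, nrow(windows))
  ok <- !is.na(het[hits$site])
  agg <- tapply(het[hits$site][ok], hits$window[ok], sum)
  pi_sum[as.integer(names(agg))] <- agg
  cnt <- tapply(rep(1L, sum(ok)), hits$window[ok], sum)
  n_used[as.integer(names(cnt))] <- cnt
  tot <- tapply(rep(1L, length(hits$site)), hits$window, sum)
  n_tot[as.integer(names(tot))] <- tot
  windows$pi <- pi_sum / (windows$end - windows$start + 1)
  windows$pi[n_tot > 0 & n_used == 0] <- NA_real_  # all-missing group
  windows$n_snps <- n_tot
  windows
}

#' Windowed Hudson FST
#'
#' Ratio-of-averages Hudson estimator: per site the numerator is
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`; the window FST is the ratio of the sums. Sites
#' where either group has fewer than 2 non-missing alleles are excluded;
#' windows with zero denominator get `NA`.
#'
#' @param gt [genotype_table()].
#' @param samples_a,samples_b the two groups (non-empty, disjoint not
#'   required).
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @return `windows` with `fst` and `n_snps_fst` columns.
#' @export
window_fst <- function(gt, samples_a, samples_b, windows) {
  if (length(samples_a) == 0 || length(samples_b) == 0) stop("empty group")
  a <- .site_allele_stats(gt, samples_a)
  b <- .site_allele_stats(gt, samples_b)
  usable <- a$n >= 2 & b$n >= 2
  num <- ifelse(usable,
                (a$p - b$p)^2 - a$p * (1 - a$p) / (a$n - 1) -
                  b$p * (1 - b$p) / (b$n - 1),
                NA_real_)
  den <- ifelse(usable, a$p * (1 - b$p) + b$p * (1 - a$p), NA_real_)
  hits <- .site_window_hits(gt$sites, windows)
  ok <- !is.na(num[hits$site])
  num_sum <- rep(0, nrow(windows)); den_sum <- rep(0, nrow(windows))
  n_used <- rep(0L, nrow(windows))
  agg_n <- tapply(num[hits$site][ok], hits$window[ok], sum)
  num_sum[as.integer(names(agg_n))] <- agg_n
  agg_d <- tapply(den[hits$site][ok], hits$window[ok], sum)
  den_sum[as.integer(names(agg_d))] <- agg_d
  cnt <- tapply(rep(1L, sum(ok)), hits$window[ok], sum)
  n_used[as.integer(names(cnt))] <- cnt
  windows$fst <- ifelse(den_sum > 0, num_sum / den_sum, NA_real_)
  windows$n_snps_fst <- n_used
  windows
}

#' PLINK-style LD pruning
#'
#' Within each sliding window of `window_snps` SNPs (advancing `step_snps`
#' at a time, per chromosome): while any retained pair has squared genotype
#' correlation above `r2_max`, the later member of the highest-r2 pair is
#' removed. Monomorphic sites have undefined r2 and are always retained.
#' The result is order-deterministic.
#'
#' @param gt [genotype_table()] with at least 2 samples.
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps step in SNPs (default 5).
#' @param r2_max r-squared threshold (default 0.5, strict `>` removal).
#' @return pruned [genotype_table()]; `attr(, "n_removed")` counts removed
#'   sites.
#' @export
ld_prune <- function(gt, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  if (length(gt$samples) < 2) stop("need at least 2 samples")
  removed <- rep(FALSE, nrow(gt$sites))
  for (ch in unique(gt$sites$chrom)) {
    idx <- which(gt$sites$chrom == ch)
    n <- length(idx)
    if (n < 2) next
    for (s in seq(1, max(1, n - 1), by = step_snps)) {
      widx <- idx[s:min(s + window_snps - 1, n)]
      widx <- widx[!removed[widx]]
      if (length(widx) < 2) next
      G <- gt$geno[widx, , drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(t(G), use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0       # monomorphic/insufficient data: keep
      r2[lower.tri(r2, diag = TRUE)] <- 0
      while (max(r2) > r2_max) {
        hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]  # deterministic
        drop_local <- max(hit)      # the later member (upper triangle: col)
        removed[widx[drop_local]] <- TRUE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
  }
  out <- genotype_subset(gt, which(!removed))
  attr(out, "n_removed") <- sum(removed)
  out
}

#' Joint top-quantile selective-sweep scan
#'
#' Windows whose FST and theta-pi ratio both strictly exceed their empirical
#' top-`1 - quantile` thresholds (default: top 5%) are selected; adjacent or
#' overlapping selected windows are merged into candidate selection regions.
#' Thresholds are empirical quantiles (linear interpolation) over finite
#' windows; ties at the threshold are excluded (strict `>`), and infinite
#' pi ratios (diversity lost entirely in the candidate group) always pass
#' the ratio criterion.
#'
#' @param stats data.frame with `chrom`, `start`, `end`, `fst`, `pi_ratio`.
#' @param quantile quantile for both thresholds (default 0.95).
#' @param comparison optional label (e.g. `"female-vs-male"`).
#' @return list of class `"sweep_scan"`: `thresholds` (`fst_q`, `ratio_q`),
#'   `windows` (input plus `selected`), `regions` (merged intervals),
#'   `comparison`.
#' @export
scan_sweeps <- function(stats, quantile = 0.95, comparison = "") {
  fin_fst <- stats$fst[is.finite(stats$fst)]
  fin_ratio <- stats$pi_ratio[is.finite(stats$pi_ratio)]
  if (length(fin_fst) < 20 || length(fin_ratio) < 20)
    stop("need at least 20 finite windows")
  fst_q <- stats::quantile(fin_fst, quantile, names = FALSE, type = 7)
  ratio_q <- stats::quantile(fin_ratio, quantile, names = FALSE, type = 7)
  sel <- !is.na(stats$fst) & !is.na(stats$pi_ratio) &
    stats$fst > fst_q & stats$pi_ratio > ratio_q
  stats$selected <- sel
  regions <- lapply(sort(unique(stats$chrom[sel])), function(ch) {
    ssel <- sel & stats$chrom == ch
    red <- IRanges::reduce(IRanges::IRanges(stats$start[ssel],
                                            stats$end[ssel]),
                           min.gapwidth = 1L)
    data.frame(chrom = ch, start = IRanges::start(red),
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions)
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
  structure(list(thresholds = c(fst_q = fst_q, ratio_q = ratio_q),
                 windows = stats, regions = regions,
                 comparison = comparison),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf(
    "sweep_scan%s: %d selected window(s) in %d region(s); FST > %.4f, pi ratio > %.4f\n",
    if (nzchar(x$comparison)) paste0(" [", x$comparison, "]") else "",
    sum(x$windows$selected), nrow(x$regions),
    x$thresholds["fst_q"], x$thresholds["ratio_q"]))
  invisible(x)
}

#' End-to-end sweep scan between two groups
#'
#' Convenience wrapper: tiles the genome, computes per-window pi for both
#' groups and Hudson FST between them, forms the theta-pi ratio
#' `pi(reference) / pi(candidate)` -- so a sweep in the candidate group
#' raises the ratio -- and calls [scan_sweeps()].
#'
#' @param gt [genotype_table()].
#' @param groups named character vector or list mapping group name ->
#'   sample ids.
#' @param candidate group under test for a sweep (reduced diversity).
#' @param reference contrast group.
#' @param chrom_lengths named lengths; defaults to the max position per
#'   chromosome.
#' @param window_size window size in bp (default 5000).
#' @param quantile top quantile (default 0.95).
#' @return [scan_sweeps()] result; `$windows` carries `pi_ref`, `pi_cand`,
#'   `pi_ratio`, `fst`.
#' @export
sweep_scan <- function(gt, groups, candidate, reference,
                       chrom_lengths = NULL, window_size = 5000,
                       quantile = 0.95) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gt$sites$pos, gt$sites$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  win <- make_genome_windows(chrom_lengths, window_size)
  ref <- window_pi(gt, groups[[reference]], win)
  cand <- window_pi(gt, groups[[candidate]], win)
  fst <- window_fst(gt, groups[[reference]], groups[[candidate]], win)
  stats_df <- win
  stats_df$pi_ref <- ref$pi
  stats_df$pi_cand <- cand$pi
  stats_df$pi_ratio <- ifelse(
    is.na(ref$pi) | is.na(cand$pi), NA_real_,
    ifelse(cand$pi > 0, ref$pi / cand$pi,
           ifelse(ref$pi > 0, Inf, NA_real_)))
  stats_df$fst <- fst$fst
  stats_df$n_snps <- ref$n_snps
  scan_sweeps(stats_df, quantile,
              comparison = paste0(reference, "-vs-", candidate))
}

#' Overlap between selection regions and a candidate interval
#'
#' @param regions data.frame with `chrom`, `start`, `end` (e.g.
#'   `sweep_scan$regions`).
#' @param candidate [interval()], e.g. a putative sex-determination region.
#' @return list with `overlap_bp` (total base-pair overlap, inclusive
#'   coordinates) and `fully_contains` (TRUE iff the candidate lies entirely
#'   within one region).
#' @export
overlap_regions <- function(regions, candidate) {
  sel <- regions$chrom == candidate$chrom
  if (!any(sel)) return(list(overlap_bp = 0, fully_contains = FALSE))
  ov <- pmax(0, pmin(regions$end[sel], candidate$end) -
               pmax(regions$start[sel], candidate$start) + 1)
  contains <- any(regions$start[sel] <= candidate$start &
                    regions$end[sel] >= candidate$end)
  list(overlap_bp = sum(ov), fully_contains = contains)
}

#' Pairwise allele-sharing distance matrix
#'
#' Distance between two samples is the mean absolute dosage difference over
#' sites non-missing in both, divided by 2 (0 = identical genotypes, 1 =
#' opposite homozygotes everywhere). `restrict` filters sites to an interval
#' first (e.g. the SDR) for region-restricted phylogenies.
#'
#' @param gt [genotype_table()] with at least 3 samples.
#' @param restrict optional [interval()].
#' @return symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
snp_distance_matrix <- function(gt, restrict = NULL) {
  if (length(gt$samples) < 3) stop("need at least 3 samples")
  if (!is.null(restrict)) {
    keep <- gt$sites$chrom == restrict$chrom &
      gt$sites$pos >= restrict$start & gt$sites$pos <= restrict$end
    gt <- genotype_subset(gt, which(keep))
  }
  g <- gt$geno
  n <- length(gt$samples)
  d <- matrix(0, n, n, dimnames = list(gt$samples, gt$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(shared))
        stop("no shared non-missing sites between ", gt$samples[i],
             " and ", gt$samples[j])
      d[i, j] <- d[j, i] <- mean(abs(g[shared, i] - g[shared, j])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero.
#'
#' @param dm symmetric distance matrix with >= 3 leaves (zero diagonal).
#' @return `phylo` tree with `tip.label` equal to the sample set.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 leaves")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Does an unrooted tree separate a group of leaves?
#'
#' TRUE when some internal edge bipartitions the leaf set exactly into
#' `group` versus the rest (i.e. the group is a clade in the unrooted
#' sense).
#'
#' @param tree `phylo` object.
#' @param group character vector of tip labels.
#' @return logical.
#' @export
tree_separates_group <- function(tree, group) {
  tips <- tree$tip.label
  group <- intersect(group, tips)
  if (length(group) < 1 || length(group) >= length(tips)) return(FALSE)
  if (length(group) == 1) return(TRUE)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(group, labs))
  anti <- sort(setdiff(seq_along(labs), target))
  any(vapply(parts, function(p) {
    ps <- sort(p)
    identical(ps, target) || identical(ps, anti)
  }, logical(1)))
}
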