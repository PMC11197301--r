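# Independent oracles used to validate the package's estimators: these are
# deliberately written as direct/brute-force implementations (recursive
# pathway enumeration, bitmaps, per-site loops) and share no code with R/.

# --- NG86 oracle: recursive pathway enumeration -----------------------------

oracle_ng86 <- function(seq_a, seq_b) {
  gc_map <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) gc_map[[cod]]
  split_codons <- function(s) {
    s <- toupper(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  syn_sites_codon <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    aa <- translate1(cod)
    s <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b
      if (translate1(paste(alt, collapse = "")) == aa) s <- s + 1
    }
    s / 3
  }
  # all minimal pathways c1 -> c2, excluding stop intermediates/endpoints
  paths <- function(c1, c2, allow_stop = FALSE) {
    ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
    pos <- which(ch1 != ch2)
    if (length(pos) == 0) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      mid <- ch1; mid[p] <- ch2[p]
      midc <- paste(mid, collapse = "")
      if (!allow_stop && translate1(midc) == "*") next
      step_syn <- translate1(c1) == translate1(midc)
      for (rest in paths(midc, c2, allow_stop)) {
        out[[length(out) + 1]] <-
          rest + if (step_syn) c(1, 0) else c(0, 1)
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_sites_codon(ca[i]) + syn_sites_codon(cb[i])) / 2
    pw <- paths(ca[i], cb[i])
    if (length(pw) == 0) pw <- paths(ca[i], cb[i], allow_stop = TRUE)
    avg <- Reduce(`+`, pw) / length(pw)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

# --- longest monotone chain oracle (memoized recursion over successors) -----

oracle_longest_chain_len <- function(ra, rb, max_gap) {
  longest_dir <- function(x, y) {
    n <- length(x)
    memo <- rep(NA_integer_, n)
    rec <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      succ <- which(x > x[i] & x - x[i] <= max_gap &
                      y > y[i] & y - y[i] <= max_gap)
      best <- 0L
      for (j in succ) best <- max(best, rec(j))
      memo[i] <<- 1L + best
      memo[i]
    }
    if (n == 0) return(0L)
    max(vapply(seq_len(n), rec, integer(1)))
  }
  max(longest_dir(ra, rb), longest_dir(ra, -rb))
}

# --- per-site popgen oracles ------------------------------------------------

oracle_window_pi <- function(geno, win_len) {
  tot <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    g <- g[!is.na(g)]
    n <- 2 * length(g)
    if (n < 2) next
    p <- sum(g) / n
    tot <- tot + 2 * p * (1 - p) * n / (n - 1)
  }
  tot / win_len
}

oracle_window_fst <- function(geno_a, geno_b) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(geno_a))) {
    ga <- geno_a[i, ]; ga <- ga[!is.na(ga)]
    gb <- geno_b[i, ]; gb <- gb[!is.na(gb)]
    n1 <- 2 * length(ga); n2 <- 2 * length(gb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(ga) / n1; p2 <- sum(gb) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# --- base-level interval union via bitmap (toy chromosomes only) ------------

oracle_union_length <- function(starts, ends, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  sum(mask)
}

# --- exhaustive robustness average ------------------------------------------

oracle_robustness_exhaustive <- function(net, k) {
  n <- igraph::vcount(net)
  subsets <- utils::combn(n, k)
  vals <- apply(subsets, 2, function(drop) {
    g2 <- igraph::delete_vertices(net, drop)
    if (igraph::vcount(g2) == 0) return(0)
    max(igraph::components(g2)$csize) / n
  })
  mean(vals)
}
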