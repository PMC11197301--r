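# Nei-Gojobori (1986) synonymous/nonsynonymous counting with Jukes-Cantor
# multiple-hit correction.
#
# Site counting: each codon position contributes f/3 synonymous sites, where
# f is the fraction of the three possible single-nucleotide changes that are
# synonymous; changes to stop codons count as nonsynonymous. Sites are
# averaged over the two sequences. Difference counting: codons differing at
# more than one position are resolved by averaging over all minimal
# substitution pathways, excluding pathways that pass through a stop codon
# (if every pathway is blocked, all pathways are used).

.ng86 <- new.env(parent = emptyenv())

.ng86_tables <- function() {
  if (!is.null(.ng86$codons)) return(.ng86)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))

  syn_sites <- rep(NA_real_, n)
  syn_pos <- matrix(NA_real_, n, 3, dimnames = list(codons, NULL))
  syn_alt <- vector("list", n)    # synonymous replacement bases per position
  nonsyn_alt <- vector("list", n) # nonsynonymous non-stop replacements
  names(syn_alt) <- names(nonsyn_alt) <- codons
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    sa <- list(character(0), character(0), character(0))
    na_ <- list(character(0), character(0), character(0))
    for (p in 1:3) {
      for (b in setdiff(bases, cmat[i, p])) {
        alt <- cmat[i, ]
        alt[p] <- b
        alt_aa <- gc_map[[paste(alt, collapse = "")]]
        if (alt_aa == aa[i]) {
          sa[[p]] <- c(sa[[p]], b)  # stop-codon changes stay nonsyn
        } else if (alt_aa != "*") {
          na_[[p]] <- c(na_[[p]], b)
        }
      }
      syn_pos[i, p] <- length(sa[[p]]) / 3
    }
    syn_sites[i] <- sum(syn_pos[i, ])
    syn_alt[[i]] <- sa
    nonsyn_alt[[i]] <- na_
  }

  # per-pair (Sd, Nd) by minimal-pathway enumeration
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  path_counts <- function(i, j) {
    diff_pos <- which(cmat[i, ] != cmat[j, ])
    d <- length(diff_pos)
    if (d == 0) return(c(0, 0))
    pm <- perms[[as.character(d)]]
    walk <- function(order_idx, allow_stop) {
      cur <- cmat[i, ]
      sd <- 0; nd <- 0
      for (p in diff_pos[order_idx]) {
        nxt <- cur
        nxt[p] <- cmat[j, p]
        aa_from <- gc_map[[paste(cur, collapse = "")]]
        aa_to <- gc_map[[paste(nxt, collapse = "")]]
        if (aa_to == "*" && !allow_stop) return(NULL)
        if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(seq_len(nrow(pm)), function(r) walk(pm[r, ], FALSE))
    res <- res[!vapply(res, is.null, TRUE)]
    if (length(res) == 0)
      res <- lapply(seq_len(nrow(pm)), function(r) walk(pm[r, ], TRUE))
    cnt <- Reduce(`+`, res) / length(res)
    cnt
  }

  sd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  sense <- which(aa != "*")
  for (i in sense) for (j in sense) {
    pc <- path_counts(i, j)
    sd_mat[i, j] <- pc[1]
    nd_mat[i, j] <- pc[2]
  }

  .ng86$codons <- codons
  .ng86$aa <- aa
  .ng86$sense <- which(aa != "*")
  .ng86$syn_sites <- stats::setNames(syn_sites, codons)
  .ng86$syn_pos <- syn_pos
  .ng86$syn_alt <- syn_alt
  .ng86$nonsyn_alt <- nonsyn_alt
  .ng86$sd <- sd_mat
  .ng86$nd <- nd_mat
  .ng86
}

# split aligned CDS into codon index vectors; drops codon columns containing
# gaps or Ns in either sequence, drops a shared terminal stop.
.codon_indices <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length")
  if (nchar(seq_a) %% 3 != 0)
    stop("alignment length must be divisible by 3")
  tb <- .ng86_tables()
  n_codon <- nchar(seq_a) %/% 3
  starts <- seq(1, by = 3, length.out = n_codon)
  ca <- substring(seq_a, starts, starts + 2)
  cb <- substring(seq_b, starts, starts + 2)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) stop("no ungapped codons in alignment")
  ia <- match(ca, tb$codons)
  ib <- match(cb, tb$codons)
  stop_a <- tb$aa[ia] == "*"
  stop_b <- tb$aa[ib] == "*"
  k <- length(ia)
  if (stop_a[k] || stop_b[k]) {  # terminal stop codon: excluded from counts
    if (stop_a[k] && stop_b[k]) {
      ia <- ia[-k]; ib <- ib[-k]
      stop_a <- stop_a[-k]; stop_b <- stop_b[-k]
    }
  }
  if (any(stop_a) || any(stop_b))
    stop("internal stop codon in alignment")
  list(ia = ia, ib = ib, tb = tb)
}

#' Nei-Gojobori site and difference counts
#'
#' @param seq_a,seq_b equal-length aligned CDS strings (length divisible by
#'   3). Codon columns containing `-` or `N` are dropped; internal stop
#'   codons are an error.
#' @return list of class `"ng86_counts"` with `S` (synonymous sites), `N`
#'   (nonsynonymous sites), `Sd`, `Nd` (differences). `S + N` equals the
#'   counted alignment length in nucleotides.
#' @export
ng86_counts <- function(seq_a, seq_b) {
  ci <- .codon_indices(seq_a, seq_b)
  tb <- ci$tb
  s_a <- sum(tb$syn_sites[ci$ia])
  s_b <- sum(tb$syn_sites[ci$ib])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ci$ia) - S
  Sd <- sum(tb$sd[cbind(ci$ia, ci$ib)])
  Nd <- sum(tb$nd[cbind(ci$ia, ci$ib)])
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd), class = "ng86_counts")
}

#' @export
print.ng86_counts <- function(x, ...) {
  cat(sprintf("NG86 counts: S = %.3f, N = %.3f, Sd = %.3f, Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`. Proportions at or beyond the JC divergence
#' ceiling (`p >= 0.75`) are saturated and return `NA`.
#'
#' @param p proportion of differences per site, in `[0, 1]`.
#' @return corrected distance (vectorized); `NA` where saturated.
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  out <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  out
}

#' Estimate Ka and Ks for an aligned CDS pair (NG86 + Jukes-Cantor)
#'
#' `Ks = jc_correct(Sd/S)`, `Ka = jc_correct(Nd/N)`. The estimate is
#' symmetric in its two sequences.
#'
#' @inheritParams ng86_counts
#' @return list of class `"kaks_result"`: `Ka`, `Ks`, `omega` (Ka/Ks, `NA`
#'   when Ks is 0 or saturated), `counts`, and saturation flags.
#' @export
estimate_ka_ks <- function(seq_a, seq_b) {
  cnt <- ng86_counts(seq_a, seq_b)
  if (cnt$S <= 0 || cnt$N <= 0)
    stop("degenerate alignment: S or N is zero")
  Ks <- jc_correct(cnt$Sd / cnt$S)
  Ka <- jc_correct(cnt$Nd / cnt$N)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(Ka = Ka, Ks = Ks, omega = omega, counts = cnt,
                 saturated_ks = is.na(Ks), saturated_ka = is.na(Ka)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %s, Ks = %s, Ka/Ks = %s\n",
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$omega, digits = 4)))
  invisible(x)
}

#' Estimate Ka/Ks for a set of aligned pairs
#'
#' @param pairs data.frame with columns `seq_a`, `seq_b` (and optionally
#'   `gene_a`, `gene_b`, carried through).
#' @return data.frame with `S, N, Sd, Nd, Ka, Ks, omega` per pair; saturated
#'   rates are `NA`.
#' @export
estimate_ka_ks_set <- function(pairs) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cnt <- ng86_counts(pairs$seq_a[i], pairs$seq_b[i])
    Ks <- if (cnt$S > 0) jc_correct(cnt$Sd / cnt$S) else NA_real_
    Ka <- if (cnt$N > 0) jc_correct(cnt$Nd / cnt$N) else NA_real_
    data.frame(S = cnt$S, N = cnt$N, Sd = cnt$Sd, Nd = cnt$Nd,
               Ka = Ka, Ks = Ks,
               omega = ifelse(!is.na(Ka) & !is.na(Ks) & Ks > 0,
                              Ka / Ks, NA_real_))
  })
  out <- do.call(rbind, res)
  extra <- intersect(c("gene_a", "gene_b"), names(pairs))
  if (length(extra)) out <- cbind(pairs[extra], out)
  rownames(out) <- NULL
  out
}
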