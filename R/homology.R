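# Homology tables, collinear block chaining in gene-rank space, and
# classification of paralog pairs as ECH-derived, tandem, or other.

#' Build a best-hit table from outfmt6-like rows
#'
#' Self-hits are removed, hits at or above the E-value ceiling are dropped
#' (the published filter is strict: E < 1e-5), and at most `max_hits` hits
#' are kept per query, ordered by descending bitscore.
#'
#' @param hits data.frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (see [read_hits_tsv()]).
#' @param e_ceiling strict E-value ceiling (default `1e-5`).
#' @param max_hits hits retained per query (default 5).
#' @return data.frame of class `"hit_table"` sorted by query then descending
#'   bitscore.
#' @export
build_hit_table <- function(hits, e_ceiling = 1e-5, max_hits = 5) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  for (nm in c("evalue", "bitscore")) {
    if (!is.numeric(hits[[nm]])) {
      val <- suppressWarnings(as.numeric(hits[[nm]]))
      if (anyNA(val))
        stop("non-numeric ", nm, " at row ", which(is.na(val))[1])
      hits[[nm]] <- val
    }
  }
  keep <- hits$qseqid != hits$sseqid & hits$evalue < e_ceiling
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$qseqid, -out$bitscore, out$sseqid), , drop = FALSE]
  if (nrow(out) > 0) {
    nth <- stats::ave(seq_len(nrow(out)), out$qseqid, FUN = seq_along)
    out <- out[nth <= max_hits, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Best hit per query
#'
#' @param hit_table [build_hit_table()] result.
#' @return data.frame with one row per query: the highest-bitscore hit.
#' @export
best_hits <- function(hit_table) {
  if (nrow(hit_table) == 0) return(hit_table)
  first <- !duplicated(hit_table$qseqid)
  out <- hit_table[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# longest strictly-monotone chain in rank space with per-step gap bounds on
# both axes; O(n^2) DP, ties broken toward the smallest earlier index so the
# result is deterministic. Returns integer indices of the chain (in order).
.longest_chain <- function(x, y, max_gap) {
  n <- length(x)
  ord <- order(x, y)
  xo <- x[ord]; yo <- y[ord]
  dp <- rep(1L, n)
  pred <- rep(0L, n)
  for (j in seq_len(n)) {
    if (j == 1) next
    i <- seq_len(j - 1)
    okay <- xo[i] < xo[j] & (xo[j] - xo[i]) <= max_gap &
      yo[i] < yo[j] & (yo[j] - yo[i]) <= max_gap
    if (any(okay)) {
      cand <- i[okay]
      best <- cand[which.max(dp[cand])]  # which.max -> earliest tie
      dp[j] <- dp[best] + 1L
      pred[j] <- best
    }
  }
  endj <- which.max(dp)
  chain <- integer(dp[endj])
  k <- dp[endj]; j <- endj
  while (j > 0) {
    chain[k] <- j
    j <- pred[j]
    k <- k - 1L
  }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Within each chromosome pair, anchors are greedily partitioned into maximal
#' strictly monotone chains in gene-rank space (increasing on both axes for
#' `same` orientation, increasing/decreasing for `inverted`), with
#' consecutive-anchor rank gaps bounded by `max_rank_gap` on both axes.
#' Blocks do not share anchors; chains shorter than `min_block_size` are
#' discarded. These are the diagonals of a homologous-gene dotplot.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`.
#' @param ann_a,ann_b [genome_annotation()] objects providing chromosome and
#'   rank for each gene (use the same annotation twice for a self-comparison).
#' @param min_block_size minimum anchors per block (default 5).
#' @param max_rank_gap maximum rank gap between consecutive anchors
#'   (default 25).
#' @return list of class `"collinear_blocks"`; each element has `chrom_a`,
#'   `chrom_b`, `orientation` (`"same"`/`"inverted"`), `n_anchors` and an
#'   `anchors` data.frame (`gene_a`, `gene_b`, `rank_a`, `rank_b`) in chain
#'   order.
#' @export
chain_collinear_blocks <- function(anchors, ann_a, ann_b,
                                   min_block_size = 5, max_rank_gap = 25) {
  ga <- ann_a$genes; gb <- ann_b$genes
  ia <- match(anchors$gene_a, ga$gene_id)
  ib <- match(anchors$gene_b, gb$gene_id)
  if (anyNA(ia)) stop("unknown gene in annotation A: ",
                      anchors$gene_a[is.na(ia)][1])
  if (anyNA(ib)) stop("unknown gene in annotation B: ",
                      anchors$gene_b[is.na(ib)][1])
  tab <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                    chrom_a = ga$chrom[ia], chrom_b = gb$chrom[ib],
                    rank_a = ga$rank[ia], rank_b = gb$rank[ib],
                    stringsAsFactors = FALSE)
  blocks <- list()
  for (key in sort(unique(paste(tab$chrom_a, tab$chrom_b, sep = "\r")))) {
    sub <- tab[paste(tab$chrom_a, tab$chrom_b, sep = "\r") == key, ,
               drop = FALSE]
    repeat {
      if (nrow(sub) < min_block_size) break
      same <- .longest_chain(sub$rank_a, sub$rank_b, max_rank_gap)
      inv <- .longest_chain(sub$rank_a, -sub$rank_b, max_rank_gap)
      use_same <- length(same) >= length(inv)
      chain <- if (use_same) same else inv
      if (length(chain) < min_block_size) break
      sel <- sub[chain, , drop = FALSE]
      blocks[[length(blocks) + 1]] <- list(
        chrom_a = sel$chrom_a[1], chrom_b = sel$chrom_b[1],
        orientation = if (use_same) "same" else "inverted",
        n_anchors = nrow(sel),
        anchors = data.frame(gene_a = sel$gene_a, gene_b = sel$gene_b,
                             rank_a = sel$rank_a, rank_b = sel$rank_b,
                             stringsAsFactors = FALSE))
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  structure(blocks, class = "collinear_blocks")
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat(sprintf("collinear_blocks: %d block(s), %d anchor(s)\n", length(x),
              sum(vapply(x, `[[`, 0, "n_anchors"))))
  invisible(x)
}

# set of anchor keys covered by any block
.block_keys <- function(blocks) {
  unlist(lapply(blocks, function(b)
    anchor_key(b$anchors$gene_a, b$anchors$gene_b)), use.names = FALSE)
}

#' Classify paralog pairs as ECH-derived, tandem, or other
#'
#' A pair is `ech` when it lies in a collinear block and its Ks falls inside
#' `mu ± 2 sigma` of the ECH peak; `tandem` when both genes share a
#' chromosome with rank gap at most `tandem_max_rank_gap`. The two labels are
#' not exclusive (a pair satisfying both is reported under both with a
#' warning); a pair satisfying neither, or with missing Ks and no tandem
#' evidence, is `other`.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param blocks [chain_collinear_blocks()] result (self-comparison).
#' @param ks numeric vector of Ks per pair (`NA` allowed).
#' @param annotation [genome_annotation()] for both genes.
#' @param ech_peak one-row [fit_ks_peaks()] result (or list with `mu`,
#'   `sigma`).
#' @param tandem_max_rank_gap maximum rank separation for tandem pairs
#'   (default 5).
#' @return data.frame with logical `is_ech`, `is_tandem` and a `class`
#'   column (`"ech"`, `"tandem"`, `"ech|tandem"`, `"other"`).
#' @export
classify_paralogs <- function(pairs, blocks, ks, annotation, ech_peak,
                              tandem_max_rank_gap = 5) {
  g <- annotation$genes
  ia <- match(pairs$gene_a, g$gene_id)
  ib <- match(pairs$gene_b, g$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene absent from the annotation")
  in_block <- anchor_key(pairs$gene_a, pairs$gene_b) %in% .block_keys(blocks)
  lo <- ech_peak$mu[1] - 2 * ech_peak$sigma[1]
  hi <- ech_peak$mu[1] + 2 * ech_peak$sigma[1]
  is_ech <- in_block & !is.na(ks) & ks >= lo & ks <= hi
  is_tandem <- g$chrom[ia] == g$chrom[ib] &
    abs(g$rank[ia] - g$rank[ib]) <= tandem_max_rank_gap
  if (any(is.na(ks)))
    message("classify_paralogs: ", sum(is.na(ks)),
            " pair(s) with missing Ks treated as non-ECH")
  both <- is_ech & is_tandem
  if (any(both))
    warning(sum(both), " pair(s) satisfy both the ECH and tandem criteria; ",
            "reported under both labels")
  cls <- ifelse(both, "ech|tandem",
                ifelse(is_ech, "ech", ifelse(is_tandem, "tandem", "other")))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             ks = ks, is_ech = is_ech, is_tandem = is_tandem, class = cls,
             stringsAsFactors = FALSE)
}

#' Count duplicated genes retained in collinear blocks
#'
#' For a self-comparison, counts the distinct genes participating in at least
#' one intra-genome collinear block, and the fraction of the annotated gene
#' set they represent (e.g. 4494 of 27,635 genes formats as `"16.26%"`).
#'
#' @param blocks [chain_collinear_blocks()] result from a self-comparison.
#' @param annotation the genome's [genome_annotation()].
#' @return list with `n_genes`, `fraction`, `percent` (half-up, 2 decimals)
#'   and `label` (e.g. `"16.26%"`).
#' @export
count_retained_duplicates <- function(blocks, annotation) {
  n_total <- nrow(annotation$genes)
  if (n_total == 0) stop("annotation has zero genes")
  genes <- unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b)), use.names = FALSE))
  n <- length(genes)
  list(n_genes = n, fraction = n / n_total,
       percent = percent_of(n, n_total),
       label = format_percent(n, n_total))
}
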