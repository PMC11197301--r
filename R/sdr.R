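# Ortholog-anchored interval lift-over (how a putative sex-determination
# region is transferred between assemblies) and SDR haplotype gene-content
# comparison.

#' Lift an interval across genomes via ortholog anchors
#'
#' Anchors whose A-side gene overlaps the source interval are collected,
#' extended by `flank_anchors` anchors on each side (in A-coordinate order);
#' the target interval spans the leftmost to rightmost B-coordinates of
#' those anchors. Orientation is the sign of the rank correlation between
#' A and B positions of the anchors used.
#'
#' @param anchors data.frame of one-to-one ortholog anchors with columns
#'   `gene_a`, `chrom_a`, `start_a`, `end_a`, `gene_b`, `chrom_b`,
#'   `start_b`, `end_b`.
#' @param source [interval()] on genome A.
#' @param flank_anchors anchors added on each side (default 1).
#' @return list of class `"mapped_interval"`: `source`, `target`
#'   ([interval()]), `anchors` (A-side gene ids used), `orientation`
#'   (`"same"`/`"inverted"`).
#' @export
liftover_interval <- function(anchors, source, flank_anchors = 1) {
  a <- anchors[anchors$chrom_a == source$chrom, , drop = FALSE]
  if (nrow(a) < 2) stop("unmappable interval: fewer than 2 anchors on ",
                        source$chrom)
  a <- a[order(a$start_a), , drop = FALSE]
  hit <- which(a$end_a >= source$start & a$start_a <= source$end)
  if (length(hit) == 0) {
    # fall back to the flanking anchors around the insertion point
    left <- which(a$end_a < source$start)
    right <- which(a$start_a > source$end)
    hit <- c(utils::tail(left, flank_anchors),
             utils::head(right, flank_anchors))
    if (length(hit) == 0) stop("unmappable interval: no overlapping or ",
                               "flanking anchors")
  } else {
    lo <- max(1, min(hit) - flank_anchors)
    hi <- min(nrow(a), max(hit) + flank_anchors)
    hit <- lo:hi
  }
  used <- a[hit, , drop = FALSE]
  chrom_b <- names(sort(table(used$chrom_b), decreasing = TRUE))[1]
  used_b <- used[used$chrom_b == chrom_b, , drop = FALSE]
  orientation <- "same"
  if (nrow(used_b) >= 2) {
    rho <- suppressWarnings(stats::cor(used_b$start_a, used_b$start_b,
                                       method = "spearman"))
    if (!is.na(rho) && rho < 0) orientation <- "inverted"
  }
  structure(list(source = source,
                 target = interval(chrom_b, min(used_b$start_b),
                                   max(used_b$end_b)),
                 anchors = used_b$gene_a,
                 orientation = orientation),
            class = "mapped_interval")
}

#' @export
print.mapped_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d -> %s:%d-%d (%s, %d anchors)\n",
              x$source$chrom, x$source$start, x$source$end,
              x$target$chrom, x$target$start, x$target$end,
              x$orientation, length(x$anchors)))
  invisible(x)
}

#' Read a haplotype gene-content table
#'
#' @param path TSV with columns `gene_id`, `label` (functional label),
#'   rows in genomic order; `#` lines are comments. A fusion gene may carry
#'   several labels (one row per label).
#' @return data.frame with `gene_id`, `label`.
#' @export
read_gene_content <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "label") %in% names(df)))
    stop("gene content table needs columns gene_id, label")
  df
}

# case-folded, whitespace-collapsed label
.normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Compare the gene content of two haplotypes
#'
#' Functional labels are normalized (case-folded, whitespace-collapsed) and
#' compared as multisets: `gained` are labels present in A beyond their
#' multiplicity in B, `lost` the converse; `shared` keeps one entry per
#' common occurrence. `order_conserved` is TRUE when the shared labels
#' appear in the same relative order in both lists (excess duplicate
#' occurrences beyond the common multiplicity are dropped from the end).
#'
#' @param a,b data.frames with `label` (and optionally `gene_id`), rows in
#'   genomic order, e.g. from [read_gene_content()].
#' @return list of class `"content_diff"`: `shared`, `gained`, `lost`
#'   (label character vectors), `order_conserved`.
#' @export
compare_gene_content <- function(a, b) {
  la <- .normalize_label(a$label)
  lb <- .normalize_label(b$label)
  cnt_a <- table(la); cnt_b <- table(lb)
  labels <- union(names(cnt_a), names(cnt_b))
  gained <- character(0); lost <- character(0); shared <- character(0)
  for (lb1 in labels) {
    na <- if (lb1 %in% names(cnt_a)) cnt_a[[lb1]] else 0L
    nb <- if (lb1 %in% names(cnt_b)) cnt_b[[lb1]] else 0L
    shared <- c(shared, rep(lb1, min(na, nb)))
    if (na > nb) gained <- c(gained, rep(lb1, na - nb))
    if (nb > na) lost <- c(lost, rep(lb1, nb - na))
  }
  # keep the first `min(count)` occurrences of each shared label, in order
  keep_shared <- function(lv) {
    other <- if (identical(lv, la)) lb else la
    cnt_other <- table(other)
    seen <- stats::setNames(integer(length(unique(lv))), unique(lv))
    keep <- logical(length(lv))
    for (i in seq_along(lv)) {
      lim <- if (lv[i] %in% names(cnt_other)) cnt_other[[lv[i]]] else 0L
      if (seen[[lv[i]]] < lim) {
        keep[i] <- TRUE
        seen[[lv[i]]] <- seen[[lv[i]]] + 1L
      }
    }
    lv[keep]
  }
  seq_a <- keep_shared(la)
  seq_b <- keep_shared(lb)
  structure(list(shared = shared, gained = gained, lost = lost,
                 order_conserved = identical(seq_a, seq_b)),
            class = "content_diff")
}

#' @export
print.content_diff <- function(x, ...) {
  cat(sprintf("content_diff: %d shared, %d gained, %d lost; order %s\n",
              length(x$shared), length(x$gained), length(x$lost),
              if (x$order_conserved) "conserved" else "rearranged"))
  if (length(x$gained)) cat("  gained:", paste(x$gained, collapse = ", "), "\n")
  if (length(x$lost)) cat("  lost:  ", paste(x$lost, collapse = ", "), "\n")
  invisible(x)
}

#' Count genes overlapping an interval
#'
#' A gene is counted when its span overlaps the interval by at least 1 bp
#' (inclusive coordinates), so a gene abutting the interval end exactly is
#' counted.
#'
#' @param annotation [genome_annotation()].
#' @param region [interval()].
#' @return integer count.
#' @export
count_genes_in_interval <- function(annotation, region) {
  g <- annotation$genes
  if (!(region$chrom %in% annotation$chromosomes$name))
    stop("unknown chromosome: ", region$chrom)
  sum(g$chrom == region$chrom & g$end >= region$start &
        g$start <= region$end)
}
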