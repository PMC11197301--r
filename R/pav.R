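# Windowed genome-specific-segment calling and species-specific PAV gene
# assignment: the query genome is cut into 500-bp windows stepping 100 bp,
# windows that fail to align to the reference or align with < 25% coverage
# are genome-specific, and genes inside the merged specific segments are the
# query's PAV genes.

#' Sliding windows over chromosomes
#'
#' 1-based windows starting at 1, 1+step, ...; only full-length windows are
#' emitted, so chromosomes shorter than `size` yield none (reported via
#' message).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 500).
#' @param step step between window starts in bp (default 100; must satisfy
#'   `0 < step <= size`).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 500, step = 100) {
  if (step <= 0 || step > size) stop("need 0 < step <= size")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < size) {
      message("make_windows: ", ch, " shorter than window size, skipped")
      return(NULL)
    }
    starts <- seq(1, len - size + 1, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Alignment coverage per window
#'
#' Coverage is the length of the union of alignment intervals intersected
#' with the window, divided by the window length; `aligned` records whether
#' any alignment interval overlaps the window at all.
#'
#' @param windows data.frame from [make_windows()].
#' @param alignments data.frame of query-side intervals with columns
#'   `chrom`, `start`, `end` (or `qchrom`, `qstart`, `qend` as produced by
#'   [read_alignment_intervals()]).
#' @return `windows` with added `covered_bp`, `covered_fraction`, `aligned`.
#' @export
window_coverage <- function(windows, alignments) {
  if (all(c("qchrom", "qstart", "qend") %in% names(alignments)))
    alignments <- data.frame(chrom = alignments$qchrom,
                             start = alignments$qstart,
                             end = alignments$qend)
  covered <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wsel <- windows$chrom == ch
    win <- IRanges::IRanges(windows$start[wsel], windows$end[wsel])
    aln <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(aln) == 0) next
    red <- IRanges::reduce(IRanges::IRanges(aln$start, aln$end))
    ov <- IRanges::findOverlaps(win, red)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      win[S4Vectors::queryHits(ov)], red[S4Vectors::subjectHits(ov)]))
    cov_ch <- numeric(length(win))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    cov_ch[as.integer(names(agg))] <- agg
    covered[wsel] <- cov_ch
  }
  windows$covered_bp <- covered
  windows$covered_fraction <- covered / (windows$end - windows$start + 1)
  windows$aligned <- covered > 0
  windows
}

#' Call genome-specific segments from window coverage
#'
#' Windows that failed to align or aligned with coverage strictly below the
#' threshold are specific; overlapping or adjacent specific windows are
#' merged into maximal segments. A window at exactly the threshold is NOT
#' specific (the published filter is strict `< 25%`).
#'
#' @param coverage data.frame from [window_coverage()].
#' @param threshold coverage threshold (default 0.25, strict `<`).
#' @return list of class `"specific_segments"` with `segments` (merged,
#'   sorted, disjoint intervals), `n_windows_specific`, `n_segments`,
#'   `total_length` (bp) and the threshold used.
#' @export
call_specific_segments <- function(coverage, threshold = 0.25) {
  spec <- !coverage$aligned | coverage$covered_fraction < threshold
  segs <- lapply(sort(unique(coverage$chrom)), function(ch) {
    sel <- spec & coverage$chrom == ch
    if (!any(sel)) return(NULL)
    red <- IRanges::reduce(IRanges::IRanges(coverage$start[sel],
                                            coverage$end[sel]))
    data.frame(chrom = ch, start = IRanges::start(red),
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs))
    segs <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  structure(list(segments = segs,
                 n_windows_specific = sum(spec),
                 n_segments = nrow(segs),
                 total_length = sum(segs$end - segs$start + 1),
                 threshold = threshold),
            class = "specific_segments")
}

#' @export
print.specific_segments <- function(x, ...) {
  cat(sprintf(
    "specific_segments: %d merged segment(s) (%d specific windows), %s bp\n",
    x$n_segments, x$n_windows_specific,
    format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Assign species-specific PAV genes
#'
#' A gene is listed when the fraction of its span overlapped by specific
#' segments reaches `min_gene_overlap` (default 0.5); `mode = "contained"`
#' instead requires strict containment of the whole gene span.
#'
#' @param segments [call_specific_segments()] result.
#' @param annotation query-genome [genome_annotation()].
#' @param min_gene_overlap minimum overlapped fraction of the gene span.
#' @param mode `"fraction"` or `"contained"`.
#' @return data.frame of listed genes with `overlap_bp` and
#'   `overlap_fraction`.
#' @export
assign_pav_genes <- function(segments, annotation, min_gene_overlap = 0.5,
                             mode = c("fraction", "contained")) {
  mode <- match.arg(mode)
  g <- annotation$genes
  segs <- segments$segments
  ov_bp <- numeric(nrow(g))
  for (ch in unique(g$chrom)) {
    gsel <- g$chrom == ch
    ssel <- segs$chrom == ch
    if (!any(ssel)) next
    gir <- IRanges::IRanges(g$start[gsel], g$end[gsel])
    sir <- IRanges::reduce(IRanges::IRanges(segs$start[ssel],
                                            segs$end[ssel]))
    hits <- IRanges::findOverlaps(gir, sir)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      gir[S4Vectors::queryHits(hits)], sir[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    tmp <- numeric(sum(gsel))
    tmp[as.integer(names(agg))] <- agg
    ov_bp[gsel] <- tmp
  }
  span <- g$end - g$start + 1
  frac <- ov_bp / span
  keep <- if (mode == "contained") frac >= 1 else frac >= min_gene_overlap
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                    end = g$end, overlap_bp = ov_bp, overlap_fraction = frac,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard index between two interval sets
#'
#' Base-level intersection over union; used to score recovery of implanted
#' specific segments against truth.
#'
#' @param a,b data.frames with `chrom`, `start`, `end`.
#' @return numeric in `[0, 1]` (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  chroms <- union(a$chrom, b$chrom)
  inter <- 0; uni <- 0
  for (ch in chroms) {
    ia <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == ch],
                                           a$end[a$chrom == ch]))
    ib <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == ch],
                                           b$end[b$chrom == ch]))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) return(1)
  inter / uni
}
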