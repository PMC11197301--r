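# Readers/writers for on-disk formats and the shared containers used by every
# stage: FASTA (Biostrings), GFF3 (rtracklayer), VCF (vcfR), PAF / BED-like
# alignment tables and outfmt6 hit tables (plain TSV).

#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased and `U` is mapped to `T` so RNA-coded input can be
#' used as CDS. The record id is the first whitespace-delimited token of the
#' header; the remainder is kept as the description.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `seq`, `description`, in file order.
#'   Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0)
    return(data.frame(id = character(), seq = character(),
                      description = character(), stringsAsFactors = FALSE))
  header <- names(ss)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    stop("duplicate id ", dup)
  }
  seq <- chartr("u", "t", toupper(as.character(ss)))
  seq <- chartr("U", "T", seq)
  data.frame(id = id, seq = unname(seq), description = desc,
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with `id`, `seq` (and optionally `description`),
#'   or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.character(records))
    records <- data.frame(id = names(records), seq = unname(records),
                          description = "", stringsAsFactors = FALSE)
  ss <- Biostrings::BStringSet(records$seq)
  desc <- records$description %||% rep("", nrow(records))
  names(ss) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Genome annotation container
#'
#' Holds chromosome lengths and gene models with a 0-based along-chromosome
#' rank (genes sorted by start within each chromosome), the substrate for
#' collinearity chaining, PAV gene assignment and interval lift-over.
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @return object of class `"genome_annotation"`; `$genes` carries a `rank`
#'   column, consecutive and unique within each chromosome.
#' @export
genome_annotation <- function(chromosomes, genes) {
  chromosomes <- data.frame(name = as.character(chromosomes$name),
                            length = as.numeric(chromosomes$length),
                            stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start][1]
    stop("gene ", bad, " has end < start")
  }
  unknown <- setdiff(genes$chrom, chromosomes$name)
  if (length(unknown) > 0)
    stop("gene chromosome not declared: ", unknown[1])
  clen <- stats::setNames(chromosomes$length, chromosomes$name)
  over <- genes$end > clen[genes$chrom]
  if (any(over))
    stop("gene ", genes$gene_id[over][1], " extends past its chromosome end")
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chrom,
                           FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosomes, %d genes\n",
              nrow(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Features of type `gene` are kept. Chromosome lengths come from
#' `##sequence-region` pragmas or, failing that, from `chrom_lengths`.
#'
#' @param path GFF3 file.
#' @param chrom_lengths optional named vector of chromosome lengths used when
#'   the file has no `##sequence-region` pragmas.
#' @return [genome_annotation()] object (genes ranked per chromosome).
#' @export
read_gff3 <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[tolower(as.character(gr$type)) == "gene"]
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("gene feature without ID attribute in ", path)
  # chromosome lengths: pragmas first, argument as fallback
  hdr <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
  if (length(hdr) > 0) {
    parts <- strsplit(trimws(hdr), "\\s+")
    chroms <- data.frame(name = vapply(parts, `[`, "", 2),
                         length = as.numeric(vapply(parts, `[`, "", 4)),
                         stringsAsFactors = FALSE)
  } else if (!is.null(chrom_lengths)) {
    chroms <- data.frame(name = names(chrom_lengths),
                         length = as.numeric(chrom_lengths),
                         stringsAsFactors = FALSE)
  } else {
    stop("no ##sequence-region pragmas in ", path,
         "; supply chrom_lengths")
  }
  genome_annotation(
    chroms,
    data.frame(gene_id = as.character(ids),
               chrom = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               strand = as.character(GenomicRanges::strand(genes)),
               stringsAsFactors = FALSE))
}

#' Write a genome annotation to GFF3
#'
#' @param ann [genome_annotation()] object.
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  strand <- ifelse(g$strand %in% c("+", "-"), g$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = strand)
  gr$type <- "gene"
  gr$ID <- g$gene_id
  sl <- stats::setNames(ann$chromosomes$length, ann$chromosomes$name)
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit ##sequence-region pragmas; add them so the
  # chromosome lengths survive a round trip
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^##sequence-region", lines))) {
    pragmas <- sprintf("##sequence-region %s 1 %s", ann$chromosomes$name,
                       format(ann$chromosomes$length, scientific = FALSE,
                              trim = TRUE))
    writeLines(c(lines[1], pragmas, lines[-1]), path)
  }
  invisible(path)
}

#' Diploid genotype table
#'
#' @param samples character vector of sample ids.
#' @param sites data.frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (biallelic SNPs only; positions strictly increasing within chromosome).
#' @param geno integer matrix, sites x samples, ALT-allele dosage in
#'   \{0, 1, 2\}, `NA` = missing.
#' @return object of class `"genotype_table"`.
#' @export
genotype_table <- function(samples, sites, geno) {
  samples <- as.character(samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites) || ncol(geno) != length(samples))
    stop("geno must be n_sites x n_samples")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L))
    stop("only biallelic SNP sites are allowed")
  for (chrom in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == chrom]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within ", chrom)
  }
  dimnames(geno) <- list(NULL, samples)
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d sites on %d chromosome(s)\n",
              length(x$samples), nrow(x$sites), length(unique(x$sites$chrom))))
  invisible(x)
}

# Subset a genotype table by site index (and optionally by sample id).
genotype_subset <- function(gt, site_idx = NULL, samples = NULL) {
  site_idx <- site_idx %||% seq_len(nrow(gt$sites))
  samples <- samples %||% gt$samples
  genotype_table(samples,
                 gt$sites[site_idx, , drop = FALSE],
                 gt$geno[site_idx, samples, drop = FALSE])
}

#' Read diploid SNP genotypes from a VCF file
#'
#' Multiallelic and non-SNP records are skipped (count reported via message and
#' the `n_skipped` attribute). `./.` becomes missing. Tetraploid-coded GT
#' fields (four alleles) are either collapsed to a presence dosage (any ALT
#' -> 1, all-ALT -> 2, all-REF -> 0) or the affected samples are dropped.
#'
#' @param path VCF v4.x file with GT in FORMAT.
#' @param tetraploid `"collapse"` (default) or `"exclude"` (drop any sample
#'   carrying a four-allele genotype).
#' @return [genotype_table()].
#' @export
read_vcf <- function(path, tetraploid = c("collapse", "exclude")) {
  tetraploid <- match.arg(tetraploid)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  keep <- nchar(fix$REF) == 1L & !is.na(fix$ALT) & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped,
            " multiallelic/non-SNP record(s)")
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt_raw)
  n_sites <- nrow(gt_raw)
  dos <- matrix(NA_integer_, n_sites, length(samples),
                dimnames = list(NULL, samples))
  ploidy4 <- matrix(FALSE, n_sites, length(samples))
  for (j in seq_along(samples)) {
    cells <- gt_raw[, j]
    alleles <- strsplit(cells, "[/|]")
    for (i in seq_len(n_sites)) {
      a <- alleles[[i]]
      if (length(a) == 0 || all(is.na(cells[i])) || all(a == ".")) next
      if (any(a == ".")) next  # partially missing -> missing
      ai <- suppressWarnings(as.integer(a))
      if (anyNA(ai) || any(ai > 1L) || !(length(ai) %in% c(2L, 4L)))
        stop("malformed GT '", cells[i], "' at record ", i,
             " sample ", samples[j])
      if (length(ai) == 4L) {
        ploidy4[i, j] <- TRUE
        dos[i, j] <- if (all(ai == 1L)) 2L else if (any(ai == 1L)) 1L else 0L
      } else {
        dos[i, j] <- sum(ai)
      }
    }
  }
  if (tetraploid == "exclude") {
    drop <- colSums(ploidy4) > 0
    if (any(drop))
      message("read_vcf: excluded ", sum(drop), " tetraploid sample(s): ",
              paste(samples[drop], collapse = ", "))
    samples <- samples[!drop]
    dos <- dos[, !drop, drop = FALSE]
  }
  ord <- order(fix$CHROM, as.numeric(fix$POS))
  out <- genotype_table(samples,
                        data.frame(chrom = fix$CHROM[ord],
                                   pos = as.numeric(fix$POS[ord]),
                                   ref = fix$REF[ord], alt = fix$ALT[ord],
                                   stringsAsFactors = FALSE),
                        dos[ord, , drop = FALSE])
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_records") <- n_in
  out
}

#' Write a genotype table as a minimal VCF v4.2 file
#'
#' Intended for serializing simulated populations; only CHROM/POS/REF/ALT and
#' diploid GT fields are emitted.
#'
#' @param gt [genotype_table()].
#' @param path output file.
#' @export
write_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], nrow = nrow(gt$geno))
  gt_str[is.na(gt$geno)] <- "./."
  lines <- paste(gt$sites$chrom, format(gt$sites$pos, scientific = FALSE,
                                        trim = TRUE),
                 ".", gt$sites$ref, gt$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read whole-genome alignment intervals
#'
#' Supported dialects: `"paf"` (minimap2-style, 0-based half-open, converted
#' on read to the package's 1-based inclusive convention) and `"bed_tsv"`
#' (6/7-column TSV, already 1-based inclusive:
#' `qchrom qstart qend tchrom tstart tend [identity]`).
#'
#' @param path alignment file.
#' @param dialect `"paf"` or `"bed_tsv"`.
#' @return data.frame with columns `qchrom,qstart,qend,tchrom,tstart,tend,
#'   identity,strand` (PAF extras `qlen,tlen,nmatch,alnlen,mapq` retained for
#'   lossless round-trip).
#' @export
read_alignment_intervals <- function(path, dialect = c("paf", "bed_tsv")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(qchrom = character(), qstart = numeric(),
                      qend = numeric(), tchrom = character(),
                      tstart = numeric(), tend = numeric(),
                      identity = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  raw <- tryCatch(utils::read.delim(path, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) return(empty)
  if (dialect == "paf") {
    if (ncol(raw) < 12) stop("PAF requires >= 12 columns")
    out <- data.frame(qchrom = as.character(raw[[1]]),
                      qstart = raw[[3]] + 1, qend = raw[[4]],
                      tchrom = as.character(raw[[6]]),
                      tstart = raw[[8]] + 1, tend = raw[[9]],
                      identity = raw[[10]] / raw[[11]],
                      strand = as.character(raw[[5]]),
                      qlen = raw[[2]], tlen = raw[[7]],
                      nmatch = raw[[10]], alnlen = raw[[11]],
                      mapq = raw[[12]], stringsAsFactors = FALSE)
    if (any(raw[[3]] < 0 | raw[[8]] < 0))
      stop("negative coordinates in PAF")
  } else {
    if (ncol(raw) < 6) stop("bed_tsv requires >= 6 columns")
    out <- data.frame(qchrom = as.character(raw[[1]]),
                      qstart = as.numeric(raw[[2]]), qend = as.numeric(raw[[3]]),
                      tchrom = as.character(raw[[4]]),
                      tstart = as.numeric(raw[[5]]), tend = as.numeric(raw[[6]]),
                      identity = if (ncol(raw) >= 7) as.numeric(raw[[7]])
                                 else NA_real_,
                      strand = "+", stringsAsFactors = FALSE)
  }
  if (any(out$qstart < 1 | out$tstart < 1 | out$qend < out$qstart |
          out$tend < out$tstart))
    stop("negative or inverted coordinates in ", path)
  out
}

#' Write alignment intervals
#'
#' Inverse of [read_alignment_intervals()]; PAF coordinates are converted back
#' to 0-based half-open so that a read/write cycle is lossless.
#'
#' @param x data.frame from [read_alignment_intervals()] or with compatible
#'   columns.
#' @param path output file.
#' @param dialect `"paf"` or `"bed_tsv"`.
#' @export
write_alignment_intervals <- function(x, path, dialect = c("paf", "bed_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "paf") {
    alnlen <- x$alnlen %||% (x$qend - x$qstart + 1)
    df <- data.frame(x$qchrom, x$qlen %||% x$qend, x$qstart - 1, x$qend,
                     x$strand %||% "+", x$tchrom, x$tlen %||% x$tend,
                     x$tstart - 1, x$tend,
                     x$nmatch %||% round((x$identity %||% 1) * alnlen),
                     alnlen, x$mapq %||% 60)
  } else {
    df <- data.frame(x$qchrom, x$qstart, x$qend, x$tchrom, x$tstart, x$tend,
                     x$identity %||% NA_real_)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt6-like hit table
#'
#' @param path 12-column TSV in the standard outfmt6 column order
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`).
#' @return data.frame with those column names; non-numeric score fields raise
#'   an error naming the row.
#' @export
read_hits_tsv <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0)
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)), cols))
  if (ncol(raw) < 12) stop("hit table requires 12 columns (outfmt6)")
  raw <- raw[, 1:12]
  names(raw) <- cols
  for (nm in cols[3:12]) {
    val <- suppressWarnings(as.numeric(raw[[nm]]))
    if (anyNA(val) && any(is.na(val) & !is.na(raw[[nm]]))) {
      row <- which(is.na(val) & !is.na(raw[[nm]]))[1]
      stop("non-numeric ", nm, " at row ", row)
    }
    raw[[nm]] <- val
  }
  raw
}
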