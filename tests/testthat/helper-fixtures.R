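# Small in-code fixture builders shared across test files.

# genotype table from a dosage matrix given as sites x samples
toy_gt <- function(geno, chrom = "chr1", pos = NULL) {
  geno <- as.matrix(geno)
  ns <- ncol(geno)
  samples <- colnames(geno)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ns))
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 10
  genotype_table(samples,
                 data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                            stringsAsFactors = FALSE),
                 matrix(as.integer(geno), nrow = nrow(geno),
                        dimnames = list(NULL, samples)))
}

# annotation with evenly spaced 100-bp genes per chromosome
toy_annotation <- function(genes_per_chrom, chrom_len = 100000,
                           gene_len = 100, spacing = 1000) {
  chroms <- names(genes_per_chrom)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    n <- genes_per_chrom[[ch]]
    starts <- seq(1, by = spacing, length.out = n)
    data.frame(gene_id = sprintf("%s_g%03d", ch, seq_len(n)), chrom = ch,
               start = starts, end = starts + gene_len - 1, strand = "+",
               stringsAsFactors = FALSE)
  }))
  genome_annotation(data.frame(name = chroms, length = chrom_len), genes)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a minimal VCF with given GT string rows (sites x samples)
write_toy_vcf <- function(gt_rows, samples, chrom = "chr1",
                          pos = NULL, ref = "A", alt = "G") {
  n <- length(gt_rows)
  if (is.null(pos)) pos <- seq_len(n) * 100
  alt <- rep_len(alt, n); ref <- rep_len(ref, n)
  body <- vapply(seq_len(n), function(i)
    paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), character(1))
  write_tmp(c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"),
              body), ext = ".vcf")
}
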