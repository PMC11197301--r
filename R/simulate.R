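# Synthetic-data generators. Every downstream stage can be exercised on
# simulated inputs with a known truth table: codon pairs diverged to a target
# NG86 Ks, genome pairs with retained whole-genome-duplication paralogs,
# rank-space inversions and implanted species-specific segments, three-group
# diploid populations carrying a localized sex-linked sweep, and random
# gene-interaction networks.

# p = proportion of differing sites implied by a Jukes-Cantor distance d
.jc_inverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Mutate a codon-index vector so the expected NG86 synonymous (and
# nonsynonymous) difference proportions are p_s (p_a). Substitutions are
# placed per codon with probability proportional to the codon's NG86 site
# content in the category, with the per-sequence substitution COUNT set to
# p*S (stochastic rounding) rather than i.i.d. sampling, and at most one
# substitution per category per codon: pinning the count avoids the Jensen
# bias of the Jukes-Cantor transform, and the one-hit-per-codon constraint
# keeps individually synonymous changes from composing into a
# nonsynonymous codon state. Returns list(idx, n_syn, n_nonsyn).
.mutate_codons <- function(idx, p_s, p_a = 0) {
  tb <- .ng86_tables()
  n <- length(idx)
  codmat <- do.call(rbind, strsplit(tb$codons[idx], ""))
  draw_count <- function(m_exact) {
    floor(m_exact) + (stats::runif(1) < (m_exact - floor(m_exact)))
  }
  # pick target codons with prob ~ per-codon site weight, one hit per codon
  pick_codons <- function(w_codon, p, exclude = integer(0)) {
    m <- draw_count(p * sum(w_codon))  # count from the FULL site total
    w_codon[exclude] <- 0
    avail <- which(w_codon > 0)
    if (m == 0 || length(avail) == 0) return(integer(0))
    if (m > length(avail)) m <- length(avail)
    sample(avail, m, prob = w_codon[avail])
  }
  apply_changes <- function(sel, w_pos, alt_list) {
    for (ci in sel) {
      w <- w_pos[ci, ]
      pp <- if (sum(w > 0) == 1) which(w > 0) else
        sample(which(w > 0), 1, prob = w[w > 0])
      cur <- match(paste(codmat[ci, ], collapse = ""), tb$codons)
      alts <- alt_list[[cur]][[pp]]
      if (length(alts) == 0) next
      codmat[ci, pp] <<- if (length(alts) == 1) alts else sample(alts, 1)
    }
  }
  w_syn <- tb$syn_pos[idx, , drop = FALSE]      # n x 3 site fractions
  w_non <- 1 - w_syn
  syn_sel <- pick_codons(rowSums(w_syn), p_s)
  apply_changes(syn_sel, w_syn, tb$syn_alt)
  non_sel <- integer(0)
  if (p_a > 0) {
    non_sel <- pick_codons(rowSums(w_non), p_a, exclude = syn_sel)
    apply_changes(non_sel, w_non, tb$nonsyn_alt)
  }
  list(idx = match(apply(codmat, 1, paste, collapse = ""), tb$codons),
       n_syn = length(syn_sel), n_nonsyn = length(non_sel))
}

.codon_string <- function(idx) {
  paste(.ng86_tables()$codons[idx], collapse = "")
}

.random_sense_codons <- function(n) {
  tb <- .ng86_tables()
  sample(tb$sense, n, replace = TRUE)
}

#' Simulate codon-aligned sequence pairs at a target Ks
#'
#' Each pair descends from a random sense-codon ancestor; substitutions are
#' placed at synonymous (and optionally nonsynonymous) positions so the
#' expected NG86 Ks (Ka) of the set equals the target. Stop codons are never
#' introduced. Realized per-pair substitution counts are recorded in the
#' truth table.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence (>= 50).
#' @param target_ks target synonymous rate (>= 0); targets implying a
#'   difference proportion at the Jukes-Cantor ceiling (`p >= 0.75`) are an
#'   error.
#' @param target_ka target nonsynonymous rate (default 0).
#' @param seed integer seed.
#' @return list with `pairs` (data.frame `pair_id`, `seq_a`, `seq_b`) and
#'   `truth` (data.frame `pair_id`, `n_syn`, `n_nonsyn`).
#' @export
simulate_codon_pair_set <- function(n_pairs, n_codons, target_ks,
                                    target_ka = 0, seed = 1) {
  if (n_codons < 50) stop("n_codons must be >= 50")
  if (target_ks < 0 || target_ka < 0) stop("targets must be >= 0")
  p_s <- .jc_inverse(target_ks)
  p_a <- .jc_inverse(target_ka)
  if (!is.finite(p_s) || p_s >= 0.75 || !is.finite(p_a) || p_a >= 0.75)
    stop("target implies a difference proportion at or beyond the ",
         "Jukes-Cantor ceiling (p >= 0.75)")
  with_seed(seed, {
    res <- lapply(seq_len(n_pairs), function(i) {
      anc <- .random_sense_codons(n_codons)
      mut <- .mutate_codons(anc, p_s, p_a)
      list(seq_a = .codon_string(anc), seq_b = .codon_string(mut$idx),
           n_syn = mut$n_syn, n_nonsyn = mut$n_nonsyn)
    })
    list(pairs = data.frame(
           pair_id = sprintf("pair%05d", seq_len(n_pairs)),
           seq_a = vapply(res, `[[`, "", "seq_a"),
           seq_b = vapply(res, `[[`, "", "seq_b"),
           stringsAsFactors = FALSE),
         truth = data.frame(
           pair_id = sprintf("pair%05d", seq_len(n_pairs)),
           n_syn = vapply(res, `[[`, 0L, "n_syn"),
           n_nonsyn = vapply(res, `[[`, 0L, "n_nonsyn")))
  })
}

#' Simulate a reference/query genome pair with known truth
#'
#' Two annotated genomes share collinear gene order. Chromosomes are taken
#' in pairs (1-2, 3-4, ...) and a fraction `wgd_retention` of their genes
#' carries a retained whole-genome-duplication paralog on the partner
#' chromosome, diverged to `wgd_ks` (the fraction of genes participating in
#' paralog pairs equals `wgd_retention`). Query orthologs are diverged to
#' `ortholog_ks`. The query additionally carries `n_inversions` rank-space
#' inversions and implanted query-specific segments absent from the
#' reference; the emitted alignment table covers all shared sequence and
#' nothing inside the implants.
#'
#' @param n_chromosomes number of chromosomes (even, paired for paralogs).
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length CDS length in bp (multiple of 3).
#' @param intergenic_gap bp between genes.
#' @param ortholog_ks,wgd_ks divergence targets (defaults 0.026 and 1.25,
#'   the ortholog and ECH-paralog peaks of the grape comparison).
#' @param wgd_retention fraction of genes with a retained paralog, in
#'   `[0, 1]`.
#' @param n_inversions implanted inversions (runs of `inversion_genes`
#'   consecutive query genes in reversed order).
#' @param inversion_genes genes per inversion.
#' @param specific_segments numeric vector of implant lengths (bp), query
#'   only; a segment longer than the chromosome is an error.
#' @param seed integer seed.
#' @return list with `ref_annotation`, `qry_annotation`
#'   ([genome_annotation()]), `ref_cds`, `qry_cds` (named character),
#'   `alignments` (query->reference interval table), `hits_cross` /
#'   `hits_self_ref` (outfmt6-like data.frames) and `truth` (paralog and
#'   ortholog pairs, inversions, implanted segments).
#' @export
simulate_genome_pair <- function(n_chromosomes = 4,
                                 genes_per_chromosome = 200,
                                 gene_length = 300,
                                 intergenic_gap = 700,
                                 ortholog_ks = 0.026,
                                 wgd_ks = 1.25,
                                 wgd_retention = 0.2,
                                 n_inversions = 2,
                                 inversion_genes = 20,
                                 specific_segments = c(5000, 5000, 8000),
                                 seed = 1) {
  if (wgd_retention < 0 || wgd_retention > 1)
    stop("wgd_retention must be in [0, 1]")
  if (ortholog_ks < 0 || wgd_ks < 0) stop("Ks targets must be >= 0")
  if (gene_length %% 3 != 0) stop("gene_length must be a multiple of 3")
  n_cod <- gene_length / 3
  unit <- gene_length + intergenic_gap
  chrom_len <- genes_per_chromosome * unit + intergenic_gap
  if (any(specific_segments >= chrom_len))
    stop("implanted segment longer than the chromosome")
  chroms <- sprintf("chr%d", seq_len(n_chromosomes))
  p_ortho <- .jc_inverse(ortholog_ks)
  p_wgd <- .jc_inverse(wgd_ks)

  with_seed(seed, {
    gene_id <- function(genome, c, i) sprintf("%sG%02dg%04d", genome, c, i)
    n <- genes_per_chromosome

    # reference CDS, with paralogs on partner chromosomes
    ref_idx <- vector("list", n_chromosomes)
    paralog_truth <- NULL
    for (c in seq_len(n_chromosomes)) {
      ref_idx[[c]] <- lapply(seq_len(n), function(i)
        .random_sense_codons(n_cod))
    }
    for (c in seq(1, n_chromosomes - 1, by = 2)) {
      m <- round(wgd_retention * n)
      if (m > 0) {
        retained <- sort(sample(n, m))
        for (i in retained) {
          mut <- .mutate_codons(ref_idx[[c]][[i]], p_wgd)
          ref_idx[[c + 1]][[i]] <- mut$idx
          paralog_truth <- rbind(paralog_truth, data.frame(
            gene_a = gene_id("ref", c, i), gene_b = gene_id("ref", c + 1, i),
            n_syn = mut$n_syn, stringsAsFactors = FALSE))
        }
      }
    }

    # query CDS: orthologs of every reference gene
    qry_idx <- vector("list", n_chromosomes)
    ortho_truth <- NULL
    for (c in seq_len(n_chromosomes)) {
      qry_idx[[c]] <- lapply(seq_len(n), function(i) {
        .mutate_codons(ref_idx[[c]][[i]], p_ortho)$idx
      })
      ortho_truth <- rbind(ortho_truth, data.frame(
        gene_a = gene_id("ref", c, seq_len(n)),
        gene_b = gene_id("qry", c, seq_len(n)), stringsAsFactors = FALSE))
    }

    # query gene order: implant inversions (rank-space)
    perm <- lapply(seq_len(n_chromosomes), function(c) seq_len(n))
    inv_truth <- NULL
    if (n_inversions > 0) {
      inv_chroms <- sample(n_chromosomes, n_inversions, replace = TRUE)
      used <- lapply(seq_len(n_chromosomes), function(c) logical(n))
      for (k in seq_len(n_inversions)) {
        c <- inv_chroms[k]
        for (try in 1:50) {
          s <- sample(n - inversion_genes + 1, 1)
          span <- s:(s + inversion_genes - 1)
          if (!any(used[[c]][span])) {
            perm[[c]][span] <- rev(perm[[c]][span])
            used[[c]][span] <- TRUE
            inv_truth <- rbind(inv_truth, data.frame(
              chrom = chroms[c], first_gene = s,
              last_gene = s + inversion_genes - 1, stringsAsFactors = FALSE))
            break
          }
        }
      }
    }

    # implanted query-specific segments: assign to chromosomes round-robin,
    # inserted at random inter-gene boundaries
    seg_truth <- NULL
    implants <- vector("list", n_chromosomes)
    if (length(specific_segments) > 0) {
      seg_chrom <- rep(seq_len(n_chromosomes),
                       length.out = length(specific_segments))
      for (k in seq_along(specific_segments)) {
        c <- seg_chrom[k]
        implants[[c]] <- rbind(implants[[c]], data.frame(
          slot = sample(0:n, 1), len = specific_segments[k]))
      }
    }

    # assemble annotations and coordinate tables
    ref_genes <- NULL; qry_genes <- NULL; pav_truth <- NULL
    ref_cds <- character(0); qry_cds <- character(0)
    alignments <- NULL
    qry_chrom_len <- numeric(n_chromosomes)
    for (c in seq_len(n_chromosomes)) {
      starts_ref <- intergenic_gap + (seq_len(n) - 1) * unit + 1
      ref_genes <- rbind(ref_genes, data.frame(
        gene_id = gene_id("ref", c, seq_len(n)), chrom = chroms[c],
        start = starts_ref, end = starts_ref + gene_length - 1,
        strand = "+", stringsAsFactors = FALSE))
      for (i in seq_len(n))
        ref_cds[gene_id("ref", c, i)] <- .codon_string(ref_idx[[c]][[i]])

      imp <- implants[[c]]
      if (!is.null(imp)) imp <- imp[order(imp$slot), , drop = FALSE]
      # offset accumulated before each gene slot
      offset_at_slot <- function(s) {
        if (is.null(imp)) 0 else sum(imp$len[imp$slot < s])
      }
      # query gene at slot s is ortholog perm[[c]][s]
      slot_start <- vapply(seq_len(n), function(s)
        intergenic_gap + (s - 1) * unit + 1 + offset_at_slot(s), numeric(1))
      g <- perm[[c]]
      inverted <- g != seq_len(n)
      qg <- data.frame(
        gene_id = gene_id("qry", c, g), chrom = chroms[c],
        start = slot_start, end = slot_start + gene_length - 1,
        strand = ifelse(inverted, "-", "+"), stringsAsFactors = FALSE)
      qry_genes <- rbind(qry_genes, qg)
      for (i in seq_len(n))
        qry_cds[gene_id("qry", c, i)] <- .codon_string(qry_idx[[c]][[i]])

      total_imp <- if (is.null(imp)) 0 else sum(imp$len)
      qlen <- chrom_len + total_imp
      qry_chrom_len[c] <- qlen
      # implant intervals in query coordinates; alignment = complement
      if (!is.null(imp)) {
        ins_at <- vapply(seq_len(nrow(imp)), function(k) {
          base <- imp$slot[k] * unit + intergenic_gap  # end of slot's gap
          base + sum(imp$len[seq_len(k - 1)][imp$slot[seq_len(k - 1)] <=
                                               imp$slot[k]])
        }, numeric(1))
        seg_start <- ins_at + 1
        seg_end <- ins_at + imp$len
        seg_truth <- rbind(seg_truth, data.frame(
          chrom = chroms[c], start = seg_start, end = seg_end,
          stringsAsFactors = FALSE))
        # each implant large enough carries one query-specific (PAV) gene
        for (k in which(imp$len >= 2 * gene_length)) {
          gid <- sprintf("qryG%02dspec%02d", c, k)
          gs <- seg_start[k] + floor((imp$len[k] - gene_length) / 2)
          qry_genes <- rbind(qry_genes, data.frame(
            gene_id = gid, chrom = chroms[c], start = gs,
            end = gs + gene_length - 1, strand = "+",
            stringsAsFactors = FALSE))
          qry_cds[gid] <- .codon_string(.random_sense_codons(n_cod))
          pav_truth <- rbind(pav_truth, data.frame(
            gene_id = gid, chrom = chroms[c], start = gs,
            end = gs + gene_length - 1, stringsAsFactors = FALSE))
        }
        bounds <- sort(c(0, seg_start - 1, seg_end, qlen))
        piece_start <- bounds[seq(1, length(bounds), by = 2)] + 1
        piece_end <- bounds[seq(2, length(bounds), by = 2)]
        keep <- piece_end >= piece_start
        piece_start <- piece_start[keep]; piece_end <- piece_end[keep]
        # reference coordinate = query coordinate minus implant offset
        off <- vapply(piece_start, function(x)
          sum(imp$len[(imp$slot * unit + intergenic_gap +
                         cumsum(imp$len) - imp$len) < x]), numeric(1))
        alignments <- rbind(alignments, data.frame(
          qchrom = chroms[c], qstart = piece_start, qend = piece_end,
          tchrom = chroms[c], tstart = piece_start - off,
          tend = piece_end - off, identity = 0.995,
          stringsAsFactors = FALSE))
      } else {
        alignments <- rbind(alignments, data.frame(
          qchrom = chroms[c], qstart = 1, qend = qlen,
          tchrom = chroms[c], tstart = 1, tend = qlen, identity = 0.995,
          stringsAsFactors = FALSE))
      }
    }

    ref_ann <- genome_annotation(
      data.frame(name = chroms, length = chrom_len), ref_genes)
    qry_ann <- genome_annotation(
      data.frame(name = chroms, length = qry_chrom_len), qry_genes)

    # outfmt6-like hit tables; noise rows exercise the E-value filter
    mk_hits <- function(q, s, evalue, bits) data.frame(
      qseqid = q, sseqid = s, pident = 98, length = gene_length / 3,
      mismatch = 2, gapopen = 0, qstart = 1, qend = gene_length / 3,
      sstart = 1, send = gene_length / 3, evalue = evalue,
      bitscore = bits, stringsAsFactors = FALSE)
    hits_cross <- mk_hits(ortho_truth$gene_a, ortho_truth$gene_b,
                          1e-180, 500)
    n_noise <- max(3, round(nrow(hits_cross) * 0.02))
    noise <- mk_hits(sample(ref_genes$gene_id, n_noise),
                     sample(qry_genes$gene_id, n_noise), 1e-5, 30)
    hits_cross <- rbind(hits_cross, noise)
    self_rows <- mk_hits(ref_genes$gene_id, ref_genes$gene_id, 0, 600)
    hits_self <- rbind(self_rows,
                       if (!is.null(paralog_truth))
                         mk_hits(paralog_truth$gene_a, paralog_truth$gene_b,
                                 1e-50, 200))

    list(ref_annotation = ref_ann, qry_annotation = qry_ann,
         ref_cds = ref_cds, qry_cds = qry_cds,
         alignments = alignments,
         hits_cross = hits_cross, hits_self_ref = hits_self,
         truth = list(paralog_pairs = paralog_truth,
                      ortholog_pairs = ortho_truth,
                      inversions = inv_truth,
                      specific_segments = seg_truth,
                      pav_genes = pav_truth))
  })
}

#' Simulate a three-group diploid population with a sex-linked sweep
#'
#' Outside the sweep interval, allele frequencies are drawn from a symmetric
#' Beta calibrated so the expected windowed diversity equals
#' `background_pi`, then diversified into two ancestry clusters ("origins",
#' assigned orthogonally to sex) by a Balding-Nichols draw at
#' `structure_fst`: this reproduces the situation where genome-wide
#' phylogeny and structure group samples by ancestry, not sex. Inside the
#' sweep, the swept group's frequencies are pulled toward fixation
#' (`p * sweep_pi_reduction`) while the other groups share a frequency
#' displaced by `sweep_fst_boost`, producing reduced diversity in the swept
#' group and elevated FST against it -- so only a region-restricted tree
#' groups samples by sex.
#'
#' @param n_per_group named counts for `female`, `male`, `hermaphrodite`.
#' @param n_sites number of SNP sites.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param background_pi expected per-bp windowed diversity (default 0.005);
#'   must be below half the SNP density.
#' @param sweep_interval [interval()] inside the chromosome; must contain at
#'   least 50 SNPs.
#' @param sweep_pi_reduction multiplicative diversity reduction in `(0, 1]`
#'   (1 = null model).
#' @param sweep_fst_boost allele-frequency displacement in `[0, 1]`.
#' @param swept_group which group carries the sweep (default `"male"`).
#' @param structure_fst Balding-Nichols differentiation between the two
#'   sex-orthogonal ancestry clusters (default 0.15; 0 disables structure).
#' @param seed integer seed.
#' @return list with `gt` ([genotype_table()]), `labels` (named group
#'   vector), `groups` (group -> sample ids), `origins` (named ancestry
#'   cluster vector) and `truth`.
#' @export
simulate_population <- function(n_per_group = c(female = 10, male = 5,
                                                hermaphrodite = 9),
                                n_sites = 10000,
                                chrom = "chr2",
                                chrom_length = 500000,
                                background_pi = 0.005,
                                sweep_interval = interval("chr2", 200001,
                                                          220000),
                                sweep_pi_reduction = 0.1,
                                sweep_fst_boost = 0.6,
                                swept_group = "male",
                                structure_fst = 0.15,
                                seed = 1) {
  if (sweep_pi_reduction <= 0 || sweep_pi_reduction > 1)
    stop("sweep_pi_reduction must be in (0, 1]")
  if (sweep_fst_boost < 0 || sweep_fst_boost > 1)
    stop("sweep_fst_boost must be in [0, 1]")
  if (structure_fst < 0 || structure_fst >= 1)
    stop("structure_fst must be in [0, 1)")
  if (sweep_interval$chrom != chrom || sweep_interval$end > chrom_length)
    stop("sweep_interval must lie within the chromosome")
  if (!swept_group %in% names(n_per_group)) stop("unknown swept_group")
  density <- n_sites / chrom_length
  # pooling two Balding-Nichols origins shrinks heterozygosity by 1 - F/2;
  # calibrate the base Beta so the realized diversity hits background_pi
  target_het <- background_pi / density / (1 - structure_fst / 2)
  if (target_het >= 0.5)
    stop("background_pi too high for the SNP density")
  shape <- target_het / (1 - 2 * target_het)  # E[2p(1-p)] = a/(2a+1)

  with_seed(seed, {
    pos <- sort(sample.int(chrom_length, n_sites))
    p_bg <- stats::rbeta(n_sites, shape, shape)
    in_sweep <- pos >= sweep_interval$start & pos <= sweep_interval$end
    if (sum(in_sweep) < 50)
      stop("fewer than 50 SNPs fall inside the sweep interval; ",
           "increase n_sites or widen the interval")
    # per-origin background frequencies (Balding-Nichols around p_bg)
    bn_draw <- function(p, F) {
      if (F <= 0) return(p)
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      q <- stats::rbeta(length(p), pmax(a, 1e-6), pmax(b, 1e-6))
      q
    }
    p_origin <- cbind(bn_draw(p_bg, structure_fst),
                      bn_draw(p_bg, structure_fst))
    p_swept_sweep <- p_bg[in_sweep] * sweep_pi_reduction
    p_other_sweep <- pmin(p_swept_sweep + sweep_fst_boost, 1)

    prefix <- c(female = "F", male = "M", hermaphrodite = "H")
    samples <- unlist(lapply(names(n_per_group), function(g)
      sprintf("%s%02d", prefix[[g]], seq_len(n_per_group[[g]]))))
    labels <- stats::setNames(rep(names(n_per_group), n_per_group), samples)
    # ancestry clusters alternate within each sex group: orthogonal to sex
    origins <- stats::setNames(unlist(lapply(n_per_group, function(k)
      rep_len(c(1L, 2L), k)), use.names = FALSE), samples)
    geno <- matrix(NA_integer_, n_sites, length(samples),
                   dimnames = list(NULL, samples))
    for (s in samples) {
      p <- p_origin[, origins[[s]]]
      if (labels[[s]] == swept_group) {
        p[in_sweep] <- p_swept_sweep
      } else {
        p[in_sweep] <- p_other_sweep
      }
      geno[, s] <- stats::rbinom(n_sites, 2, p)
    }
    gt <- genotype_table(samples,
                         data.frame(chrom = chrom, pos = pos, ref = "A",
                                    alt = "G", stringsAsFactors = FALSE),
                         geno)
    groups <- split(samples, labels[samples])
    list(gt = gt, labels = labels, groups = groups, origins = origins,
         truth = list(sweep_interval = sweep_interval,
                      swept_group = swept_group,
                      n_snps_in_sweep = sum(in_sweep),
                      background_pi = background_pi,
                      sweep_pi_reduction = sweep_pi_reduction,
                      sweep_fst_boost = sweep_fst_boost,
                      structure_fst = structure_fst))
  })
}

#' Simulate a gene-interaction network
#'
#' @param n_nodes number of genes (>= 2).
#' @param mean_degree expected degree (`< n_nodes`).
#' @param model `"erdos_renyi"` (G(n, p) with `p = mean_degree/(n-1)`) or
#'   `"scale_free"` (preferential attachment with
#'   `m = round(mean_degree/2)` edges per step).
#' @param seed integer seed.
#' @return simple undirected `igraph` graph with vertex names
#'   `gene001, ...`.
#' @export
simulate_network <- function(n_nodes, mean_degree,
                             model = c("erdos_renyi", "scale_free"),
                             seed = 1) {
  model <- match.arg(model)
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (mean_degree >= n_nodes) stop("mean_degree must be < n_nodes")
  g <- with_seed(seed, {
    if (model == "erdos_renyi") {
      igraph::sample_gnp(n_nodes, p = mean_degree / (n_nodes - 1))
    } else {
      igraph::sample_pa(n_nodes, m = max(1, round(mean_degree / 2)),
                        directed = FALSE)
    }
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("gene%03d", seq_len(n_nodes))
  g
}
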