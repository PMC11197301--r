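---
title: "Methods: divergence dating, PAV calling, sweep scanning and SDR mapping in grapediverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence dating, PAV calling, sweep scanning and SDR mapping in grapediverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapediverge)
```

# Scope

`grapediverge` packages the comparative-genomics and population-genomics
computations used to characterize wild grape (*Vitis*) genomes: how long ago
species diverged (anchored on the ancient core eudicot-common hexaploidy,
ECH), which parts of a genome are species-specific (presence/absence
variation, PAV), where selection has acted between sexes (selective-sweep
scans and the putative sex-determination region, SDR), and how robust a
gene-interaction network is to gene loss. Every stage consumes standard
formats (FASTA, GFF3, VCF, PAF, BLAST outfmt6 tables) and every stage can be
exercised on synthetic inputs with a known truth table, which is how the
test suite validates the estimators end to end.

All internal coordinates are 1-based inclusive (the GFF3 convention);
0-based half-open inputs (PAF) are converted at the I/O boundary and back on
write.

# Ka/Ks by Nei-Gojobori counting

`ng86_counts()` implements the classic NG86 scheme. Each codon position
contributes $f/3$ synonymous sites, where $f$ is the fraction of the three
possible single-nucleotide changes at that position that preserve the amino
acid; changes producing a stop codon count as nonsynonymous sites. Site
totals are averaged over the two sequences, so $S + N$ always equals the
aligned length in nucleotides. Codons differing at more than one position
are resolved by averaging the synonymous/nonsynonymous step classifications
over all minimal substitution pathways, excluding pathways that pass
through a stop codon (in the rare case where every pathway is blocked, all
pathways are used). Both rates are completed with the Jukes-Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$; proportions at or
beyond $p = 0.75$ are reported as saturated (`NA`) rather than numbers.

The implementation precomputes the $64 \times 64$ pathway-averaged
difference table once per session; the test suite compares it against an
independent recursive pathway-enumeration oracle over all $61 \times 61$
sense-codon pairs.

The package deliberately implements NG86 rather than the Yang-Nielsen
refinement: equal-rate counting is the stated model for the Ks values the
downstream dating consumes, and its behavior is fully checkable by
enumeration.

# Ks peaks and divergence dating

`fit_ks_peaks()` fits a univariate Gaussian mixture to (block-median) Ks
values by expectation-maximization, initialized with a seeded k-means so
results are deterministic given the seed, and reports components in the
`mu (± sigma)` convention of genome papers. Peak recovery is tested at
$n = 4000$ (absolute error below 0.02 on both $\mu$ and $\sigma$) and
cross-checked against an independent mixture implementation (mclust).
Degenerate inputs (zero variance, fewer than 50 values or fewer than ten
per component) are rejected rather than fitted.

`calibrate_divergence()` applies the linear molecular clock
$T = K_s^{ortho} \cdot T_{ECH} / K_s^{ECH}$. The ECH age defaults to
130 Mya and is an explicit argument, since literature values span roughly
130-150 Mya. With ortholog peaks at 0.025-0.026 and ECH-paralog peaks at
1.25-1.29 this places the grape species splits at roughly 2.3-2.8 Mya;
`calibrate_divergence_range()` maps peak ranges to the implied band.

# Collinearity and paralog classes

`chain_collinear_blocks()` works in gene-rank space: within each chromosome
pair, anchors are greedily peeled into maximal strictly monotone chains
(increasing-increasing for `same` orientation, increasing-decreasing for
`inverted`), with consecutive-anchor rank gaps bounded on both axes. The
defaults (minimum 5 anchors per block, maximum rank gap 25) mirror common
collinearity-tool defaults and are arguments, not constants. Ties in the
dynamic program are broken toward the earliest candidate so the output is
deterministic. Each emitted block is verified in the tests to be exactly as
long as an exhaustive longest-chain oracle permits on the remaining
anchors.

`classify_paralogs()` labels a pair *ECH-derived* when it lies in a
collinear block and its Ks falls within $\mu \pm 2\sigma$ of the fitted ECH
peak, and *tandem* when both genes share a chromosome within a rank gap of
5 (an argument; the threshold is a convention, not a published value). The
two labels are deliberately not exclusive — published NBS-gene counts
overlap (34 ECH + 42 tandem out of 64) — so a pair satisfying both is
reported under both with a warning. `count_retained_duplicates()` counts
distinct genes in intra-genome blocks and formats the fraction with
half-up rounding, the convention behind printed values such as 16.26%.

# Specific segments and PAV genes

The PAV procedure follows the windowed-coverage recipe: the query genome is
cut into 500-bp windows stepping 100 bp (`make_windows()`; trailing
sub-size windows are dropped so every coverage fraction has the same
denominator), per-window coverage is the clipped union of alignment
intervals (`window_coverage()`), and windows that fail to align or align
with coverage strictly below 25% are genome-specific
(`call_specific_segments()`; the boundary is strict, so exactly 25% is not
specific). Overlapping or adjacent specific windows are merged into maximal
segments; both the merged segment count and the raw specific-window count
are reported, since published "segment" counts do not state whether
windows were merged. Genes whose span is at least half covered by specific
segments are the species-specific PAV genes (`assign_pav_genes()`;
"within a segment" is not defined by the procedure's sources, so the 50%
threshold is an argument and a strict-containment mode is provided).

On simulated genome pairs with implanted segments, called segments match
truth at base-level Jaccard >= 0.9 and implanted PAV genes are recovered
exactly.

# Sweep scanning

Per window (default 5-kb non-overlapping tiles, matching the granularity at
which sweep regions are conventionally reported), `window_pi()` computes
nucleotide diversity as the sum over SNPs of the unbiased per-site
heterozygosity $2\hat p(1-\hat p)\,n/(n-1)$ divided by the window length in
bp, and `window_fst()` the Hudson ratio-of-averages estimator
$$F_{ST} = \frac{\sum_s (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}}{\sum_s p_1(1-p_2) + p_2(1-p_1)}.$$
Hudson's estimator was chosen because the upstream tooling behind published
scans does not pin down an estimator; both statistics are validated against
per-site brute-force oracles on small tables. Missing genotypes are
excluded site-wise from allele-frequency denominators (pairwise complete),
never imputed; sites with fewer than two non-missing alleles in a group are
skipped.

`scan_sweeps()` selects windows whose FST *and* θπ ratio both strictly
exceed their empirical 95% quantiles (linear interpolation; strict `>`
excludes ties, so a degenerate all-equal scan selects nothing) and merges
adjacent selected windows into candidate regions. The θπ ratio is oriented
as π(reference)/π(candidate) so a sweep in the candidate group raises the
ratio; the orientation is recorded in the result. `ld_prune()` provides
PLINK-style pruning (50-SNP windows advancing by 5, r² > 0.5 removes the
later member of the worst pair) for analyses that need thinned markers;
monomorphic sites have undefined r² and are always retained.

# SNP trees and the SDR

`snp_distance_matrix()` uses the allele-sharing distance (mean absolute
dosage difference over shared non-missing sites, halved), optionally
restricted to an interval such as the SDR, and `nj_tree()` builds a
neighbor-joining tree (negative branch lengths clamped to zero).
Neighbor-joining replaces the maximum-likelihood tree of typical
resequencing pipelines because the package only asserts topology-level
grouping claims — which leaves sit together — and NJ supports those while
remaining fast and deterministic. `tree_separates_group()` checks whether
some edge bipartitions the leaves exactly into a group versus the rest.

`liftover_interval()` transfers an interval between genomes through
one-to-one ortholog anchors: anchors overlapping the source, widened by a
configurable flank (default 1) on each side, span the target; orientation
comes from the rank correlation of anchor positions. Gene anchors, rather
than base-level alignment, are the lift-over unit because the published
"orthologous DNA mapping" leaves the mechanism open and anchor spans are
robust to local alignment noise. `compare_gene_content()` compares
haplotype gene-content lists as label multisets and reports gained/lost
labels plus whether the shared labels keep their relative order. The
packaged female-haplotype tables encode the Amur grape aldolase-TPP fusion
gene as two label rows on one gene id, so the label-level diff isolates the
real content difference (one FMO lost, one uncharacterized gene gained).
The packaged SDR gene annotation is an explicitly synthetic stand-in: the
16 gene ids and the interval are real, but per-gene coordinates are not
public, so the genes are placed evenly across the interval.

# Network robustness

`robustness()` removes a fixed number (or half-up-rounded percentage) of
nodes — uniformly at random over many trials, or deterministically by
descending degree with name-order tie-breaks — and reports the mean
fraction of the *original* node count remaining in the largest connected
component. The largest-component-fraction convention is adopted and
documented because published robustness tables delegate their formula to
prior work without reproducing it; for the same reason no published table
values are claimed as reference results. Random mode is validated against
the exhaustive average over all removal subsets on small graphs.

# The synthetic-data generators

The generators define the study conditions for all tests; their defaults
are fixed once and are not tuning knobs.

**Codon pairs** (`simulate_codon_pair_set()`): each pair descends from a
random sense-codon ancestor; substitutions are placed per codon with
probability proportional to the codon's NG86 site content in the relevant
category, with the per-pair substitution *count* pinned to $p \cdot S$
(stochastic rounding) and at most one substitution per category per codon.
Pinning the count removes the Jensen bias the convex Jukes-Cantor transform
would otherwise add to the mean, and the one-hit rule prevents two
individually synonymous changes from composing into a nonsynonymous codon
state; with these two choices the mean recovered Ks tracks the target to
within ~0.005 at the ECH scale. The generator intentionally matches NG86's
own site definitions — NG86 is the estimator under test, so a full codon
model would only blur what a recovery failure means.

**Genome pairs** (`simulate_genome_pair()`): two annotated genomes with
identical gene layout (default 4 chromosomes x 200 genes of 300 bp spaced
700 bp); chromosome pairs carry retained whole-genome-duplication paralogs
at a set retention (default 0.2, meaning the fraction of genes
participating in paralog pairs — so recovered duplicated-gene fractions
equal the knob), diverged to the ECH target Ks 1.25; query orthologs are
diverged to 0.026. The query additionally receives rank-space inversions
and implanted specific segments (each large implant carries one
query-specific gene), and the emitted alignment table covers exactly the
shared sequence. Hit tables include self-hits, paralog hits and noise rows
at the E-value ceiling so the strict `< 1e-5` filter is exercised.

**Populations** (`simulate_population()`): 10 female, 5 male and 9
hermaphrodite diploids, 10,000 SNPs on a 500-kb chromosome. Background
allele frequencies come from a symmetric Beta calibrated so expected
windowed diversity equals `background_pi` (default 0.005/bp), then split
into two *ancestry clusters assigned orthogonally to sex* by a
Balding-Nichols draw at F = 0.15 (the calibration divides by $1 - F/2$ to
compensate for the pooling effect). The ancestry layer is essential to
reproduce the observed contrast: resequencing panels group by provenance,
not sex, in genome-wide trees; without background structure *any*
localized sex-linked signal, however small, dominates an otherwise
structureless distance matrix and the genome-wide tree would spuriously
cluster by sex. Inside the sweep interval (default 20 kb, ~4% of SNPs) the
swept group's frequencies are multiplied by `sweep_pi_reduction` (0.1) and
the other groups are displaced by `sweep_fst_boost` (0.6). Frequencies, not
genealogies, are modified: the acceptance surface is window statistics, so
coalescent realism is out of scope. A consequence worth knowing: under
label permutation the sweep interval remains a region of unusual allele
frequencies, so permuted scans can still clip it occasionally — the
permutation control therefore asserts collapsed *coverage* of the interval,
not zero overlap.

**Networks** (`simulate_network()`): Erdős–Rényi G(n, p) or preferential
attachment, simplified, with named vertices.

What the generators do *not* emulate: sequencing error, missing-data
patterns of real resequencing, indel/SV alignment noise, recombination
gradients, linked selection outside the sweep, or assembly artifacts.
Passing tests therefore demonstrate correctness of the estimators under
clean signals of realistic magnitude, not robustness to every failure mode
of real data.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to be
informative while staying quick: 400-2000 codon pairs of 300 codons for Ks
recovery, genome pairs of 4 x 100-150 genes for collinearity/PAV, 25-100
population replicates of 4000 SNPs for sweep detection, 200-4000 network
trials. These sizes are the package's choices for routine validation; all
generators accept larger values. Every stochastic function takes an
explicit seed and restores the caller's RNG state (`withr::with_seed`), so
identical seeds give byte-identical outputs; `run_demo()` writes its
resolved configuration next to its report.

# Known limitations

- NG86 assumes equal base frequencies and no transition/transversion bias;
  Ks from biased genes will differ from codon-model estimates.
- Rank-space chaining detects inversions as reversed-rank blocks only; it
  does not call base-level breakpoints.
- The Hudson FST ratio-of-averages is undefined in windows with no
  polymorphism in either group (reported `NA`, excluded from quantiles).
- Lift-over assumes one-to-one anchors; paralogy-confounded anchor maps
  should be filtered to reciprocal best pairs first.
- Tetraploid VCF genotypes are either collapsed to presence dosage or
  excluded; true tetrasomic allele frequencies are not modeled.
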