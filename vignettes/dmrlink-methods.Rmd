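---
title: "Methods: differential methylation calling and methylome-transcriptome linking"
author: "dmrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation calling and methylome-transcriptome linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrlink)
```

## Scope and model

`dmrlink` implements the downstream computation of a two-condition plant
epigenomics design: whole-genome bisulfite sequencing (WGBS) of the same
tissue under two treatments (one library per condition), paired with
replicated RNA-seq, analysed from per-cytosine methylation count tables
onward. Read alignment and methylation extraction are upstream of the
package; the canonical input is a methratio-style table of
(chrom, pos, strand, context, methylated reads, coverage).

The analysis chain is:

1. **Conversion rate.** Bisulfite converts unmethylated cytosine to uracil;
   the per-read probability that an unmethylated cytosine still reads as C
   (the false-methylation rate) is the complement of the conversion rate,
   estimated by pooling reads over an unmethylated spike-in
   (`estimate_conversion_rate()`): `rate = 1 - sum(meth) / sum(coverage)`.
2. **Methylcytosines.** At each site covered by at least 4 reads the
   methylated-read count is tested against conversion failure alone with a
   one-sided binomial tail at `p0 = 1 - rate` (`call_mc()`), adjusted by
   Benjamini-Hochberg at `alpha = 0.05`. Equivalently, `min_mc_reads()`
   reports the minimal significant ("anticipated") count per coverage.
   Whether the original analysis corrected for multiple testing is not
   documented; both the level and the correction method are exposed, with
   BH as the conservative default.
3. **DmCs.** Jointly covered sites are tested with a two-sided Fisher exact
   test on the 2x2 read-count table; a differentially methylated cytosine
   requires `p < 0.05` and an absolute level change of at least 0.20
   (`call_dmcs()`).
4. **DMRs.** A seed-and-extend scan per context (`call_dmrs()`), described
   below.
5. **Feature association.** Multi-label classification of sites against
   genes/TEs/flanks (`classify_position()`), midpoint-based DMR assignment
   to the nearest gene (`assign_dmr()`), fold enrichment
   `(DmC_f/DmC_t)/(mC_f/mC_t)` with hypergeometric tails (`enrichment()`),
   metagene bins (5 body fifths + 10 x 300 bp flanks, `metagene_bins()`)
   and TSS/TES distance histograms (`dmr_distance_profile()`).
6. **Expression.** FPKM arithmetic (`compute_fpkm()`), DEG calls at
   divergence probability >= 0.8 and fold >= 2 (`call_degs()`), DET calls
   by an exact conditional binomial rate-ratio test with BH adjustment
   after discarding gene-overlapping TEs (`call_dets()`).
7. **Linking.** DMR-DEG interaction sites restricted to CDS placements and
   UP/DOWN placements within 2 kb of the TSS/TES, signed by the product of
   the methylation and expression changes (`link_dmr_deg()`); DMR-DET
   association by closed-interval overlap with the TE body
   (`link_dmr_det()`).

Every numeric rule sits in `pipeline_config()` with the published values
as defaults; deviating values warn but are accepted.

## The DMR scan

Motifs are strand-specific cytosines of one context covered by at least
`min_coverage` (4) reads in both conditions. CG and CHG are
strand-symmetric, so they are screened on the Watson strand only; CHH is
screened separately per strand.

A window of 5 adjacent motifs seeds a candidate region when

* at least 4 of the 5 motifs share the same **response direction**,
* all adjacent gaps are below 200 bp, and
* the two-sided Wilcoxon rank-sum test comparing the window's condition-A
  levels with its condition-B levels gives `p < 0.05`.

The candidate is extended one motif at a time downstream while the next
motif matches the seed's majority direction, stays within the gap limit,
and the rank-sum test recomputed over the whole grown region remains
significant; the first violation closes the region at the last conforming
motif ("until differential significance disappeared" is read as a stopping
condition, not a skip rule). Windows slide by one motif, so overlapping
same-direction candidates arise and are merged by union. Regions shorter
than 50 bp or with an absolute mean level difference below 0.1 are then
discarded. Region boundaries are the first and last member motifs; the
region delta is the unweighted mean of per-motif level differences
(coverage weighting would couple the region statistic to sampling depth;
the unweighted mean matches the per-motif reading of the filters).

### Response direction: why DmC status is the default

The defining texts leave "same response pattern" open between two
readings: the raw sign of the per-motif level difference, or same-direction
differential methylation of the motif itself. The package implements both
(`dmr_params(response = )`) and defaults to `"dmc"`: a motif responds only
when it is itself a DmC (Fisher `p < 0.05`, `|delta| >= 0.20`), in the
direction of its change.

The reason is quantitative. Under the sign reading, the only per-window
evidence is the rank-sum test at `alpha = 0.05`; an exact 5v5 rank-sum
fires on just under 5% of null windows, and a genome of a million motifs
offers a million windows, so a null comparison yields thousands of
spurious regions that survive the length and delta filters (measured on a
60 kb null simulation: about 120 false regions; extrapolated to 2 Mb,
thousands). That defeats the purpose of region calling in a design with
one library per condition. Under the DmC reading, seeding requires four
independently significant, direction-consistent sites within a 5-motif
window; the null probability of that event is orders of magnitude below
the per-window alpha, and a 2 Mb null simulation yields zero regions,
while 300 bp planted regions at |delta| = 0.5 are recovered with recall
and precision 1.0 (the packaged benchmark asserts >= 0.8). The Wilcoxon
test is retained as the region-level decision during seeding and
extension, exactly as printed.

The rank-sum test is the two-group test, exact by complete enumeration of
all group assignments (conditioning on midranks when ties are present) up
to group size 7 — `choose(10, 5) = 252` splits for a seed window — and a
tie-corrected, continuity-corrected normal approximation beyond that, the
same convention as `stats::wilcox.test()`. Because both groups are the
same motifs under two conditions, group sizes are always equal, and the
conditional null is symmetric, making the "double the smaller tail" and
"total mass at least as extreme" two-sided rules coincide. A paired
signed-rank reading of the test was considered and set aside: with 5
pairs its smallest attainable two-sided p-value is 1/16, so no 5-motif
window could ever seed.

## The synthetic study generator

`sim_config()` fixes the whole design: uniform-random chromosome sequences
(CHH-dominant, as in real plant genomes), context baseline levels
`CG = 0.6, CHG = 0.3, CHH = 0.08` (typical plant shoot-tissue ranges:
high CG, intermediate CHG, low CHH), Poisson read coverage (default mean
20; the depth distribution of the original libraries is not published, so
this is a design choice), a bisulfite conversion rate of 0.9951, and
triplicate lognormal expression libraries. Planted DMRs shift the true
level of matching-context cytosines inside their interval; planted
DEG/DET effects shift condition-B expression by a log2 effect. Conversion
error is applied per unmethylated molecule with probability
`1 - conversion_rate`; methylated molecules read without error.

What the generator does *not* emulate: read-level errors other than
conversion failure, coverage autocorrelation along the genome, CG-island
structure, biological replicate variance in the methylomes (the emulated
design pools hundreds of apices into one library per condition), and
genome-scale heterochromatin organisation. Passing the packaged benchmarks
therefore demonstrates correctness of the algorithms under the stated
noise model, not performance on real libraries.

The planted-DMR benchmark used by the tests is one 2 Mb chromosome with
60 planted 300 bp regions (20 per context) at |delta| = 0.5 and coverage
mean 30, signed so that no true level clips the [0, 1] range
(CG 0.6 -> 0.1, CHG 0.3 -> 0.8, CHH 0.08 -> 0.58); matching requires 50%
reciprocal overlap with matching context. These sizes keep the full suite
under a minute while leaving hundreds of motifs per region.

## Numerical and degenerate-input choices

* Fisher, binomial and hypergeometric tails are computed through
  `dhyper`/`pbinom`/`phyper`; the vectorised 2x2 Fisher test reproduces
  `stats::fisher.test`'s minimum-likelihood two-sided rule to 1e-10 and
  exists because the scan evaluates it for hundreds of thousands of sites.
* `rate = 1` with a nonzero methylated count gives `p = 0` without
  division errors; `0/0` tables give `p = 1`.
* An empty spike-in table (or zero pooled reads) is an estimation error,
  not a silent `NaN`.
* Chromosome-end cytosines whose context cannot be resolved are excluded
  rather than defaulted to CHH.
* Midpoints use `floor((start + end) / 2)`; equidistant nearest-gene ties
  break toward the lower gene id; DMR-TE overlap counts a single shared
  base pair.
* Zero-count enrichment denominators (`mC_feature = 0`) report `NA` with
  the counts preserved rather than an infinite fold.
* The log2 fold change substitutes a 0.01 FPKM pseudocount for zero
  condition means; the DEG fold criterion is evaluated symmetrically
  (larger mean over smaller).
* The divergence probability consumed by the DEG filter is an input
  column in real analyses; the packaged stand-in (replicate-pair sign
  concordance) exists so the synthetic pipeline runs end to end and is
  not a calibrated posterior.
* The DET test is an exact conditional binomial rate-ratio test: with one
  library per condition there is no dispersion estimate, so the pooled
  count is split binomially under the null with success probability
  proportional to library totals. The adjustment behind "adjusted
  p-values" is not documented upstream; BH is used.
* Zone labels reconcile two printed definitions: "genic" is the gene body
  plus 2 kb flanks, while the 2-5 kb shell around TSS/TES is labelled
  `proximal_2to5kb` and positions beyond 5 kb of every TSS/TES are
  intergenic. Multi-labelling is intentional throughout.
* Interaction-site counting is per (DMR, gene) pair — a gene linked by
  several DMRs contributes several sites — and UTR/intron placements are
  excluded by default (`include_intragenic = TRUE` restores them).

## Worked example

```{r example}
cfg <- sim_config(
  seed = 11, chromosome_length = 120000, gene_count = 10, te_count = 6,
  coverage_mean = 25,
  planted_dmrs = data.frame(chrom = "Chr1", start = 40001, end = 40400,
                            context = "CG", delta = -0.45))
ann <- generate_annotation(cfg)
mp <- generate_methylome_pair(cfg, ann)
dmrs <- call_dmrs(mp$a, mp$b)
dmrs[, c("chrom", "start", "end", "context", "n_motifs", "delta",
         "direction")]
assign_dmr(dmrs, ann)[, c("midpoint", "zone", "gene_id", "placement",
                          "distance", "te_overlap")]
```

The packaged fixtures of the published worked examples are available via
`load_table_fixtures("table1")` (differentially expressed TEs with their
associated DMR intervals) and `load_table_fixtures("table2")` (putative
epiregulated genes with expression change and DMR descriptors), and the
acceptance script `scripts/acceptance.R` recomputes the conversion-rate
recovery from scratch.

## Known limitations

* One WGBS library per condition: the Fisher/rank-sum machinery quantifies
  sampling noise, not biological variance between replicates.
* The scan is single-threaded; a 2 Mb chromosome at coverage 30 takes
  roughly half a minute.
* ncRNA annotation, GO/KEGG classification, phylogenetics and plotting are
  out of scope.
* BED/GFF3/TSV dialects are the subsets described in the I/O functions;
  CX-report and bedGraph dialects are not parsed.
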