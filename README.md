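# dmrlink

Differential DNA methylation calling and methylome–transcriptome linking
for two-condition bisulfite sequencing designs.

## The problem

Environmental cues such as photoperiod reshape plant DNA methylation, and
methylation changes near genes can accompany — and putatively drive —
expression changes. `dmrlink` implements the downstream computation of a
study design that profiles the same tissue under two conditions with
whole-genome bisulfite sequencing (one library per condition) and
replicated RNA-seq, and asks which differentially methylated regions
(DMRs) sit in or near differentially expressed genes (DEGs) and
transposable elements (DETs), and with which sign of association. It is
aimed at analysts who already have per-cytosine methylation count tables
(methratio-style), a GFF3/BED annotation and expression tables, and who
want the region calling, enrichment and linking steps as tested, reusable
functions.

## The statistics at its core

* **Conversion-adjusted mC calling.** With bisulfite conversion rate *r*
  (estimated from an unmethylated spike-in, here 99.51% by default), a
  site with coverage *n* and *m* methylated reads is a methylcytosine when
  the one-sided binomial tail P(X ≥ m | n, p₀ = 1 − r) survives BH
  correction at α = 0.05.
* **DmCs.** Two-sided Fisher's exact test per jointly covered site
  (coverage ≥ 4 in both conditions); a DmC needs p < 0.05 and a
  methylation-level change ≥ 0.20.
* **DMRs.** A seed-and-extend scan over CG/CHG/CHH motif tracks (CG/CHG on
  Watson, CHH per strand): a 5-motif window seeds when ≥ 4 motifs respond
  in the same direction, gaps stay < 200 bp, and the exact two-sided
  Wilcoxon rank-sum test of condition-A vs condition-B levels gives
  p < 0.05; regions extend downstream until significance disappears, then
  drop if shorter than 50 bp or with |mean level difference| < 0.1.
* **Enrichment.** Fold = (DmC_feature/DmC_total)/(mC_feature/mC_total)
  with hypergeometric tail p-values, over feature labels, metagene bins
  (5 body bins + 10 × 300 bp flanks) and 100 bp TSS/TES distance bins.
* **Expression.** FPKM; DEGs at divergence probability ≥ 0.8 and
  fold ≥ 2; DETs by an exact conditional binomial rate-ratio test with BH
  adjustment, after discarding gene-overlapping TEs.
* **Epiregulation.** One interaction site per (DMR, DEG) pair with the DMR
  in the CDS or within 2 kb of the TSS/TES; the association is *negative*
  when methylation and expression change in opposite directions.

A deterministic simulator (`sim_config()`, `simulate_study()`) generates
complete synthetic studies — genome, annotation, two-condition methylomes
with planted DMRs, spike-in controls, replicated expression with planted
effects — together with truth tables, so the whole chain is testable
without external data.

## Worked example

```r
library(dmrlink)

cfg <- sim_config(
  seed = 11, chromosome_length = 120000, gene_count = 10, te_count = 6,
  coverage_mean = 25,
  planted_dmrs = data.frame(chrom = "Chr1", start = 40001, end = 40400,
                            context = "CG", delta = -0.45))
ann <- generate_annotation(cfg)
mp  <- generate_methylome_pair(cfg, ann)

estimate_conversion_rate(generate_conversion_control(cfg, 20000))
#> conversion rate 99.5076% (20000 sites, 501459 reads, 2469 unconverted)

dmrs <- call_dmrs(mp$a, mp$b)
dmrs[, c("chrom", "start", "end", "context", "n_motifs", "delta", "direction")]
#>   chrom start   end context n_motifs      delta direction
#> 1  Chr1 40020 40425      CG       27 -0.4752057      down

assign_dmr(dmrs, ann)[, c("midpoint", "zone", "gene_id", "placement",
                          "distance", "te_overlap")]
#>   midpoint  zone gene_id placement distance te_overlap
#> 1    40222 genic    g004        UP      337      FALSE
```

The planted 400 bp CG demethylation (Δ = −0.45) is recovered as a single
`down` region whose boundaries are the first and last significant motifs,
and its midpoint lands 337 bp upstream of the nearest simulated gene — the
kind of promoter-hypomethylation/upregulation candidate the linking stage
(`link_dmr_deg()`) classifies by association sign. `run_pipeline()` wires
all stages over a simulated study and writes every report as TSV plus a
checksum manifest.

Packaged fixtures of the published worked examples are available through
`load_table_fixtures("table1")` (the ten differentially expressed TEs and
their associated DMR intervals) and `load_table_fixtures("table2")` (the
ten putative epiregulated genes with expression changes and DMR
descriptors such as `UP,CHG(1283;0.15)`).

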