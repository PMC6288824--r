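# Shared in-code fixtures: a tiny handwritten annotation, exact-count
# cytosine tables for region-scan tests, and the planted-DMR benchmark
# configuration.

# Two genes (one per strand) and two TEs on a 50 kb chromosome:
#   gA (+): 10001-13000, TSS 10001; UTR 10001-10200, CDS 10201-11000 and
#           11501-12800, intron 11001-11500, UTR 12801-13000
#   gB (-): 30001-32000, TSS 32000; CDS only
#   teA: 10801-11200 (overlaps gA CDS/intron); teB: 40001-40500 (gene-free)
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(10001L, 30001L), end = c(13000L, 32000L),
    strand = c("+", "-"),
    tss = c(10001L, 32000L), tes = c(13000L, 30001L),
    stringsAsFactors = FALSE)
  parts <- data.frame(
    gene_id = c("gA", "gA", "gA", "gA", "gA", "gB"),
    type = c("UTR", "CDS", "intron", "CDS", "UTR", "CDS"),
    start = c(10001L, 10201L, 11001L, 11501L, 12801L, 30001L),
    end = c(10200L, 11000L, 11500L, 12800L, 13000L, 32000L),
    stringsAsFactors = FALSE)
  tes <- data.frame(
    te_id = c("teA", "teB"), chrom = "chr1",
    start = c(10801L, 40001L), end = c(11200L, 40500L),
    family = c("LTR/Gypsy", "unknown"), stringsAsFactors = FALSE)
  structure(list(sequences = NULL, genes = genes, parts = parts, tes = tes),
            class = "dmrlink_annotation")
}

# Cytosine tables realising exact levels at fixed coverage; levels must be
# multiples of 1/coverage.
exact_cyto_pair <- function(pos, level_a, level_b, coverage = 20L,
                            chrom = "chr1", strand = "+", context = "CG") {
  stopifnot(length(level_a) == length(pos), length(level_b) == length(pos))
  mk <- function(lv) {
    meth <- as.integer(round(lv * coverage))
    stopifnot(all(abs(meth - lv * coverage) < 1e-9))
    data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
               context = context, meth_reads = meth,
               coverage = as.integer(coverage), stringsAsFactors = FALSE)
  }
  list(a = mk(level_a), b = mk(level_b))
}

# Planted-DMR benchmark: one 2 Mb chromosome, 60 planted 300 bp DMRs (20
# per context) at |delta| = 0.5, coverage mean 30. Deltas are signed so
# that no true level is clamped: CG 0.6 -> 0.1, CHG 0.3 -> 0.8,
# CHH 0.08 -> 0.58.
dmr_benchmark_config <- function(seed, null = FALSE) {
  contexts <- rep(c("CG", "CHG", "CHH"), times = 20)
  deltas <- c(CG = -0.5, CHG = 0.5, CHH = 0.5)[contexts]
  starts <- 15000L + (seq_len(60) - 1L) * 32000L
  planted <- data.frame(chrom = "Chr1", start = starts,
                        end = starts + 299L, context = contexts,
                        delta = unname(deltas), stringsAsFactors = FALSE)
  sim_config(seed = seed, n_chromosomes = 1L, chromosome_length = 2000000L,
             gene_count = 0L, te_count = 0L, coverage_mean = 30,
             planted_dmrs = if (null) NULL else planted)
}

# reciprocal-overlap matching of called regions against planted truth
match_dmrs <- function(calls, truth, min_reciprocal = 0.5) {
  matched_truth <- logical(nrow(truth))
  matched_call <- logical(nrow(calls))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      if (calls$chrom[j] != truth$chrom[i] ||
          calls$context[j] != truth$context[i]) next
      ov <- min(calls$end[j], truth$end[i]) -
        max(calls$start[j], truth$start[i]) + 1L
      if (ov <= 0) next
      len_c <- calls$end[j] - calls$start[j] + 1L
      len_t <- truth$end[i] - truth$start[i] + 1L
      if (ov >= min_reciprocal * len_c && ov >= min_reciprocal * len_t) {
        matched_truth[i] <- TRUE
        matched_call[j] <- TRUE
      }
    }
  }
  list(recall = mean(matched_truth),
       precision = if (nrow(calls)) mean(matched_call) else NA_real_,
       matched_truth = matched_truth, matched_call = matched_call)
}
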