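# Simulation configuration for the two-condition WGBS + RNA-seq design.

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-data generator into one validated
#' object. The defaults describe a small two-condition plant WGBS + RNA-seq
#' study: a CHH-dominant uniform-random genome, context-specific baseline
#' methylation (high CG, intermediate CHG, low CHH, as in plant genomes),
#' Poisson read coverage, a bisulfite conversion rate of 99.51%, and
#' triplicate expression libraries.
#'
#' @param seed Integer seed; every generator call is deterministic given the
#'   full configuration including this seed.
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param chromosome_length Length of each chromosome in bp. Must be at
#'   least 10 times the longest planted DMR.
#' @param gene_count,te_count Number of genes / transposable elements to
#'   place across the genome.
#' @param te_gene_overlap_fraction Fraction of TEs placed so that they
#'   overlap a gene (exercises the gene-overlap TE discard rule).
#' @param baseline_levels Named fractions in \[0, 1\]: the true methylation
#'   level of CG, CHG and CHH cytosines outside planted DMRs.
#' @param coverage_mean Mean of the Poisson read-coverage distribution.
#' @param coverage_floor Lower bound applied to drawn coverages (default 0,
#'   i.e. none).
#' @param conversion_rate Bisulfite conversion rate in (0.9, 1\]; its
#'   complement is the per-read false-methylation probability of an
#'   unmethylated molecule.
#' @param planted_dmrs `NULL` or a data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `context` (`CG`/`CHG`/`CHH`) and `delta`
#'   (condition B minus condition A true level, in \[-1, 1\]). Recoverable
#'   truth entries should satisfy `end - start + 1 >= 50` and
#'   `|delta| >= 0.1`.
#' @param planted_degs `NULL` or a data.frame with columns `gene_id` and
#'   `log2_effect` (expression shift of condition B).
#' @param planted_dets `NULL` or a data.frame with columns `te_id` and
#'   `log2_effect`.
#' @param replicates RNA-seq replicates per condition (genes; TE expression
#'   follows the single-library-per-condition WGBS design).
#' @param library_size Total mapped fragments per expression library, used
#'   to convert simulated counts to FPKM.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, chromosome_length = 50000, gene_count = 5)
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 1L,
                       chromosome_length = 200000L,
                       gene_count = 20L,
                       te_count = 10L,
                       te_gene_overlap_fraction = 0.2,
                       baseline_levels = c(CG = 0.6, CHG = 0.3, CHH = 0.08),
                       coverage_mean = 20,
                       coverage_floor = 0L,
                       conversion_rate = 0.9951,
                       planted_dmrs = NULL,
                       planted_degs = NULL,
                       planted_dets = NULL,
                       replicates = 3L,
                       library_size = 2e7) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_chromosomes >= 1L, chromosome_length > 0L,
    gene_count >= 0L, te_count >= 0L,
    te_gene_overlap_fraction >= 0, te_gene_overlap_fraction <= 1,
    coverage_mean > 0, coverage_floor >= 0L,
    replicates >= 1L, library_size > 0
  )
  if (!(conversion_rate > 0.9 && conversion_rate <= 1.0)) {
    stop("conversion_rate must lie in (0.9, 1]")
  }
  if (!all(c("CG", "CHG", "CHH") %in% names(baseline_levels))) {
    stop("baseline_levels must name CG, CHG and CHH")
  }
  if (any(baseline_levels < 0 | baseline_levels > 1)) {
    stop("baseline levels must lie in [0, 1]")
  }
  if (!is.null(planted_dmrs)) {
    need <- c("chrom", "start", "end", "context", "delta")
    if (!all(need %in% names(planted_dmrs))) {
      stop("planted_dmrs needs columns: ", paste(need, collapse = ", "))
    }
    stopifnot(all(planted_dmrs$start <= planted_dmrs$end),
              all(abs(planted_dmrs$delta) <= 1),
              all(planted_dmrs$context %in% c("CG", "CHG", "CHH")))
    if (chromosome_length < 10 * max(planted_dmrs$end - planted_dmrs$start + 1)) {
      stop("chromosome_length must be >= 10 x the longest planted DMR")
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    gene_count = as.integer(gene_count),
    te_count = as.integer(te_count),
    te_gene_overlap_fraction = te_gene_overlap_fraction,
    baseline_levels = baseline_levels[c("CG", "CHG", "CHH")],
    coverage_mean = coverage_mean,
    coverage_floor = as.integer(coverage_floor),
    conversion_rate = conversion_rate,
    planted_dmrs = planted_dmrs,
    planted_degs = planted_degs,
    planted_dets = planted_dets,
    replicates = as.integer(replicates),
    library_size = library_size
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x",
      x$chromosome_length, "bp;", x$gene_count, "genes,", x$te_count, "TEs\n")
  cat("  baselines CG/CHG/CHH:",
      paste(format(x$baseline_levels), collapse = "/"),
      " coverage ~Pois(", x$coverage_mean, ")",
      " conversion ", x$conversion_rate, "\n", sep = "")
  cat("  planted DMRs:", if (is.null(x$planted_dmrs)) 0 else nrow(x$planted_dmrs),
      " seed:", x$seed, "\n")
  invisible(x)
}
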