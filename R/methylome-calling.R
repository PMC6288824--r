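# Conversion-rate estimation and conversion-adjusted methylcytosine calling.

#' Estimate the bisulfite conversion rate from a spike-in control
#'
#' Pools all reads over the unmethylated control cytosines: the conversion
#' rate is one minus the fraction of reads that still report methylation,
#' i.e. `1 - sum(meth_reads) / sum(coverage)`.
#'
#' @param control Data.frame with `meth_reads` and `coverage` columns (e.g.
#'   from [generate_conversion_control()] or [read_cytosine_table()]).
#' @return List of class `conversion_estimate`: `rate`, `n_sites`,
#'   `total_reads`, `meth_reads`.
#' @examples
#' estimate_conversion_rate(data.frame(meth_reads = 49, coverage = 10000))
#' @export
estimate_conversion_rate <- function(control) {
  stopifnot(is.data.frame(control),
            all(c("meth_reads", "coverage") %in% names(control)))
  total <- sum(as.numeric(control$coverage))
  if (nrow(control) == 0L || total == 0) {
    stop("cannot estimate conversion rate: no covered control sites")
  }
  meth <- sum(as.numeric(control$meth_reads))
  structure(list(rate = 1 - meth / total,
                 n_sites = nrow(control),
                 total_reads = total,
                 meth_reads = meth),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf("conversion rate %.4f%% (%d sites, %g reads, %g unconverted)\n",
              100 * x$rate, x$n_sites, x$total_reads, x$meth_reads))
  invisible(x)
}

#' Call methylcytosines with a conversion-adjusted binomial test
#'
#' At each site the methylated-read count is compared with the count
#' expected from conversion failure alone: the one-sided binomial tail
#' `P(X >= meth_reads | n = coverage, p0 = 1 - rate)`. P-values are
#' adjusted by Benjamini-Hochberg over all tested sites and a site is
#' called methylated when its adjusted value falls below `alpha`.
#'
#' @param records Cytosine data.frame (chrom, pos, strand, context,
#'   meth_reads, coverage), already coverage-filtered upstream.
#' @param conversion A `conversion_estimate` (or a bare rate in \[0, 1\]).
#' @param alpha Significance level after adjustment (default 0.05).
#' @param adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`; `"none"` disables correction).
#' @return The input with columns `p_value`, `q_value`, `is_mc` appended.
#' @export
call_mc <- function(records, conversion, alpha = 0.05, adjust = "BH") {
  rate <- if (inherits(conversion, "conversion_estimate")) conversion$rate
          else conversion
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  p0 <- 1 - rate
  records$p_value <- binom_tail_p(records$meth_reads, records$coverage, p0)
  records$q_value <- stats::p.adjust(records$p_value, method = adjust)
  records$is_mc <- records$q_value < alpha & records$meth_reads > 0L
  records
}

#' Minimal significant methylated-read count per coverage
#'
#' The smallest methylated-read count whose one-sided binomial tail
#' probability (at false-methylation rate `1 - rate`) falls below `alpha`
#' -- the "anticipated number" a methylcytosine must reach at a given read
#' coverage. Reported per coverage for unadjusted p-values.
#'
#' @param coverage Integer vector of coverages.
#' @param rate Bisulfite conversion rate.
#' @param alpha Per-site significance level (default 0.05).
#' @return Integer vector: minimal count per coverage (`NA` when even full
#'   methylation is not significant).
#' @export
min_mc_reads <- function(coverage, rate, alpha = 0.05) {
  p0 <- 1 - rate
  vapply(coverage, function(n) {
    for (m in seq_len(n)) {
      if (binom_tail_p(m, n, p0) < alpha) return(m)
    }
    NA_integer_
  }, integer(1))
}
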