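# Exact and approximate small-sample tests used throughout the pipeline.
#
# The rank-sum and 2x2 Fisher routines are implemented here rather than
# called row-by-row from stats:: because the region scan evaluates them for
# hundreds of thousands of candidate windows; stats::wilcox.test and
# stats::fisher.test remain the reference implementations in the test suite.

.dmrlink_cache <- new.env(parent = emptyenv())

# all n1-subsets of 1..(n1+n2), as an n1 x choose(n1+n2, n1) index matrix
.rank_sum_splits <- function(n1, n2) {
  key <- paste0("splits_", n1, "_", n2)
  if (!is.null(.dmrlink_cache[[key]])) return(.dmrlink_cache[[key]])
  m <- utils::combn(n1 + n2, n1)
  .dmrlink_cache[[key]] <- m
  m
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Compares two small samples of methylation levels. For group sizes up to
#' `exact_limit` the p-value is computed by complete enumeration of all
#' `choose(n1 + n2, n1)` group assignments, conditioning on the observed
#' (mid-)ranks, so ties are handled exactly. Larger samples use the normal
#' approximation with tie correction and continuity correction, as
#' `stats::wilcox.test()` does.
#'
#' @param x,y Numeric vectors (the per-motif methylation levels of the two
#'   conditions within a candidate window).
#' @param exact_limit Largest group size for which the exact conditional
#'   enumeration is used (default 7, i.e. at most `choose(14, 7) = 3432`
#'   splits).
#' @return The two-sided p-value.
#' @examples
#' rank_sum_p(c(0.9, 0.85, 0.9, 0.95, 0.9), c(0.1, 0.15, 0.1, 0.05, 0.1))
#' @export
rank_sum_p <- function(x, y, exact_limit = 7L) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (max(n1, n2) <= exact_limit) {
    splits <- .rank_sum_splits(n1, n2)
    w_all <- .colSums(matrix(r[splits], nrow = n1), n1, ncol(splits))
    # two-sided: total probability of rank sums at least as extreme as w_obs
    # (distance from the conditional mean), uniform over all splits
    mu <- n1 * (n1 + n2 + 1) / 2
    d_obs <- abs(w_obs - mu)
    p <- sum(abs(w_all - mu) >= d_obs - 1e-9) / ncol(splits)
    return(min(1, p))
  }
  # normal approximation with tie correction + continuity correction
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Vectorized two-sided Fisher's exact test for 2x2 count tables
#'
#' One table per element: `[[m1, u1], [m2, u2]]` with `m` = methylated and
#' `u` = unmethylated read counts in the two conditions. The two-sided
#' p-value sums all hypergeometric outcomes whose probability does not
#' exceed that of the observed table (the same rule as
#' `stats::fisher.test()`).
#'
#' @param m1,u1,m2,u2 Integer vectors of equal length.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_test_2x2(10, 0, 0, 10)
#' @export
fisher_test_2x2 <- function(m1, u1, m2, u2) {
  n <- length(m1)
  stopifnot(length(u1) == n, length(m2) == n, length(u2) == n)
  if (n == 0L) return(numeric(0))
  if (any(c(m1, u1, m2, u2) < 0)) stop("counts must be non-negative")
  p <- numeric(n)
  for (i in seq_len(n)) {
    mm <- m1[i] + m2[i]          # total methylated (white balls)
    uu <- u1[i] + u2[i]          # total unmethylated (black balls)
    k <- m1[i] + u1[i]           # draws = condition-A reads
    if (mm == 0L || uu == 0L || k == 0L || m2[i] + u2[i] == 0L) {
      p[i] <- 1
      next
    }
    lo <- max(0L, k - uu)
    hi <- min(k, mm)
    d <- stats::dhyper(lo:hi, mm, uu, k)
    d_obs <- d[m1[i] - lo + 1L]
    p[i] <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }
  p
}

#' One-sided binomial tail probability P(X >= q)
#'
#' Upper-tail probability of observing at least `q` successes in `size`
#' trials at success probability `prob`; the elementary quantity behind the
#' conversion-adjusted methylcytosine call.
#'
#' @param q Observed count (vectorized).
#' @param size Number of trials (read coverage).
#' @param prob Per-trial success probability (the false-methylation rate).
#' @return `P(X >= q)` for a Binomial(size, prob) variable.
#' @export
binom_tail_p <- function(q, size, prob) {
  ifelse(q <= 0, 1, stats::pbinom(q - 1, size, prob, lower.tail = FALSE))
}

#' Hypergeometric enrichment tail probability
#'
#' Probability of drawing at least (`lower.tail = FALSE`) or at most
#' (`lower.tail = TRUE`) `q` feature members in `k` draws from a universe of
#' `m + n` sites of which `m` belong to the feature.
#'
#' @param q Observed feature members among the draws.
#' @param m Feature members in the universe.
#' @param n Non-members in the universe.
#' @param k Number of draws.
#' @param lower.tail If `FALSE` (default) return `P(X >= q)` (enrichment);
#'   otherwise `P(X <= q)` (depletion).
#' @return Tail probability.
#' @export
hyper_tail_p <- function(q, m, n, k, lower.tail = FALSE) {
  if (lower.tail) {
    stats::phyper(q, m, n, k, lower.tail = TRUE)
  } else {
    stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  }
}
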