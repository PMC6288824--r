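# Expression quantification and differential calls: FPKM, DEG criteria
# (divergence probability + fold change), and exact-rate-ratio DET calls
# with the gene-overlap discard rule.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / (length/1000 * totals/1e6)`.
#'
#' @param fragment_count Mapped fragments for the feature (vectorized).
#' @param feature_length_bp Feature length in bp.
#' @param total_mapped_fragments Library total.
#' @return FPKM values.
#' @examples
#' compute_fpkm(1000, 1000, 1e6)  # 1000
#' @export
compute_fpkm <- function(fragment_count, feature_length_bp,
                         total_mapped_fragments) {
  if (any(feature_length_bp <= 0)) stop("feature length must be positive")
  if (any(total_mapped_fragments <= 0)) stop("library total must be positive")
  fragment_count / (feature_length_bp / 1000 * total_mapped_fragments / 1e6)
}

#' Naive divergence probability from replicate concordance
#'
#' A documented stand-in for an externally computed divergence probability
#' (e.g. NOISeq's): the fraction of cross-condition replicate pairs whose
#' difference agrees in sign with the difference of condition means. It
#' ranges over \[0, 1\], approaches 1 for consistent strong changes and
#' about 0.5 for null genes; it is not a calibrated posterior probability
#' and exists so that the synthetic pipeline runs end to end.
#'
#' @param fpkm_a,fpkm_b Numeric matrices (features x replicates).
#' @return Numeric vector of concordance probabilities, `NA` for features
#'   with equal condition means.
#' @export
divergence_probability <- function(fpkm_a, fpkm_b) {
  fpkm_a <- as.matrix(fpkm_a); fpkm_b <- as.matrix(fpkm_b)
  stopifnot(nrow(fpkm_a) == nrow(fpkm_b))
  vapply(seq_len(nrow(fpkm_a)), function(i) {
    d_mean <- mean(fpkm_b[i, ]) - mean(fpkm_a[i, ])
    if (d_mean == 0) return(NA_real_)
    pairs <- outer(fpkm_b[i, ], fpkm_a[i, ], "-")
    mean(sign(pairs) == sign(d_mean))
  }, numeric(1))
}

#' Summarize a long expression table into per-feature records
#'
#' @param expr Long data.frame: feature_id, condition (`"A"`/`"B"`),
#'   replicate, fpkm.
#' @param pseudocount FPKM added when a condition mean is zero before
#'   forming the log2 fold change (default 0.01).
#' @return Data.frame: feature_id, mean_fpkm_a, mean_fpkm_b, log2fc (B over
#'   A), probability (replicate-concordance stand-in).
#' @export
summarize_expression <- function(expr, pseudocount = 0.01) {
  ids <- sort(unique(expr$feature_id))
  wide <- function(cond) {
    e <- expr[expr$condition == cond, ]
    reps <- sort(unique(e$replicate))
    m <- matrix(NA_real_, length(ids), length(reps),
                dimnames = list(ids, reps))
    m[cbind(match(e$feature_id, ids), match(e$replicate, reps))] <- e$fpkm
    m
  }
  ma <- wide("A"); mb <- wide("B")
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  la <- ifelse(mean_a > 0, mean_a, pseudocount)
  lb <- ifelse(mean_b > 0, mean_b, pseudocount)
  data.frame(feature_id = ids,
             mean_fpkm_a = unname(mean_a), mean_fpkm_b = unname(mean_b),
             log2fc = unname(log2(lb / la)),
             probability = divergence_probability(ma, mb),
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its divergence probability reaches `prob_threshold`
#' (default 0.8) and its fold change (larger condition mean over smaller,
#' with pseudocount) reaches `fold_threshold` (default 2). Direction follows
#' the sign of the log2 fold change (B over A).
#'
#' @param records Data.frame from [summarize_expression()] (or with columns
#'   feature_id, mean_fpkm_a, mean_fpkm_b, log2fc, probability).
#' @param prob_threshold,fold_threshold DEG criteria.
#' @param pseudocount FPKM substituted for zero condition means.
#' @return The input with fold_change, is_deg and direction appended;
#'   records with missing probability are flagged not-DEG and counted in
#'   `attr(, "skipped")`.
#' @export
call_degs <- function(records, prob_threshold = 0.8, fold_threshold = 2,
                      pseudocount = 0.01) {
  la <- ifelse(records$mean_fpkm_a > 0, records$mean_fpkm_a, pseudocount)
  lb <- ifelse(records$mean_fpkm_b > 0, records$mean_fpkm_b, pseudocount)
  fc <- pmax(la / lb, lb / la)
  skipped <- sum(is.na(records$probability))
  if (skipped) {
    warning(skipped, " record(s) without divergence probability skipped")
  }
  records$fold_change <- fc
  records$is_deg <- !is.na(records$probability) &
    records$probability >= prob_threshold & fc >= fold_threshold
  records$direction <- ifelse(records$log2fc > 0, "up",
                              ifelse(records$log2fc < 0, "down",
                                     NA_character_))
  attr(records, "skipped") <- skipped
  records
}

#' Call differentially expressed TEs
#'
#' TEs overlapping a protein-coding gene are discarded before testing. Each
#' remaining TE is tested with an exact conditional binomial rate-ratio
#' test: given the two libraries' totals, the condition-A count among the
#' pooled `count_a + count_b` fragments is Binomial with success probability
#' `total_a / (total_a + total_b)` under the null of equal expression
#' rates. P-values (two-sided, minimum-likelihood rule as in
#' `stats::binom.test()`) are Benjamini-Hochberg adjusted across TEs;
#' significance requires an adjusted value below `alpha`.
#'
#' @param te_records Data.frame: te_id, count_a, count_b, length (bp), and
#'   optionally fpkm_a/fpkm_b.
#' @param annotation A `dmrlink_annotation` providing TE intervals and gene
#'   spans for the overlap discard.
#' @param total_a,total_b Library totals (mapped fragments).
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Data.frame of tested TEs with p_value, adjusted_p, is_det,
#'   direction; discarded TEs are absent (count in `attr(, "discarded")`).
#' @export
call_dets <- function(te_records, annotation, total_a, total_b,
                      alpha = 0.05) {
  tes <- annotation$tes
  genes <- annotation$genes
  drop_ids <- character(0)
  if (nrow(tes) && nrow(genes)) {
    ov <- GenomicRanges::findOverlaps(
      .as_gr(tes$chrom, tes$start, tes$end),
      .as_gr(genes$chrom, genes$start, genes$end))
    drop_ids <- tes$te_id[unique(S4Vectors::queryHits(ov))]
  }
  discarded <- sum(te_records$te_id %in% drop_ids)
  rec <- te_records[!te_records$te_id %in% drop_ids, , drop = FALSE]
  p0 <- total_a / (total_a + total_b)
  rec$p_value <- vapply(seq_len(nrow(rec)), function(i) {
    tot <- rec$count_a[i] + rec$count_b[i]
    if (tot == 0L) return(1)
    stats::binom.test(rec$count_a[i], tot, p = p0)$p.value
  }, numeric(1))
  rec$adjusted_p <- stats::p.adjust(rec$p_value, method = "BH")
  # direction of condition B relative to A on the rate scale
  rate_a <- rec$count_a / total_a
  rate_b <- rec$count_b / total_b
  rec$is_det <- rec$adjusted_p < alpha
  rec$direction <- ifelse(rate_b > rate_a, "up",
                          ifelse(rate_b < rate_a, "down", NA_character_))
  attr(rec, "discarded") <- discarded
  rec
}
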