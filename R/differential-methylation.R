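# Differential methylation: per-cytosine Fisher tests (DmCs) and the
# seed-and-extend windowed rank-sum scan for differentially methylated
# regions (DMRs).

#' Test one cytosine for differential methylation
#'
#' Two-sided Fisher's exact test on the 2x2 table of methylated and
#' unmethylated read counts in the two conditions. A site is a DmC when the
#' p-value is below `p_threshold` and the absolute methylation-level change
#' reaches `delta_threshold` (defaults: 0.05 and 0.20).
#'
#' @param site_a,site_b One-row cytosine data.frames for the same
#'   chrom/pos/strand/context in conditions A and B.
#' @param p_threshold,delta_threshold DmC thresholds.
#' @return One-row data.frame: chrom, pos, strand, context, level_a,
#'   level_b, delta (B - A), p_value, is_dmc, direction (hyper/hypo).
#' @export
test_dmc <- function(site_a, site_b, p_threshold = 0.05,
                     delta_threshold = 0.20) {
  stopifnot(site_a$chrom == site_b$chrom, site_a$pos == site_b$pos,
            site_a$strand == site_b$strand,
            site_a$context == site_b$context)
  call_dmcs(site_a, site_b, p_threshold, delta_threshold,
            min_coverage = 0L)
}

#' Call differentially methylated cytosines
#'
#' Joins two per-cytosine count tables on (chrom, pos, strand, context),
#' keeps sites covered by at least `min_coverage` reads in both conditions,
#' and applies Fisher's exact test with the p-value and level-change rule.
#'
#' @param a,b Cytosine data.frames for conditions A and B.
#' @param p_threshold,delta_threshold DmC thresholds (defaults 0.05, 0.20).
#' @param min_coverage Per-condition coverage filter (default 4).
#' @return Data.frame with one row per jointly covered site: chrom, pos,
#'   strand, context, level_a, level_b, delta, p_value, is_dmc, direction.
#' @export
call_dmcs <- function(a, b, p_threshold = 0.05, delta_threshold = 0.20,
                      min_coverage = 4L) {
  a <- a[a$coverage >= min_coverage, , drop = FALSE]
  b <- b[b$coverage >= min_coverage, , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand, sep = "\r")
  key_b <- paste(b$chrom, b$pos, b$strand, sep = "\r")
  idx <- match(key_a, key_b)
  keep <- !is.na(idx)
  a <- a[keep, , drop = FALSE]
  b <- b[idx[keep], , drop = FALSE]
  if (nrow(a) && !all(a$context == b$context)) {
    stop("context mismatch between conditions at matched positions")
  }
  level_a <- ifelse(a$coverage > 0, a$meth_reads / a$coverage, NA_real_)
  level_b <- ifelse(b$coverage > 0, b$meth_reads / b$coverage, NA_real_)
  p <- fisher_test_2x2(a$meth_reads, a$coverage - a$meth_reads,
                       b$meth_reads, b$coverage - b$meth_reads)
  delta <- level_b - level_a
  out <- data.frame(
    chrom = a$chrom, pos = a$pos, strand = a$strand, context = a$context,
    level_a = level_a, level_b = level_b, delta = delta, p_value = p,
    stringsAsFactors = FALSE)
  out$is_dmc <- out$p_value < p_threshold & abs(out$delta) >= delta_threshold
  out$direction <- ifelse(out$delta > 0, "hyper",
                          ifelse(out$delta < 0, "hypo", NA_character_))
  out
}

#' DMR-calling parameters
#'
#' All thresholds of the region scan, defaulting to the published rule set:
#' windows of 5 motifs, at least 4 sharing the response direction, rank-sum
#' p below 0.05, inter-motif gaps below 200 bp, minimum region length 50 bp
#' and minimum absolute region-level difference 0.1.
#'
#' @param window Seed window size in motifs.
#' @param min_same Minimum motifs in the window sharing the majority
#'   direction.
#' @param wilcoxon_p Significance threshold for the rank-sum test.
#' @param max_gap Maximum distance (bp, exclusive) between adjacent member
#'   motifs.
#' @param min_len Minimum region length in bp (inclusive ends).
#' @param min_region_delta Minimum absolute mean level difference.
#' @param min_coverage Per-condition coverage for a position to count as a
#'   motif.
#' @param response How a motif's response direction is classified.
#'   `"dmc"` (default): a motif responds only when it is itself a DmC
#'   (Fisher p below `dmc_p` and absolute level change at least
#'   `dmc_delta`), in the direction of its level change; non-DmC motifs
#'   count as neither direction. `"sign"`: the raw sign of the level
#'   difference (zero counts as neither direction). The `"sign"` reading
#'   admits a per-window false-positive rate near the rank-sum alpha, which
#'   floods a genome-scale null with spurious regions; the `"dmc"` reading
#'   keeps the windowed rank-sum test as the region-level decision while
#'   requiring per-site evidence, and is the default for that reason.
#' @param dmc_p,dmc_delta Per-site DmC thresholds used when
#'   `response = "dmc"` (defaults 0.05 and 0.20).
#' @param exact_limit Passed to [rank_sum_p()].
#' @return Named list of parameters.
#' @export
dmr_params <- function(window = 5L, min_same = 4L, wilcoxon_p = 0.05,
                       max_gap = 200L, min_len = 50L,
                       min_region_delta = 0.1, min_coverage = 4L,
                       response = c("dmc", "sign"), dmc_p = 0.05,
                       dmc_delta = 0.20, exact_limit = 7L) {
  response <- match.arg(response)
  stopifnot(window >= 2L, min_same >= 1L, min_same <= window,
            wilcoxon_p > 0, wilcoxon_p <= 1, max_gap >= 1L, min_len >= 1L,
            min_region_delta >= 0, min_coverage >= 0L,
            dmc_p > 0, dmc_p <= 1, dmc_delta >= 0, dmc_delta <= 1)
  list(window = as.integer(window), min_same = as.integer(min_same),
       wilcoxon_p = wilcoxon_p, max_gap = as.integer(max_gap),
       min_len = as.integer(min_len), min_region_delta = min_region_delta,
       min_coverage = as.integer(min_coverage), response = response,
       dmc_p = dmc_p, dmc_delta = dmc_delta,
       exact_limit = as.integer(exact_limit))
}

#' Call differentially methylated regions
#'
#' Seed-and-extend scan per context. CG and CHG (strand-symmetric) are
#' screened on the Watson strand only; CHH is screened separately on each
#' strand. A motif is a position covered by at least `min_coverage` reads in
#' both conditions. A sliding window of `window` motifs seeds a candidate
#' when at least `min_same` motifs share the same response direction (by
#' default same-direction DmC status; see `response` in [dmr_params()]),
#' all adjacent gaps are below `max_gap`, and the two-sided Wilcoxon
#' rank-sum test of the window's condition-A versus condition-B levels is
#' significant. The candidate is
#' extended motif by motif downstream while the next motif matches the
#' window's majority direction, stays within the gap limit, and the test
#' recomputed over the grown region remains significant; the first violation
#' closes the region at the last conforming motif. Overlapping
#' same-direction candidates are merged; regions shorter than `min_len` or
#' with mean level difference below `min_region_delta` are discarded.
#'
#' @param a,b Cytosine data.frames for conditions A and B.
#' @param contexts Contexts to scan (default all three).
#' @param params A [dmr_params()] list.
#' @return Data.frame of regions: chrom, start, end, context, strand_scope,
#'   n_motifs, mean_level_a, mean_level_b, delta, p_value, direction.
#' @export
call_dmrs <- function(a, b, contexts = c("CG", "CHG", "CHH"),
                      params = dmr_params()) {
  contexts <- match.arg(contexts, c("CG", "CHG", "CHH"), several.ok = TRUE)
  key_a <- paste(a$chrom, a$pos, a$strand, sep = "\r")
  key_b <- paste(b$chrom, b$pos, b$strand, sep = "\r")
  idx <- match(key_a, key_b)
  keep <- !is.na(idx) & a$coverage >= params$min_coverage &
    b$coverage[idx] >= params$min_coverage
  a2 <- a[keep, , drop = FALSE]
  b2 <- b[idx[keep], , drop = FALSE]
  la <- a2$meth_reads / a2$coverage
  lb <- b2$meth_reads / b2$coverage

  out <- list()
  for (ctx in contexts) {
    scopes <- if (ctx == "CHH") c(watson = "+", crick = "-") else c(watson = "+")
    for (sc in names(scopes)) {
      sel <- a2$context == ctx & a2$strand == scopes[[sc]]
      for (ch in unique(a2$chrom[sel])) {
        s <- which(sel & a2$chrom == ch)
        s <- s[order(a2$pos[s])]
        resp <- .motif_response(a2[s, , drop = FALSE], b2[s, , drop = FALSE],
                                la[s], lb[s], params)
        regions <- .dmr_scan(a2$pos[s], la[s], lb[s], resp, params)
        if (nrow(regions) == 0L) next
        regions$chrom <- ch
        regions$context <- ctx
        regions$strand_scope <- sc
        out[[length(out) + 1L]] <- regions
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      strand_scope = character(0), n_motifs = integer(0),
                      mean_level_a = numeric(0), mean_level_b = numeric(0),
                      delta = numeric(0), p_value = numeric(0),
                      direction = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[, c("chrom", "start", "end", "context", "strand_scope",
                 "n_motifs", "mean_level_a", "mean_level_b", "delta",
                 "p_value", "direction")]
  res <- res[order(res$chrom, res$start, res$context, res$strand_scope), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-motif response direction in {-1, 0, +1}. "sign": raw sign of the
# level difference. "dmc": direction only for motifs that are DmCs (Fisher
# p < dmc_p and |delta| >= dmc_delta); the Fisher test is evaluated only
# where the delta filter can pass.
.motif_response <- function(ra, rb, la, lb, params) {
  d <- lb - la
  if (params$response == "sign") return(sign(d))
  resp <- integer(length(d))
  cand <- which(abs(d) >= params$dmc_delta)
  if (length(cand)) {
    p <- fisher_test_2x2(ra$meth_reads[cand],
                         ra$coverage[cand] - ra$meth_reads[cand],
                         rb$meth_reads[cand],
                         rb$coverage[cand] - rb$meth_reads[cand])
    ok <- p < params$dmc_p
    resp[cand[ok]] <- sign(d[cand[ok]])
  }
  resp
}

# Core scan over one (chromosome, context, strand) motif track.
# pos must be sorted ascending; la/lb are the per-motif levels; resp is the
# per-motif response direction.
.dmr_scan <- function(pos, la, lb, resp, params) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_motifs = integer(0), mean_level_a = numeric(0),
                      mean_level_b = numeric(0), delta = numeric(0),
                      p_value = numeric(0), direction = character(0))
  n <- length(pos)
  w <- params$window
  if (n < w) return(empty)
  if (is.unsorted(pos)) stop("motif positions must be sorted")

  sgn <- as.integer(resp)
  gaps <- diff(pos)
  n_win <- n - w + 1L

  # vectorized seed pre-screen: sign counts and max gap per window
  # (embed() row i spans indices i..i+w-1, elements reversed within the row,
  # which is irrelevant for counts and maxima)
  emb_sgn <- stats::embed(sgn, w)
  pos_cnt <- rowSums(emb_sgn == 1)
  neg_cnt <- rowSums(emb_sgn == -1)
  if (w >= 2L) {
    emb_gap <- stats::embed(gaps, w - 1L)
    gap_max <- emb_gap[, 1L]
    for (cc in seq_len(ncol(emb_gap))[-1L]) {
      gap_max <- pmax(gap_max, emb_gap[, cc])
    }
  } else {
    gap_max <- rep(0L, n_win)
  }
  starts_ok <- gap_max < params$max_gap &
    (pos_cnt >= params$min_same | neg_cnt >= params$min_same)
  dirs <- ifelse(pos_cnt >= neg_cnt, 1L, -1L)

  cand <- which(starts_ok)
  regions <- list()
  for (i in cand) {
    jw <- i + w - 1L
    p_seed <- rank_sum_p(la[i:jw], lb[i:jw], params$exact_limit)
    if (p_seed >= params$wilcoxon_p) next
    dir <- dirs[i]
    j <- jw
    p_cur <- p_seed
    while (j < n) {
      nxt <- j + 1L
      if (sgn[nxt] != dir) break
      if (pos[nxt] - pos[j] >= params$max_gap) break
      p_try <- rank_sum_p(la[i:nxt], lb[i:nxt], params$exact_limit)
      if (p_try >= params$wilcoxon_p) break
      j <- nxt
      p_cur <- p_try
    }
    regions[[length(regions) + 1L]] <- c(i, j, dir)
  }
  if (!length(regions)) return(empty)
  reg <- do.call(rbind, regions)

  # merge overlapping (or touching) same-direction candidate index ranges
  merged <- list()
  for (d in c(1L, -1L)) {
    rd <- reg[reg[, 3L] == d, , drop = FALSE]
    if (!nrow(rd)) next
    rd <- rd[order(rd[, 1L]), , drop = FALSE]
    cur <- rd[1L, ]
    for (r in seq_len(nrow(rd))[-1L]) {
      if (rd[r, 1L] <= cur[2L]) {
        cur[2L] <- max(cur[2L], rd[r, 2L])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- rd[r, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }

  rows <- lapply(merged, function(m) {
    i <- m[1L]; j <- m[2L]
    ma <- mean(la[i:j]); mb <- mean(lb[i:j])
    data.frame(start = pos[i], end = pos[j], n_motifs = j - i + 1L,
               mean_level_a = ma, mean_level_b = mb, delta = mb - ma,
               p_value = rank_sum_p(la[i:j], lb[i:j], params$exact_limit),
               direction = if (m[3L] > 0L) "up" else "down",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$end - res$start + 1L >= params$min_len &
               abs(res$delta) >= params$min_region_delta, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}
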