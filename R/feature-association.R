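# Association of cytosines and DMRs with genomic features: multi-label
# classification, DMR-to-gene assignment, hypergeometric enrichment,
# metagene bin profiles and TSS/TES distance profiles.

.as_gr <- function(chrom, start, end = start) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# logical matrix (positions x labels) of genomic-feature membership;
# multi-membership is intentional.
.feature_labels <- function(chrom, pos, annotation, genic_flank = 2000L,
                            intergenic_dist = 5000L) {
  genes <- annotation$genes
  parts <- annotation$parts
  tes <- annotation$tes
  n <- length(pos)
  labels <- c("TE", "gene_body", "CDS", "intron", "UTR",
              "up2kb", "down2kb", "up5kb", "down5kb", "intergenic")
  m <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  if (n == 0L) return(m)
  pgr <- .as_gr(chrom, pos)
  hit <- function(fchrom, fstart, fend) {
    if (length(fstart) == 0L) return(logical(n))
    ov <- GenomicRanges::findOverlaps(pgr, .as_gr(fchrom, pmax(1L, fstart), fend))
    out <- logical(n)
    out[S4Vectors::queryHits(ov)] <- TRUE
    out
  }
  m[, "TE"] <- hit(tes$chrom, tes$start, tes$end)
  m[, "gene_body"] <- hit(genes$chrom, genes$start, genes$end)
  if (nrow(parts)) {
    pchrom <- genes$chrom[match(parts$gene_id, genes$gene_id)]
    for (ty in c("CDS", "intron", "UTR")) {
      sel <- parts$type == ty
      m[, ty] <- hit(pchrom[sel], parts$start[sel], parts$end[sel])
    }
  }
  if (nrow(genes)) {
    plus <- genes$strand == "+"
    up_start <- ifelse(plus, genes$tss - genic_flank, genes$tss + 1L)
    up_end <- ifelse(plus, genes$tss - 1L, genes$tss + genic_flank)
    dn_start <- ifelse(plus, genes$tes + 1L, genes$tes - genic_flank)
    dn_end <- ifelse(plus, genes$tes + genic_flank, genes$tes - 1L)
    m[, "up2kb"] <- hit(genes$chrom, up_start, up_end)
    m[, "down2kb"] <- hit(genes$chrom, dn_start, dn_end)
    up5_start <- ifelse(plus, genes$tss - intergenic_dist, genes$tss + 1L)
    up5_end <- ifelse(plus, genes$tss - 1L, genes$tss + intergenic_dist)
    dn5_start <- ifelse(plus, genes$tes + 1L, genes$tes - intergenic_dist)
    dn5_end <- ifelse(plus, genes$tes + intergenic_dist, genes$tes - 1L)
    m[, "up5kb"] <- hit(genes$chrom, up5_start, up5_end)
    m[, "down5kb"] <- hit(genes$chrom, dn5_start, dn5_end)
    # intergenic: > intergenic_dist from every TSS and TES
    anchors <- c(genes$tss, genes$tes)
    achrom <- c(genes$chrom, genes$chrom)
    near <- hit(achrom, anchors - intergenic_dist, anchors + intergenic_dist)
    m[, "intergenic"] <- !near
  } else {
    m[, "intergenic"] <- TRUE
  }
  m
}

#' Classify a genomic position against all feature categories
#'
#' Returns every applicable label: a position may belong to several features
#' at once (e.g. a CDS covered by a TE). A genic region is the gene body
#' plus the surrounding 2-kb flanks; positions more than `intergenic_dist`
#' (default 5 kb) from every TSS and TES are intergenic. Upstream/downstream
#' orientation respects gene strand.
#'
#' @param chrom,pos Position (scalars).
#' @param annotation A `dmrlink_annotation` (genes, parts, tes).
#' @param genic_flank Width of the up/down flank labels `up2kb`/`down2kb`.
#' @param intergenic_dist Distance beyond which a position is intergenic;
#'   also the width of the `up5kb`/`down5kb` labels.
#' @return Character vector of labels, subset of TE, gene_body, CDS, intron,
#'   UTR, up2kb, down2kb, up5kb, down5kb, intergenic.
#' @export
classify_position <- function(chrom, pos, annotation, genic_flank = 2000L,
                              intergenic_dist = 5000L) {
  stopifnot(length(chrom) == 1L, length(pos) == 1L, pos >= 1L)
  if (!is.null(annotation$sequences) &&
      chrom %in% names(annotation$sequences) &&
      pos > nchar(annotation$sequences[[chrom]])) {
    stop("position ", pos, " beyond end of ", chrom)
  }
  m <- .feature_labels(chrom, pos, annotation, genic_flank, intergenic_dist)
  colnames(m)[m[1L, ]]
}

#' Assign a DMR to its zone, nearest gene and placement
#'
#' Position is judged at the region midpoint, `floor((start + end) / 2)`.
#' Zone is `genic` when the midpoint lies in a gene body or its 2-kb flank,
#' `proximal_2to5kb` when within 5 kb of a TSS/TES but outside the genic
#' region, else `intergenic`. Genic and proximal DMRs are assigned to the
#' single nearest gene (minimal midpoint distance to the nearer of TSS/TES,
#' zero inside the body; ties broken by lower gene id). Placement within a
#' gene follows the part at the midpoint (CDS/intron/UTR, else `body`);
#' outside it is `UP` (5' of the TSS, distance midpoint to TSS) or `DOWN`
#' (3' of the TES, distance midpoint to TES). TE overlap is interval
#' intersection of the full DMR with any TE body.
#'
#' @param dmrs Data.frame of regions (chrom, start, end, plus any columns
#'   from [call_dmrs()]).
#' @param annotation A `dmrlink_annotation`.
#' @param genic_flank,intergenic_dist Zone parameters (defaults 2000, 5000).
#' @return The input with midpoint, zone, gene_id, placement, distance and
#'   te_overlap columns appended.
#' @export
assign_dmr <- function(dmrs, annotation, genic_flank = 2000L,
                       intergenic_dist = 5000L) {
  n <- nrow(dmrs)
  genes <- annotation$genes
  parts <- annotation$parts
  mid <- as.integer(floor((dmrs$start + dmrs$end) / 2))
  zone <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  placement <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    inside <- mid[i] >= g$start & mid[i] <= g$end
    d <- ifelse(inside, 0L,
                pmin(abs(mid[i] - g$tss), abs(mid[i] - g$tes)))
    zone[i] <- if (any(mid[i] >= g$start - genic_flank &
                       mid[i] <= g$end + genic_flank)) "genic"
               else if (min(d) <= intergenic_dist) "proximal_2to5kb"
               else "intergenic"
    if (zone[i] == "intergenic") next
    ord <- order(d, g$gene_id)
    gi <- ord[1L]
    gene_id[i] <- g$gene_id[gi]
    if (inside[gi]) {
      pr <- parts[parts$gene_id == g$gene_id[gi] &
                    parts$start <= mid[i] & parts$end >= mid[i], , drop = FALSE]
      placement[i] <- if (nrow(pr)) pr$type[1L] else "body"
      if (placement[i] == "UTR") placement[i] <- "UTR"
      distance[i] <- 0L
    } else {
      # strand-oriented: 5' of the TSS is UP, 3' of the TES is DOWN
      before_tss <- if (g$strand[gi] == "+") mid[i] < g$tss[gi]
                    else mid[i] > g$tss[gi]
      if (before_tss) {
        placement[i] <- "UP"
        distance[i] <- abs(mid[i] - g$tss[gi])
      } else {
        placement[i] <- "DOWN"
        distance[i] <- abs(mid[i] - g$tes[gi])
      }
    }
  }

  te_overlap <- logical(n)
  if (nrow(annotation$tes) && n > 0L) {
    ov <- GenomicRanges::findOverlaps(
      .as_gr(dmrs$chrom, dmrs$start, dmrs$end),
      .as_gr(annotation$tes$chrom, annotation$tes$start, annotation$tes$end))
    te_overlap[S4Vectors::queryHits(ov)] <- TRUE
  }
  out <- dmrs
  out$midpoint <- mid
  out$zone <- zone
  out$gene_id <- gene_id
  out$placement <- placement
  out$distance <- distance
  out$te_overlap <- te_overlap
  out
}

#' Fold enrichment with hypergeometric significance
#'
#' For each feature, fold = `(dmc_feature / dmc_total) / (mc_feature /
#' mc_total)`; the p-value is the hypergeometric tail probability of
#' drawing at least `dmc_feature` feature members in `dmc_total` draws from
#' a universe of `mc_total` sites containing `mc_feature` members (upper
#' tail when fold >= 1, lower tail otherwise; `two_sided = TRUE` doubles
#' the smaller tail, capped at 1).
#'
#' @param dmc_feature,mc_feature Per-feature DmC and mC counts (vectors).
#' @param dmc_total,mc_total Universe sizes (scalars or vectors).
#' @param feature Optional feature/bin identifiers.
#' @param two_sided Report a two-sided p-value (default `FALSE`).
#' @return Data.frame: feature, dmc_feature, dmc_total, mc_feature,
#'   mc_total, fold, p_value. Features with `mc_feature = 0` have `NA` fold
#'   and p-value (undefined denominator).
#' @export
enrichment <- function(dmc_feature, dmc_total, mc_feature, mc_total,
                       feature = NULL, two_sided = FALSE) {
  k <- length(dmc_feature)
  stopifnot(length(mc_feature) == k, all(dmc_total > 0), all(mc_total > 0),
            all(dmc_feature <= dmc_total), all(mc_feature <= mc_total))
  if (is.null(feature)) feature <- as.character(seq_len(k))
  fold <- (dmc_feature / dmc_total) / (mc_feature / mc_total)
  fold[mc_feature == 0] <- NA_real_
  upper <- hyper_tail_p(dmc_feature, mc_feature, mc_total - mc_feature,
                        dmc_total, lower.tail = FALSE)
  lower <- hyper_tail_p(dmc_feature, mc_feature, mc_total - mc_feature,
                        dmc_total, lower.tail = TRUE)
  p <- if (two_sided) pmin(1, 2 * pmin(upper, lower)) else
    ifelse(!is.na(fold) & fold >= 1, upper, lower)
  p[mc_feature == 0] <- NA_real_
  data.frame(feature = feature,
             dmc_feature = dmc_feature,
             dmc_total = rep_len(dmc_total, k),
             mc_feature = mc_feature,
             mc_total = rep_len(mc_total, k),
             fold = fold, p_value = p, stringsAsFactors = FALSE)
}

#' Feature enrichment of DmCs against the mC universe
#'
#' Classifies both site sets against the annotation and runs [enrichment()]
#' per feature label.
#'
#' @param dmc Data.frame of DmC positions (chrom, pos).
#' @param mc Data.frame of the mC universe (chrom, pos); the DmCs must be a
#'   subset of it.
#' @param annotation A `dmrlink_annotation`.
#' @param genic_flank,intergenic_dist See [classify_position()].
#' @param two_sided See [enrichment()].
#' @return [enrichment()] table, one row per feature label.
#' @export
feature_enrichment <- function(dmc, mc, annotation, genic_flank = 2000L,
                               intergenic_dist = 5000L, two_sided = FALSE) {
  md <- .feature_labels(dmc$chrom, dmc$pos, annotation, genic_flank,
                        intergenic_dist)
  mm <- .feature_labels(mc$chrom, mc$pos, annotation, genic_flank,
                        intergenic_dist)
  enrichment(colSums(md), nrow(dmc), colSums(mm), nrow(mc),
             feature = colnames(md), two_sided = two_sided)
}

# ordered bin labels of the metagene scheme
.metagene_labels <- function(body_bins, flank_bins) {
  c(paste0("up", flank_bins:1), paste0("body", seq_len(body_bins)),
    paste0("down", seq_len(flank_bins)))
}

#' Metagene bin counts
#'
#' Counts items (site or midpoint positions) in 5 equally sized gene-body
#' bins plus 10 fixed-width (300 bp) bins upstream of the TSS and
#' downstream of the TES, strand-oriented; upstream/downstream bin 1 is the
#' bin nearest the gene. An item is counted in every gene window it falls
#' in.
#'
#' @param items Data.frame with chrom and pos columns.
#' @param annotation A `dmrlink_annotation`.
#' @param body_bins Number of gene-body bins (default 5).
#' @param flank_bins Number of flank bins per side (default 10).
#' @param flank_bin_size Flank bin width in bp (default 300).
#' @return Data.frame: bin (ordered factor, upstream -> body -> downstream),
#'   count.
#' @export
metagene_bins <- function(items, annotation, body_bins = 5L,
                          flank_bins = 10L, flank_bin_size = 300L) {
  genes <- annotation$genes
  labels <- .metagene_labels(body_bins, flank_bins)
  counts <- stats::setNames(integer(length(labels)), labels)
  if (nrow(genes) && nrow(items)) {
    win <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      len <- g$end - g$start + 1L
      if (len < body_bins) next
      plus <- g$strand == "+"
      # body bins: equal fifths of the strand-oriented body
      bnd <- floor(len * (0:body_bins) / body_bins)   # offsets from TSS
      for (b in seq_len(body_bins)) {
        off0 <- bnd[b]; off1 <- bnd[b + 1L] - 1L
        s <- if (plus) g$tss + off0 else g$tss - off1
        e <- if (plus) g$tss + off1 else g$tss - off0
        win[[length(win) + 1L]] <- data.frame(
          chrom = g$chrom, start = s, end = e, bin = paste0("body", b))
      }
      for (b in seq_len(flank_bins)) {
        # upstream bin b: (b-1)*w+1 .. b*w bp 5' of the TSS
        s <- if (plus) g$tss - b * flank_bin_size else
          g$tss + (b - 1L) * flank_bin_size + 1L
        e <- if (plus) g$tss - (b - 1L) * flank_bin_size - 1L else
          g$tss + b * flank_bin_size
        win[[length(win) + 1L]] <- data.frame(
          chrom = g$chrom, start = s, end = e, bin = paste0("up", b))
        s <- if (plus) g$tes + (b - 1L) * flank_bin_size + 1L else
          g$tes - b * flank_bin_size
        e <- if (plus) g$tes + b * flank_bin_size else
          g$tes - (b - 1L) * flank_bin_size - 1L
        win[[length(win) + 1L]] <- data.frame(
          chrom = g$chrom, start = s, end = e, bin = paste0("down", b))
      }
    }
    win <- do.call(rbind, win)
    win <- win[win$end >= 1L, , drop = FALSE]
    win$start <- pmax(1L, win$start)
    ov <- GenomicRanges::findOverlaps(
      .as_gr(items$chrom, items$pos),
      .as_gr(win$chrom, win$start, win$end))
    tab <- table(win$bin[S4Vectors::subjectHits(ov)])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  data.frame(bin = factor(labels, levels = labels, ordered = TRUE),
             count = unname(counts))
}

#' Histogram of DMR midpoint distances to the nearest TSS/TES
#'
#' Distance is zero for midpoints inside a gene body, otherwise the minimum
#' over genes of the distance to the nearer of TSS and TES. Counts are
#' binned at `bin_size` bp up to `max_dist`, separately per context.
#'
#' @param dmrs Data.frame of regions (chrom, start, end, context).
#' @param annotation A `dmrlink_annotation`.
#' @param bin_size Bin width in bp (default 100).
#' @param max_dist Largest distance kept (default 2000).
#' @return Data.frame: context, bin (1-based; bin 1 = \[0, bin_size)),
#'   dist_lo, dist_hi, count.
#' @export
dmr_distance_profile <- function(dmrs, annotation, bin_size = 100L,
                                 max_dist = 2000L) {
  genes <- annotation$genes
  n_bins <- as.integer(ceiling(max_dist / bin_size))
  grid <- expand.grid(context = unique(dmrs$context),
                      bin = seq_len(n_bins), stringsAsFactors = FALSE)
  grid$dist_lo <- (grid$bin - 1L) * bin_size
  grid$dist_hi <- grid$bin * bin_size
  grid$count <- 0L
  if (nrow(dmrs) == 0L) return(grid)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  d <- vapply(seq_len(nrow(dmrs)), function(i) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_real_)
    if (any(mid[i] >= g$start & mid[i] <= g$end)) return(0)
    min(pmin(abs(mid[i] - g$tss), abs(mid[i] - g$tes)))
  }, numeric(1))
  keep <- !is.na(d) & d < max_dist
  if (any(keep)) {
    bin <- pmin(floor(d[keep] / bin_size) + 1L, n_bins)
    tab <- table(dmrs$context[keep], bin)
    for (ctx in rownames(tab)) {
      for (b in colnames(tab)) {
        sel <- grid$context == ctx & grid$bin == as.integer(b)
        grid$count[sel] <- grid$count[sel] + tab[ctx, b]
      }
    }
  }
  grid
}
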