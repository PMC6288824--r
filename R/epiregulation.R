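# Linking differential methylation to differential expression: DMR-DEG
# interaction sites with association sign, and DMR-DET overlap tables.

#' Format a DMR descriptor
#'
#' Text form `placement,context(distance;delta)` for flanking DMRs (e.g.
#' `UP,CHG(1283;0.15)`) and `placement,context(delta)` for intragenic ones
#' (e.g. `CDS,CG(0.26)`).
#'
#' @param placement `UP`, `DOWN`, `CDS`, `intron`, `UTR` or `body`.
#' @param context Methylation context.
#' @param distance Midpoint distance to TSS (UP) or TES (DOWN); ignored for
#'   intragenic placements.
#' @param delta Methylation-level change.
#' @return Character vector of descriptors.
#' @export
dmr_descriptor <- function(placement, context, distance, delta) {
  ifelse(placement %in% c("UP", "DOWN"),
         sprintf("%s,%s(%d;%.2f)", placement, context, as.integer(distance),
                 delta),
         sprintf("%s,%s(%.2f)", placement, context, delta))
}

#' Link DMRs to differentially expressed genes
#'
#' One interaction site per (DMR, DEG) pair in which the DMR's assigned
#' gene is a DEG and the DMR placement qualifies: inside the CDS, or
#' upstream/downstream with midpoint distance below `link_dist` (default
#' 2 kb to the TSS or TES). The association is `negative` when the
#' methylation change and the expression change have opposite signs,
#' `positive` otherwise. UTR- and intron-placed DMRs are excluded by
#' default (set `include_intragenic = TRUE` to keep every intragenic
#' placement).
#'
#' @param dmr_assignments Output of [assign_dmr()] (must carry context,
#'   delta, gene_id, placement, distance).
#' @param deg_calls Output of [call_degs()]; only rows with `is_deg` are
#'   linked.
#' @param link_dist Maximum UP/DOWN midpoint distance in bp (exclusive).
#' @param include_intragenic Also link intron/UTR/body placements.
#' @return List: `sites` (one row per interaction: gene_id, feature_kind,
#'   expression_log2fc, dmr columns, methylation_delta, association,
#'   descriptor) and `summary` (total_sites, negative_sites,
#'   negative_fraction, genes_negative, candidates -- the per-gene table
#'   sorted by gene id).
#' @export
link_dmr_deg <- function(dmr_assignments, deg_calls, link_dist = 2000L,
                         include_intragenic = FALSE) {
  degs <- deg_calls[deg_calls$is_deg, , drop = FALSE]
  ok_placement <- dmr_assignments$placement %in%
    c("CDS", "UP", "DOWN", if (include_intragenic) c("intron", "UTR", "body"))
  near <- !dmr_assignments$placement %in% c("UP", "DOWN") |
    (!is.na(dmr_assignments$distance) & dmr_assignments$distance < link_dist)
  cand <- dmr_assignments[ok_placement & near &
                            !is.na(dmr_assignments$gene_id) &
                            dmr_assignments$gene_id %in% degs$feature_id, ,
                          drop = FALSE]
  if (nrow(cand)) {
    di <- match(cand$gene_id, degs$feature_id)
    sites <- data.frame(
      gene_id = cand$gene_id,
      feature_kind = "deg",
      expression_log2fc = degs$log2fc[di],
      chrom = cand$chrom, start = cand$start, end = cand$end,
      context = cand$context, placement = cand$placement,
      distance = cand$distance,
      methylation_delta = cand$delta,
      stringsAsFactors = FALSE)
    sites$association <- ifelse(
      sign(sites$expression_log2fc) * sign(sites$methylation_delta) == -1,
      "negative", "positive")
    sites$descriptor <- dmr_descriptor(sites$placement, sites$context,
                                       sites$distance,
                                       sites$methylation_delta)
    sites <- sites[order(sites$gene_id, sites$chrom, sites$start), ,
                   drop = FALSE]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(gene_id = character(0), feature_kind = character(0),
                        expression_log2fc = numeric(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        context = character(0), placement = character(0),
                        distance = integer(0), methylation_delta = numeric(0),
                        association = character(0), descriptor = character(0))
  }
  neg <- sites$association == "negative"
  candidates <- if (nrow(sites)) {
    agg <- stats::aggregate(descriptor ~ gene_id + expression_log2fc, sites,
                            paste, collapse = ",")
    agg <- agg[order(agg$gene_id), c("gene_id", "expression_log2fc",
                                     "descriptor")]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(gene_id = character(0), expression_log2fc = numeric(0),
               descriptor = character(0))
  }
  list(sites = sites,
       summary = list(
         total_sites = nrow(sites),
         negative_sites = sum(neg),
         negative_fraction = if (nrow(sites)) mean(neg) else NA_real_,
         genes_negative = length(unique(sites$gene_id[neg])),
         candidates = candidates))
}

#' Link DMRs to differentially expressed TEs
#'
#' Per DET, every DMR whose interval overlaps the TE body (closed
#' intervals; a single shared bp counts) extended by `flank` bp. DETs with
#' no overlapping DMR are still reported with an `NA` DMR row.
#'
#' @param dmrs Data.frame of regions (chrom, start, end, context,
#'   direction).
#' @param det_calls Output of [call_dets()]; only `is_det` rows are linked.
#' @param annotation A `dmrlink_annotation` providing TE intervals and
#'   families.
#' @param flank Bp added to each side of the TE body before overlap
#'   testing (default 0).
#' @return Data.frame, one row per DET-DMR pairing (or single NA-DMR row):
#'   te_id, family, fpkm_a, fpkm_b (when present in `det_calls`),
#'   dmr_start, dmr_end, dmr_context, dmr_direction.
#' @export
link_dmr_det <- function(dmrs, det_calls, annotation, flank = 0L) {
  dets <- det_calls[det_calls$is_det, , drop = FALSE]
  tes <- annotation$tes
  out <- list()
  for (i in seq_len(nrow(dets))) {
    ti <- match(dets$te_id[i], tes$te_id)
    if (is.na(ti)) stop("DET ", dets$te_id[i], " missing from annotation")
    lo <- tes$start[ti] - flank; hi <- tes$end[ti] + flank
    hit <- dmrs$chrom == tes$chrom[ti] & dmrs$start <= hi & dmrs$end >= lo
    base <- data.frame(
      te_id = dets$te_id[i], family = tes$family[ti],
      fpkm_a = if ("fpkm_a" %in% names(dets)) dets$fpkm_a[i] else NA_real_,
      fpkm_b = if ("fpkm_b" %in% names(dets)) dets$fpkm_b[i] else NA_real_,
      stringsAsFactors = FALSE)
    if (any(hit)) {
      d <- dmrs[hit, , drop = FALSE]
      d <- d[order(d$start, d$end, d$context), , drop = FALSE]
      out[[i]] <- cbind(base[rep(1L, nrow(d)), , drop = FALSE],
                        data.frame(dmr_start = d$start, dmr_end = d$end,
                                   dmr_context = d$context,
                                   dmr_direction = d$direction))
    } else {
      out[[i]] <- cbind(base, data.frame(dmr_start = NA_integer_,
                                         dmr_end = NA_integer_,
                                         dmr_context = NA_character_,
                                         dmr_direction = NA_character_))
    }
  }
  if (!length(out)) {
    return(data.frame(te_id = character(0), family = character(0),
                      fpkm_a = numeric(0), fpkm_b = numeric(0),
                      dmr_start = integer(0), dmr_end = integer(0),
                      dmr_context = character(0),
                      dmr_direction = character(0)))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$te_id, res$dmr_start), , drop = FALSE]
}

#' Cluster genomic positions into regions
#'
#' Groups sorted positions on the same chromosome whenever consecutive
#' positions are at most `max_gap` apart; used e.g. to count the distinct
#' genomic neighbourhoods occupied by a set of features at Mb scale.
#'
#' @param chrom,pos Position vectors.
#' @param max_gap Largest within-cluster gap in bp (default 1e6).
#' @return Data.frame: chrom, start, end, n (members per cluster).
#' @export
cluster_positions <- function(chrom, pos, max_gap = 1e6) {
  stopifnot(length(chrom) == length(pos))
  if (!length(pos)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n = integer(0)))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) > max_gap)
  id <- cumsum(new_cluster)
  data.frame(chrom = tapply(chrom, id, `[`, 1L),
             start = as.numeric(tapply(pos, id, min)),
             end = as.numeric(tapply(pos, id, max)),
             n = as.integer(table(id)), row.names = NULL,
             stringsAsFactors = FALSE)
}
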