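# End-to-end wiring of the stages with a single validated threshold set and
# a checksum manifest for reproducibility.

#' Pipeline configuration
#'
#' Every numeric rule of the analysis as a named, defaulted parameter. The
#' defaults are the published rule set: coverage >= 4; DmC p < 0.05 with
#' level change >= 0.20; DMR windows of 5 motifs with >= 4 sharing the
#' response direction, rank-sum p < 0.05, gaps < 200 bp, length >= 50 bp and
#' region delta >= 0.1; DEG probability >= 0.8 with fold >= 2; DET adjusted
#' p < 0.05; genic flank 2 kb, intergenic beyond 5 kb, 5 body bins + 10
#' flank bins of 300 bp, DMR-DEG link distance < 2 kb. Deviating values are
#' accepted (with a warning) so long as they are structurally valid.
#'
#' @param min_coverage,dmc_p,dmc_delta,window,min_same,wilcoxon_p,max_gap,min_len,min_region_delta,deg_prob,deg_fold,det_alpha,mc_alpha,intergenic_dist,genic_flank,flank_bins,flank_bin_size,body_bins,link_dist
#'   Stage thresholds; see the stage functions for their meaning.
#' @param seed Seed forwarded to the simulator when [run_pipeline()]
#'   simulates its inputs.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_coverage = 4L, dmc_p = 0.05,
                            dmc_delta = 0.20, window = 5L, min_same = 4L,
                            wilcoxon_p = 0.05, max_gap = 200L, min_len = 50L,
                            min_region_delta = 0.1, deg_prob = 0.8,
                            deg_fold = 2, det_alpha = 0.05, mc_alpha = 0.05,
                            intergenic_dist = 5000L, genic_flank = 2000L,
                            flank_bins = 10L, flank_bin_size = 300L,
                            body_bins = 5L, link_dist = 2000L, seed = 1L) {
  defaults <- list(min_coverage = 4L, dmc_p = 0.05, dmc_delta = 0.20,
                   window = 5L, min_same = 4L, wilcoxon_p = 0.05,
                   max_gap = 200L, min_len = 50L, min_region_delta = 0.1,
                   deg_prob = 0.8, deg_fold = 2, det_alpha = 0.05,
                   mc_alpha = 0.05, intergenic_dist = 5000L,
                   genic_flank = 2000L, flank_bins = 10L,
                   flank_bin_size = 300L, body_bins = 5L, link_dist = 2000L)
  cfg <- list(min_coverage = min_coverage, dmc_p = dmc_p,
              dmc_delta = dmc_delta, window = window, min_same = min_same,
              wilcoxon_p = wilcoxon_p, max_gap = max_gap, min_len = min_len,
              min_region_delta = min_region_delta, deg_prob = deg_prob,
              deg_fold = deg_fold, det_alpha = det_alpha,
              mc_alpha = mc_alpha, intergenic_dist = intergenic_dist,
              genic_flank = genic_flank, flank_bins = flank_bins,
              flank_bin_size = flank_bin_size, body_bins = body_bins,
              link_dist = link_dist, seed = as.integer(seed))
  stopifnot(cfg$min_coverage >= 0, cfg$dmc_p > 0, cfg$dmc_p <= 1,
            cfg$dmc_delta >= 0, cfg$dmc_delta <= 1, cfg$window >= 2,
            cfg$min_same >= 1, cfg$min_same <= cfg$window,
            cfg$wilcoxon_p > 0, cfg$wilcoxon_p <= 1, cfg$max_gap >= 1,
            cfg$min_len >= 1, cfg$min_region_delta >= 0,
            cfg$deg_prob >= 0, cfg$deg_prob <= 1, cfg$deg_fold >= 1,
            cfg$det_alpha > 0, cfg$det_alpha <= 1,
            cfg$mc_alpha > 0, cfg$mc_alpha <= 1,
            cfg$intergenic_dist >= cfg$genic_flank, cfg$flank_bins >= 1,
            cfg$flank_bin_size >= 1, cfg$body_bins >= 1, cfg$link_dist >= 1)
  for (nm in names(defaults)) {
    if (!isTRUE(all.equal(cfg[[nm]], defaults[[nm]], check.attributes = FALSE))) {
      warning("pipeline_config: ", nm, " = ", cfg[[nm]],
              " deviates from the published default ", defaults[[nm]],
              call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on a simulated study
#'
#' Simulates a two-condition study from `sim`, then runs every stage in
#' dependency order -- conversion-rate estimation, methylcytosine calling,
#' DmC and DMR detection, feature association and enrichment, expression
#' summaries with DEG/DET calls, and DMR-DEG/DET linking -- writing each
#' report as TSV into `out_dir` together with an md5 checksum manifest.
#'
#' @param sim A [sim_config()] describing the study to simulate.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param n_control_sites Spike-in sites for the conversion control.
#' @return Invisibly, a list with every intermediate result plus
#'   `manifest` (data.frame: file, md5).
#' @export
run_pipeline <- function(sim, out_dir, config = pipeline_config(),
                         n_control_sites = 20000L) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(sim, n_control_sites)
  ann <- study$annotation

  conv <- estimate_conversion_rate(study$control)
  mc_a <- call_mc(study$methylomes$a[study$methylomes$a$coverage >=
                                       config$min_coverage, ],
                  conv, alpha = config$mc_alpha)
  dmcs <- call_dmcs(study$methylomes$a, study$methylomes$b,
                    p_threshold = config$dmc_p,
                    delta_threshold = config$dmc_delta,
                    min_coverage = config$min_coverage)
  dmrs <- call_dmrs(study$methylomes$a, study$methylomes$b,
                    params = dmr_params(
                      window = config$window, min_same = config$min_same,
                      wilcoxon_p = config$wilcoxon_p,
                      max_gap = config$max_gap, min_len = config$min_len,
                      min_region_delta = config$min_region_delta,
                      min_coverage = config$min_coverage,
                      dmc_p = config$dmc_p, dmc_delta = config$dmc_delta))
  assignments <- assign_dmr(dmrs, ann, genic_flank = config$genic_flank,
                            intergenic_dist = config$intergenic_dist)
  enr <- feature_enrichment(
    dmcs[dmcs$is_dmc, c("chrom", "pos")],
    mc_a[mc_a$is_mc, c("chrom", "pos")], ann,
    genic_flank = config$genic_flank,
    intergenic_dist = config$intergenic_dist)
  profile <- dmr_distance_profile(dmrs, ann, max_dist = config$link_dist)

  expr <- summarize_expression(study$expression$genes)
  degs <- call_degs(expr, prob_threshold = config$deg_prob,
                    fold_threshold = config$deg_fold)
  te_long <- study$expression$tes
  te_wide <- data.frame(
    te_id = te_long$te_id[te_long$condition == "A"],
    count_a = te_long$count[te_long$condition == "A"],
    fpkm_a = te_long$fpkm[te_long$condition == "A"],
    length = te_long$length[te_long$condition == "A"],
    stringsAsFactors = FALSE)
  ib <- match(te_wide$te_id, te_long$te_id[te_long$condition == "B"])
  te_b <- te_long[te_long$condition == "B", ]
  te_wide$count_b <- te_b$count[ib]
  te_wide$fpkm_b <- te_b$fpkm[ib]
  dets <- call_dets(te_wide, ann, total_a = sim$library_size,
                    total_b = sim$library_size, alpha = config$det_alpha)

  deg_links <- link_dmr_deg(assignments, degs, link_dist = config$link_dist)
  det_links <- link_dmr_det(dmrs, dets, ann)

  files <- c(
    conversion = "conversion_estimate.tsv",
    dmc = "dmc_calls.tsv", dmr = "dmr_calls.tsv",
    dmr_bed = "dmr_calls.bed",
    assignments = "dmr_assignments.tsv", enrichment = "dmc_enrichment.tsv",
    distance_profile = "dmr_distance_profile.tsv",
    deg = "deg_calls.tsv", det = "det_calls.tsv",
    interaction_sites = "interaction_sites.tsv",
    epiregulation_candidates = "epiregulation_candidates.tsv",
    det_dmr = "det_dmr.tsv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_tsv_with_header(data.frame(rate = conv$rate, n_sites = conv$n_sites,
                                   total_reads = conv$total_reads),
                        paths["conversion"])
  write_tsv_with_header(dmcs[dmcs$is_dmc, , drop = FALSE], paths["dmc"])
  write_tsv_with_header(dmrs, paths["dmr"])
  write_dmr_bed(dmrs, paths["dmr_bed"])
  write_tsv_with_header(assignments, paths["assignments"])
  write_tsv_with_header(enr, paths["enrichment"])
  write_tsv_with_header(profile, paths["distance_profile"])
  write_tsv_with_header(degs, paths["deg"])
  write_tsv_with_header(dets, paths["det"])
  write_tsv_with_header(deg_links$sites, paths["interaction_sites"])
  write_tsv_with_header(deg_links$summary$candidates,
                        paths["epiregulation_candidates"])
  write_tsv_with_header(det_links, paths["det_dmr"])

  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv_with_header(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(study = study, conversion = conv, dmcs = dmcs, dmrs = dmrs,
                 assignments = assignments, enrichment = enr,
                 distance_profile = profile, degs = degs, dets = dets,
                 deg_links = deg_links, det_links = det_links,
                 manifest = manifest))
}
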