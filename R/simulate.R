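# Synthetic two-condition WGBS + RNA-seq study generator.
#
# Every generator derives its RNG stream from the config seed plus a fixed
# per-stage offset, so each stage is reproducible on its own and the whole
# simulation is byte-identical for an identical configuration.

.stage_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Generate reference sequences and gene/TE annotation
#'
#' Simulates uniform-random chromosome sequences (CHH-dominant, as in real
#' plant genomes), places non-overlapping gene models (each with TSS/TES, at
#' least one CDS, optional UTRs and inferred introns) and TE intervals, a
#' configurable fraction of which overlap genes so that the gene-overlap TE
#' discard rule can be exercised downstream.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `dmrlink_annotation` with elements `sequences`
#'   (named character vector), `genes` (data.frame: gene_id, chrom, start,
#'   end, strand, tss, tes), `parts` (gene_id, type in CDS/UTR/intron,
#'   start, end) and `tes` (te_id, chrom, start, end, family).
#' @examples
#' ann <- generate_annotation(sim_config(seed = 1, chromosome_length = 50000,
#'                                       gene_count = 5, te_count = 4))
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .stage_seed(config, 0L)
  L <- config$chromosome_length
  chroms <- paste0("Chr", seq_len(config$n_chromosomes))
  sequences <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))

  # distribute genes/TEs across chromosomes as evenly as possible
  split_counts <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + c(rep(1L, extra), rep(0L, k - extra))
  }
  gene_per_chrom <- split_counts(config$gene_count, config$n_chromosomes)
  te_per_chrom <- split_counts(config$te_count, config$n_chromosomes)

  genes <- list(); parts <- list(); gid <- 0L
  for (ci in seq_along(chroms)) {
    ng <- gene_per_chrom[ci]
    if (ng == 0L) next
    lens <- sample(800:2500, ng, replace = TRUE)
    free <- L - sum(lens)
    if (free < ng + 1L) {
      stop("cannot place ", ng, " genes of total length ", sum(lens),
           " on a ", L, " bp chromosome (capacity error)")
    }
    u <- stats::runif(ng + 1L)
    gaps <- floor(free * u / sum(u))
    starts <- 1L + cumsum(gaps[seq_len(ng)]) +
      c(0L, cumsum(utils::head(lens, -1L)))
    for (gi in seq_len(ng)) {
      gid <- gid + 1L
      g <- .build_gene(sprintf("g%03d", gid), chroms[ci],
                       starts[gi], starts[gi] + lens[gi] - 1L)
      genes[[gid]] <- g$gene
      parts[[gid]] <- g$parts
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               tss = integer(0), tes = integer(0))
  parts <- if (length(parts)) do.call(rbind, parts) else
    data.frame(gene_id = character(0), type = character(0),
               start = integer(0), end = integer(0))

  tes <- .place_tes(config, chroms, te_per_chrom, genes, L)
  structure(list(sequences = sequences, genes = genes, parts = parts,
                 tes = tes),
            class = "dmrlink_annotation")
}

# One gene model: exon/intron alternation over [s, e], terminal UTRs on the
# strand-oriented 5' and 3' exons, remainder CDS.
.build_gene <- function(id, chrom, s, e) {
  len <- e - s + 1L
  strand <- sample(c("+", "-"), 1L)
  k <- sample(1:3, 1L)
  n_intron <- k - 1L
  intron_lens <- if (n_intron > 0L) {
    max_intron <- max(60L, (len - k * 60L) %/% max(1L, n_intron))
    sample(60:min(200L, max_intron), n_intron, replace = TRUE)
  } else integer(0)
  exon_total <- len - sum(intron_lens)
  stopifnot(exon_total >= k * 60L)
  extra <- exon_total - k * 60L
  cuts <- if (k > 1L) sort(sample(0:extra, k - 1L, replace = TRUE)) else integer(0)
  exon_lens <- diff(c(0L, cuts, extra)) + 60L

  # alternate exon/intron from the left genomic end
  cur <- s; exons <- matrix(0L, k, 2L); introns <- matrix(0L, n_intron, 2L)
  for (i in seq_len(k)) {
    exons[i, ] <- c(cur, cur + exon_lens[i] - 1L)
    cur <- cur + exon_lens[i]
    if (i <= n_intron) {
      introns[i, ] <- c(cur, cur + intron_lens[i] - 1L)
      cur <- cur + intron_lens[i]
    }
  }
  exons[k, 2L] <- e  # absorb rounding

  u5 <- sample(0:120, 1L); u3 <- sample(0:120, 1L)
  first_exon <- if (strand == "+") 1L else k    # strand-oriented 5' exon
  last_exon <- if (strand == "+") k else 1L
  u5 <- min(u5, exons[first_exon, 2L] - exons[first_exon, 1L])
  u3 <- min(u3, exons[last_exon, 2L] - exons[last_exon, 1L])

  utr <- list()
  if (u5 > 0L) {
    utr[[length(utr) + 1L]] <- if (strand == "+")
      c(exons[1L, 1L], exons[1L, 1L] + u5 - 1L) else
      c(exons[k, 2L] - u5 + 1L, exons[k, 2L])
  }
  if (u3 > 0L) {
    utr[[length(utr) + 1L]] <- if (strand == "+")
      c(exons[k, 2L] - u3 + 1L, exons[k, 2L]) else
      c(exons[1L, 1L], exons[1L, 1L] + u3 - 1L)
  }
  # CDS = exon minus UTR coverage
  cds <- list()
  for (i in seq_len(k)) {
    lo <- exons[i, 1L]; hi <- exons[i, 2L]
    for (uv in utr) {
      if (uv[1L] <= lo && uv[2L] >= lo) lo <- uv[2L] + 1L
      if (uv[1L] <= hi && uv[2L] >= hi) hi <- uv[1L] - 1L
    }
    if (lo <= hi) cds[[length(cds) + 1L]] <- c(lo, hi)
  }
  pr <- rbind(
    if (length(cds)) data.frame(type = "CDS", do.call(rbind, cds)),
    if (length(utr)) data.frame(type = "UTR", do.call(rbind, utr)),
    if (n_intron > 0L) data.frame(type = "intron", introns)
  )
  names(pr)[2:3] <- c("start", "end")
  pr <- data.frame(gene_id = id, pr, stringsAsFactors = FALSE)
  pr <- pr[order(pr$start), , drop = FALSE]
  list(
    gene = data.frame(gene_id = id, chrom = chrom, start = s, end = e,
                      strand = strand,
                      tss = if (strand == "+") s else e,
                      tes = if (strand == "+") e else s,
                      stringsAsFactors = FALSE),
    parts = pr
  )
}

.place_tes <- function(config, chroms, te_per_chrom, genes, L) {
  fams <- c("LTR/Gypsy", "LTR/Copia", "DNA/MuDR", "unknown")
  tes <- list(); tid <- 0L
  n_overlap_total <- round(config$te_gene_overlap_fraction * config$te_count)
  placed_overlap <- 0L
  for (ci in seq_along(chroms)) {
    nt <- te_per_chrom[ci]
    if (nt == 0L) next
    g <- genes[genes$chrom == chroms[ci], , drop = FALSE]
    for (ti in seq_len(nt)) {
      tid <- tid + 1L
      len <- sample(200:1500, 1L)
      want_overlap <- placed_overlap < n_overlap_total
      if (want_overlap && nrow(g) > 0L) {
        gi <- sample(nrow(g), 1L)
        start <- sample(g$start[gi]:g$end[gi], 1L)
        start <- min(start, L - len + 1L)
        placed_overlap <- placed_overlap + 1L
      } else {
        if (want_overlap) stop("cannot place gene-overlapping TEs without genes")
        ok <- FALSE
        for (attempt in 1:1000) {
          start <- sample(L - len + 1L, 1L)
          if (nrow(g) == 0L ||
              !any(start <= g$end & (start + len - 1L) >= g$start)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("cannot place a TE outside genes (capacity error)")
      }
      tes[[tid]] <- data.frame(
        te_id = sprintf("te%03d", tid), chrom = chroms[ci],
        start = start, end = start + len - 1L,
        family = sample(fams, 1L), stringsAsFactors = FALSE)
    }
  }
  if (length(tes)) do.call(rbind, tes) else
    data.frame(te_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), family = character(0))
}

#' Generate a pair of per-cytosine methylation count tables
#'
#' For every strand-specific cytosine with resolvable context, coverage is
#' drawn from a Poisson distribution around `coverage_mean` (independently
#' per condition, shared position set), and the methylated-read count from a
#' binomial whose success probability is the true level plus the
#' false-methylation probability `(1 - conversion_rate)` applied to the
#' unmethylated fraction. Planted DMRs shift the true level of
#' matching-context cytosines inside their interval by `delta` (clamped to
#' \[0, 1\]) in condition B.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [generate_annotation()] (provides the
#'   sequences).
#' @return List with `a`, `b` (data.frames: chrom, pos, strand, context,
#'   meth_reads, coverage) and `truth` (list: dmrs, conversion_rate).
#' @export
generate_methylome_pair <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "dmrlink_annotation"))
  planted <- config$planted_dmrs
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      if (!planted$chrom[i] %in% names(annotation$sequences)) {
        stop("planted DMR on unknown chromosome ", planted$chrom[i])
      }
      if (planted$start[i] < 1L ||
          planted$end[i] > nchar(annotation$sequences[[planted$chrom[i]]])) {
        stop("planted DMR ", i, " outside chromosome bounds")
      }
    }
  }
  .stage_seed(config, 1L)
  err <- 1 - config$conversion_rate
  res_a <- list(); res_b <- list()
  for (ch in names(annotation$sequences)) {
    ctx <- cytosine_contexts(annotation$sequences[[ch]])
    n <- nrow(ctx)
    level_a <- unname(config$baseline_levels[ctx$context])
    level_b <- level_a
    if (!is.null(planted)) {
      pl <- planted[planted$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(pl))) {
        hit <- ctx$pos >= pl$start[i] & ctx$pos <= pl$end[i] &
          ctx$context == pl$context[i]
        level_b[hit] <- level_b[hit] + pl$delta[i]
      }
    }
    level_b <- pmin(1, pmax(0, level_b))
    draw <- function(level) {
      cov <- pmax(stats::rpois(n, config$coverage_mean), config$coverage_floor)
      p_obs <- level + (1 - level) * err
      meth <- stats::rbinom(n, cov, p_obs)
      data.frame(chrom = ch, pos = ctx$pos, strand = ctx$strand,
                 context = ctx$context, meth_reads = meth, coverage = cov,
                 stringsAsFactors = FALSE)
    }
    res_a[[ch]] <- draw(level_a)
    res_b[[ch]] <- draw(level_b)
  }
  list(
    a = do.call(rbind, c(res_a, list(make.row.names = FALSE))),
    b = do.call(rbind, c(res_b, list(make.row.names = FALSE))),
    truth = list(dmrs = planted, conversion_rate = config$conversion_rate)
  )
}

#' Generate an unmethylated spike-in conversion control
#'
#' Emulates the unmethylated phage DNA spiked into a bisulfite library to
#' measure conversion efficiency: every control cytosine is truly
#' unmethylated, so methylated-read counts arise only from conversion
#' failure at rate `1 - conversion_rate`.
#'
#' @param config A [sim_config()].
#' @param n_sites Number of control cytosines (default 50000).
#' @return Data.frame (chrom, pos, strand, context, meth_reads, coverage);
#'   zero rows when `n_sites = 0` (a downstream estimator must then error).
#' @export
generate_conversion_control <- function(config, n_sites = 50000L) {
  stopifnot(inherits(config, "sim_config"), n_sites >= 0L)
  .stage_seed(config, 2L)
  if (n_sites == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      meth_reads = integer(0), coverage = integer(0)))
  }
  cov <- pmax(stats::rpois(n_sites, config$coverage_mean), config$coverage_floor)
  meth <- stats::rbinom(n_sites, cov, 1 - config$conversion_rate)
  data.frame(chrom = "lambda_spikein", pos = seq_len(n_sites), strand = "+",
             context = "CHH", meth_reads = meth, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Generate replicated expression tables with planted effects
#'
#' Per-gene FPKM is lognormal around a gene-specific mean, with planted DEG
#' effects shifting condition B by `log2_effect`. TEs follow the
#' one-library-per-condition design: raw fragment counts are Poisson with a
#' TE-specific mean (shifted for planted DETs) and converted to FPKM using
#' the configured library size.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [generate_annotation()].
#' @return List with `genes` (feature_id, condition, replicate, fpkm),
#'   `tes` (te_id, condition, count, fpkm, length) and `truth` (degs, dets).
#' @export
generate_expression_tables <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "dmrlink_annotation"))
  .stage_seed(config, 3L)
  genes <- annotation$genes
  reps <- config$replicates

  deg_effect <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (!is.null(config$planted_degs)) {
    bad <- setdiff(config$planted_degs$gene_id, genes$gene_id)
    if (length(bad)) stop("planted DEG for unknown gene: ", bad[1])
    deg_effect[config$planted_degs$gene_id] <- config$planted_degs$log2_effect
  }
  base_mean <- stats::rlnorm(nrow(genes), meanlog = log(20), sdlog = 1)
  gene_rows <- list()
  for (cond in c("A", "B")) {
    mu <- base_mean * if (cond == "B") 2^deg_effect else 1
    for (r in seq_len(reps)) {
      fpkm <- mu * exp(stats::rnorm(nrow(genes), 0, 0.25))
      gene_rows[[paste(cond, r)]] <- data.frame(
        feature_id = genes$gene_id, condition = cond, replicate = r,
        fpkm = fpkm, stringsAsFactors = FALSE)
    }
  }

  tes <- annotation$tes
  det_effect <- stats::setNames(rep(0, nrow(tes)), tes$te_id)
  if (!is.null(config$planted_dets)) {
    bad <- setdiff(config$planted_dets$te_id, tes$te_id)
    if (length(bad)) stop("planted DET for unknown TE: ", bad[1])
    det_effect[config$planted_dets$te_id] <- config$planted_dets$log2_effect
  }
  te_len <- tes$end - tes$start + 1L
  te_base_fpkm <- stats::rlnorm(nrow(tes), meanlog = log(5), sdlog = 1.2)
  te_rows <- list(
    data.frame(te_id = character(0), condition = character(0),
               count = integer(0), fpkm = numeric(0), length = integer(0),
               stringsAsFactors = FALSE))
  for (cond in if (nrow(tes)) c("A", "B") else character(0)) {
    mu_fpkm <- te_base_fpkm * if (cond == "B") 2^det_effect else 1
    mu_count <- mu_fpkm * (te_len / 1000) * (config$library_size / 1e6)
    count <- stats::rpois(nrow(tes), mu_count)
    te_rows[[cond]] <- data.frame(
      te_id = tes$te_id, condition = cond, count = count,
      fpkm = if (nrow(tes)) compute_fpkm(count, te_len, config$library_size)
             else numeric(0),
      length = te_len, stringsAsFactors = FALSE)
  }
  list(
    genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
    tes = do.call(rbind, c(te_rows, list(make.row.names = FALSE))),
    truth = list(
      degs = data.frame(gene_id = names(deg_effect),
                        log2_effect = unname(deg_effect),
                        stringsAsFactors = FALSE),
      dets = data.frame(te_id = names(det_effect),
                        log2_effect = unname(det_effect),
                        stringsAsFactors = FALSE))
  )
}

#' Run the full simulation
#'
#' Convenience wrapper producing annotation, methylome pair, conversion
#' control and expression tables from one configuration, plus a combined
#' truth table.
#'
#' @param config A [sim_config()].
#' @param n_control_sites Sites in the spike-in control.
#' @return List: annotation, methylomes, control, expression, truth.
#' @export
simulate_study <- function(config, n_control_sites = 50000L) {
  ann <- generate_annotation(config)
  meth <- generate_methylome_pair(config, ann)
  ctrl <- generate_conversion_control(config, n_control_sites)
  expr <- generate_expression_tables(config, ann)
  list(annotation = ann, methylomes = meth, control = ctrl, expression = expr,
       truth = list(dmrs = meth$truth$dmrs,
                    degs = expr$truth$degs,
                    dets = expr$truth$dets,
                    conversion_rate = config$conversion_rate))
}
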