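# Synthetic study generator: determinism, planted truth, noise model.

test_that("annotation generation is deterministic and honours counts", {
  cfg <- sim_config(seed = 3, chromosome_length = 80000, gene_count = 10,
                    te_count = 10, te_gene_overlap_fraction = 0.3)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 10)
  expect_equal(nrow(a1$tes), 10)
  # byte-identical GFF3 for the same config
  f1 <- tempfile(); f2 <- tempfile()
  dmrlink:::write_annotation_gff3(a1, f1)
  dmrlink:::write_annotation_gff3(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty annotation config yields sequences only", {
  cfg <- sim_config(seed = 1, chromosome_length = 5000, gene_count = 0,
                    te_count = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$tes), 0)
  expect_equal(nchar(ann$sequences[["Chr1"]]), 5000)
})

test_that("genes do not overlap and each has at least one CDS", {
  cfg <- sim_config(seed = 9, chromosome_length = 100000, gene_count = 15,
                    te_count = 0)
  ann <- generate_annotation(cfg)
  g <- ann$genes[order(ann$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  for (id in g$gene_id) {
    pr <- ann$parts[ann$parts$gene_id == id, ]
    expect_true(any(pr$type == "CDS"))
    expect_true(all(pr$start >= g$start[g$gene_id == id] &
                      pr$end <= g$end[g$gene_id == id]))
  }
})

test_that("the requested fraction of TEs overlaps genes (interval-intersection oracle)", {
  cfg <- sim_config(seed = 21, chromosome_length = 150000, gene_count = 12,
                    te_count = 10, te_gene_overlap_fraction = 0.3)
  ann <- generate_annotation(cfg)
  n_overlap <- sum(vapply(seq_len(nrow(ann$tes)), function(i) {
    any(ann$tes$start[i] <= ann$genes$end &
          ann$tes$end[i] >= ann$genes$start &
          ann$tes$chrom[i] == ann$genes$chrom)
  }, logical(1)))
  expect_equal(n_overlap, 3)
})

test_that("impossible gene packing raises a capacity error", {
  expect_error(generate_annotation(
    sim_config(seed = 1, chromosome_length = 4000, gene_count = 10)),
    "capacity")
})

test_that("methylome generation is deterministic and respects count bounds", {
  cfg <- sim_config(seed = 13, chromosome_length = 20000, gene_count = 0,
                    te_count = 0)
  ann <- generate_annotation(cfg)
  m1 <- generate_methylome_pair(cfg, ann)
  m2 <- generate_methylome_pair(cfg, ann)
  expect_identical(m1, m2)
  for (tab in list(m1$a, m1$b)) {
    expect_true(all(tab$meth_reads <= tab$coverage))
    expect_true(all(tab$meth_reads >= 0))
  }
  # both conditions share the position grid
  expect_identical(m1$a[c("chrom", "pos", "strand", "context")],
                   m1$b[c("chrom", "pos", "strand", "context")])
})

test_that("perfect conversion with zero baseline yields zero methylated reads", {
  cfg <- sim_config(seed = 2, chromosome_length = 10000, gene_count = 0,
                    te_count = 0,
                    baseline_levels = c(CG = 0, CHG = 0, CHH = 0),
                    conversion_rate = 1.0)
  mp <- generate_methylome_pair(cfg, generate_annotation(cfg))
  expect_true(all(mp$a$meth_reads == 0))
  expect_true(all(mp$b$meth_reads == 0))
})

test_that("conversion failure alone reproduces the expected background level", {
  cfg <- sim_config(seed = 4, chromosome_length = 60000, gene_count = 0,
                    te_count = 0,
                    baseline_levels = c(CG = 0, CHG = 0, CHH = 0),
                    conversion_rate = 0.9951)
  mp <- generate_methylome_pair(cfg, generate_annotation(cfg))
  lev <- sum(mp$a$meth_reads) / sum(mp$a$coverage)
  se <- sqrt(0.0049 * 0.9951 / sum(mp$a$coverage))
  expect_lt(abs(lev - 0.0049), 3 * se)
})

test_that("a planted delta shifts the observed block mean by the planted amount", {
  planted <- data.frame(chrom = "Chr1", start = 5001, end = 6000,
                        context = "CG", delta = -0.5)
  cfg <- sim_config(seed = 8, chromosome_length = 60000, gene_count = 0,
                    te_count = 0, coverage_mean = 30,
                    planted_dmrs = planted)
  mp <- generate_methylome_pair(cfg, generate_annotation(cfg))
  sel <- mp$a$context == "CG" & mp$a$pos >= 5001 & mp$a$pos <= 6000
  d <- mp$b$meth_reads[sel] / mp$b$coverage[sel] -
    mp$a$meth_reads[sel] / mp$a$coverage[sel]
  expect_lt(abs(mean(d) + 0.5), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("observed delta converges to the planted delta at deep coverage", {
  planted <- data.frame(chrom = "Chr1", start = 2001, end = 2500,
                        context = "CHH", delta = 0.3)
  cfg <- sim_config(seed = 6, chromosome_length = 20000, gene_count = 0,
                    te_count = 0, coverage_mean = 200,
                    planted_dmrs = planted)
  mp <- generate_methylome_pair(cfg, generate_annotation(cfg))
  sel <- mp$a$context == "CHH" & mp$a$pos >= 2001 & mp$a$pos <= 2500
  d <- mean(mp$b$meth_reads[sel] / mp$b$coverage[sel]) -
    mean(mp$a$meth_reads[sel] / mp$a$coverage[sel])
  expect_lt(abs(d - 0.3), 0.05)
})

test_that("out-of-bounds planted DMRs are rejected", {
  planted <- data.frame(chrom = "Chr1", start = 19000, end = 21000,
                        context = "CG", delta = 0.3)
  cfg <- sim_config(seed = 1, chromosome_length = 50000, gene_count = 0,
                    te_count = 0, planted_dmrs = planted)
  cfg$planted_dmrs$end <- 60000L
  expect_error(generate_methylome_pair(cfg, generate_annotation(cfg)),
               "bounds")
})

test_that("conversion control is unmethylated up to conversion failure", {
  cfg <- sim_config(seed = 3, conversion_rate = 1.0)
  ctrl <- generate_conversion_control(cfg, 2000)
  expect_true(all(ctrl$meth_reads == 0))
  cfg2 <- sim_config(seed = 3, conversion_rate = 0.9951)
  ctrl2 <- generate_conversion_control(cfg2, 50000)
  est <- estimate_conversion_rate(ctrl2)
  expect_lt(abs(est$rate - 0.9951), 0.001)
  empty <- generate_conversion_control(cfg2, 0)
  expect_equal(nrow(empty), 0)
  expect_error(estimate_conversion_rate(empty), "control")
})

test_that("expression tables carry the replicate structure and planted effects", {
  cfg <- sim_config(seed = 17, chromosome_length = 100000, gene_count = 12,
                    te_count = 4, replicates = 3,
                    planted_degs = data.frame(gene_id = "g003",
                                              log2_effect = 2.0))
  ann <- generate_annotation(cfg)
  ex <- generate_expression_tables(cfg, ann)
  per <- table(ex$genes$condition, ex$genes$replicate)
  expect_equal(dim(per), c(2L, 3L))
  expect_true(all(per == 12))
  expect_true(all(ex$genes$fpkm >= 0))
  expect_equal(ex$truth$degs$log2_effect[ex$truth$degs$gene_id == "g003"], 2)
})

test_that("a planted expression effect is recovered in the mean log2 fold change", {
  cfg <- sim_config(seed = 19, chromosome_length = 100000, gene_count = 10,
                    te_count = 0, replicates = 12,
                    planted_degs = data.frame(gene_id = "g005",
                                              log2_effect = 2.0))
  ex <- generate_expression_tables(cfg, generate_annotation(cfg))
  s <- summarize_expression(ex$genes)
  expect_lt(abs(s$log2fc[s$feature_id == "g005"] - 2.0), 0.5)
  # and null genes stay near zero
  expect_lt(max(abs(s$log2fc[s$feature_id != "g005"])), 1)
})

test_that("with no planted effects the DEG filter fires on (almost) nothing", {
  cfg <- sim_config(seed = 23, chromosome_length = 150000, gene_count = 20,
                    te_count = 0, replicates = 3)
  ex <- generate_expression_tables(cfg, generate_annotation(cfg))
  degs <- call_degs(summarize_expression(ex$genes))
  expect_equal(sum(degs$is_deg), 0)
})
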