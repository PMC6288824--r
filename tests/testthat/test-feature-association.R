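# Feature classification, DMR assignment, enrichment and profiles on the
# handwritten two-gene annotation.

test_that("positions collect every applicable feature label", {
  ann <- tiny_annotation()
  # inside gA's first CDS and inside teA
  expect_setequal(classify_position("chr1", 10900, ann),
                  c("gene_body", "CDS", "TE"))
  # intron of gA under teA
  expect_setequal(classify_position("chr1", 11100, ann),
                  c("gene_body", "intron", "TE"))
  # UTR at the gene start
  expect_true("UTR" %in% classify_position("chr1", 10100, ann))
  # far from everything: intergenic only
  expect_equal(classify_position("chr1", 45000, ann), "intergenic")
})

test_that("flank labels respect strand orientation", {
  ann <- tiny_annotation()
  # 1500 bp upstream of plus-strand gA (TSS 10001)
  lab <- classify_position("chr1", 10001 - 1500, ann)
  expect_true(all(c("up2kb", "up5kb") %in% lab))
  expect_false("down2kb" %in% lab)
  # 1500 bp upstream of minus-strand gB (TSS 32000): numerically right
  lab2 <- classify_position("chr1", 32000 + 1500, ann)
  expect_true(all(c("up2kb", "up5kb") %in% lab2))
  expect_false("down2kb" %in% lab2)
  # 3 kb upstream of gB: in the 5 kb shell but not the 2 kb flank
  lab3 <- classify_position("chr1", 32000 + 3000, ann)
  expect_true("up5kb" %in% lab3)
  expect_false("up2kb" %in% lab3)
})

test_that("positions beyond 5 kb of every TSS/TES are intergenic", {
  ann <- tiny_annotation()
  expect_true("intergenic" %in% classify_position("chr1", 20000, ann))
  expect_false("intergenic" %in% classify_position("chr1", 14000, ann))
})

test_that("DMR assignment follows midpoint, nearest gene and placement rules", {
  ann <- tiny_annotation()
  # midpoint 1283 bp upstream of gA's TSS
  d <- data.frame(chrom = "chr1", start = 10001 - 1283 - 10,
                  end = 10001 - 1283 + 10, context = "CHG", delta = 0.15)
  a <- assign_dmr(d, ann)
  expect_equal(a$zone, "genic")
  expect_equal(a$gene_id, "gA")
  expect_equal(a$placement, "UP")
  expect_equal(a$distance, 1283)
  expect_equal(dmr_descriptor(a$placement, a$context, a$distance, a$delta),
               "UP,CHG(1283;0.15)")
  # wholly inside a CDS: placement CDS, distance 0
  d2 <- data.frame(chrom = "chr1", start = 10300, end = 10400,
                   context = "CG", delta = 0.26)
  a2 <- assign_dmr(d2, ann)
  expect_equal(a2$placement, "CDS")
  expect_equal(a2$distance, 0)
  expect_equal(dmr_descriptor(a2$placement, a2$context, a2$distance,
                              a2$delta), "CDS,CG(0.26)")
  # downstream of minus-strand gB (numerically left of 30001)
  d3 <- data.frame(chrom = "chr1", start = 29480, end = 29520,
                   context = "CHH", delta = -0.2)
  a3 <- assign_dmr(d3, ann)
  expect_equal(a3$gene_id, "gB")
  expect_equal(a3$placement, "DOWN")
  expect_equal(a3$distance, 30001 - 29500)
  # intergenic midpoint
  d4 <- data.frame(chrom = "chr1", start = 44000, end = 44100,
                   context = "CG", delta = 0.3)
  expect_equal(assign_dmr(d4, ann)$zone, "intergenic")
})

test_that("equidistant midpoints break ties toward the lower gene id", {
  genes <- data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(1000L, 3000L), end = c(1400L, 3400L), strand = "+",
    tss = c(1000L, 3000L), tes = c(1400L, 3400L), stringsAsFactors = FALSE)
  ann <- structure(list(sequences = NULL, genes = genes,
                        parts = data.frame(gene_id = character(0),
                                           type = character(0),
                                           start = integer(0),
                                           end = integer(0)),
                        tes = data.frame(te_id = character(0),
                                         chrom = character(0),
                                         start = integer(0),
                                         end = integer(0),
                                         family = character(0))),
                   class = "dmrlink_annotation")
  # midpoint 2200: 800 from gB's TES (1400) and 800 from gA's TSS (3000)
  d <- data.frame(chrom = "chr1", start = 2150, end = 2250, context = "CG",
                  delta = 0.2)
  expect_equal(assign_dmr(d, ann)$gene_id, "gA")
})

test_that("TE overlap is interval intersection of the full DMR", {
  ann <- tiny_annotation()
  d <- data.frame(chrom = "chr1",
                  start = c(11150, 11300, 40500, 40501),
                  end = c(11260, 11400, 40600, 40600),
                  context = "CG", delta = 0.2)
  a <- assign_dmr(d, ann)
  # teA ends 11200; teB ends 40500 (single-bp touch counts)
  expect_equal(a$te_overlap, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("fold enrichment follows the printed formula with hypergeometric tails", {
  e <- enrichment(10, 100, 50, 1000, feature = "TE")
  expect_equal(e$fold, 2.0)
  expect_equal(e$p_value,
               hyper_tail_p(10, 50, 950, 100, lower.tail = FALSE))
  # identity case: fold exactly 1, p well above significance
  e2 <- enrichment(5, 100, 50, 1000)
  expect_equal(e2$fold, 1.0)
  expect_gte(e2$p_value, 0.05)
  # enumeration example: universe 20, feature 10, draws 5, observed 5
  e3 <- enrichment(5, 5, 10, 20)
  expect_equal(e3$p_value, 252 / 15504, tolerance = 1e-12)
  # zero-count feature reported as missing
  e4 <- enrichment(0, 10, 0, 100)
  expect_true(is.na(e4$fold))
})

test_that("on a true partition the mC-weighted mean fold equals one", {
  set.seed(61)
  mc_feature <- c(200L, 300L, 500L)
  dmc_feature <- c(30L, 10L, 40L)
  e <- enrichment(dmc_feature, sum(dmc_feature), mc_feature,
                  sum(mc_feature))
  expect_equal(sum(e$fold * mc_feature / sum(mc_feature)), 1,
               tolerance = 1e-12)
})

test_that("hypergeometric enrichment p-values are super-uniform under null resampling", {
  set.seed(62)
  mc_total <- 2000L
  mc_feature <- 400L
  in_feature <- c(rep(TRUE, mc_feature), rep(FALSE, mc_total - mc_feature))
  p <- replicate(400, {
    draw <- sample(in_feature, 100)
    e <- enrichment(sum(draw), 100L, mc_feature, mc_total, two_sided = TRUE)
    e$p_value
  })
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= q), q + 3 * sqrt(q * (1 - q) / 400))
  }
})

test_that("metagene bins are strand-oriented with bin 1 nearest the gene", {
  ann <- tiny_annotation()
  # plus-strand gA: TSS 10001; item at TSS-150 -> upstream bin 1
  out <- metagene_bins(data.frame(chrom = "chr1", pos = 10001 - 150), ann)
  expect_equal(out$count[out$bin == "up1"], 1)
  expect_equal(sum(out$count), 1)
  # body offset 999 of a 3000 bp body falls in body bin 2 (fifths of 600)
  out2 <- metagene_bins(data.frame(chrom = "chr1", pos = 10001 + 999), ann)
  expect_equal(out2$count[out2$bin == "body2"], 1)
  # last body position falls in the final body bin
  out3 <- metagene_bins(data.frame(chrom = "chr1", pos = 13000), ann)
  expect_equal(out3$count[out3$bin == "body5"], 1)
  # minus-strand gB: 100 bp numerically right of the body -> upstream bin 1
  out4 <- metagene_bins(data.frame(chrom = "chr1", pos = 32000 + 100), ann)
  expect_equal(out4$count[out4$bin == "up1"], 1)
})

test_that("distance profile bins DMR midpoints at 100 bp resolution", {
  ann <- tiny_annotation()
  mk <- function(mid) data.frame(chrom = "chr1", start = mid - 5,
                                 end = mid + 5, context = "CG")
  # midpoint 650 bp from gA's TSS -> bin 7 (600-700)
  prof <- dmr_distance_profile(mk(10001 - 650), ann)
  expect_equal(prof$count[prof$bin == 7], 1)
  expect_equal(sum(prof$count), 1)
  # midpoint inside a body -> distance 0 -> bin 1
  prof2 <- dmr_distance_profile(mk(11000), ann)
  expect_equal(prof2$count[prof2$bin == 1], 1)
})

test_that("uniform DMRs on a gene-free chromosome give a flat distance profile", {
  genes <- data.frame(gene_id = "g", chrom = "chr9", start = 1L, end = 10L,
                      strand = "+", tss = 1L, tes = 10L,
                      stringsAsFactors = FALSE)
  ann <- structure(list(sequences = NULL, genes = genes,
                        parts = data.frame(gene_id = character(0),
                                           type = character(0),
                                           start = integer(0),
                                           end = integer(0)),
                        tes = data.frame(te_id = character(0),
                                         chrom = character(0),
                                         start = integer(0),
                                         end = integer(0),
                                         family = character(0))),
                   class = "dmrlink_annotation")
  set.seed(63)
  mids <- sample(11:2010, 3000, replace = TRUE)  # distances uniform on 1..2000
  dmrs <- data.frame(chrom = "chr9", start = mids, end = mids,
                     context = "CG")
  prof <- dmr_distance_profile(dmrs, ann, bin_size = 500, max_dist = 2000)
  counts <- prof$count
  # distances beyond the gene neighbourhood are uniform; expect each of the
  # 4 bins within 3 sigma of the binomial expectation
  kept <- sum(counts)
  expected <- kept / length(counts)
  sigma <- sqrt(kept * (1 / length(counts)) * (1 - 1 / length(counts)))
  expect_true(all(abs(counts - expected) < 4 * sigma))
})
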