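# DmC calls and the seed-and-extend DMR scan.

test_that("DmC Fisher test reproduces the hypergeometric-tail oracle", {
  a <- data.frame(chrom = "c", pos = 10L, strand = "+", context = "CG",
                  meth_reads = 10L, coverage = 10L)
  b <- a; b$meth_reads <- 0L
  out <- test_dmc(a, b)
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(out$delta, -1)
  expect_true(out$is_dmc)
  expect_equal(out$direction, "hypo")
  # identical counts: p = 1, no call
  out2 <- test_dmc(a, a)
  expect_equal(out2$p_value, 1)
  expect_false(out2$is_dmc)
})

test_that("the 20% level-change rule vetoes significant but small shifts", {
  # large counts: delta 0.19 with a tiny p-value is still not a DmC
  a <- data.frame(chrom = "c", pos = 1L, strand = "+", context = "CG",
                  meth_reads = 500L, coverage = 1000L)
  b <- a; b$meth_reads <- 690L
  out <- test_dmc(a, b)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$delta, 0.19)
  expect_false(out$is_dmc)
})

test_that("mismatched positions violate the test_dmc contract", {
  a <- data.frame(chrom = "c", pos = 1L, strand = "+", context = "CG",
                  meth_reads = 1L, coverage = 10L)
  b <- a; b$pos <- 2L
  expect_error(test_dmc(a, b))
})

test_that("call_dmcs joins on position and applies the coverage filter", {
  a <- data.frame(chrom = "c", pos = c(1L, 2L, 3L), strand = "+",
                  context = "CG", meth_reads = c(8L, 8L, 8L),
                  coverage = c(10L, 10L, 3L))
  b <- data.frame(chrom = "c", pos = c(1L, 3L, 4L), strand = "+",
                  context = "CG", meth_reads = c(0L, 0L, 0L),
                  coverage = c(10L, 10L, 10L))
  out <- call_dmcs(a, b)
  expect_equal(out$pos, 1L)   # pos 2/4 unmatched, pos 3 under-covered
  expect_true(out$is_dmc)
})

# exact-count motif run shared by the scan tests: 5 motifs, 15 bp apart,
# strongly methylated in A and demethylated in B
perfect_run <- function(spacing = 15L, coverage = 20L) {
  pos <- 1000L + spacing * (0:4)
  exact_cyto_pair(pos,
                  level_a = c(0.9, 0.85, 0.9, 0.95, 0.9),
                  level_b = c(0.1, 0.15, 0.1, 0.05, 0.1),
                  coverage = coverage)
}

test_that("a clean run yields one DMR whose p equals the exact enumeration", {
  run <- perfect_run()
  dmrs <- call_dmrs(run$a, run$b)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(dmrs$direction, "down")
  expect_equal(dmrs$n_motifs, 5)
  expect_equal(dmrs$start, 1000)
  expect_equal(dmrs$end, 1060)
  expect_equal(dmrs$delta, mean(c(0.1, 0.15, 0.1, 0.05, 0.1)) -
                 mean(c(0.9, 0.85, 0.9, 0.95, 0.9)))
})

test_that("regions shorter than 50 bp are discarded", {
  run <- perfect_run(spacing = 10L)   # span 41 bp
  expect_equal(nrow(call_dmrs(run$a, run$b)), 0)
})

test_that("a 250 bp gap splits an otherwise perfect run", {
  pos <- c(1000L, 1015L, 1030L, 1045L, 1060L,
           1310L, 1325L, 1340L, 1355L, 1370L)   # 250 bp between motifs 5/6
  lv_a <- rep(0.9, 10); lv_b <- rep(0.1, 10)
  run <- exact_cyto_pair(pos, lv_a, lv_b)
  dmrs <- call_dmrs(run$a, run$b)
  expect_equal(nrow(dmrs), 2)
  expect_equal(dmrs$start, c(1000, 1310))
  expect_equal(dmrs$end, c(1060, 1370))
  # without the gap the same levels give a single merged region
  pos2 <- 1000L + 15L * (0:9)
  run2 <- exact_cyto_pair(pos2, lv_a, lv_b)
  dmrs2 <- call_dmrs(run2$a, run2$b)
  expect_equal(nrow(dmrs2), 1)
  expect_equal(dmrs2$n_motifs, 10)
})

test_that("extension stops at the first non-conforming motif", {
  # motifs 6-7 flip direction; the region must end at motif 5
  pos <- 1000L + 15L * (0:6)
  run <- exact_cyto_pair(pos,
                         level_a = c(rep(0.9, 5), 0.1, 0.1),
                         level_b = c(rep(0.1, 5), 0.9, 0.9))
  dmrs <- call_dmrs(run$a, run$b)
  down <- dmrs[dmrs$direction == "down", ]
  expect_equal(nrow(down), 1)
  expect_equal(down$end, 1060)
})

test_that("condition swap flips every direction and preserves p-values", {
  set.seed(51)
  pos <- sort(sample(1000:4000, 60))
  cov <- 20L
  la <- sample(0:cov, 60, replace = TRUE) / cov
  lb <- pmin(1, pmax(0, la + sample(c(-0.5, 0, 0.5), 60, TRUE,
                                    prob = c(.3, .4, .3))))
  lb <- round(lb * cov) / cov
  run <- exact_cyto_pair(pos, la, lb, coverage = cov)
  fwd <- call_dmrs(run$a, run$b)
  rev <- call_dmrs(run$b, run$a)
  expect_equal(nrow(fwd), nrow(rev))
  if (nrow(fwd)) {
    expect_equal(fwd$start, rev$start)
    expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
    expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
    expect_true(all(fwd$direction != rev$direction))
  }
})

test_that("every reported DMR satisfies all four printed constraints", {
  cfg <- sim_config(seed = 33, chromosome_length = 150000, gene_count = 0,
                    te_count = 0, coverage_mean = 30,
                    planted_dmrs = data.frame(
                      chrom = "Chr1",
                      start = c(20001L, 60001L, 100001L),
                      end = c(20300L, 60300L, 100300L),
                      context = c("CG", "CHG", "CHH"),
                      delta = c(-0.5, 0.5, 0.5)))
  mp <- generate_methylome_pair(cfg, generate_annotation(cfg))
  dmrs <- call_dmrs(mp$a, mp$b)
  expect_gt(nrow(dmrs), 0)
  expect_true(all(dmrs$end - dmrs$start + 1 >= 50))
  expect_true(all(abs(dmrs$delta) >= 0.1))
  expect_true(all(dmrs$n_motifs >= 5))
  expect_true(all(dmrs$p_value < 0.05))
  # gap rule: recheck member motifs of each region against the raw tables
  for (k in seq_len(nrow(dmrs))) {
    strand <- if (dmrs$context[k] != "CHH") "+" else
      c(watson = "+", crick = "-")[[dmrs$strand_scope[k]]]
    sel <- mp$a$context == dmrs$context[k] & mp$a$strand == strand &
      mp$a$pos >= dmrs$start[k] & mp$a$pos <= dmrs$end[k] &
      mp$a$coverage >= 4 & mp$b$coverage >= 4
    expect_true(all(diff(sort(mp$a$pos[sel])) < 200))
  }
})

test_that("CG and CHG scans use Watson only while CHH scans both strands", {
  pos <- 1000L + 15L * (0:4)
  crick <- exact_cyto_pair(pos, rep(0.9, 5), rep(0.1, 5), strand = "-",
                           context = "CG")
  expect_equal(nrow(call_dmrs(crick$a, crick$b)), 0)
  crick_chh <- exact_cyto_pair(pos, rep(0.9, 5), rep(0.1, 5), strand = "-",
                               context = "CHH")
  out <- call_dmrs(crick_chh$a, crick_chh$b)
  expect_equal(nrow(out), 1)
  expect_equal(out$strand_scope, "crick")
})

test_that("fewer than five motifs yields an empty result without error", {
  run <- exact_cyto_pair(1000L + 15L * (0:3), rep(0.9, 4), rep(0.1, 4))
  out <- call_dmrs(run$a, run$b)
  expect_equal(nrow(out), 0)
})

test_that("the sign response mode admits sub-DmC shifts that the dmc mode rejects", {
  pos <- 1000L + 15L * (0:4)
  run <- exact_cyto_pair(pos, rep(0.50, 5), rep(0.65, 5))
  # |delta| = 0.15 < 0.20: no motif is a DmC, so the default scan is silent
  expect_equal(nrow(call_dmrs(run$a, run$b)), 0)
  out <- call_dmrs(run$a, run$b,
                   params = dmr_params(response = "sign"))
  expect_equal(nrow(out), 1)
  expect_equal(out$delta, 0.15, tolerance = 1e-12)
})
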