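test_that("expression groups use boundary-literal RPKM cuts", {
  g <- expression_group(c(10, 0.1, 10.01, 0.5, 0, 1, 1.001, 200))
  expect_equal(as.character(g),
               c("intermediate", "silenced", "high", "low", "silenced",
                 "low", "intermediate", "high"))
  expect_true(is.ordered(g))
  expect_error(expression_group(-1), "non-negative")
})

test_that("metaprofile pools per bin, flips minus-strand anchors, and keeps
          empty bins missing", {
  # uniform 0.75 sites every 5 bp: flat profile
  pos <- seq(0, 400, by = 5)
  flat <- make_calls("chr1", pos, "+", "GCH", meth = 3, unmeth = 1)
  prof <- metaprofile(flat, data.table(chrom = "chr1", pos = 200L),
                      flank = 100, bin = 20)
  expect_equal(nrow(prof), 10L)
  expect_true(all(prof$level == 0.75))
  expect_equal(sum(prof$n_sites), sum(pos >= 100 & pos < 300))

  # asymmetric signal mirrors under a minus-strand anchor
  asym <- make_calls("chr1", c(90, 110), "+", "GCH",
                     meth = c(0, 8), unmeth = c(8, 0))
  anc_p <- data.table(chrom = "chr1", pos = 100L, strand = "+")
  anc_m <- data.table(chrom = "chr1", pos = 100L, strand = "-")
  pp <- metaprofile(asym, anc_p, flank = 40, bin = 20)
  pm <- metaprofile(asym, anc_m, flank = 40, bin = 20)
  expect_equal(pp$level, rev(pm$level))
  expect_equal(pp[bin_center == 10, level], 1)
  expect_equal(pp[bin_center == -10, level], 0)
  # bins without sites are NA with n = 0, never 0
  expect_true(all(is.na(pp[n_sites == 0, level])))
  expect_error(metaprofile(flat, data.table(chrom = "x", pos = 1L)[0]),
               "non-empty")
})

test_that("simulated promoters are open at the TSS and hypomethylated", {
  cfg <- sim_config(seed = 21, genome_length = 4e5, n_ndr = 0, n_genes = 60,
                    promoter_open_range = c(0.75, 0.95))
  sim <- simulate_genome(cfg)
  s <- simulate_sample(sim)
  anchors <- sim$genes[, .(chrom, pos = tss, strand)]
  gch <- metaprofile(s, anchors, "GCH", flank = 1000, bin = 50)
  core <- gch[abs(bin_center) < 150, mean(level, na.rm = TRUE)]
  flank <- gch[abs(bin_center) > 800, mean(level, na.rm = TRUE)]
  expect_gt(core, flank + 0.3)
  # endogenous methylation dips at the TSS (soma regime)
  wcg <- metaprofile(s, anchors, "WCG", flank = 1000, bin = 50)
  expect_lt(wcg[abs(bin_center) < 300, mean(level, na.rm = TRUE)],
            wcg[abs(bin_center) > 700, mean(level, na.rm = TRUE)] - 0.2)
})

test_that("protection peaks on planted nucleosome cores versus linkers", {
  cfg <- sim_config(seed = 22, genome_length = 4e5, n_ndr = 0, n_genes = 60,
                    open_prob_bg = 0.6)
  sim <- simulate_genome(cfg)
  s <- simulate_sample(sim)
  plus1 <- sim$nucleosomes[index == 1L]
  anchors <- plus1[, .(chrom, pos = (start + end) %/% 2L)]
  prof <- metaprofile(s, anchors, "GCH", flank = 200, bin = 20,
                      strand_aware = FALSE)
  core_prot <- 1 - prof[abs(bin_center) < 60, mean(level, na.rm = TRUE)]
  linker_prot <- 1 - prof[abs(bin_center) > 100, mean(level, na.rm = TRUE)]
  expect_gt(core_prot, linker_prot + 0.2)
})

test_that("promoter summaries expose both channels and handle no coverage", {
  cfg <- sim_config(seed = 23, genome_length = 1e5, n_ndr = 0, n_genes = 10,
                    promoter_open_range = c(0.9, 0.9))
  sim <- simulate_genome(cfg)
  s <- simulate_sample(sim)
  ps <- promoter_summary(sim$genes[, .(gene_id, chrom, tss)], s,
                         flank = 120)
  # promoter NDR spans TSS +/- 150 at open 0.9: expected GCH level is
  # open * efficiency plus the conversion-failure floor
  expected <- 0.9 * 0.93 + (1 - 0.9 * 0.93) * 0.013
  expect_equal(mean(ps$gch_level), expected, tolerance = 0.05)
  ghost <- promoter_summary(
    data.table(gene_id = "none", chrom = "chrZ", tss = 500L), s)
  expect_true(is.na(ghost$gch_level) && is.na(ghost$wcg_level))
})

test_that("rank correlations match hand-computed Spearman values", {
  expect_equal(expression_correlations(1:5, 1:5)$r1, 1)
  expect_equal(expression_correlations(c(1, 2, 3, 4, 5),
                                       c(2, 1, 4, 3, 5))$r1, 0.8)
  expect_error(expression_correlations(1:4, 1:4), "fewer than 5")
  # constant vector -> undefined correlation, not an error
  cc <- expression_correlations(1:6, c(2, 1, 4, 3, 6, 5), rep(0.5, 6))
  expect_true(is.na(cc$r2))
})

test_that("coupled simulation yields positive accessibility and negative
          methylation correlations with ordered groups", {
  cfg <- sim_config(seed = 24, genome_length = 8e5, n_ndr = 0,
                    n_genes = 250)
  sim <- simulate_genome(cfg)
  s <- simulate_sample(sim)
  ex <- simulate_expression(sim)
  ps <- promoter_summary(sim$genes[, .(gene_id, chrom, tss)], s)
  cc <- expression_correlations(ex$rpkm, ps$gch_level, ps$wcg_level)
  expect_gt(cc$r1, 0.5)
  expect_lt(cc$r2, -0.3)
  grp <- expression_group(ex$rpkm)
  means <- tapply(ps$gch_level, grp, mean, na.rm = TRUE)
  expect_true(all(diff(means) > 0))
  sm <- expression_sliding_mean(ex$rpkm, ps$gch_level, window = 50)
  expect_gt(utils::tail(sm$mean_signal, 1), utils::head(sm$mean_signal, 1))
})
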