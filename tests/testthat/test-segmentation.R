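test_that("genome background pools qualifying GCH counts", {
  calls <- make_calls("chr1", c(2, 6, 11), "+", rep("GCH", 3),
                      meth = c(4, 2, 0), unmeth = c(1, 3, 5))
  bg <- compute_background(calls, min_depth = 3)
  expect_equal(bg$level, 6 / 15)
  expect_equal(bg$total_meth, 6)
  expect_equal(bg$total_unmeth, 9)
  single <- make_calls("chr1", 2, "+", "GCH", 3, 7)
  expect_equal(compute_background(single)$level, 0.3)
  wcg_only <- make_calls("chr1", 2, "+", "WCG", 3, 7)
  expect_error(compute_background(wcg_only), "no GCH site")
})

test_that("window test matches the first-principles 2x2 chi-squared", {
  grid <- CJ(a = c(0L, 1L, 5L, 30L, 60L), b = c(0L, 2L, 10L, 60L),
             bgp = c(0.3, 0.5))
  grid <- grid[a + b > 0]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    bm <- round(g$bgp * 1e5); bu <- 1e5 - bm
    got <- window_chi2_test(g$a, g$b, bm, bu)
    want <- chi2_oracle(g$a, g$b, bm, bu)
    expect_equal(got$statistic, want$stat, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # direction and magnitude on extreme windows
  open <- window_chi2_test(60, 0, 5e5, 5e5)
  expect_equal(open$direction, "open")
  expect_gt(-log10(open$p_value), 5)
  closed <- window_chi2_test(0, 60, 5e5, 5e5)
  expect_equal(closed$direction, "closed")
  expect_gt(-log10(closed$p_value), 3)
  # equal proportions: statistic 0, p 1, no direction
  eq <- window_chi2_test(5, 5, 1e3, 1e3)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$direction, "none")
  # zero-depth window is skipped (undefined p)
  z <- window_chi2_test(0, 0, 1e3, 1e3)
  expect_true(is.na(z$p_value))
  expect_equal(z$direction, "none")
})

test_that("chi-squared p ordering agrees with the exact binomial per side", {
  n <- 20L; bm <- 3e5; bu <- 7e5; p0 <- bm / (bm + bu)
  for (side in list(seq(ceiling(n * p0) + 1L, n), seq(0L, floor(n * p0)))) {
    chi_p <- sapply(side, function(a)
      window_chi2_test(a, n - a, bm, bu)$p_value)
    exact_p <- sapply(side, function(a)
      stats::binom.test(a, n, p0)$p.value)
    expect_equal(order(chi_p), order(exact_p))
  }
})

# crafted run: high-openness GCH sites at 10..90, deep uniform background
.run_calls <- function() {
  bg_pos <- seq(1000, by = 10, length.out = 2000)
  make_calls("chr1",
             pos = c(seq(10, 90, by = 20), bg_pos),
             strand = "+", context = "GCH",
             meth = c(rep(50L, 5), rep(3L, length(bg_pos))),
             unmeth = c(rep(0L, 5), rep(3L, length(bg_pos))))
}

test_that("merged runs below the minimum segment length are discarded", {
  calls <- .run_calls()
  bg <- compute_background(calls)
  # the significant windows span [0, 120): shorter than 140 -> dropped
  none <- call_ndrs(calls, bg, window = 40, step = 20, score_cut = 3,
                    min_len = 140)
  expect_equal(nrow(none), 0L)
  some <- call_ndrs(calls, bg, window = 40, step = 20, score_cut = 3,
                    min_len = 120)
  expect_equal(nrow(some), 1L)
  expect_equal(some$end - some$start, 120L)
  expect_equal(some$seg_type, "NDR")
  expect_equal(some$n_windows, 5L)
})

test_that("a uniform genome yields no segments and cutoffs are monotone", {
  set.seed(9)
  n <- 3000
  uni <- make_calls("chr1", pos = sort(sample(0:60000, n)), strand = "+",
                    context = "GCH", meth = rbinom(n, 8, 0.4),
                    unmeth = 8 - rbinom(n, 8, 0.4))
  bg <- compute_background(uni)
  expect_equal(nrow(call_ndrs(uni, bg)), 0L)
  expect_equal(nrow(call_nucleosomes(uni, bg)), 0L)
  cfg <- sim_config(seed = 6, genome_length = 2e5, n_ndr = 40)
  s <- simulate_sample(simulate_genome(cfg))
  bg2 <- compute_background(s)
  n_seg <- sapply(c(2, 5, 10, 20), function(cut)
    nrow(call_ndrs(s, bg2, score_cut = cut)))
  expect_true(all(diff(n_seg) <= 0))
})

test_that("open and closed calls at one window geometry never overlap", {
  cfg <- sim_config(seed = 7, genome_length = 3e5, n_ndr = 20, n_genes = 30,
                    open_prob_bg = 0.6)
  s <- simulate_sample(simulate_genome(cfg))
  bg <- compute_background(s)
  # a single window cannot be enriched in both directions, so merged
  # opposite-direction segments at one geometry can share at most the
  # window/step straddle (window - step bp), never a full window
  ndr <- call_ndrs(s, bg, window = 40, step = 20, score_cut = 3,
                   min_len = 60)
  nuc <- call_nucleosomes(s, bg)
  expect_gt(nrow(ndr), 0L)
  expect_gt(nrow(nuc), 0L)
  ny <- nuc[, .(chrom, nstart = start, nend = end)]
  setkey(ny, chrom, nstart, nend)
  ov <- foverlaps(ndr[, .(chrom, start = start, end = end)],
                  ny, by.x = c("chrom", "start", "end"), nomatch = NULL)
  width <- pmin(ov$end, ov$nend) - pmax(ov$start, ov$nstart)
  expect_true(all(width <= 40L - 20L))
  # and segments of one type do not overlap each other
  expect_true(all(ndr[, diff(start) >= head(end - start, -1) | .N == 1,
                      by = chrom]$V1))
})

test_that("direction inversion swaps what gets called", {
  cfg <- sim_config(seed = 8, genome_length = 2e5, n_ndr = 40)
  s <- simulate_sample(simulate_genome(cfg))
  bg <- compute_background(s)
  straight <- call_ndrs(s, bg)
  inverted <- call_nucleosomes(s, bg, window = 100, step = 20,
                               score_cut = 5, min_len = 140,
                               invert_directions = TRUE)
  expect_equal(straight[, .(chrom, start, end, score)],
               inverted[, .(chrom, start, end, score)])
})

test_that("NDR proximity classification is center-to-TSS with a literal
          2 kb boundary", {
  seg <- data.table(chrom = "chr1",
                    start = c(0L, 0L, 9900L),
                    end = c(200L, 4200L, 10100L),
                    seg_type = "NDR", score = 10, n_windows = 2L)
  tss <- data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                    pos = c(2099L, 10000L))
  cl <- classify_ndrs(seg, tss)
  # centers: 100 (1,999 from g1 -> proximal), 2100 (interesting: 1 bp from
  # g1? no: |2100-2099| = 1 -> proximal), 10000 (at g2 -> proximal, 0)
  expect_equal(cl$distance, c(1999, 1, 0))
  expect_equal(cl$proximity, rep("proximal", 3))
  # exact 2,000 bp tie is distal
  seg2 <- data.table(chrom = "chr1", start = 3999L, end = 4199L,
                     seg_type = "NDR", score = 10, n_windows = 2L)
  cl2 <- classify_ndrs(seg2, tss[1])
  expect_equal(cl2$distance, 2000)
  expect_equal(cl2$proximity, "distal")
  expect_error(classify_ndrs(seg, tss[0]), "at least one TSS")
  # chromosome without a TSS -> distal at infinite distance
  seg3 <- data.table(chrom = "chrZ", start = 0L, end = 200L,
                     seg_type = "NDR", score = 10, n_windows = 2L)
  cl3 <- classify_ndrs(seg3, tss)
  expect_equal(cl3$proximity, "distal")
  expect_equal(cl3$distance, Inf)
})

test_that("identical input and parameters give byte-identical BED output", {
  cfg <- sim_config(seed = 9, genome_length = 1e5, n_ndr = 20)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  for (f in c(f1, f2)) {
    s <- simulate_sample(simulate_genome(cfg))
    write_segments_bed(call_ndrs(s), f)
  }
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  bed <- fread(f1, header = FALSE)
  expect_true(all(bed$V5 <= 1000L))
  expect_true(all(bed$V4 == "NDR"))
})
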