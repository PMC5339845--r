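# Reference sequence used throughout: contexts at known positions.
ref <- c(chr1 = "AACGTGCATTACGGCAAGCGTT")
# plus strand: C2 (ACG->WCG), C6 (GCA->GCH), C18 (GCG, excluded), ...
# minus strand: G3, G5, G12, G13, ... with their own minus-read contexts

test_that("per-site level is the methylated fraction, undefined at depth 0", {
  expect_equal(site_level(3, 1), 0.75)
  expect_equal(site_level(0, 5), 0)
  expect_equal(site_level(7, 0), 1)
  expect_true(is.na(site_level(0, 0)))
})

test_that("cytosine-report reader types rows and drops GCG/CCG", {
  idx <- build_context_index(ref)
  f <- withr::local_tempfile(fileext = ".txt")
  # one WCG row, one GCH row, one GCG row (pos 13 on + strand is GCG: CGG
  # context? use an indexed GCG site), via the index itself
  gcg <- context_sites(idx, "GCG")[1L]
  writeLines(c("chr1\t3\t+\t3\t1",                       # pos 2, WCG
               "chr1\t7\t+\t5\t5",                       # pos 6, GCH
               sprintf("chr1\t%d\t%s\t2\t2", gcg$pos + 1L, gcg$strand)),
             f)
  expect_message(calls <- read_cytosine_report(f, idx), "GCG/CCG")
  expect_s3_class(calls, "nome_calls")
  expect_equal(nrow(calls$sites), 2L)
  expect_equal(as.character(sort(calls$sites$context)), c("WCG", "GCH"))
  expect_equal(calls$sites[pos == 2L, meth], 3L)
})

test_that("reader handles empty files, bad rows, and duplicates", {
  idx <- build_context_index(ref)
  f <- withr::local_tempfile(fileext = ".txt")
  file.create(f)
  expect_equal(nrow(read_cytosine_report(f, idx)$sites), 0L)

  writeLines("chr1\t3\t+\t-1\t1", f)
  expect_error(read_cytosine_report(f, idx), "malformed")

  writeLines("chr1\t999\t+\t1\t1", f)
  expect_error(read_cytosine_report(f, idx), "off chromosome")

  writeLines(c("chr1\t3\t+\t3\t1", "chr1\t3\t+\t1\t0"), f)
  expect_warning(calls <- read_cytosine_report(f, idx), "duplicate")
  expect_equal(calls$sites[pos == 2L, .(meth, unmeth)],
               data.table(meth = 4L, unmeth = 1L))

  # rows at positions absent from the index are dropped with a message
  writeLines(c("chr1\t3\t+\t3\t1", "chr1\t1\t+\t1\t1"), f)
  expect_message(calls <- read_cytosine_report(f, idx), "not present")
  expect_equal(nrow(calls$sites), 1L)
})

test_that("coverage dialect is auto-detected and strand recovered", {
  idx <- build_context_index(ref)
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t3\t3\t75\t3\t1",       # pos 2, + strand WCG
               "chr1\t4\t4\t100\t2\t0"),     # pos 3, - strand site
             f)
  calls <- read_cytosine_report(f, idx)
  expect_equal(nrow(calls$sites), 2L)
  expect_equal(calls$sites[pos == 2L, strand], "+")
  expect_equal(calls$sites[pos == 3L, strand], "-")
})

test_that("cytosine report writing round-trips through the reader", {
  cfg <- sim_config(seed = 11, genome_length = 2e4, n_ndr = 5)
  sim <- simulate_genome(cfg)
  s <- simulate_sample(sim)
  f <- withr::local_tempfile(fileext = ".txt")
  write_cytosine_report(s, f)
  back <- read_cytosine_report(f, sim$context_index,
                               sample_id = s$sample_id)
  expect_equal(back$sites[order(chrom, pos, strand),
                          .(chrom, pos, strand, meth, unmeth)],
               s$sites[order(chrom, pos, strand),
                       .(chrom, pos, strand, meth, unmeth)])
})

test_that("region levels pool counts, not per-site means", {
  calls <- make_calls(chrom = "chr1", pos = c(2, 6), strand = "+",
                      context = c("GCH", "GCH"),
                      meth = c(2, 8), unmeth = c(2, 0))
  r <- region_level(calls, "chr1", 0, 17, "GCH", min_depth = 3)
  expect_equal(r$level, 10 / 12)
  expect_equal(r$n_sites, 2L)
  # one site of depth 2 under min_depth 3 is undefined, not zero
  shallow <- make_calls("chr1", 2, "+", "GCH", 1, 1)
  r2 <- region_level(shallow, "chr1", 0, 17, "GCH", min_depth = 3)
  expect_true(is.na(r2$level))
  expect_equal(r2$n_sites, 0L)
  # a common per-site proportion survives pooling regardless of depths
  eq <- make_calls("chr1", c(2, 6, 11), "+", rep("GCH", 3),
                   meth = c(3, 6, 30), unmeth = c(1, 2, 10))
  expect_equal(region_level(eq, "chr1", 0, 17, "GCH")$level, 0.75)
})

test_that("pooling is consistent over disjoint regions and depth filter is
          monotone", {
  set.seed(42)
  n <- 50
  calls <- make_calls("chr1", pos = seq(0, by = 7, length.out = n),
                      strand = "+", context = "GCH",
                      meth = rbinom(n, 10, 0.4),
                      unmeth = 10 - rbinom(n, 10, 0.4))
  whole <- region_level(calls, "chr1", 0, 400, "GCH")
  parts <- region_levels(calls, data.table(
    chrom = "chr1", start = c(0L, 200L), end = c(200L, 400L)), "GCH")
  expect_equal(whole$pooled_meth, sum(parts$pooled_meth))
  expect_equal(whole$pooled_unmeth, sum(parts$pooled_unmeth))
  expect_equal(whole$level,
               sum(parts$pooled_meth) /
                 (sum(parts$pooled_meth) + sum(parts$pooled_unmeth)))
  n_used <- sapply(1:8, function(d)
    region_level(calls, "chr1", 0, 400, "GCH", min_depth = d)$n_sites)
  expect_true(all(diff(n_used) <= 0))
})

test_that("genome WCG means order FGC below soma as generated", {
  cfg <- sim_config(seed = 2, genome_length = 1e5, n_ndr = 0)
  sim <- simulate_genome(cfg)
  fgc <- simulate_sample(sim, cell_type = "fgc", seed = 10)
  soma <- simulate_sample(sim, cell_type = "soma", seed = 11)
  expect_equal(genome_mean_level(
    make_calls("chr1", c(1, 5), "+", "WCG", c(4, 6), c(0, 0))), 1)
  expect_lt(genome_mean_level(fgc, "WCG"), genome_mean_level(soma, "WCG"))
})
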