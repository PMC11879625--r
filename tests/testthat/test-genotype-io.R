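test_that("all-sites VCF parsing keeps invariant records and classifies genotypes", {
  f <- write_toy_vcf(c(
    vcf_row(pos = 100, alt = ".", calls = "0/0:60:20"),
    vcf_row(pos = 101, alt = ".", calls = "0/0:60:20"),
    vcf_row(pos = 102, alt = "T", calls = "0/1:60:20")))
  s <- read_sites(f)
  expect_equal(n_sites(s), 3L)
  expect_equal(unname(s$gt[, "s1"]), c("hom_ref", "hom_ref", "het"))
  expect_equal(s$alt, c(".", ".", "T"))
  expect_false(any(s$multiallelic))

  # ./. call, hom_alt, multiallelic het
  f2 <- write_toy_vcf(c(
    vcf_row(pos = 10, alt = "T", calls = "./."),
    vcf_row(pos = 11, alt = "T", calls = "1/1:60:20"),
    vcf_row(pos = 12, alt = "T,G", calls = "1/2:60:20")))
  s2 <- read_sites(f2)
  expect_equal(unname(s2$gt[, 1]), c("missing", "hom_alt", "het"))
  expect_true(is.na(s2$gq[1, 1]))
  expect_equal(s2$multiallelic, c(FALSE, FALSE, TRUE))

  # empty body, valid header
  s3 <- read_sites(write_toy_vcf(character(0)))
  expect_equal(n_sites(s3), 0L)
})

test_that("malformed VCF records error with a line number", {
  f <- write_toy_vcf(c(vcf_row(pos = 1), "chr1\t2\tbroken"))
  expect_error(read_sites(f), "line 7")
  f2 <- tempfile(fileext = ".vcf")
  writeLines("not a vcf", f2)
  expect_error(read_sites(f2), "header")
})

test_that("the four filter rules act at site and genotype level", {
  cfg <- filter_config()
  # QUAL below 20 drops the whole site
  low_q <- read_sites(write_toy_vcf(vcf_row(pos = 5, qual = 19)))
  expect_equal(n_sites(apply_filters(low_q, cfg)), 0L)
  # QUAL 30 with GQ 19: site kept, call set missing
  low_gq <- read_sites(write_toy_vcf(vcf_row(pos = 5, qual = 30,
                                             calls = "0/0:19:20")))
  out <- apply_filters(low_gq, cfg)
  expect_equal(n_sites(out), 1L)
  expect_equal(unname(out$gt[1, 1]), "missing")

  # six records: one failing each rule, two clean; the two clean records
  # are the only ones retained with an intact call
  f <- write_toy_vcf(c(
    vcf_row(pos = 1, qual = 10),                      # site qual
    vcf_row(pos = 2, calls = "0/0:60:100"),           # mean depth 100 > 30
    vcf_row(pos = 3, calls = "0/0:10:20"),            # GQ 10 < 20
    vcf_row(pos = 4, calls = "0/0:60:2"),             # DP 2 < 5
    vcf_row(pos = 5),
    vcf_row(pos = 6, alt = "T", calls = "0/1:60:20")))
  out <- apply_filters(read_sites(f), cfg)
  expect_equal(out$pos, 3:6)
  expect_equal(unname(out$gt[, 1]),
               c("missing", "missing", "hom_ref", "het"))
  log <- attr(out, "filter_log")
  expect_equal(log$dropped_site_qual, 1L)
  expect_equal(log$dropped_mean_dp, 1L)
  expect_equal(log$masked_gq, 1L)
  expect_equal(log$masked_dp, 1L)
})

test_that("mean-depth rule averages over non-missing calls and missing GQ/DP fails a call", {
  # two samples: DP 50 and 8 -> mean 29 < 30, kept; DP 50 alone -> dropped
  f <- write_toy_vcf(c(
    vcf_row(pos = 1, calls = paste("0/0:60:50", "0/0:60:8", sep = "\t")),
    vcf_row(pos = 2, calls = paste("0/0:60:50", "./.", sep = "\t"))),
    samples = c("a", "b"))
  out <- apply_filters(read_sites(f))
  expect_equal(out$pos, 1L)
  # a called genotype with undefined GQ/DP is conservatively set missing
  f2 <- write_toy_vcf("chr1\t1\t.\tA\t.\t50\t.\t.\tGT\t0/0")
  out2 <- apply_filters(read_sites(f2))
  expect_equal(unname(out2$gt[1, 1]), "missing")
})

test_that("filtering is idempotent", {
  sim <- simulate_genotypes(1e4, c(chr1 = 3e4), seed = 5, sample = "s1")
  once <- apply_filters(as_genotype_sites(sim))
  twice <- apply_filters(once)
  attr(once, "filter_log") <- attr(twice, "filter_log") <- NULL
  expect_identical(unclass(once), unclass(twice))
})

test_that("callable mask merges runs and matches a per-position oracle", {
  pos <- c(1:100, 201:300)
  gs <- genotype_sites(rep("chr1", 200), pos, rep(50, 200), rep(".", 200),
                       matrix("hom_ref", 200, 1), matrix(60, 200, 1),
                       matrix(20, 200, 1), "s1")
  m <- build_callable_mask(gs, c(chr1 = 400))
  expect_equal(m$s1$start, c(0, 200))
  expect_equal(m$s1$end, c(100, 300))
  expect_equal(unname(callable_length(m)), 200)

  # no genotyped sites -> empty mask
  gs0 <- genotype_sites("chr1", 1, 50, ".", matrix("missing", 1, 1),
                        matrix(NA_real_, 1, 1), matrix(NA_real_, 1, 1), "s1")
  expect_equal(nrow(build_callable_mask(gs0, c(chr1 = 10))$s1), 0L)

  # random sparse genome vs brute-force scan, and length conservation
  set.seed(42)
  for (rep in 1:5) {
    p <- sort(sample.int(500, 80))
    gt <- sample(c("hom_ref", "het", "missing"), 80, replace = TRUE)
    gs <- genotype_sites(rep("chr1", 80), p, rep(50, 80), rep(".", 80),
                         matrix(gt, 80, 1), matrix(60, 80, 1),
                         matrix(20, 80, 1), "s1")
    m <- build_callable_mask(gs, c(chr1 = 500))$s1
    o <- oracle_mask_intervals(p[gt != "missing"], 500)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
    expect_equal(sum(m$end - m$start), sum(gt != "missing"))
  }
  # unsorted input errors
  gs_bad <- genotype_sites(rep("chr1", 2), c(5, 2), c(50, 50), c(".", "."),
                           matrix("hom_ref", 2, 1), matrix(60, 2, 1),
                           matrix(20, 2, 1), "s1")
  expect_error(build_callable_mask(gs_bad, c(chr1 = 10)), "sorted")
})

test_that("VCF writing round-trips genotypes, QUAL and contig lengths", {
  sim <- simulate_genotypes(5e3, c(chrA = 2e4, chrB = 1e4), seed = 9,
                            sample = "ind")
  gs <- as_genotype_sites(sim)
  f <- tempfile(fileext = ".vcf")
  write_sites_vcf(gs, f, c(chrA = 2e4, chrB = 1e4))
  back <- read_sites(f)
  expect_identical(back$gt, gs$gt)
  expect_equal(back$qual, gs$qual)
  expect_equal(attr(back, "contig_lengths"), c(chrA = 2e4, chrB = 1e4))
  # GQ/DP agree wherever the genotype is called
  called <- gs$gt != "missing"
  expect_equal(back$gq[called], gs$gq[called])
  expect_equal(back$dp[called], gs$dp[called])
})
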