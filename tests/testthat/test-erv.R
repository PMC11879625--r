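toy_erv <- function(pos, family, divergence, assess = 0,
                    filter_status = "PASS", chrom = "chr1",
                    gt = NULL, n_samples = 4) {
  n <- length(pos)
  if (is.null(gt))
    gt <- matrix("hom_ref", n, n_samples,
                 dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  erv_calls(chrom = chrom, pos = pos, family = family,
            divergence = divergence,
            assess = rep_len(assess, n),
            filter_status = rep_len(filter_status, n), gt = gt)
}

test_that("overlapping calls collapse to the most similar consensus", {
  # within 100 bp, different families: lower divergence wins
  calls <- toy_erv(c(1000, 1050), c("A", "B"), c(5, 8))
  out <- resolve_overlaps(calls)
  expect_equal(out$family, "A")
  # 300 bp apart: both kept
  out2 <- resolve_overlaps(toy_erv(c(1000, 1300), c("A", "B"), c(5, 8)))
  expect_equal(nrow(out2), 2L)
  # same family: untouched even when adjacent
  out3 <- resolve_overlaps(toy_erv(c(1000, 1050), c("A", "A"), c(5, 8)))
  expect_equal(nrow(out3), 2L)
  # transitive chain 0-80-160: single cluster, one survivor
  out4 <- resolve_overlaps(toy_erv(c(100, 180, 260), c("A", "B", "C"),
                                   c(9, 3, 7)))
  expect_equal(out4$family, "B")
  # divergence tie breaks by earlier position
  out5 <- resolve_overlaps(toy_erv(c(500, 560), c("B", "A"), c(4, 4)))
  expect_equal(out5$pos, 500L)
  expect_error(resolve_overlaps(toy_erv(c(50, 10), c("A", "B"), c(1, 2))),
               "sorted")
})

test_that("overlap resolution matches the all-pairs clustering oracle", {
  for (s in c(1, 2, 3)) {
    calls <- random_erv_calls(200, seed = s)
    out <- resolve_overlaps(calls)
    keep <- oracle_overlap_keep(calls, 100)
    expect_equal(out$pos, calls$pos[keep])
    expect_equal(out$family, calls$family[keep])
  }
})

test_that("evidence filters remove ASSESS, FILTER and missingness failures", {
  gt16 <- function(n_missing) {
    g <- rep("hom_ref", 16)
    if (n_missing > 0) g[seq_len(n_missing)] <- "missing"
    matrix(g, 1, 16, dimnames = list(NULL, paste0("s", 1:16)))
  }
  # ASSESS = 3 is removed (flag >= 3 means imprecise breakpoint)
  c1 <- toy_erv(100, "A", 5, assess = 3, n_samples = 16)
  expect_equal(nrow(filter_erv_calls(c1)), 0L)
  # 5 of 16 genotypes missing = 0.3125 > 0.25 -> removed
  c2 <- toy_erv(100, "A", 5, gt = gt16(5))
  expect_equal(nrow(filter_erv_calls(c2)), 0L)
  # 4 of 16 = 0.25 is not "greater than 25%" -> kept
  c3 <- toy_erv(100, "A", 5, gt = gt16(4))
  expect_equal(nrow(filter_erv_calls(c3)), 1L)

  # ten calls built to fail one rule each, seven survivors
  calls <- toy_erv(pos = seq(1000, 10000, by = 1000),
                   family = rep("A", 10), divergence = 1:10,
                   assess = c(4, rep(0, 9)),
                   filter_status = c("PASS", "lc", rep("PASS", 8)),
                   gt = do.call(rbind, c(list(gt16(0), gt16(0), gt16(6)),
                                         rep(list(gt16(0)), 7))))
  out <- filter_erv_calls(calls)
  expect_equal(nrow(out), 7L)
  log <- attr(out, "filter_log")
  expect_equal(log$removed_assess, 1L)
  expect_equal(log$removed_filter, 1L)
  expect_equal(log$removed_missing, 1L)
})

test_that("homozygous non-reference counts are raw hom_alt tallies", {
  gt <- matrix(c("hom_alt", "hom_alt", "hom_alt", "het", "het", "missing",
                 rep("hom_ref", 6)), 6, 2,
               dimnames = list(NULL, c("a", "b")))
  calls <- toy_erv(seq(1000, 6000, by = 1000), rep("A", 6), 1:6, gt = gt)
  res <- count_hom_nonref(calls)
  expect_equal(res$n_hom_nonref, c(3L, 0L))
  expect_equal(res$n_polymorphic_total, c(6L, 6L))
  expect_equal(count_hom_nonref(calls, "b")$n_hom_nonref, 0L)
  expect_error(count_hom_nonref(calls, "nope"), "unknown sample")
})

test_that("filter order commutes with overlap resolution on isolated failures", {
  # evidence failures restricted to calls outside overlap clusters: the two
  # processing orders must then give the same survivors
  calls <- random_erv_calls(150, seed = 9)
  calls$divergence <- calls$divergence + seq_len(150) * 1e-6 # break ties
  d_prev <- c(Inf, diff(calls$pos))
  d_next <- c(diff(calls$pos), Inf)
  same_prev <- c(FALSE, calls$chrom[-1] == calls$chrom[-150])
  same_next <- c(calls$chrom[-1] == calls$chrom[-150], FALSE)
  clustered <- (same_prev & d_prev <= 100) | (same_next & d_next <= 100)
  calls$assess[clustered] <- 0L
  calls$filter_status[clustered] <- "PASS"
  gt <- attr(calls, "gt")
  gt[clustered, ] <- "hom_ref"
  attr(calls, "gt") <- gt
  a <- filter_erv_calls(resolve_overlaps(calls))
  b <- resolve_overlaps(filter_erv_calls(calls))
  expect_identical(attr(a, "gt"), attr(b, "gt"))
  attr(a, "filter_log") <- attr(b, "filter_log") <- NULL
  attr(a, "gt") <- attr(b, "gt") <- NULL
  expect_equal(a, b)
})

test_that("retained calls are monotone in the missingness threshold", {
  calls <- random_erv_calls(300, seed = 13)
  fracs <- c(0, 0.25, 0.5, 1)
  kept <- vapply(fracs, function(f)
    nrow(filter_erv_calls(calls, erv_filter_config(max_missing_fraction = f))),
    numeric(1))
  expect_true(all(diff(kept) >= 0))
  homs <- vapply(fracs, function(f) sum(count_hom_nonref(
    filter_erv_calls(calls,
                     erv_filter_config(max_missing_fraction = f)))$n_hom_nonref),
    numeric(1))
  expect_true(all(diff(homs) >= 0))
})

test_that("deleterious insertions fix more often in small populations", {
  ne <- c(small = 500, big = 50000)
  res <- sapply(1:5, function(s) {
    out <- simulate_erv(ne, erv_sim_config(n_loci = 2000), seed = s)
    out$truth$expected_hom_nonref
  })
  expect_gt(mean(res["small", ]), mean(res["big", ]))
})

test_that("MELT-style VCF writing and reading round-trips calls", {
  calls <- random_erv_calls(50, seed = 31)
  f <- tempfile(fileext = ".vcf")
  write_erv_vcf(calls, f)
  back <- read_erv_vcf(f)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$family, calls$family)
  expect_equal(back$divergence, calls$divergence, tolerance = 1e-4)
  expect_equal(back$assess, calls$assess)
  expect_equal(back$filter_status, calls$filter_status)
  expect_identical(attr(back, "gt"), attr(calls, "gt"))
})
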