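small_cfg <- function(seed = 11L)
  archipelago_config(
    islands = data.frame(sample = c("a", "b", "c", "d", "e"),
                         island = paste0("isl_", 1:5),
                         group = "g",
                         area_km2 = c(10, 50, 200, 1000, 4000)),
    genome = c(chr1 = 2e5, chr2 = 1e5),
    erv = erv_sim_config(n_loci = 500, generations = 1500),
    master_seed = seed)

test_that("derived seeds are deterministic, distinct and valid", {
  s1 <- derive_seed(1, "geno", "ind01")
  expect_identical(s1, derive_seed(1, "geno", "ind01"))
  expect_false(s1 == derive_seed(1, "geno", "ind02"))
  expect_false(s1 == derive_seed(2, "geno", "ind01"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("the sparse tallies equal the full VCF pipeline on every island", {
  sim <- simulate_archipelago(small_cfg())
  for (id in c("a", "c", "e")) {
    g <- sim$genomes[[id]]
    f <- tempfile(fileext = ".vcf")
    write_sites_vcf(as_genotype_sites(g), f, g$genome)
    filt <- apply_filters(read_sites(f))
    w_vcf <- tally_windows(filt, make_windows(g$genome, 25000), id)
    w_sparse <- sim_window_tallies(g, 25000)
    expect_equal(as.numeric(w_vcf$n_genotyped),
                 as.numeric(w_sparse$n_genotyped))
    expect_equal(as.numeric(w_vcf$n_het), as.numeric(w_sparse$n_het))
  }
})

test_that("the filter stage recovers the planted pass/fail labels exactly", {
  sim <- simulate_genotypes(2e4, c(chr1 = 1.5e5), seed = 99, sample = "s1")
  f <- tempfile(fileext = ".vcf")
  write_sites_vcf(as_genotype_sites(sim), f, c(chr1 = 1.5e5))
  filt <- apply_filters(read_sites(f))
  planted <- sim$fails$chr1
  # dropped records = exactly the planted site-level failures
  dropped <- setdiff(seq_len(1.5e5), filt$pos)
  expect_identical(dropped, sort(c(planted$site_qual, planted$mean_dp)))
  # missing calls among retained records = planted masks + planted missing
  masked <- filt$pos[filt$gt[, 1] == "missing"]
  expect_identical(sort(masked),
                   sort(c(planted$missing, planted$gq, planted$dp)))
  # per-rule tallies agree with the generator's ground truth
  log <- attr(filt, "filter_log")
  expect_equal(log$dropped_site_qual, length(planted$site_qual))
  expect_equal(log$dropped_mean_dp, length(planted$mean_dp))
  expect_equal(log$masked_gq, length(planted$gq))
  expect_equal(log$masked_dp, length(planted$dp))
})

test_that("zero artifact rates leave nothing for the filters to remove", {
  sim <- simulate_genotypes(1e4, c(chr1 = 5e4), missing_rate = 0,
                            fail_rates = qual_fail_rates(0, 0, 0, 0),
                            seed = 2)
  filt <- apply_filters(as_genotype_sites(sim))
  log <- attr(filt, "filter_log")
  expect_equal(log$n_retained, 5e4)
  expect_equal(log$masked_gq + log$masked_dp + log$dropped_site_qual +
                 log$dropped_mean_dp, 0L)
  w <- sim_window_tallies(sim)
  expect_equal(w$n_genotyped, w$width)
})

test_that("neutral Wright-Fisher fixation converges to the initial frequency", {
  q <- wf_evolve(10000, 50, s = 0, q0 = 0.5, generations = 2000, seed = 3)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(mean(q == 1) - 0.5), 3 * se)
  expect_lt(mean(q > 0 & q < 1), 0.01)  # essentially all absorbed
  # zero generations: frequencies untouched
  expect_equal(wf_evolve(100, 50, -0.1, 0.3, 0, seed = 1), rep(0.3, 100))
  # oversize populations error unless rescaled
  expect_error(wf_evolve(10, 1e6, 0, 0.5, 1, rescale = FALSE), "cap")
})

test_that("ERV ground truth matches the pipeline's own counts", {
  out <- simulate_erv(c(a = 800, b = 20000),
                      erv_sim_config(n_loci = 800, generations = 1500),
                      seed = 5)
  kept <- filter_erv_calls(resolve_overlaps(out$calls))
  counts <- count_hom_nonref(kept)
  expect_equal(counts$n_hom_nonref,
               unname(out$truth$expected_hom_nonref[counts$sample]))
  expect_equal(nrow(kept), out$truth$n_retained)
})

test_that("scaled MSMC output with zero noise round-trips the trajectory", {
  tr <- default_trajectory(1000)
  ep <- simulate_msmc_output(tr, noise_sd = 0)
  back <- unscale_trajectory(ep)
  expect_equal(back$t_start, tr$t_start, tolerance = 1e-12)
  expect_equal(back$ne, tr$ne, tolerance = 1e-12)
  expect_equal(harmonic_mean_ne(back), harmonic_mean_ne(tr),
               tolerance = 1e-12)
})

test_that("area-to-Ne power law spans the configured range", {
  ne <- island_ne(archipelago_config())
  expect_equal(unname(range(ne)), c(1e3, 4e5))
  expect_equal(unname(ne), 100 * archipelago_config()$islands$area_km2)
})

test_that("a written archipelago is byte-identical under one seed and analyzable from disk", {
  cfg <- small_cfg(seed = 21L)
  d1 <- file.path(tempdir(), "arch1"); d2 <- file.path(tempdir(), "arch2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- build_archipelago(cfg, d1)
  m2 <- build_archipelago(cfg, d2)
  expect_identical(m1$md5, m2$md5)
  expect_error(build_archipelago(cfg, d1), "overwrite")

  res_disk <- analyze_archipelago_dir(d1)
  res_mem <- analyze_archipelago(simulate_archipelago(cfg))
  expect_equal(res_disk$table$genome_het, res_mem$table$genome_het,
               tolerance = 1e-12)
  expect_equal(res_disk$table$roh_total_bp, res_mem$table$roh_total_bp)
  expect_equal(res_disk$table$erv_hom_nonref, res_mem$table$erv_hom_nonref)
  expect_equal(res_disk$table$harmonic_ne, res_mem$table$harmonic_ne,
               tolerance = 1e-9)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mean ROH length decreases with island Ne across replicate archipelagos", {
  ne <- c(1e3, 5e3, 2e4, 1e5, 4e5)
  totals <- sapply(1:10, function(s) {
    vapply(seq_along(ne), function(i) {
      g <- simulate_genotypes(ne[i], c(chr1 = 1e6),
                              seed = derive_seed(100L + s, "roh", i))
      w <- sim_window_tallies(g)
      summarize_roh(merge_segments(call_roh_windows(w)),
                    sum(w$n_genotyped))$total_length_bp
    }, numeric(1))
  })
  avg <- rowMeans(totals)   # ordered by increasing Ne
  expect_true(all(diff(avg) <= 0))
})
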