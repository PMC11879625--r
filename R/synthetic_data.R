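# Synthetic archipelago with known ground truth.
#
# The generator emulates the study design the pipeline targets: one diploid
# individual sequenced per island, island area acting as a proxy for
# effective population size. Genotypes follow a tract-based pairwise-TMRCA
# model: the genome is split into exponential-length tracts, each tract
# draws a pairwise coalescence time T ~ Exp(rate 1/(2 Ne)) generations, and
# heterozygous sites fall within the tract at per-site probability
# min(2 mu_g T, 1) — so genome-wide expected heterozygosity is
# theta = 4 Ne mu_g, and low-T tracts produce multi-window runs of
# homozygosity. Quality, depth and missingness failures are planted at
# known positions so the filter stage can be checked against ground truth
# exactly. ERV insertion polymorphisms drift under Wright-Fisher sampling
# with genic selection, and demographic trajectories are written in the
# scaled MSMC2 output format.

#' Derive a deterministic sub-stream seed
#'
#' Stable hash of the master seed plus a stream label, kept below 2^31 so
#' it is a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param ... stream labels (island id, component name, replicate number).
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  label <- paste(c(master_seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

#' Per-rule quality failure rates for the genotype simulator
#'
#' @param site_qual fraction of sites planted with QUAL below threshold.
#' @param mean_dp fraction planted with excessive depth (site dropped).
#' @param gq fraction of calls planted with low genotype quality.
#' @param dp fraction of calls planted with low depth.
#' @return Named numeric vector.
#' @export
qual_fail_rates <- function(site_qual = 0.01, mean_dp = 0.005, gq = 0.02,
                            dp = 0.02) {
  r <- c(site_qual = site_qual, mean_dp = mean_dp, gq = gq, dp = dp)
  stopifnot(all(r >= 0 & r <= 1))
  r
}

#' Simulate an all-sites diploid genome for one island individual
#'
#' @param ne diploid effective population size of the island.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param mu_g per-generation mutation rate per site.
#' @param tract_mean_bp mean TMRCA-tract length (default 50 kbp).
#' @param missing_rate fraction of positions with an uncalled genotype.
#' @param fail_rates per-rule planted failure rates, see
#'   [qual_fail_rates()].
#' @param seed integer seed.
#' @param sample sample id.
#' @return A `sim_genome` object: tract table, heterozygous positions,
#'   planted failure positions per rule, and the ground-truth theta.
#' @export
simulate_genotypes <- function(ne, genome, mu_g = 3.16e-9,
                               tract_mean_bp = 50000, missing_rate = 0.02,
                               fail_rates = qual_fail_rates(),
                               seed = 1L, sample = "ind01") {
  stopifnot(ne > 0, all(genome > 0), !is.null(names(genome)),
            missing_rate >= 0, missing_rate <= 1)
  if (tract_mean_bp <= 0) stop("tract_mean_bp must be positive")
  set.seed(seed)
  het_pos <- list(); fails <- list(); tracts <- list()
  rules <- c("site_qual", "mean_dp", "missing", "gq", "dp")
  rates <- c(fail_rates[c("site_qual", "mean_dp")],
             missing = unname(missing_rate), fail_rates[c("gq", "dp")])
  for (ch in names(genome)) {
    L <- genome[[ch]]
    # tract boundaries: exponential lengths truncated at the chromosome end
    n_guess <- ceiling(L / tract_mean_bp * 1.5) + 20
    lens <- stats::rexp(n_guess, rate = 1 / tract_mean_bp)
    while (sum(lens) < L)
      lens <- c(lens, stats::rexp(n_guess, rate = 1 / tract_mean_bp))
    ends <- pmin(ceiling(cumsum(lens)), L)
    ends <- unique(ends[seq_len(which(ends == L)[1L])])
    starts <- c(0, ends[-length(ends)])
    tl <- ends - starts
    tmrca <- stats::rexp(length(tl), rate = 1 / (2 * ne))
    p_het <- pmin(2 * mu_g * tmrca, 1)
    n_het <- stats::rbinom(length(tl), tl, p_het)
    hp <- unlist(lapply(which(n_het > 0), function(i)
      starts[i] + sample.int(tl[i], n_het[i])), use.names = FALSE)
    het_pos[[ch]] <- sort(as.integer(hp))
    tracts[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                               tmrca = tmrca)
    # planted failures: independent draws per rule, deduplicated with a
    # fixed precedence so every position has exactly one ground-truth label
    drawn <- lapply(rules, function(r)
      sort(sample.int(L, stats::rbinom(1L, L, rates[[r]]))))
    names(drawn) <- rules
    seen <- integer(0)
    for (r in rules) {
      drawn[[r]] <- setdiff(drawn[[r]], seen)
      seen <- c(seen, drawn[[r]])
    }
    fails[[ch]] <- drawn
  }
  structure(list(sample = sample, ne = ne, mu_g = mu_g, genome = genome,
                 tract_mean_bp = tract_mean_bp,
                 tracts = do.call(rbind, tracts),
                 het_pos = het_pos, fails = fails,
                 theta = 4 * ne * mu_g),
            class = "sim_genome")
}

#' @exportS3Method base::print
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome '%s': %d chrom(s), %.3g bp, Ne = %g, theta = %.3g\n",
              x$sample, length(x$genome), sum(x$genome), x$ne, x$theta))
  invisible(x)
}

# union of all planted failure positions (site drops, masks, missing) per
# chromosome: post-filter these positions carry no genotype
sim_removed_pos <- function(sim) {
  lapply(sim$fails, function(f) sort(unique(unlist(f, use.names = FALSE))))
}

#' Materialize a simulated genome as explicit per-position records
#'
#' Expands the sparse simulation into a [genotype_sites()] object with one
#' record per position, with QUAL/GQ/DP values constructed so each planted
#' failure trips exactly its intended filter rule (QUAL 10 vs minimum 20,
#' GQ 10 vs 20, DP 2 vs minimum 5, DP 60 vs mean-depth maximum 30; passing
#' records carry QUAL 50, GQ 60, DP 20). Intended for small genomes; the
#' windowed fast path ([sim_window_tallies()]) covers large ones.
#'
#' @param sim a `sim_genome` object.
#' @param max_sites refuse to materialize more than this many records.
#' @return A `genotype_sites` object.
#' @export
as_genotype_sites <- function(sim, max_sites = 5e6) {
  stopifnot(inherits(sim, "sim_genome"))
  if (sum(sim$genome) > max_sites)
    stop("genome too large to materialize; use sim_window_tallies()")
  per_chrom <- lapply(names(sim$genome), function(ch) {
    L <- sim$genome[[ch]]
    f <- sim$fails[[ch]]
    qual <- rep(50, L); qual[f$site_qual] <- 10
    gq <- rep(60, L); gq[f$gq] <- 10
    dp <- rep(20, L); dp[f$dp] <- 2; dp[f$mean_dp] <- 60
    gt <- rep("hom_ref", L)
    gt[sim$het_pos[[ch]]] <- "het"
    gt[f$missing] <- "missing"
    alt <- rep(".", L); alt[sim$het_pos[[ch]]] <- "T"
    list(chrom = rep(ch, L), pos = seq_len(L), qual = qual, alt = alt,
         gt = gt, gq = gq, dp = dp)
  })
  cat1 <- function(fld) unlist(lapply(per_chrom, `[[`, fld), use.names = FALSE)
  genotype_sites(chrom = cat1("chrom"), pos = cat1("pos"),
                 qual = cat1("qual"), alt = cat1("alt"),
                 gt = matrix(cat1("gt"), ncol = 1),
                 gq = matrix(cat1("gq"), ncol = 1),
                 dp = matrix(cat1("dp"), ncol = 1), samples = sim$sample)
}

#' Post-filter window tallies straight from the sparse simulation
#'
#' Computes the same per-window `n_genotyped` / `n_het` counts that reading
#' the simulated VCF and running [apply_filters()] + [tally_windows()]
#' yields, without materializing per-position records: every position is
#' genotyped except the planted failures, and a heterozygous site counts
#' only if its call survives filtering.
#'
#' @param sim a `sim_genome` object.
#' @param width window width in bp.
#' @return Tallied window data frame (as from [tally_windows()]).
#' @export
sim_window_tallies <- function(sim, width = 25000) {
  stopifnot(inherits(sim, "sim_genome"))
  w <- make_windows(sim$genome, width)
  removed <- sim_removed_pos(sim)
  het_eff <- lapply(names(sim$genome), function(ch)
    setdiff(sim$het_pos[[ch]], removed[[ch]]))
  names(het_eff) <- names(sim$genome)
  cnt <- tally_positions(w, removed, het_eff)
  w$n_genotyped <- w$width - cnt$n_genotyped
  w$n_het <- cnt$n_het
  w
}

#' Wright-Fisher allele-frequency evolution for insertion loci
#'
#' Each locus starts at frequency `q0` and evolves by binomial sampling of
#' `2 ne` gametes per generation under genic selection `s` against the
#' insertion allele. Populations larger than `wf_cap` are rescaled to the
#' cap with `s` scaled up to keep `2 ne s` constant, preserving the
#' selection-drift balance at desk scale.
#'
#' @param n_loci number of independent loci.
#' @param ne diploid population size.
#' @param s selection coefficient of the insertion allele (<= 0 when
#'   deleterious).
#' @param q0 initial insertion frequency.
#' @param generations number of WF generations.
#' @param wf_cap maximum simulated population size (default 10,000).
#' @param rescale rescale `ne > wf_cap` populations (default `TRUE`);
#'   when `FALSE`, oversize populations are an error.
#' @param seed integer seed.
#' @return Numeric vector of final insertion frequencies.
#' @export
wf_evolve <- function(n_loci, ne, s, q0, generations, wf_cap = 10000,
                      rescale = TRUE, seed = 1L) {
  stopifnot(q0 >= 0, q0 <= 1, generations >= 0, n_loci >= 1, ne >= 1)
  if (ne > wf_cap) {
    if (!rescale)
      stop("2*ne exceeds the Wright-Fisher cap; rescale to wf_cap ",
           "(keeping 2*ne*s constant) or raise wf_cap")
    s <- s * ne / wf_cap
    ne <- wf_cap
  }
  set.seed(seed)
  two_n <- round(2 * ne)
  q <- rep(q0, n_loci)
  active <- which(q > 0 & q < 1)
  for (g in seq_len(generations)) {
    if (!length(active)) break
    qa <- q[active]
    p_sel <- qa * (1 + s) / (1 + qa * s)
    q[active] <- stats::rbinom(length(active), two_n, p_sel) / two_n
    active <- active[q[active] > 0 & q[active] < 1]
  }
  q
}

#' ERV drift-selection simulation settings
#'
#' @param n_loci polymorphic insertion loci per archipelago.
#' @param s genic selection coefficient against the insertion.
#' @param q0 initial insertion frequency (shared ancestral polymorphism).
#' @param generations WF generations since islands were colonized.
#' @param wf_cap population-size cap for the WF engine, see [wf_evolve()].
#' @param assess_fail_rate fraction of loci planted with ASSESS >= 3.
#' @param filter_fail_rate fraction planted with a non-PASS FILTER.
#' @param missing_fail_rate fraction planted with > 25% missing genotypes.
#' @param dup_rate fraction of loci given a companion call from a second
#'   element family within 100 bp (exercises overlap resolution).
#' @return An `erv_sim_config` object.
#' @export
erv_sim_config <- function(n_loci = 3000, s = -1e-4, q0 = 0.2,
                           generations = 4000, wf_cap = 10000,
                           assess_fail_rate = 0.05, filter_fail_rate = 0.05,
                           missing_fail_rate = 0.03, dup_rate = 0.05) {
  stopifnot(q0 >= 0, q0 <= 1, generations >= 1, n_loci >= 1)
  structure(list(n_loci = n_loci, s = s, q0 = q0, generations = generations,
                 wf_cap = wf_cap, assess_fail_rate = assess_fail_rate,
                 filter_fail_rate = filter_fail_rate,
                 missing_fail_rate = missing_fail_rate, dup_rate = dup_rate),
            class = "erv_sim_config")
}

#' Simulate MELT-style ERV insertion polymorphisms across islands
#'
#' Loci drift independently in each island population under [wf_evolve()];
#' one diploid individual per island is then genotyped (two gametes drawn
#' at the final frequency). ASSESS, FILTER, missingness and cross-family
#' duplicate calls are planted at configured rates with the planted labels
#' recorded as ground truth.
#'
#' @param ne named numeric vector of island population sizes (names are
#'   sample ids).
#' @param cfg an [erv_sim_config()].
#' @param seed integer seed.
#' @return List: `calls` (an `erv_calls` object including planted
#'   artifacts) and `truth` (per-island fixation counts, expected
#'   post-filter hom-alt counts, and the planted keep/remove labels).
#' @export
simulate_erv <- function(ne, cfg = erv_sim_config(), seed = 1L) {
  stopifnot(!is.null(names(ne)), all(ne >= 1))
  n <- cfg$n_loci
  q <- sapply(names(ne), function(id)
    wf_evolve(n, ne[[id]], cfg$s, cfg$q0, cfg$generations, cfg$wf_cap,
              seed = derive_seed(seed, "wf", id)))
  q <- matrix(q, nrow = n, dimnames = list(NULL, names(ne)))
  set.seed(derive_seed(seed, "erv-annot"))
  copies <- matrix(stats::rbinom(length(q), 2L, q), nrow = n)
  gt <- matrix(c("hom_ref", "het", "hom_alt")[copies + 1L], nrow = n,
               dimnames = list(NULL, names(ne)))
  fixed <- colSums(q == 1)

  families <- sprintf("ERVK%02d", 1:10)
  fam <- sample(families, n, replace = TRUE)
  div <- round(stats::runif(n, 0.5, 15), 4)
  pos <- cumsum(sample(300:5000, n, replace = TRUE))
  assess <- sample(0:2, n, replace = TRUE)
  filt <- rep("PASS", n)
  plant <- function(rate) sample.int(n, round(rate * n))
  i_assess <- plant(cfg$assess_fail_rate)
  assess[i_assess] <- sample(3:5, length(i_assess), replace = TRUE)
  i_filt <- plant(cfg$filter_fail_rate)
  filt[i_filt] <- "lc"
  i_miss <- plant(cfg$missing_fail_rate)
  n_isl <- length(ne)
  n_miss_fail <- floor(0.25 * n_isl) + 1L # just over the 25% threshold
  for (i in i_miss)
    gt[i, sample.int(n_isl, n_miss_fail)] <- "missing"

  # companion calls from a second family within 100 bp, higher divergence:
  # overlap resolution must remove the companion, keep the original
  i_dup <- sort(plant(cfg$dup_rate))
  dup_fam <- vapply(fam[i_dup], function(f) sample(setdiff(families, f), 1L),
                    "")
  dup <- data.frame(pos = pos[i_dup] + sample(10:100, length(i_dup),
                                              replace = TRUE),
                    family = dup_fam,
                    divergence = round(div[i_dup] +
                                         stats::runif(length(i_dup), 2, 8), 4),
                    assess = sample(0:2, length(i_dup), replace = TRUE))

  base <- data.frame(pos = pos, family = fam, divergence = div,
                     assess = assess, filter_status = filt,
                     is_companion = FALSE, locus = seq_len(n))
  comp <- data.frame(pos = dup$pos, family = dup$family,
                     divergence = dup$divergence, assess = dup$assess,
                     filter_status = "PASS", is_companion = TRUE,
                     locus = i_dup)
  all_calls <- rbind(base, comp)
  o <- order(all_calls$pos)
  all_calls <- all_calls[o, ]
  gt_all <- gt[all_calls$locus, , drop = FALSE]
  calls <- erv_calls(chrom = "chr1", pos = all_calls$pos,
                     family = all_calls$family,
                     divergence = all_calls$divergence,
                     assess = all_calls$assess,
                     filter_status = all_calls$filter_status, gt = gt_all)
  keep_locus <- !(seq_len(n) %in% c(i_assess, i_filt, i_miss))
  truth <- list(
    q_final = q, fixed_count = fixed,
    keep_locus = keep_locus,
    is_companion = all_calls$is_companion,
    locus = all_calls$locus,
    expected_hom_nonref = colSums(gt[keep_locus, , drop = FALSE] ==
                                    "hom_alt"),
    n_retained = sum(keep_locus))
  list(calls = calls, truth = truth)
}

#' Emit a trajectory as scaled MSMC2 output
#'
#' Exact inverse of [unscale_trajectory()], with optional multiplicative
#' log-normal noise on lambda; `noise_sd = 0` round-trips exactly.
#'
#' @param trajectory real-unit trajectory (`t_start`, `t_end`, `ne`).
#' @param p a [scaling_params()].
#' @param noise_sd standard deviation of log-normal noise on lambda.
#' @param seed seed for the noise draw.
#' @param path if non-`NULL`, write an MSMC2 `.final.txt` file there.
#' @return Data frame of scaled epochs, invisibly when writing.
#' @export
simulate_msmc_output <- function(trajectory, p = scaling_params(),
                                 noise_sd = 0, seed = 1L, path = NULL) {
  scaled <- rescale_trajectory(trajectory, p)
  if (noise_sd > 0) {
    set.seed(seed)
    scaled$lambda <- scaled$lambda *
      exp(stats::rnorm(nrow(scaled), 0, noise_sd))
  }
  if (!is.null(path)) {
    utils::write.table(format(scaled, scientific = TRUE, digits = 17),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(scaled))
  }
  scaled
}

#' Default piecewise-constant trajectory for an island
#'
#' Three epochs emulating post-glacial demography: the current size `ne`
#' for the last 50 kyr, 1.5x during 50-200 kyr, and 2x beyond, so both
#' recent and harmonic-mean Ne scale linearly with `ne`.
#'
#' @param ne current effective size.
#' @return Real-unit trajectory data frame.
#' @export
default_trajectory <- function(ne) {
  data.frame(t_start = c(0, 5e4, 2e5), t_end = c(5e4, 2e5, 1e6),
             ne = ne * c(1, 1.5, 2))
}

#' Archipelago simulation settings
#'
#' The default archipelago has eight islands spanning 10-4,000 km2 with
#' effective size proportional to area (`ne = ne_c * area^ne_b`,
#' `ne_c = 100` individuals per km2, `ne_b = 1`), giving Ne from 1,000 to
#' 400,000 — so expected heterozygosity `4 Ne mu_g` spans 1.3e-5 to 5.1e-3
#' across islands.
#'
#' @param islands data frame with `sample`, `island`, `group`, `area_km2`.
#' @param ne_c,ne_b coefficients of the area-to-Ne power law.
#' @param mu_per_year mutation rate (substitutions/site/year).
#' @param generation_time_years generation time.
#' @param genome named chromosome lengths in bp.
#' @param tract_mean_bp mean TMRCA-tract length.
#' @param missing_rate,fail_rates genotype artifact rates, see
#'   [simulate_genotypes()].
#' @param erv an [erv_sim_config()].
#' @param msmc_noise_sd log-normal noise on simulated MSMC2 lambdas.
#' @param master_seed master seed; all component streams derive from it.
#' @return An `archipelago_config` object.
#' @export
archipelago_config <- function(
    islands = data.frame(
      sample = sprintf("ind%02d", 1:8),
      island = sprintf("island%02d", 1:8),
      group = rep(c("small", "mid", "large"), c(3, 2, 3)),
      area_km2 = c(10, 25, 60, 150, 400, 1000, 2200, 4000)),
    ne_c = 100, ne_b = 1,
    mu_per_year = 3.16e-9, generation_time_years = 1,
    genome = c(chr1 = 6e7, chr2 = 4e7),
    tract_mean_bp = 50000, missing_rate = 0.02,
    fail_rates = qual_fail_rates(),
    erv = erv_sim_config(), msmc_noise_sd = 0.1,
    master_seed = 1L) {
  stopifnot(all(islands$area_km2 > 0), all(genome > 0))
  structure(list(islands = islands, ne_c = ne_c, ne_b = ne_b,
                 mu_per_year = mu_per_year,
                 generation_time_years = generation_time_years,
                 genome = genome, tract_mean_bp = tract_mean_bp,
                 missing_rate = missing_rate, fail_rates = fail_rates,
                 erv = erv, msmc_noise_sd = msmc_noise_sd,
                 master_seed = as.integer(master_seed)),
            class = "archipelago_config")
}

#' True island effective sizes under a config
#' @param cfg an [archipelago_config()].
#' @return Named numeric vector (sample id -> Ne).
#' @export
island_ne <- function(cfg) {
  ne <- cfg$ne_c * cfg$islands$area_km2^cfg$ne_b
  names(ne) <- cfg$islands$sample
  ne
}

#' Simulate a full archipelago in memory
#'
#' Generates, for every island, the sparse all-sites genome, the shared
#' ERV polymorphism call set, and a noisy scaled demographic trajectory,
#' along with the ground truth needed for parameter-recovery tests.
#'
#' @param cfg an [archipelago_config()].
#' @return List of class `sim_archipelago`: `cfg`, `islands` (with true
#'   `ne`), `genomes` (per-island `sim_genome`), `erv` (calls + truth),
#'   `msmc` (per-island scaled epochs), `trajectories` (true, real units).
#' @export
simulate_archipelago <- function(cfg = archipelago_config()) {
  ne <- island_ne(cfg)
  mu_g <- cfg$mu_per_year * cfg$generation_time_years
  p <- scaling_params(cfg$mu_per_year, cfg$generation_time_years)
  genomes <- lapply(names(ne), function(id)
    simulate_genotypes(ne[[id]], cfg$genome, mu_g, cfg$tract_mean_bp,
                       cfg$missing_rate, cfg$fail_rates,
                       seed = derive_seed(cfg$master_seed, "geno", id),
                       sample = id))
  names(genomes) <- names(ne)
  erv <- simulate_erv(ne, cfg$erv, seed = derive_seed(cfg$master_seed, "erv"))
  trajectories <- lapply(ne, default_trajectory)
  msmc <- lapply(names(ne), function(id)
    simulate_msmc_output(trajectories[[id]], p, cfg$msmc_noise_sd,
                         seed = derive_seed(cfg$master_seed, "msmc", id)))
  names(msmc) <- names(ne)
  islands <- cfg$islands
  islands$ne <- ne[islands$sample]
  structure(list(cfg = cfg, islands = islands, genomes = genomes, erv = erv,
                 msmc = msmc, trajectories = trajectories),
            class = "sim_archipelago")
}

#' Run the full analysis pipeline on a simulated archipelago
#'
#' Per island: window tallies, heterozygosity summaries, the windowed ROH
#' caller, homozygous non-reference ERV counts after overlap resolution and
#' filtering, and demographic summaries from the scaled trajectories. Ends
#' with the island-size statistical layer.
#'
#' @param sim a `sim_archipelago` from [simulate_archipelago()].
#' @param width window width in bp (default 25,000).
#' @param min_frac minimum genotyped window fraction (default 0.8).
#' @param horizon_years harmonic-mean horizon (default 200,000).
#' @return List: `table` (metrics table), `stats` (regressions,
#'   correlations, LASSO), and the per-island summary data frames.
#' @export
analyze_archipelago <- function(sim, width = 25000, min_frac = 0.8,
                                horizon_years = 200000) {
  stopifnot(inherits(sim, "sim_archipelago"))
  p <- scaling_params(sim$cfg$mu_per_year, sim$cfg$generation_time_years)
  ids <- sim$islands$sample
  het <- list(); roh <- list(); nes <- list()
  for (id in ids) {
    w <- sim_window_tallies(sim$genomes[[id]], width)
    het[[id]] <- het_summary(w, id, min_frac)
    calls <- call_roh_windows(w, min_frac)
    segs <- merge_segments(calls)
    roh[[id]] <- summarize_roh(segs, sum(w$n_genotyped), id)
    traj <- unscale_trajectory(sim$msmc[[id]], p)
    nes[[id]] <- ne_summary(traj, id, horizon_years)
  }
  erv_kept <- filter_erv_calls(resolve_overlaps(sim$erv$calls))
  erv_counts <- count_hom_nonref(erv_kept)
  tab <- assemble_table(sim$islands, do.call(rbind, het),
                        do.call(rbind, roh), erv_counts,
                        do.call(rbind, nes))
  list(table = tab, stats = island_stats(tab),
       het = do.call(rbind, het), roh = do.call(rbind, roh),
       erv = erv_counts, ne = do.call(rbind, nes))
}

#' Write a simulated archipelago to disk
#'
#' Emits per-island all-sites VCFs (this materializes every position, so
#' use a desk-scale genome), the MELT-style ERV VCF, MSMC2 `.final.txt`
#' files, the island metadata CSV, a ground-truth JSON, and a manifest
#' with md5 checksums.
#'
#' @param cfg an [archipelago_config()] (keep the genome small).
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest data frame (`file`, `md5`), invisibly.
#' @export
build_archipelago <- function(cfg, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_archipelago(cfg)
  files <- character(0)
  for (id in sim$islands$sample) {
    f <- file.path(out_dir, paste0(id, ".allsites.vcf"))
    write_sites_vcf(as_genotype_sites(sim$genomes[[id]]), f, cfg$genome)
    files <- c(files, f)
    fm <- file.path(out_dir, paste0(id, ".final.txt"))
    utils::write.table(format(sim$msmc[[id]], scientific = TRUE,
                              digits = 17),
                       fm, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, fm)
  }
  fe <- file.path(out_dir, "erv.melt.vcf")
  write_erv_vcf(sim$erv$calls, fe)
  fi <- file.path(out_dir, "islands.csv")
  utils::write.csv(sim$islands, fi, row.names = FALSE)
  fg <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    ne = as.list(island_ne(cfg)),
    theta = as.list(4 * island_ne(cfg) * cfg$mu_per_year *
                      cfg$generation_time_years),
    erv_fixed = as.list(sim$erv$truth$fixed_count),
    erv_expected_hom_nonref = as.list(sim$erv$truth$expected_hom_nonref)),
    fg, auto_unbox = TRUE, digits = NA)
  files <- c(files, fe, fi, fg)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Analyze an archipelago directory written by [build_archipelago()]
#'
#' The file-based twin of [analyze_archipelago()]: reads the all-sites
#' VCFs, applies the genotype filters, and runs every downstream stage.
#'
#' @param dir directory produced by [build_archipelago()].
#' @param cfg_filters a [filter_config()].
#' @param width,min_frac,horizon_years as in [analyze_archipelago()].
#' @return Same structure as [analyze_archipelago()].
#' @export
analyze_archipelago_dir <- function(dir, cfg_filters = filter_config(),
                                    width = 25000, min_frac = 0.8,
                                    horizon_years = 200000) {
  islands <- utils::read.csv(file.path(dir, "islands.csv"))
  het <- list(); roh <- list(); nes <- list()
  for (id in islands$sample) {
    sites <- read_sites(file.path(dir, paste0(id, ".allsites.vcf")))
    filt <- apply_filters(sites, cfg_filters)
    chrom_len <- attr(sites, "contig_lengths")
    if (is.null(chrom_len))
      chrom_len <- tapply(filt$pos, filt$chrom, max)[unique(filt$chrom)]
    w <- make_windows(chrom_len, width)
    w <- tally_windows(filt, w, id)
    het[[id]] <- het_summary(w, id, min_frac)
    segs <- merge_segments(call_roh_windows(w, min_frac))
    roh[[id]] <- summarize_roh(segs, sum(w$n_genotyped), id)
    epochs <- read_msmc(file.path(dir, paste0(id, ".final.txt")))
    traj <- unscale_trajectory(epochs)
    nes[[id]] <- ne_summary(traj, id, horizon_years)
  }
  erv <- read_erv_vcf(file.path(dir, "erv.melt.vcf"))
  erv_counts <- count_hom_nonref(filter_erv_calls(resolve_overlaps(erv)))
  tab <- assemble_table(islands, do.call(rbind, het), do.call(rbind, roh),
                        erv_counts, do.call(rbind, nes))
  list(table = tab, stats = island_stats(tab),
       het = do.call(rbind, het), roh = do.call(rbind, roh),
       erv = erv_counts, ne = do.call(rbind, nes))
}
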