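# Per-individual observed heterozygosity over all genotyped sites (variant
# and invariant), tallied in fixed-width genome windows.

#' Tile a genome into fixed-width windows
#'
#' Non-overlapping windows from position 0; a trailing partial window is
#' retained and flagged `full = FALSE`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (default 25 kbp).
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `width`, `full`.
#' @export
make_windows <- function(chrom_lengths, width = 25000) {
  if (width <= 0) stop("window width must be positive")
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = ch, start = starts, end = ends,
               width = ends - starts, full = (ends - starts) == width)
  })
  do.call(rbind, out)
}

# Shared counting core: genotyped and heterozygous 1-based positions per
# chromosome are assigned to windows by integer division. Both the VCF path
# and the sparse simulator path funnel through this. Windows come from
# make_windows(), so each chromosome's windows are a contiguous row block
# tiled from 0, which lets positions map to global window indices without
# string keys.
tally_positions <- function(windows, geno_pos, het_pos) {
  win_width <- max(windows$width)
  chroms <- unique(windows$chrom)
  n_per <- as.integer(table(factor(windows$chrom, levels = chroms)))
  offset <- stats::setNames(cumsum(c(0L, n_per[-length(n_per)])), chroms)
  nwin <- nrow(windows)
  count_in <- function(plist) {
    ids <- unlist(lapply(names(plist), function(ch)
      offset[[ch]] + (plist[[ch]] - 1) %/% win_width + 1), use.names = FALSE)
    if (!length(ids)) return(integer(nwin))
    tabulate(ids, nbins = nwin)
  }
  windows$n_genotyped <- count_in(geno_pos)
  windows$n_het <- count_in(het_pos)
  windows
}

#' Tally genotyped and heterozygous sites per window
#'
#' Each genotyped (non-missing) site for `sample` increments exactly one
#' window's `n_genotyped`; heterozygous sites also increment `n_het`.
#'
#' @param sites a filtered `genotype_sites` object, sorted by (chrom, pos).
#' @param windows output of [make_windows()].
#' @param sample sample name (defaults to the only sample).
#' @return `windows` with `n_genotyped` and `n_het` columns added.
#' @export
tally_windows <- function(sites, windows, sample = NULL) {
  stopifnot(inherits(sites, "genotype_sites"))
  sample <- pick_sample(sites$samples, sample)
  chrom_len <- tapply(windows$end, windows$chrom, max)
  if (length(sites$pos)) {
    if (!all(sites$chrom %in% windows$chrom))
      stop("site on a chromosome absent from the window tiling")
    if (any(sites$pos > chrom_len[sites$chrom]))
      stop("site position beyond chromosome length covered by windows")
  }
  gt <- sites$gt[, sample]
  split_pos <- function(sel) split(sites$pos[sel], sites$chrom[sel])
  tally_positions(windows, split_pos(gt != "missing"), split_pos(gt == "het"))
}

pick_sample <- function(samples, sample) {
  if (is.null(sample)) {
    if (length(samples) != 1L)
      stop("sample must be given when the object holds several samples")
    return(samples)
  }
  if (!(sample %in% samples)) stop("unknown sample id: ", sample)
  sample
}

#' Genome-wide observed heterozygosity
#'
#' The fraction of genotyped sites (variant and invariant) that are
#' heterozygous: total het sites over total genotyped sites, pooled across
#' all windows including partial ones.
#'
#' @param windows tallied windows from [tally_windows()].
#' @return A single proportion in `[0, 1]`.
#' @export
genome_heterozygosity <- function(windows) {
  ng <- sum(windows$n_genotyped)
  if (ng == 0) stop("no genotyped sites: heterozygosity undefined")
  sum(windows$n_het) / ng
}

#' Variability in heterozygosity across windows
#'
#' Sample standard deviation (or coefficient of variation) of per-window
#' heterozygosity, over full-width windows with at least
#' `min_genotyped_fraction` of their span genotyped. Partial terminal
#' windows are excluded so that unequal window support does not inflate the
#' spread.
#'
#' @param windows tallied windows from [tally_windows()].
#' @param min_genotyped_fraction minimum genotyped fraction for a window to
#'   be used (default 0.8, matching the ROH window rule).
#' @param stat `"sd"` (default) or `"cv"` (sd / mean).
#' @return Numeric scalar; errors when fewer than two windows qualify.
#' @export
heterozygosity_variability <- function(windows, min_genotyped_fraction = 0.8,
                                       stat = c("sd", "cv")) {
  stat <- match.arg(stat)
  use <- windows$full & windows$n_genotyped >=
    min_genotyped_fraction * windows$width
  if (sum(use) < 2L)
    stop("fewer than 2 windows pass the genotyped-fraction threshold")
  h <- windows$n_het[use] / windows$n_genotyped[use]
  s <- stats::sd(h)
  if (stat == "cv") s <- s / mean(h)
  s
}

#' Per-sample heterozygosity summary
#'
#' @param windows tallied windows from [tally_windows()].
#' @param sample sample id to record.
#' @param min_genotyped_fraction passed to [heterozygosity_variability()].
#' @return One-row data frame: `sample`, `genome_het`, `het_sd`, `het_cv`,
#'   `n_windows_used`.
#' @export
het_summary <- function(windows, sample, min_genotyped_fraction = 0.8) {
  use <- windows$full & windows$n_genotyped >=
    min_genotyped_fraction * windows$width
  data.frame(sample = sample,
             genome_het = genome_heterozygosity(windows),
             het_sd = heterozygosity_variability(windows,
                                                 min_genotyped_fraction),
             het_cv = heterozygosity_variability(windows,
                                                 min_genotyped_fraction, "cv"),
             n_windows_used = sum(use))
}
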