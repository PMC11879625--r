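# Windowed runs-of-homozygosity calling: a full-width window qualifies when
# it contains no heterozygous genotype and at least 80% of its span is
# genotyped (20+ kbp of a 25 kbp window). Consecutive qualifying windows
# merge into maximal segments.

#' Classify windows for the ROH rule
#'
#' A window qualifies iff it is full-width, has zero heterozygous sites, and
#' has at least `min_frac` of its width genotyped. Every window receives a
#' reason: `"pass"`, `"has_het"`, `"insufficient_genotyped"`, or
#' `"partial_window"`. A window with heterozygosity takes `"has_het"` even
#' when it is also data-poor.
#'
#' @param windows tallied windows from [tally_windows()].
#' @param min_frac minimum genotyped fraction (default 0.8).
#' @return `windows` with logical `qualifies` and character `reason` added.
#' @export
call_roh_windows <- function(windows, min_frac = 0.8) {
  stopifnot(all(c("n_genotyped", "n_het") %in% names(windows)))
  reason <- rep("pass", nrow(windows))
  reason[windows$n_genotyped < min_frac * windows$width] <-
    "insufficient_genotyped"
  reason[windows$n_het > 0] <- "has_het"
  reason[!windows$full] <- "partial_window"
  windows$qualifies <- reason == "pass"
  windows$reason <- reason
  windows
}

#' Merge qualifying windows into ROH segments
#'
#' Maximal runs of consecutive qualifying windows on one chromosome become
#' one segment; any non-qualifying window terminates a run, as do
#' chromosome boundaries. With `bridge_missing = TRUE`, windows failing only
#' the genotyped-fraction rule are skipped without terminating the run (the
#' bridged span is not added to segment length).
#'
#' @param calls output of [call_roh_windows()], ordered by genome position.
#' @param bridge_missing allow data-poor windows to bridge a run.
#' @return Data frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open), `n_windows`, `length_bp` (qualifying-window bp only).
#' @export
merge_segments <- function(calls, bridge_missing = FALSE) {
  stopifnot(all(c("qualifies", "reason") %in% names(calls)))
  for (ch in unique(calls$chrom)) {
    s <- calls$start[calls$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      stop("windows must be ordered by position within chromosome")
  }
  breaks <- !calls$qualifies
  if (bridge_missing) breaks <- breaks & calls$reason != "insufficient_genotyped"
  # run id increments at every break or chromosome change; qualifying
  # windows sharing an id are consecutive (or bridged) and form one segment
  chrom_change <- c(TRUE, calls$chrom[-1L] != calls$chrom[-nrow(calls)])
  run_id <- cumsum(breaks | chrom_change)
  q <- calls$qualifies
  if (!any(q)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      length_bp = numeric(0)))
  }
  segs <- lapply(split(which(q), run_id[q]), function(idx) {
    data.frame(chrom = calls$chrom[idx[1L]],
               start = calls$start[idx[1L]],
               end = calls$end[idx[length(idx)]],
               n_windows = length(idx),
               length_bp = sum(calls$width[idx]))
  })
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  segs[order(match(segs$chrom, unique(calls$chrom)), segs$start), ,
       drop = FALSE]
}

#' Summarize ROH for one individual
#'
#' @param segments output of [merge_segments()].
#' @param callable_length_bp total callable genome length for the sample.
#' @param sample sample id to record.
#' @return One-row data frame: `sample`, `n_segments`,
#'   `n_qualifying_windows`, `total_length_bp`, `f_roh`.
#' @export
summarize_roh <- function(segments, callable_length_bp, sample = NA_character_) {
  if (callable_length_bp <= 0)
    stop("callable length must be positive for f_roh")
  total <- sum(segments$length_bp)
  data.frame(sample = sample,
             n_segments = nrow(segments),
             n_qualifying_windows = sum(segments$n_windows),
             total_length_bp = total,
             f_roh = total / callable_length_bp)
}
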