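# Post-processing of MELT-style polymorphic ERV insertion calls: overlap
# resolution between element families, evidence filters, and per-individual
# homozygous non-reference counts.

#' Read a MELT-style ERV insertion VCF
#'
#' Expects INFO keys `FAMILY` (element consensus id), `DIV` (percent
#' divergence from consensus) and `ASSESS` (integer evidence flag), the
#' standard FILTER column, and per-sample GT.
#'
#' @param path path to the VCF.
#' @return An `erv_calls` object: data frame of calls (`chrom`, `pos`,
#'   `family`, `divergence`, `assess`, `filter_status`) with a genotype
#'   matrix attached as the `gt` attribute.
#' @export
read_erv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- matrix(classify_gt(vcfR::extract.gt(v, element = "GT")),
               nrow = nrow(fix))
  colnames(gt) <- colnames(v@gt)[-1L]
  erv_calls(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
            family = vcfR::extract.info(v, "FAMILY"),
            divergence = as.numeric(vcfR::extract.info(v, "DIV")),
            assess = as.integer(vcfR::extract.info(v, "ASSESS")),
            filter_status = fix[, "FILTER"], gt = gt)
}

#' Construct an erv_calls object
#'
#' @param chrom,pos insertion coordinates (1-based).
#' @param family ERV consensus identifier per call.
#' @param divergence percent divergence from consensus, in `[0, 100]`.
#' @param assess MELT ASSESS evidence flag (non-negative integer).
#' @param filter_status FILTER column string (`"PASS"` or a reason).
#' @param gt genotype matrix (calls x samples) with entries in
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @return An `erv_calls` data frame with the genotype matrix as attribute.
#' @export
erv_calls <- function(chrom, pos, family, divergence, assess, filter_status,
                      gt) {
  stopifnot(all(divergence >= 0 & divergence <= 100, na.rm = TRUE),
            all(assess >= 0, na.rm = TRUE))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   family = as.character(family),
                   divergence = as.numeric(divergence),
                   assess = as.integer(assess),
                   filter_status = as.character(filter_status))
  gt <- as.matrix(gt)
  stopifnot(nrow(gt) == nrow(df))
  attr(df, "gt") <- gt
  class(df) <- c("erv_calls", "data.frame")
  df
}

erv_subset <- function(calls, keep) {
  gt <- attr(calls, "gt")[keep, , drop = FALSE]
  out <- as.data.frame(calls)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gt") <- gt
  class(out) <- c("erv_calls", "data.frame")
  out
}

#' Resolve multi-family overlapping calls
#'
#' Calls within `radius` bp of each other are clustered transitively
#' (single linkage) per chromosome. A cluster containing more than one
#' element family is collapsed to its single most similar call (minimum
#' divergence; ties broken by earlier position, then lexicographic family).
#' Clusters from a single family are left untouched.
#'
#' @param calls an `erv_calls` object sorted by (chrom, pos).
#' @param radius clustering radius in bp (default 100).
#' @return The deduplicated `erv_calls`.
#' @export
resolve_overlaps <- function(calls, radius = 100) {
  stopifnot(radius >= 0)
  n <- nrow(calls)
  if (n <= 1L) return(calls)
  ord <- order(match(calls$chrom, unique(calls$chrom)), calls$pos)
  if (!identical(ord, seq_len(n))) stop("calls must be sorted by (chrom, pos)")
  new_cluster <- c(TRUE, calls$chrom[-1L] != calls$chrom[-n] |
                     calls$pos[-1L] - calls$pos[-n] > radius)
  cl <- cumsum(new_cluster)
  keep <- rep(TRUE, n)
  for (idx in split(seq_len(n), cl)) {
    if (length(unique(calls$family[idx])) > 1L) {
      o <- order(calls$divergence[idx], calls$pos[idx], calls$family[idx])
      keep[idx] <- FALSE
      keep[idx[o[1L]]] <- TRUE
    }
  }
  erv_subset(calls, keep)
}

#' ERV call filter configuration
#'
#' @param max_assess calls with `assess >=` this value are removed
#'   (default 3, dropping imprecise-breakpoint / weak-evidence calls).
#' @param require_pass drop calls whose FILTER is not `"PASS"`.
#' @param max_missing_fraction maximum fraction of missing sample genotypes
#'   (default 0.25).
#' @return An `erv_filter_config` object.
#' @export
erv_filter_config <- function(max_assess = 3, require_pass = TRUE,
                              max_missing_fraction = 0.25) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            max_assess >= 0)
  structure(list(max_assess = max_assess, require_pass = require_pass,
                 max_missing_fraction = max_missing_fraction),
            class = "erv_filter_config")
}

#' Filter ERV calls on evidence, FILTER status and missingness
#'
#' A call survives iff `assess < max_assess`, FILTER is `PASS` (when
#' required), and the fraction of missing sample genotypes does not exceed
#' `max_missing_fraction`. Per-rule removal counts are attached as the
#' `"filter_log"` attribute.
#'
#' @param calls an `erv_calls` object.
#' @param cfg an [erv_filter_config()].
#' @return The retained `erv_calls` with a `filter_log` attribute.
#' @export
filter_erv_calls <- function(calls, cfg = erv_filter_config()) {
  gt <- attr(calls, "gt")
  miss_frac <- rowMeans(gt == "missing")
  fail_assess <- calls$assess >= cfg$max_assess
  fail_pass <- if (cfg$require_pass) calls$filter_status != "PASS"
               else rep(FALSE, nrow(calls))
  fail_miss <- miss_frac > cfg$max_missing_fraction
  keep <- !(fail_assess | fail_pass | fail_miss)
  out <- erv_subset(calls, keep)
  attr(out, "filter_log") <- list(
    n_input = nrow(calls), removed_assess = sum(fail_assess),
    removed_filter = sum(fail_pass & !fail_assess),
    removed_missing = sum(fail_miss & !fail_assess & !fail_pass),
    n_retained = sum(keep))
  out
}

#' Write an erv_calls object as a MELT-style VCF
#'
#' @param calls an `erv_calls` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_erv_vcf <- function(calls, path) {
  gt <- attr(calls, "gt")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"ERV consensus\">",
           "##INFO=<ID=DIV,Number=1,Type=Float,Description=\"Percent divergence from consensus\">",
           "##INFO=<ID=ASSESS,Number=1,Type=Integer,Description=\"Evidence flag\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  if (!nrow(calls)) { writeLines(hdr, path); return(invisible(path)) }
  code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  cells <- matrix(code[gt], nrow = nrow(calls))
  info <- sprintf("FAMILY=%s;DIV=%.4f;ASSESS=%d", calls$family,
                  calls$divergence, calls$assess)
  body <- paste(calls$chrom, calls$pos, ".", "A", "<INS:ME>", ".",
                calls$filter_status, info, "GT", sep = "\t")
  body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Count homozygous non-reference ERV insertions per individual
#'
#' Raw count of `hom_alt` genotypes among the (filtered) polymorphic calls;
#' missing genotypes adjust neither numerator nor denominator.
#'
#' @param calls a filtered `erv_calls` object.
#' @param sample sample id, or `NULL` for all samples.
#' @return Data frame with `sample`, `n_hom_nonref`, `n_polymorphic_total`.
#' @export
count_hom_nonref <- function(calls, sample = NULL) {
  gt <- attr(calls, "gt")
  ids <- if (is.null(sample)) colnames(gt) else sample
  if (!all(ids %in% colnames(gt)))
    stop("unknown sample id: ", paste(setdiff(ids, colnames(gt)), collapse = ", "))
  data.frame(sample = ids,
             n_hom_nonref = colSums(gt[, ids, drop = FALSE] == "hom_alt"),
             n_polymorphic_total = nrow(calls), row.names = NULL)
}
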