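# Reading all-sites VCFs and applying site/genotype quality filters.
#
# A "genotype_sites" object holds one row per VCF record (variant AND
# invariant) and one column per sample in its genotype matrices. Genotypes
# are stored as one of "hom_ref", "het", "hom_alt", "missing". Internal
# coordinates elsewhere in the package are 0-based half-open; VCF stays
# 1-based and conversion happens only at I/O boundaries.

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a genotype_sites object
#'
#' Container for a set of genotyped positions (variant and invariant) across
#' one or more samples. Usually produced by [read_sites()] or by the
#' synthetic-data generator, not called directly.
#'
#' @param chrom character vector of sequence names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param qual numeric vector of phred-scaled site qualities (`NA` allowed).
#' @param alt character vector of ALT fields (`"."` for invariant sites).
#' @param gt character matrix (sites x samples) with entries in
#'   `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param gq,dp numeric matrices (sites x samples) of genotype quality and
#'   depth; `NA` where the field is undefined.
#' @param samples character vector of sample names (matrix column names).
#' @return An object of class `genotype_sites`.
#' @export
genotype_sites <- function(chrom, pos, qual, alt, gt, gq, dp, samples) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(qual) == n, length(alt) == n)
  pos <- as.integer(pos)
  if (n > 0L && any(pos < 1L)) stop("positions must be >= 1 (VCF is 1-based)")
  if (n > 0L && any(!is.na(qual) & qual < 0)) stop("site_qual must be >= 0")
  gt <- as.matrix(gt); gq <- as.matrix(gq); dp <- as.matrix(dp)
  if (nrow(gt) != n || ncol(gt) != length(samples))
    stop("gt matrix must be n_sites x n_samples")
  stopifnot(all(dim(gq) == dim(gt)), all(dim(dp) == dim(gt)))
  bad <- !(gt %in% GT_LEVELS)
  if (any(bad)) stop("unknown genotype code: ", gt[which(bad)[1L]])
  colnames(gt) <- colnames(gq) <- colnames(dp) <- samples
  structure(
    list(chrom = as.character(chrom), pos = pos, qual = as.numeric(qual),
         alt = as.character(alt), multiallelic = grepl(",", alt),
         gt = gt, gq = gq, dp = dp, samples = samples),
    class = "genotype_sites")
}

#' @exportS3Method base::print
print.genotype_sites <- function(x, ...) {
  cat(sprintf("genotype_sites: %d sites, %d sample(s) [%s]\n",
              length(x$pos), length(x$samples),
              paste(utils::head(x$samples, 4), collapse = ", ")))
  inv <- sum(x$alt == "." | x$alt == "<NON_REF>")
  cat(sprintf("  invariant: %d, variant: %d, multiallelic: %d\n",
              inv, length(x$pos) - inv, sum(x$multiallelic)))
  invisible(x)
}

#' Number of sites in a genotype_sites object
#' @param x a `genotype_sites` object.
#' @return integer site count.
#' @export
n_sites <- function(x) length(x$pos)

# Classify a raw VCF GT string. "." anywhere -> missing; equal alleles and
# all "0" -> hom_ref; unequal alleles -> het (multiallelic hets count as
# het); equal non-zero -> hom_alt.
classify_gt <- function(gt_raw) {
  out <- rep("missing", length(gt_raw))
  ok <- !is.na(gt_raw) & !grepl("\\.", gt_raw)
  parts <- strsplit(gt_raw[ok], "[/|]")
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
  cls <- ifelse(a1 != a2, "het", ifelse(a1 == "0", "hom_ref", "hom_alt"))
  out[ok] <- cls
  out
}

#' Read an all-sites VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a [genotype_sites()]
#' object, keeping invariant records (ALT `"."` or `<NON_REF>`). Multiallelic
#' records are flagged via the `multiallelic` field, never dropped. GQ and DP
#' are taken from the FORMAT fields when present and `NA` otherwise.
#'
#' @param path path to the VCF file.
#' @return A `genotype_sites` object.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_body(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) samples <- character(0)
  if (n == 0L) {
    empty <- matrix(character(0), 0, length(samples))
    return(genotype_sites(character(0), integer(0), numeric(0), character(0),
                          empty, matrix(numeric(0), 0, length(samples)),
                          matrix(numeric(0), 0, length(samples)), samples))
  }
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(classify_gt(gt_raw), nrow = n)
  num_fmt <- function(el) {
    keys <- unique(unlist(strsplit(v@gt[, 1L], ":")))
    if (!(el %in% keys)) return(matrix(NA_real_, n, length(samples)))
    m <- suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    matrix(as.numeric(m), nrow = n)
  }
  out <- genotype_sites(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                        alt = alt, gt = gt, gq = num_fmt("GQ"),
                        dp = num_fmt("DP"), samples = samples)
  ctg <- grep("^##contig=", v@meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1",
                                            ctg)))
    if (!anyNA(lens)) attr(out, "contig_lengths") <- stats::setNames(lens, ids)
  }
  out
}

# Structural pre-check so malformed records fail with a line number rather
# than an opaque parser message.
check_vcf_body <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stop("malformed VCF header in ", path, ": missing ##fileformat line")
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) stop("malformed VCF header in ", path, ": no #CHROM line")
  ncol_expect <- length(strsplit(lines[hdr[1L]], "\t")[[1L]])
  body <- setdiff(seq_along(lines), c(which(startsWith(lines, "#"))))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t")[[1L]])
    if (nzchar(lines[i]) && nf != ncol_expect)
      stop("malformed VCF record at line ", i, ": expected ", ncol_expect,
           " fields, found ", nf)
  }
  invisible(TRUE)
}

#' Genotype filter configuration
#'
#' Thresholds for the four site/genotype filters: minimum site quality,
#' minimum genotype quality, minimum depth per call, and maximum per-site
#' mean depth across non-missing samples.
#'
#' @param min_site_qual phred site quality below which a site is dropped.
#' @param min_gq phred genotype quality below which a call is set missing.
#' @param min_dp read depth below which a call is set missing.
#' @param max_mean_dp per-site mean depth (across non-missing calls) above
#'   which the whole site is dropped.
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_site_qual = 20, min_gq = 20, min_dp = 5,
                          max_mean_dp = 30) {
  stopifnot(min_site_qual >= 0, min_gq >= 0, min_dp >= 0, max_mean_dp >= 0,
            min_dp <= max_mean_dp)
  structure(list(min_site_qual = min_site_qual, min_gq = min_gq,
                 min_dp = min_dp, max_mean_dp = max_mean_dp),
            class = "filter_config")
}

#' Apply site and genotype filters
#'
#' Drops a site when its QUAL is below `min_site_qual` or its mean depth
#' across non-missing calls exceeds `max_mean_dp`; on surviving sites, sets
#' a sample call to missing when its GQ or DP is below threshold. A called
#' genotype with an undefined GQ or DP fails conservatively. The operation
#' is idempotent. Tallies of dropped and masked records are attached as the
#' `"filter_log"` attribute.
#'
#' @param sites a `genotype_sites` object.
#' @param cfg a [filter_config()].
#' @param snps_only if `TRUE`, additionally drop multiallelic and indel
#'   records (alleles longer than one base).
#' @return The filtered `genotype_sites`, with a `filter_log` attribute
#'   listing per-rule counts.
#' @export
apply_filters <- function(sites, cfg = filter_config(), snps_only = FALSE) {
  stopifnot(inherits(sites, "genotype_sites"), inherits(cfg, "filter_config"))
  n <- n_sites(sites)
  called <- sites$gt != "missing"
  dp_called <- ifelse(called, sites$dp, NA_real_)
  mean_dp <- rowMeans(dp_called, na.rm = TRUE)      # NaN when nothing called
  drop_qual <- !is.na(sites$qual) & sites$qual < cfg$min_site_qual # NA QUAL passes
  drop_dp <- !is.nan(mean_dp) & mean_dp > cfg$max_mean_dp
  drop_snp <- if (snps_only) sites$multiallelic else rep(FALSE, n)
  drop <- drop_qual | drop_dp | drop_snp

  # genotype-level: low GQ, low DP, or undefined GQ/DP on a called genotype
  fail_gq <- called & (is.na(sites$gq) | sites$gq < cfg$min_gq)
  fail_dp <- called & (is.na(sites$dp) | sites$dp < cfg$min_dp)
  mask <- (fail_gq | fail_dp) & !drop
  gt <- sites$gt
  gt[mask] <- "missing"

  keep <- !drop
  out <- genotype_sites(sites$chrom[keep], sites$pos[keep], sites$qual[keep],
                        sites$alt[keep],
                        gt[keep, , drop = FALSE],
                        sites$gq[keep, , drop = FALSE],
                        sites$dp[keep, , drop = FALSE], sites$samples)
  attr(out, "filter_log") <- list(
    n_input = n,
    dropped_site_qual = sum(drop_qual),
    dropped_mean_dp = sum(drop_dp & !drop_qual),
    dropped_snps_only = sum(drop_snp & !drop_qual & !drop_dp),
    masked_gq = sum(fail_gq & !drop),
    masked_dp = sum(fail_dp & !fail_gq & !drop),
    n_retained = sum(keep))
  out
}

#' Build a per-sample callable mask
#'
#' For each sample, collects every position carrying a non-missing
#' (post-filter) genotype and merges adjacent positions into maximal
#' 0-based half-open intervals.
#'
#' @param sites a filtered `genotype_sites` object, sorted by (chrom, pos).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return A named list (one element per sample) of data frames with
#'   columns `chrom`, `start`, `end` (0-based half-open).
#' @export
build_callable_mask <- function(sites, chrom_lengths) {
  stopifnot(inherits(sites, "genotype_sites"))
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_along(ord)))
    stop("sites must be sorted by (chrom, pos)")
  if (length(sites$pos) &&
      any(sites$pos > chrom_lengths[sites$chrom]))
    stop("site position beyond chromosome length")
  lapply_named(sites$samples, function(s) {
    ok <- sites$gt[, s] != "missing"
    res <- lapply(unique(sites$chrom), function(ch) {
      p <- sites$pos[ok & sites$chrom == ch]
      if (!length(p)) return(NULL)
      ir <- IRanges::reduce(IRanges::IRanges(start = p, width = 1L))
      data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir))
    })
    res <- do.call(rbind, res)
    if (is.null(res))
      res <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
    res
  })
}

#' Total callable length per sample
#' @param mask result of [build_callable_mask()].
#' @return named numeric vector of summed interval lengths (bp).
#' @export
callable_length <- function(mask) {
  vapply(mask, function(m) sum(m$end - m$start), numeric(1))
}

#' Write a callable mask as BED
#' @param mask result of [build_callable_mask()] for one sample (data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_callable_bed <- function(mask, path) {
  utils::write.table(mask, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype_sites object as an all-sites VCF
#'
#' Emits VCF 4.2 with GT:GQ:DP FORMAT fields; invariant sites carry
#' ALT = ".". Used both to export filtered data and by the synthetic
#' generator.
#'
#' @param sites a `genotype_sites` object.
#' @param path output path (plain text; use a `.vcf` suffix).
#' @param chrom_lengths optional named vector of chromosome lengths,
#'   emitted as `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, path, chrom_lengths = NULL) {
  stopifnot(inherits(sites, "genotype_sites"))
  contigs <- if (!is.null(chrom_lengths))
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)) else character(0)
  hdr <- c("##fileformat=VCFv4.2", contigs,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sites$samples), collapse = "\t"))
  n <- n_sites(sites)
  if (n == 0L) { writeLines(hdr, path); return(invisible(path)) }
  gt_code <- matrix(c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                      missing = "./.")[sites$gt], nrow = n)
  fmt_num <- function(m) ifelse(is.na(m), ".", format(m, trim = TRUE,
                                                      scientific = FALSE))
  cells <- matrix(paste(gt_code, fmt_num(sites$gq), fmt_num(sites$dp),
                        sep = ":"), nrow = n)
  cells[sites$gt == "missing"] <- "./."
  ref <- rep("A", n)
  alt <- ifelse(sites$alt %in% c(".", ""), ".", sites$alt)
  qual <- ifelse(is.na(sites$qual), ".",
                 format(sites$qual, trim = TRUE, scientific = FALSE))
  body <- paste(sites$chrom, sites$pos, ".", ref, alt, qual, ".", ".",
                "GT:GQ:DP", sep = "\t")
  body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

lapply_named <- function(nm, f) {
  out <- lapply(nm, f)
  names(out) <- nm
  out
}
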