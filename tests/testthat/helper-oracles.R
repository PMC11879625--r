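# Independent brute-force oracles used to validate the vectorized
# implementations, plus small fixture builders. Oracles deliberately use
# naive per-element loops so they share no code path with the package.

# per-position interval construction: scan a 0/1 callable vector
oracle_mask_intervals <- function(positions, chrom_length) {
  callable <- rep(FALSE, chrom_length)
  callable[positions] <- TRUE
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (p in seq_len(chrom_length)) {
    if (callable[p] && !in_run) { starts <- c(starts, p - 1L); in_run <- TRUE }
    if (!callable[p] && in_run) { ends <- c(ends, p - 1L); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, chrom_length)
  data.frame(start = starts, end = ends)
}

# per-site window tally
oracle_window_tally <- function(windows, chrom, pos, is_het) {
  ng <- integer(nrow(windows)); nh <- integer(nrow(windows))
  for (i in seq_along(pos)) {
    w <- which(windows$chrom == chrom[i] & windows$start < pos[i] &
                 pos[i] <= windows$end)
    ng[w] <- ng[w] + 1L
    if (is_het[i]) nh[w] <- nh[w] + 1L
  }
  cbind(n_genotyped = ng, n_het = nh)
}

# run-length scan over ROH window calls
oracle_roh_segments <- function(calls) {
  segs <- list()
  cur <- NULL
  for (i in seq_len(nrow(calls))) {
    new_chrom <- !is.null(cur) && calls$chrom[i] != cur$chrom
    if (calls$qualifies[i]) {
      if (is.null(cur) || new_chrom) {
        if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
        cur <- data.frame(chrom = calls$chrom[i], start = calls$start[i],
                          end = calls$end[i], n_windows = 1L)
      } else {
        cur$end <- calls$end[i]
        cur$n_windows <- cur$n_windows + 1L
      }
    } else if (!is.null(cur)) {
      segs[[length(segs) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
  if (!length(segs))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0)))
  do.call(rbind, segs)
}

# O(n^2) single-linkage clustering of ERV calls, then the keep rule
oracle_overlap_keep <- function(calls, radius) {
  n <- nrow(calls)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (calls$chrom[i] == calls$chrom[j] &&
          abs(calls$pos[i] - calls$pos[j]) <= radius &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- rep(TRUE, n)
  for (cp in unique(comp)) {
    idx <- which(comp == cp)
    if (length(unique(calls$family[idx])) > 1L) {
      o <- order(calls$divergence[idx], calls$pos[idx], calls$family[idx])
      keep[idx] <- FALSE
      keep[idx[o[1L]]] <- TRUE
    }
  }
  keep
}

# cyclic coordinate descent for (1/(2n))||y - b0 - X b||^2 + lambda ||b||_1
oracle_lasso_cd <- function(x, y, lambda, tol = 1e-14, max_iter = 100000) {
  n <- nrow(x); p <- ncol(x)
  b0 <- mean(y)
  yc <- y - b0
  b <- rep(0, p)
  v <- colSums(x^2) / n
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  r <- yc
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- b[j]
      z <- sum(x[, j] * r) / n + v[j] * bj_old
      b[j] <- soft(z, lambda) / v[j]
      if (b[j] != bj_old) {
        r <- r - x[, j] * (b[j] - bj_old)
        delta <- max(delta, abs(b[j] - bj_old))
      }
    }
    if (delta < tol) break
  }
  list(intercept = b0, beta = b)
}

# KKT / subgradient residual of a lasso solution at penalty lambda
lasso_kkt_gap <- function(x, y, beta, lambda) {
  n <- nrow(x)
  g <- as.numeric(crossprod(x, (y - mean(y)) - x %*% beta)) / n
  gap <- numeric(length(beta))
  nz <- beta != 0
  gap[nz] <- abs(g[nz] - lambda * sign(beta[nz]))
  gap[!nz] <- pmax(abs(g[!nz]) - lambda, 0)
  max(gap)
}

# 1-year-grid numerical integration of the harmonic mean
oracle_harmonic_grid <- function(trajectory, horizon) {
  mids <- seq(0.5, horizon - 0.5, by = 1)
  ne <- vapply(mids, function(t) {
    i <- which(trajectory$t_start <= t &
                 (t < trajectory$t_end | is.infinite(trajectory$t_end)))
    trajectory$ne[i[1L]]
  }, numeric(1))
  horizon / sum(1 / ne)
}

# minimal single/multi-sample VCF fixture from body lines
write_toy_vcf <- function(body, samples = "s1",
                          path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vcf_row <- function(chrom = "chr1", pos, alt = ".", qual = 50,
                    calls = "0/0:60:20") {
  paste(c(chrom, pos, ".", "A", alt, qual, ".", ".", "GT:GQ:DP", calls),
        collapse = "\t")
}

# random tallied window track for ROH stress tests
random_call_track <- function(n_windows, seed, n_chrom = 2,
                              width = 25000) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_windows,
                       replace = TRUE))
  start <- unlist(lapply(table(chrom), function(k) (seq_len(k) - 1) * width),
                  use.names = FALSE)
  w <- data.frame(chrom = chrom, start = start, end = start + width,
                  width = width, full = TRUE)
  w$full[sample.int(n_windows, max(1, n_windows %/% 50))] <- FALSE
  w$n_genotyped <- sample(round(0.7 * width):width, n_windows, replace = TRUE)
  w$n_het <- stats::rbinom(n_windows, 2, 0.4)
  w
}

# random ERV call set with clustered positions for overlap stress tests
random_erv_calls <- function(n, seed, radius = 100) {
  set.seed(seed)
  n1 <- n %/% 2
  # dense position range so a good fraction of calls fall within the radius
  erv_calls(chrom = rep(c("chr1", "chr2"), c(n1, n - n1)),
            pos = c(sort(sample.int(n1 * 120, n1)),
                    sort(sample.int((n - n1) * 120, n - n1))),
            family = sample(sprintf("ERVK%02d", 1:6), n, replace = TRUE),
            divergence = round(stats::runif(n, 0, 15), 3),
            assess = sample(0:5, n, replace = TRUE),
            filter_status = sample(c("PASS", "lc"), n, replace = TRUE,
                                   prob = c(0.9, 0.1)),
            gt = matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                               n * 4, replace = TRUE,
                               prob = c(0.5, 0.25, 0.15, 0.1)),
                        nrow = n, dimnames = list(NULL, paste0("s", 1:4))))
}
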