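# The island-size statistical layer: assemble the island x metrics table,
# fit log10(area) simple regressions (optionally with and without declared
# outliers), compute the pairwise correlation matrix behind the
# correlogram, and run LASSO variable selection (alpha = 1, lambda by
# cross-validation; leave-one-out by default given the small n of island
# studies).

METRIC_COLS <- c("log10_area", "genome_het", "het_sd", "recent_ne",
                 "harmonic_ne", "roh_n", "roh_total_bp", "erv_hom_nonref")

#' Assemble the island-by-metrics table
#'
#' Full outer join of the per-sample summaries on `sample`; missing metrics
#' stay `NA`. Island size enters as `log10_area`.
#'
#' @param islands data frame with `sample`, `island`, `area_km2` (> 0) and
#'   optionally `group`.
#' @param het per-sample [het_summary()] rows.
#' @param roh per-sample [summarize_roh()] rows.
#' @param erv per-sample [count_hom_nonref()] rows.
#' @param ne per-sample [ne_summary()] rows.
#' @return Data frame, one row per island, with columns `sample`, `island`,
#'   `area_km2`, `log10_area`, `genome_het`, `het_sd`, `recent_ne`,
#'   `harmonic_ne`, `roh_n`, `roh_total_bp`, `erv_hom_nonref`.
#' @export
assemble_table <- function(islands, het = NULL, roh = NULL, erv = NULL,
                           ne = NULL) {
  stopifnot(all(c("sample", "island", "area_km2") %in% names(islands)),
            all(islands$area_km2 > 0))
  if (anyDuplicated(islands$sample))
    stop("duplicate sample id in island table")
  tab <- islands
  tab$log10_area <- log10(tab$area_km2)
  take <- function(tab, d, cols, rename = cols) {
    if (is.null(d)) return(tab)
    if (anyDuplicated(d$sample)) stop("duplicate sample id in summary table")
    d <- d[, c("sample", cols), drop = FALSE]
    names(d) <- c("sample", rename)
    merge(tab, d, by = "sample", all = TRUE)
  }
  tab <- take(tab, het, c("genome_het", "het_sd"))
  tab <- take(tab, ne, c("recent_ne", "harmonic_mean_ne"),
              c("recent_ne", "harmonic_ne"))
  tab <- take(tab, roh, c("n_segments", "total_length_bp"),
              c("roh_n", "roh_total_bp"))
  tab <- take(tab, erv, "n_hom_nonref", "erv_hom_nonref")
  for (cl in METRIC_COLS) if (!cl %in% names(tab)) tab[[cl]] <- NA_real_
  tab[order(tab$sample), c("sample", "island", "area_km2", METRIC_COLS)]
}

#' Simple linear regression of a metric on island size
#'
#' Ordinary least squares of `response ~ predictor` with Pearson r and a
#' two-sided p-value. When `exclude` names islands, a second fit without
#' them is returned alongside the full fit, mirroring the
#' with/without-outlier presentation.
#'
#' @param table metrics table from [assemble_table()].
#' @param response column name of the response metric.
#' @param predictor column name of the predictor (default `"log10_area"`).
#' @param exclude character vector of island names to drop in the paired
#'   fit (default none).
#' @return Data frame with one row per fit (`fit = "all"` and, when
#'   `exclude` is non-empty, `fit = "excluded"`): `slope`, `intercept`,
#'   `r`, `r_squared`, `p_value`, `n`, `excluded`.
#' @export
simple_regression <- function(table, response, predictor = "log10_area",
                              exclude = character(0)) {
  one_fit <- function(d, label, excluded) {
    cc <- stats::complete.cases(d[, c(response, predictor)])
    d <- d[cc, , drop = FALSE]
    if (nrow(d) < 3L) stop("need at least 3 complete cases for regression")
    fit <- stats::lm(stats::reformulate(predictor, response), data = d)
    sm <- summary(fit)
    r <- stats::cor(d[[predictor]], d[[response]])
    data.frame(response = response, predictor = predictor, fit = label,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = r, r_squared = r * r,
               p_value = sm$coefficients[2L, 4L], n = nrow(d),
               excluded = paste(excluded, collapse = ";"))
  }
  out <- one_fit(table, "all", character(0))
  if (length(exclude)) {
    keep <- !(table$island %in% exclude)
    out <- rbind(out, one_fit(table[keep, , drop = FALSE], "excluded",
                              exclude))
  }
  out
}

#' Pairwise Pearson correlation matrix of the metrics
#'
#' Pairwise-complete correlations among the numeric metric columns, as
#' visualized in a correlogram. Constant columns give `NA` entries and are
#' listed in the `"undefined"` attribute rather than propagating NaN.
#'
#' @param table metrics table from [assemble_table()].
#' @param columns metric columns to include (default all eight).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, columns = METRIC_COLS) {
  columns <- intersect(columns, names(table))
  x <- as.matrix(table[, columns, drop = FALSE])
  const <- apply(x, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && stats::sd(v) == 0
  })
  m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  m[const, ] <- NA_real_
  m[, const] <- NA_real_
  diag(m) <- 1
  attr(m, "undefined") <- columns[const]
  m
}

#' LASSO variable selection
#'
#' L1-penalized least squares (elastic-net alpha = 1) with the penalty
#' weight chosen by cross-validation — leave-one-out by default, which is
#' deterministic and appropriate for island-scale n. Predictors are
#' standardized to zero mean and unit variance before fitting, so
#' coefficients are returned on the standardized scale; the response is
#' centred but not scaled.
#'
#' @param table metrics table (complete cases are used).
#' @param response column name of the response (the island-size analysis
#'   uses `log10_area` with the genomic metrics as predictors).
#' @param predictors character vector of predictor column names.
#' @param nfolds number of CV folds; `NULL` (default) means leave-one-out.
#' @param seed fold-assignment seed, used only when `nfolds` is given.
#' @return A list of class `lasso_fit`: `coefficients` (named, standardized
#'   scale, zero = excluded), `intercept`, `selected` (names of nonzero
#'   coefficients), `lambda_selected`, `cv_scheme`, `n`.
#' @export
lasso_select <- function(table, response = "log10_area",
                         predictors = setdiff(METRIC_COLS, response),
                         nfolds = NULL, seed = 1L) {
  cc <- stats::complete.cases(table[, c(response, predictors)])
  d <- table[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < 5L) stop("need at least 5 complete cases for LASSO")
  if (!is.null(nfolds) && nfolds > n)
    stop("more folds than cases; use leave-one-out (nfolds = NULL)")
  x <- scale(as.matrix(d[, predictors, drop = FALSE]))
  if (any(is.na(x)))
    stop("constant predictor column(s): ",
         paste(predictors[apply(is.na(x), 2L, any)], collapse = ", "))
  y <- d[[response]]
  if (is.null(nfolds)) {
    foldid <- seq_len(n)
    scheme <- "leave-one-out"
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), n))
    scheme <- sprintf("%d-fold (seed %d)", nfolds, seed)
  }
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          grouped = FALSE, standardize = FALSE,
                          thresh = 1e-14, maxit = 1e7)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(co) <- c("(Intercept)", predictors)
  beta <- co[-1L]
  structure(list(response = response,
                 coefficients = beta,
                 intercept = co[[1L]],
                 selected = names(beta)[beta != 0],
                 lambda_selected = cv$lambda.min,
                 cv_scheme = scheme, n = n),
            class = "lasso_fit")
}

#' @exportS3Method base::print
print.lasso_fit <- function(x, ...) {
  cat(sprintf("LASSO fit: %s ~ %d predictors (n = %d, %s CV)\n",
              x$response, length(x$coefficients), x$n, x$cv_scheme))
  cat(sprintf("  lambda = %.6g; selected: %s\n", x$lambda_selected,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Run the full statistical layer
#'
#' Simple regressions of each genomic metric on log island area (with Holm
#' correction added alongside raw p-values), the correlation matrix, and
#' the LASSO with island size as response.
#'
#' @param table metrics table from [assemble_table()].
#' @param exclude islands excluded in paired regression fits.
#' @return List with `regressions`, `correlations`, `lasso`.
#' @export
island_stats <- function(table, exclude = character(0)) {
  metrics <- setdiff(METRIC_COLS, "log10_area")
  metrics <- metrics[vapply(metrics, function(m)
    sum(stats::complete.cases(table[, c(m, "log10_area")])) >= 3, logical(1))]
  regs <- do.call(rbind, lapply(metrics, function(m)
    simple_regression(table, m, exclude = exclude)))
  all_rows <- regs$fit == "all"
  regs$p_holm <- NA_real_
  regs$p_holm[all_rows] <- stats::p.adjust(regs$p_value[all_rows], "holm")
  list(regressions = regs,
       correlations = correlation_matrix(table),
       lasso = lasso_select(table))
}
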