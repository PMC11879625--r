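# Conversion of scaled MSMC2 output (times in per-site mutation units,
# coalescence rates lambda) to real-time Ne trajectories, and the two
# scalar summaries used downstream: recent Ne and the time-weighted
# harmonic-mean Ne over a horizon (default the last 200,000 years).
#
# Conventions (MSMC2 user guide): with per-generation mutation rate
# mu_g = mu_per_year * generation_time, real time in years is
# scaled_time / mu_g * generation_time, and Ne = 1 / (2 * mu_g * lambda).

#' Scaling parameters for MSMC2 output
#'
#' @param mu_per_year mutation rate in substitutions/site/year
#'   (default 3.16e-9).
#' @param generation_time_years generation time in years (default 1).
#' @return A `scaling_params` object.
#' @export
scaling_params <- function(mu_per_year = 3.16e-9,
                           generation_time_years = 1.0) {
  stopifnot(mu_per_year > 0, generation_time_years > 0)
  structure(list(mu_per_year = mu_per_year,
                 generation_time_years = generation_time_years),
            class = "scaling_params")
}

#' Read an MSMC2 final output table
#'
#' Whitespace-delimited with a header line:
#' `time_index left_time_boundary right_time_boundary lambda`.
#'
#' @param path path to a `.final.txt` file.
#' @return Data frame of scaled epochs.
#' @export
read_msmc <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  need <- c("time_index", "left_time_boundary", "right_time_boundary",
            "lambda")
  if (!all(need %in% names(d)))
    stop("not an MSMC2 final table: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Convert scaled epochs to a real-unit trajectory
#'
#' @param epochs data frame with `left_time_boundary`,
#'   `right_time_boundary` (per-site mutation units; the last right boundary
#'   may be `Inf`) and `lambda` (scaled coalescence rate).
#' @param p a [scaling_params()].
#' @return Data frame with `t_start`, `t_end` (years before present) and
#'   `ne` (diploid effective size).
#' @export
unscale_trajectory <- function(epochs, p = scaling_params()) {
  stopifnot(inherits(p, "scaling_params"))
  if (any(epochs$lambda <= 0)) stop("lambda must be positive")
  mu_g <- p$mu_per_year * p$generation_time_years
  data.frame(
    t_start = epochs$left_time_boundary / mu_g * p$generation_time_years,
    t_end = epochs$right_time_boundary / mu_g * p$generation_time_years,
    ne = 1 / (2 * mu_g * epochs$lambda))
}

#' Convert a real-unit trajectory back to scaled epochs
#'
#' Exact inverse of [unscale_trajectory()]; also used by the synthetic
#' generator to emit MSMC2-format fixtures.
#'
#' @param trajectory data frame with `t_start`, `t_end`, `ne`.
#' @param p a [scaling_params()].
#' @return Data frame of scaled epochs with `time_index`.
#' @export
rescale_trajectory <- function(trajectory, p = scaling_params()) {
  stopifnot(inherits(p, "scaling_params"), all(trajectory$ne > 0))
  mu_g <- p$mu_per_year * p$generation_time_years
  data.frame(
    time_index = seq_len(nrow(trajectory)) - 1L,
    left_time_boundary = trajectory$t_start * mu_g / p$generation_time_years,
    right_time_boundary = trajectory$t_end * mu_g / p$generation_time_years,
    lambda = 1 / (2 * mu_g * trajectory$ne))
}

check_trajectory <- function(trajectory) {
  if (!nrow(trajectory)) stop("empty trajectory")
  if (any(trajectory$ne <= 0)) stop("ne must be positive")
  o <- order(trajectory$t_start)
  trajectory <- trajectory[o, , drop = FALSE]
  if (trajectory$t_start[1L] > 0)
    stop("trajectory does not cover time 0")
  if (nrow(trajectory) > 1L) {
    gaps <- trajectory$t_start[-1L] - trajectory$t_end[-nrow(trajectory)]
    if (any(abs(gaps) > 1e-6 * pmax(1, trajectory$t_start[-1L])))
      stop("gap or overlap in trajectory epoch coverage")
  }
  trajectory
}

#' Recent effective population size
#'
#' Ne of the epoch containing time zero; the most recent MSMC2 epoch is
#' noisy, so `skip_first = TRUE` returns the next epoch instead.
#'
#' @param trajectory real-unit trajectory (`t_start`, `t_end`, `ne`).
#' @param skip_first skip the most recent epoch.
#' @return Numeric Ne.
#' @export
recent_ne <- function(trajectory, skip_first = FALSE) {
  trajectory <- check_trajectory(trajectory)
  i <- if (skip_first && nrow(trajectory) > 1L) 2L else 1L
  trajectory$ne[i]
}

#' Time-weighted harmonic-mean Ne over a horizon
#'
#' `horizon / sum(dt_i / ne_i)` with epochs clipped to `[0, horizon)`; the
#' final epoch is treated as unbounded. The harmonic mean is the quantity
#' governing long-term drift, because drift compounds inversely with Ne.
#'
#' @param trajectory real-unit trajectory (`t_start`, `t_end`, `ne`).
#' @param horizon_years horizon in years before present (default 200,000).
#' @return Numeric Ne.
#' @export
harmonic_mean_ne <- function(trajectory, horizon_years = 200000) {
  stopifnot(horizon_years > 0)
  trajectory <- check_trajectory(trajectory)
  trajectory$t_end[nrow(trajectory)] <- Inf
  lo <- pmax(trajectory$t_start, 0)
  hi <- pmin(trajectory$t_end, horizon_years)
  dt <- pmax(hi - lo, 0)
  if (abs(sum(dt) - horizon_years) > 1e-6 * horizon_years)
    stop("trajectory does not cover the full horizon")
  horizon_years / sum(dt / trajectory$ne)
}

#' Per-sample demographic summary
#'
#' @param trajectory real-unit trajectory.
#' @param sample sample id to record.
#' @param horizon_years harmonic-mean horizon (default 200,000 years).
#' @param skip_first passed to [recent_ne()].
#' @return One-row data frame: `sample`, `recent_ne`, `harmonic_mean_ne`,
#'   `horizon_years`.
#' @export
ne_summary <- function(trajectory, sample, horizon_years = 200000,
                       skip_first = FALSE) {
  data.frame(sample = sample,
             recent_ne = recent_ne(trajectory, skip_first),
             harmonic_mean_ne = harmonic_mean_ne(trajectory, horizon_years),
             horizon_years = horizon_years)
}
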