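#' Performance summary of a batch
#'
#' Performance is the mean collected payoff per agent per trial, averaged
#' over agents, trials (optionally a window, e.g. the last 100 of 200 trials
#' to isolate post-convergence behaviour) and replicates. Improvement
#' subtracts the expected payoff of a uniform-random policy in the same
#' environment. The 95% CI half-width uses a normal approximation across
#' replicate means.
#'
#' @param batch A [run_batch()] result.
#' @param task Bandit task for the baseline; defaults to the batch's own.
#' @param window Optional length-2 integer `c(first, last)` trial window.
#' @return A list of class `performance_summary`: `mean_payoff`, `ci95`,
#'   `focal_mean` (agent 1, all trials), `improvement`, `window`, `n_sims`.
#' @export
performance <- function(batch, task = NULL, window = NULL) {
  stopifnot(inherits(batch, "carl_batch"))
  if (is.null(task)) task <- batch$config$task
  task <- as_bandit_task(task)
  trials <- batch$config$trials
  if (is.null(window)) window <- c(1L, trials)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > trials ||
      window[1] > window[2])
    stop("window must be c(first, last) within [1, ", trials, "]",
         call. = FALSE)
  rep_means <- rowMeans(batch$payoff_trial[, window[1]:window[2], drop = FALSE])
  structure(list(
    mean_payoff = mean(rep_means),
    ci95 = 1.96 * stats::sd(rep_means) / sqrt(length(rep_means)),
    focal_mean = mean(batch$payoff_agent[, 1L]),
    improvement = mean(rep_means) - expected_random_performance(task),
    window = window, n_sims = batch$config$n_sims),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance> mean payoff/agent/trial = %.4f +/- %.4f (95%% CI), improvement = %.4f\n  focal (agent 1) mean = %.4f over trials [%d, %d], %d replicates\n",
    x$mean_payoff, x$ci95, x$improvement, x$focal_mean,
    x$window[1], x$window[2], x$n_sims))
  invisible(x)
}

#' Final Q-value gap
#'
#' The gap `Q(best arm) - Q(worst arm)` for one agent, where "best" is arm 1
#' (the higher reward probability in every preset). Negative gaps mean the
#' agent has come to favor the objectively worse arm. For an unbiased,
#' converged solo learner with exhaustive sampling the gap approaches the
#' difference of the arms' expected payoffs, 0.4 in every preset.
#'
#' @param final_q An agent x arm matrix (one replicate) or a
#'   replicate x agent x arm array (a batch's `final_q`).
#' @param agent Agent index (default 1, the focal agent).
#' @return A single gap, or a vector of per-replicate gaps.
#' @export
qgap <- function(final_q, agent = 1L) {
  if (is.matrix(final_q)) {
    if (agent < 1L || agent > nrow(final_q))
      stop("agent index out of range", call. = FALSE)
    return(final_q[agent, 1L] - final_q[agent, 2L])
  }
  if (is.array(final_q) && length(dim(final_q)) == 3L) {
    if (agent < 1L || agent > dim(final_q)[2])
      stop("agent index out of range", call. = FALSE)
    return(final_q[, agent, 1L] - final_q[, agent, 2L])
  }
  stop("final_q must be an agent x arm matrix or a sims x agent x arm array",
       call. = FALSE)
}

#' Behavior profile from a Q-value gap
#'
#' The softmax probability of choosing the best arm given a Q-value gap:
#' `1 / (1 + exp(-beta * gap))`. Monotone in the gap and bounded, so the mean
#' behavior profile of a gap distribution (compute per replicate, then
#' average) is the statistic that tracks performance, not the mean gap.
#'
#' @param qgap Numeric vector of Q-value gaps.
#' @param beta Inverse temperature >= 0.
#' @return Probabilities in \[0, 1\], same length as `qgap`.
#' @export
behavior_profile <- function(qgap, beta) {
  stopifnot(beta >= 0)
  z <- pmin(pmax(beta * qgap, -500), 500)
  1 / (1 + exp(-z))
}

#' Locate the modes of a Q-value-gap distribution
#'
#' Fits a Gaussian kernel density estimate (Scott's rule bandwidth by
#' default) on a fixed grid spanning `[-1 - 3h, 1 + 3h]` and extracts strict
#' local maxima, discarding any whose height is below `prominence` times the
#' global maximum (suppresses grid noise). One mode means a single
#' performance regime; two or more signal a bifurcation into high- and
#' low-performance regimes.
#'
#' @param samples Numeric vector of gaps (or gap differences); at least
#'   `min_n` values.
#' @param bw Bandwidth: `"scott"` (default, [stats::bw.nrd()]), `"silverman"`
#'   ([stats::bw.nrd0()]) or a positive number.
#' @param n_grid Number of grid points (default 512).
#' @param prominence Relative height threshold for keeping a peak
#'   (default 0.01).
#' @param min_n Minimum sample size (default 50).
#' @return A list of class `regime_summary`: `peaks` (data.frame with
#'   `location`, `height`, `relative_height`, sorted by location), the
#'   `bandwidth`, grid `range`, and `n` samples used.
#' @export
kde_peaks <- function(samples, bw = "scott", n_grid = 512L,
                      prominence = 0.01, min_n = 50L) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < min_n)
    stop("need at least ", min_n, " samples for density estimation",
         call. = FALSE)
  h <- if (is.numeric(bw)) bw
       else switch(match.arg(bw, c("scott", "silverman")),
                   scott = stats::bw.nrd(samples),
                   silverman = stats::bw.nrd0(samples))
  if (!is.finite(h) || h <= 0) h <- 1e-3  # degenerate (constant) samples
  lim <- max(1, max(abs(samples)))
  dens <- stats::density(samples, bw = h, n = n_grid,
                         from = -lim - 3 * h, to = lim + 3 * h)
  y <- dens$y
  k <- 2:(n_grid - 1L)
  is_peak <- y[k] > y[k - 1L] & y[k] > y[k + 1L]
  loc <- dens$x[k][is_peak]
  ht <- y[k][is_peak]
  keep <- ht >= prominence * max(y)
  loc <- loc[keep]; ht <- ht[keep]
  ord <- order(loc)
  structure(list(
    peaks = data.frame(location = loc[ord], height = ht[ord],
                       relative_height = ht[ord] / max(ht)),
    bandwidth = h, range = range(dens$x), n = length(samples)),
    class = "regime_summary")
}

#' @export
print.regime_summary <- function(x, ...) {
  cat(sprintf("<regime_summary> %d peak(s), bandwidth %.4f, n = %d\n",
              nrow(x$peaks), x$bandwidth, x$n))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Within-group divergence of final Q-value gaps
#'
#' Per replicate, the difference between the focal agent's and another
#' agent's final Q-value gaps. Consensus shows up as a single mode at zero;
#' polarization — agents of the same run settling in different performance
#' regimes — as off-zero side modes (inspect with [kde_peaks()]).
#'
#' @param batch A [run_batch()] result with n >= 2.
#' @param focal Focal agent index (default 1).
#' @param other Comparison agent index (default 2).
#' @return A list of class `polarization_summary`: `gap_differences`
#'   (one per replicate) and `pair`.
#' @export
polarization <- function(batch, focal = 1L, other = 2L) {
  stopifnot(inherits(batch, "carl_batch"))
  n <- batch$config$n
  if (n < 2L) stop("polarization needs at least 2 agents", call. = FALSE)
  if (other < 1L || other > n || focal < 1L || focal > n || focal == other)
    stop("agent indices must be distinct and within 1..", n, call. = FALSE)
  structure(list(
    gap_differences = qgap(batch$final_q, focal) - qgap(batch$final_q, other),
    pair = c(focal, other)),
    class = "polarization_summary")
}

#' Group size at which a biased curve catches the unbiased one
#'
#' Given mean payoffs on a common grid of group sizes, returns the smallest
#' n at which the biased groups' mean meets or exceeds the unbiased groups'
#' (ties count as a crossing). Read from discrete group sizes, as in the
#' performance-versus-group-size curves it summarises.
#'
#' @param curve_biased,curve_unbiased Numeric vectors of mean payoffs over
#'   the same group sizes.
#' @param n_grid Integer vector of group sizes (default `seq_along`).
#' @return The crossing group size, or `NA` if the biased curve never
#'   catches up on the grid. Attribute `"bracket"` holds the last n below
#'   and first n at/above when a crossing exists beyond the first grid point.
#' @export
intersection_group_size <- function(curve_biased, curve_unbiased,
                                    n_grid = seq_along(curve_biased)) {
  if (length(curve_biased) != length(curve_unbiased) ||
      length(curve_biased) != length(n_grid))
    stop("curves and n_grid must have equal lengths", call. = FALSE)
  at_or_above <- curve_biased >= curve_unbiased
  if (!any(at_or_above)) return(NA_integer_)
  i <- which(at_or_above)[1]
  out <- n_grid[i]
  if (i > 1L) attr(out, "bracket") <- c(n_grid[i - 1L], n_grid[i])
  out
}

#' Optimal bias strength from a mean-profile curve
#'
#' Returns the grid bias strength maximising the mean behavior profile
#' (first maximum on ties). Also flags whether the curve is non-decreasing
#' across the grid, the signature of the scarce-resource regime where
#' stronger bias keeps helping.
#'
#' @param b Numeric grid of bias strengths (>= 3 points).
#' @param mean_profile Mean behavior profile at each grid point.
#' @return The argmax bias strength, with attribute `"non_decreasing"`.
#' @export
optimal_bias <- function(b, mean_profile) {
  if (length(b) != length(mean_profile) || length(b) < 3L)
    stop("need matching grids with at least 3 bias strengths", call. = FALSE)
  ord <- order(b)
  b <- b[ord]; mean_profile <- mean_profile[ord]
  out <- b[which.max(mean_profile)]
  attr(out, "non_decreasing") <- all(diff(mean_profile) >= 0)
  out
}
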