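#' Experiment configuration
#'
#' Bundles everything one batch of replicate simulations needs: the bandit
#' task, group size, trial count, learning-rate specification, inverse
#' temperature, replicate count, base seed and which trajectories to record.
#'
#' @param task A [bandit_task()], preset name, or `(p1, p2)` pair.
#' @param n Group size (>= 1). Agents observe every other agent's action and
#'   payoff (fully connected group).
#' @param trials Number of trials T (>= 1).
#' @param bias A [bias_spec()] (or list coercible to one).
#' @param beta Inverse temperature shared by all agents (default 4, the
#'   value fitted in the human bandit literature this model builds on).
#' @param n_sims Number of replicate simulations.
#' @param seed Base RNG seed; replicate streams are derived from it.
#' @param q0 Initial Q-value pair, identical across agents (default (0, 0),
#'   the symmetric uninformative point of \[-1, 1\]).
#' @param record Character subset of `c("q_values", "choices", "payoffs")`:
#'   full per-trial trajectories to keep (summaries are always kept).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task, n, trials, bias, beta = 4,
                              n_sims = 1L, seed = 1L, q0 = c(0, 0),
                              record = character()) {
  task <- as_bandit_task(task)
  bias <- as_bias_spec(bias)
  n <- as.integer(n); trials <- as.integer(trials); n_sims <- as.integer(n_sims)
  if (n < 1L || trials < 1L || n_sims < 1L)
    stop("n, trials and n_sims must all be >= 1", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  stopifnot(length(q0) == 2L, all(q0 >= -1 & q0 <= 1))
  if (length(record))
    record <- match.arg(record, c("q_values", "choices", "payoffs"),
                        several.ok = TRUE)
  structure(list(task = task, n = n, trials = trials, bias = bias,
                 beta = beta, n_sims = n_sims, seed = as.integer(seed),
                 q0 = as.numeric(q0), record = record),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  a <- resolve_bias(x$bias)
  cat(sprintf(
    "<experiment_config> task (%g, %g), n = %d, T = %d, a+ = %g, a- = %g, b = %g,\n  beta = %g, n_sims = %d, seed = %d\n",
    x$task$p1, x$task$p2, x$n, x$trials, a[1], a[2], a[1] / a[2],
    x$beta, x$n_sims, x$seed))
  invisible(x)
}

#' Run one replicate simulation
#'
#' Executes `trials` synchronous rounds: every agent draws an arm from its
#' softmax policy, payoffs are sampled independently, and every agent updates
#' both Q-values from all n agents' outcomes (confirmatory prediction errors
#' weighted by `alpha_plus`, disconfirmatory by `alpha_minus`, 1/n scaling).
#'
#' Two engines are provided: the production C++ loop (`"cpp"`) and an
#' independent pure-R reference built from [classify_feedback()] and
#' [carl_update()] (`"r"`). They consume the RNG stream in the same order and
#' produce bit-identical results under the same seed; the R engine exists as
#' an oracle and costs roughly two orders of magnitude more time.
#'
#' @param config An [experiment_config()] (its `n_sims` is ignored here).
#' @param seed Optional seed set before the run; if `NULL` the current RNG
#'   state is used.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A list of class `simulation_result` with `final_q` (n x 2 matrix),
#'   `payoff_trial_mean` (length-T vector, mean payoff over agents per trial),
#'   `payoff_agent_mean` (length-n vector, mean payoff over trials per agent)
#'   and any requested trajectories (`q_values`: T x n x 2, `choices`,
#'   `payoffs`: T x n).
#' @export
run_simulation <- function(config, seed = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "experiment_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  a <- resolve_bias(config$bias)
  res <- if (engine == "cpp") {
    carl_sim_cpp(config$n, config$trials, config$task$p1, config$task$p2,
                 a[["alpha_plus"]], a[["alpha_minus"]], config$beta,
                 matrix(config$q0, config$n, 2, byrow = TRUE),
                 "q_values" %in% config$record,
                 "choices" %in% config$record,
                 "payoffs" %in% config$record)
  } else {
    run_simulation_r(config, a)
  }
  res$config <- config
  class(res) <- "simulation_result"
  res
}

# Reference engine: literal per-agent composition of the module primitives.
run_simulation_r <- function(config, alphas) {
  n <- config$n; trials <- config$trials
  states <- replicate(n, agent_state(config$q0, alphas[["alpha_plus"]],
                                     alphas[["alpha_minus"]], config$beta),
                      simplify = FALSE)
  rec_q <- "q_values" %in% config$record
  rec_c <- "choices" %in% config$record
  rec_p <- "payoffs" %in% config$record
  q_traj <- if (rec_q) array(NA_real_, c(trials, n, 2))
  c_traj <- if (rec_c) matrix(NA_integer_, trials, n)
  p_traj <- if (rec_p) matrix(NA_integer_, trials, n)
  payoff_trial_mean <- numeric(trials)
  payoff_agent_sum <- numeric(n)

  for (t in seq_len(trials)) {
    qmat <- do.call(rbind, lapply(states, `[[`, "q"))
    actions <- choose_actions(qmat, config$beta)
    payoffs <- sample_payoffs(config$task, actions)
    payoff_trial_mean[t] <- mean(payoffs)
    payoff_agent_sum <- payoff_agent_sum + payoffs
    # simultaneous updates: every agent classifies the same trial snapshot
    states <- lapply(seq_len(n), function(i)
      carl_update(states[[i]], classify_feedback(i, actions, payoffs), n))
    if (rec_q) q_traj[t, , ] <- do.call(rbind, lapply(states, `[[`, "q"))
    if (rec_c) c_traj[t, ] <- actions
    if (rec_p) p_traj[t, ] <- payoffs
  }
  out <- list(final_q = do.call(rbind, lapply(states, `[[`, "q")),
              payoff_trial_mean = payoff_trial_mean,
              payoff_agent_mean = payoff_agent_sum / trials)
  if (rec_q) out$q_values <- q_traj
  if (rec_c) out$choices <- c_traj
  if (rec_p) out$payoffs <- p_traj
  out
}

#' Run a batch of replicate simulations
#'
#' Replicate k runs under its own RNG stream seeded by the k-th value of a
#' seed vector drawn once from the base seed, so results do not depend on
#' execution order and are bit-reproducible.
#'
#' @inheritParams run_simulation
#' @return An object of class `carl_batch` with `final_q`
#'   (n_sims x n x 2 array), `payoff_trial` (n_sims x T matrix of
#'   agent-averaged payoffs), `payoff_agent` (n_sims x n matrix of
#'   trial-averaged payoffs), the `config`, and `records` (list of per-
#'   replicate trajectory lists, if any were requested).
#' @export
run_batch <- function(config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "experiment_config"))
  engine <- match.arg(engine)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_sims)
  final_q <- array(NA_real_, c(config$n_sims, config$n, 2))
  payoff_trial <- matrix(NA_real_, config$n_sims, config$trials)
  payoff_agent <- matrix(NA_real_, config$n_sims, config$n)
  records <- if (length(config$record)) vector("list", config$n_sims)
  for (k in seq_len(config$n_sims)) {
    res <- run_simulation(config, seed = rep_seeds[k], engine = engine)
    final_q[k, , ] <- res$final_q
    payoff_trial[k, ] <- res$payoff_trial_mean
    payoff_agent[k, ] <- res$payoff_agent_mean
    if (length(config$record))
      records[[k]] <- res[config$record]
  }
  structure(list(final_q = final_q, payoff_trial = payoff_trial,
                 payoff_agent = payoff_agent, records = records,
                 config = config),
            class = "carl_batch")
}

#' @export
print.carl_batch <- function(x, ...) {
  cat(sprintf("<carl_batch> %d replicates of:\n", x$config$n_sims))
  print(x$config)
  cat(sprintf("  mean payoff/agent/trial = %.4f\n", mean(x$payoff_trial)))
  invisible(x)
}

#' Sweep a parameter grid
#'
#' Runs [run_batch()] over the cross product of group sizes, bias
#' specifications and tasks, and returns one tidy summary row per cell. Cell
#' seeds are drawn once from the base seed so cells are order-independent.
#'
#' @param n Integer vector of group sizes.
#' @param bias A list of [bias_spec()] objects (names become the `bias`
#'   column; unnamed specs are labelled `scheme:b`).
#' @param task Character vector of preset names and/or a list of
#'   [bandit_task()] objects.
#' @param trials,n_sims,beta,q0 Shared settings, as in [experiment_config()].
#' @param seed Base seed for the whole sweep.
#' @param window Optional trial window (length-2 integer) passed to
#'   [performance()] for the payoff summaries.
#' @return A data.frame with one row per (task, n, bias) cell: the cell
#'   parameters, `mean_payoff`, `ci95`, `focal_mean`, `improvement`
#'   (performance minus the random-policy baseline), `mean_gap_focal` (mean
#'   final Q-value gap of agent 1) and `mean_profile_focal` (mean final
#'   behavior profile of agent 1).
#' @export
sweep_grid <- function(n, bias, task, trials, n_sims, beta = 4,
                       q0 = c(0, 0), seed = 1L, window = NULL) {
  if (inherits(bias, "bias_spec")) bias <- list(bias)
  if (is.character(task) || inherits(task, "bandit_task")) task <- as.list(task)
  labels <- names(bias)
  if (is.null(labels)) labels <- rep("", length(bias))
  for (i in seq_along(bias)) {
    bias[[i]] <- as_bias_spec(bias[[i]])
    if (labels[i] == "")
      labels[i] <- sprintf("%s:%g", bias[[i]]$scheme, bias[[i]]$b)
  }
  cells <- expand.grid(i_task = seq_along(task), i_n = seq_along(n),
                       i_bias = seq_along(bias))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    tk <- as_bandit_task(task[[cells$i_task[r]]])
    bs <- bias[[cells$i_bias[r]]]
    cfg <- experiment_config(tk, n[cells$i_n[r]], trials, bs, beta = beta,
                             n_sims = n_sims, seed = cell_seeds[r], q0 = q0)
    batch <- run_batch(cfg)
    perf <- performance(batch, window = window)
    gaps <- qgap(batch$final_q, agent = 1L)
    a <- resolve_bias(bs)
    data.frame(preset = if (is.null(tk$preset)) NA_character_ else tk$preset,
               p1 = tk$p1, p2 = tk$p2, n = cfg$n,
               bias = labels[cells$i_bias[r]], b = bs$b,
               alpha_plus = a[["alpha_plus"]], alpha_minus = a[["alpha_minus"]],
               beta = beta, trials = trials, n_sims = n_sims,
               seed = cell_seeds[r],
               mean_payoff = perf$mean_payoff, ci95 = perf$ci95,
               focal_mean = perf$focal_mean, improvement = perf$improvement,
               mean_gap_focal = mean(gaps),
               mean_profile_focal = mean(behavior_profile(gaps, beta)))
  })
  do.call(rbind, rows)
}
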