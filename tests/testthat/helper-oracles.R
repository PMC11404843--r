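# Independent oracles used across test files. These deliberately re-derive
# quantities from first principles (plain arithmetic on sampled outcomes)
# rather than calling the implementation paths they check.

# Standard collective Rescorla-Wagner update with a single learning rate:
# every observed outcome on an arm moves that arm's Q toward the payoff,
# scaled by alpha/n. Equivalent to the asymmetric rule when both rates agree.
rw_collective_update <- function(q_pair, actions, payoffs, alpha, n) {
  for (arm in 1:2) {
    on_arm <- actions == arm
    if (any(on_arm))
      q_pair[arm] <- q_pair[arm] +
        alpha * sum(payoffs[on_arm] - q_pair[arm]) / n
  }
  q_pair
}

# Solo two-rate learner with counterfactual-free feedback: positive
# prediction errors on the chosen arm use alpha_plus, negative alpha_minus.
# The n = 1 collective model must reduce to this.
solo_two_rate_update <- function(q_pair, action, payoff, ap, am) {
  rate <- if (payoff > q_pair[action]) ap else am
  q_pair[action] <- q_pair[action] + rate * (payoff - q_pair[action])
  q_pair
}

# Monte-Carlo estimate of the expected one-trial Q increment of agent i in
# the two-agent stochastic model, policies frozen at the given state (no Q
# feedback within the estimate). Vectorised direct arithmetic on the update
# rule definition; independent of both simulation engines and of
# deterministic_step().
mc_expected_increment <- function(st, m = 1e5) {
  xi <- softmax_policy(st$q_i, st$beta, 1)
  xj <- softmax_policy(st$q_j, st$beta, 1)
  p <- c(st$task$p1, st$task$p2)
  act_i <- ifelse(stats::runif(m) < xi, 1L, 2L)
  act_j <- ifelse(stats::runif(m) < xj, 1L, 2L)
  pay_i <- ifelse(stats::runif(m) < p[act_i], 1L, -1L)
  pay_j <- ifelse(stats::runif(m) < p[act_j], 1L, -1L)
  inc <- matrix(0, m, 2)
  for (arm in 1:2) {
    q <- st$q_i[arm]
    chose <- act_i == arm
    # outcomes observed on this arm, split by who produced them
    n_rew <- (chose & pay_i == 1L) + (act_j == arm & pay_j == 1L)
    n_pen <- (chose & pay_i == -1L) + (act_j == arm & pay_j == -1L)
    inc[, arm] <- ifelse(chose,
      (st$alpha_plus * n_rew * (1 - q) + st$alpha_minus * n_pen * (-1 - q)) / 2,
      (st$alpha_plus * n_pen * (-1 - q) + st$alpha_minus * n_rew * (1 - q)) / 2)
  }
  list(mean = colMeans(inc), se = apply(inc, 2, stats::sd) / sqrt(m))
}

# Small batch runner used by several analysis tests.
quick_batch <- function(task, n, trials, ap, am, n_sims, seed, beta = 4) {
  cfg <- experiment_config(task, n = n, trials = trials,
                           bias = bias_spec("explicit", alpha_plus = ap,
                                            alpha_minus = am),
                           beta = beta, n_sims = n_sims, seed = seed)
  run_batch(cfg)
}
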