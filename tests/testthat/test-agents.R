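test_that("bias schemes resolve to the conventional learning-rate pairs", {
  expect_equal(resolve_bias(bias_spec("fixed_sum", b = 3)),
               c(alpha_plus = 0.15, alpha_minus = 0.05))
  expect_equal(resolve_bias(bias_spec("fixed_sum", b = 17 / 3)),
               c(alpha_plus = 0.17, alpha_minus = 0.03))
  expect_equal(resolve_bias(bias_spec("fixed_sum", b = 9)),
               c(alpha_plus = 0.18, alpha_minus = 0.02))
  expect_equal(resolve_bias(bias_spec("fixed_sum", b = 1)),
               c(alpha_plus = 0.1, alpha_minus = 0.1))
  expect_equal(resolve_bias(bias_spec("fixed_minus", b = 5)),
               c(alpha_plus = 0.5, alpha_minus = 0.1))
  # derived b equals the rate ratio in every scheme
  for (spec in list(bias_spec("fixed_sum", b = 2.5),
                    bias_spec("fixed_minus", b = 4),
                    bias_spec("explicit", alpha_plus = 0.12,
                              alpha_minus = 0.03))) {
    a <- resolve_bias(spec)
    expect_equal(unname(a[1] / a[2]), spec$b)
  }
  expect_error(bias_spec("fixed_sum", b = -1), "positive")
  expect_error(resolve_bias(bias_spec("fixed_minus", b = 11)), "\\(0, 1\\]")
})

test_that("softmax policy matches the logistic of the Q-value difference", {
  expect_equal(softmax_policy(c(0.9, -0.3), beta = 0), 0.5)
  expect_equal(softmax_policy(c(0.4, 0.4), beta = 12), 0.5)
  expect_equal(softmax_policy(c(0.4, 0), beta = 4), 1 / (1 + exp(-1.6)))
  # complementarity and numerical safety at extreme beta
  q <- c(-0.2, 0.7)
  expect_equal(softmax_policy(q, 4, 1) + softmax_policy(q, 4, 2), 1)
  expect_equal(softmax_policy(c(1, -1), beta = 1e6), 1)
  expect_equal(softmax_policy(c(-1, 1), beta = 1e6), 0)
})

test_that("choose_actions samples i.i.d. across agents from each softmax", {
  set.seed(42)
  q <- matrix(c(1, -1), 3, 2, byrow = TRUE)
  expect_true(all(choose_actions(q, beta = 1e6) == 1L))  # greedy limit
  draws <- replicate(4000, choose_actions(matrix(0, 3, 2), beta = 0))
  expect_lt(abs(mean(draws == 1L) - 0.5), 3 * sqrt(0.25 / length(draws)))
  # independence across agents: chi-square on the 2x2 table of agents 1, 2
  tab <- table(draws[1, ], draws[2, ])
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)
})

test_that("feedback partition classifies outcomes from the focal view", {
  # solo rewarded agent confirms itself
  p <- classify_feedback(1, actions = 1L, payoffs = 1L)
  expect_equal(p$r_c, 1L)
  expect_equal(lengths(p[c("p_c", "r_u", "p_u")]), c(p_c = 0L, r_u = 0L,
                                                     p_u = 0L))
  # same arm, opposite outcomes
  p <- classify_feedback(1, actions = c(1L, 1L), payoffs = c(1L, -1L))
  expect_equal(p$r_c, 1L)
  expect_equal(p$p_c, 2L)
  # peer rewarded on the alternative arm is disconfirmatory
  p <- classify_feedback(1, actions = c(1L, 2L), payoffs = c(1L, 1L))
  expect_equal(p$r_c, 1L)
  expect_equal(p$r_u, 2L)
  expect_error(classify_feedback(1, c(1L, 2L), 1L), "same length")
})

test_that("partition sets are disjoint and cover all n agents (property)", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    actions <- sample(1:2, n, replace = TRUE)
    payoffs <- sample(c(-1L, 1L), n, replace = TRUE)
    focal <- sample(n, 1)
    p <- classify_feedback(focal, actions, payoffs)
    members <- c(p$r_c, p$p_c, p$r_u, p$p_u)
    expect_equal(sort(members), 1:n)
    expect_true(focal %in% c(p$r_c, p$p_c))
  }
})

test_that("update rule reproduces hand-derived increments", {
  # n = 1, reward from Q = 0: chosen arm moves to alpha_plus
  st <- agent_state(c(0, 0), alpha_plus = 0.15, alpha_minus = 0.05)
  up <- carl_update(st, classify_feedback(1, 1L, 1L), n = 1)
  expect_equal(up$q, c(0.15, 0))
  # n = 2, both rewarded on the same arm: (1/2)(a+ + a+) (1 - 0) = a+
  up <- carl_update(st, classify_feedback(1, c(1L, 1L), c(1L, 1L)), n = 2)
  expect_equal(up$q, c(0.15, 0))
  # prediction error vanishes at the bound
  st1 <- agent_state(c(1, 0), alpha_plus = 0.18, alpha_minus = 0.02)
  up <- carl_update(st1, classify_feedback(1, c(1L, 1L), c(1L, 1L)), n = 2)
  expect_equal(up$q, c(1, 0))
  # penalty on the unchosen arm is confirmatory and pushes it toward -1
  up <- carl_update(st, classify_feedback(1, c(1L, 2L), c(1L, -1L)), n = 2)
  expect_equal(up$q, c(0.15 * 0.5, 0.15 * (-1) * 0.5))
  expect_error(carl_update(st, classify_feedback(1, c(1L, 1L), c(1L, 1L)),
                           n = 5), "partition covers")
})

test_that("Q-values stay in [-1, 1] under any stream, even at rate 1", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    st <- agent_state(stats::runif(2, -1, 1),
                      alpha_plus = sample(c(1, stats::runif(1)), 1),
                      alpha_minus = sample(c(1, stats::runif(1)), 1))
    for (t in 1:100) {
      actions <- sample(1:2, n, replace = TRUE)
      payoffs <- sample(c(-1L, 1L), n, replace = TRUE)
      st <- carl_update(st, classify_feedback(1, actions, payoffs), n)
      expect_true(all(st$q >= -1 & st$q <= 1))
    }
  }
})

test_that("unbiased update equals the single-rate collective RW oracle", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    alpha <- stats::runif(1, 0.01, 1)
    q0 <- stats::runif(2, -1, 1)
    actions <- sample(1:2, n, replace = TRUE)
    payoffs <- sample(c(-1L, 1L), n, replace = TRUE)
    st <- agent_state(q0, alpha_plus = alpha, alpha_minus = alpha)
    got <- carl_update(st, classify_feedback(1, actions, payoffs), n)$q
    expect_equal(got, rw_collective_update(q0, actions, payoffs, alpha, n))
  }
})

test_that("the n = 1 model reduces to a solo positivity-biased learner", {
  set.seed(29)
  for (rep in 1:40) {
    q0 <- stats::runif(2, -1, 1)
    ap <- stats::runif(1, 0.02, 0.5); am <- stats::runif(1, 0.02, 0.5)
    action <- sample(1:2, 1)
    payoff <- sample(c(-1L, 1L), 1)
    st <- agent_state(q0, alpha_plus = ap, alpha_minus = am)
    got <- carl_update(st, classify_feedback(1, action, payoff), n = 1)$q
    expect_equal(got, solo_two_rate_update(q0, action, payoff, ap, am))
  }
})
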