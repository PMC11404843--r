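#' Deterministic two-agent model state
#'
#' State of the expected-update (mean-field) version of the collective
#' asymmetric learning model for two agents: both agents' Q-value pairs plus
#' the shared parameters. Averaging each stochastic update over its
#' probability of occurrence removes simulation noise, so trajectories can be
#' inspected in a single run and fixed points probed directly.
#'
#' @param q_i,q_j Numeric Q-value pairs for agents i and j, each in \[-1, 1\].
#' @param alpha_plus,alpha_minus Learning rates in (0, 1\].
#' @param beta Inverse temperature >= 0.
#' @param task A [bandit_task()], preset name, or `(p1, p2)` pair.
#' @return An object of class `deterministic_state`.
#' @export
deterministic_state <- function(q_i = c(0, 0), q_j = c(0, 0),
                                alpha_plus = 0.1, alpha_minus = 0.1,
                                beta = 4, task = "rich") {
  task <- as_bandit_task(task)
  stopifnot(length(q_i) == 2L, length(q_j) == 2L,
            all(abs(c(q_i, q_j)) <= 1), beta >= 0,
            alpha_plus > 0, alpha_plus <= 1, alpha_minus > 0, alpha_minus <= 1)
  structure(list(q_i = as.numeric(q_i), q_j = as.numeric(q_j),
                 alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                 beta = beta, task = task),
            class = "deterministic_state")
}

#' Expected update of a chosen arm's Q-value
#'
#' The expected prediction-error increment for an arm the agent chose:
#' a reward (probability `p_a`) is confirmatory, a penalty disconfirmatory,
#' giving `alpha_plus * p_a * (1 - q_a) + alpha_minus * (1 - p_a) * (-1 - q_a)`.
#' Its zero is the chosen-arm stationary value
#' `q* = (a+ p - a- (1-p)) / (a+ p + a- (1-p))`.
#'
#' @param q_a Current Q-value of the arm.
#' @param p_a Arm reward probability in \[0, 1\].
#' @param alpha_plus,alpha_minus Learning rates.
#' @return The expected increment (unscaled by group size or choice
#'   probabilities).
#' @export
expected_update_chosen <- function(q_a, p_a, alpha_plus, alpha_minus) {
  stopifnot(all(p_a >= 0 & p_a <= 1))
  alpha_plus * p_a * (1 - q_a) + alpha_minus * (1 - p_a) * (-1 - q_a)
}

#' Expected update of an unchosen arm's Q-value
#'
#' As [expected_update_chosen()] with the learning rates swapped: on the arm
#' the agent did not choose, a reward observed on a peer is disconfirmatory
#' and a penalty confirmatory.
#'
#' @inheritParams expected_update_chosen
#' @export
expected_update_unchosen <- function(q_a, p_a, alpha_plus, alpha_minus) {
  expected_update_chosen(q_a, p_a, alpha_minus, alpha_plus)
}

det_increment <- function(state, scaling) {
  p <- c(state$task$p1, state$task$p2)
  x_i <- vapply(1:2, function(a) softmax_policy(state$q_i, state$beta, a),
                numeric(1))
  x_j <- vapply(1:2, function(a) softmax_policy(state$q_j, state$beta, a),
                numeric(1))
  inc_for <- function(q_self, x_self, x_other) {
    dc <- expected_update_chosen(q_self, p, state$alpha_plus,
                                 state$alpha_minus)
    du <- expected_update_unchosen(q_self, p, state$alpha_plus,
                                   state$alpha_minus)
    inc <- x_self * (1 + x_other) * dc + (1 - x_self) * x_other * du
    if (scaling == "expected") inc / 2 else inc
  }
  list(inc_i = inc_for(state$q_i, x_i, x_j),
       inc_j = inc_for(state$q_j, x_j, x_i),
       x_i = x_i, x_j = x_j)
}

#' One step of the deterministic two-agent model
#'
#' For each agent and each arm `a`, the Q-value is incremented by
#' `X_self(a) * (1 + X_other(a)) * delta_c(a) + (1 - X_self(a)) * X_other(a)
#' * delta_u(a)`, where the behavior profiles `X` come from the softmax at
#' the current Q-values and `delta_c` / `delta_u` are the expected chosen /
#' unchosen updates. All four arm values advance simultaneously from the
#' start-of-step state, so swapping the agents swaps trajectories exactly and
#' a symmetric state stays symmetric.
#'
#' Scaling: the combination above, as printed in its source, is exactly twice
#' the stochastic model's expected one-trial increment (the 1/n = 1/2 factor
#' of the collective update is dropped). `scaling = "expected"` (default)
#' multiplies by 1/2 and matches a Monte-Carlo expected-update oracle;
#' `"printed"` keeps the doubled form. Both have identical fixed points; the
#' printed form just runs at doubled speed.
#'
#' @param state A [deterministic_state()].
#' @param scaling `"expected"` (probability-consistent, default) or
#'   `"printed"`.
#' @return The next `deterministic_state`.
#' @export
deterministic_step <- function(state, scaling = c("expected", "printed")) {
  stopifnot(inherits(state, "deterministic_state"))
  scaling <- match.arg(scaling)
  d <- det_increment(state, scaling)
  state$q_i <- state$q_i + d$inc_i
  state$q_j <- state$q_j + d$inc_j
  state
}

#' Iterate the deterministic model
#'
#' @param state0 Initial [deterministic_state()].
#' @param steps Number of steps (>= 1).
#' @param scaling Passed to [deterministic_step()].
#' @return A data.frame with columns `step` (0..steps), `agent` ("i"/"j"),
#'   `arm` (1/2), `q` and `x` (behavior profile at that state).
#' @export
trajectory <- function(state0, steps, scaling = c("expected", "printed")) {
  stopifnot(steps >= 1)
  scaling <- match.arg(scaling)
  state <- state0
  rows <- vector("list", steps + 1L)
  snap <- function(s, step) {
    data.frame(step = step, agent = rep(c("i", "j"), each = 2),
               arm = rep(1:2, 2), q = c(s$q_i, s$q_j),
               x = c(vapply(1:2, function(a) softmax_policy(s$q_i, s$beta, a),
                            numeric(1)),
                     vapply(1:2, function(a) softmax_policy(s$q_j, s$beta, a),
                            numeric(1))))
  }
  rows[[1]] <- snap(state, 0L)
  for (k in seq_len(steps)) {
    state <- deterministic_step(state, scaling)
    rows[[k + 1L]] <- snap(state, k)
  }
  do.call(rbind, rows)
}

#' Find a fixed point by damped iteration
#'
#' Applies `q <- q + damping * increment(q)` until the largest absolute
#' increment falls below `tol`. Stability is probed elsewhere by epsilon-
#' perturbation of the returned point rather than by Jacobian eigenvalues.
#'
#' @param state0 Starting [deterministic_state()].
#' @param tol Convergence tolerance on the raw increment (default 1e-10).
#' @param damping Step damping factor in (0, 1\].
#' @param max_iter Iteration cap.
#' @param scaling Passed to the increment computation.
#' @return The converged `deterministic_state`, with attribute `"iterations"`.
#' @export
find_fixed_point <- function(state0, tol = 1e-10, damping = 0.5,
                             max_iter = 100000L,
                             scaling = c("expected", "printed")) {
  scaling <- match.arg(scaling)
  state <- state0
  for (k in seq_len(max_iter)) {
    d <- det_increment(state, scaling)
    if (max(abs(c(d$inc_i, d$inc_j))) < tol) {
      attr(state, "iterations") <- k
      return(state)
    }
    state$q_i <- state$q_i + damping * d$inc_i
    state$q_j <- state$q_j + damping * d$inc_j
  }
  warning("fixed-point iteration did not converge within max_iter")
  attr(state, "iterations") <- max_iter
  state
}
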