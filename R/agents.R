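#' Agent state for collective asymmetric Q-learning
#'
#' Holds an agent's Q-value pair (one per arm, each in \[-1, 1\]), its
#' confirmatory and disconfirmatory learning rates and its softmax inverse
#' temperature. Q-values stay in \[-1, 1\] under the update rule because
#' payoffs are bounded in \[-1, +1\] and each update is a 1/n-scaled
#' convex-combination step.
#'
#' @param q Numeric pair of initial Q-values, each in \[-1, 1\].
#' @param alpha_plus Confirmatory learning rate in (0, 1\].
#' @param alpha_minus Disconfirmatory learning rate in (0, 1\].
#' @param beta Inverse temperature, >= 0.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(q = c(0, 0), alpha_plus = 0.1, alpha_minus = 0.1,
                        beta = 4) {
  stopifnot(is.numeric(q), length(q) == 2L)
  if (any(q < -1 | q > 1)) stop("Q-values must lie in [-1, 1]", call. = FALSE)
  if (alpha_plus <= 0 || alpha_plus > 1 || alpha_minus <= 0 || alpha_minus > 1)
    stop("learning rates must lie in (0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(q = as.numeric(q), alpha_plus = alpha_plus,
                 alpha_minus = alpha_minus, beta = beta),
            class = "agent_state")
}

#' Specify a confirmation-bias strength
#'
#' Bias strength is the ratio `b = alpha_plus / alpha_minus`: `b > 1` is a
#' confirmation bias, `b < 1` a disconfirmation bias, `b = 1` unbiased. Two
#' parameterisations are used in practice, plus explicit rates:
#' \describe{
#'   \item{`fixed_sum`}{rates sum to 0.2: `(0.2 b / (1+b), 0.2 / (1+b))`.
#'     Reproduces the printed pairs, e.g. b = 3 -> (0.15, 0.05),
#'     b = 17/3 -> (0.17, 0.03), b = 9 -> (0.18, 0.02), b = 1 -> (0.1, 0.1).}
#'   \item{`fixed_minus`}{`alpha_minus = 0.1` held fixed,
#'     `alpha_plus = b * 0.1` (bias-strength sweeps).}
#'   \item{`explicit`}{rates given directly; `b` is derived.}
#' }
#'
#' @param scheme One of `"fixed_sum"`, `"fixed_minus"`, `"explicit"`.
#' @param b Bias strength (> 0); required for the first two schemes.
#' @param alpha_plus,alpha_minus Explicit rates (scheme `"explicit"`).
#' @return An object of class `bias_spec`.
#' @seealso [resolve_bias()]
#' @export
bias_spec <- function(scheme = c("fixed_sum", "fixed_minus", "explicit"),
                      b = NULL, alpha_plus = NULL, alpha_minus = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "explicit") {
    if (is.null(alpha_plus) || is.null(alpha_minus))
      stop("explicit scheme requires alpha_plus and alpha_minus",
           call. = FALSE)
    if (alpha_plus <= 0 || alpha_minus <= 0)
      stop("learning rates must be positive", call. = FALSE)
    b <- alpha_plus / alpha_minus
  } else {
    if (is.null(b) || !is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0)
      stop("bias strength b must be a single positive number", call. = FALSE)
  }
  structure(list(scheme = scheme, b = as.numeric(b),
                 alpha_plus = alpha_plus, alpha_minus = alpha_minus),
            class = "bias_spec")
}

#' Resolve a bias specification to a learning-rate pair
#'
#' @param spec A [bias_spec()], or a list coercible to one
#'   (`list(scheme=, b=)` or `list(alpha_plus=, alpha_minus=)`).
#' @return Named numeric vector `c(alpha_plus=, alpha_minus=)`.
#' @export
#' @examples
#' resolve_bias(bias_spec("fixed_sum", b = 3))    # 0.15, 0.05
#' resolve_bias(bias_spec("fixed_minus", b = 5))  # 0.50, 0.10
resolve_bias <- function(spec) {
  spec <- as_bias_spec(spec)
  out <- switch(spec$scheme,
    fixed_sum   = c(0.2 * spec$b / (1 + spec$b), 0.2 / (1 + spec$b)),
    fixed_minus = c(0.1 * spec$b, 0.1),
    explicit    = c(spec$alpha_plus, spec$alpha_minus))
  names(out) <- c("alpha_plus", "alpha_minus")
  if (any(out <= 0) || any(out > 1))
    stop("resolved learning rates must lie in (0, 1]; got (",
         paste(signif(out, 4), collapse = ", "), ")", call. = FALSE)
  out
}

as_bias_spec <- function(spec) {
  if (inherits(spec, "bias_spec")) return(spec)
  if (is.list(spec)) {
    if (!is.null(spec$alpha_plus) && !is.null(spec$alpha_minus) &&
        (is.null(spec$scheme) || spec$scheme == "explicit"))
      return(bias_spec("explicit", alpha_plus = spec$alpha_plus,
                       alpha_minus = spec$alpha_minus))
    if (!is.null(spec$scheme) && !is.null(spec$b))
      return(bias_spec(spec$scheme, b = spec$b))
  }
  stop("cannot interpret bias specification", call. = FALSE)
}

#' Softmax (logistic) choice probability
#'
#' Probability that an agent with Q-values `q` picks `arm`:
#' `1 / (1 + exp(-beta * (Q(arm) - Q(other))))`. The two arms'
#' probabilities sum to 1. `beta = 0` gives the uniform-random policy;
#' `beta -> Inf` the greedy one. The exponent is clamped at +/-500 so the
#' function is numerically safe at any beta; an exact Q tie returns 0.5.
#'
#' @param q Numeric pair of Q-values.
#' @param beta Inverse temperature, >= 0.
#' @param arm Target arm (1 or 2).
#' @return Choice probability in \[0, 1\].
#' @export
softmax_policy <- function(q, beta, arm = 1L) {
  stopifnot(length(q) == 2L, beta >= 0, arm %in% c(1L, 2L))
  z <- beta * (q[arm] - q[3L - arm])
  z <- min(max(z, -500), 500)
  1 / (1 + exp(-z))
}

#' Sample synchronous arm choices for a group
#'
#' Each agent draws its arm independently from its own softmax policy; all
#' agents choose simultaneously (no within-trial sequencing).
#'
#' @param q Numeric `n x 2` matrix of Q-values (rows = agents).
#' @param beta Inverse temperature (scalar, shared by the group).
#' @return Integer vector of arm choices in `{1, 2}`.
#' @export
choose_actions <- function(q, beta) {
  q <- rbind(q)  # accept a bare pair for n = 1
  z <- pmin(pmax(beta * (q[, 1] - q[, 2]), -500), 500)
  x1 <- 1 / (1 + exp(-z))
  ifelse(stats::runif(nrow(q)) < x1, 1L, 2L)
}

#' Partition a trial's outcomes into feedback classes for one agent
#'
#' From the focal agent's point of view every agent in the group (itself
#' included) falls into exactly one of four disjoint sets:
#' \describe{
#'   \item{`r_c`}{chose the focal agent's arm and was rewarded (+1) —
#'     confirmatory;}
#'   \item{`p_c`}{chose the focal agent's arm and was penalised (-1) —
#'     disconfirmatory;}
#'   \item{`r_u`}{chose the other arm and was rewarded — disconfirmatory;}
#'   \item{`p_u`}{chose the other arm and was penalised — confirmatory.}
#' }
#' Their sizes always sum to the group size.
#'
#' @param focal Index of the focal agent (1-based).
#' @param actions Integer vector of all agents' arm choices (1 or 2).
#' @param payoffs Integer vector of all agents' payoffs (+1 or -1).
#' @return An object of class `feedback_partition`: list with integer index
#'   vectors `r_c`, `p_c`, `r_u`, `p_u`, plus `chosen` and `unchosen` arms.
#' @export
classify_feedback <- function(focal, actions, payoffs) {
  n <- length(actions)
  if (length(payoffs) != n)
    stop("actions and payoffs must have the same length", call. = FALSE)
  if (focal < 1L || focal > n) stop("focal index out of range", call. = FALSE)
  if (!all(actions %in% c(1L, 2L)) || !all(payoffs %in% c(-1L, 1L)))
    stop("actions must be in {1,2} and payoffs in {-1,+1}", call. = FALSE)
  chosen <- actions[focal]
  same <- actions == chosen
  rew <- payoffs == 1L
  idx <- seq_len(n)
  structure(list(r_c = idx[same & rew],  p_c = idx[same & !rew],
                 r_u = idx[!same & rew], p_u = idx[!same & !rew],
                 chosen = chosen, unchosen = 3L - chosen),
            class = "feedback_partition")
}

#' Collective asymmetric Q-value update for one agent
#'
#' Applies the 1/n-scaled asymmetric Rescorla-Wagner update built from all n
#' agents' outcomes. With `|r_c|` rewards and `|p_c|` penalties observed on
#' the chosen arm (Q-value `Q_c`) and `|r_u|`, `|p_u|` on the unchosen arm
#' (`Q_u`):
#' \deqn{Q_c \mathrel{+}= \frac{1}{n}\left[\alpha^+ |r_c| (1 - Q_c) +
#'   \alpha^- |p_c| (-1 - Q_c)\right]}
#' \deqn{Q_u \mathrel{+}= \frac{1}{n}\left[\alpha^+ |p_u| (-1 - Q_u) +
#'   \alpha^- |r_u| (1 - Q_u)\right]}
#' Both prediction errors use start-of-trial Q-values, and the result stays
#' in \[-1, 1\] whenever the rates are at most 1.
#'
#' @param state An [agent_state()].
#' @param partition A [classify_feedback()] result for this agent's trial.
#' @param n Group size (the partition must cover exactly n agents).
#' @return The updated `agent_state`.
#' @export
carl_update <- function(state, partition, n) {
  stopifnot(inherits(state, "agent_state"),
            inherits(partition, "feedback_partition"))
  sizes <- lengths(partition[c("r_c", "p_c", "r_u", "p_u")])
  if (sum(sizes) != n)
    stop("partition covers ", sum(sizes), " agents but n = ", n,
         call. = FALSE)
  c_arm <- partition$chosen
  u_arm <- partition$unchosen
  qc <- state$q[c_arm]
  qu <- state$q[u_arm]
  state$q[c_arm] <- qc + (state$alpha_plus * sizes[["r_c"]] * (1 - qc) +
                          state$alpha_minus * sizes[["p_c"]] * (-1 - qc)) / n
  state$q[u_arm] <- qu + (state$alpha_plus * sizes[["p_u"]] * (-1 - qu) +
                          state$alpha_minus * sizes[["r_u"]] * (1 - qu)) / n
  state
}
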