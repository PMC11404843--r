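#' Two-armed Bernoulli bandit with payoffs in {+1, -1}
#'
#' Each arm pays +1 ("reward") with its own probability and -1 ("penalty")
#' otherwise, so arm `j`'s expected payoff is `2 * p_j - 1`. Arm 1 carries
#' `p1` and is the better arm in all three scarcity presets.
#'
#' @param p1,p2 Reward probabilities of arms 1 and 2, each in \[0, 1\].
#' @return An object of class `bandit_task`: a list with fields `p1`, `p2`.
#' @seealso [scarcity_preset()], [sample_payoffs()],
#'   [expected_random_performance()]
#' @export
#' @examples
#' bandit_task(0.9, 0.7)
bandit_task <- function(p1, p2) {
  stopifnot(is.numeric(p1), length(p1) == 1L, is.numeric(p2), length(p2) == 1L)
  if (is.na(p1) || is.na(p2) || p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2)),
            class = "bandit_task")
}

#' @export
print.bandit_task <- function(x, ...) {
  cat(sprintf("<bandit_task> p1 = %g, p2 = %g (expected payoffs %g, %g)\n",
              x$p1, x$p2, 2 * x$p1 - 1, 2 * x$p2 - 1))
  invisible(x)
}

#' Scarcity presets for the bandit environment
#'
#' Three canonical resource-scarcity regimes: `"poor"` (rewards rare on both
#' arms, p = 0.3 / 0.1), `"mixed"` (0.6 / 0.4) and `"rich"` (rewards common,
#' 0.9 / 0.7). The better arm always exceeds the worse by 0.2 in reward
#' probability, i.e. by 0.4 in expected payoff.
#'
#' @param name `"poor"`, `"mixed"` or `"rich"`.
#' @return A [bandit_task()].
#' @export
#' @examples
#' scarcity_preset("rich")
scarcity_preset <- function(name) {
  presets <- list(poor  = c(0.3, 0.1),
                  mixed = c(0.6, 0.4),
                  rich  = c(0.9, 0.7))
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown scarcity preset; valid presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  p <- presets[[name]]
  task <- bandit_task(p[1], p[2])
  task$preset <- name
  task
}

as_bandit_task <- function(task) {
  if (inherits(task, "bandit_task")) return(task)
  if (is.character(task)) return(scarcity_preset(task))
  if (is.numeric(task) && length(task) == 2L)
    return(bandit_task(task[1], task[2]))
  stop("task must be a bandit_task, a preset name, or a (p1, p2) pair",
       call. = FALSE)
}

#' Sample payoffs for a vector of arm choices
#'
#' Each agent's payoff is an independent Bernoulli draw on its chosen arm:
#' +1 with that arm's reward probability, otherwise -1. Agents choosing the
#' same arm on the same trial receive independent draws.
#'
#' @param task A [bandit_task()] (or preset name).
#' @param actions Integer vector of arm choices (1 or 2), one per agent.
#' @return Integer vector of payoffs in `{+1, -1}`, same length as `actions`.
#' @export
sample_payoffs <- function(task, actions) {
  task <- as_bandit_task(task)
  actions <- as.integer(actions)
  if (length(actions) < 1L || anyNA(actions) || !all(actions %in% c(1L, 2L)))
    stop("actions must be a vector of arm indices in {1, 2}", call. = FALSE)
  p <- c(task$p1, task$p2)[actions]
  ifelse(stats::runif(length(actions)) < p, 1L, -1L)
}

#' Expected payoff of a uniform-random policy
#'
#' The baseline against which performance improvement is measured: an agent
#' choosing each arm with probability 1/2 earns `p1 + p2 - 1` per trial in
#' expectation (-0.6 / 0 / 0.6 in the poor / mixed / rich presets).
#'
#' @param task A [bandit_task()] (or preset name).
#' @return A single number in \[-1, 1\].
#' @export
expected_random_performance <- function(task) {
  task <- as_bandit_task(task)
  task$p1 + task$p2 - 1
}
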