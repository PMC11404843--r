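---
title: "Collective asymmetric Q-learning on a two-armed bandit: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective asymmetric Q-learning on a two-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carlbandit)
```

## The model

`carlbandit` simulates a group of $n$ reinforcement-learning agents that
repeatedly face the same static two-armed bandit. Arm $j$ pays $+1$
("reward") with probability $p_j$ and $-1$ ("penalty") otherwise, so its
expected payoff is $2p_j - 1$. Three scarcity presets are built in —
poor $(0.3, 0.1)$, mixed $(0.6, 0.4)$ and rich $(0.9, 0.7)$ — all with the
same expected-payoff gap of $0.4$ between arms.

Agents sit on a fully connected observation graph: at the end of every
trial each agent sees every agent's action and payoff (its own included).
Each agent $i$ keeps a Q-value per arm, bounded in $[-1, 1]$, and chooses
with a logistic softmax,
$$X^i_a = \frac{1}{1 + e^{-\beta\,(Q^i_a - Q^i_c)}},$$
where $\beta \ge 0$ is the inverse temperature ($\beta = 0$ is the uniform
policy, $\beta \to \infty$ greedy). All shipped designs use $\beta = 4$, a
value in the range fitted to human two-armed-bandit behaviour.

Every observed outcome generates a prediction error, and the update is
*asymmetric*: outcomes that confirm the focal agent's choice — a reward on
its chosen arm, or a penalty on the arm it rejected, whoever produced them
— are weighted by a confirmatory learning rate $\alpha^+$; disconfirming
outcomes (penalty on the chosen arm, reward on the rejected arm) by
$\alpha^-$. Writing $|r_c|, |p_c|$ for the counts of rewards and penalties
observed on the chosen arm $c$ and $|r_u|, |p_u|$ for the unchosen arm $u$:
$$Q_c \mathrel{+}= \tfrac{1}{n}\big[\alpha^+ |r_c|\,(1 - Q_c) +
  \alpha^- |p_c|\,(-1 - Q_c)\big], \qquad
  Q_u \mathrel{+}= \tfrac{1}{n}\big[\alpha^+ |p_u|\,(-1 - Q_u) +
  \alpha^- |r_u|\,(1 - Q_u)\big].$$
The $1/n$ scaling keeps every update a sub-unit convex step, hence the
$[-1, 1]$ bound (property-tested, including at rates of 1). The ratio
$b = \alpha^+/\alpha^-$ is the *bias strength*: $b > 1$ is a confirmation
bias, $b < 1$ a disconfirmation bias. With $b = 1$ the rule collapses to a
single-rate collective Rescorla–Wagner update, and with $n = 1$ to a solo
positivity-biased learner; both reductions are tested against independent
oracle implementations.

Two learning-rate parameterisations recur in the literature this model
comes from, and both are first-class here (`bias_spec()`):
`fixed_sum` holds $\alpha^+ + \alpha^- = 0.2$ (so $b = 3$ gives
$0.15/0.05$, $b = 9$ gives $0.18/0.02$), and `fixed_minus` holds
$\alpha^- = 0.1$ with $\alpha^+ = b \cdot 0.1$ (used in bias-strength
sweeps). Conventional decimal pairs are stored verbatim in the experiment
presets rather than re-derived from $b$, to avoid representation drift.

## Scheduling and randomness

Within a trial everything is synchronous: all agents choose from the
start-of-trial Q-values, all payoffs are drawn independently (co-acting
agents get independent draws from the same arm — the update sums over
individual outcomes, so shared draws would be a different model), and all
agents update simultaneously from the start-of-trial state. Replicate $k$
of a batch runs under its own seed, drawn once from the base seed, so
batches are order-independent and bit-reproducible.

The production engine is a small C++ loop; an independent pure-R engine
composed from the exported primitives (`classify_feedback()`,
`carl_update()`) consumes the RNG stream in the same order and is asserted
bit-identical in the tests. A full 1000-replicate, 1000-trial, 5-agent cell
takes about 0.2 s.

Initial Q-values default to $(0, 0)$ for every agent. Only "strictly
identical" starting values are required by the model's consensus argument;
zero is the symmetric uninformative point of $[-1, 1]$ and makes the
consensus fixed point directly testable. It is configurable (`q0`) for
probing sensitivity to initial conditions.

## The deterministic two-agent model

To study the dynamics without sampling noise, the two-agent model is
iterated in expectation. The expected increment of arm $a$'s value when
chosen (probability of reward $p_a$) is
$$\delta^c = \alpha^+ p_a (1 - Q_a) + \alpha^- (1 - p_a)(-1 - Q_a),$$
and when unchosen the rates swap ($\delta^u$). Combining the three
choice scenarios of agents $i$ and $j$ with their softmax probabilities
gives the per-step map implemented in `deterministic_step()`:
$$Q^i_a \mathrel{+}= s \cdot \big[ X^i_a (1 + X^j_a)\,\delta^c +
  (1 - X^i_a)\,X^j_a\,\delta^u \big].$$

**A scaling note.** The bracketed combination is the form this model is
usually quoted in, but it is exactly *twice* the stochastic model's
expected one-trial increment: enumerating the scenarios with the $1/n =
1/2$ update scaling gives $\tfrac12 X^i_a(1+X^j_a)\delta^c +
\tfrac12(1-X^i_a)X^j_a\delta^u$. We verified this with a Monte-Carlo
oracle ($10^5$ frozen-policy draws of the stochastic update at random
states): the halved form matches within 3 standard errors, the unscaled
form sits at $2\times$ and is rejected. `deterministic_step()` therefore
defaults to `scaling = "expected"` ($s = 1/2$) and offers
`scaling = "printed"` ($s = 1$). The two have identical fixed points — a
positive constant factor does not move zeros — so all qualitative
stability conclusions are unaffected; only the time axis stretches.

Fixed points are located by damped fixed-point iteration (damping 0.5,
tolerance $10^{-10}$); stability is probed by $\varepsilon = 10^{-3}$
perturbations rather than Jacobian eigenvalues, mirroring how the
phenomenon is usually argued. Unbiased dynamics contract onto the
consensus point $Q_a = 2p_a - 1$ in every preset. At supercritical bias
(e.g. $b = 5$ under `fixed_minus`) the consensus line is still invariant —
symmetric states stay exactly symmetric — but unstable in the mixed and
rich presets: a $10^{-3}$ perturbation grows into an order-one divergence
of the two agents' Q-value gaps within 500 steps, while in the poor preset
it stays below $10^{-2}$. This is the deterministic skeleton of the
polarization seen in the stochastic runs.

## Analyses

*Performance* is the mean collected payoff per agent per trial, averaged
over replicates; *improvement* subtracts the uniform-random baseline
$p_1 + p_2 - 1$ ($-0.6/0/0.6$ by preset). Confidence intervals use a
normal approximation across replicate means (the construction is not
pinned down by convention; this is the documented default and is isolated
in `performance()`). Windowed performance (e.g. the last 100 of 200
trials) isolates the post-convergence regime.

The *final Q-value gap* $\Delta Q_f = Q(\text{best}) - Q(\text{worst})$ of
a focal agent (agent 1; agents are exchangeable, which is tested) is the
regime variable: negative gaps mean the agent favors the objectively
worse arm. Because the softmax is bounded and nonlinear, distributions of
gaps are compared through the *behavior profile*
$X_f = 1/(1 + e^{-\beta \Delta Q_f})$, converted per replicate and then
averaged — averaging the gap first and converting after would misrank
bimodal conditions.

*Regime detection* (`kde_peaks()`) fits a Gaussian KDE with Scott's-rule
bandwidth on a fixed grid spanning the gap support $\pm 3$ bandwidths and
reports strict local maxima with heights and relative heights, discarding
maxima below a configurable *prominence* threshold (default 1% of the
global maximum, intended to suppress grid noise). *Polarization*
(`polarization()`) applies the same machinery to within-run differences
between two agents' final gaps: consensus is a single mode at 0,
polarization shows off-zero modes.

### What the detector finds, honestly

At the shipped defaults the qualitative picture is: rich and mixed
environments bifurcate into a high- and a low-performance regime past a
moderate bias strength, with within-run polarization in pairs; the poor
environment is dominated by a single high-performance regime at all bias
strengths up to 5.

One caveat is worth stating precisely. In the poor preset at $b \ge 3$
about 3% of replicates end in a genuine incorrect attractor (gap near
$-0.6$, matching the closed-form stationary values of an agent locked on
the worse arm). These produce real, low KDE side-lobes with relative
heights of roughly 1–5%, which the 1% prominence default keeps. Genuine
regime peaks in the bifurcating conditions measure at $\ge 89\%$ relative
height, so any threshold of 5% or more yields the clean "poor is
unimodal" reading; at the 1% default the strict one-peak claim fails for
those cells, and the corresponding acceptance assertions are deliberately
left failing rather than recalibrated after the fact. Users doing regime
counting should choose `prominence` consciously with this gap in mind.

*Crossing points* (`intersection_group_size()`) report the smallest group
size at which a biased payoff curve meets the unbiased one on a discrete
grid of group sizes. The underlying difference at the crossing is tiny
(a few $10^{-4}$ at 500 replicates), so curves are compared under common
random numbers — identical per-group-size seeds across bias conditions —
which removes between-condition sampling noise without touching the
marginal estimates. *Optimal bias* (`optimal_bias()`) is the grid argmax
of the mean behavior profile over a bias-strength sweep; in the rich
preset with $n = 2$ the curve has a plateau over $b \in [1.5, 2.5]$ whose
internal differences are below one standard error at 1000 replicates, so
the reported argmax there is stable only up to one grid step.

## What a green test establishes — and what it does not

There is no external data: the "synthetic data" of this package *is* the
model, run at the canonical designs (group sizes 1–20, $T$ of 100–1000,
500–1000 replicates, $\beta = 4$). Green tests establish that the
implementation realises the stated update rule, policy, and expectation
dynamics (checked against independent oracles), and that the canonical
designs reproduce the reference quantitative results at desk scale. They
do not establish anything about non-stationary bandits, more than two
arms, partially observable or heterogeneous groups, asynchronous choice,
or other inverse temperatures — all outside this package's scope (the
$\beta$ parameter is exposed, but only $\beta = 4$ is validated).

## Numerical choices

* Softmax exponent clamped at $\pm 500$; exact Q ties give exactly 0.5.
* Payoffs are integer $\pm 1$; Q arithmetic is double precision.
* Replicate seeds are drawn with `sample.int(.Machine$integer.max, ...)`
  from the base seed (32-bit safe); the C++ engine uses R's own RNG
  stream, so `set.seed()` governs everything.
* KDE: `stats::density`, `bw.nrd` (Scott) by default, 512 grid points;
  degenerate (constant) samples fall back to a fixed tiny bandwidth.
* Fixed-point iteration: damping 0.5, tolerance $10^{-10}$ on the raw
  increment, hard cap $10^5$ iterations with a warning.
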