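# carlbandit

Agent-based simulation of **collective asymmetric reinforcement learning**:
groups of Q-learning agents with confirmation-biased learning rates solving
a static two-armed Bernoulli bandit under full mutual observation.

## The problem

How does a confirmation bias — weighting belief-confirming evidence more
heavily than disconfirming evidence — affect decision-making when learners
watch each other? This package implements the minimal model for that
question. A group of `n` agents repeatedly chooses between two arms paying
+1 with probabilities `p1 > p2` and −1 otherwise (scarcity presets: poor
0.3/0.1, mixed 0.6/0.4, rich 0.9/0.7). Every agent observes every agent's
action and payoff, keeps one Q-value per arm (bounded in [−1, 1]), chooses
via a softmax with inverse temperature β, and updates both arms from all
`n` observed outcomes with *asymmetric* learning rates:

- **confirmatory** outcomes — reward on the agent's chosen arm, penalty on
  the rejected arm — are weighted by α⁺;
- **disconfirmatory** outcomes — penalty on the chosen arm, reward on the
  rejected arm — by α⁻;

each prediction-error sum scaled by 1/n. Bias strength is `b = α⁺/α⁻`.
The package provides the stochastic simulator (C++ inner loop, bit-exact
pure-R reference engine), the deterministic two-agent expected-update model
for fixed-point and stability analysis, and the analysis suite:
performance and improvement over the random-policy baseline `p1 + p2 − 1`,
final-Q-value-gap distributions, behavior profiles, KDE regime (peak)
detection, biased-vs-unbiased crossing group sizes, optimal bias strength,
and within-group polarization.

Typical phenomenology at β = 4: a moderate confirmation bias helps groups
nearly everywhere and the benefit grows with group size, but in resource-
rich environments small strongly-biased groups bifurcate into high- and
low-performance regimes, polarize, and underperform unbiased groups.

## Worked example

Five weakly confirmation-biased agents (α⁺ = 0.15, α⁻ = 0.05, b = 3) in
the rich environment, 1000 replicates of 1000 trials:

```r
library(carlbandit)
cfg <- experiment_config("rich", n = 5, trials = 1000,
                         bias = bias_spec("fixed_sum", b = 3),
                         n_sims = 1000, seed = 1)
batch <- run_batch(cfg)
performance(batch)
#> <performance> mean payoff/agent/trial = 0.7765 +/- 0.0007 (95% CI), improvement = 0.1765
#>   focal (agent 1) mean = 0.7750 over trials [1, 1000], 1000 replicates

gaps <- qgap(batch$final_q, agent = 1)
mean(behavior_profile(gaps, beta = 4))
#> [1] 0.9487
kde_peaks(gaps)
#> <regime_summary> 1 peak(s), bandwidth 0.0501, n = 1000
#>   location   height relative_height
#>  0.8847201 2.211348               1
```

The group earns 0.78 per agent per trial — 0.18 above the random-policy
baseline of 0.6 — and the focal agent ends up choosing the best arm 95% of
the time; the single KDE peak at gap ≈ 0.88 says every replicate lands in
the same high-performance regime. Shrink the group to 2 and strengthen the
bias to b = 9 and the picture flips to polarization — the distribution of
the two agents' gap differences has symmetric off-zero modes, i.e. one
agent learns the task while its partner locks onto the wrong arm:

```r
cfg2 <- experiment_config("rich", n = 2, trials = 1000,
                          bias = bias_spec("fixed_sum", b = 9),
                          n_sims = 1000, seed = 1)
kde_peaks(polarization(run_batch(cfg2))$gap_differences)
#> <regime_summary> 2 peak(s), bandwidth 0.4661, n = 1000
#>   location    height relative_height
#>  -1.693328 0.3656380       0.9484628
#>   1.676808 0.3855059       1.0000000
```

The canonical experiment designs are available as presets
(`experiment_preset("fig2")`, etc., run with `run_preset()`), and a small
CLI covers the same ground:

```sh
Rscript -e 'carlbandit::carl_cli()' sweep --experiment fig2 --seed 1 --out out/
Rscript -e 'carlbandit::carl_cli()' deterministic --preset rich --b 3 \
    --steps 500 --perturb 1e-3 --out traj.csv
```

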