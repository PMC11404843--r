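#include <Rcpp.h>
using namespace Rcpp;

// Collective asymmetric Q-learning, one replicate.
//
// Per trial (synchronous, fully connected group):
//   1. every agent draws an arm from its softmax policy;
//   2. payoffs are sampled independently (+1 w.p. p[arm], else -1);
//   3. every agent updates both Q-values from ALL n agents' outcomes,
//      weighting confirmatory prediction errors by alpha_plus and
//      disconfirmatory ones by alpha_minus, each sum scaled by 1/n.
// All updates use start-of-trial Q-values (simultaneous accumulation).
//
// RNG: R's stream via unif_rand(), drawn in the exact order of the pure-R
// reference engine (n choice uniforms, then n payoff uniforms, per trial)
// so both engines are bit-identical under the same seed.

// [[Rcpp::export]]
List carl_sim_cpp(int n, int trials, double p1, double p2,
                  double alpha_plus, double alpha_minus, double beta,
                  NumericMatrix q0,
                  bool rec_q, bool rec_choices, bool rec_payoffs) {
  NumericMatrix q(n, 2);
  for (int i = 0; i < n; ++i) {
    q(i, 0) = q0(i, 0);
    q(i, 1) = q0(i, 1);
  }

  NumericVector payoff_trial_mean(trials);
  NumericVector payoff_agent_sum(n);
  NumericVector q_traj;
  IntegerVector choice_traj, payoff_traj;
  if (rec_q) q_traj = NumericVector(Dimension(trials, n, 2));
  if (rec_choices) choice_traj = IntegerVector(trials * n);
  if (rec_payoffs) payoff_traj = IntegerVector(trials * n);

  std::vector<int> choice(n);     // 0 = arm 1 (prob p1), 1 = arm 2
  std::vector<int> payoff(n);
  double p[2] = {p1, p2};

  for (int t = 0; t < trials; ++t) {
    // choices: P(arm 1) = logistic(beta * (q0 - q1)), exponent clamped
    for (int i = 0; i < n; ++i) {
      double z = beta * (q(i, 0) - q(i, 1));
      if (z > 500.0) z = 500.0;
      if (z < -500.0) z = -500.0;
      double x1 = 1.0 / (1.0 + std::exp(-z));
      choice[i] = (unif_rand() < x1) ? 0 : 1;
    }
    // payoffs, independent across agents
    double psum = 0.0;
    for (int i = 0; i < n; ++i) {
      payoff[i] = (unif_rand() < p[choice[i]]) ? 1 : -1;
      psum += payoff[i];
      payoff_agent_sum[i] += payoff[i];
    }
    payoff_trial_mean[t] = psum / n;

    // per-arm reward / penalty counts (shared by all agents)
    int n_rew[2] = {0, 0}, n_pen[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      if (payoff[i] == 1) n_rew[choice[i]]++; else n_pen[choice[i]]++;
    }

    if (rec_choices)
      for (int i = 0; i < n; ++i) choice_traj[t + trials * i] = choice[i] + 1;
    if (rec_payoffs)
      for (int i = 0; i < n; ++i) payoff_traj[t + trials * i] = payoff[i];

    // simultaneous update from start-of-trial Q
    for (int i = 0; i < n; ++i) {
      int c = choice[i], u = 1 - c;
      double qc = q(i, c), qu = q(i, u);
      double upd_c = (alpha_plus  * n_rew[c] * (1.0 - qc) +
                      alpha_minus * n_pen[c] * (-1.0 - qc)) / n;
      double upd_u = (alpha_plus  * n_pen[u] * (-1.0 - qu) +
                      alpha_minus * n_rew[u] * (1.0 - qu)) / n;
      q(i, c) = qc + upd_c;
      q(i, u) = qu + upd_u;
    }

    if (rec_q)
      for (int i = 0; i < n; ++i) {
        q_traj[t + trials * i] = q(i, 0);
        q_traj[t + trials * i + trials * n] = q(i, 1);
      }
  }

  for (int i = 0; i < n; ++i) payoff_agent_sum[i] /= trials;

  List out = List::create(
    _["final_q"] = q,
    _["payoff_trial_mean"] = payoff_trial_mean,
    _["payoff_agent_mean"] = payoff_agent_sum);
  if (rec_q) out["q_values"] = q_traj;
  if (rec_choices) {
    choice_traj.attr("dim") = Dimension(trials, n);
    out["choices"] = choice_traj;
  }
  if (rec_payoffs) {
    payoff_traj.attr("dim") = Dimension(trials, n);
    out["payoffs"] = payoff_traj;
  }
  return out;
}
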