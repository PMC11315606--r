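// Fast likelihood replays for the MF (SARSA) and MB (forward learning +
// backward planning) models. These are specialised to trees whose (state,
// action) pairs have two-element successor pairs -- every tree built by
// build_default_tree() -- so the transition model reduces to the probability
// of the designated likely successor. The general R implementations in
// R/mf-learner.R and R/mb-learner.R are the reference; tests assert exact
// agreement between the two routes.
#include <Rcpp.h>
using namespace Rcpp;

static inline void softmax2(double q0, double q1, double tau,
                            double &p0, double &p1) {
  double z0 = tau * q0, z1 = tau * q1;
  double m = z0 > z1 ? z0 : z1;
  double e0 = std::exp(z0 - m), e1 = std::exp(z1 - m);
  double s = e0 + e1;
  p0 = e0 / s;
  p1 = e1 / s;
}

// Per-choice probabilities of the chosen actions under the SARSA learner.
// States/actions 0-based; two choices per trial in trial order.
// [[Rcpp::export]]
NumericVector mf_replay_cpp(IntegerVector a1, IntegerVector s2,
                            IntegerVector a2, NumericVector reward,
                            int n_s2, double alpha, double tau) {
  int n = a1.size();
  NumericVector lik(2 * n);
  std::vector<double> Q1(2, 0.0);
  std::vector<double> Q2(n_s2 * 2, 0.0);
  for (int i = 0; i < n; ++i) {
    double p0, p1;
    softmax2(Q1[0], Q1[1], tau, p0, p1);
    lik[2 * i] = a1[i] == 0 ? p0 : p1;
    int j = s2[i];
    softmax2(Q2[j * 2], Q2[j * 2 + 1], tau, p0, p1);
    lik[2 * i + 1] = a2[i] == 0 ? p0 : p1;
    // SARSA updates: (s1,a1) bootstraps from pre-update Q2(s2,a2); then
    // (s2,a2) from the terminal reward (continuation value 0). gamma = 1.
    double d1 = 0.0 + Q2[j * 2 + a2[i]] - Q1[a1[i]];
    Q1[a1[i]] += alpha * d1;
    double d2 = reward[i] - Q2[j * 2 + a2[i]];
    Q2[j * 2 + a2[i]] += alpha * d2;
  }
  return lik;
}

// Per-choice probabilities under the MB learner. succ1: 2 x 2 (row = stage-1
// action; cols likely/unlikely stage-2 id). succ2: (n_s2 * 2) x 2 (row =
// s2 * 2 + action; cols likely/unlikely terminal id). goal_reward: n_trials x
// n_terminal matrix of goal-contingent terminal rewards.
// [[Rcpp::export]]
NumericVector mb_replay_cpp(IntegerVector a1, IntegerVector s2,
                            IntegerVector a2, IntegerVector s3,
                            NumericMatrix goal_reward,
                            IntegerMatrix succ1, IntegerMatrix succ2,
                            int n_s2, double eta, double tau) {
  int n = a1.size();
  NumericVector lik(2 * n);
  // Transition model as probability of the likely successor; a degenerate
  // pair (likely == unlikely) is pinned at 1.
  std::vector<double> p1(2), p2(n_s2 * 2);
  for (int a = 0; a < 2; ++a) p1[a] = succ1(a, 0) == succ1(a, 1) ? 1.0 : 0.5;
  for (int k = 0; k < n_s2 * 2; ++k)
    p2[k] = succ2(k, 0) == succ2(k, 1) ? 1.0 : 0.5;
  std::vector<double> Q2(n_s2 * 2), v2(n_s2), Q1(2);
  for (int i = 0; i < n; ++i) {
    // Backward planning sweep under this trial's goal map.
    for (int j = 0; j < n_s2; ++j) {
      for (int a = 0; a < 2; ++a) {
        int k = j * 2 + a;
        Q2[k] = p2[k] * goal_reward(i, succ2(k, 0)) +
                (1.0 - p2[k]) * goal_reward(i, succ2(k, 1));
      }
      v2[j] = Q2[j * 2] > Q2[j * 2 + 1] ? Q2[j * 2] : Q2[j * 2 + 1];
    }
    for (int a = 0; a < 2; ++a)
      Q1[a] = p1[a] * v2[succ1(a, 0)] + (1.0 - p1[a]) * v2[succ1(a, 1)];
    double pr0, pr1;
    softmax2(Q1[0], Q1[1], tau, pr0, pr1);
    lik[2 * i] = a1[i] == 0 ? pr0 : pr1;
    // Forward update of the stage-1 row from the observed transition. The
    // stage-2 values do not depend on the stage-1 row, so the choice-2
    // snapshot equals the trial-start plan.
    if (succ1(a1[i], 0) != succ1(a1[i], 1)) {
      if (s2[i] == succ1(a1[i], 0)) p1[a1[i]] += eta * (1.0 - p1[a1[i]]);
      else p1[a1[i]] *= (1.0 - eta);
    }
    int j = s2[i];
    softmax2(Q2[j * 2], Q2[j * 2 + 1], tau, pr0, pr1);
    lik[2 * i + 1] = a2[i] == 0 ? pr0 : pr1;
    int k = j * 2 + a2[i];
    if (succ2(k, 0) != succ2(k, 1)) {
      if (s3[i] == succ2(k, 0)) p2[k] += eta * (1.0 - p2[k]);
      else p2[k] *= (1.0 - eta);
    }
  }
  return lik;
}
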