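#pragma once
#include <vector>
#include <cmath>

// Shared generative-model likelihood kernels. A subject's data is the
// concatenation of responded trials over blocks; block_start holds the
// offset of each block plus a terminal sentinel, and agent state resets at
// every block start.

struct SubjData {
  std::vector<int> choice;       // 0 = left, 1 = right
  std::vector<int> reward;       // 0 / 1
  std::vector<int> block_start;  // size n_blocks + 1, last = total trials
};

inline double log_softmax_choice_2(double w_chosen, double w_other,
                                   double beta) {
  double d = beta * (w_other - w_chosen);
  if (d > 35.0) return -d;
  return -log1p(exp(d));
}

// pw, when non-null, receives per-trial log-likelihoods.
inline double rl_loglik_subj(const SubjData& s, double alpha_pos,
                             double alpha_neg, double beta, double st,
                             bool counterfactual, double* pw = 0) {
  double total = 0.0;
  for (size_t b = 0; b + 1 < s.block_start.size(); ++b) {
    double q0 = 0.5, q1 = 0.5;
    int last = -1;
    for (int t = s.block_start[b]; t < s.block_start[b + 1]; ++t) {
      int a = s.choice[t];
      int r = s.reward[t];
      double w0 = q0 + (last == 0 ? st : 0.0);
      double w1 = q1 + (last == 1 ? st : 0.0);
      double ll = (a == 0) ? log_softmax_choice_2(w0, w1, beta)
                           : log_softmax_choice_2(w1, w0, beta);
      if (pw) pw[t] = ll;
      total += ll;
      double rate = (r == 1) ? alpha_pos : alpha_neg;
      double qc = (a == 0) ? q0 : q1;
      double qu = (a == 0) ? q1 : q0;
      double qc_new = qc + rate * ((double)r - qc);
      double qu_new = counterfactual ? qu + rate * ((1.0 - (double)r) - qu) : qu;
      if (a == 0) { q0 = qc_new; q1 = qu_new; }
      else { q1 = qc_new; q0 = qu_new; }
      last = a;
    }
  }
  return total;
}

inline double bi_loglik_subj(const SubjData& s, double p_reward,
                             double p_switch, double beta, double st,
                             double epsilon, double* pw = 0) {
  double total = 0.0;
  for (size_t b = 0; b + 1 < s.block_start.size(); ++b) {
    double bel = 0.5;
    int last = -1;
    for (int t = s.block_start[b]; t < s.block_start[b + 1]; ++t) {
      int a = s.choice[t];
      int r = s.reward[t];
      double w0 = bel + (last == 0 ? st : 0.0);
      double w1 = (1.0 - bel) + (last == 1 ? st : 0.0);
      double ll = (a == 0) ? log_softmax_choice_2(w0, w1, beta)
                           : log_softmax_choice_2(w1, w0, beta);
      if (pw) pw[t] = ll;
      total += ll;
      double lik_left, lik_right;
      if (a == 0) {
        lik_left = (r == 1) ? p_reward : 1.0 - p_reward;
        lik_right = (r == 1) ? epsilon : 1.0 - epsilon;
      } else {
        lik_left = (r == 1) ? epsilon : 1.0 - epsilon;
        lik_right = (r == 1) ? p_reward : 1.0 - p_reward;
      }
      double num = lik_left * bel;
      double den = num + lik_right * (1.0 - bel);
      double post = (den > 0.0) ? num / den : 0.5;
      bel = (1.0 - p_switch) * post + p_switch * (1.0 - post);
      last = a;
    }
  }
  return total;
}
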