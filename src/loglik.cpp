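#include <Rcpp.h>
#include "models.h"
using namespace Rcpp;

// Session log-likelihoods for the two generative choice models, evaluated over
// responded trials only (non-response trials are dropped upstream: they carry
// no action-outcome pair and leave agent state untouched).
//
// Blocks are independent sequences: agent state (values/beliefs and the
// previous action used by the stickiness bonus) resets at each block start.
// Sides are coded 0 = left, 1 = right. The trial-level kernels live in
// models.h and are shared with the hierarchical sampler.

static SubjData blocks_to_subjdata(List blocks) {
  SubjData s;
  s.block_start.push_back(0);
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    IntegerVector choice = blk["choice"];
    IntegerVector reward = blk["reward"];
    for (int t = 0; t < choice.size(); ++t) {
      s.choice.push_back(choice[t]);
      s.reward.push_back(reward[t]);
    }
    s.block_start.push_back((int)s.choice.size());
  }
  return s;
}

// [[Rcpp::export(name = ".rl_loglik_cpp")]]
NumericVector rl_loglik_cpp(List blocks, double alpha_pos, double alpha_neg,
                            double beta, double st, bool counterfactual,
                            bool pointwise) {
  SubjData s = blocks_to_subjdata(blocks);
  NumericVector out(pointwise ? (int)s.choice.size() : 1);
  double total = rl_loglik_subj(s, alpha_pos, alpha_neg, beta, st,
                                counterfactual,
                                pointwise ? out.begin() : (double*)0);
  if (!pointwise) out[0] = total;
  return out;
}

// [[Rcpp::export(name = ".bi_loglik_cpp")]]
NumericVector bi_loglik_cpp(List blocks, double p_reward, double p_switch,
                            double beta, double st, double epsilon,
                            bool pointwise) {
  SubjData s = blocks_to_subjdata(blocks);
  NumericVector out(pointwise ? (int)s.choice.size() : 1);
  double total = bi_loglik_subj(s, p_reward, p_switch, beta, st, epsilon,
                                pointwise ? out.begin() : (double*)0);
  if (!pointwise) out[0] = total;
  return out;
}
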