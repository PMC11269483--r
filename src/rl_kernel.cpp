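#include <Rcpp.h>
using namespace Rcpp;

// Additive-logit softmax over the two presented options.
// Stickiness indicators use the previous trial of the same session only.
static inline double prob_left(double qL, double qR, double beta,
                               double k_side, double k_stim,
                               int last_stim, int last_side,
                               int stim_left, int stim_right) {
  double xl = beta * qL;
  double xr = beta * qR;
  if (last_stim > 0) {
    if (stim_left == last_stim)  xl += k_stim;
    if (stim_right == last_stim) xr += k_stim;
  }
  if (last_side == 1) xl += k_side;
  else if (last_side == 2) xr += k_side;
  // logistic form of the two-option softmax; stable for any logit gap
  return 1.0 / (1.0 + std::exp(xr - xl));
}

static inline void update_q(double* q, int chosen, int reinforced,
                            double a_rew, double a_pun, double rho,
                            double q0, int rho_mode) {
  double alpha = reinforced ? a_rew : a_pun;
  q[chosen - 1] += alpha * ((double)reinforced - q[chosen - 1]);
  if (rho < 1.0) {
    for (int k = 0; k < 3; ++k) {
      if (k == chosen - 1) continue;
      q[k] = (rho_mode == 0) ? rho * q[k] + (1.0 - rho) * q0 : rho * q[k];
    }
  }
}

// Per-subject log-likelihood of observed choices.
// subj_start: 0-based row offsets, length n_subjects + 1.
// theta: n_subjects x 6 (alpha_rew, alpha_pun, beta, kappa_side, kappa_stim, rho),
// natural scale. Q-values carry across sessions; stickiness resets per session.
// [[Rcpp::export]]
NumericVector cpp_loglik(IntegerVector subj_start, IntegerVector session,
                         IntegerVector left, IntegerVector right,
                         IntegerVector chosen, IntegerVector side,
                         IntegerVector reinforced, NumericMatrix theta,
                         double q0, int rho_mode) {
  int S = subj_start.size() - 1;
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    double a_rew = theta(s, 0), a_pun = theta(s, 1), beta = theta(s, 2);
    double k_side = theta(s, 3), k_stim = theta(s, 4), rho = theta(s, 5);
    double q[3] = {q0, q0, q0};
    int last_stim = 0, last_side = 0, cur_session = NA_INTEGER;
    double ll = 0.0;
    for (int i = subj_start[s]; i < subj_start[s + 1]; ++i) {
      if (session[i] != cur_session) {
        cur_session = session[i];
        last_stim = 0;
        last_side = 0;
      }
      double pL = prob_left(q[left[i] - 1], q[right[i] - 1], beta, k_side,
                            k_stim, last_stim, last_side, left[i], right[i]);
      double p = (side[i] == 1) ? pL : 1.0 - pL;
      if (p < 1e-300) p = 1e-300;
      ll += std::log(p);
      update_q(q, chosen[i], reinforced[i], a_rew, a_pun, rho, q0, rho_mode);
      last_stim = chosen[i];
      last_side = side[i];
    }
    out[s] = ll;
  }
  return out;
}

// Forward simulation of one agent over an encoded schedule.
// reward_prob: per-stimulus reward probabilities (index = stimulus id - 1),
// already reflecting the current contingency (reversed or not).
// q_init: starting Q-values (carry state across phases).
// Uses R's RNG: two uniforms per trial (choice, outcome).
// [[Rcpp::export]]
List cpp_simulate(IntegerVector session, IntegerVector left,
                  IntegerVector right, NumericVector params,
                  NumericVector reward_prob, NumericVector q_init,
                  double q0, int rho_mode) {
  int n = session.size();
  IntegerVector chosen(n), side(n), reinforced(n);
  double a_rew = params[0], a_pun = params[1], beta = params[2];
  double k_side = params[3], k_stim = params[4], rho = params[5];
  double q[3] = {q_init[0], q_init[1], q_init[2]};
  int last_stim = 0, last_side = 0, cur_session = NA_INTEGER;
  for (int i = 0; i < n; ++i) {
    if (session[i] != cur_session) {
      cur_session = session[i];
      last_stim = 0;
      last_side = 0;
    }
    double pL = prob_left(q[left[i] - 1], q[right[i] - 1], beta, k_side,
                          k_stim, last_stim, last_side, left[i], right[i]);
    double u_choice = R::unif_rand();
    double u_reward = R::unif_rand();
    int pick_left = (u_choice < pL) ? 1 : 0;
    int c = pick_left ? left[i] : right[i];
    int r = (u_reward < reward_prob[c - 1]) ? 1 : 0;
    chosen[i] = c;
    side[i] = pick_left ? 1 : 2;
    reinforced[i] = r;
    update_q(q, c, r, a_rew, a_pun, rho, q0, rho_mode);
    last_stim = c;
    last_side = side[i];
  }
  return List::create(_["chosen"] = chosen, _["side"] = side,
                      _["reinforced"] = reinforced,
                      _["q_final"] = NumericVector::create(q[0], q[1], q[2]));
}
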