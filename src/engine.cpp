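#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared forward machinery for the RLWM agent.
//
// Per-trial loop (one block = one fresh pair of Q tables, all entries 1/3):
//   w      = rho * min(1, K/ns)
//   pi     = w * softmax(beta * Q_WM[s,]) + (1-w) * softmax(beta * Q_RL[s,])
//   pi'    = (1-eps) * pi + eps/3
//   after feedback on valid trials:
//     Q_RL[s,a] += alpha * (r - Q_RL[s,a])         (delta rule)
//     Q_WM[s,a]  = r                               (one-shot storage)
//     Q_WM      += phi * (1/3 - Q_WM)              (decay of every entry)
// Invalid (timeout) trials contribute no likelihood and trigger no update.

static const int NA_ACTIONS = 3;
static const double Q0 = 1.0 / 3.0;

struct AgentTables {
  std::vector<double> qrl, qwm;
  int ns;
  void reset(int ns_) {
    ns = ns_;
    qrl.assign(ns * NA_ACTIONS, Q0);
    qwm.assign(ns * NA_ACTIONS, Q0);
  }
};

static inline void softmax3(const double *q, double beta, double *out) {
  double m = std::max(q[0], std::max(q[1], q[2]));
  double e0 = std::exp(beta * (q[0] - m));
  double e1 = std::exp(beta * (q[1] - m));
  double e2 = std::exp(beta * (q[2] - m));
  double z = e0 + e1 + e2;
  out[0] = e0 / z; out[1] = e1 / z; out[2] = e2 / z;
}

static inline void policy_at(const AgentTables &tab, int s,
                             double rho, double eps, double beta,
                             double k_over_ns, double *pol) {
  double w = rho * std::min(1.0, k_over_ns);
  double pw[3], pr[3];
  softmax3(&tab.qwm[s * NA_ACTIONS], beta, pw);
  softmax3(&tab.qrl[s * NA_ACTIONS], beta, pr);
  for (int a = 0; a < NA_ACTIONS; ++a) {
    double mixed = w * pw[a] + (1.0 - w) * pr[a];
    pol[a] = (1.0 - eps) * mixed + eps / NA_ACTIONS;
  }
}

static inline void update_after_feedback(AgentTables &tab, int s, int a,
                                         double r, double alpha, double phi) {
  double *qrl = &tab.qrl[s * NA_ACTIONS];
  qrl[a] += alpha * (r - qrl[a]);
  tab.qwm[s * NA_ACTIONS + a] = r;
  int n = tab.ns * NA_ACTIONS;
  for (int i = 0; i < n; ++i)
    tab.qwm[i] += phi * (Q0 - tab.qwm[i]);
}

// Negative log-likelihood of realized choices; probability of the chosen
// action is floored at 1e-12 inside the log only.
// [[Rcpp::export]]
double rlwm_nll_cpp(double alpha, double phi, double rho, double epsilon,
                    double beta, double K,
                    IntegerVector block, IntegerVector stim,
                    IntegerVector set_size, IntegerVector action,
                    IntegerVector reward, LogicalVector valid) {
  int n = block.size();
  AgentTables tab;
  int cur = INT_MIN;
  double nll = 0.0, pol[3];
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur) { cur = block[t]; tab.reset(set_size[t]); }
    if (!valid[t]) continue;
    int s = stim[t], a = action[t];
    policy_at(tab, s, rho, epsilon, beta, K / set_size[t], pol);
    nll -= std::log(std::max(pol[a], 1e-12));
    update_after_feedback(tab, s, a, (double)reward[t], alpha, phi);
  }
  return nll;
}

// Full policy matrix along the realized history (one row per trial,
// including invalid trials, whose rows are the pre-trial policy).
// [[Rcpp::export]]
NumericMatrix rlwm_policy_cpp(double alpha, double phi, double rho,
                              double epsilon, double beta, double K,
                              IntegerVector block, IntegerVector stim,
                              IntegerVector set_size, IntegerVector action,
                              IntegerVector reward, LogicalVector valid) {
  int n = block.size();
  NumericMatrix out(n, NA_ACTIONS);
  AgentTables tab;
  int cur = INT_MIN;
  double pol[3];
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur) { cur = block[t]; tab.reset(set_size[t]); }
    policy_at(tab, stim[t], rho, epsilon, beta, K / set_size[t], pol);
    for (int a = 0; a < NA_ACTIONS; ++a) out(t, a) = pol[a];
    if (valid[t])
      update_after_feedback(tab, stim[t], action[t], (double)reward[t],
                            alpha, phi);
  }
  return out;
}

// Generative pass: choices sampled via the supplied uniform draws u
// (one per trial), reward deterministic from the correct-action map.
// [[Rcpp::export]]
List rlwm_sim_cpp(double alpha, double phi, double rho, double epsilon,
                  double beta, double K,
                  IntegerVector block, IntegerVector stim,
                  IntegerVector set_size, IntegerVector correct,
                  NumericVector u, bool return_policy) {
  int n = block.size();
  IntegerVector action(n), reward(n);
  NumericMatrix pmat = return_policy ? NumericMatrix(n, NA_ACTIONS)
                                     : NumericMatrix(0, 0);
  AgentTables tab;
  int cur = INT_MIN;
  double pol[3];
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur) { cur = block[t]; tab.reset(set_size[t]); }
    int s = stim[t];
    policy_at(tab, s, rho, epsilon, beta, K / set_size[t], pol);
    if (return_policy)
      for (int a = 0; a < NA_ACTIONS; ++a) pmat(t, a) = pol[a];
    double cum = 0.0;
    int a = NA_ACTIONS - 1;
    for (int j = 0; j < NA_ACTIONS; ++j) {
      cum += pol[j];
      if (u[t] < cum) { a = j; break; }
    }
    int r = (a == correct[t]) ? 1 : 0;
    action[t] = a; reward[t] = r;
    update_after_feedback(tab, s, a, (double)r, alpha, phi);
  }
  if (return_policy)
    return List::create(_["action"] = action, _["reward"] = reward,
                        _["policy"] = pmat);
  return List::create(_["action"] = action, _["reward"] = reward);
}
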