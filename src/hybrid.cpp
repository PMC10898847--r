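#include <Rcpp.h>
using namespace Rcpp;

// Hybrid model-based / model-free agent for the two-state, two-option
// sequential task. Conventions shared by the likelihood and the simulator:
//  - actions, states and second-stage options are coded 0/1;
//  - action a's common transition leads to state a;
//  - all Q values start at 0;
//  - the chosen second-stage option updates as (1-alpha)*q + r, the chosen
//    first-stage action's model-free value is replaced by that same quantity,
//    and every unchosen value decays by (1-alpha);
//  - missing entries are coded -1; a trial with a missing first-stage choice
//    is skipped entirely (no likelihood term, no value update); a trial with
//    only the second stage missing contributes the first-stage term and the
//    repetition indicator, but no value update (nothing was observed).

static const double P_FLOOR = 1e-12;

static inline double softmax_p(double v_chosen, double v_other) {
  // probability of the chosen option, computed stably
  double m = v_chosen > v_other ? v_chosen : v_other;
  double num = std::exp(v_chosen - m);
  double den = num + std::exp(v_other - m);
  double p = num / den;
  return p < P_FLOOR ? P_FLOOR : p;
}

// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par, IntegerVector c1, IntegerVector s,
                          IntegerVector c2, IntegerVector r) {
  const double alpha = par[0], bmb = par[1], bmf = par[2], brep = par[3],
               bcons = par[4];
  const int n = c1.size();
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev = -1;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    const int a1 = c1[t];
    if (a1 < 0) continue;

    double v[2];
    for (int a = 0; a < 2; ++a) {
      const double qmb = q2[a][0] > q2[a][1] ? q2[a][0] : q2[a][1];
      v[a] = bmb * qmb + bmf * q1[a] + (a == prev ? brep : 0.0);
    }
    ll += std::log(softmax_p(v[a1], v[1 - a1]));
    prev = a1;

    const int st = s[t], a2 = c2[t], rew = r[t];
    if (st < 0 || a2 < 0 || rew < 0) continue;

    ll += std::log(softmax_p(bcons * q2[st][a2], bcons * q2[st][1 - a2]));

    const double upd = (1.0 - alpha) * q2[st][a2] + rew;
    for (int ss = 0; ss < 2; ++ss)
      for (int aa = 0; aa < 2; ++aa) q2[ss][aa] *= (1.0 - alpha);
    q2[st][a2] = upd;
    q1[a1] = upd;
    q1[1 - a1] *= (1.0 - alpha);
  }
  return ll;
}

// Generative counterpart of cpp_session_loglik. probs is n x 4 with columns
// (state0/optA, state0/optB, state1/optA, state1/optB). miss1/miss2 mark
// trials where the simulated participant omits a response. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_session(NumericVector par, NumericMatrix probs,
                          double common_prob, LogicalVector miss1,
                          LogicalVector miss2) {
  const double alpha = par[0], bmb = par[1], bmf = par[2], brep = par[3],
               bcons = par[4];
  const int n = probs.nrow();
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev = -1;

  IntegerVector c1(n, NA_INTEGER), s(n, NA_INTEGER), c2(n, NA_INTEGER),
      r(n, NA_INTEGER);
  LogicalVector common(n, NA_LOGICAL);

  for (int t = 0; t < n; ++t) {
    if (miss1[t]) continue;

    double v[2];
    for (int a = 0; a < 2; ++a) {
      const double qmb = q2[a][0] > q2[a][1] ? q2[a][0] : q2[a][1];
      v[a] = bmb * qmb + bmf * q1[a] + (a == prev ? brep : 0.0);
    }
    const int a1 = (R::runif(0.0, 1.0) < softmax_p(v[0], v[1])) ? 0 : 1;
    c1[t] = a1;
    prev = a1;

    const bool is_common = R::runif(0.0, 1.0) < common_prob;
    const int st = is_common ? a1 : 1 - a1;
    s[t] = st;
    common[t] = is_common;

    if (miss2[t]) continue;

    const int a2 =
        (R::runif(0.0, 1.0) < softmax_p(bcons * q2[st][0], bcons * q2[st][1]))
            ? 0
            : 1;
    c2[t] = a2;
    const int rew = (R::runif(0.0, 1.0) < probs(t, 2 * st + a2)) ? 1 : 0;
    r[t] = rew;

    const double upd = (1.0 - alpha) * q2[st][a2] + rew;
    for (int ss = 0; ss < 2; ++ss)
      for (int aa = 0; aa < 2; ++aa) q2[ss][aa] *= (1.0 - alpha);
    q2[st][a2] = upd;
    q1[a1] = upd;
    q1[1 - a1] *= (1.0 - alpha);
  }
  return List::create(_["c1"] = c1, _["s"] = s, _["c2"] = c2, _["r"] = r,
                      _["common"] = common);
}
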