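#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise choice log-probabilities for the four model families.
//
// Family codes (see R/rl_models.R, model_family()):
//   1  dual-rate Q-learning, inverse-gain softmax  (Q divided by beta)
//   2  dual-rate Q-learning, inverse-temperature softmax (Q times beta)
//   3  ES: dual-rate + forgetting decay + initial bias + irreducible noise
//   4  RLf-CK: single rate + forgetting decay + choice kernel
//
// Parameter vector layout (constrained scale):
//   family 1, 2 : a_gain, a_loss, beta
//   family 3    : a_gain, a_loss, beta, phi, xi, q0
//   family 4    : alpha,  phi,    beta, a_ck, tau
//
// Per-trial order of operations (families 3, 4): choice probability from the
// current state; (ES only, first trial of a pair) chosen Q set to q0; RW
// update of the chosen stimulus; forgetting decay of all six Q-values;
// (RLf-CK only) choice-kernel update of the presented pair.

static const double BETA_GAIN_FLOOR = 1e-6;

// stable log softmax probability of the option with logit lc against lo
static inline double log_p_logit(double lc, double lo) {
  double d = lo - lc;
  if (d > 35.0) return -d;
  return -log1p(exp(d));
}

// fills out[lo..lo+len) with per-trial log choice probabilities for one subject
static void subject_logp(const int* pair, const int* chosen, const int* other,
                         const int* reward, int len,
                         const double* pars, int family, double* out) {
  double q[7] = {0, 0, 0, 0, 0, 0, 0};
  double ck[7] = {0, 0, 0, 0, 0, 0, 0};
  bool seen[4] = {false, false, false, false};

  for (int t = 0; t < len; ++t) {
    int c = chosen[t], o = other[t], p = pair[t];
    double r = (double)reward[t];
    double lp;

    if (family == 1) {
      if (q[c] == q[o]) {
        lp = -M_LN2;  // exact 0.5 before any division
      } else {
        double b = pars[2] < BETA_GAIN_FLOOR ? BETA_GAIN_FLOOR : pars[2];
        lp = log_p_logit(q[c] / b, q[o] / b);
      }
    } else if (family == 2) {
      lp = log_p_logit(q[c] * pars[2], q[o] * pars[2]);
    } else if (family == 3) {
      double beta = pars[2], xi = pars[4];
      double ps = 1.0 / (1.0 + exp((q[o] - q[c]) * beta));
      lp = log((1.0 - xi) * ps + 0.5 * xi);
    } else {
      double beta = pars[2], tau = pars[4];
      lp = log_p_logit(q[c] * beta + ck[c] * tau, q[o] * beta + ck[o] * tau);
    }
    out[t] = lp;

    if (family == 3 && !seen[p]) {  // initial bias on a pair's first trial
      q[c] = pars[5];
      seen[p] = true;
    }

    double pe = r - q[c];
    double lr;
    if (family == 4) {
      lr = pars[0];
    } else {
      lr = pe > 0 ? pars[0] : pars[1];
    }
    q[c] += lr * pe;

    if (family == 3 || family == 4) {
      double phi = family == 3 ? pars[3] : pars[1];
      for (int i = 1; i <= 6; ++i) q[i] *= (1.0 - phi);
    }
    if (family == 4) {
      double a_ck = pars[3];
      ck[c] += a_ck * (1.0 - ck[c]);
      ck[o] += a_ck * (0.0 - ck[o]);
    }
  }
}

// Per-trial log choice probabilities for a whole cohort, one parameter row
// per subject. subj_start is 0-based into the trial vectors; trials of a
// subject must be contiguous and chronologically ordered.
// [[Rcpp::export]]
NumericVector cohort_trial_logp_cpp(IntegerVector subj_start, IntegerVector subj_len,
                                    IntegerVector pair, IntegerVector chosen,
                                    IntegerVector other, IntegerVector reward,
                                    NumericMatrix pars, int family) {
  int n_sub = subj_start.size();
  NumericVector out(pair.size());
  std::vector<double> pv(pars.ncol());
  for (int s = 0; s < n_sub; ++s) {
    for (int k = 0; k < pars.ncol(); ++k) pv[k] = pars(s, k);
    subject_logp(&pair[subj_start[s]], &chosen[subj_start[s]], &other[subj_start[s]],
                 &reward[subj_start[s]], subj_len[s], pv.data(), family,
                 &out[subj_start[s]]);
  }
  return out;
}

// Per-subject summed log-likelihoods (same inputs as cohort_trial_logp_cpp).
// [[Rcpp::export]]
NumericVector cohort_logp_cpp(IntegerVector subj_start, IntegerVector subj_len,
                              IntegerVector pair, IntegerVector chosen,
                              IntegerVector other, IntegerVector reward,
                              NumericMatrix pars, int family) {
  int n_sub = subj_start.size();
  NumericVector out(n_sub);
  std::vector<double> buf;
  std::vector<double> pv(pars.ncol());
  for (int s = 0; s < n_sub; ++s) {
    buf.resize(subj_len[s]);
    for (int k = 0; k < pars.ncol(); ++k) pv[k] = pars(s, k);
    subject_logp(&pair[subj_start[s]], &chosen[subj_start[s]], &other[subj_start[s]],
                 &reward[subj_start[s]], subj_len[s], pv.data(), family, buf.data());
    double tot = 0.0;
    for (int t = 0; t < subj_len[s]; ++t) tot += buf[t];
    out[s] = tot;
  }
  return out;
}
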