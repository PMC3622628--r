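#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Streaming (online) EM for the two-sample mixture model.
//
// Sufficient statistics are running averages of per-read posteriors:
//   q_p   over pure-sample reads (sums to 1),
//   q_ma, q_mb over mixed-sample reads (jointly sum to 1).
// Each incoming read is folded in with step size gamma = (n+2)^(-forget),
// n counting that sample's processed reads (continuing across epochs).
// The averages are stored as value-vector * global-multiplier so an
// update touches only the read's candidate transcripts; the M-step is
// implicit because alpha and tau are deterministic functions of the
// averages:
//   tau_a   = (S_ma + (beta_a-1)/Nm) / (1 + (beta_a+beta_b-2)/Nm)
//   alpha_a = (q_p + q_ma) / (1 + S_ma)     [S_ma = sum_t q_ma]
//   alpha_b = q_mb / S_mb                   [S_mb = sum_t q_mb]
// (the simplex-renormalised form of the M-step; see m_step() in R).

static double stream_log_lik(const IntegerVector& off, const IntegerVector& tx,
                             const NumericVector& w, const NumericVector& leff,
                             const std::vector<double>& num_per_tx) {
  // num_per_tx holds the per-transcript numerator (already includes any
  // tau factors); per-read term is sum over candidates of num/leff*w.
  double lp = 0.0;
  int n_reads = off.size() - 1;
  for (int i = 0; i < n_reads; ++i) {
    double z = 0.0;
    for (int j = off[i] - 1; j < off[i + 1] - 1; ++j) {
      int t = tx[j] - 1;
      z += num_per_tx[t] / leff[t] * w[j];
    }
    if (z > 0.0 && std::isfinite(z)) lp += std::log(z);
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_online_em(IntegerVector p_off, IntegerVector p_tx, NumericVector p_w,
                   IntegerVector m_off, IntegerVector m_tx, NumericVector m_w,
                   NumericVector leff,
                   IntegerVector sched_sample,  // 0 = pure, 1 = mixed
                   IntegerVector sched_read,    // 1-based read index in its sample
                   IntegerVector epoch_len,     // schedule entries per epoch
                   double tau_a0, double beta_a, double beta_b,
                   double forget, double tol, double tau_floor) {
  const int T = leff.size();
  const int Np = p_off.size() - 1;
  const int Nm = m_off.size() - 1;
  const double tau_b0 = 1.0 - tau_a0;

  std::vector<double> vp(T, 1.0 / T), vma(T, tau_a0 / T), vmb(T, tau_b0 / T);
  double cp = 1.0, cm = 1.0;
  double S_ma = tau_a0, S_mb = tau_b0;
  long n_p = 0, n_m = 0;
  long n_skipped = 0;
  const double prior_shift = (Nm > 0) ? (beta_a + beta_b - 2.0) / Nm : 0.0;

  std::vector<double> trace;
  long pos = 0;
  int epochs_run = 0;
  double last_lp = NA_REAL;

  for (int ep = 0; ep < epoch_len.size(); ++ep) {
    for (long s = 0; s < epoch_len[ep]; ++s, ++pos) {
      const int smp = sched_sample[pos];
      const int ri = sched_read[pos] - 1;
      // current tau from running sums (fixed at prior mean if no mixed data)
      double tau_a = (Nm > 0)
        ? (S_ma + (beta_a - 1.0) / Nm) / (1.0 + prior_shift)
        : tau_a0;
      double tau_b = 1.0 - tau_a;
      if (!std::isfinite(tau_a)) stop("online EM diverged: tau is not finite");

      if (smp == 0) {
        // pure read: E-step numerators alpha_a/leff * w
        const int j0 = p_off[ri] - 1, j1 = p_off[ri + 1] - 1;
        double z = 0.0;
        double num[64];
        int k = j1 - j0;
        if (k > 64) stop("more than 64 candidate alignments for one read");
        for (int j = j0; j < j1; ++j) {
          int t = p_tx[j] - 1;
          double qp = cp * vp[t];
          double qma = cm * vma[t];
          // alpha_a renormalised onto the simplex: sum(q_p + q_ma) = 1 + S_ma
          double aa = (Nm > 0) ? (qp + qma) / (1.0 + S_ma) : qp;
          num[j - j0] = aa / leff[t] * p_w[j];
          z += num[j - j0];
        }
        if (!(z > 0.0) || !std::isfinite(z)) { ++n_skipped; continue; }
        double gamma = std::pow((double)n_p + 2.0, -forget);
        cp *= (1.0 - gamma);
        for (int j = j0; j < j1; ++j)
          vp[p_tx[j] - 1] += gamma * (num[j - j0] / z) / cp;
        ++n_p;
        if (cp < 1e-200) {
          for (int t = 0; t < T; ++t) vp[t] *= cp;
          cp = 1.0;
        }
      } else {
        // mixed read: numerators tau_a*alpha_a = tau_a*(q_p+q_ma)/(1+tau_a)
        // and tau_b*alpha_b = q_mb, each / leff * w
        const int j0 = m_off[ri] - 1, j1 = m_off[ri + 1] - 1;
        double za = 0.0, zb = 0.0;
        double numa[64], numb[64];
        int k = j1 - j0;
        if (k > 64) stop("more than 64 candidate alignments for one read");
        for (int j = j0; j < j1; ++j) {
          int t = m_tx[j] - 1;
          double qp = cp * vp[t];
          double qma = cm * vma[t];
          double qmb = cm * vmb[t];
          // renormalised alpha: alpha_a = (q_p+q_ma)/(1+S_ma),
          // alpha_b = q_mb/S_mb
          double aa = (qp + qma) / (1.0 + S_ma);
          double ab = (S_mb > 0.0) ? qmb / S_mb : 0.0;
          numa[j - j0] = tau_a * aa / leff[t] * m_w[j];
          numb[j - j0] = tau_b * ab / leff[t] * m_w[j];
          za += numa[j - j0];
          zb += numb[j - j0];
        }
        double z = za + zb;
        if (!(z > 0.0) || !std::isfinite(z)) { ++n_skipped; continue; }
        double gamma = std::pow((double)n_m + 2.0, -forget);
        cm *= (1.0 - gamma);
        for (int j = j0; j < j1; ++j) {
          int t = m_tx[j] - 1;
          vma[t] += gamma * (numa[j - j0] / z) / cm;
          vmb[t] += gamma * (numb[j - j0] / z) / cm;
        }
        S_ma = (1.0 - gamma) * S_ma + gamma * (za / z);
        S_mb = (1.0 - gamma) * S_mb + gamma * (zb / z);
        ++n_m;
        if (cm < 1e-200) {
          for (int t = 0; t < T; ++t) { vma[t] *= cm; vmb[t] *= cm; }
          cm = 1.0;
        }
      }
    }
    ++epochs_run;

    // epoch-end log posterior with current implicit parameters
    double tau_a = (Nm > 0)
      ? (S_ma + (beta_a - 1.0) / Nm) / (1.0 + prior_shift)
      : tau_a0;
    double tau_b = 1.0 - tau_a;
    std::vector<double> num_a(T), num_m(T);
    for (int t = 0; t < T; ++t) {
      double qp = cp * vp[t], qma = cm * vma[t], qmb = cm * vmb[t];
      double aa = (Nm > 0) ? (qp + qma) / (1.0 + S_ma) : qp;
      double ab = (S_mb > 0.0) ? qmb / S_mb : 0.0;
      num_a[t] = aa;
      num_m[t] = tau_a * aa + tau_b * ab;
    }
    double lp = stream_log_lik(p_off, p_tx, p_w, leff, num_a);
    if (Nm > 0) {
      lp += stream_log_lik(m_off, m_tx, m_w, leff, num_m);
      if (beta_a > 1.0 && tau_a > 0.0) lp += (beta_a - 1.0) * std::log(tau_a);
      if (beta_b > 1.0 && tau_b > 0.0) lp += (beta_b - 1.0) * std::log(tau_b);
    }
    if (!std::isfinite(lp)) stop("online EM diverged: log-posterior not finite");
    trace.push_back(lp);
    if (ep > 0 && std::fabs(lp - last_lp) <
          tol * (std::fabs(last_lp) + 1e-12)) {
      last_lp = lp;
      break;
    }
    last_lp = lp;
  }

  double tau_a = (Nm > 0)
    ? (S_ma + (beta_a - 1.0) / Nm) / (1.0 + prior_shift)
    : tau_a0;
  double tau_b = 1.0 - tau_a;
  NumericVector q_p(T), q_ma(T), q_mb(T), alpha_a(T), alpha_b(T);
  bool tau_b_floored = (Nm > 0) && (tau_b < tau_floor);
  for (int t = 0; t < T; ++t) {
    q_p[t] = cp * vp[t];
    q_ma[t] = cm * vma[t];
    q_mb[t] = cm * vmb[t];
    alpha_a[t] = (Nm > 0) ? (q_p[t] + q_ma[t]) / (1.0 + S_ma) : q_p[t];
    alpha_b[t] = (Nm == 0 || tau_b_floored || S_mb <= 0.0)
      ? 1.0 / T : q_mb[t] / S_mb;
  }
  return List::create(
    _["alpha_a"] = alpha_a, _["alpha_b"] = alpha_b,
    _["tau_a"] = tau_a, _["tau_b"] = tau_b,
    _["q_p"] = q_p, _["q_ma"] = q_ma, _["q_mb"] = q_mb,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["epochs_run"] = epochs_run,
    _["n_skipped"] = (double)n_skipped,
    _["tau_b_floored"] = tau_b_floored,
    _["n_steps_pure"] = (double)n_p, _["n_steps_mixed"] = (double)n_m);
}
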