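#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// MAP-EM for the correlation-motif mixture.
//
// Inputs are the per-study null/alternative log-density matrices lf0, lf1
// (G x D) evaluated at the observed moderated t-statistics, plus starting
// values for the mixing proportions pi (K) and motif matrix Q (K x D).
//
// Per gene g and class k the collapsed log-likelihood term is
//   L[g,k] = sum_d log( q[k,d] f1[g,d] + (1-q[k,d]) f0[g,d] )
//          = sum_d lf0[g,d] + sum_d log1p( q[k,d] * (f1/f0 - 1) ),
// which needs a single log per (g,k,d) because the ratio f1/f0 is bounded
// (it tends to c^df as |t| grows), so E = exp(lf1 - lf0) is precomputed once.
//
// M-step (posterior-mode updates under Dir(2,...,2) and Beta(2,2) priors):
//   pi[k]  = (sum_g z[g,k] + 1) / (G + K)
//   q[k,d] = (sum_g z[g,k] r[g,k,d] + 1) / (sum_g z[g,k] + 2)
// with r[g,k,d] = q f1 / (q f1 + (1-q) f0).
//
// The objective traced is the log posterior of Eq.-style MAP inference:
//   sum_g log sum_k pi_k exp(L[g,k]) + sum_k log pi_k
//   + sum_{k,d} log(q[k,d] (1 - q[k,d])).
// The trace records the objective at the parameters entering each
// iteration; convergence is relative change below tol.
namespace {

struct EmWork {
  int G, D, K;
  std::vector<double> Em1, base;   // f1/f0 - 1 per (g,d); sum_d lf0 per g
  std::vector<double> Sz, Szr;     // sufficient statistics of the last pass
  double q_lo, q_hi, pi_floor;

  // One E-pass at (pi, Q): fills Sz, Szr and returns the observed-data
  // log-likelihood at the INPUT parameters.
  double epass(const std::vector<double>& pi, const std::vector<double>& Q) {
    std::fill(Sz.begin(), Sz.end(), 0.0);
    std::fill(Szr.begin(), Szr.end(), 0.0);
    double loglik = 0.0;
    std::vector<double> Lg(K), rg((size_t)K * D);
    for (int g = 0; g < G; ++g) {
      const double* em = &Em1[(size_t)g * D];
      for (int k = 0; k < K; ++k) {
        // running product of per-study factors u = q f1/f0 + (1-q), logged
        // in chunks to stay inside double range: one log per (g,k)
        double s = 0.0, P = 1.0;
        for (int d = 0; d < D; ++d) {
          const double q = Q[(size_t)k * D + d];
          const double u = 1.0 + q * em[d];
          P *= u;
          if (P > 1e280 || P < 1e-280) { s += std::log(P); P = 1.0; }
          rg[(size_t)k * D + d] = q * (em[d] + 1.0) / u;
        }
        Lg[k] = s + std::log(P) + std::log(pi[k]);
      }
      double m = Lg[0];
      for (int k = 1; k < K; ++k) if (Lg[k] > m) m = Lg[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { Lg[k] = std::exp(Lg[k] - m); tot += Lg[k]; }
      loglik += base[g] + m + std::log(tot);
      for (int k = 0; k < K; ++k) {
        const double z = Lg[k] / tot;
        Sz[k] += z;
        for (int d = 0; d < D; ++d)
          Szr[(size_t)k * D + d] += z * rg[(size_t)k * D + d];
      }
    }
    return loglik;
  }

  double logprior(const std::vector<double>& pi,
                  const std::vector<double>& Q) const {
    double prior = 0.0;
    for (int k = 0; k < K; ++k) {
      prior += std::log(pi[k]);
      for (int d = 0; d < D; ++d)
        prior += std::log(Q[(size_t)k * D + d]) +
                 std::log1p(-Q[(size_t)k * D + d]);
    }
    return prior;
  }

  // MAP M-step from the current sufficient statistics.
  void mstep(std::vector<double>& pi, std::vector<double>& Q) const {
    double psum = 0.0;
    for (int k = 0; k < K; ++k) {
      pi[k] = (Sz[k] + 1.0) / (G + K);
      if (pi[k] < pi_floor) pi[k] = pi_floor;
      psum += pi[k];
    }
    for (int k = 0; k < K; ++k) pi[k] /= psum;
    for (int k = 0; k < K; ++k)
      for (int d = 0; d < D; ++d) {
        double q = (Szr[(size_t)k * D + d] + 1.0) / (Sz[k] + 2.0);
        if (q < q_lo) q = q_lo;
        if (q > q_hi) q = q_hi;
        Q[(size_t)k * D + d] = q;
      }
  }

  // One EM step: returns the objective at the input parameters and advances
  // them in place.
  double step(std::vector<double>& pi, std::vector<double>& Q) {
    double lp = epass(pi, Q) + logprior(pi, Q);
    mstep(pi, Q);
    return lp;
  }

  void project(std::vector<double>& pi, std::vector<double>& Q) const {
    double psum = 0.0;
    for (int k = 0; k < K; ++k) {
      if (pi[k] < pi_floor) pi[k] = pi_floor;
      psum += pi[k];
    }
    for (int k = 0; k < K; ++k) pi[k] /= psum;
    for (size_t i = 0; i < Q.size(); ++i) {
      if (Q[i] < q_lo) Q[i] = q_lo;
      if (Q[i] > q_hi) Q[i] = q_hi;
    }
  }
};

} // namespace

static EmWork make_work(const NumericMatrix& lf0, const NumericMatrix& lf1,
                        int K, double q_lo, double q_hi, double pi_floor) {
  EmWork w;
  w.G = lf0.nrow(); w.D = lf0.ncol(); w.K = K;
  w.q_lo = q_lo; w.q_hi = q_hi; w.pi_floor = pi_floor;
  w.Em1.resize((size_t)w.G * w.D);
  w.base.resize(w.G);
  for (int g = 0; g < w.G; ++g) {
    double b = 0.0;
    for (int d = 0; d < w.D; ++d) {
      double e = std::exp(lf1(g, d) - lf0(g, d));
      if (e > 1e300) e = 1e300;   // huge df + large |t| regime
      w.Em1[(size_t)g * w.D + d] = e - 1.0;
      b += lf0(g, d);
    }
    w.base[g] = b;
  }
  w.Sz.resize(K);
  w.Szr.resize((size_t)K * w.D);
  return w;
}

static List em_result(EmWork& w, std::vector<double>& pi,
                      std::vector<double>& Q, double lp, int iter,
                      bool converged, const std::vector<double>& trace) {
  // report the objective/likelihood consistent with the returned parameters
  double ll = w.epass(pi, Q);
  NumericMatrix Qout(w.K, w.D);
  for (int k = 0; k < w.K; ++k)
    for (int d = 0; d < w.D; ++d) Qout(k, d) = Q[(size_t)k * w.D + d];
  return List::create(
    _["pi"] = NumericVector(pi.begin(), pi.end()), _["Q"] = Qout,
    _["log_posterior"] = ll + w.logprior(pi, Q), _["log_likelihood"] = ll,
    _["n_iter"] = iter, _["converged"] = converged,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["Sz"] = NumericVector(w.Sz.begin(), w.Sz.end()));
}

// Plain MAP-EM. The trace records the objective at the parameters entering
// each iteration; convergence is relative change below tol.
// [[Rcpp::export]]
List cm_em_cpp(const NumericMatrix& lf0, const NumericMatrix& lf1,
               const NumericVector& pi0, const NumericMatrix& Q0,
               double tol, int max_iter,
               double q_lo, double q_hi, double pi_floor) {
  const int K = pi0.size(), D = lf0.ncol();
  EmWork w = make_work(lf0, lf1, K, q_lo, q_hi, pi_floor);
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> Q((size_t)K * D);
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < D; ++d) Q[(size_t)k * D + d] = Q0(k, d);
  std::vector<double> trace;
  double lp_old = R_NegInf;
  bool converged = false;
  int iter;
  std::vector<double> pi_prev, Q_prev;
  for (iter = 1; iter <= max_iter; ++iter) {
    pi_prev = pi; Q_prev = Q;
    double lp = w.step(pi, Q);
    trace.push_back(lp);
    if (iter > 1 && std::fabs(lp - lp_old) < tol * (std::fabs(lp_old) + 1e-12)) {
      converged = true;
      pi = pi_prev; Q = Q_prev;  // parameters at which lp was evaluated
      break;
    }
    lp_old = lp;
  }
  if (iter > max_iter) iter = max_iter;
  return em_result(w, pi, Q, lp_old, iter, converged, trace);
}

// MAP-EM accelerated by safeguarded squared extrapolation (SQUAREM-style):
// each cycle takes two EM steps, extrapolates along the parameter change,
// and accepts the extrapolated point only if one further EM step from it
// does not decrease the objective, so the recorded trace stays monotone and
// every accepted point is reachable by EM ascent. n_iter counts EM-step
// equivalents.
// [[Rcpp::export]]
List cm_em_accel_cpp(const NumericMatrix& lf0, const NumericMatrix& lf1,
                     const NumericVector& pi0, const NumericMatrix& Q0,
                     double tol, int max_iter,
                     double q_lo, double q_hi, double pi_floor) {
  const int K = pi0.size(), D = lf0.ncol();
  EmWork w = make_work(lf0, lf1, K, q_lo, q_hi, pi_floor);
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> Q((size_t)K * D);
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < D; ++d) Q[(size_t)k * D + d] = Q0(k, d);
  const size_t P = (size_t)K + Q.size();
  std::vector<double> th0(P), th1(P), th2(P), ths(P);
  auto pack = [&](std::vector<double>& th) {
    std::copy(pi.begin(), pi.end(), th.begin());
    std::copy(Q.begin(), Q.end(), th.begin() + K);
  };
  auto unpack = [&](const std::vector<double>& th) {
    std::copy(th.begin(), th.begin() + K, pi.begin());
    std::copy(th.begin() + K, th.end(), Q.begin());
  };
  std::vector<double> trace;
  bool converged = false;
  int nstep = 0;
  double f_last = R_NegInf;
  while (nstep < max_iter) {
    pack(th0);
    double f0 = w.step(pi, Q); ++nstep;      // objective at th0
    pack(th1);
    double f1 = w.step(pi, Q); ++nstep;      // objective at th1
    pack(th2);
    trace.push_back(f0);
    trace.push_back(f1);
    if (std::fabs(f1 - f0) < tol * (std::fabs(f0) + 1e-12)) {
      converged = true;
      unpack(th1);                            // parameters achieving f1
      f_last = f1;
      break;
    }
    double rr = 0.0, vv = 0.0;
    for (size_t i = 0; i < P; ++i) {
      const double r = th1[i] - th0[i];
      const double v = th2[i] - th1[i] - r;
      rr += r * r;
      vv += v * v;
    }
    double alpha = vv > 0 ? -std::sqrt(rr / vv) : -1.0;
    if (alpha > -1.0) alpha = -1.0;
    if (alpha < -16.0) alpha = -16.0;
    for (size_t i = 0; i < P; ++i) {
      const double r = th1[i] - th0[i];
      const double v = th2[i] - th1[i] - r;
      ths[i] = th0[i] - 2.0 * alpha * r + alpha * alpha * v;
    }
    unpack(ths);
    w.project(pi, Q);
    pack(ths);
    double fs = w.step(pi, Q); ++nstep;      // EM step from extrapolation
    if (fs >= f1) {
      trace.push_back(fs);                    // accept: monotone by test
      f_last = fs;
    } else {
      unpack(th2);                            // reject: fall back to plain EM
      f_last = f1;
    }
  }
  return em_result(w, pi, Q, f_last, nstep, converged, trace);
}
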