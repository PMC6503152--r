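#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step Heun (predictor-corrector) integration of the delayed
// six-population circuit:
//   vddot_j = (sum_k C[j,k] * S(v_k(t - D[j,k])) + I_j(t)
//              - 2 vdot_j - v_j / T_j) / T_j
// with S the centered logistic of per-population slope R. Delayed firing
// rates come from a ring buffer of past sigmoid outputs (the sigmoid
// depends only on the source population, so one buffered value per
// population per step suffices; all lags are at least one step, so the
// corrector stage can read the predictor's buffer slot). Exogenous input
// is a precomputed path for the two driven populations (MP, REL).
//
// [[Rcpp::export]]
List integrate_tc_cpp(NumericMatrix C, IntegerMatrix lag, NumericVector T,
                      NumericVector R, NumericMatrix input,
                      IntegerVector input_rows, double dt, int keep_every,
                      NumericVector v0, NumericVector vd0) {
  const int P = 6;
  const int nsteps = input.nrow();
  if (C.nrow() != P || C.ncol() != P) stop("C must be 6x6");
  int maxlag = 0, minlag = 1 << 30;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < P; ++j) {
      if (lag(i, j) > maxlag) maxlag = lag(i, j);
      if (C(i, j) != 0.0 && lag(i, j) < minlag) minlag = lag(i, j);
    }
  if (minlag < 1) stop("all coupled lags must be at least one step");
  const int nbuf = maxlag + 2;

  std::vector<double> v(P), vd(P);
  for (int j = 0; j < P; ++j) { v[j] = v0[j]; vd[j] = vd0[j]; }

  // ring buffer of sigmoid outputs, initialized at the starting state
  std::vector<double> sbuf((size_t)nbuf * P);
  auto sig = [](double x, double r) {
    return 1.0 / (1.0 + std::exp(-r * x)) - 0.5;
  };
  for (int b = 0; b < nbuf; ++b)
    for (int j = 0; j < P; ++j) sbuf[(size_t)b * P + j] = sig(v[j], R[j]);

  const int nkeep = nsteps / keep_every;
  NumericMatrix out(nkeep, P);
  int kept = 0;

  // delayed synaptic drive at buffer position `pos` for population j
  auto drive = [&](int pos, int j) {
    double s = 0.0;
    for (int k = 0; k < P; ++k) {
      double c = C(j, k);
      if (c != 0.0) {
        int b = pos - lag(j, k);
        if (b < 0) b += nbuf;
        s += c * sbuf[(size_t)b * P + k];
      }
    }
    return s;
  };

  std::vector<double> k1v(P), k1d(P), vp(P), vdp(P);
  for (int t = 0; t < nsteps; ++t) {
    const int cur = t % nbuf;
    const int nxt = (t + 1) % nbuf;
    for (int j = 0; j < P; ++j) sbuf[(size_t)cur * P + j] = sig(v[j], R[j]);
    // predictor (Euler)
    for (int j = 0; j < P; ++j) {
      double acc = drive(cur, j);
      double vdd = (acc - 2.0 * vd[j] - v[j] / T[j]) / T[j];
      k1v[j] = vd[j];
      k1d[j] = vdd;
      vp[j] = v[j] + dt * vd[j];
      vdp[j] = vd[j] + dt * vdd;
    }
    // inputs at t and t+1 (held at the final value on the last step)
    const int t2 = (t + 1 < nsteps) ? t + 1 : t;
    // corrector: slopes at t+dt using the predictor state; delayed terms
    // read the buffer one step ahead (lags >= 1 step keep this causal)
    for (int j = 0; j < P; ++j)
      sbuf[(size_t)nxt * P + j] = sig(vp[j], R[j]);
    bool bad = false;
    for (int j = 0; j < P; ++j) {
      double acc1 = drive(cur, j);
      double acc2 = drive(nxt, j);
      for (int m = 0; m < input_rows.size(); ++m) {
        if (input_rows[m] - 1 == j) {
          acc1 += input(t, m);
          acc2 += input(t2, m);
        }
      }
      double k1dd = (acc1 - 2.0 * vd[j] - v[j] / T[j]) / T[j];
      double k2dd = (acc2 - 2.0 * vdp[j] - vp[j] / T[j]) / T[j];
      v[j] += 0.5 * dt * (vd[j] + vdp[j]);
      vd[j] += 0.5 * dt * (k1dd + k2dd);
      if (!std::isfinite(v[j]) || std::fabs(v[j]) > 1e6) bad = true;
    }
    if (bad)
      stop("simulation diverged at t = %f s", t * dt);
    if ((t + 1) % keep_every == 0 && kept < nkeep) {
      for (int j = 0; j < P; ++j) out(kept, j) = v[j];
      ++kept;
    }
  }
  NumericVector vout(P), vdout(P);
  for (int j = 0; j < P; ++j) { vout[j] = v[j]; vdout[j] = vd[j]; }
  return List::create(_["v"] = out, _["state_v"] = vout,
                      _["state_vd"] = vdout);
}
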