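// Continuous-time recurrent neural network integrator for the ventral nerve
// cord chain. Forward Euler at dt (default 0.5 ms). Dense weight tables are
// fine at this scale (<= 49 neurons).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Integrate tau_i dV_i/dt = -V_i + sum_j W(j,i) sigma(V_j + theta_j)
//                            + sum_j G(j,i) (V_j - V_i) + tonic_i
// Silenced neurons are clamped at V = 0 with zero synaptic output and their
// gap junctions disconnected (equivalent to removing every edge they touch).
// Records V and S every `record_stride` steps (at t = k * stride * dt).
// [[Rcpp::export]]
List simulate_circuit_cpp(NumericMatrix W, NumericMatrix G,
                          NumericVector tau, NumericVector theta,
                          NumericVector V0, LogicalVector silenced,
                          NumericVector tonic, double dt, int n_steps,
                          int record_stride) {
  const int n = tau.size();
  if (W.nrow() != n || W.ncol() != n || G.nrow() != n || G.ncol() != n)
    stop("wiring tables do not match neuron count");
  if (dt <= 0) stop("dt must be positive");
  if (record_stride < 1) stop("record_stride must be >= 1");

  std::vector<double> V(n), S(n), dV(n), invtau(n);
  std::vector<char> off(n);
  for (int i = 0; i < n; ++i) {
    off[i] = silenced[i] ? 1 : 0;
    V[i] = off[i] ? 0.0 : V0[i];
    invtau[i] = 1.0 / tau[i];
  }

  // sparse views of the dense tables: most entries are structural zeros
  std::vector<int> w_src, w_dst, g_src, g_dst;
  std::vector<double> w_val, g_val;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (W(j, i) != 0.0) { w_src.push_back(j); w_dst.push_back(i); w_val.push_back(W(j, i)); }
      if (G(j, i) != 0.0) { g_src.push_back(j); g_dst.push_back(i); g_val.push_back(G(j, i)); }
    }

  const int n_rec = n_steps / record_stride;
  NumericMatrix Vrec(n_rec, n);
  NumericVector trec(n_rec);
  double *vrec = REAL(Vrec);
  int rec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) S[i] = off[i] ? 0.0 : sigm(V[i] + theta[i]);
    for (int i = 0; i < n; ++i) dV[i] = off[i] ? 0.0 : tonic[i];
    for (size_t e = 0; e < w_val.size(); ++e)
      dV[w_dst[e]] += w_val[e] * S[w_src[e]];
    for (size_t e = 0; e < g_val.size(); ++e) {
      const int j = g_src[e], i = g_dst[e];
      if (!off[j] && !off[i]) dV[i] += g_val[e] * (V[j] - V[i]);
    }
    for (int i = 0; i < n; ++i)
      if (!off[i]) V[i] += dt * invtau[i] * (-V[i] + dV[i]);

    if (step % record_stride == 0) {
      for (int i = 0; i < n; ++i) vrec[rec + n_rec * i] = V[i];
      trec[rec] = step * dt;
      ++rec;
    }
  }

  NumericVector Vfin(n);
  for (int i = 0; i < n; ++i) Vfin[i] = V[i];
  // synaptic outputs are recovered vectorized on the R side
  return List::create(_["time"] = trec, _["V"] = Vrec, _["V_final"] = Vfin);
}
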