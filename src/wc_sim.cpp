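#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Delay-coupled stochastic Wilson-Cowan network, Euler-Maruyama.
//
// State per region k: excitatory E_k, inhibitory I_k.
//   tau dE_k = [-E_k + (SEmax - rE E_k) SE(C_EE E_k - C_EI I_k
//               + C_E sum_j A_jk E_j(t - d_jk) + P_k)] dt + sqrt(sigma dt) dW
//   tau dI_k = [-I_k + (SImax - rI I_k) SI(C_IE E_k - C_II I_k
//               + C_I sum_j A_jk I_j(t - d_jk))] dt + sqrt(sigma dt) dV
// with S(x) = 1/(1+exp(-a(x-theta))) - 1/(1+exp(a theta)).
// History for t < 0 is held at the initial value. Noise uses R's RNG so that
// set.seed() in R controls reproducibility.

static inline double sigmoid_c(double x, double a, double theta) {
  return 1.0 / (1.0 + std::exp(-a * (x - theta))) -
         1.0 / (1.0 + std::exp(a * theta));
}

// [[Rcpp::export]]
List wc_simulate_cpp(NumericMatrix A, IntegerMatrix delay_steps,
                     NumericVector P, List params,
                     double dt, int n_steps, int record_every,
                     double init_value, double sigma) {
  const int n = A.nrow();
  if (A.ncol() != n || delay_steps.nrow() != n || delay_steps.ncol() != n)
    stop("adjacency and delay matrices must be square and conformable");
  if (P.size() != n) stop("stimulus vector length mismatch");

  const double tau = as<double>(params["tau"]);
  const double rE = as<double>(params["r_E"]);
  const double rI = as<double>(params["r_I"]);
  const double CEE = as<double>(params["C_EE"]);
  const double CEI = as<double>(params["C_EI"]);
  const double CIE = as<double>(params["C_IE"]);
  const double CII = as<double>(params["C_II"]);
  const double CE = as<double>(params["C_E"]);
  const double CI = as<double>(params["C_I"]);
  const double aE = as<double>(params["a_E"]);
  const double thE = as<double>(params["theta_E"]);
  const double aI = as<double>(params["a_I"]);
  const double thI = as<double>(params["theta_I"]);
  const double SEmax = 1.0 - 1.0 / (1.0 + std::exp(aE * thE));
  const double SImax = 1.0 - 1.0 / (1.0 + std::exp(aI * thI));

  // adjacency lists of incoming edges per region (A_jk: column k)
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<double>> wt(n);
  std::vector<std::vector<int>> dl(n);
  int max_delay = 0;
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      double w = A(j, k);
      if (w != 0.0) {
        nb[k].push_back(j);
        wt[k].push_back(w);
        int d = delay_steps(j, k);
        if (d < 0) stop("negative delay step");
        dl[k].push_back(d);
        if (d > max_delay) max_delay = d;
      }
    }
  }

  const int L = max_delay + 1;  // ring buffer length
  std::vector<double> Ebuf((size_t)L * n, init_value);
  std::vector<double> Ibuf((size_t)L * n, init_value);
  std::vector<double> E(n, init_value), I(n, init_value);
  std::vector<double> Enew(n), Inew(n);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix Erec(n_rec, n), Irec(n_rec, n);
  NumericVector times(n_rec);

  const double sdt = dt / tau;
  const double noise_amp = std::sqrt(sigma * dt) / tau;
  const bool noisy = sigma > 0.0;
  RNGScope rngscope;

  int rec = 0;
  for (int t = 0; t <= n_steps; ++t) {
    const int slot = t % L;
    double *Es = &Ebuf[(size_t)slot * n];
    double *Is = &Ibuf[(size_t)slot * n];
    for (int k = 0; k < n; ++k) { Es[k] = E[k]; Is[k] = I[k]; }

    if (t % record_every == 0) {
      for (int k = 0; k < n; ++k) { Erec(rec, k) = E[k]; Irec(rec, k) = I[k]; }
      times[rec] = t * dt;
      ++rec;
    }
    if (t == n_steps) break;

    for (int k = 0; k < n; ++k) {
      double couplE = 0.0, couplI = 0.0;
      const int deg = (int)nb[k].size();
      const int *jj = deg ? nb[k].data() : nullptr;
      const double *ww = deg ? wt[k].data() : nullptr;
      const int *dd = deg ? dl[k].data() : nullptr;
      for (int e = 0; e < deg; ++e) {
        int ds = t - dd[e];
        int s = (ds >= 0) ? (ds % L) : (ds + L) % L;  // pre-history slots hold init_value
        couplE += ww[e] * Ebuf[(size_t)s * n + jj[e]];
        couplI += ww[e] * Ibuf[(size_t)s * n + jj[e]];
      }
      double xE = CEE * E[k] - CEI * I[k] + CE * couplE + P[k];
      double xI = CIE * E[k] - CII * I[k] + CI * couplI;
      double dE = -E[k] + (SEmax - rE * E[k]) * sigmoid_c(xE, aE, thE);
      double dI = -I[k] + (SImax - rI * I[k]) * sigmoid_c(xI, aI, thI);
      Enew[k] = E[k] + sdt * dE;
      Inew[k] = I[k] + sdt * dI;
      if (noisy) {
        Enew[k] += noise_amp * norm_rand();
        Inew[k] += noise_amp * norm_rand();
      }
    }
    std::swap(E, Enew);
    std::swap(I, Inew);

    if ((t & 1023) == 0) {
      for (int k = 0; k < n; ++k) {
        if (!std::isfinite(E[k]) || !std::isfinite(I[k])) {
          stop("state blew up (non-finite) at step %d, region %d", t + 1,
               k + 1);
        }
      }
    }
  }

  for (int k = 0; k < n; ++k) {
    if (!std::isfinite(E[k]) || !std::isfinite(I[k]))
      stop("state blew up (non-finite) at final step, region %d", k + 1);
  }

  return List::create(_["E"] = Erec, _["I"] = Irec, _["times"] = times);
}
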