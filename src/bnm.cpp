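#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Conductance-based neural-mass node (mean excitatory potential V, mean
// inhibitory potential Z, slow potassium gating W) with sigmoidal
// voltage-dependent Ca/Na activation, relaxational K dynamics and a mean
// firing-rate output Q_V. Long-range excitatory input enters the excitatory
// equation through the row-normalized coupling matrix scaled by aee.
struct NodePars {
  double gCa, VCa, TCa, dCa;
  double gK,  VK,  TK,  dK;
  double gNa, VNa, TNa, dNa;
  double gL,  VL;
  double VT, dV, ZT, dZ, QVmax, QZmax;
  double aei, aie, ane, ani, rNMDA, b, phi, tau, I;
  double aee_l, aee_s, gc;
};

static NodePars unpack(const NumericVector& p) {
  NodePars q;
  q.gCa = p["gCa"]; q.VCa = p["VCa"]; q.TCa = p["TCa"]; q.dCa = p["dCa"];
  q.gK  = p["gK"];  q.VK  = p["VK"];  q.TK  = p["TK"];  q.dK  = p["dK"];
  q.gNa = p["gNa"]; q.VNa = p["VNa"]; q.TNa = p["TNa"]; q.dNa = p["dNa"];
  q.gL  = p["gL"];  q.VL  = p["VL"];
  q.VT  = p["VT"];  q.dV  = p["dV"];  q.ZT  = p["ZT"];  q.dZ  = p["dZ"];
  q.QVmax = p["QVmax"]; q.QZmax = p["QZmax"];
  q.aei = p["aei"]; q.aie = p["aie"];
  q.ane = p["ane"]; q.ani = p["ani"]; q.rNMDA = p["rNMDA"];
  q.b = p["b"]; q.phi = p["phi"]; q.tau = p["tau"]; q.I = p["I"];
  q.aee_l = p["aee_l"]; q.aee_s = p["aee_s"]; q.gc = p["gc"];
  return q;
}

static inline double sigm(double x, double thr, double del) {
  return 0.5 * (1.0 + std::tanh((x - thr) / del));
}

static void derivs(const std::vector<double>& V, const std::vector<double>& Z,
                   const std::vector<double>& W, const NumericMatrix& K,
                   double aee, const NodePars& q,
                   std::vector<double>& qv,
                   std::vector<double>& dV, std::vector<double>& dZ,
                   std::vector<double>& dW) {
  const int n = V.size();
  for (int i = 0; i < n; ++i)
    qv[i] = q.QVmax * sigm(V[i], q.VT, q.dV);
  for (int i = 0; i < n; ++i) {
    double net = 0.0;
    for (int j = 0; j < n; ++j) net += K(i, j) * qv[j];
    const double exc = (q.aee_l + q.aee_s * aee) * qv[i] + q.gc * aee * net;
    const double mCa = sigm(V[i], q.TCa, q.dCa);
    const double mNa = sigm(V[i], q.TNa, q.dNa);
    const double mK  = sigm(V[i], q.TK,  q.dK);
    const double QZ  = q.QZmax * sigm(Z[i], q.ZT, q.dZ);
    dV[i] = -(q.gCa + q.rNMDA * exc) * mCa * (V[i] - q.VCa)
            - (q.gNa * mNa + exc) * (V[i] - q.VNa)
            - q.gK * W[i] * (V[i] - q.VK)
            - q.gL * (V[i] - q.VL)
            - q.aie * Z[i] * QZ
            + q.ane * q.I;
    dZ[i] = q.b * (q.ani * q.I + q.aei * V[i] * qv[i]);
    dW[i] = q.phi * (mK - W[i]) / q.tau;
  }
}

// Time-derivatives of (V, Z, W) for a given state; used for fixed-point and
// finite-difference checks. state is n x 3 (columns V, Z, W).
// [[Rcpp::export]]
NumericMatrix cpp_bnm_deriv(NumericMatrix state, NumericMatrix K,
                            double aee, NumericVector pars) {
  const int n = state.nrow();
  NodePars q = unpack(pars);
  std::vector<double> V(n), Z(n), W(n), qv(n), dV(n), dZ(n), dW(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state(i, 0); Z[i] = state(i, 1); W[i] = state(i, 2);
  }
  derivs(V, Z, W, K, aee, q, qv, dV, dZ, dW);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = dV[i]; out(i, 1) = dZ[i]; out(i, 2) = dW[i];
  }
  return out;
}

// Euler–Maruyama integration. dt is the step in model time; noise_sd is the
// per-step SD of the Wiener increment added to V (0 disables the RNG
// entirely, so noise-free runs are bit-reproducible and seed-independent).
// Every decim-th step after burn_steps is recorded; the output is the firing
// rate Q_V, n_out x n.
// [[Rcpp::export]]
NumericMatrix cpp_bnm_integrate(NumericMatrix K, double aee,
                                NumericMatrix state0, int n_out, int decim,
                                double dt, double noise_sd, int burn_steps,
                                NumericVector pars) {
  const int n = state0.nrow();
  NodePars q = unpack(pars);
  std::vector<double> V(n), Z(n), W(n), qv(n), dV(n), dZ(n), dW(n);
  for (int i = 0; i < n; ++i) {
    V[i] = state0(i, 0); Z[i] = state0(i, 1); W[i] = state0(i, 2);
  }
  NumericMatrix out(n_out, n);
  const bool noisy = noise_sd > 0.0;
  long long step = 0;
  for (int t = -1; t < n_out; ++t) {
    const int nstep = (t < 0) ? burn_steps : decim;
    for (int s = 0; s < nstep; ++s) {
      derivs(V, Z, W, K, aee, q, qv, dV, dZ, dW);
      for (int i = 0; i < n; ++i) {
        V[i] += dt * dV[i];
        if (noisy) V[i] += noise_sd * norm_rand();
        Z[i] += dt * dZ[i];
        W[i] += dt * dW[i];
      }
      ++step;
    }
    if (t >= 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(V[i]) || !std::isfinite(Z[i]) || !std::isfinite(W[i]))
          stop("neural-mass integration diverged at step %d (node %d, aee = %f)",
               (int)step, i + 1, aee);
        out(t, i) = q.QVmax * sigm(V[i], q.VT, q.dV);
      }
    } else {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]))
          stop("neural-mass integration diverged during burn-in (node %d, aee = %f)",
               i + 1, aee);
    }
  }
  return out;
}
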