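// Brute-force fixed-step reference integrator (classical RK4) for the
// LIF-TUM network. Used as an independent oracle for the event-driven
// scheme on small motifs. When a threshold crossing is detected inside a
// step, the step is redone up to the linearly interpolated crossing time
// (local error O(dt^2)) so that resets and synaptic jumps are applied at
// the crossing, not at the grid point.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct RefNet {
  int n, nE;
  std::vector<int> post, pre, KI;
  std::vector<std::vector<int> > eff, aff;
  std::vector<double> G, TI, TR, TF, U, Ib;
  double tauM, Vth, Vr;

  // state layout: [V (n) | Y (nE) | Z (nE) | u (nE)]
  void rhs(const std::vector<double>& s, std::vector<double>& d) const {
    const double* V = &s[0];
    const double* Y = &s[n];
    const double* Z = &s[n + nE];
    const double* u = &s[n + 2 * nE];
    double* dV = &d[0];
    double* dY = &d[n];
    double* dZ = &d[n + nE];
    double* du = &d[n + 2 * nE];
    for (int i = 0; i < n; ++i) {
      double isyn = 0.0;
      if (KI[i] > 0) {
        for (int k : aff[i]) isyn += G[k] * Y[k];
        isyn /= KI[i];
      }
      dV[i] = (-V[i] + isyn + Ib[i]) / tauM;
    }
    for (int k = 0; k < nE; ++k) {
      dY[k] = -Y[k] / TI[k];
      dZ[k] = Y[k] / TI[k] - Z[k] / TR[k];
      du[k] = TF[k] > 0 ? -(u[k] - U[k]) / TF[k] : 0.0;
    }
  }

  void rk4step(std::vector<double>& s, double h,
               std::vector<double>& k1, std::vector<double>& k2,
               std::vector<double>& k3, std::vector<double>& k4,
               std::vector<double>& tmp) const {
    size_t m = s.size();
    rhs(s, k1);
    for (size_t q = 0; q < m; ++q) tmp[q] = s[q] + 0.5 * h * k1[q];
    rhs(tmp, k2);
    for (size_t q = 0; q < m; ++q) tmp[q] = s[q] + 0.5 * h * k2[q];
    rhs(tmp, k3);
    for (size_t q = 0; q < m; ++q) tmp[q] = s[q] + h * k3[q];
    rhs(tmp, k4);
    for (size_t q = 0; q < m; ++q)
      s[q] += h / 6.0 * (k1[q] + 2 * k2[q] + 2 * k3[q] + k4[q]);
  }
};

} // namespace

// [[Rcpp::export(name = ".rk4Simulate")]]
List rk4Simulate(IntegerVector edgePost, IntegerVector edgePre,
                 NumericVector edgeG, NumericVector edgeTI,
                 NumericVector edgeTR, NumericVector edgeTF,
                 NumericVector edgeU,
                 NumericVector Ib, double duration, double dt,
                 double tauM, double Vth, double Vr,
                 NumericVector v0) {
  RefNet N;
  N.n = Ib.size(); N.nE = edgePost.size();
  N.tauM = tauM; N.Vth = Vth; N.Vr = Vr;
  N.Ib.assign(Ib.begin(), Ib.end());
  N.G.assign(edgeG.begin(), edgeG.end());
  N.TI.assign(edgeTI.begin(), edgeTI.end());
  N.TR.assign(edgeTR.begin(), edgeTR.end());
  N.U.assign(edgeU.begin(), edgeU.end());
  N.TF.resize(N.nE);
  N.post.resize(N.nE); N.pre.resize(N.nE);
  N.eff.assign(N.n, std::vector<int>());
  N.aff.assign(N.n, std::vector<int>());
  for (int k = 0; k < N.nE; ++k) {
    N.post[k] = edgePost[k] - 1; N.pre[k] = edgePre[k] - 1;
    N.TF[k] = NumericVector::is_na(edgeTF[k]) ? -1.0 : edgeTF[k];
    N.eff[N.pre[k]].push_back(k);
    N.aff[N.post[k]].push_back(k);
  }
  N.KI.assign(N.n, 0);
  for (int i = 0; i < N.n; ++i) N.KI[i] = (int)N.aff[i].size();

  size_t m = N.n + 3 * (size_t)N.nE;
  std::vector<double> s(m, 0.0), s0(m), k1(m), k2(m), k3(m), k4(m), tmp(m);
  for (int i = 0; i < N.n; ++i) s[i] = v0[i];
  for (int k = 0; k < N.nE; ++k) s[N.n + 2 * N.nE + k] = N.U[k];

  std::vector<double> spikeT;
  std::vector<int> spikeId;
  double t = 0.0;
  long iterGuard = (long)(duration / dt) * 4 + 1000;
  while (t < duration && --iterGuard > 0) {
    double h = std::min(dt, duration - t);
    s0 = s;
    N.rk4step(s, h, k1, k2, k3, k4, tmp);
    double fracMin = 2.0;
    for (int i = 0; i < N.n; ++i) {
      if (s[i] >= Vth) {
        double f = (Vth - s0[i]) / (s[i] - s0[i]);
        if (f < fracMin) fracMin = f;
      }
    }
    if (fracMin > 1.0) { t += h; continue; }
    // redo the step up to the earliest interpolated crossing
    double h1 = std::max(fracMin * h, 0.0);
    if (h1 > 1e-12) {
      s = s0;
      N.rk4step(s, h1, k1, k2, k3, k4, tmp);
    } else {
      s = s0;
    }
    t += h1;
    for (int i = 0; i < N.n; ++i) {
      if (s[i] >= Vth - 1e-7) {
        spikeT.push_back(t);
        spikeId.push_back(i + 1);
        s[i] = Vr;
        for (int k : N.eff[i]) {
          double& Y = s[N.n + k];
          double& Z = s[N.n + N.nE + k];
          double& u = s[N.n + 2 * N.nE + k];
          if (N.TF[k] > 0) u = u + N.U[k] * (1.0 - u);
          Y += u * (1.0 - Y - Z);
        }
      }
    }
  }
  return List::create(_["time"] = NumericVector(spikeT.begin(), spikeT.end()),
                      _["neuron"] = IntegerVector(spikeId.begin(),
                                                  spikeId.end()));
}
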