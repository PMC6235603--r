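// Event-driven integration of the LIF network with TUM short-term
// plasticity. Between spikes every state variable has a closed form:
//   Y_ij(t) = Y0 exp(-t/TI)
//   Z_ij(t) = Z0 exp(-t/TR) + (Y0/TI) * (exp(-t/TI) - exp(-t/TR)) / (1/TR - 1/TI)
//   X = 1 - Y - Z
//   u_ij(t) = U + (u0 - U) exp(-t/TF)          (facilitating edges only)
//   tau_m dV/dt = -V + I_eff + (1/K_I) sum_j G_ij Y_ij(t)
// so V(t) is a sum of exponentials whose threshold crossing is located by
// guaranteed bracketing (interval bounds exploiting the monotonicity of
// each exponential term) plus bisection to 1e-10 ms.
//
// Lazy-update scheme: each neuron and each edge carries its own clock.
// Invariant: a neuron's clock is never older than the last jump of any of
// its afferent edges (targets are advanced before the jump is applied),
// so free closed-form evolution is always valid.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double ROOT_TOL = 1e-10;   // ms
const double TIE_TOL = 1e-12;    // simultaneity tolerance, ms

struct EdgeState {
  int post, pre;
  double G, TI, TR, TF, U;  // TF < 0 encodes "no facilitation"
  double Y, Z, u;
  double t;                 // edge clock (last jump / init), ms
};

struct Term { double B, T; };  // contribution B * exp(-dt/T) to V

class Simulator {
public:
  int n;
  double tauM, Vth, Vr, noiseDelta;
  std::vector<EdgeState> edges;
  std::vector<std::vector<int> > eff, aff;  // by pre / by post
  std::vector<double> V, tV, Ib, Ieff;
  std::vector<int> KI;
  std::vector<bool> deleted;
  std::vector<double> nextCross;            // absolute, per neuron
  // DC boundaries: absolute time, neuron, new drive value
  struct Boundary { double t; int neuron; double drive; };
  std::vector<Boundary> bounds;
  size_t nextBound = 0;

  std::vector<double> spikeT;
  std::vector<int> spikeId;

  double edgeYat(const EdgeState& e, double t) const {
    return e.Y * std::exp(-(t - e.t) / e.TI);
  }

  void edgeXZat(const EdgeState& e, double t, double& X, double& Y,
                double& Z) const {
    double dt = t - e.t;
    Y = e.Y * std::exp(-dt / e.TI);
    double a = 1.0 / e.TR - 1.0 / e.TI;
    double eR = std::exp(-dt / e.TR);
    double Zc;
    if (std::fabs(a) < 1e-12) {
      Zc = e.Z * eR + e.Y * dt / e.TI * eR;
    } else {
      Zc = e.Z * eR + (e.Y / e.TI) * (std::exp(-dt / e.TI) - eR) / a;
    }
    Z = Zc;
    X = 1.0 - Y - Z;
  }

  void advanceEdge(EdgeState& e, double t) {
    if (t <= e.t) return;
    double X, Y, Z;
    edgeXZat(e, t, X, Y, Z);
    e.Y = Y; e.Z = Z;
    if (e.TF > 0)
      e.u = e.U + (e.u - e.U) * std::exp(-(t - e.t) / e.TF);
    e.t = t;
  }

  // build the exponential-sum representation of V_i(t_i + dt)
  void buildTerms(int i, std::vector<Term>& terms, double& C0,
                  double& base) const {
    terms.clear();
    base = Ieff[i];
    double sumB = 0.0;
    if (KI[i] > 0) {
      for (int k : aff[i]) {
        const EdgeState& e = edges[k];
        if (deleted[e.pre]) continue;   // deleted neurons do not transmit
        double Y0 = edgeYat(e, tV[i]);
        if (std::fabs(Y0) < 1e-15) continue;
        double A = e.G * Y0 / KI[i];
        double T = e.TI;
        if (std::fabs(T - tauM) < 1e-9) T += 1e-6;  // avoid resonance
        double B = A * T / (T - tauM);
        terms.push_back({B, T});
        sumB += B;
      }
    }
    C0 = V[i] - base - sumB;
  }

  double evalV(const std::vector<Term>& terms, double C0, double base,
               double dt) const {
    double v = base + C0 * std::exp(-dt / tauM);
    for (const Term& tm : terms) v += tm.B * std::exp(-dt / tm.T);
    return v;
  }

  // sup of V over [d1, d2]: each exponential term is monotone in dt
  double upperBound(const std::vector<Term>& terms, double C0, double base,
                    double d1, double d2) const {
    double v = base + C0 * std::exp(-(C0 > 0 ? d1 : d2) / tauM);
    for (const Term& tm : terms)
      v += tm.B * std::exp(-(tm.B > 0 ? d1 : d2) / tm.T);
    return v;
  }

  double bisect(const std::vector<Term>& terms, double C0, double base,
                double lo, double hi) const {
    while (hi - lo > ROOT_TOL) {
      double mid = 0.5 * (lo + hi);
      if (evalV(terms, C0, base, mid) >= Vth) hi = mid; else lo = mid;
    }
    return hi;
  }

  // earliest crossing in (d1, d2) given V < Vth at both ends, or -1
  double interior(const std::vector<Term>& terms, double C0, double base,
                  double d1, double d2, int depth) const {
    if (depth > 60 || d2 - d1 < ROOT_TOL) return -1.0;
    if (upperBound(terms, C0, base, d1, d2) < Vth) return -1.0;
    double m = 0.5 * (d1 + d2);
    double fm = evalV(terms, C0, base, m);
    if (fm >= Vth) return bisect(terms, C0, base, d1, m);
    double left = interior(terms, C0, base, d1, m, depth + 1);
    if (left >= 0) return left;
    return interior(terms, C0, base, m, d2, depth + 1);
  }

  // next DC boundary affecting neuron i, strictly after t
  double nextBoundFor(int i, double t) const {
    for (size_t b = nextBound; b < bounds.size(); ++b)
      if (bounds[b].neuron == i && bounds[b].t > t) return bounds[b].t;
    return INF;
  }

  // earliest threshold crossing of neuron i (absolute time), valid until
  // the neuron's next DC boundary (where it will be recomputed)
  double computeCross(int i, double tEnd) {
    if (deleted[i]) return INF;
    std::vector<Term> terms;
    double C0, base;
    buildTerms(i, terms, C0, base);
    double lim = std::min(tEnd, nextBoundFor(i, tV[i])) - tV[i];
    if (lim <= 0) return INF;
    double d1 = 0.0, step = 0.5;
    double f1 = evalV(terms, C0, base, 0.0);
    if (f1 >= Vth) return tV[i] + TIE_TOL;  // defensive; V should be < Vth
    const double HORIZON = 2e5;
    while (d1 < lim && d1 < HORIZON) {
      // no crossing is ever possible if even the all-positive-part bound
      // (negative terms discarded) stays below threshold
      double posb = base + (C0 > 0 ? C0 * std::exp(-d1 / tauM) : 0.0);
      for (const Term& tm : terms)
        if (tm.B > 0) posb += tm.B * std::exp(-d1 / tm.T);
      if (posb < Vth - 1e-14) return INF;
      double d2 = std::min(d1 + step, lim);
      double f2 = evalV(terms, C0, base, d2);
      if (f2 >= Vth) return tV[i] + bisect(terms, C0, base, d1, d2);
      if (upperBound(terms, C0, base, d1, d2) >= Vth) {
        double r = interior(terms, C0, base, d1, d2, 0);
        if (r >= 0) return tV[i] + r;
      }
      d1 = d2;
      step = std::min(step * 2.0, 64.0);
    }
    return INF;
  }

  // advance neuron i's membrane potential to absolute time t
  void advanceNeuron(int i, double t) {
    if (t <= tV[i]) return;
    std::vector<Term> terms;
    double C0, base;
    buildTerms(i, terms, C0, base);
    V[i] = evalV(terms, C0, base, t - tV[i]);
    tV[i] = t;
  }
};

} // namespace

// [[Rcpp::export(name = ".edSimulate")]]
List edSimulate(IntegerVector edgePost, IntegerVector edgePre,
                NumericVector edgeG, NumericVector edgeTI,
                NumericVector edgeTR, NumericVector edgeTF,
                NumericVector edgeU,
                NumericVector Ib, LogicalVector inhib,
                double duration, double burnIn,
                double tauM, double Vth, double Vr,
                double noiseDelta,
                IntegerVector deletions,
                IntegerVector dcNeuron, NumericVector dcAmp,
                NumericVector dcOn, NumericVector dcOff,
                double traceDt, IntegerVector traceNeurons,
                NumericVector v0,
                double maxSpikes) {
  Simulator S;
  S.n = Ib.size();
  S.tauM = tauM; S.Vth = Vth; S.Vr = Vr; S.noiseDelta = noiseDelta;
  int nE = edgePost.size();
  S.edges.resize(nE);
  S.eff.assign(S.n, std::vector<int>());
  S.aff.assign(S.n, std::vector<int>());
  for (int k = 0; k < nE; ++k) {
    EdgeState& e = S.edges[k];
    e.post = edgePost[k] - 1; e.pre = edgePre[k] - 1;
    e.G = edgeG[k]; e.TI = edgeTI[k]; e.TR = edgeTR[k];
    e.TF = NumericVector::is_na(edgeTF[k]) ? -1.0 : edgeTF[k];
    e.U = edgeU[k];
    e.Y = 0.0; e.Z = 0.0; e.u = e.U; e.t = 0.0;
    S.eff[e.pre].push_back(k);
    S.aff[e.post].push_back(k);
  }
  S.V.assign(S.n, Vr); S.tV.assign(S.n, 0.0);
  S.Ib.assign(Ib.begin(), Ib.end());
  S.Ieff = S.Ib;
  S.KI.assign(S.n, 0);
  for (int i = 0; i < S.n; ++i) S.KI[i] = (int)S.aff[i].size();
  S.deleted.assign(S.n, false);
  for (int d : deletions) S.deleted[d - 1] = true;
  for (int i = 0; i < S.n; ++i) S.V[i] = v0[i];

  double tEnd = burnIn + duration;
  // DC boundaries on the internal clock (analysis clock + burnIn)
  for (int k = 0; k < dcNeuron.size(); ++k) {
    int nb = dcNeuron[k] - 1;
    S.bounds.push_back({burnIn + dcOn[k], nb, dcAmp[k]});
    S.bounds.push_back({burnIn + dcOff[k], nb, Ib[nb]});
  }
  std::sort(S.bounds.begin(), S.bounds.end(),
            [](const Simulator::Boundary& a, const Simulator::Boundary& b) {
              return a.t < b.t; });

  S.nextCross.assign(S.n, INF);
  for (int i = 0; i < S.n; ++i) S.nextCross[i] = S.computeCross(i, tEnd);

  // trace sampling
  bool doTrace = traceDt > 0 && traceNeurons.size() > 0;
  std::vector<int> trN(traceNeurons.begin(), traceNeurons.end());
  for (int& x : trN) --x;
  std::vector<double> trT;
  std::vector<std::vector<double> > trXout, trXin;
  double nextSample = doTrace ? burnIn : INF;

  std::vector<int> firing;
  long guard = 0;
  while (true) {
    double tCross = INF;
    for (int i = 0; i < S.n; ++i) tCross = std::min(tCross, S.nextCross[i]);
    double tBound = S.nextBound < S.bounds.size() ? S.bounds[S.nextBound].t
                                                  : INF;
    double tNext = std::min(tCross, tBound);
    // emit trace samples up to the next event
    while (doTrace && nextSample <= std::min(tNext, tEnd) + TIE_TOL &&
           nextSample <= tEnd + TIE_TOL) {
      trT.push_back(nextSample - burnIn);
      std::vector<double> xo(trN.size(), NA_REAL), xi(trN.size(), NA_REAL);
      for (size_t q = 0; q < trN.size(); ++q) {
        int i = trN[q];
        double sx = 0; int m = 0;
        for (int k : S.eff[i]) {
          double X, Y, Z;
          S.edgeXZat(S.edges[k], nextSample, X, Y, Z);
          sx += X; ++m;
        }
        if (m) xo[q] = sx / m;
        sx = 0; m = 0;
        for (int k : S.aff[i]) {
          double X, Y, Z;
          S.edgeXZat(S.edges[k], nextSample, X, Y, Z);
          sx += X; ++m;
        }
        if (m) xi[q] = sx / m;
      }
      trXout.push_back(xo); trXin.push_back(xi);
      nextSample += traceDt;
    }
    if (tNext > tEnd) break;

    if (tBound <= tCross) {
      // apply every boundary at this time
      double tb = tBound;
      while (S.nextBound < S.bounds.size() &&
             S.bounds[S.nextBound].t <= tb + TIE_TOL) {
        const Simulator::Boundary& b = S.bounds[S.nextBound];
        S.advanceNeuron(b.neuron, b.t);
        S.Ieff[b.neuron] = b.drive;
        ++S.nextBound;
        S.nextCross[b.neuron] = S.computeCross(b.neuron, tEnd);
      }
      continue;
    }

    double t = tCross;
    firing.clear();
    for (int i = 0; i < S.n; ++i)
      if (S.nextCross[i] <= t + TIE_TOL) firing.push_back(i);
    std::vector<int> touched;
    for (int j : firing) {               // ascending index order
      S.advanceNeuron(j, t);
      if (t >= burnIn) {
        S.spikeT.push_back(t - burnIn);
        S.spikeId.push_back(j + 1);
      }
      // reset (uniform in [Vr - delta, Vr + delta] if noisy)
      S.V[j] = noiseDelta > 0 ? R::runif(Vr - noiseDelta, Vr + noiseDelta)
                              : Vr;
      for (int k : S.eff[j]) {
        EdgeState& e = S.edges[k];
        if (S.deleted[e.post]) continue;
        S.advanceNeuron(e.post, t);      // before the jump (lazy invariant)
        S.advanceEdge(e, t);
        if (e.TF > 0) e.u = e.u + e.U * (1.0 - e.u);  // update-then-use
        double rel = e.u * (1.0 - e.Y - e.Z);
        e.Y += rel;
        touched.push_back(e.post);
      }
      touched.push_back(j);
      if (++guard > (long)maxSpikes)
        stop("spike budget exceeded (runaway dynamics?)");
    }
    std::sort(touched.begin(), touched.end());
    touched.erase(std::unique(touched.begin(), touched.end()),
                  touched.end());
    for (int i : touched) S.nextCross[i] = S.computeCross(i, tEnd);
  }

  List traces = R_NilValue;
  if (doTrace) {
    int m = trT.size(), q = trN.size();
    NumericMatrix xo(m, q), xi(m, q);
    for (int r = 0; r < m; ++r)
      for (int c = 0; c < q; ++c) {
        xo(r, c) = trXout[r][c];
        xi(r, c) = trXin[r][c];
      }
    traces = List::create(_["time"] = NumericVector(trT.begin(), trT.end()),
                          _["xout"] = xo, _["xin"] = xi,
                          _["neurons"] = traceNeurons);
  }
  return List::create(_["time"] = NumericVector(S.spikeT.begin(),
                                                S.spikeT.end()),
                      _["neuron"] = IntegerVector(S.spikeId.begin(),
                                                  S.spikeId.end()),
                      _["traces"] = traces);
}
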