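#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Marcus jump for one neuron: the exact post-jump voltage produced by an
// instantaneous conductance jump (We, Wi),
//   V' = Vmix + (V - Vmix) * exp(-(We+Wi)),
// with Vmix = (We*Ve + Wi*Vi) / (We + Wi). We + Wi = 0 leaves V unchanged.
// Anchoring the convex combination at Vmix keeps fully saturating jumps
// (exp(-W) underflowing to 0) exactly inside [Vi, Ve] in floating point,
// which the equivalent V + (Vmix - V) * (1 - exp(-W)) form does not.
static inline double marcus_post(double V, double We, double Wi,
                                 double Ve, double Vi) {
  double Wtot = We + Wi;
  if (Wtot <= 0.0) return V;
  double Vmix = (We * Ve + Wi * Vi) / Wtot;
  return Vmix + (V - Vmix) * std::exp(-Wtot);
}

// Event-driven Marcus simulation of n uncoupled neurons sharing an event
// train. times: N event times (increasing); We, Wi: N x n jump matrices;
// tau, Ve, Vi, Irest: per-neuron parameter vectors; V0: initial voltages at
// time 0. Returns the N x n matrix of post-event voltages.
// [[Rcpp::export]]
NumericMatrix marcus_simulate_cpp(NumericVector times, NumericMatrix We,
                                  NumericMatrix Wi, NumericVector tau,
                                  NumericVector Ve, NumericVector Vi,
                                  NumericVector Irest, NumericVector V0) {
  int N = times.size();
  int n = V0.size();
  NumericMatrix out(N, n);
  std::vector<double> V(n);
  for (int a = 0; a < n; ++a) V[a] = V0[a];
  double t = 0.0;
  for (int k = 0; k < N; ++k) {
    double dt = times[k] - t;
    if (dt < 0.0) stop("event times must be nondecreasing");
    for (int a = 0; a < n; ++a) {
      // exponential relaxation toward Irest, then the Marcus update
      double v = Irest[a] + (V[a] - Irest[a]) * std::exp(-dt / tau[a]);
      v = marcus_post(v, We(k, a), Wi(k, a), Ve[a], Vi[a]);
      V[a] = v;
      out(k, a) = v;
    }
    t = times[k];
  }
  return out;
}

// Gap-junction-coupled pair with identical membrane time constant tau.
// Between events the pair relaxes under
//   dV1/dt = (I1 - V1)/tau + (g/tau) (V2 - V1)
//   dV2/dt = (I2 - V2)/tau + (g/tau) (V1 - V2)
// solved exactly in the symmetric/antisymmetric eigenbasis with decay rates
// 1/tau and (1 + 2 g)/tau. Marcus updates apply per neuron unchanged.
// [[Rcpp::export]]
NumericMatrix gap_pair_simulate_cpp(NumericVector times, NumericMatrix We,
                                    NumericMatrix Wi, double tau,
                                    NumericVector Ve, NumericVector Vi,
                                    NumericVector Irest, double g,
                                    NumericVector V0) {
  int N = times.size();
  NumericMatrix out(N, 2);
  double V1 = V0[0], V2 = V0[1];
  double s_star = 0.5 * (Irest[0] + Irest[1]);
  double d_star = 0.5 * (Irest[0] - Irest[1]) / (1.0 + 2.0 * g);
  double t = 0.0;
  for (int k = 0; k < N; ++k) {
    double dt = times[k] - t;
    if (dt < 0.0) stop("event times must be nondecreasing");
    double s = 0.5 * (V1 + V2), d = 0.5 * (V1 - V2);
    s = s_star + (s - s_star) * std::exp(-dt / tau);
    d = d_star + (d - d_star) * std::exp(-dt * (1.0 + 2.0 * g) / tau);
    V1 = s + d;
    V2 = s - d;
    V1 = marcus_post(V1, We(k, 0), Wi(k, 0), Ve[0], Vi[0]);
    V2 = marcus_post(V2, We(k, 1), Wi(k, 1), Ve[1], Vi[1]);
    out(k, 0) = V1;
    out(k, 1) = V2;
    t = times[k];
  }
  return out;
}

// Euler integration of the finite synaptic time-constant AONCB dynamics for
// one neuron: each synaptic event at time times[k] switches on box-car
// conductances Ge/G = We[k]/eps, Gi/G = Wi[k]/eps for a duration
// tau_s = eps * tau, so that the integrated weight matches the dimensionless
// jump. Returns stationary statistics (mean, variance, third central moment
// via raw accumulators) collected after burn_in, plus a thinned voltage
// sample for distributional comparisons.
// [[Rcpp::export]]
List euler_finite_synapse_cpp(NumericVector times, NumericVector We,
                              NumericVector Wi, double tau, double Ve,
                              double Vi, double Irest, double eps,
                              double dt, double T, double burn_in,
                              double V0, int thin) {
  if (eps <= 0.0) stop("eps must be > 0");
  double tau_s = eps * tau;
  if (dt >= tau_s) stop("dt_euler must be smaller than tau_s");
  int N = times.size();
  double V = V0;
  double t = 0.0;
  int next_ev = 0;
  std::deque<std::pair<double, std::pair<double, double> > > active;
  double sumWe = 0.0, sumWi = 0.0;
  double s1 = 0.0, s2 = 0.0, s3 = 0.0;
  long nstat = 0;
  std::vector<double> samples;
  long step = 0;
  while (t < T) {
    while (next_ev < N && times[next_ev] <= t) {
      double we = We[next_ev], wi = Wi[next_ev];
      active.push_back(std::make_pair(times[next_ev] + tau_s,
                                      std::make_pair(we, wi)));
      sumWe += we;
      sumWi += wi;
      ++next_ev;
    }
    while (!active.empty() && active.front().first <= t) {
      sumWe -= active.front().second.first;
      sumWi -= active.front().second.second;
      active.pop_front();
    }
    double ge = sumWe / eps, gi = sumWi / eps;
    double dV = (-V + ge * (Ve - V) + gi * (Vi - V) + Irest) / tau;
    V += dt * dV;
    t += dt;
    ++step;
    if (t > burn_in) {
      s1 += V;
      s2 += V * V;
      s3 += V * V * V;
      ++nstat;
      if (thin > 0 && step % thin == 0) samples.push_back(V);
    }
  }
  double m = s1 / nstat;
  double var = s2 / nstat - m * m;
  double m3 = s3 / nstat - 3.0 * m * (s2 / nstat) + 2.0 * m * m * m;
  return List::create(_["mean"] = m, _["variance"] = var,
                      _["third_central"] = m3, _["n"] = (double)nstat,
                      _["samples"] = samples);
}
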