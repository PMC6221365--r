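#include <Rcpp.h>
using namespace Rcpp;

// Izhikevich two-variable neuron:
//   dv/dt = 0.04 v^2 + 5 v + 140 - u + I
//   du/dt = a (b v - u)
//   if v >= 30 mV: spike; v <- c, u <- u + d
//
// Forward Euler with two half-steps for v per full step of u, applied on an
// internal substep grid of n_sub substeps per sampling step dt. The reset is
// checked on the state entering each substep (a substep whose v has reached
// the 30 mV cutoff resets instead of integrating), and v is clamped at the
// cutoff after integration so a step reaching exactly 30 counts as a spike
// and no emitted sample exceeds 30 mV.

static inline double dvdt(double v, double u, double I) {
  return 0.04 * v * v + 5.0 * v + 140.0 - u + I;
}

// One sampling step of duration dt (n_sub substeps) for a single unit.
// Returns true if a reset fired within the step.
static inline bool izh_step(double &v, double &u,
                            double a, double b, double c, double d,
                            double I, double dt, int n_sub) {
  bool fired = false;
  double h = dt / n_sub;
  for (int s = 0; s < n_sub; ++s) {
    if (v >= 30.0) {
      v = c;
      u += d;
      fired = true;
    } else {
      v += 0.5 * h * dvdt(v, u, I);
      v += 0.5 * h * dvdt(v, u, I);
      u += h * a * (b * v - u);
      if (v > 30.0) v = 30.0;
    }
  }
  return fired;
}

// [[Rcpp::export]]
List izh_simulate_cpp(double v0, double u0,
                      double a, double b, double c, double d,
                      NumericVector I, double dt, int n_sub) {
  int n = I.size();
  NumericVector v_out(n), u_out(n);
  LogicalVector spiked(n);
  double v = v0, u = u0;
  for (int i = 0; i < n; ++i) {
    spiked[i] = izh_step(v, u, a, b, c, d, I[i], dt, n_sub);
    // samples on which the reset fired are logged at the 30 mV spike peak,
    // as the device streams them; the integrator state continues from the
    // post-reset trajectory
    v_out[i] = spiked[i] ? 30.0 : v;
    u_out[i] = u;
  }
  return List::create(_["v"] = v_out, _["u"] = u_out, _["spiked"] = spiked,
                      _["v_end"] = v, _["u_end"] = u);
}

// Co-simulation of several units coupled by single-exponential current
// synapses. A spike in the source unit at sampling step k increments the
// target port's synaptic state after step k completes, so the postsynaptic
// jump is first seen at step k + 1 (one-step conduction delay).
// pars: n_units x 6 (a, b, c, d, v0, u0); i_ext: n_steps x n_units summed
// non-synaptic drive; edges 0-based.
// [[Rcpp::export]]
List izh_network_cpp(NumericMatrix pars, NumericMatrix i_ext,
                     IntegerVector e_src, IntegerVector e_dst,
                     IntegerVector e_port, NumericVector e_gain,
                     double tau_syn, double dt, int n_sub) {
  int n_steps = i_ext.nrow(), n_units = i_ext.ncol(), n_edges = e_src.size();
  NumericMatrix v_out(n_steps, n_units), u_out(n_steps, n_units);
  NumericMatrix syn1(n_steps, n_units), syn2(n_steps, n_units);
  LogicalMatrix spiked(n_steps, n_units);
  LogicalMatrix ev1(n_steps, n_units), ev2(n_steps, n_units);

  std::vector<double> v(n_units), u(n_units), s1(n_units, 0.0), s2(n_units, 0.0);
  std::vector<bool> fired(n_units, false);
  for (int j = 0; j < n_units; ++j) { v[j] = pars(j, 4); u[j] = pars(j, 5); }
  double decay = std::exp(-dt / tau_syn);

  for (int i = 0; i < n_steps; ++i) {
    for (int j = 0; j < n_units; ++j) {
      syn1(i, j) = s1[j];
      syn2(i, j) = s2[j];
      double I = i_ext(i, j) + s1[j] + s2[j];
      fired[j] = izh_step(v[j], u[j], pars(j, 0), pars(j, 1), pars(j, 2),
                          pars(j, 3), I, dt, n_sub);
      v_out(i, j) = fired[j] ? 30.0 : v[j];
      u_out(i, j) = u[j];
      spiked(i, j) = fired[j];
    }
    for (int j = 0; j < n_units; ++j) {
      s1[j] *= decay;
      s2[j] *= decay;
    }
    for (int k = 0; k < n_edges; ++k) {
      if (fired[e_src[k]]) {
        int tgt = e_dst[k];
        if (e_port[k] == 1) s1[tgt] += e_gain[k];
        else               s2[tgt] += e_gain[k];
        if (i + 1 < n_steps) {
          if (e_port[k] == 1) ev1(i + 1, tgt) = true;
          else               ev2(i + 1, tgt) = true;
        }
      }
    }
  }
  return List::create(_["v"] = v_out, _["u"] = u_out, _["spiked"] = spiked,
                      _["i_syn1"] = syn1, _["i_syn2"] = syn2,
                      _["syn1_event"] = ev1, _["syn2_event"] = ev2);
}

// First-order photoreceptor adaptation: the adaptation state A relaxes toward
// the light level L with time constant tau (ms); the transduced current is
// polarity * gain * (L - A) + baseline. A starts adapted to the initial light
// level (steady state in whatever conditions precede the recording).
// [[Rcpp::export]]
NumericVector photo_current_cpp(NumericVector light, double polarity,
                                double gain, double tau, double baseline,
                                double dt) {
  int n = light.size();
  NumericVector out(n);
  double A = light[0];
  double k = dt / tau;
  for (int i = 0; i < n; ++i) {
    out[i] = polarity * gain * (light[i] - A) + baseline;
    A += k * (light[i] - A);
  }
  return out;
}

// Exponentially decaying current synapse driven by sorted 0-based event
// sample indices. Each event adds an instantaneous jump of `gain`.
// [[Rcpp::export]]
NumericVector synapse_current_cpp(IntegerVector event_idx, double gain,
                                  double tau, int n, double dt) {
  NumericVector out(n);
  double s = 0.0, decay = std::exp(-dt / tau);
  int n_ev = event_idx.size(), next = 0;
  for (int i = 0; i < n; ++i) {
    while (next < n_ev && event_idx[next] == i) { s += gain; ++next; }
    out[i] = s;
    s *= decay;
  }
  return out;
}
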