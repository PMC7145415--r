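#include <Rcpp.h>
#include "kc.h"
using namespace Rcpp;

// Simulate a single Kenyon cell driven by current and synaptic
// conductance waveforms (each either empty or of length n_steps).
// Returns the voltage trace (n_steps + 1 samples) and spike times
// (upward 0 mV crossings, 2 ms refractory).
// [[Rcpp::export]]
List simulate_kc_cpp(NumericVector P, double dt, int n_steps,
                     NumericVector i_wave, NumericVector g_exc_wave,
                     double e_exc, NumericVector g_inh_wave, double e_inh,
                     double v0) {
    if (P.size() != KC_NPAR) stop("bad KC parameter vector length");
    KCTables T;
    kc_build_tables(REAL(P), dt, T);
    double V = v0;
    double x[KC_NGATE];
    for (int g = 0; g < KC_NGATE; ++g) x[g] = kc_gate_steady(REAL(P), g, V);
    NumericVector v(n_steps + 1);
    v[0] = V;
    std::vector<double> spikes;
    double last_spike = -1e9;
    const double refrac = 2.0;
    for (int s = 0; s < n_steps; ++s) {
        double I = i_wave.size() ? i_wave[s] : 0.0;
        double ge = g_exc_wave.size() ? g_exc_wave[s] : 0.0;
        double gi = g_inh_wave.size() ? g_inh_wave[s] : 0.0;
        double Vn = kc_step(REAL(P), T, dt, V, x, ge, e_exc, gi, e_inh, I);
        if (!std::isfinite(Vn)) stop("KC integration diverged");
        double t = (s + 1) * dt;
        if (V < 0.0 && Vn >= 0.0 && t - last_spike > refrac) {
            spikes.push_back(t);
            last_spike = t;
        }
        V = Vn;
        v[s + 1] = V;
    }
    return List::create(_["v"] = v, _["spikes"] = NumericVector(spikes.begin(),
                                                                spikes.end()));
}

// Izhikevich two-variable model with conductance-based synaptic input:
//   v' = 0.04 v^2 + 5 v + 140 - u + I_total
//   u' = a (b v - u);  spike at v >= 30: v <- c, u <- u + d
// [[Rcpp::export]]
List simulate_ig_cpp(double a, double b, double c, double d, double i_base,
                     double dt, int n_steps, NumericVector i_wave,
                     NumericVector g_exc_wave, double e_exc,
                     NumericVector g_inh_wave, double e_inh, double v0) {
    double v = v0, u = b * v0;
    NumericVector vt(n_steps + 1);
    vt[0] = v;
    std::vector<double> spikes;
    for (int s = 0; s < n_steps; ++s) {
        double I = i_base + (i_wave.size() ? i_wave[s] : 0.0);
        if (g_exc_wave.size()) I += g_exc_wave[s] * (e_exc - v);
        if (g_inh_wave.size()) I += g_inh_wave[s] * (e_inh - v);
        v += dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
        u += dt * a * (b * v - u);
        if (v >= 30.0) {
            spikes.push_back((s + 1) * dt);
            v = c;
            u += d;
            vt[s + 1] = 30.0;
        } else vt[s + 1] = v;
        if (!std::isfinite(v)) stop("IG integration diverged");
    }
    return List::create(_["v"] = vt,
                        _["spikes"] = NumericVector(spikes.begin(),
                                                    spikes.end()));
}
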