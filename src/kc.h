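#ifndef MBGGN_KC_H
#define MBGGN_KC_H

#include <cmath>
#include <vector>

// Single-compartment Hodgkin-Huxley-type Kenyon-cell model with five
// voltage-gated currents: fast Na (m^3 h), slow Na (m^3 h), delayed
// rectifier K (n^4), transient A-type K (m^3 h) and slow transient
// outward K (m^2 h).  Gating kinetics are Boltzmann activations with
// bell-shaped voltage-dependent time constants:
//   xinf(V) = 1 / (1 + exp((vh - V)/slope))
//   tau(V)  = tau_base + tau_amp / (1 + ((V - tau_vh)/tau_sig)^2)
// Integration: exponential Euler for gates, implicit Euler for voltage.
// Parameter vector layout (see kc_params() on the R side):
//   [0] C_nF [1] g_leak_uS [2] E_leak [3] E_Na [4] E_K
//   [5..9] gbar: naf nas kdr ka kst (uS)
//   [10..] 9 gates x 6 kinetic constants (vh slope tau_base tau_amp
//          tau_vh tau_sig)

#define KC_NGATE 9
#define KC_NPAR (10 + KC_NGATE * 6)

struct KCTables {
    int npts;
    double vmin, dv;
    std::vector<double> xinf[KC_NGATE];
    std::vector<double> decay[KC_NGATE];   // exp(-dt/tau(V))
};

static const int KC_GPOW[KC_NGATE] = {3, 1, 3, 1, 4, 3, 1, 2, 1};
// gate -> current: 0,1 naf; 2,3 nas; 4 kdr; 5,6 ka; 7,8 kst

inline void kc_build_tables(const double *P, double dt, KCTables &T) {
    T.npts = 1801;
    T.vmin = -120.0;
    T.dv = 0.1;
    for (int g = 0; g < KC_NGATE; ++g) {
        const double *k = P + 10 + 6 * g;
        T.xinf[g].resize(T.npts);
        T.decay[g].resize(T.npts);
        for (int i = 0; i < T.npts; ++i) {
            double V = T.vmin + i * T.dv;
            T.xinf[g][i] = 1.0 / (1.0 + std::exp((k[0] - V) / k[1]));
            double z = (V - k[4]) / k[5];
            double tau = k[2] + k[3] / (1.0 + z * z);
            T.decay[g][i] = std::exp(-dt / tau);
        }
    }
}

inline double kc_lut(const std::vector<double> &tab, const KCTables &T,
                     double V) {
    double f = (V - T.vmin) / T.dv;
    if (f <= 0) return tab[0];
    if (f >= T.npts - 1) return tab[T.npts - 1];
    int i = (int)f;
    double w = f - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
}

inline double kc_gate_steady(const double *P, int g, double V) {
    const double *k = P + 10 + 6 * g;
    return 1.0 / (1.0 + std::exp((k[0] - V) / k[1]));
}

// One implicit-Euler step of a single KC.  x is the 9-gate state; g_exc /
// g_inh are total synaptic conductances (uS) with reversals E_exc / E_inh;
// I_inj in nA.  Returns the new voltage.
inline double kc_step(const double *P, const KCTables &T, double dt,
                      double V, double *x, double g_exc, double E_exc,
                      double g_inh, double E_inh, double I_inj) {
    for (int g = 0; g < KC_NGATE; ++g) {
        double xi = kc_lut(T.xinf[g], T, V);
        double a = kc_lut(T.decay[g], T, V);
        x[g] = xi + (x[g] - xi) * a;
    }
    double n2 = x[4] * x[4];
    double g_naf = P[5] * x[0] * x[0] * x[0] * x[1];
    double g_nas = P[6] * x[2] * x[2] * x[2] * x[3];
    double g_kdr = P[7] * n2 * n2;
    double g_ka = P[8] * x[5] * x[5] * x[5] * x[6];
    double g_kst = P[9] * x[7] * x[7] * x[8];
    double g_na = g_naf + g_nas;
    double g_k = g_kdr + g_ka + g_kst;
    double cdt = P[0] / dt;
    double num = cdt * V + P[1] * P[2] + g_na * P[3] + g_k * P[4] +
                 g_exc * E_exc + g_inh * E_inh + I_inj;
    double den = cdt + P[1] + g_na + g_k + g_exc + g_inh;
    return num / den;
}

#endif
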