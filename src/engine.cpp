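#include <Rcpp.h>
#include "hines.h"
#include "kc.h"
using namespace Rcpp;

// Coupled simulation of the mushroom-body circuit: a passive GGN cable,
// a population of HH-type KCs, structured PN spike drive, graded GGN->KC
// feedback, and (optionally) the Izhikevich neuron IG in several wiring
// variants.  Coupling is staggered by one time step in the
// cross-population direction: KC graded inhibition and IG graded drive
// read the GGN compartment voltages of the previous step, while KC/IG
// spikes enter GGN synapses on the current step (after their delays).
//
// All indices arriving from R are 1-based; steps are 0-based internally.

struct DblExp {
    double fr, fd;   // per-step decay factors
    double norm;     // peak-normalization factor
};

static DblExp make_dblexp(double tau_r, double tau_d, double dt) {
    DblExp s;
    s.fr = std::exp(-dt / tau_r);
    s.fd = std::exp(-dt / tau_d);
    double tp = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
    s.norm = 1.0 / (std::exp(-tp / tau_d) - std::exp(-tp / tau_r));
    return s;
}

// [[Rcpp::export]]
List engine_run_cpp(List cable, List kcs, List pn, List kc_ggn, List ext,
                    List ig, List control) {
    // --- cable ---
    IntegerVector parent1 = cable["parent"];
    NumericVector g_ax = cable["g_ax"], g_leak = cable["g_leak"],
                  C = cable["C"];
    double E_rest = as<double>(cable["E_rest"]);
    bool frozen = as<bool>(cable["frozen"]);
    int ncomp = parent1.size();
    std::vector<int> par(ncomp);
    for (int i = 0; i < ncomp; ++i) par[i] = parent1[i] - 1;
    // static axial part of the diagonal
    std::vector<double> ax_diag(ncomp, 0.0);
    for (int i = 0; i < ncomp; ++i) {
        ax_diag[i] += g_ax[i];
        if (par[i] >= 0) ax_diag[par[i]] += g_ax[i];
    }

    // --- control ---
    double dt = as<double>(control["dt"]);
    int n_steps = as<int>(control["n_steps"]);
    int rec_every = as<int>(control["record_every"]);
    IntegerVector rec_comps = control["record_comps"];
    int ow0 = as<int>(control["odor_on_step"]);
    int ow1 = as<int>(control["odor_off_step"]);
    IntegerVector kc_rec = control["kc_record"];

    // --- KC population ---
    int n_kc = as<int>(kcs["n_kc"]);
    NumericVector P = kcs["params"];
    if (n_kc > 0 && P.size() != KC_NPAR) stop("bad KC parameter vector");
    KCTables T;
    if (n_kc > 0) kc_build_tables(REAL(P), dt, T);
    double kc_v0 = as<double>(kcs["v0"]);
    DblExp exc = make_dblexp(as<double>(kcs["exc_tau_r"]),
                             as<double>(kcs["exc_tau_d"]), dt);
    double e_exc = as<double>(kcs["e_exc"]);
    NumericVector gbar_in = kcs["graded_gbar"];
    IntegerVector assign1 = kcs["graded_assign"];
    double g_vhalf = as<double>(kcs["graded_vhalf"]);
    double g_slope = as<double>(kcs["graded_slope"]);
    double g_tau = as<double>(kcs["graded_tau"]);
    double e_inh = as<double>(kcs["graded_erev"]);
    double g_decay = std::exp(-dt / g_tau);
    NumericVector i_amp = kcs["i_amp"];
    int i_on = as<int>(kcs["i_on_step"]), i_off = as<int>(kcs["i_off_step"]);

    // graded-activation lookup table
    std::vector<double> sinf_tab(1801);
    for (int i = 0; i < 1801; ++i) {
        double V = -120.0 + 0.1 * i;
        sinf_tab[i] = 1.0 / (1.0 + std::exp((g_vhalf - V) / g_slope));
    }
    auto sinf = [&](double V) {
        double f = (V + 120.0) / 0.1;
        if (f <= 0) return sinf_tab[0];
        if (f >= 1800) return sinf_tab[1800];
        int i = (int)f; double w = f - i;
        return sinf_tab[i] * (1 - w) + sinf_tab[i + 1] * w;
    };

    // --- PN -> KC events (sorted by step) ---
    IntegerVector ev_step = pn["ev_step"];
    IntegerVector ev_kc = pn["ev_kc"];
    NumericVector ev_w = pn["ev_w"];
    R_xlen_t n_ev = ev_step.size(), ev_ptr = 0;

    // --- KC -> GGN ---
    int kg_mode = as<int>(kc_ggn["mode"]);   // 0 events, 1 kernel, 2 none
    IntegerVector kg_target1 = kc_ggn["target"];
    NumericVector kg_w = kc_ggn["w"];
    IntegerVector kg_delay = kc_ggn["delay_steps"];
    DblExp kg = make_dblexp(as<double>(kc_ggn["tau_r"]),
                            as<double>(kc_ggn["tau_d"]), dt);
    double kg_erev = as<double>(kc_ggn["e_rev"]);
    NumericVector kernel = kc_ggn["kernel"];
    int Lk = kernel.size();
    std::vector<double> kring(Lk > 0 ? Lk : 1, 0.0);
    int kpos = 0;
    // ring of future arrival slots; spikes land delay+1 steps after they
    // fire (the one-step stagger of the cross-population coupling)
    int D2 = 2;
    for (int k = 0; k < kg_delay.size(); ++k)
        if (kg_delay[k] + 2 > D2) D2 = kg_delay[k] + 2;
    std::vector<std::vector<std::pair<int, double> > > ring2(D2);

    // --- external compartment drive (distributed-synapse experiments) ---
    IntegerVector ex_step = ext["ev_step"];
    IntegerVector ex_comp1 = ext["ev_comp"];
    NumericVector ex_w = ext["ev_w"];
    DblExp exs = make_dblexp(as<double>(ext["tau_r"]),
                             as<double>(ext["tau_d"]), dt);
    double ex_erev = as<double>(ext["e_rev"]);
    R_xlen_t n_ex = ex_step.size(), ex_ptr = 0;

    // --- IG ---
    bool has_ig = as<bool>(ig["has"]);
    double ig_a = as<double>(ig["a"]), ig_b = as<double>(ig["b"]),
           ig_c = as<double>(ig["c"]), ig_d = as<double>(ig["d"]);
    double ig_ibase = as<double>(ig["i_base"]);
    int ig_comp = as<int>(ig["comp"]) - 1;
    double ggn_ig_gbar = as<double>(ig["ggn_ig_gbar"]);
    double e_ggn_ig = as<double>(ig["e_ggn_ig"]);
    double ig_ggn_w = as<double>(ig["ig_ggn_w"]);
    double ig_ggn_tau = as<double>(ig["ig_ggn_tau"]);
    double e_ig_ggn = as<double>(ig["e_ig_ggn"]);
    double ig_ggn_decay = std::exp(-dt / ig_ggn_tau);
    NumericVector kc_ig_w = ig["kc_ig_w"];
    int kc_ig_delay = as<int>(ig["kc_ig_delay_steps"]);
    IntegerVector pn_ig_steps = ig["pn_ig_steps"];
    double pn_ig_w = as<double>(ig["pn_ig_w"]);
    DblExp igs = make_dblexp(as<double>(ig["syn_tau_r"]),
                             as<double>(ig["syn_tau_d"]), dt);
    double e_exc_ig = 0.0;
    R_xlen_t n_pnig = pn_ig_steps.size(), pnig_ptr = 0;
    std::vector<double> ring_kcig(kc_ig_delay + 1, 0.0);

    // --- state ---
    std::vector<double> Vc(ncomp, E_rest), diag(ncomp), rhs(ncomp);
    std::vector<double> A2(ncomp, 0.0), B2(ncomp, 0.0);  // KC->GGN
    std::vector<double> A3(ncomp, 0.0), B3(ncomp, 0.0);  // external drive
    std::vector<char> clamped(ncomp, 0);
    std::vector<double> cv(ncomp, 0.0);
    double g_igggn = 0.0;

    std::vector<double> kcV(n_kc, kc_v0), Ae(n_kc, 0.0), Be(n_kc, 0.0);
    std::vector<double> sgr(n_kc, sinf(E_rest));
    std::vector<double> gates(static_cast<size_t>(n_kc) * KC_NGATE);
    for (int k = 0; k < n_kc; ++k)
        for (int g = 0; g < KC_NGATE; ++g)
            gates[(size_t)k * KC_NGATE + g] = kc_gate_steady(REAL(P), g, kc_v0);
    std::vector<double> last_spk(n_kc, -1e9);

    double ig_v = has_ig ? ig_c : 0.0, ig_u = has_ig ? ig_b * ig_c : 0.0;
    double Aig = 0.0, Big = 0.0, s_gi = sinf(E_rest);

    // --- outputs ---
    int n_rec_t = n_steps / rec_every + 1;
    NumericMatrix ggn_v(n_rec_t, rec_comps.size());
    NumericMatrix kc_vrec(n_rec_t, kc_rec.size());
    NumericVector ig_vrec(has_ig ? n_rec_t : 0);
    NumericVector t_rec(n_rec_t);
    std::vector<int> spk_id;
    std::vector<double> spk_t;
    std::vector<double> ig_spikes;
    std::vector<double> comp_vsum(ncomp, 0.0);
    long ow_count = 0;
    int rec_i = 0;
    // sample at t = 0
    for (int j = 0; j < rec_comps.size(); ++j)
        ggn_v(0, j) = Vc[rec_comps[j] - 1];
    for (int j = 0; j < kc_rec.size(); ++j)
        kc_vrec(0, j) = kcV[kc_rec[j] - 1];
    if (has_ig) ig_vrec[0] = ig_v;
    t_rec[0] = 0.0;
    rec_i = 1;

    for (int s = 0; s < n_steps; ++s) {
        double t1 = (s + 1) * dt;

        // PN arrivals into KC excitatory synapses
        while (ev_ptr < n_ev && ev_step[ev_ptr] <= s) {
            if (ev_step[ev_ptr] == s) {
                int k = ev_kc[ev_ptr];
                double a = ev_w[ev_ptr] * exc.norm;
                Ae[k] += a; Be[k] += a;
            }
            ++ev_ptr;
        }
        // external compartment events
        while (ex_ptr < n_ex && ex_step[ex_ptr] <= s) {
            if (ex_step[ex_ptr] == s) {
                int cmp = ex_comp1[ex_ptr] - 1;
                double a = ex_w[ex_ptr] * exs.norm;
                A3[cmp] += a; B3[cmp] += a;
            }
            ++ex_ptr;
        }
        // delayed KC->GGN arrivals
        if (kg_mode == 0) {
            std::vector<std::pair<int, double> > &slot = ring2[s % D2];
            for (size_t q = 0; q < slot.size(); ++q) {
                double a = slot[q].second * kg.norm;
                A2[slot[q].first] += a; B2[slot[q].first] += a;
            }
            slot.clear();
        }

        // --- KC population update ---
        bool in_stim = (s >= i_on && s < i_off);
        for (int k = 0; k < n_kc; ++k) {
            Ae[k] *= exc.fr; Be[k] *= exc.fd;
            double g_e = Be[k] - Ae[k];
            int ac = assign1[k] - 1;
            double vpre = (ac >= 0 && !frozen) ? Vc[ac] : E_rest;
            double si = sinf(vpre);
            sgr[k] = si + (sgr[k] - si) * g_decay;
            double g_i = gbar_in[k] * sgr[k];
            double I = (in_stim && i_amp.size()) ? i_amp[k] : 0.0;
            double Vn = kc_step(REAL(P), T, dt, kcV[k],
                                &gates[(size_t)k * KC_NGATE], g_e, e_exc,
                                g_i, e_inh, I);
            if (kcV[k] < 0.0 && Vn >= 0.0 && t1 - last_spk[k] > 2.0) {
                last_spk[k] = t1;
                spk_id.push_back(k + 1);
                spk_t.push_back(t1);
                if (kg_mode == 0 && kg_w[k] != 0.0) {
                    int slot = (s + kg_delay[k] + 1) % D2;
                    ring2[slot].push_back(
                        std::make_pair(kg_target1[k] - 1, kg_w[k]));
                } else if (kg_mode == 1 && kg_w[k] != 0.0) {
                    for (int j = 0; j < Lk; ++j)
                        kring[(kpos + j) % Lk] += kg_w[k] * kernel[j];
                }
                if (has_ig && kc_ig_w.size()) {
                    ring_kcig[(s + kc_ig_delay) % (kc_ig_delay + 1)] +=
                        kc_ig_w[k];
                }
            }
            kcV[k] = Vn;
        }

        // --- IG update ---
        if (has_ig) {
            Aig *= igs.fr; Big *= igs.fd;
            if (kc_ig_w.size()) {
                double w = ring_kcig[s % (kc_ig_delay + 1)];
                if (w != 0.0) {
                    Aig += w * igs.norm; Big += w * igs.norm;
                    ring_kcig[s % (kc_ig_delay + 1)] = 0.0;
                }
            }
            while (pnig_ptr < n_pnig && pn_ig_steps[pnig_ptr] <= s) {
                if (pn_ig_steps[pnig_ptr] == s) {
                    Aig += pn_ig_w * igs.norm; Big += pn_ig_w * igs.norm;
                }
                ++pnig_ptr;
            }
            double vpre = frozen ? E_rest : Vc[ig_comp];
            double si = sinf(vpre);
            s_gi = si + (s_gi - si) * g_decay;
            double I = ig_ibase + (Big - Aig) * (e_exc_ig - ig_v) +
                       ggn_ig_gbar * s_gi * (e_ggn_ig - ig_v);
            ig_v += dt * (0.04 * ig_v * ig_v + 5.0 * ig_v + 140.0 - ig_u + I);
            ig_u += dt * ig_a * (ig_b * ig_v - ig_u);
            if (ig_v >= 30.0) {
                ig_spikes.push_back(t1);
                ig_v = ig_c;
                ig_u += ig_d;
                g_igggn += ig_ggn_w;      // IG -> GGN IPSP conductance
            }
        }
        g_igggn *= ig_ggn_decay;

        // --- GGN cable step ---
        if (!frozen) {
            double gk = 0.0;
            if (kg_mode == 1 && Lk > 0) {
                gk = kring[kpos];
                kring[kpos] = 0.0;
                kpos = (kpos + 1) % Lk;
            }
            for (int i = 0; i < ncomp; ++i) {
                A2[i] *= kg.fr; B2[i] *= kg.fd;
                A3[i] *= exs.fr; B3[i] *= exs.fd;
                double gs1 = B2[i] - A2[i];
                double gs2 = B3[i] - A3[i];
                double gsyn = gs1 + gs2;
                double gsynE = gs1 * kg_erev + gs2 * ex_erev;
                if (kg_mode == 1 && i == (kg_target1.size() ?
                                          kg_target1[0] - 1 : -1)) {
                    gsyn += gk;
                    gsynE += gk * kg_erev;
                }
                if (has_ig && i == ig_comp) {
                    gsyn += g_igggn;
                    gsynE += g_igggn * e_ig_ggn;
                }
                double cdt = C[i] / dt;
                diag[i] = cdt + g_leak[i] + gsyn + ax_diag[i];
                rhs[i] = cdt * Vc[i] + g_leak[i] * E_rest + gsynE;
            }
            hines_solve(ncomp, par.data(), REAL(g_ax), diag, rhs,
                        clamped.data(), cv.data(), Vc.data());
            if (!std::isfinite(Vc[0]))
                stop("network simulation diverged at t = %f ms", t1);
        }

        // odor-window voltage accumulation (for attenuation/correlation)
        if (s >= ow0 && s < ow1 && !frozen) {
            for (int i = 0; i < ncomp; ++i) comp_vsum[i] += Vc[i];
            ++ow_count;
        }

        if ((s + 1) % rec_every == 0 && rec_i < n_rec_t) {
            for (int j = 0; j < rec_comps.size(); ++j)
                ggn_v(rec_i, j) = Vc[rec_comps[j] - 1];
            for (int j = 0; j < kc_rec.size(); ++j)
                kc_vrec(rec_i, j) = kcV[kc_rec[j] - 1];
            if (has_ig) ig_vrec[rec_i] = ig_v;
            t_rec[rec_i] = t1;
            ++rec_i;
        }
    }

    NumericVector comp_v_mean(ncomp);
    for (int i = 0; i < ncomp; ++i)
        comp_v_mean[i] = ow_count > 0 ? comp_vsum[i] / ow_count : E_rest;

    return List::create(
        _["t"] = t_rec,
        _["ggn_v"] = ggn_v,
        _["kc_spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
        _["kc_spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
        _["kc_v"] = kc_vrec,
        _["ig_v"] = ig_vrec,
        _["ig_spikes"] = NumericVector(ig_spikes.begin(), ig_spikes.end()),
        _["comp_v_mean"] = comp_v_mean);
}
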