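#include <Rcpp.h>
#include "hines.h"
using namespace Rcpp;

// Solve the passive-cable linear system on a tree.
// parent: 1-based parent compartment (0 for root), parent[i] < i.
// g_ax: axial conductance to parent (uS), 0 for root.
// diag_add: non-axial diagonal terms (leak + C/dt + synaptic, uS).
// rhs: right-hand side (nA).
// clamp_comp / clamp_v: 1-based clamped compartments and commands (mV).
// [[Rcpp::export]]
NumericVector hines_solve_cpp(IntegerVector parent, NumericVector g_ax,
                              NumericVector diag_add, NumericVector rhs,
                              IntegerVector clamp_comp,
                              NumericVector clamp_v) {
    int n = parent.size();
    std::vector<int> par(n);
    std::vector<double> diag(n), r(n), g(n);
    for (int i = 0; i < n; ++i) {
        par[i] = parent[i] - 1;
        if (par[i] >= i) stop("compartments must be parent-before-child");
        g[i] = g_ax[i];
        diag[i] = diag_add[i] + g_ax[i];
        r[i] = rhs[i];
    }
    for (int i = 1; i < n; ++i) diag[par[i]] += g[i];
    std::vector<char> clamped(n, 0);
    std::vector<double> cv(n, 0.0);
    for (int k = 0; k < clamp_comp.size(); ++k) {
        int c = clamp_comp[k] - 1;
        if (c < 0 || c >= n) stop("clamp compartment out of range");
        clamped[c] = 1;
        cv[c] = clamp_v[k];
    }
    NumericVector v(n);
    hines_solve(n, par.data(), g.data(), diag, r, clamped.data(),
                cv.data(), REAL(v));
    return v;
}
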