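#ifndef MBGGN_HINES_H
#define MBGGN_HINES_H

#include <vector>

// Exact O(N) solve of the symmetric tree-structured linear system arising
// from a branched cable:
//   d[i] v[i] - g[i] v[parent[i]] - sum_children g[c] v[c] = r[i]
// Compartments must be ordered parent-before-child (parent[i] < i, root
// parent = -1, g[root] = 0).  diag must already contain the full diagonal
// (axial terms included).  Clamped compartments are held exactly at their
// commands via Dirichlet substitution.
inline void hines_solve(int n, const int *parent, const double *g,
                        std::vector<double> &diag, std::vector<double> &rhs,
                        const char *clamped, const double *clamp_v,
                        double *v) {
    for (int i = n - 1; i >= 1; --i) {
        int p = parent[i];
        if (clamped[i]) {
            // child's voltage known: move coupling into parent's rhs
            if (!clamped[p]) rhs[p] += g[i] * clamp_v[i];
            continue;
        }
        if (clamped[p]) continue;  // resolved at back-substitution
        double f = g[i] / diag[i];
        diag[p] -= f * g[i];
        rhs[p] += f * rhs[i];
    }
    if (clamped[0]) v[0] = clamp_v[0];
    else v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
        if (clamped[i]) { v[i] = clamp_v[i]; continue; }
        int p = parent[i];
        double vp = v[p];
        v[i] = (rhs[i] + g[i] * vp) / diag[i];
    }
}

#endif
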