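#include <Rcpp.h>
using namespace Rcpp;

// Per-species particle counts in cubic subdomains (blocks) of a periodic
// cubic box.  Membership is half-open per axis: particle p is inside the
// block with origin o and edge a iff ((x_p - o) mod L0) < a for each axis,
// so tiling blocks never double-count a particle and blocks may straddle
// the periodic boundary.
//
// pos:     N x 3, coordinates wrapped into [0, L0)
// species: 0-based species index per particle
// origins: K x 3 block origins in [0, L0)
// edges:   length-K block edge per origin (edges[k] in (0, L0])
// returns: K x n_species integer count matrix
// [[Rcpp::export]]
IntegerMatrix cpp_block_counts(NumericMatrix pos, IntegerVector species,
                               int n_species, double L0,
                               NumericMatrix origins, NumericVector edges) {
    const int n = pos.nrow();
    const int k = origins.nrow();
    if (edges.size() != k)
        stop("edges must have one entry per origin");
    IntegerMatrix counts(k, n_species);

    const double *px = &pos(0, 0), *py = &pos(0, 1), *pz = &pos(0, 2);
    for (int b = 0; b < k; ++b) {
        const double ox = origins(b, 0), oy = origins(b, 1), oz = origins(b, 2);
        const double a = edges[b];
        for (int i = 0; i < n; ++i) {
            double dx = px[i] - ox; if (dx < 0) dx += L0;
            if (dx >= a) continue;
            double dy = py[i] - oy; if (dy < 0) dy += L0;
            if (dy >= a) continue;
            double dz = pz[i] - oz; if (dz < 0) dz += L0;
            if (dz >= a) continue;
            ++counts(b, species[i]);
        }
    }
    return counts;
}
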