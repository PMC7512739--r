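#include <Rcpp.h>
#include "pcg32.h"
using namespace Rcpp;

// Truncated-and-shifted 12-6 Lennard-Jones forces in a cubic periodic box,
// with per-species-pair epsilon/sigma and a single cutoff rc.  The shift
// makes U(rc) = 0 exactly; the force keeps its truncation discontinuity at
// rc (the potential is the model, not a smoothed variant of it).

struct LJTable {
    int s;                       // number of species
    std::vector<double> c12;     // 4 eps sig^12, indexed i*s+j
    std::vector<double> c6;      // 4 eps sig^6
    std::vector<double> ushift;  // U_LJ(rc) per pair
    double rc2;

    LJTable(NumericMatrix eps, NumericMatrix sig, double rc) {
        s = eps.nrow();
        c12.resize(s * s); c6.resize(s * s); ushift.resize(s * s);
        rc2 = rc * rc;
        for (int i = 0; i < s; ++i)
            for (int j = 0; j < s; ++j) {
                double e = eps(i, j), sg = sig(i, j);
                double s6 = sg * sg * sg; s6 *= s6;
                c6[i * s + j] = 4.0 * e * s6;
                c12[i * s + j] = 4.0 * e * s6 * s6;
                double ir6 = s6 / (rc2 * rc2 * rc2);
                ushift[i * s + j] = 4.0 * e * (ir6 * ir6 - ir6);
            }
    }
};

static inline double min_image(double d, double L, double hL) {
    if (d > hL) d -= L; else if (d < -hL) d += L;
    return d;
}

// Accumulate the pair (i,j) interaction; returns false on overlap.
static inline bool pair_accum(const LJTable &lj, int si, int sj,
                              double dx, double dy, double dz,
                              double &fx, double &fy, double &fz,
                              double &pe, double &vir) {
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= lj.rc2) return true;
    if (r2 < 1e-12) return false;
    int idx = si * lj.s + sj;
    double ir2 = 1.0 / r2;
    double ir6 = ir2 * ir2 * ir2;
    double a12 = lj.c12[idx] * ir6 * ir6;   // 4 eps (sig/r)^12
    double a6 = lj.c6[idx] * ir6;           // 4 eps (sig/r)^6
    pe += a12 - a6 - lj.ushift[idx];
    double w = 12.0 * a12 - 6.0 * a6;       // r dU/dr with sign flipped
    vir += w;
    double fscale = w * ir2;                // |F|/r
    fx = fscale * dx; fy = fscale * dy; fz = fscale * dz;
    return true;
}

// Brute-force O(N^2) minimum-image evaluation; the oracle for the cell list.
static void forces_brute(const std::vector<double> &x, const std::vector<double> &y,
                         const std::vector<double> &z, const IntegerVector &species,
                         const LJTable &lj, double L0,
                         std::vector<double> &fx, std::vector<double> &fy,
                         std::vector<double> &fz, double &pe, double &vir) {
    int n = x.size();
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pe = 0.0; vir = 0.0;
    double hL = 0.5 * L0;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            double dx = min_image(x[i] - x[j], L0, hL);
            double dy = min_image(y[i] - y[j], L0, hL);
            double dz = min_image(z[i] - z[j], L0, hL);
            double gx, gy, gz;
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= lj.rc2) continue;
            if (!pair_accum(lj, species[i], species[j], dx, dy, dz,
                            gx, gy, gz, pe, vir))
                stop("particle overlap (r ~ 0) between particles %d and %d",
                     i + 1, j + 1);
            fx[i] += gx; fy[i] += gy; fz[i] += gz;
            fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
        }
}

// Linked-cell list force evaluation; rebuilt on every call (every step).
struct CellList {
    int nc;                 // cells per dimension
    double cell;            // cell edge
    std::vector<int> head;  // first particle per cell
    std::vector<int> next;  // linked list

    void build(const std::vector<double> &x, const std::vector<double> &y,
               const std::vector<double> &z, double L0, double rc) {
        nc = (int)std::floor(L0 / rc);
        if (nc < 3) { nc = 0; return; }  // fall back to brute force
        cell = L0 / nc;
        int n = x.size();
        head.assign(nc * nc * nc, -1);
        next.assign(n, -1);
        for (int i = 0; i < n; ++i) {
            int cx = (int)(x[i] / cell); if (cx >= nc) cx = nc - 1;
            int cy = (int)(y[i] / cell); if (cy >= nc) cy = nc - 1;
            int cz = (int)(z[i] / cell); if (cz >= nc) cz = nc - 1;
            int c = (cx * nc + cy) * nc + cz;
            next[i] = head[c];
            head[c] = i;
        }
    }
};

static void forces_cell(const std::vector<double> &x, const std::vector<double> &y,
                        const std::vector<double> &z, const IntegerVector &species,
                        const LJTable &lj, double L0, double rc, CellList &cl,
                        std::vector<double> &fx, std::vector<double> &fy,
                        std::vector<double> &fz, double &pe, double &vir) {
    cl.build(x, y, z, L0, rc);
    if (cl.nc == 0) {  // box too small for cells
        forces_brute(x, y, z, species, lj, L0, fx, fy, fz, pe, vir);
        return;
    }
    int n = x.size(), nc = cl.nc;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pe = 0.0; vir = 0.0;
    double hL = 0.5 * L0;
    for (int cx = 0; cx < nc; ++cx)
        for (int cy = 0; cy < nc; ++cy)
            for (int cz = 0; cz < nc; ++cz) {
                int c = (cx * nc + cy) * nc + cz;
                for (int dxc = -1; dxc <= 1; ++dxc)
                    for (int dyc = -1; dyc <= 1; ++dyc)
                        for (int dzc = -1; dzc <= 1; ++dzc) {
                            int ncx = (cx + dxc + nc) % nc;
                            int ncy = (cy + dyc + nc) % nc;
                            int ncz = (cz + dzc + nc) % nc;
                            int c2 = (ncx * nc + ncy) * nc + ncz;
                            if (c2 < c) continue;  // each cell pair once
                            for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
                                int jstart = (c2 == c) ? cl.next[i] : cl.head[c2];
                                for (int j = jstart; j >= 0; j = cl.next[j]) {
                                    double dx = min_image(x[i] - x[j], L0, hL);
                                    double dy = min_image(y[i] - y[j], L0, hL);
                                    double dz = min_image(z[i] - z[j], L0, hL);
                                    double r2 = dx * dx + dy * dy + dz * dz;
                                    if (r2 >= lj.rc2) continue;
                                    double gx, gy, gz;
                                    if (!pair_accum(lj, species[i], species[j],
                                                    dx, dy, dz, gx, gy, gz, pe, vir))
                                        stop("particle overlap (r ~ 0) between particles %d and %d",
                                             i + 1, j + 1);
                                    fx[i] += gx; fy[i] += gy; fz[i] += gz;
                                    fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
                                }
                            }
                        }
            }
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector species, double L0,
                NumericMatrix eps, NumericMatrix sig, double rc,
                std::string method) {
    int n = pos.nrow();
    LJTable lj(eps, sig, rc);
    std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
    for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
    double pe = 0.0, vir = 0.0;
    if (method == "brute") {
        forces_brute(x, y, z, species, lj, L0, fx, fy, fz, pe, vir);
    } else {
        CellList cl;
        forces_cell(x, y, z, species, lj, L0, rc, cl, fx, fy, fz, pe, vir);
    }
    NumericMatrix f(n, 3);
    for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
    return List::create(_["forces"] = f, _["potential_energy"] = pe,
                        _["virial"] = vir);
}

static inline double wrap01(double v, double L) {
    v -= L * std::floor(v / L);
    if (v >= L) v = 0.0;  // guard rounding at the upper edge
    if (v < 0) v = 0.0;
    return v;
}

// Langevin NVT dynamics with BAOAB splitting (mass = 1 for all species).
// gamma = 0 reduces exactly to velocity Verlet (NVE), which is how the
// integrator is validated by the energy-drift test.
// [[Rcpp::export]]
List cpp_run_nvt(NumericMatrix pos0, IntegerVector species, double L0,
                 NumericMatrix eps, NumericMatrix sig, double rc,
                 double dt, double gamma, double kT,
                 int n_equil, int n_prod, int stride, double seed) {
    int n = pos0.nrow();
    LJTable lj(eps, sig, rc);
    CellList cl;
    std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
    std::vector<double> fx(n), fy(n), fz(n);
    for (int i = 0; i < n; ++i) {
        x[i] = wrap01(pos0(i, 0), L0);
        y[i] = wrap01(pos0(i, 1), L0);
        z[i] = wrap01(pos0(i, 2), L0);
    }

    pcg32 rng((uint64_t)seed);
    double vsd = std::sqrt(kT);
    for (int i = 0; i < n; ++i) {
        vx[i] = vsd * rng.rnorm();
        vy[i] = vsd * rng.rnorm();
        vz[i] = vsd * rng.rnorm();
    }
    // remove centre-of-mass drift of the initial draw
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < n; ++i) { mx += vx[i]; my += vy[i]; mz += vz[i]; }
    mx /= n; my /= n; mz /= n;
    for (int i = 0; i < n; ++i) { vx[i] -= mx; vy[i] -= my; vz[i] -= mz; }

    double pe = 0.0, vir = 0.0;
    forces_cell(x, y, z, species, lj, L0, rc, cl, fx, fy, fz, pe, vir);

    double c1 = std::exp(-gamma * dt);
    double c2 = std::sqrt(kT * (1.0 - c1 * c1));
    bool thermostat = gamma > 0.0;
    double half = 0.5 * dt;

    int total = n_equil + n_prod;
    int n_frames = (stride > 0) ? n_prod / stride : 0;
    List frames(n_frames);
    NumericVector frame_pe(n_frames), frame_ke(n_frames), frame_vir(n_frames);
    IntegerVector frame_step(n_frames);
    int fidx = 0;

    for (int step = 1; step <= total; ++step) {
        for (int i = 0; i < n; ++i) {          // B
            vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
        }
        for (int i = 0; i < n; ++i) {          // A
            x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i];
        }
        if (thermostat) {                      // O
            for (int i = 0; i < n; ++i) {
                vx[i] = c1 * vx[i] + c2 * rng.rnorm();
                vy[i] = c1 * vy[i] + c2 * rng.rnorm();
                vz[i] = c1 * vz[i] + c2 * rng.rnorm();
            }
        }
        for (int i = 0; i < n; ++i) {          // A
            x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i];
            x[i] = wrap01(x[i], L0); y[i] = wrap01(y[i], L0); z[i] = wrap01(z[i], L0);
        }
        forces_cell(x, y, z, species, lj, L0, rc, cl, fx, fy, fz, pe, vir);
        for (int i = 0; i < n; ++i) {          // B
            vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
        }
        for (int i = 0; i < n; ++i) {
            if (!std::isfinite(x[i]) || !std::isfinite(fx[i]))
                stop("integration unstable at step %d (non-finite position/force); use a smaller timestep", step);
        }
        if (step > n_equil && stride > 0 && (step - n_equil) % stride == 0 &&
            fidx < n_frames) {
            NumericMatrix fr(n, 3);
            double ke = 0.0;
            for (int i = 0; i < n; ++i) {
                fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
                ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
            }
            frames[fidx] = fr;
            frame_pe[fidx] = pe;
            frame_ke[fidx] = 0.5 * ke;
            frame_vir[fidx] = vir;
            frame_step[fidx] = step - n_equil;
            ++fidx;
        }
        if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    }

    NumericMatrix pos_final(n, 3);
    for (int i = 0; i < n; ++i) {
        pos_final(i, 0) = x[i]; pos_final(i, 1) = y[i]; pos_final(i, 2) = z[i];
    }
    return List::create(_["frames"] = frames, _["potential_energy"] = frame_pe,
                        _["kinetic_energy"] = frame_ke, _["virial"] = frame_vir,
                        _["step"] = frame_step, _["final_positions"] = pos_final);
}
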