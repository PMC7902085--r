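#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal unit system: A, kcal/mol, amu, fs.
// 1 (kcal/mol/A)/amu = FCONV A/fs^2.
static const double FCONV = 4.184e-4;
static const double KB = 0.0019872041; // kcal/(mol K)

struct CGSystem {
    int n;
    NumericVector mass;
    IntegerVector idxA, idxB;          // 0-based bead indices per chain
    double massA, massB;
    // Go contacts (global 0-based indices)
    IntegerVector c_i, c_j;
    NumericVector c_rmin, c_eps;
    // intra-chain elastic network
    IntegerVector b_i, b_j;
    NumericVector b_r0, b_k;
    // chain-A positional tethers to reference pose
    double tether_k;
    NumericMatrix ref;                 // n x 3 reference pose
    // flat-bottom confinement of chain-B COM
    double r_cavity, wall_k;
};

static CGSystem unpack(const List& sys) {
    CGSystem s;
    s.mass = sys["mass"];
    s.n = s.mass.size();
    s.idxA = sys["idxA"];
    s.idxB = sys["idxB"];
    s.c_i = sys["contact_i"];
    s.c_j = sys["contact_j"];
    s.c_rmin = sys["contact_rmin"];
    s.c_eps = sys["contact_eps"];
    s.b_i = sys["bond_i"];
    s.b_j = sys["bond_j"];
    s.b_r0 = sys["bond_r0"];
    s.b_k = sys["bond_k"];
    s.tether_k = as<double>(sys["tether_k"]);
    s.ref = as<NumericMatrix>(sys["ref"]);
    s.r_cavity = as<double>(sys["r_cavity"]);
    s.wall_k = as<double>(sys["wall_k"]);
    s.massA = 0.0; s.massB = 0.0;
    for (int a = 0; a < s.idxA.size(); ++a) s.massA += s.mass[s.idxA[a]];
    for (int b = 0; b < s.idxB.size(); ++b) s.massB += s.mass[s.idxB[b]];
    return s;
}

static inline void com_of(const CGSystem& s, const double* x,
                          const IntegerVector& idx, double mtot, double* out) {
    out[0] = out[1] = out[2] = 0.0;
    for (int a = 0; a < idx.size(); ++a) {
        int i = idx[a];
        double m = s.mass[i];
        out[0] += m * x[3 * i];
        out[1] += m * x[3 * i + 1];
        out[2] += m * x[3 * i + 2];
    }
    out[0] /= mtot; out[1] /= mtot; out[2] /= mtot;
}

// Potential energy and (optionally) forces; positions flattened row-major
// per bead (x1,y1,z1,x2,...). f may be NULL.
static double eval_potential(const CGSystem& s, const double* x, double* f,
                             bool has_bias, double bias_d0, double bias_k) {
    double U = 0.0;
    if (f) std::fill(f, f + 3 * s.n, 0.0);

    // Go contacts: eps * ((rmin/r)^12 - 2 (rmin/r)^6), minimum -eps at rmin
    for (int c = 0; c < s.c_i.size(); ++c) {
        int i = s.c_i[c], j = s.c_j[c];
        double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 <= 0.0) stop("singular Go contact: zero inter-bead distance for pair %d-%d", i + 1, j + 1);
        double r = std::sqrt(r2);
        double sr2 = (s.c_rmin[c] * s.c_rmin[c]) / r2;
        double sr6 = sr2 * sr2 * sr2;
        U += s.c_eps[c] * (sr6 * sr6 - 2.0 * sr6);
        if (f) {
            // dU/dr = (12 eps / r) (sr6 - sr12)
            double dUdr = 12.0 * s.c_eps[c] * (sr6 - sr6 * sr6) / r;
            for (int k = 0; k < 3; ++k) {
                double fc = -dUdr * d[k] / r;
                f[3*i + k] += fc;
                f[3*j + k] -= fc;
            }
        }
    }

    // intra-chain elastic network, U = (k/2)(r - r0)^2
    for (int b = 0; b < s.b_i.size(); ++b) {
        int i = s.b_i[b], j = s.b_j[b];
        double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
        double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        double dr = r - s.b_r0[b];
        U += 0.5 * s.b_k[b] * dr * dr;
        if (f && r > 0.0) {
            double dUdr = s.b_k[b] * dr;
            for (int k = 0; k < 3; ++k) {
                double fc = -dUdr * d[k] / r;
                f[3*i + k] += fc;
                f[3*j + k] -= fc;
            }
        }
    }

    // chain-A tethers to the reference pose (pins position + orientation)
    if (s.tether_k > 0.0) {
        for (int a = 0; a < s.idxA.size(); ++a) {
            int i = s.idxA[a];
            for (int k = 0; k < 3; ++k) {
                double dx = x[3*i + k] - s.ref(i, k);
                U += 0.5 * s.tether_k * dx * dx;
                if (f) f[3*i + k] -= s.tether_k * dx;
            }
        }
    }

    // half-harmonic wall on chain-B COM radius (flat inside r_cavity)
    if (s.wall_k > 0.0) {
        double cb[3];
        com_of(s, x, s.idxB, s.massB, cb);
        double R = std::sqrt(cb[0]*cb[0] + cb[1]*cb[1] + cb[2]*cb[2]);
        if (R > s.r_cavity) {
            double dr = R - s.r_cavity;
            U += 0.5 * s.wall_k * dr * dr;
            if (f && R > 0.0) {
                for (int a = 0; a < s.idxB.size(); ++a) {
                    int i = s.idxB[a];
                    double w = s.mass[i] / s.massB;
                    for (int k = 0; k < 3; ++k)
                        f[3*i + k] -= s.wall_k * dr * cb[k] / R * w;
                }
            }
        }
    }

    // umbrella bias on COM-COM distance, U = (k/2)(d - d0)^2
    if (has_bias && bias_k > 0.0) {
        double ca[3], cb[3];
        com_of(s, x, s.idxA, s.massA, ca);
        com_of(s, x, s.idxB, s.massB, cb);
        double d[3] = {ca[0] - cb[0], ca[1] - cb[1], ca[2] - cb[2]};
        double dist = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        double dr = dist - bias_d0;
        U += 0.5 * bias_k * dr * dr;
        if (f && dist > 0.0) {
            for (int k = 0; k < 3; ++k) {
                double g = bias_k * dr * d[k] / dist;
                for (int a = 0; a < s.idxA.size(); ++a) {
                    int i = s.idxA[a];
                    f[3*i + k] -= g * s.mass[i] / s.massA;
                }
                for (int b = 0; b < s.idxB.size(); ++b) {
                    int i = s.idxB[b];
                    f[3*i + k] += g * s.mass[i] / s.massB;
                }
            }
        }
    }
    return U;
}

// [[Rcpp::export]]
double cg_energy_cpp(List sys, NumericMatrix pos, bool has_bias,
                     double bias_d0, double bias_k) {
    CGSystem s = unpack(sys);
    if (pos.nrow() != s.n) stop("position count does not match bead count");
    std::vector<double> x(3 * s.n);
    for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) x[3*i + k] = pos(i, k);
    return eval_potential(s, x.data(), NULL, has_bias, bias_d0, bias_k);
}

// [[Rcpp::export]]
NumericMatrix cg_forces_cpp(List sys, NumericMatrix pos, bool has_bias,
                            double bias_d0, double bias_k) {
    CGSystem s = unpack(sys);
    if (pos.nrow() != s.n) stop("position count does not match bead count");
    std::vector<double> x(3 * s.n), f(3 * s.n);
    for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) x[3*i + k] = pos(i, k);
    eval_potential(s, x.data(), f.data(), has_bias, bias_d0, bias_k);
    NumericMatrix out(s.n, 3);
    for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) out(i, k) = f[3*i + k];
    return out;
}

// BAOAB Langevin integrator.  dt in fs, friction in ps^-1, T in K.
// Uses R's RNG stream (set.seed on the R side gives bit reproducibility).
// [[Rcpp::export]]
List run_baoab_cpp(List sys, NumericMatrix start, double dt, double friction,
                   double temperature, int n_steps, int stride,
                   bool has_bias, double bias_d0, double bias_k,
                   bool draw_velocities) {
    CGSystem s = unpack(sys);
    if (start.nrow() != s.n) stop("start positions do not match bead count");
    if (stride < 1) stop("save_stride must be >= 1");
    RNGScope scope;

    std::vector<double> x(3 * s.n), v(3 * s.n, 0.0), f(3 * s.n);
    for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) x[3*i + k] = start(i, k);

    double kT = KB * temperature * FCONV;  // amu A^2/fs^2
    if (draw_velocities) {
        for (int i = 0; i < s.n; ++i) {
            double sd = std::sqrt(kT / s.mass[i]);
            for (int k = 0; k < 3; ++k) v[3*i + k] = sd * norm_rand();
        }
    }

    double gamma = friction * 1e-3;        // fs^-1
    double c1 = std::exp(-gamma * dt);
    double c2 = std::sqrt(1.0 - c1 * c1);

    int n_frames = n_steps / stride + 1;
    NumericMatrix frames(n_frames, 3 * s.n);

    eval_potential(s, x.data(), f.data(), has_bias, bias_d0, bias_k);
    for (int k = 0; k < 3 * s.n; ++k) frames(0, k) = x[k];

    int saved = 1;
    for (int step = 1; step <= n_steps; ++step) {
        for (int i = 0; i < s.n; ++i) {
            double am = 0.5 * dt * FCONV / s.mass[i];
            for (int k = 0; k < 3; ++k) v[3*i + k] += am * f[3*i + k];
        }
        for (int k = 0; k < 3 * s.n; ++k) x[k] += 0.5 * dt * v[k];
        for (int i = 0; i < s.n; ++i) {
            double sd = std::sqrt(kT / s.mass[i]);
            for (int k = 0; k < 3; ++k)
                v[3*i + k] = c1 * v[3*i + k] + c2 * sd * norm_rand();
        }
        for (int k = 0; k < 3 * s.n; ++k) x[k] += 0.5 * dt * v[k];
        eval_potential(s, x.data(), f.data(), has_bias, bias_d0, bias_k);
        for (int i = 0; i < s.n; ++i) {
            double am = 0.5 * dt * FCONV / s.mass[i];
            for (int k = 0; k < 3; ++k) v[3*i + k] += am * f[3*i + k];
        }
        if (step % stride == 0) {
            bool ok = true;
            for (int k = 0; k < 3 * s.n; ++k)
                if (!std::isfinite(x[k])) { ok = false; break; }
            if (!ok) stop("integrator blow-up: non-finite coordinates at step %d", step);
            for (int k = 0; k < 3 * s.n; ++k) frames(saved, k) = x[k];
            ++saved;
        }
    }

    NumericMatrix vel(s.n, 3), fin(s.n, 3);
    for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) {
            vel(i, k) = v[3*i + k];
            fin(i, k) = x[3*i + k];
        }
    return List::create(_["frames"] = frames, _["final_positions"] = fin,
                        _["final_velocities"] = vel);
}

// Sample a discrete Markov chain using R's RNG (1-based states).
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix T, int n_steps, int start) {
    int n = T.nrow();
    RNGScope scope;
    // cumulative rows
    std::vector<double> cum(n * n);
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) {
            acc += T(i, j);
            cum[i * n + j] = acc;
        }
    }
    IntegerVector out(n_steps);
    int s = start - 1;
    out[0] = s + 1;
    for (int t = 1; t < n_steps; ++t) {
        double u = unif_rand();
        const double* row = &cum[s * n];
        int j = 0;
        while (j < n - 1 && u > row[j]) ++j;
        s = j;
        out[t] = s + 1;
    }
    return out;
}
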