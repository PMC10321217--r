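// Compiled core: pair interactions, rigid-body overdamped integrator,
// patch contact detection, pair-distance histogram, multiple-tau correlator.
// All lengths in sigma, energies in epsilon, times in tau_Br (k_B = 1).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>

using namespace Rcpp;

namespace {

inline double minimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64; Box-Muller normals. Self-contained
// so that trajectories are bit-reproducible for a given integer seed.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    zig_init();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;   s[3] = rotl(s[3], 45);
    return res;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)

  // Marsaglia-Tsang 128-layer ziggurat for standard normals.
  static uint32_t zkn[128];
  static double zwn[128], zfn[128];
  static bool zready;
  static void zig_init() {
    if (zready) return;
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    zkn[0] = static_cast<uint32_t>((dn / q) * m1);
    zkn[1] = 0;
    zwn[0] = q / m1;
    zwn[127] = dn / m1;
    zfn[0] = 1.0;
    zfn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      zkn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      zfn[i] = std::exp(-0.5 * dn * dn);
      zwn[i] = dn / m1;
    }
    zready = true;
  }
  double norm() {
    for (;;) {
      const int32_t hz = static_cast<int32_t>(next() >> 32);
      const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      const uint32_t ahz =
          (hz >= 0) ? static_cast<uint32_t>(hz)
                    : static_cast<uint32_t>(-static_cast<int64_t>(hz));
      if (ahz < zkn[iz]) return hz * zwn[iz];
      const double r = 3.442619855899;
      double x = hz * zwn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(1.0 - unif()) / r;
          y = -std::log(1.0 - unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      if (zfn[iz] + unif() * (zfn[iz - 1] - zfn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }
};

uint32_t Rng::zkn[128];
double Rng::zwn[128];
double Rng::zfn[128];
bool Rng::zready = false;

// ---------------------------------------------------------- quaternions ---
inline void quat_to_mat(const double* q, double* R) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

inline void axis_angle_quat(double wx, double wy, double wz, double* dq) {
  const double th = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (th < 1e-14) { dq[0] = 1; dq[1] = dq[2] = dq[3] = 0; return; }
  const double h = 0.5 * th, s = std::sin(h) / th;
  dq[0] = std::cos(h); dq[1] = wx * s; dq[2] = wy * s; dq[3] = wz * s;
}

inline void quat_mul(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// ----------------------------------------------------------- force field --
// Bead type codes: 0 = CORE, 1 = ARM (both finite, WCA), 2 = PATCH (Morse).
struct FF {
  double eps_rep, eps_m, a_m, r0_m, rcut_p;
  bool shift;
  double wca_cut2, rcut_p2, ushift;
};

FF make_ff(const List& p) {
  FF f;
  f.eps_rep = as<double>(p["eps_rep"]);
  f.eps_m   = as<double>(p["eps_m"]);
  f.a_m     = as<double>(p["a_m"]);
  f.r0_m    = as<double>(p["r0_m"]);
  f.rcut_p  = as<double>(p["r_cut_patch"]);
  f.shift   = as<bool>(p["shift"]);
  const double wc = std::pow(2.0, 1.0 / 6.0);
  f.wca_cut2 = wc * wc;
  f.rcut_p2  = f.rcut_p * f.rcut_p;
  double ex = std::exp(-f.a_m * (f.rcut_p - f.r0_m));
  f.ushift = f.shift ? f.eps_m * ((1.0 - ex) * (1.0 - ex) - 1.0) : 0.0;
  return f;
}

// WCA energy/force for r2 < wca_cut2. Returns energy, sets f_over_r.
inline double wca_pair(double r2, const FF& ff, double& f_over_r) {
  const double inv2 = 1.0 / r2;
  const double sr6 = inv2 * inv2 * inv2;
  const double sr12 = sr6 * sr6;
  f_over_r = 24.0 * ff.eps_rep * (2.0 * sr12 - sr6) * inv2;
  return 4.0 * ff.eps_rep * (sr12 - sr6) + ff.eps_rep;
}

// Morse energy/force for r < rcut_p.
inline double morse_pair(double r, const FF& ff, double& f_over_r) {
  const double ex = std::exp(-ff.a_m * (r - ff.r0_m));
  const double om = 1.0 - ex;
  // dU/dr = 2 eps a ex (1 - ex); force on i along +dr is -dU/dr
  f_over_r = -2.0 * ff.eps_m * ff.a_m * ex * om / std::max(r, 1e-12);
  return ff.eps_m * (om * om - 1.0) - ff.ushift;
}

// ------------------------------------------------------------ simulation --
struct Sim {
  int N, nb;
  double L;
  std::vector<double> cen, quat;   // 3N, 4N
  std::vector<int> img;            // 3N
  std::vector<double> loc;         // 3*nb template-local bead coords
  std::vector<int> btype;          // nb
  FF ff;
  double r_int, rlist2, skin;

  std::vector<double> bw, boff;    // world bead positions / offsets, 3*nb*N
  std::vector<double> F, Tq;       // net force/torque per star, 3N
  std::vector<int> pa, pb;         // star-pair Verlet list
  std::vector<double> accd;        // displacement since last list build
  double energy;
  double W[6];                     // virial xx yy zz xy xz yz
  int n_overlap;

  void world_beads() {
    double R[9];
    for (int i = 0; i < N; ++i) {
      quat_to_mat(&quat[4 * i], R);
      const double cx = cen[3 * i], cy = cen[3 * i + 1], cz = cen[3 * i + 2];
      for (int b = 0; b < nb; ++b) {
        const double lx = loc[3 * b], ly = loc[3 * b + 1], lz = loc[3 * b + 2];
        const double ox = R[0] * lx + R[1] * ly + R[2] * lz;
        const double oy = R[3] * lx + R[4] * ly + R[5] * lz;
        const double oz = R[6] * lx + R[7] * ly + R[8] * lz;
        const int k = 3 * (nb * i + b);
        boff[k] = ox; boff[k + 1] = oy; boff[k + 2] = oz;
        bw[k] = cx + ox; bw[k + 1] = cy + oy; bw[k + 2] = cz + oz;
      }
    }
  }

  void build_pairs() {
    pa.clear(); pb.clear();
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        const double dx = minimg(cen[3 * i] - cen[3 * j], L);
        const double dy = minimg(cen[3 * i + 1] - cen[3 * j + 1], L);
        const double dz = minimg(cen[3 * i + 2] - cen[3 * j + 2], L);
        if (dx * dx + dy * dy + dz * dz < rlist2) { pa.push_back(i); pb.push_back(j); }
      }
    }
    std::fill(accd.begin(), accd.end(), 0.0);
  }

  void eval() {
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(Tq.begin(), Tq.end(), 0.0);
    std::fill(W, W + 6, 0.0);
    energy = 0.0;
    n_overlap = 0;
    const double ri2 = r_int * r_int;
    const size_t npair = pa.size();
    for (size_t p = 0; p < npair; ++p) {
      const int a = pa[p], b = pb[p];
      double dcx = cen[3 * a] - cen[3 * b];
      double dcy = cen[3 * a + 1] - cen[3 * b + 1];
      double dcz = cen[3 * a + 2] - cen[3 * b + 2];
      const double mx = minimg(dcx, L), my = minimg(dcy, L), mz = minimg(dcz, L);
      if (mx * mx + my * my + mz * mz > ri2) continue;
      // shift to bring star b's beads next to star a
      const double shx = dcx - mx, shy = dcy - my, shz = dcz - mz;
      const double cbx = cen[3 * b] + shx, cby = cen[3 * b + 1] + shy,
                   cbz = cen[3 * b + 2] + shz;
      // bead of a can only interact if within patch_offset + wca cutoff
      // of star b's centre
      const double reach = 2.5 + 1.1225;
      const double reach2 = reach * reach;
      for (int bi = 0; bi < nb; ++bi) {
        const int ti = btype[bi];
        const int ki = 3 * (nb * a + bi);
        const double xi = bw[ki], yi = bw[ki + 1], zi = bw[ki + 2];
        const double dbx = xi - cbx, dby = yi - cby, dbz = zi - cbz;
        if (dbx * dbx + dby * dby + dbz * dbz > reach2) continue;
        for (int bj = 0; bj < nb; ++bj) {
          const int tj = btype[bj];
          const bool patchpair = (ti == 2 && tj == 2);
          if (!patchpair && (ti == 2 || tj == 2)) continue;
          const int kj = 3 * (nb * b + bj);
          const double dx = xi - (bw[kj] + shx);
          const double dy = yi - (bw[kj + 1] + shy);
          const double dz = zi - (bw[kj + 2] + shz);
          const double r2 = dx * dx + dy * dy + dz * dz;
          double e = 0.0, f_over_r = 0.0;
          if (patchpair) {
            if (r2 >= ff.rcut_p2) continue;
            e = morse_pair(std::sqrt(r2), ff, f_over_r);
          } else {
            if (r2 >= ff.wca_cut2) continue;
            if (r2 < 0.25) ++n_overlap;
            e = wca_pair(r2, ff, f_over_r);
          }
          energy += e;
          const double fx = f_over_r * dx, fy = f_over_r * dy, fz = f_over_r * dz;
          F[3 * a] += fx; F[3 * a + 1] += fy; F[3 * a + 2] += fz;
          F[3 * b] -= fx; F[3 * b + 1] -= fy; F[3 * b + 2] -= fz;
          // torque about each star's centre
          Tq[3 * a]     += boff[ki + 1] * fz - boff[ki + 2] * fy;
          Tq[3 * a + 1] += boff[ki + 2] * fx - boff[ki] * fz;
          Tq[3 * a + 2] += boff[ki] * fy - boff[ki + 1] * fx;
          Tq[3 * b]     -= boff[kj + 1] * fz - boff[kj + 2] * fy;
          Tq[3 * b + 1] -= boff[kj + 2] * fx - boff[kj] * fz;
          Tq[3 * b + 2] -= boff[kj] * fy - boff[kj + 1] * fx;
          W[0] += dx * fx; W[1] += dy * fy; W[2] += dz * fz;
          W[3] += dx * fy; W[4] += dx * fz; W[5] += dy * fz;
        }
      }
    }
  }

  // Greedy nearest-partner matching of patches within r_bond.
  int contacts(double r_bond, std::vector<std::array<int, 4>>* bonds) {
    struct Cand { double d2; int pi, pj; };
    std::vector<Cand> cand;
    const double rb2 = r_bond * r_bond;
    const size_t npair = pa.size();
    for (size_t p = 0; p < npair; ++p) {
      const int a = pa[p], b = pb[p];
      double dcx = cen[3 * a] - cen[3 * b];
      double dcy = cen[3 * a + 1] - cen[3 * b + 1];
      double dcz = cen[3 * a + 2] - cen[3 * b + 2];
      const double shx = dcx - minimg(dcx, L);
      const double shy = dcy - minimg(dcy, L);
      const double shz = dcz - minimg(dcz, L);
      for (int bi = 0; bi < nb; ++bi) {
        if (btype[bi] != 2) continue;
        const int ki = 3 * (nb * a + bi);
        for (int bj = 0; bj < nb; ++bj) {
          if (btype[bj] != 2) continue;
          const int kj = 3 * (nb * b + bj);
          const double dx = bw[ki] - (bw[kj] + shx);
          const double dy = bw[ki + 1] - (bw[kj + 1] + shy);
          const double dz = bw[ki + 2] - (bw[kj + 2] + shz);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < rb2) cand.push_back({d2, nb * a + bi, nb * b + bj});
        }
      }
    }
    std::sort(cand.begin(), cand.end(),
              [](const Cand& x, const Cand& y) { return x.d2 < y.d2; });
    std::vector<char> used(static_cast<size_t>(N) * nb, 0);
    int nc = 0;
    for (const Cand& c : cand) {
      if (used[c.pi] || used[c.pj]) continue;
      used[c.pi] = used[c.pj] = 1;
      ++nc;
      if (bonds) bonds->push_back({c.pi / nb, c.pi % nb, c.pj / nb, c.pj % nb});
    }
    return nc;
  }
};

}  // namespace

// ------------------------------------------------------------ exports -----

// [[Rcpp::export]]
NumericMatrix cpp_world_beads(NumericMatrix centers, NumericMatrix quats,
                              NumericMatrix local) {
  const int N = centers.nrow(), nb = local.nrow();
  NumericMatrix out(N * nb, 3);
  double R[9], q[4];
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 4; ++k) q[k] = quats(i, k);
    quat_to_mat(q, R);
    for (int b = 0; b < nb; ++b) {
      const double lx = local(b, 0), ly = local(b, 1), lz = local(b, 2);
      out(nb * i + b, 0) = centers(i, 0) + R[0] * lx + R[1] * ly + R[2] * lz;
      out(nb * i + b, 1) = centers(i, 1) + R[3] * lx + R[4] * ly + R[5] * lz;
      out(nb * i + b, 2) = centers(i, 2) + R[6] * lx + R[7] * ly + R[8] * lz;
    }
  }
  return out;
}

// Brute-force O(n^2) bead-level energy/forces/virial with per-pair minimum
// image. Oracle path and analysis path for arbitrary (possibly wrapped)
// bead coordinates.
// [[Rcpp::export]]
List cpp_bead_forces(NumericMatrix pos, IntegerVector mol, IntegerVector type,
                     double boxL, List ffpars) {
  const FF ff = make_ff(ffpars);
  const int n = pos.nrow();
  NumericMatrix Fm(n, 3);
  double W[6] = {0, 0, 0, 0, 0, 0};
  double energy = 0.0;
  int n_overlap = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      const int ti = type[i], tj = type[j];
      const bool patchpair = (ti == 2 && tj == 2);
      if (!patchpair && (ti == 2 || tj == 2)) continue;
      const double dx = minimg(pos(i, 0) - pos(j, 0), boxL);
      const double dy = minimg(pos(i, 1) - pos(j, 1), boxL);
      const double dz = minimg(pos(i, 2) - pos(j, 2), boxL);
      const double r2 = dx * dx + dy * dy + dz * dz;
      double e = 0.0, f_over_r = 0.0;
      if (patchpair) {
        if (r2 >= ff.rcut_p2) continue;
        e = morse_pair(std::sqrt(r2), ff, f_over_r);
      } else {
        if (r2 >= ff.wca_cut2) continue;
        if (r2 < 0.25) ++n_overlap;
        e = wca_pair(r2, ff, f_over_r);
      }
      energy += e;
      const double fx = f_over_r * dx, fy = f_over_r * dy, fz = f_over_r * dz;
      Fm(i, 0) += fx; Fm(i, 1) += fy; Fm(i, 2) += fz;
      Fm(j, 0) -= fx; Fm(j, 1) -= fy; Fm(j, 2) -= fz;
      W[0] += dx * fx; W[1] += dy * fy; W[2] += dz * fz;
      W[3] += dx * fy; W[4] += dx * fz; W[5] += dy * fz;
    }
  }
  NumericMatrix Wm(3, 3);
  Wm(0, 0) = W[0]; Wm(1, 1) = W[1]; Wm(2, 2) = W[2];
  Wm(0, 1) = Wm(1, 0) = W[3]; Wm(0, 2) = Wm(2, 0) = W[4];
  Wm(1, 2) = Wm(2, 1) = W[5];
  return List::create(_["forces"] = Fm, _["energy"] = energy,
                      _["virial"] = Wm, _["n_overlap"] = n_overlap);
}

// Patch contact detection with greedy nearest-partner tie-break.
// mol/arm label each patch site; indices are returned as given.
// [[Rcpp::export]]
DataFrame cpp_contacts(NumericMatrix ppos, IntegerVector mol, IntegerVector arm,
                       double boxL, double r_bond) {
  const int n = ppos.nrow();
  struct Cand { double d2; int i, j; };
  std::vector<Cand> cand;
  const double rb2 = r_bond * r_bond;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      const double dx = minimg(ppos(i, 0) - ppos(j, 0), boxL);
      const double dy = minimg(ppos(i, 1) - ppos(j, 1), boxL);
      const double dz = minimg(ppos(i, 2) - ppos(j, 2), boxL);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rb2) cand.push_back({d2, i, j});
    }
  }
  std::sort(cand.begin(), cand.end(),
            [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });
  std::vector<char> used(n, 0);
  std::vector<int> ma, aa, mb, ab;
  std::vector<double> dist;
  for (const Cand& c : cand) {
    if (used[c.i] || used[c.j]) continue;
    used[c.i] = used[c.j] = 1;
    ma.push_back(mol[c.i]); aa.push_back(arm[c.i]);
    mb.push_back(mol[c.j]); ab.push_back(arm[c.j]);
    dist.push_back(std::sqrt(c.d2));
  }
  return DataFrame::create(_["mol_a"] = ma, _["arm_a"] = aa,
                           _["mol_b"] = mb, _["arm_b"] = ab,
                           _["dist"] = dist);
}

// Pair-distance histogram with minimum image (for g(r)).
// [[Rcpp::export]]
NumericVector cpp_pair_hist(NumericMatrix pos, double boxL, double binw,
                            int nbins) {
  NumericVector h(nbins);
  const int n = pos.nrow();
  const double rmax2 = (binw * nbins) * (binw * nbins);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = minimg(pos(i, 0) - pos(j, 0), boxL);
      const double dy = minimg(pos(i, 1) - pos(j, 1), boxL);
      const double dz = minimg(pos(i, 2) - pos(j, 2), boxL);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax2) continue;
      const int k = static_cast<int>(std::sqrt(r2) / binw);
      if (k < nbins) h[k] += 1.0;
    }
  }
  return h;
}

// Overdamped rigid-body Brownian dynamics.
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix centers0, NumericMatrix quats0,
                IntegerMatrix images0, NumericMatrix local,
                IntegerVector btype, double boxL, double temperature,
                List ffpars, double D_t, double D_r, double dt,
                int n_steps, int record_every, int stress_every,
                bool save_frames, double r_bond, double neighbor_skin,
                double t0, double seed) {
  Sim S;
  S.N = centers0.nrow();
  S.nb = local.nrow();
  S.L = boxL;
  S.ff = make_ff(ffpars);
  S.skin = neighbor_skin;
  // farthest interacting bead pair: patch sites at 2.5 sigma + patch cutoff,
  // or outer arm beads at 2 sigma + WCA cutoff
  const double reach_p = 2.0 * 2.5 + S.ff.rcut_p;
  const double reach_w = 2.0 * 2.0 + std::pow(2.0, 1.0 / 6.0);
  S.r_int = std::max(reach_p, reach_w);
  const double rl = S.r_int + S.skin;
  S.rlist2 = rl * rl;

  S.cen.assign(centers0.begin(), centers0.end());
  // R matrices are column-major; repack to interleaved xyz
  S.cen.resize(3 * S.N);
  S.quat.resize(4 * S.N);
  S.img.resize(3 * S.N);
  for (int i = 0; i < S.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      S.cen[3 * i + k] = centers0(i, k);
      S.img[3 * i + k] = images0(i, k);
    }
    for (int k = 0; k < 4; ++k) S.quat[4 * i + k] = quats0(i, k);
  }
  S.loc.resize(3 * S.nb);
  S.btype.assign(btype.begin(), btype.end());
  for (int b = 0; b < S.nb; ++b)
    for (int k = 0; k < 3; ++k) S.loc[3 * b + k] = local(b, k);
  S.bw.resize(3 * S.nb * S.N);
  S.boff.resize(3 * S.nb * S.N);
  S.F.resize(3 * S.N);
  S.Tq.resize(3 * S.N);
  S.accd.assign(3 * S.N, 0.0);

  Rng rng(static_cast<uint64_t>(seed));

  const double mu_t = D_t / temperature;
  const double mu_r = D_r / temperature;
  const double cap = 0.1;  // max per-step centre displacement, sigma

  const int nrec = (record_every > 0) ? n_steps / record_every + 1 : 0;
  const int nstr = (stress_every > 0) ? n_steps / stress_every + 1 : 0;
  NumericVector rec_t(nrec), rec_E(nrec), rec_Pxy(nrec), rec_Pxz(nrec),
      rec_Pyz(nrec);
  IntegerVector rec_Nc(nrec);
  NumericVector str_t(nstr), str_xy(nstr), str_xz(nstr), str_yz(nstr);
  NumericVector fr_cen, fr_quat;
  IntegerVector fr_img;
  if (save_frames) {
    fr_cen = NumericVector(static_cast<R_xlen_t>(nrec) * S.N * 3);
    fr_quat = NumericVector(static_cast<R_xlen_t>(nrec) * S.N * 4);
    fr_img = IntegerVector(static_cast<R_xlen_t>(nrec) * S.N * 3);
  }

  const double V = boxL * boxL * boxL;
  int n_rebuild = 0, n_halved = 0, n_overlap_tot = 0;
  int irec = 0, istr = 0;

  S.build_pairs();
  ++n_rebuild;

  std::vector<double> newc(3 * S.N), dxs(3 * S.N), wvec(3);
  std::vector<double> newq(4 * S.N);
  // Leimkuhler-Matthews noise buffers: the update uses the average of the
  // previous and current step's Gaussians, giving O(dt^2) configurational
  // sampling accuracy at no extra force evaluations.
  std::vector<double> gt_prev(3 * S.N), gr_prev(3 * S.N);
  std::vector<double> gt_cur(3 * S.N), gr_cur(3 * S.N);
  for (int k = 0; k < 3 * S.N; ++k) {
    gt_prev[k] = rng.norm();
    gr_prev[k] = rng.norm();
  }

  for (int s = 0; s <= n_steps; ++s) {
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    S.world_beads();
    S.eval();
    if (!std::isfinite(S.energy))
      stop("non-finite energy at step %d (time %g tau_Br)", s, t0 + s * dt);
    n_overlap_tot += S.n_overlap;

    if (record_every > 0 && s % record_every == 0 && irec < nrec) {
      rec_t[irec] = t0 + s * dt;
      rec_E[irec] = S.energy;
      rec_Pxy[irec] = S.W[3] / V;
      rec_Pxz[irec] = S.W[4] / V;
      rec_Pyz[irec] = S.W[5] / V;
      rec_Nc[irec] = S.contacts(r_bond, nullptr);
      if (save_frames) {
        for (int i = 0; i < S.N; ++i) {
          for (int k = 0; k < 3; ++k) {
            fr_cen[irec + static_cast<R_xlen_t>(nrec) * (i + S.N * k)] =
                S.cen[3 * i + k];
            fr_img[irec + static_cast<R_xlen_t>(nrec) * (i + S.N * k)] =
                S.img[3 * i + k];
          }
          for (int k = 0; k < 4; ++k)
            fr_quat[irec + static_cast<R_xlen_t>(nrec) * (i + S.N * k)] =
                S.quat[4 * i + k];
        }
      }
      ++irec;
    }
    if (stress_every > 0 && s % stress_every == 0 && istr < nstr) {
      str_t[istr] = t0 + s * dt;
      str_xy[istr] = S.W[3] / V;
      str_xz[istr] = S.W[4] / V;
      str_yz[istr] = S.W[5] / V;
      ++istr;
    }
    if (s == n_steps) break;

    // Euler-Maruyama update with displacement cap: on violation the whole
    // step is redone with dt halved (fresh noise at the reduced step).
    double dtl = dt;
    for (int k = 0; k < 3 * S.N; ++k) {
      gt_cur[k] = rng.norm();
      gr_cur[k] = rng.norm();
    }
    for (int attempt = 0;; ++attempt) {
      if (attempt > 8)
        stop("step %d: displacement cap still exceeded after 8 dt halvings", s);
      const double sd_t = 0.5 * std::sqrt(2.0 * D_t * dtl);
      const double sd_r = 0.5 * std::sqrt(2.0 * D_r * dtl);
      double maxd2 = 0.0;
      for (int i = 0; i < S.N; ++i) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          const double dx = mu_t * S.F[3 * i + k] * dtl +
              sd_t * (gt_prev[3 * i + k] + gt_cur[3 * i + k]);
          dxs[3 * i + k] = dx;
          newc[3 * i + k] = S.cen[3 * i + k] + dx;
          d2 += dx * dx;
        }
        if (d2 > maxd2) maxd2 = d2;
        const double wx = mu_r * S.Tq[3 * i] * dtl +
            sd_r * (gr_prev[3 * i] + gr_cur[3 * i]);
        const double wy = mu_r * S.Tq[3 * i + 1] * dtl +
            sd_r * (gr_prev[3 * i + 1] + gr_cur[3 * i + 1]);
        const double wz = mu_r * S.Tq[3 * i + 2] * dtl +
            sd_r * (gr_prev[3 * i + 2] + gr_cur[3 * i + 2]);
        double dq[4], qn[4];
        axis_angle_quat(wx, wy, wz, dq);
        quat_mul(dq, &S.quat[4 * i], qn);
        const double nrm = std::sqrt(qn[0] * qn[0] + qn[1] * qn[1] +
                                     qn[2] * qn[2] + qn[3] * qn[3]);
        for (int k = 0; k < 4; ++k) newq[4 * i + k] = qn[k] / nrm;
      }
      if (maxd2 > cap * cap) { dtl *= 0.5; ++n_halved; continue; }
      break;
    }
    double maxacc2 = 0.0;
    for (int i = 0; i < S.N; ++i) {
      for (int k = 0; k < 3; ++k) {
        double x = newc[3 * i + k];
        const double n = std::floor(x / S.L);
        S.cen[3 * i + k] = x - n * S.L;
        S.img[3 * i + k] += static_cast<int>(n);
        S.accd[3 * i + k] += dxs[3 * i + k];
      }
      const double a2 = S.accd[3 * i] * S.accd[3 * i] +
                        S.accd[3 * i + 1] * S.accd[3 * i + 1] +
                        S.accd[3 * i + 2] * S.accd[3 * i + 2];
      if (a2 > maxacc2) maxacc2 = a2;
      for (int k = 0; k < 4; ++k) S.quat[4 * i + k] = newq[4 * i + k];
    }
    if (maxacc2 > 0.25 * S.skin * S.skin) {
      S.build_pairs();
      ++n_rebuild;
    }
    std::swap(gt_prev, gt_cur);
    std::swap(gr_prev, gr_cur);
  }

  NumericMatrix cen_out(S.N, 3), quat_out(S.N, 4);
  IntegerMatrix img_out(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      cen_out(i, k) = S.cen[3 * i + k];
      img_out(i, k) = S.img[3 * i + k];
    }
    for (int k = 0; k < 4; ++k) quat_out(i, k) = S.quat[4 * i + k];
  }
  List series = List::create(
      _["time"] = rec_t, _["energy"] = rec_E, _["n_contacts"] = rec_Nc,
      _["Pxy"] = rec_Pxy, _["Pxz"] = rec_Pxz, _["Pyz"] = rec_Pyz);
  List stress = List::create(_["time"] = str_t, _["Pxy"] = str_xy,
                             _["Pxz"] = str_xz, _["Pyz"] = str_yz);
  List out = List::create(
      _["centers"] = cen_out, _["quats"] = quat_out, _["images"] = img_out,
      _["series"] = series, _["stress"] = stress,
      _["n_rebuild"] = n_rebuild, _["n_halved"] = n_halved,
      _["n_overlap"] = n_overlap_tot, _["time"] = t0 + n_steps * dt);
  if (save_frames) {
    fr_cen.attr("dim") = IntegerVector::create(nrec, S.N, 3);
    fr_quat.attr("dim") = IntegerVector::create(nrec, S.N, 4);
    fr_img.attr("dim") = IntegerVector::create(nrec, S.N, 3);
    out["frame_centers"] = fr_cen;
    out["frame_quats"] = fr_quat;
    out["frame_images"] = fr_img;
  }
  return out;
}

// ----------------------------------------------- multiple-tau correlator --
// Hierarchical block-averaging correlator (p points per level, averaging
// factor m). State travels as an R list so it can be accumulated across
// batches of samples.

namespace {
void mt_push_one(double v, int lvl, int p, int m, int maxlev, double* buf,
                 int* nfill, double* acc, int* nacc, double* corr,
                 double* cnt) {
  if (lvl >= maxlev) return;
  double* b = buf + static_cast<size_t>(lvl) * p;
  const int top = std::min(nfill[lvl], p - 1);
  for (int k = top; k > 0; --k) b[k] = b[k - 1];
  b[0] = v;
  if (nfill[lvl] < p) ++nfill[lvl];
  const int k0 = (lvl == 0) ? 0 : p / m;
  for (int k = k0; k < nfill[lvl]; ++k) {
    corr[static_cast<size_t>(lvl) * p + k] += b[0] * b[k];
    cnt[static_cast<size_t>(lvl) * p + k] += 1.0;
  }
  acc[lvl] += v;
  if (++nacc[lvl] == m) {
    const double a = acc[lvl] / m;
    acc[lvl] = 0.0;
    nacc[lvl] = 0;
    mt_push_one(a, lvl + 1, p, m, maxlev, buf, nfill, acc, nacc, corr, cnt);
  }
}
}  // namespace

// [[Rcpp::export]]
List cpp_mt_push(List state, NumericVector x) {
  const int p = as<int>(state["p"]);
  const int m = as<int>(state["m"]);
  const int maxlev = as<int>(state["max_levels"]);
  NumericVector buf = clone(as<NumericVector>(state["buf"]));
  IntegerVector nfill = clone(as<IntegerVector>(state["nfill"]));
  NumericVector acc = clone(as<NumericVector>(state["acc"]));
  IntegerVector nacc = clone(as<IntegerVector>(state["nacc"]));
  NumericVector corr = clone(as<NumericVector>(state["corr"]));
  NumericVector cnt = clone(as<NumericVector>(state["cnt"]));
  double total = as<double>(state["count"]);
  double sum = as<double>(state["sum"]);
  double sumsq = as<double>(state["sumsq"]);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    mt_push_one(x[i], 0, p, m, maxlev, buf.begin(), nfill.begin(),
                acc.begin(), nacc.begin(), corr.begin(), cnt.begin());
    total += 1.0;
    sum += x[i];
    sumsq += x[i] * x[i];
  }
  return List::create(_["p"] = p, _["m"] = m, _["max_levels"] = maxlev,
                      _["buf"] = buf, _["nfill"] = nfill, _["acc"] = acc,
                      _["nacc"] = nacc, _["corr"] = corr, _["cnt"] = cnt,
                      _["count"] = total, _["sum"] = sum, _["sumsq"] = sumsq);
}
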