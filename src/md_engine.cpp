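// Reduced-scale coarse-grained molecular dynamics engine: velocity-Verlet
// integration of a bead-spring fibril with two-regime bonds, 12-6
// Lennard-Jones cohesion, optional harmonic backbone angles, a Langevin
// thermostat, a per-bead speed cap, and strain-controlled axial box
// deformation with affine remap.  Periodic along z only.
//
// Units: length Angstrom, time fs, energy kcal/mol, mass g/mol,
// temperature K.  MVV2E converts m*v^2 (g/mol * A^2/fs^2) to kcal/mol.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const double MVV2E = 2390.0574;          // (g/mol)(A/fs)^2 -> kcal/mol
const double KB = 0.0019872041;          // kcal/mol/K
const double P2MPA = 6947.695;           // kcal/mol/A^3 -> MPa

// Fast Gaussian stream for the thermostat noise (R's norm_rand costs too
// much at ~5e4 draws per step).  xoshiro256+ seeded via splitmix64 from an
// integer drawn from the R RNG, so set.seed() still controls every run.
struct Gauss {
  uint64_t s[4];
  double spare;
  bool has_spare = false;
  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) {  // splitmix64
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    has_spare = false;
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double runif() {
    return (next() >> 11) * 1.1102230246251565e-16;  // 2^-53
  }
  inline double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1, u2;
    do { u1 = runif(); } while (u1 <= 1e-300);
    u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(6.283185307179586 * u2);
    has_spare = true;
    return r * std::cos(6.283185307179586 * u2);
  }
};

struct Sys {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> chain;
  std::vector<char> bonded;  // bond i -> i+1 intact
  // explicit extra bonds (arbitrary pairs, e.g. a chain wrapped across the
  // periodic boundary); same potential as the backbone bonds
  std::vector<int> wrap_a, wrap_b;
  std::vector<char> wrap_ok;
  double zlo, Lz;
};

inline double wrapdz(double dz, double Lz) {
  // valid for |dz| < 1.5 Lz, always true for interaction vectors
  double h = 0.5 * Lz;
  if (dz > h) return dz - Lz;
  if (dz < -h) return dz + Lz;
  return dz;
}

struct Params {
  double mass, k0, k1, r0, r1, rbreak, eps, sigma, cutoff;
  double angle_k, dt, damp, vmax, kBT;
  bool thermostat, angles;
};

// cell list over a lateral bounding box, periodic in z (head/next arrays)
struct Cells {
  double x0, y0, cell;
  int nx, ny, nz;
  std::vector<int> head, next;
  void build(const Sys &S, double cutoff_skin) {
    cell = cutoff_skin;
    double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30;
    for (int i = 0; i < S.n; i++) {
      xmin = std::min(xmin, S.x[i]); xmax = std::max(xmax, S.x[i]);
      ymin = std::min(ymin, S.y[i]); ymax = std::max(ymax, S.y[i]);
    }
    x0 = xmin - 1e-6; y0 = ymin - 1e-6;
    nx = std::max(1, (int)((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)((ymax - y0) / cell) + 1);
    nz = (int)(S.Lz / cell);
    if (nz < 3) nz = 1;  // avoid double counting through the z wrap
    head.assign((size_t)nx * ny * nz, -1);
    next.assign(S.n, -1);
    for (int i = 0; i < S.n; i++) {
      int ix = (int)((S.x[i] - x0) / cell);
      int iy = (int)((S.y[i] - y0) / cell);
      double zz = S.z[i] - S.zlo;
      zz -= S.Lz * std::floor(zz / S.Lz);
      int iz = std::min(nz - 1, (int)(zz / (S.Lz / nz)));
      ix = std::min(std::max(ix, 0), nx - 1);
      iy = std::min(std::max(iy, 0), ny - 1);
      size_t c = (size_t)(iz * ny + iy) * nx + ix;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// excluded from LJ: beads joined by one intact bond, or two intact bonds
inline bool excluded(const Sys &S, int a, int b) {
  if (S.chain[a] != S.chain[b]) return false;
  int lo = std::min(a, b), hi = std::max(a, b);
  if (hi - lo == 1) return S.bonded[lo] != 0;
  if (hi - lo == 2) return S.bonded[lo] && S.bonded[lo + 1];
  return false;
}

void build_pairs(const Sys &S, const Params &P, double skin,
                 std::vector<std::pair<int, int>> &pairs) {
  pairs.clear();
  Cells C;
  C.build(S, P.cutoff + skin);
  double rc2 = (P.cutoff + skin) * (P.cutoff + skin);
  int dzmax = (C.nz >= 3) ? 1 : 0;
  for (int iz = 0; iz < C.nz; iz++)
    for (int iy = 0; iy < C.ny; iy++)
      for (int ix = 0; ix < C.nx; ix++) {
        int hme = C.head[(size_t)(iz * C.ny + iy) * C.nx + ix];
        if (hme < 0) continue;
        // half stencil: self, then (dz=0, dy=0, dx=1), (dz=0, dy=1, all
        // dx), (dz=1, all dy/dx); dz=-1 handled from the other side
        for (int dz = 0; dz <= dzmax; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              bool self = (dx == 0 && dy == 0 && dz == 0);
              bool take = self || dz == 1 || (dz == 0 && dy == 1) ||
                          (dz == 0 && dy == 0 && dx == 1);
              if (!take) continue;
              int jx = ix + dx, jy = iy + dy;
              int jz = (iz + dz + C.nz) % C.nz;
              if (jx < 0 || jx >= C.nx || jy < 0 || jy >= C.ny) continue;
              int hyo = C.head[(size_t)(jz * C.ny + jy) * C.nx + jx];
              for (int i = hme; i >= 0; i = C.next[i]) {
                int j0 = self ? C.next[i] : hyo;
                for (int j = j0; j >= 0; j = C.next[j]) {
                  double ddx = S.x[i] - S.x[j];
                  double ddy = S.y[i] - S.y[j];
                  double ddz = wrapdz(S.z[i] - S.z[j], S.Lz);
                  if (ddx * ddx + ddy * ddy + ddz * ddz < rc2 &&
                      !excluded(S, i, j))
                    pairs.emplace_back(i, j);
                }
              }
            }
      }
}

// forces; returns potential energy, accumulates W_zz (configurational
// virial, z component)
double compute_forces(Sys &S, const Params &P,
                      const std::vector<std::pair<int, int>> &pairs,
                      double &Wzz, int &broken_now) {
  double pe = 0.0;
  Wzz = 0.0;
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  // bonds
  double e1 = 0.5 * P.k0 * (P.r1 - P.r0) * (P.r1 - P.r0);
  double f1 = P.k0 * (P.r1 - P.r0);
  auto bond_force = [&](int i, int j, char &ok) {
    if (!ok) return;
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j];
    double dz = wrapdz(S.z[i] - S.z[j], S.Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > P.rbreak) { ok = 0; broken_now++; return; }
    double fmag;
    if (r <= P.r1) {
      pe += 0.5 * P.k0 * (r - P.r0) * (r - P.r0);
      fmag = -P.k0 * (r - P.r0);
    } else {
      pe += e1 + f1 * (r - P.r1) + 0.5 * P.k1 * (r - P.r1) * (r - P.r1);
      fmag = -(f1 + P.k1 * (r - P.r1));
    }
    double fr = fmag / std::max(r, 1e-12);
    double Fx = fr * dx, Fy = fr * dy, Fz = fr * dz;
    S.fx[i] += Fx; S.fy[i] += Fy; S.fz[i] += Fz;
    S.fx[j] -= Fx; S.fy[j] -= Fy; S.fz[j] -= Fz;
    Wzz += Fz * dz;
  };
  for (size_t w = 0; w < S.wrap_a.size(); w++)
    bond_force(S.wrap_a[w], S.wrap_b[w], S.wrap_ok[w]);
  for (int i = 0; i < S.n - 1; i++) {
    if (!S.bonded[i]) continue;
    int j = i + 1;
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j];
    double dz = wrapdz(S.z[i] - S.z[j], S.Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > P.rbreak) { S.bonded[i] = 0; broken_now++; continue; }
    double fmag;  // -dE/dr
    if (r <= P.r1) {
      pe += 0.5 * P.k0 * (r - P.r0) * (r - P.r0);
      fmag = -P.k0 * (r - P.r0);
    } else {
      pe += e1 + f1 * (r - P.r1) + 0.5 * P.k1 * (r - P.r1) * (r - P.r1);
      fmag = -(f1 + P.k1 * (r - P.r1));
    }
    double fr = fmag / std::max(r, 1e-12);
    double Fx = fr * dx, Fy = fr * dy, Fz = fr * dz;
    S.fx[i] += Fx; S.fy[i] += Fy; S.fz[i] += Fz;
    S.fx[j] -= Fx; S.fy[j] -= Fy; S.fz[j] -= Fz;
    Wzz += Fz * dz;
  }
  // LJ, energy-shifted to zero at the cutoff
  double rc2 = P.cutoff * P.cutoff;
  double s2 = P.sigma * P.sigma;
  double src6 = std::pow(P.sigma / P.cutoff, 6.0);
  double e_cut = 4.0 * P.eps * (src6 * src6 - src6);
  for (const auto &pr : pairs) {
    int i = pr.first, j = pr.second;
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j];
    double dz = wrapdz(S.z[i] - S.z[j], S.Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2 || r2 < 1e-12) continue;
    double sr2 = s2 / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    pe += 4.0 * P.eps * (sr12 - sr6) - e_cut;
    double fr = 24.0 * P.eps * (2.0 * sr12 - sr6) / r2;
    double Fx = fr * dx, Fy = fr * dy, Fz = fr * dz;
    S.fx[i] += Fx; S.fy[i] += Fy; S.fz[i] += Fz;
    S.fx[j] -= Fx; S.fy[j] -= Fy; S.fz[j] -= Fz;
    Wzz += Fz * dz;
  }
  // backbone bending: cosine form E = 2 k (1 + cos theta), which matches
  // the harmonic k (theta - pi)^2 curvature at the straight configuration
  // and needs no acos in the inner loop
  if (P.angles && P.angle_k > 0) {
    double kb = 2.0 * P.angle_k;
    for (int b = 0; b + 2 < S.n; b++) {
      if (!S.bonded[b] || !S.bonded[b + 1]) continue;
      int i1 = b, i2 = b + 1, i3 = b + 2;
      double d1x = S.x[i1] - S.x[i2], d1y = S.y[i1] - S.y[i2];
      double d1z = wrapdz(S.z[i1] - S.z[i2], S.Lz);
      double d2x = S.x[i3] - S.x[i2], d2y = S.y[i3] - S.y[i2];
      double d2z = wrapdz(S.z[i3] - S.z[i2], S.Lz);
      double r1l = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
      double r2l = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
      double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1l * r2l);
      c = std::min(1.0, std::max(-1.0, c));
      pe += kb * (1.0 + c);
      double a_coef = kb;  // dE/dcos(theta)
      double a11 = a_coef * c / (r1l * r1l);
      double a12 = -a_coef / (r1l * r2l);
      double a22 = a_coef * c / (r2l * r2l);
      double F1x = a11 * d1x + a12 * d2x;
      double F1y = a11 * d1y + a12 * d2y;
      double F1z = a11 * d1z + a12 * d2z;
      double F3x = a22 * d2x + a12 * d1x;
      double F3y = a22 * d2y + a12 * d1y;
      double F3z = a22 * d2z + a12 * d1z;
      S.fx[i1] += F1x; S.fy[i1] += F1y; S.fz[i1] += F1z;
      S.fx[i3] += F3x; S.fy[i3] += F3y; S.fz[i3] += F3z;
      S.fx[i2] -= F1x + F3x; S.fy[i2] -= F1y + F3y; S.fz[i2] -= F1z + F3z;
      Wzz += F1z * d1z + F3z * d2z;
    }
  }
  return pe;
}

}  // namespace

// [[Rcpp::export]]
List cpp_md_run(NumericVector x0, NumericVector y0, NumericVector z0,
                NumericVector vx0, NumericVector vy0, NumericVector vz0,
                IntegerVector chain, LogicalVector bonded_next,
                List params, List run) {
  Sys S;
  S.n = x0.size();
  S.x.assign(x0.begin(), x0.end());
  S.y.assign(y0.begin(), y0.end());
  S.z.assign(z0.begin(), z0.end());
  S.vx.assign(vx0.begin(), vx0.end());
  S.vy.assign(vy0.begin(), vy0.end());
  S.vz.assign(vz0.begin(), vz0.end());
  S.fx.assign(S.n, 0.0); S.fy.assign(S.n, 0.0); S.fz.assign(S.n, 0.0);
  S.chain.assign(chain.begin(), chain.end());
  S.bonded.assign(bonded_next.begin(), bonded_next.end());
  if (run.containsElementNamed("wrap_a")) {
    IntegerVector wa = run["wrap_a"], wb = run["wrap_b"];
    for (int k = 0; k < wa.size(); k++) {
      S.wrap_a.push_back(wa[k] - 1);
      S.wrap_b.push_back(wb[k] - 1);
      S.wrap_ok.push_back(1);
    }
  }

  Params P;
  P.mass = as<double>(params["mass"]);
  P.k0 = as<double>(params["k0"]); P.k1 = as<double>(params["k1"]);
  P.r0 = as<double>(params["r0"]); P.r1 = as<double>(params["r1"]);
  P.rbreak = as<double>(params["r_break"]);
  P.eps = as<double>(params["lj_epsilon"]);
  P.sigma = as<double>(params["lj_sigma"]);
  P.cutoff = as<double>(params["lj_cutoff"]);
  P.angle_k = as<double>(params["angle_k"]);
  P.dt = as<double>(params["dt"]);
  P.damp = as<double>(params["damp"]);
  P.vmax = as<double>(params["vmax"]);
  P.kBT = KB * as<double>(params["temperature"]);
  P.thermostat = as<bool>(params["thermostat"]);
  P.angles = as<bool>(params["use_angles"]);

  S.zlo = as<double>(run["zlo"]);
  S.Lz = as<double>(run["Lz"]);
  double Lz0 = as<double>(run["Lz0"]);
  double lateral_area = as<double>(run["lateral_area"]);
  long long n_steps = (long long)as<double>(run["n_steps"]);
  int sample_every = as<int>(run["sample_every"]);
  int bond_sample_every = as<int>(run["bond_sample_every"]);
  double edot = as<double>(run["strain_rate_fs"]);  // per fs
  int rebuild_every = 20;
  double skin = 2.0;
  Gauss gauss;
  gauss.seed((uint64_t)as<double>(run["noise_seed"]));

  double inv_mconv = 1.0 / (P.mass * MVV2E);  // F (kcal/mol/A) -> a (A/fs^2)
  double gamma = P.damp > 0 ? 1.0 / P.damp : 0.0;
  double sig_v = std::sqrt(2.0 * gamma * P.kBT * P.dt / (P.mass * MVV2E));

  std::vector<std::pair<int, int>> pairs;
  build_pairs(S, P, skin, pairs);
  double Wzz = 0.0;
  int broken_now = 0;
  double pe = compute_forces(S, P, pairs, Wzz, broken_now);

  std::vector<double> fr_time, fr_strain, fr_stress, fr_temp, fr_pe;
  List bond_frames;
  std::vector<double> bond_frame_strain;

  for (long long step = 1; step <= n_steps; step++) {
    double half = 0.5 * P.dt * inv_mconv;
    for (int i = 0; i < S.n; i++) {
      S.vx[i] += half * S.fx[i];
      S.vy[i] += half * S.fy[i];
      S.vz[i] += half * S.fz[i];
      S.x[i] += S.vx[i] * P.dt;
      S.y[i] += S.vy[i] * P.dt;
      S.z[i] += S.vz[i] * P.dt;
    }
    // strain-controlled axial deformation with affine remap
    if (edot != 0.0) {
      double scale = 1.0 + edot * P.dt;
      S.Lz *= scale;
      for (int i = 0; i < S.n; i++)
        S.z[i] = S.zlo + (S.z[i] - S.zlo) * scale;
    }
    if (step % rebuild_every == 0) build_pairs(S, P, skin, pairs);
    pe = compute_forces(S, P, pairs, Wzz, broken_now);
    for (int i = 0; i < S.n; i++) {
      S.vx[i] += half * S.fx[i];
      S.vy[i] += half * S.fy[i];
      S.vz[i] += half * S.fz[i];
    }
    if (P.thermostat && gamma > 0) {
      double damp_f = 1.0 - gamma * P.dt;
      for (int i = 0; i < S.n; i++) {
        S.vx[i] = S.vx[i] * damp_f + sig_v * gauss.rnorm();
        S.vy[i] = S.vy[i] * damp_f + sig_v * gauss.rnorm();
        S.vz[i] = S.vz[i] * damp_f + sig_v * gauss.rnorm();
      }
    }
    if (P.vmax > 0) {
      double v2max = P.vmax * P.vmax;
      for (int i = 0; i < S.n; i++) {
        double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                    S.vz[i] * S.vz[i];
        if (v2 > v2max) {
          double f = P.vmax / std::sqrt(v2);
          S.vx[i] *= f; S.vy[i] *= f; S.vz[i] *= f;
        }
      }
    }
    for (int i = 0; i < S.n; i++) {
      if (!std::isfinite(S.x[i]) || !std::isfinite(S.z[i]))
        stop("numerical blow-up (non-finite position) at step " +
             std::to_string((long long)step));
    }
    if (step % sample_every == 0) {
      double ke_zz = 0.0, ke = 0.0;
      for (int i = 0; i < S.n; i++) {
        ke_zz += P.mass * S.vz[i] * S.vz[i] * MVV2E;
        ke += P.mass * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                        S.vz[i] * S.vz[i]) * MVV2E;
      }
      double vol = lateral_area * S.Lz;
      double stress = -(ke_zz + Wzz) / vol * P2MPA;  // tension positive
      fr_time.push_back(step * P.dt);
      fr_strain.push_back(S.Lz / Lz0 - 1.0);
      fr_stress.push_back(stress);
      fr_temp.push_back(ke / (3.0 * S.n * KB));
      fr_pe.push_back(pe);
      int frame_idx = (int)fr_time.size();
      if (bond_sample_every > 0 && frame_idx % bond_sample_every == 0) {
        std::vector<double> bl;
        bl.reserve(S.n);
        for (int i = 0; i < S.n - 1; i++) {
          if (!S.bonded[i]) continue;
          double dx = S.x[i] - S.x[i + 1], dy = S.y[i] - S.y[i + 1];
          double dz = wrapdz(S.z[i] - S.z[i + 1], S.Lz);
          bl.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
        }
        bond_frames.push_back(NumericVector(bl.begin(), bl.end()));
        bond_frame_strain.push_back(S.Lz / Lz0 - 1.0);
      }
    }
  }

  return List::create(
      _["x"] = NumericVector(S.x.begin(), S.x.end()),
      _["y"] = NumericVector(S.y.begin(), S.y.end()),
      _["z"] = NumericVector(S.z.begin(), S.z.end()),
      _["vx"] = NumericVector(S.vx.begin(), S.vx.end()),
      _["vy"] = NumericVector(S.vy.begin(), S.vy.end()),
      _["vz"] = NumericVector(S.vz.begin(), S.vz.end()),
      _["bonded_next"] = LogicalVector(S.bonded.begin(), S.bonded.end()),
      _["Lz"] = S.Lz,
      _["frame_time"] = NumericVector(fr_time.begin(), fr_time.end()),
      _["frame_strain"] = NumericVector(fr_strain.begin(), fr_strain.end()),
      _["frame_stress"] = NumericVector(fr_stress.begin(), fr_stress.end()),
      _["frame_temp"] = NumericVector(fr_temp.begin(), fr_temp.end()),
      _["frame_pe"] = NumericVector(fr_pe.begin(), fr_pe.end()),
      _["bond_frames"] = bond_frames,
      _["bond_frame_strain"] = NumericVector(bond_frame_strain.begin(),
                                             bond_frame_strain.end()),
      _["broken_bonds"] = broken_now);
}
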