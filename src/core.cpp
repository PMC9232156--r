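// Langevin bead-spring dynamics core.
//
// Integration uses the BAOAB splitting: deterministic half-kick / half-drift
// around an exact Ornstein-Uhlenbeck velocity update with friction rate
// m/zeta (zeta is the damping *time*), so the free-particle diffusivity is
// D = kBT * zeta / m.  Noise is variance-matched uniform (the convention of
// large MD engines' Langevin fixes); only second moments enter any quantity
// measured here.
//
// Two geometries: a spherical confinement of radius R (with optional
// on-sphere RATTLE-style projection of tethered telomere nodes) or a periodic
// cubic box (box_side > 0) used for unconfined diffusion measurements.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <sstream>
using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // zero mean, unit variance
  inline double unit_var() { return (2.0 * unif() - 1.0) * 1.7320508075688772935; }
};

struct Grid {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<int> head, nxt;
};

inline double wrap1(double d, double box) {
  if (box > 0.0) {
    d -= box * std::round(d / box);
  }
  return d;
}

struct Sim {
  int N;
  std::vector<double> x, v, f;
  std::vector<int> chain;
  // parameters
  double dt, kbt, m, zeta, ks, r0, eps, sigma, knuc, R, box, cap, skin;
  bool wca_on;
  double rcut, rlist;
  // pairing
  std::vector<int> siteA, siteB, siteHP;
  std::vector<int> paired;          // 0/1 per site
  std::vector<int> partner;         // node -> bonded partner node or -1
  double p_pair, p_unpair, capture;
  bool pairing_on, bonds_frozen;
  // tethering
  std::vector<int> tether;
  // RTM / bouquet
  std::vector<int> rtm_nodes;
  const double *rtm_F = nullptr;    // n_chunks x (3*n_rtm), column-major
  int n_chunks = 0, chunk_steps = 2000;
  double bq_accel = 0.0;
  double bq_focus[3] = {0, 0, 0};
  bool bq_on = false;
  // neighbor list
  std::vector<int> pi_, pj_;
  std::vector<double> x_build;
  std::vector<int> grid_head, grid_next, cx_, cy_, cz_;
  // diagnostics
  double max_r2 = 0.0, max_bond = 0.0, max_step_disp = 0.0;
  double ke_acc = 0.0;
  long n_rebuilds = 0, n_overlap = 0;
  long ke_n = 0;

  inline bool backbone_adjacent(int i, int j) const {
    return chain[i] == chain[j] && (i - j == 1 || j - i == 1);
  }

  void build_list() {
    n_rebuilds++;
    const double cell = rlist;
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    std::vector<double> xb;
    const std::vector<double> *xs = &x;
    if (box > 0.0) {
      xb.resize(3 * N);
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d) {
          double c = x[3 * i + d];
          c -= box * std::floor(c / box);
          xb[3 * i + d] = c;
        }
      xs = &xb;
      lo[0] = lo[1] = lo[2] = 0.0;
      hi[0] = hi[1] = hi[2] = box;
    } else {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d) {
          lo[d] = std::min(lo[d], (*xs)[3 * i + d]);
          hi[d] = std::max(hi[d], (*xs)[3 * i + d]);
        }
    }
    int nx, ny, nz;
    double clx, cly, clz;
    if (box > 0.0) {
      // the grid must tile the box exactly or wrapped neighbours are missed
      nx = std::max(1, (int)(box / cell));
      if (nx < 3) stop("periodic box too small for the neighbour-list cutoff");
      ny = nx; nz = nx;
      clx = cly = clz = box / nx;
    } else {
      nx = std::max(1, (int)((hi[0] - lo[0]) / cell) + 1);
      ny = std::max(1, (int)((hi[1] - lo[1]) / cell) + 1);
      nz = std::max(1, (int)((hi[2] - lo[2]) / cell) + 1);
      clx = cly = clz = cell;
    }
    grid_head.assign((size_t)nx * ny * nz, -1);
    grid_next.assign(N, -1);
    cx_.resize(N); cy_.resize(N); cz_.resize(N);
    std::vector<int> &head = grid_head, &nxt = grid_next;
    std::vector<int> &cx = cx_, &cy = cy_, &cz = cz_;
    for (int i = 0; i < N; ++i) {
      int a = (int)(((*xs)[3 * i] - lo[0]) / clx); if (a >= nx) a = nx - 1; if (a < 0) a = 0;
      int b = (int)(((*xs)[3 * i + 1] - lo[1]) / cly); if (b >= ny) b = ny - 1; if (b < 0) b = 0;
      int c = (int)(((*xs)[3 * i + 2] - lo[2]) / clz); if (c >= nz) c = nz - 1; if (c < 0) c = 0;
      cx[i] = a; cy[i] = b; cz[i] = c;
      size_t id = ((size_t)c * ny + b) * nx + a;
      nxt[i] = head[id]; head[id] = i;
    }
    pi_.clear(); pj_.clear();
    const double rl2 = rlist * rlist;
    const bool pbc = box > 0.0;
    for (int i = 0; i < N; ++i) {
      for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
          for (int dc = -1; dc <= 1; ++dc) {
            int a = cx[i] + da, b = cy[i] + db, c = cz[i] + dc;
            if (pbc) {
              a = (a + nx) % nx; b = (b + ny) % ny; c = (c + nz) % nz;
            } else {
              if (a < 0 || a >= nx || b < 0 || b >= ny || c < 0 || c >= nz) continue;
            }
            for (int j = head[((size_t)c * ny + b) * nx + a]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = wrap1(x[3 * j] - x[3 * i], box);
              double dy = wrap1(x[3 * j + 1] - x[3 * i + 1], box);
              double dz = wrap1(x[3 * j + 2] - x[3 * i + 2], box);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rl2) { pi_.push_back(i); pj_.push_back(j); }
            }
          }
    }
    x_build = x;
  }

  bool need_rebuild() const {
    if (x_build.empty()) return true;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - x_build[3 * i];
      double dy = x[3 * i + 1] - x_build[3 * i + 1];
      double dz = x[3 * i + 2] - x_build[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void forces(long step_local) {
    std::fill(f.begin(), f.end(), 0.0);
    // backbone springs (unwrapped coordinates even under PBC)
    double mb = 0.0;
    for (int i = 0; i + 1 < N; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      double dx = x[3 * (i + 1)] - x[3 * i];
      double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
      double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r > mb) mb = r;
      if (r < 1e-12) continue;  // undefined direction: no force this step
      double c = 2.0 * ks * (r - r0) / r;
      f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
      f[3 * (i + 1)] -= c * dx; f[3 * (i + 1) + 1] -= c * dy; f[3 * (i + 1) + 2] -= c * dz;
    }
    if (mb > max_bond) max_bond = mb;
    // pairing springs
    for (size_t s = 0; s < siteA.size(); ++s) {
      if (!paired[s]) continue;
      int i = siteA[s], j = siteB[s];
      double dx = wrap1(x[3 * j] - x[3 * i], box);
      double dy = wrap1(x[3 * j + 1] - x[3 * i + 1], box);
      double dz = wrap1(x[3 * j + 2] - x[3 * i + 2], box);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      if (r > max_bond) max_bond = r;
      double c = 2.0 * ks * (r - r0) / r;
      f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
      f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
    }
    // WCA excluded volume
    if (wca_on) {
      const double rc2 = rcut * rcut, s2 = sigma * sigma;
      const double deep2 = 0.09 * s2;
      for (size_t p = 0; p < pi_.size(); ++p) {
        int i = pi_[p], j = pj_[p];
        if (backbone_adjacent(i, j)) continue;
        if (partner[i] == j) continue;  // active pairing bond
        double dx = wrap1(x[3 * j] - x[3 * i], box);
        double dy = wrap1(x[3 * j + 1] - x[3 * i + 1], box);
        double dz = wrap1(x[3 * j + 2] - x[3 * i + 2], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) continue;
        if (r2 < deep2) n_overlap++;
        double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2;
        double c = 24.0 * eps * sr6 * (2.0 * sr6 - 1.0) / r2;  // >0 inside cutoff
        f[3 * i] -= c * dx; f[3 * i + 1] -= c * dy; f[3 * i + 2] -= c * dz;
        f[3 * j] += c * dx; f[3 * j + 1] += c * dy; f[3 * j + 2] += c * dz;
      }
    }
    // spherical confinement (sqrt only for the rare outside-wall nodes)
    if (box <= 0.0) {
      const double R2 = R * R;
      for (int i = 0; i < N; ++i) {
        double s2 = x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                    x[3 * i + 2] * x[3 * i + 2];
        if (s2 > max_r2) max_r2 = s2;
        if (s2 > R2) {
          double s = std::sqrt(s2);
          double c = -knuc * (s - R) * (s - R) / s;
          f[3 * i] += c * x[3 * i];
          f[3 * i + 1] += c * x[3 * i + 1];
          f[3 * i + 2] += c * x[3 * i + 2];
        }
      }
    }
    // RTM pulls
    if (rtm_F && !rtm_nodes.empty()) {
      int chunk = (int)(step_local / chunk_steps);
      if (chunk >= n_chunks) chunk = n_chunks - 1;
      int nr = (int)rtm_nodes.size();
      for (int k = 0; k < nr; ++k) {
        int i = rtm_nodes[k];
        // column-major: element (chunk, 3k+d) at (3k+d)*n_chunks + chunk
        f[3 * i]     += rtm_F[(3 * k + 0) * (size_t)n_chunks + chunk];
        f[3 * i + 1] += rtm_F[(3 * k + 1) * (size_t)n_chunks + chunk];
        f[3 * i + 2] += rtm_F[(3 * k + 2) * (size_t)n_chunks + chunk];
      }
    }
    // bouquet bias on tethered telomeres
    if (bq_on && bq_accel != 0.0) {
      for (size_t k = 0; k < tether.size(); ++k) {
        int i = tether[k];
        double dx = bq_focus[0] - x[3 * i];
        double dy = bq_focus[1] - x[3 * i + 1];
        double dz = bq_focus[2] - x[3 * i + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-9) continue;
        double c = m * bq_accel / r;
        f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
      }
    }
  }

  inline void project_positions() {
    for (size_t k = 0; k < tether.size(); ++k) {
      int i = tether[k];
      double s = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                           x[3 * i + 2] * x[3 * i + 2]);
      if (s < 1e-12) continue;
      double c = R / s;
      x[3 * i] *= c; x[3 * i + 1] *= c; x[3 * i + 2] *= c;
    }
  }

  inline void project_velocities() {
    for (size_t k = 0; k < tether.size(); ++k) {
      int i = tether[k];
      double s2 = x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                  x[3 * i + 2] * x[3 * i + 2];
      if (s2 < 1e-24) continue;
      double vr = (v[3 * i] * x[3 * i] + v[3 * i + 1] * x[3 * i + 1] +
                   v[3 * i + 2] * x[3 * i + 2]) / s2;
      v[3 * i] -= vr * x[3 * i];
      v[3 * i + 1] -= vr * x[3 * i + 1];
      v[3 * i + 2] -= vr * x[3 * i + 2];
    }
  }

  inline void drift_half(double h) {
    if (cap > 0.0) {
      const double lim = 0.5 * cap;  // half the per-step cap for each half-drift
      for (int i = 0; i < N; ++i) {
        double dx = h * v[3 * i], dy = h * v[3 * i + 1], dz = h * v[3 * i + 2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d > lim) { double c = lim / d; dx *= c; dy *= c; dz *= c; }
        x[3 * i] += dx; x[3 * i + 1] += dy; x[3 * i + 2] += dz;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        x[3 * i] += h * v[3 * i];
        x[3 * i + 1] += h * v[3 * i + 1];
        x[3 * i + 2] += h * v[3 * i + 2];
      }
    }
    project_positions();
  }

  void update_pairing(RNG &rng) {
    if (!pairing_on || bonds_frozen) return;
    const double cap2 = capture * capture;
    for (size_t s = 0; s < siteA.size(); ++s) {
      int i = siteA[s], j = siteB[s];
      if (paired[s]) {
        if (p_unpair > 0.0 && rng.unif() < p_unpair) {
          paired[s] = 0; partner[i] = -1; partner[j] = -1;
        }
      } else {
        double dx = wrap1(x[3 * j] - x[3 * i], box);
        double dy = wrap1(x[3 * j + 1] - x[3 * i + 1], box);
        double dz = wrap1(x[3 * j + 2] - x[3 * i + 2], box);
        if (dx * dx + dy * dy + dz * dz <= cap2) {
          if (rng.unif() < p_pair) {
            paired[s] = 1; partner[i] = j; partner[j] = i;
          }
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_advance(NumericMatrix pos, NumericMatrix vel, IntegerVector chain,
                 List par, IntegerVector siteA, IntegerVector siteB,
                 IntegerVector siteHP, LogicalVector paired0,
                 IntegerVector tether, IntegerVector rtm_nodes,
                 NumericMatrix rtm_forces, double n_steps_d, double sample_every_d,
                 double step0, double seed1, double seed2) {
  Sim S;
  S.N = pos.nrow();
  S.x.resize(3 * S.N); S.v.resize(3 * S.N); S.f.resize(3 * S.N);
  for (int i = 0; i < S.N; ++i)
    for (int d = 0; d < 3; ++d) {
      S.x[3 * i + d] = pos(i, d);
      S.v[3 * i + d] = vel(i, d);
    }
  S.chain.assign(chain.begin(), chain.end());
  S.dt = as<double>(par["dt"]);
  S.kbt = as<double>(par["kbt"]);
  S.m = as<double>(par["m"]);
  S.zeta = as<double>(par["zeta"]);
  S.ks = as<double>(par["k_spring"]);
  S.r0 = as<double>(par["r0"]);
  S.eps = as<double>(par["eps"]);
  S.sigma = as<double>(par["sigma"]);
  S.knuc = as<double>(par["k_nuc"]);
  S.R = as<double>(par["R"]);
  S.box = as<double>(par["box"]);
  S.cap = as<double>(par["cap"]);
  S.skin = as<double>(par["skin"]);
  S.wca_on = as<bool>(par["wca_on"]);
  S.p_pair = as<double>(par["p_pair"]);
  S.p_unpair = as<double>(par["p_unpair"]);
  S.capture = as<double>(par["capture"]);
  S.pairing_on = as<bool>(par["pairing_on"]);
  S.bonds_frozen = as<bool>(par["bonds_frozen"]);
  S.chunk_steps = as<int>(par["chunk_steps"]);
  S.bq_on = as<bool>(par["bouquet_on"]);
  S.bq_accel = as<double>(par["bouquet_accel"]);
  NumericVector focus = par["bouquet_focus"];
  for (int d = 0; d < 3; ++d) S.bq_focus[d] = focus[d];
  S.rcut = std::pow(2.0, 1.0 / 6.0) * S.sigma;
  S.rlist = S.rcut + S.skin;
  S.siteA.assign(siteA.begin(), siteA.end());
  S.siteB.assign(siteB.begin(), siteB.end());
  S.siteHP.assign(siteHP.begin(), siteHP.end());
  S.paired.assign(paired0.begin(), paired0.end());
  S.partner.assign(S.N, -1);
  for (size_t s = 0; s < S.siteA.size(); ++s)
    if (S.paired[s]) { S.partner[S.siteA[s]] = S.siteB[s]; S.partner[S.siteB[s]] = S.siteA[s]; }
  S.tether.assign(tether.begin(), tether.end());
  S.rtm_nodes.assign(rtm_nodes.begin(), rtm_nodes.end());
  if (rtm_forces.nrow() > 0 && S.rtm_nodes.size() > 0) {
    S.rtm_F = rtm_forces.begin();
    S.n_chunks = rtm_forces.nrow();
    if (rtm_forces.ncol() != 3 * (int)S.rtm_nodes.size())
      stop("rtm_forces must have 3 columns per RTM node");
  }

  // tether precondition: nodes must start near the sphere
  for (size_t k = 0; k < S.tether.size(); ++k) {
    int i = S.tether[k];
    double s = std::sqrt(S.x[3 * i] * S.x[3 * i] + S.x[3 * i + 1] * S.x[3 * i + 1] +
                         S.x[3 * i + 2] * S.x[3 * i + 2]);
    if (std::fabs(s - S.R) > 0.5 * S.sigma) {
      std::ostringstream msg;
      msg << "tethered node " << (i + 1) << " is " << std::fabs(s - S.R)
          << " length units from the nuclear sphere (limit 0.5 sigma)";
      stop(msg.str());
    }
  }
  S.project_positions();
  S.project_velocities();

  const long n_steps = (long)n_steps_d;
  const long sample_every = (long)sample_every_d;
  uint64_t seed = ((uint64_t)(int64_t)seed1 << 32) ^ (uint64_t)(int64_t)seed2;
  RNG rng(seed ^ 0xD1B54A32D192ED03ULL);

  const double c1 = std::exp(-S.dt / S.zeta);
  const double c2 = std::sqrt((1.0 - c1 * c1) * S.kbt / S.m);
  const double h = 0.5 * S.dt;
  const double h_im = h / S.m;

  long n_frames = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector fr_pos(n_frames * (long)S.N * 3);
  NumericVector fr_step(n_frames);
  LogicalMatrix fr_paired(std::max(n_frames, 1L), (int)S.siteA.size());
  long frame = 0;

  std::vector<double> x_prev(3 * S.N);
  S.build_list();
  S.forces(0);

  const bool track_disp = S.cap > 0.0;  // phase-1 style runs check every step
  for (long step = 0; step < n_steps; ++step) {
    S.update_pairing(rng);
    if (track_disp) x_prev = S.x;
    // B: half kick
    for (int i = 0; i < 3 * S.N; ++i) S.v[i] += h_im * S.f[i];
    // A: half drift
    S.drift_half(h);
    // O: exact OU velocity update
    if (S.kbt > 0.0) {
      for (int i = 0; i < 3 * S.N; ++i) S.v[i] = c1 * S.v[i] + c2 * rng.unit_var();
    } else {
      for (int i = 0; i < 3 * S.N; ++i) S.v[i] = c1 * S.v[i];
    }
    // A: half drift
    S.drift_half(h);
    if ((track_disp || (step & 3) == 3) && S.need_rebuild()) {
      for (int i = 0; i < 3 * S.N; ++i)
        if (!std::isfinite(S.x[i])) {
          std::ostringstream msg;
          msg << "non-finite coordinate at step " << (double)(step0 + step + 1);
          stop(msg.str());
        }
      S.build_list();
    }
    S.forces(step + 1 < n_steps ? step + 1 : step);
    // B: half kick
    for (int i = 0; i < 3 * S.N; ++i) S.v[i] += h_im * S.f[i];
    S.project_velocities();
    // diagnostics (kinetic energy sampled every 8th step)
    if ((step & 7) == 0) {
      double ke = 0.0;
      for (int i = 0; i < 3 * S.N; ++i) ke += S.v[i] * S.v[i];
      S.ke_acc += 0.5 * S.m * ke / S.N;
      S.ke_n++;
    }
    if (track_disp) {
      double md2 = 0.0;
      for (int i = 0; i < S.N; ++i) {
        double dx = S.x[3 * i] - x_prev[3 * i];
        double dy = S.x[3 * i + 1] - x_prev[3 * i + 1];
        double dz = S.x[3 * i + 2] - x_prev[3 * i + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > md2) md2 = d2;
      }
      double md = std::sqrt(md2);
      if (md > S.max_step_disp) S.max_step_disp = md;
    }
    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      for (int i = 0; i < S.N; ++i)
        for (int d = 0; d < 3; ++d)
          fr_pos[frame + n_frames * ((long)i + (long)S.N * d)] = S.x[3 * i + d];
      for (size_t s = 0; s < S.siteA.size(); ++s)
        fr_paired(frame, (int)s) = S.paired[s] != 0;
      fr_step[frame] = step0 + step + 1;
      frame++;
    }
  }

  NumericMatrix pos_out(S.N, 3), vel_out(S.N, 3);
  for (int i = 0; i < S.N; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = S.x[3 * i + d];
      vel_out(i, d) = S.v[3 * i + d];
    }
  LogicalVector paired_out(S.paired.size());
  for (size_t s = 0; s < S.paired.size(); ++s) paired_out[s] = S.paired[s] != 0;

  if (n_frames > 0) fr_pos.attr("dim") = IntegerVector::create((int)n_frames, S.N, 3);

  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["paired"] = paired_out,
      _["frames_pos"] = fr_pos, _["frames_step"] = fr_step,
      _["frames_paired"] = fr_paired,
      _["ke_mean"] = (S.ke_n > 0) ? S.ke_acc / S.ke_n : NA_REAL,
      _["max_step_disp"] = S.max_step_disp,
      _["max_radius"] = std::sqrt(S.max_r2),
      _["max_bond"] = S.max_bond, _["n_rebuilds"] = (double)S.n_rebuilds,
      _["n_overlap"] = (double)S.n_overlap,
      _["step"] = step0 + n_steps);
}

// Primitive-path contraction: endpoints of every chain fixed, backbone
// springs with zero rest length (pure contraction), intra-chain excluded
// volume off, inter-chain excluded volume on, overdamped FIRE minimization.
// [[Rcpp::export]]
List cpp_ppa(NumericMatrix pos, IntegerVector chain, double k_spring,
             double eps, double sigma, double ftol, double max_iter_d) {
  const int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N, 0.0), f(3 * N);
  std::vector<int> ch(chain.begin(), chain.end());
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  std::vector<bool> fixed(N, false);
  for (int i = 0; i < N; ++i) {
    bool first = (i == 0) || (ch[i] != ch[i - 1]);
    bool last = (i == N - 1) || (ch[i] != ch[i + 1]);
    if (first || last) fixed[i] = true;
  }
  const double rcut = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double rc2 = rcut * rcut, s2 = sigma * sigma;

  // FIRE parameters (standard values)
  double dt = 0.002, dtmax = 0.02;
  const double finc = 1.1, fdec = 0.5, astart = 0.1, fa = 0.99;
  double alpha = astart;
  int n_pos = 0;
  const long max_iter = (long)max_iter_d;

  double maxF = 0.0;
  // neighbor list (inter-chain only)
  std::vector<int> pi_, pj_;
  std::vector<double> x_build;
  const double skin = 0.4, rl = rcut + skin, rl2 = rl * rl;
  auto build = [&]() {
    pi_.clear(); pj_.clear();
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (ch[i] == ch[j]) continue;
        double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
               dz = x[3 * j + 2] - x[3 * i + 2];
        if (dx * dx + dy * dy + dz * dz < rl2) { pi_.push_back(i); pj_.push_back(j); }
      }
    x_build = x;
  };
  auto need_build = [&]() {
    if (x_build.empty()) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * N; i += 3) {
      double dx = x[i] - x_build[i], dy = x[i + 1] - x_build[i + 1],
             dz = x[i + 2] - x_build[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  };
  auto forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    for (int i = 0; i + 1 < N; ++i) {
      if (ch[i] != ch[i + 1]) continue;
      double dx = x[3 * (i + 1)] - x[3 * i];
      double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
      double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
      double c = 2.0 * k_spring;  // rest length 0
      f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
      f[3 * (i + 1)] -= c * dx; f[3 * (i + 1) + 1] -= c * dy; f[3 * (i + 1) + 2] -= c * dz;
    }
    for (size_t p = 0; p < pi_.size(); ++p) {
      int i = pi_[p], j = pj_[p];
      double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
             dz = x[3 * j + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 < 1e-12) continue;
      double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2;
      double c = 24.0 * eps * sr6 * (2.0 * sr6 - 1.0) / r2;
      f[3 * i] -= c * dx; f[3 * i + 1] -= c * dy; f[3 * i + 2] -= c * dz;
      f[3 * j] += c * dx; f[3 * j + 1] += c * dy; f[3 * j + 2] += c * dz;
    }
    maxF = 0.0;
    for (int i = 0; i < N; ++i) {
      if (fixed[i]) { f[3 * i] = f[3 * i + 1] = f[3 * i + 2] = 0.0; continue; }
      double m2 = f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                  f[3 * i + 2] * f[3 * i + 2];
      if (m2 > maxF) maxF = m2;
    }
    maxF = std::sqrt(maxF);
  };

  build();
  forces();
  long it = 0;
  for (; it < max_iter && maxF > ftol; ++it) {
    // FIRE velocity mixing
    double P = 0.0, vn = 0.0, fn = 0.0;
    for (int i = 0; i < 3 * N; ++i) { P += v[i] * f[i]; vn += v[i] * v[i]; fn += f[i] * f[i]; }
    vn = std::sqrt(vn); fn = std::sqrt(fn);
    if (P > 0.0) {
      double cf = (fn > 1e-30) ? alpha * vn / fn : 0.0;
      for (int i = 0; i < 3 * N; ++i) v[i] = (1.0 - alpha) * v[i] + cf * f[i];
      if (++n_pos > 5) { dt = std::min(dt * finc, dtmax); alpha *= fa; }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= fdec; alpha = astart; n_pos = 0;
    }
    for (int i = 0; i < 3 * N; ++i) v[i] += dt * f[i];
    // displacement clamp for stability
    const double maxmove = 0.05;
    for (int i = 0; i < N; ++i) {
      double dx = dt * v[3 * i], dy = dt * v[3 * i + 1], dz = dt * v[3 * i + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > maxmove) { double c = maxmove / d; dx *= c; dy *= c; dz *= c; }
      x[3 * i] += dx; x[3 * i + 1] += dy; x[3 * i + 2] += dz;
    }
    if (need_build()) build();
    forces();
  }

  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return List::create(_["pos"] = out, _["max_force"] = maxF,
                      _["iterations"] = (double)it,
                      _["converged"] = (maxF <= ftol));
}
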