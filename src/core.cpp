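// Compiled core: counter-free xoshiro256++ RNG, WCA + harmonic-bond force
// field with a cell-list neighbour search, and the overdamped Euler-Maruyama
// integrator.  Particle layout in every flat array: membrane monomers first
// (indices 0..L-1, a closed ring, monomer i bonded to (i+1) mod L), then the
// N active particles (indices L..L+N-1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256++, Box-Muller normals.
// A private generator (rather than R's global stream) keeps long compiled
// runs fast and makes the draw order an explicit, documented contract:
// per step -- active translations (x,y per particle), active rotations,
// membrane translations.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
    // avoid the all-zero state (cannot happen from splitmix64, but be safe)
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1): 53-bit mantissa, never exactly 0
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via Box-Muller (cached pair)
  inline double gauss() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Force field
// ---------------------------------------------------------------------------

struct Params {
  int L, N;
  double sigma, eps, V0, omega, D0, Dtheta, gamma, ks, r0, box, dt;
  bool wca_bonded_neighbors;
  bool translational_noise;
};

static Params read_params(const List &par) {
  Params p;
  p.L = as<int>(par["L"]);
  p.N = as<int>(par["N"]);
  p.sigma = as<double>(par["sigma"]);
  p.eps = as<double>(par["eps"]);
  p.V0 = as<double>(par["V0"]);
  p.omega = as<double>(par["omega"]);
  p.D0 = as<double>(par["D0"]);
  p.Dtheta = as<double>(par["Dtheta"]);
  p.gamma = as<double>(par["gamma"]);
  p.ks = as<double>(par["ks"]);
  p.r0 = as<double>(par["r0"]);
  p.box = as<double>(par["box"]);
  p.dt = as<double>(par["dt"]);
  p.wca_bonded_neighbors = as<bool>(par["wca_bonded_neighbors"]);
  p.translational_noise = as<bool>(par["translational_noise"]);
  return p;
}

struct ForceAccum {
  std::vector<double> fx, fy;        // total force, all particles
  std::vector<double> fax, fay;      // force on membrane from actives only
  double U;
  double min_r2;
  long n_close;                      // pairs with r < 0.3 sigma

  void init(int n, int L) {
    fx.assign(n, 0.0);
    fy.assign(n, 0.0);
    fax.assign(L, 0.0);
    fay.assign(L, 0.0);
    U = 0.0;
    min_r2 = std::numeric_limits<double>::infinity();
    n_close = 0;
  }
};

static inline bool ring_bonded(int i, int j, int L) {
  if (i >= L || j >= L) return false;
  int d = i - j;
  if (d < 0) d = -d;
  return d == 1 || d == L - 1;
}

// WCA between particles i,j given min-image displacement (dx, dy), r2 = dx^2+dy^2
static inline void wca_accum(int i, int j, double dx, double dy, double r2,
                             const Params &p, ForceAccum &F) {
  const double rc2 = std::pow(2.0, 1.0 / 3.0) * p.sigma * p.sigma;
  if (r2 < F.min_r2) F.min_r2 = r2;
  if (r2 < 0.09 * p.sigma * p.sigma) ++F.n_close;
  if (r2 >= rc2) return;
  if (r2 <= 0.0)
    stop("overlapping particles (zero pair distance) between %d and %d", i + 1, j + 1);
  double s2 = p.sigma * p.sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  F.U += 4.0 * p.eps * (s12 - s6) + p.eps;               // shifted so U(rc) = 0
  double fr = 24.0 * p.eps * (2.0 * s12 - s6) / r2;      // (1/r) dU/dr magnitude / r
  double fxij = fr * dx, fyij = fr * dy;                 // force on i (dx = xi - xj)
  F.fx[i] += fxij;
  F.fy[i] += fyij;
  F.fx[j] -= fxij;
  F.fy[j] -= fyij;
  const int L = p.L;
  if (i < L && j >= L) { F.fax[i] += fxij; F.fay[i] += fyij; }
  else if (j < L && i >= L) { F.fax[j] -= fxij; F.fay[j] -= fyij; }
}

static inline void bond_accum(int i, int j, double dx, double dy,
                              const Params &p, ForceAccum &F) {
  double r = std::sqrt(dx * dx + dy * dy);
  if (r <= 0.0) stop("overlapping bonded monomers %d and %d", i + 1, j + 1);
  double stretch = r - p.r0;
  F.U += 0.5 * p.ks * stretch * stretch;
  double fr = -p.ks * stretch / r;   // force on i along +d when compressed
  F.fx[i] += fr * dx;
  F.fy[i] += fr * dy;
  F.fx[j] -= fr * dx;
  F.fy[j] -= fr * dy;
}

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// Cell list over the periodic box, reset cost O(#occupied cells).
struct CellList {
  int ncell;          // cells per side
  double cell;        // cell side length (>= cutoff)
  std::vector<int> head, nxt, used, cellof;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             int n, double box, double cutoff) {
    int nc = (int)std::floor(box / cutoff);
    if (nc < 3) nc = 3;
    if (nc > 512) nc = 512;   // cap memory for very large boxes
    if (nc != ncell) {
      ncell = nc;
      head.assign((size_t)ncell * ncell, -1);
    } else {
      for (size_t k = 0; k < used.size(); ++k) head[used[k]] = -1;
    }
    cell = box / ncell;
    nxt.assign(n, -1);
    cellof.assign(n, 0);
    used.clear();
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[i] / cell);
      int cy = (int)std::floor(y[i] / cell);
      if (cx < 0) cx = 0; else if (cx >= ncell) cx = ncell - 1;
      if (cy < 0) cy = 0; else if (cy >= ncell) cy = ncell - 1;
      int c = cy * ncell + cx;
      cellof[i] = c;
      if (head[c] == -1) used.push_back(c);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  CellList() : ncell(-1), cell(0.0) {}
};

static void forces_brute(const std::vector<double> &x, const std::vector<double> &y,
                         const Params &p, ForceAccum &F) {
  int n = p.L + p.N;
  F.init(n, p.L);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[i] - x[j], p.box);
      double dy = min_image(y[i] - y[j], p.box);
      double r2 = dx * dx + dy * dy;
      bool bonded = ring_bonded(i, j, p.L);
      if (!bonded || p.wca_bonded_neighbors) wca_accum(i, j, dx, dy, r2, p, F);
      else {
        if (r2 < F.min_r2) F.min_r2 = r2;
        if (r2 < 0.09 * p.sigma * p.sigma) ++F.n_close;
      }
    }
  }
  for (int i = 0; i < p.L; ++i) {
    int j = (i + 1) % p.L;
    double dx = min_image(x[i] - x[j], p.box);
    double dy = min_image(y[i] - y[j], p.box);
    bond_accum(i, j, dx, dy, p, F);
  }
}

static void forces_cell(const std::vector<double> &x, const std::vector<double> &y,
                        const Params &p, ForceAccum &F, CellList &cl) {
  int n = p.L + p.N;
  F.init(n, p.L);
  double rc = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  cl.build(x, y, n, p.box, rc);
  int nc = cl.ncell;
  for (int i = 0; i < n; ++i) {
    int ci = cl.cellof[i];
    int cx = ci % nc, cy = ci / nc;
    for (int oy = -1; oy <= 1; ++oy) {
      int ncy = cy + oy;
      if (ncy < 0) ncy += nc; else if (ncy >= nc) ncy -= nc;
      for (int ox = -1; ox <= 1; ++ox) {
        int ncx = cx + ox;
        if (ncx < 0) ncx += nc; else if (ncx >= nc) ncx -= nc;
        int c = ncy * nc + ncx;
        for (int j = cl.head[c]; j != -1; j = cl.nxt[j]) {
          if (j <= i) continue;
          double dx = min_image(x[i] - x[j], p.box);
          double dy = min_image(y[i] - y[j], p.box);
          double r2 = dx * dx + dy * dy;
          bool bonded = ring_bonded(i, j, p.L);
          if (!bonded || p.wca_bonded_neighbors) wca_accum(i, j, dx, dy, r2, p, F);
          else {
            if (r2 < F.min_r2) F.min_r2 = r2;
            if (r2 < 0.09 * p.sigma * p.sigma) ++F.n_close;
          }
        }
      }
    }
  }
  for (int i = 0; i < p.L; ++i) {
    int j = (i + 1) % p.L;
    double dx = min_image(x[i] - x[j], p.box);
    double dy = min_image(y[i] - y[j], p.box);
    bond_accum(i, j, dx, dy, p, F);
  }
}

// [[Rcpp::export]]
List cav_forces_cpp(NumericMatrix pos, List par, bool brute) {
  Params p = read_params(par);
  int n = p.L + p.N;
  if (pos.nrow() != n) stop("pos must have L + N rows");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  ForceAccum F;
  if (brute) forces_brute(x, y, p, F);
  else { CellList cl; forces_cell(x, y, p, F, cl); }
  NumericMatrix mf(p.L, 2), af(p.N, 2), mfa(p.L, 2);
  for (int i = 0; i < p.L; ++i) {
    mf(i, 0) = F.fx[i];  mf(i, 1) = F.fy[i];
    mfa(i, 0) = F.fax[i]; mfa(i, 1) = F.fay[i];
  }
  for (int i = 0; i < p.N; ++i) {
    af(i, 0) = F.fx[p.L + i]; af(i, 1) = F.fy[p.L + i];
  }
  return List::create(
    _["mem_force"] = mf, _["act_force"] = af,
    _["mem_force_from_active"] = mfa,
    _["potential_energy"] = F.U,
    _["min_dist"] = std::sqrt(F.min_r2),
    _["n_close"] = (double)F.n_close);
}

// ---------------------------------------------------------------------------
// Integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cav_run_cpp(NumericMatrix pos0, NumericVector theta0, List par,
                 int n_steps, int sample_every, double seed, bool verbose) {
  Params p = read_params(par);
  const int L = p.L, N = p.N, n = L + N;
  if (pos0.nrow() != n) stop("pos0 must have L + N rows");
  if (theta0.size() != N) stop("theta0 must have N entries");
  if (sample_every < 1) stop("sample_every must be >= 1");

  std::vector<double> x(n), y(n), ux(n), uy(n), th(N);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    ux[i] = x[i]; uy[i] = y[i];
  }
  for (int i = 0; i < N; ++i) th[i] = theta0[i];

  Xoshiro rng((uint64_t)(int64_t)seed);
  CellList cl;
  ForceAccum F;

  const double dt = p.dt;
  const double mob = 1.0 / p.gamma;
  const double trn = p.translational_noise ? std::sqrt(2.0 * p.D0 * dt) : 0.0;
  const double rot = std::sqrt(2.0 * p.Dtheta * dt);
  const double invbox = 1.0 / p.box;

  int n_frames = n_steps / sample_every + 1;
  NumericVector times(n_frames);
  NumericVector Us(n_frames), min_dists(n_frames);
  // frame-major flat arrays, dims (n, 2, n_frames) set on return
  NumericVector posw((R_xlen_t)n * 2 * n_frames);
  NumericVector posu((R_xlen_t)n * 2 * n_frames);
  NumericMatrix thetas(N > 0 ? N : 1, n_frames);
  NumericVector fmemact((R_xlen_t)(L > 0 ? L : 1) * 2 * n_frames);
  long n_close_total = 0;

  int frame = 0;
  for (int s = 0; s <= n_steps; ++s) {
    forces_cell(x, y, p, F, cl);
    n_close_total += F.n_close;

    if (s % sample_every == 0) {
      double t = s * dt;
      times[frame] = t;
      Us[frame] = F.U;
      min_dists[frame] = n > 1 ? std::sqrt(F.min_r2) : NA_REAL;
      R_xlen_t off = (R_xlen_t)frame * n * 2;
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
          stop("non-finite coordinate for particle %d at step %d", i + 1, s);
        posw[off + i] = x[i];
        posw[off + n + i] = y[i];
        posu[off + i] = ux[i];
        posu[off + n + i] = uy[i];
      }
      R_xlen_t offf = (R_xlen_t)frame * (L > 0 ? L : 1) * 2;
      for (int i = 0; i < L; ++i) {
        fmemact[offf + i] = F.fax[i];
        fmemact[offf + L + i] = F.fay[i];
      }
      for (int i = 0; i < N; ++i) thetas(i, frame) = th[i];
      ++frame;
      if (verbose && s > 0 && s % 100000 == 0)
        Rcerr << "step " << s << " t=" << t << " U=" << F.U
              << " min_dist=" << (n > 1 ? std::sqrt(F.min_r2) : NA_REAL) << "\n";
      Rcpp::checkUserInterrupt();
    }
    if (s == n_steps) break;

    // documented draw order: active translations, active rotations,
    // membrane translations
    for (int i = 0; i < N; ++i) {
      int k = L + i;
      double drift_x = (p.V0 * std::cos(th[i]) + mob * F.fx[k]) * dt;
      double drift_y = (p.V0 * std::sin(th[i]) + mob * F.fy[k]) * dt;
      double dxs = drift_x + (trn > 0.0 ? trn * rng.gauss() : 0.0);
      double dys = drift_y + (trn > 0.0 ? trn * rng.gauss() : 0.0);
      x[k] += dxs; y[k] += dys; ux[k] += dxs; uy[k] += dys;
    }
    for (int i = 0; i < N; ++i) th[i] += p.omega * dt + rot * rng.gauss();
    for (int i = 0; i < L; ++i) {
      double dxs = mob * F.fx[i] * dt + (trn > 0.0 ? trn * rng.gauss() : 0.0);
      double dys = mob * F.fy[i] * dt + (trn > 0.0 ? trn * rng.gauss() : 0.0);
      x[i] += dxs; y[i] += dys; ux[i] += dxs; uy[i] += dys;
    }
    for (int i = 0; i < n; ++i) {
      x[i] -= p.box * std::floor(x[i] * invbox);
      y[i] -= p.box * std::floor(y[i] * invbox);
    }
  }

  posw.attr("dim") = IntegerVector::create(n, 2, n_frames);
  posu.attr("dim") = IntegerVector::create(n, 2, n_frames);
  fmemact.attr("dim") = IntegerVector::create(L > 0 ? L : 1, 2, n_frames);
  return List::create(
    _["times"] = times, _["pos"] = posw, _["pos_unwrapped"] = posu,
    _["theta"] = thetas, _["mem_force_from_active"] = fmemact,
    _["potential_energy"] = Us, _["min_dist"] = min_dists,
    _["n_frames"] = n_frames, _["n_close"] = (double)n_close_total);
}
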