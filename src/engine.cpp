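// Particle-based simulation core: Brownian glutamate transport in and around
// a cylindrical synaptic cleft, plus hybrid (master-equation) or stochastic
// (per-receptor jump) propagation of ligand-gated receptor kinetics.
//
// Units used throughout: length nm, time us, concentration mM, conductance pS,
// potential mV, current pA. Diffusion coefficients are nm^2/us
// (0.33 um^2/ms = 330 nm^2/us).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// 1 mM = 6.022e-4 molecules per nm^3
static const double MOL_PER_NM3_PER_MM = 6.022e-4;
static const int KMAX = 16;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64; normals via Marsaglia polar.
// Self-contained so that trajectories are bit-reproducible for a given
// (seed, stream) pair independently of R's RNG state.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  double cache;
  bool has_cache;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void init(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL
      + 0x8BADF00DULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    has_cache = false;
    cache = 0.0;
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // open interval (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    cache = v * f;
    has_cache = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Kinetic scheme in engine form.
// R0/R1: off-diagonal rate matrices, entry [i*k+j] = base rate i -> j (us^-1,
//        resp. us^-1 mM^-1 for ligand-dependent steps).
// A0/A1: transposed generators (dP/dt = A P), diagonals filled in.
// ---------------------------------------------------------------------------
struct EngineScheme {
  int k;
  std::vector<double> R0, R1, A0, A1;
  std::vector<int> open;   // 0-based open-state indices
  double gamma, erev;
  int init;                // 0-based initial state
};

static EngineScheme make_scheme(const List &pool) {
  EngineScheme sc;
  NumericMatrix Q0 = pool["q0"], Q1 = pool["q1"];
  sc.k = Q0.nrow();
  if (sc.k > KMAX) stop("kinetic scheme has too many states for the engine");
  sc.R0.assign(sc.k * sc.k, 0.0);
  sc.R1.assign(sc.k * sc.k, 0.0);
  sc.A0.assign(sc.k * sc.k, 0.0);
  sc.A1.assign(sc.k * sc.k, 0.0);
  for (int i = 0; i < sc.k; ++i) {
    for (int j = 0; j < sc.k; ++j) {
      if (i == j) continue;
      double r0 = Q0(i, j), r1 = Q1(i, j);
      if (r0 < 0 || r1 < 0) stop("negative rate in kinetic scheme");
      sc.R0[i * sc.k + j] = r0;
      sc.R1[i * sc.k + j] = r1;
      sc.A0[j * sc.k + i] += r0;   // inflow j <- i
      sc.A1[j * sc.k + i] += r1;
      sc.A0[i * sc.k + i] -= r0;   // outflow from i
      sc.A1[i * sc.k + i] -= r1;
    }
  }
  IntegerVector open = pool["open"];
  for (int i = 0; i < open.size(); ++i) sc.open.push_back(open[i] - 1);
  sc.gamma = as<double>(pool["gamma"]);
  sc.erev = as<double>(pool["erev"]);
  sc.init = as<int>(pool["init"]) - 1;
  return sc;
}

// One RK4 pass over dt with the concentration frozen, sub-stepped so that
// (max exit rate) * h <= 0.25; conserves total probability to round-off.
static void propagate_vec(const EngineScheme &sc, double C, double dt,
                          double *p) {
  const int k = sc.k;
  double A[KMAX * KMAX];
  double lmax = 0.0;
  for (int i = 0; i < k * k; ++i) A[i] = sc.A0[i] + C * sc.A1[i];
  for (int i = 0; i < k; ++i) {
    double d = -A[i * k + i];
    if (d > lmax) lmax = d;
  }
  int m = 1 + (int)(dt * lmax / 0.25);
  double h = dt / m;
  double k1[KMAX], k2[KMAX], k3[KMAX], k4[KMAX], tmp[KMAX];
  for (int s = 0; s < m; ++s) {
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += A[i * k + j] * p[j];
      k1[i] = acc;
    }
    for (int i = 0; i < k; ++i) tmp[i] = p[i] + 0.5 * h * k1[i];
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += A[i * k + j] * tmp[j];
      k2[i] = acc;
    }
    for (int i = 0; i < k; ++i) tmp[i] = p[i] + 0.5 * h * k2[i];
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += A[i * k + j] * tmp[j];
      k3[i] = acc;
    }
    for (int i = 0; i < k; ++i) tmp[i] = p[i] + h * k3[i];
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += A[i * k + j] * tmp[j];
      k4[i] = acc;
    }
    for (int i = 0; i < k; ++i)
      p[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
  double sum = 0.0;
  for (int i = 0; i < k; ++i) {
    if (p[i] < 0.0) {
      if (p[i] < -1e-4) stop("hybrid propagator produced a negative occupancy");
      p[i] = 0.0;
    }
    sum += p[i];
  }
  if (std::fabs(sum - 1.0) > 1e-6)
    stop("occupancy sum drifted beyond 1e-6 in hybrid propagation");
  for (int i = 0; i < k; ++i) p[i] /= sum;
}

// Exact-waiting-time jump simulation over one step with frozen concentration.
static int stochastic_step(const EngineScheme &sc, int s, double C, double dt,
                           Xoshiro &rng) {
  const int k = sc.k;
  double t_rem = dt;
  for (;;) {
    double lam = 0.0;
    for (int j = 0; j < k; ++j)
      lam += sc.R0[s * k + j] + C * sc.R1[s * k + j];
    if (lam <= 0.0) break;
    double tj = -std::log(rng.unif()) / lam;
    if (tj > t_rem) break;
    t_rem -= tj;
    double u = rng.unif() * lam, acc = 0.0;
    int dest = s;
    for (int j = 0; j < k; ++j) {
      double r = sc.R0[s * k + j] + C * sc.R1[s * k + j];
      if (r <= 0.0) continue;
      acc += r;
      dest = j;
      if (u <= acc) break;
    }
    s = dest;
  }
  return s;
}

static inline double open_sum(const EngineScheme &sc, const double *p) {
  double o = 0.0;
  for (size_t i = 0; i < sc.open.size(); ++i) o += p[sc.open[i]];
  return o;
}

// ---------------------------------------------------------------------------
// Per-pool runtime state.
// ---------------------------------------------------------------------------
struct PoolState {
  EngineScheme sc;
  int n;                       // receptor count
  std::vector<double> x, y, r;
  std::vector<int> bin;        // ring-bin index per receptor
  bool stochastic;
  bool use_local;              // local cylinder estimator instead of rings
  // hybrid, ring mode: one occupancy vector per distinct occupied bin
  std::vector<int> ubin, ubin_count;
  std::vector<double> P;       // k * n_vec occupancy storage
  std::vector<int> state;      // stochastic: current state per receptor
  int n_vec;                   // number of occupancy vectors in P
};

// [[Rcpp::export]]
List cpp_run_trial(double R, double ra, double delta, double Rout,
                   List pools, int q, int release_mode,
                   double dt, double duration, double vm,
                   int conc_mode, double dr, double rho_local,
                   double d_in, double d_out,
                   int seed, int stream,
                   int record_every, bool early_stop,
                   bool coarse_far, double far_buffer, double coarse_dt,
                   bool record_states, bool diagnostics) {
  if (dt <= 0) stop("dt must be positive");
  if (duration <= 0) stop("duration must be positive");
  if (q < 0) stop("q must be non-negative");
  if (dr <= 0) stop("dr must be positive");

  Xoshiro rng;
  rng.init((uint64_t)seed, (uint64_t)stream);

  const int nsteps = (int)std::ceil(duration / dt);
  const int nb = (int)std::ceil(R / dr);
  const double drive = vm / 1000.0;  // pS * mV / 1000 = pA (per unit gamma)

  // --- pools -------------------------------------------------------------
  const int npool = pools.size();
  std::vector<PoolState> ps(npool);
  bool need_ring = false, need_local = false, any_stochastic = false;
  for (int pi = 0; pi < npool; ++pi) {
    List pool = pools[pi];
    PoolState &P = ps[pi];
    P.sc = make_scheme(pool);
    NumericVector px = pool["x"], py = pool["y"];
    P.n = px.size();
    P.stochastic = as<bool>(pool["stochastic"]);
    P.use_local = (conc_mode == 1);
    P.x.assign(px.begin(), px.end());
    P.y.assign(py.begin(), py.end());
    P.r.resize(P.n);
    P.bin.resize(P.n);
    for (int i = 0; i < P.n; ++i) {
      P.r[i] = std::sqrt(P.x[i] * P.x[i] + P.y[i] * P.y[i]);
      int b = (int)(P.r[i] / dr);
      if (b >= nb) b = nb - 1;
      P.bin[i] = b;
    }
    if (P.stochastic) {
      any_stochastic = true;
      P.state.assign(P.n, P.sc.init);
      P.n_vec = 0;
    } else if (P.use_local) {
      P.n_vec = P.n;
      P.P.assign((size_t)P.n * P.sc.k, 0.0);
      for (int i = 0; i < P.n; ++i) P.P[(size_t)i * P.sc.k + P.sc.init] = 1.0;
    } else {
      // group receptors by ring bin; receptors in a bin share one vector
      std::vector<int> cnt(nb, 0);
      for (int i = 0; i < P.n; ++i) cnt[P.bin[i]]++;
      for (int b = 0; b < nb; ++b) {
        if (cnt[b] > 0) { P.ubin.push_back(b); P.ubin_count.push_back(cnt[b]); }
      }
      P.n_vec = (int)P.ubin.size();
      P.P.assign((size_t)P.n_vec * P.sc.k, 0.0);
      for (int v = 0; v < P.n_vec; ++v) P.P[(size_t)v * P.sc.k + P.sc.init] = 1.0;
    }
    if (!P.stochastic && !P.use_local) need_ring = true;
    if (P.use_local) need_local = true;
  }
  if (any_stochastic && conc_mode == 0) need_ring = true;

  // --- release ------------------------------------------------------------
  // All molecules start at the release point on the presynaptic face z = delta.
  double rx = 0.0, ry = 0.0;
  if (release_mode == 1) {
    double rr = ra * std::sqrt(rng.unif());
    double th = 2.0 * M_PI * rng.unif();
    rx = rr * std::cos(th);
    ry = rr * std::sin(th);
  }
  std::vector<double> mx(q, rx), my(q, ry), mz(q, delta);
  std::vector<char> in_cleft(q, 1);
  std::vector<int> skip(q, 0);
  int n_active = q, n_absorbed = 0;

  const double R2 = R * R, Rout2 = Rout * Rout;
  const double zc0 = delta / 2.0;  // centre of the absorbing sphere
  const int coarse_K = coarse_far ? std::max(1, (int)std::lround(coarse_dt / dt)) : 1;

  // --- recording ----------------------------------------------------------
  const int nrec_max = nsteps / record_every + 2;
  std::vector<double> rec_t; rec_t.reserve(nrec_max);
  std::vector< std::vector<double> > rec_I(npool), rec_open(npool);
  std::vector< std::vector<double> > rec_occ(npool);
  for (int pi = 0; pi < npool; ++pi) {
    rec_I[pi].reserve(nrec_max);
    rec_open[pi].reserve(nrec_max);
    if (record_states) rec_occ[pi].reserve((size_t)nrec_max * ps[pi].sc.k);
  }
  std::vector<int> rec_ncleft, rec_nout, rec_nabs;
  if (diagnostics) {
    rec_ncleft.reserve(nrec_max); rec_nout.reserve(nrec_max);
    rec_nabs.reserve(nrec_max);
  }

  std::vector<double> Cbin(nb, 0.0), binvol(nb);
  for (int b = 0; b < nb; ++b) {
    double r0 = b * dr, r1 = (b + 1) * dr;
    binvol[b] = M_PI * (r1 * r1 - r0 * r0) * delta;  // annulus (disc for b = 0)
  }
  std::vector<double> clx, cly; clx.reserve(q); cly.reserve(q);

  double peak_total = 0.0, peak_total_t = 0.0;
  std::vector<double> peak_pool(npool, 0.0), peak_pool_t(npool, 0.0);
  std::vector<double> I_now(npool, 0.0), open_now(npool, 0.0);
  std::vector<double> occ_mean(KMAX);

  // per-step evaluation of pool currents; defined as a lambda-free helper via
  // macro-ish inline code below (kept in the main loop for locality)

  int steps_done = 0;
  bool stopped_early = false;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;

    if (step > 0) {
      // ---- Brownian update of all free molecules -------------------------
      for (int i = 0; i < n_active; ) {
        if (skip[i] > 0) { skip[i]--; ++i; continue; }
        double ddt = dt;
        bool cleft = in_cleft[i] != 0;
        if (!cleft && coarse_K > 1) {
          double rho = std::sqrt(mx[i] * mx[i] + my[i] * my[i]);
          double dz = mz[i] < 0 ? -mz[i] : (mz[i] > delta ? mz[i] - delta : 0.0);
          double drr = rho - R;
          double dd = std::sqrt(drr * drr + dz * dz);
          if (dd > far_buffer) {  // far from the cleft opening: coarse step
            ddt = coarse_K * dt;
            skip[i] = coarse_K - 1;
          }
        }
        double D = cleft ? d_in : d_out;
        double sg = std::sqrt(2.0 * D * ddt);
        double nx = mx[i] + sg * rng.norm();
        double ny = my[i] + sg * rng.norm();
        double nz = mz[i] + sg * rng.norm();
        if (cleft) {
          // reflect at both membranes
          while (nz < 0.0 || nz > delta) {
            if (nz < 0.0) nz = -nz;
            if (nz > delta) nz = 2.0 * delta - nz;
          }
          if (nx * nx + ny * ny > R2) in_cleft[i] = 0;  // escaped through rim
          mx[i] = nx; my[i] = ny; mz[i] = nz;
          ++i;
        } else {
          double nrho2 = nx * nx + ny * ny;
          if (nrho2 < R2) {
            if (nz >= 0.0 && nz <= delta) {
              in_cleft[i] = 1;  // re-entered the cleft through the rim
              mx[i] = nx; my[i] = ny; mz[i] = nz;
            }
            // else: proposed move crosses a terminal membrane; reject it
            ++i;
          } else {
            double zc = nz - zc0;
            if (nrho2 + zc * zc > Rout2) {
              // absorbed at the far boundary; swap-remove from active set
              --n_active;
              mx[i] = mx[n_active]; my[i] = my[n_active]; mz[i] = mz[n_active];
              in_cleft[i] = in_cleft[n_active]; skip[i] = skip[n_active];
              ++n_absorbed;
            } else {
              mx[i] = nx; my[i] = ny; mz[i] = nz;
              ++i;
            }
          }
        }
      }
      if (n_active + n_absorbed != q)
        stop("molecule conservation violated");  // internal invariant

      // ---- concentration estimates --------------------------------------
      clx.clear(); cly.clear();
      for (int i = 0; i < n_active; ++i)
        if (in_cleft[i]) { clx.push_back(mx[i]); cly.push_back(my[i]); }
      if (need_ring) {
        std::fill(Cbin.begin(), Cbin.end(), 0.0);
        for (size_t i = 0; i < clx.size(); ++i) {
          int b = (int)(std::sqrt(clx[i] * clx[i] + cly[i] * cly[i]) / dr);
          if (b >= nb) b = nb - 1;
          Cbin[b] += 1.0;
        }
        for (int b = 0; b < nb; ++b)
          Cbin[b] = Cbin[b] / binvol[b] / MOL_PER_NM3_PER_MM;
      }

      // ---- receptor kinetics ---------------------------------------------
      const double cylvol = M_PI * rho_local * rho_local * delta;
      for (int pi = 0; pi < npool; ++pi) {
        PoolState &P = ps[pi];
        if (P.stochastic) {
          for (int i = 0; i < P.n; ++i) {
            double C;
            if (P.use_local) {
              int cnt = 0;
              double xi = P.x[i], yi = P.y[i], rl2 = rho_local * rho_local;
              for (size_t j = 0; j < clx.size(); ++j) {
                double dx = clx[j] - xi, dy = cly[j] - yi;
                if (dx * dx + dy * dy <= rl2) ++cnt;
              }
              C = cnt / cylvol / MOL_PER_NM3_PER_MM;
            } else {
              C = Cbin[P.bin[i]];
            }
            P.state[i] = stochastic_step(P.sc, P.state[i], C, dt, rng);
          }
        } else if (P.use_local) {
          double rl2 = rho_local * rho_local;
          for (int i = 0; i < P.n; ++i) {
            int cnt = 0;
            double xi = P.x[i], yi = P.y[i];
            for (size_t j = 0; j < clx.size(); ++j) {
              double dx = clx[j] - xi, dy = cly[j] - yi;
              if (dx * dx + dy * dy <= rl2) ++cnt;
            }
            double C = cnt / cylvol / MOL_PER_NM3_PER_MM;
            propagate_vec(P.sc, C, dt, &P.P[(size_t)i * P.sc.k]);
          }
        } else {
          for (int v = 0; v < P.n_vec; ++v)
            propagate_vec(P.sc, Cbin[P.ubin[v]], dt, &P.P[(size_t)v * P.sc.k]);
        }
      }
    }

    // ---- currents, peaks, recording --------------------------------------
    double I_total = 0.0;
    for (int pi = 0; pi < npool; ++pi) {
      PoolState &P = ps[pi];
      double open = 0.0;
      if (P.stochastic) {
        for (int i = 0; i < P.n; ++i) {
          for (size_t oi = 0; oi < P.sc.open.size(); ++oi)
            if (P.state[i] == P.sc.open[oi]) { open += 1.0; break; }
        }
      } else if (P.use_local) {
        for (int i = 0; i < P.n; ++i)
          open += open_sum(P.sc, &P.P[(size_t)i * P.sc.k]);
      } else {
        for (int v = 0; v < P.n_vec; ++v)
          open += P.ubin_count[v] * open_sum(P.sc, &P.P[(size_t)v * P.sc.k]);
      }
      open_now[pi] = open;
      I_now[pi] = P.sc.gamma * (vm - P.sc.erev) / 1000.0 * open;
      (void)drive;
      I_total += I_now[pi];
      if (std::fabs(I_now[pi]) > peak_pool[pi]) {
        peak_pool[pi] = std::fabs(I_now[pi]);
        peak_pool_t[pi] = t;
      }
    }
    if (std::fabs(I_total) > peak_total) {
      peak_total = std::fabs(I_total);
      peak_total_t = t;
    }

    if (step % record_every == 0 || step == nsteps) {
      rec_t.push_back(t);
      for (int pi = 0; pi < npool; ++pi) {
        rec_I[pi].push_back(I_now[pi]);
        rec_open[pi].push_back(open_now[pi]);
        if (record_states) {
          PoolState &P = ps[pi];
          int k = P.sc.k;
          for (int si = 0; si < k; ++si) occ_mean[si] = 0.0;
          if (P.stochastic) {
            for (int i = 0; i < P.n; ++i) occ_mean[P.state[i]] += 1.0;
          } else if (P.use_local) {
            for (int i = 0; i < P.n; ++i)
              for (int si = 0; si < k; ++si)
                occ_mean[si] += P.P[(size_t)i * k + si];
          } else {
            for (int v = 0; v < P.n_vec; ++v)
              for (int si = 0; si < k; ++si)
                occ_mean[si] += P.ubin_count[v] * P.P[(size_t)v * k + si];
          }
          double denom = P.n > 0 ? (double)P.n : 1.0;
          for (int si = 0; si < k; ++si)
            rec_occ[pi].push_back(occ_mean[si] / denom);
        }
      }
      if (diagnostics) {
        int ncl = 0;
        for (int i = 0; i < n_active; ++i) ncl += in_cleft[i] ? 1 : 0;
        rec_ncleft.push_back(ncl);
        rec_nout.push_back(n_active - ncl);
        rec_nabs.push_back(n_absorbed);
      }
    }
    steps_done = step;
    if (early_stop && step > 10 && peak_total > 0.0 &&
        std::fabs(I_total) < 0.01 * peak_total) {
      stopped_early = true;
      break;
    }
  }

  // --- pack results --------------------------------------------------------
  int nrec = (int)rec_t.size();
  NumericMatrix I(nrec, npool), open_mat(nrec, npool);
  for (int pi = 0; pi < npool; ++pi)
    for (int i = 0; i < nrec; ++i) {
      I(i, pi) = rec_I[pi][i];
      open_mat(i, pi) = rec_open[pi][i];
    }
  List occ_out(npool);
  if (record_states) {
    for (int pi = 0; pi < npool; ++pi) {
      int k = ps[pi].sc.k;
      NumericMatrix m(nrec, k);
      for (int i = 0; i < nrec; ++i)
        for (int si = 0; si < k; ++si)
          m(i, si) = rec_occ[pi][(size_t)i * k + si];
      occ_out[pi] = m;
    }
  }
  List out = List::create(
    _["time"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["current"] = I,
    _["open"] = open_mat,
    _["peak_total"] = peak_total,
    _["peak_total_time"] = peak_total_t,
    _["peak_pool"] = NumericVector(peak_pool.begin(), peak_pool.end()),
    _["peak_pool_time"] = NumericVector(peak_pool_t.begin(), peak_pool_t.end()),
    _["n_cleft_final"] = [&]() {
      int ncl = 0;
      for (int i = 0; i < n_active; ++i) ncl += in_cleft[i] ? 1 : 0;
      return ncl;
    }(),
    _["n_out_final"] = [&]() {
      int ncl = 0;
      for (int i = 0; i < n_active; ++i) ncl += in_cleft[i] ? 1 : 0;
      return n_active - ncl;
    }(),
    _["n_absorbed_final"] = n_absorbed,
    _["steps_done"] = steps_done,
    _["stopped_early"] = stopped_early
  );
  if (diagnostics) {
    out["n_cleft"] = IntegerVector(rec_ncleft.begin(), rec_ncleft.end());
    out["n_out"] = IntegerVector(rec_nout.begin(), rec_nout.end());
    out["n_absorbed"] = IntegerVector(rec_nabs.begin(), rec_nabs.end());
  }
  if (record_states) out["occupancy"] = occ_out;
  return out;
}

// Single hybrid master-equation step, exposed for the R-level operation and
// its oracle tests. q0/q1 in us^-1 and us^-1 mM^-1, off-diagonal rates.
// [[Rcpp::export]]
NumericVector cpp_propagate_hybrid(NumericVector p, NumericMatrix q0,
                                   NumericMatrix q1, double conc, double dt) {
  List pool = List::create(_["q0"] = q0, _["q1"] = q1,
                           _["open"] = IntegerVector::create(1),
                           _["gamma"] = 0.0, _["erev"] = 0.0, _["init"] = 1);
  EngineScheme sc = make_scheme(pool);
  if (p.size() != sc.k) stop("occupancy vector length does not match scheme");
  std::vector<double> pv(p.begin(), p.end());
  propagate_vec(sc, conc, dt, pv.data());
  return NumericVector(pv.begin(), pv.end());
}
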