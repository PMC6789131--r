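#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Units: energies eV, times ps, masses u, lengths nm, temperatures K.
static const double KB_EV = 8.617333262e-5;
static const double EV_PER_U_NM2_PS2 = 1.66053906660e-21 / 1.602176634e-19;

// ---------------------------------------------------------------------------
// Master-equation forward integrator (deterministic RK4, fixed step).
//
// dE_j/dt = sum_pairs exchange - R_j k_s (E_j - E_s,j)
// exchange for pair (a,b), donor a: k_ab (E_a - (f_a/f_b) E_b), leaving a,
// entering b; reverse rate eliminated by detailed balance.
// Temperature-dependent mode: k_ab = Omega_ab exp(-dG_ab / (kB T_local)),
// T_local = mean of the pair's kinetic temperatures.
// The heater residue is pinned (Dirichlet) at E_pin during [0, duration).
// ---------------------------------------------------------------------------

struct MEParams {
  int N;
  std::vector<int> a, b;           // 0-based pair indices
  std::vector<double> ratio;       // f_a / f_b
  std::vector<double> k_const;     // per-pair constant rate
  std::vector<double> omega, barrier;
  bool temp_dependent;
  std::vector<double> f, R, Es;
  double k_s;
  int heater;                      // 0-based, -1 for none
  double E_pin, duration;
};

static void me_rhs(const MEParams& p, double t, const std::vector<double>& E,
                   std::vector<double>& dE) {
  const bool pinned = (p.heater >= 0 && t < p.duration - 1e-12);
  for (int j = 0; j < p.N; ++j)
    dE[j] = -p.R[j] * p.k_s * (E[j] - p.Es[j]);
  const size_t np = p.a.size();
  for (size_t q = 0; q < np; ++q) {
    const int ia = p.a[q], ib = p.b[q];
    double k;
    if (p.temp_dependent) {
      const double Ta = 2.0 * E[ia] / (p.f[ia] * KB_EV);
      const double Tb = 2.0 * E[ib] / (p.f[ib] * KB_EV);
      const double Tloc = 0.5 * (Ta + Tb);
      k = (Tloc > 0) ? p.omega[q] * std::exp(-p.barrier[q] / (KB_EV * Tloc)) : 0.0;
    } else {
      k = p.k_const[q];
    }
    const double flow = k * (E[ia] - p.ratio[q] * E[ib]);
    dE[ia] -= flow;
    dE[ib] += flow;
  }
  if (pinned) dE[p.heater] = 0.0;
}

// [[Rcpp::export]]
List simulate_me_cpp(NumericVector E0, NumericVector f, NumericVector R,
                     NumericVector Es, IntegerVector pair_a, IntegerVector pair_b,
                     NumericVector k_const, NumericVector omega,
                     NumericVector barrier, bool temp_dependent, double k_s,
                     int heater, double E_pin, double duration, double h,
                     double t_total, double record_interval) {
  MEParams p;
  p.N = E0.size();
  p.a.assign(pair_a.begin(), pair_a.end());
  p.b.assign(pair_b.begin(), pair_b.end());
  p.f.assign(f.begin(), f.end());
  p.R.assign(R.begin(), R.end());
  p.Es.assign(Es.begin(), Es.end());
  p.k_const.assign(k_const.begin(), k_const.end());
  p.omega.assign(omega.begin(), omega.end());
  p.barrier.assign(barrier.begin(), barrier.end());
  for (size_t q = 0; q < p.a.size(); ++q)
    p.ratio.push_back(f[p.a[q]] / f[p.b[q]]);
  p.temp_dependent = temp_dependent;
  p.k_s = k_s;
  p.heater = heater;
  p.E_pin = E_pin;
  p.duration = duration;

  const long n_steps = (long)std::llround(t_total / h);
  const long rec_every = (long)std::llround(record_interval / h);
  if (rec_every < 1) stop("record_interval must be >= the internal step");
  const long n_rec = n_steps / rec_every + 1;

  std::vector<double> E(E0.begin(), E0.end());
  if (p.heater >= 0) E[p.heater] = E_pin;
  NumericMatrix rec(p.N, n_rec);
  NumericVector rec_t(n_rec);
  std::vector<double> k1(p.N), k2(p.N), k3(p.N), k4(p.N), tmp(p.N);

  long ri = 0;
  for (int j = 0; j < p.N; ++j) rec(j, 0) = E[j];
  rec_t[0] = 0.0;
  ri = 1;

  double Emax0 = 0;
  for (int j = 0; j < p.N; ++j) Emax0 = std::max(Emax0, E[j]);

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * h;
    me_rhs(p, t, E, k1);
    for (int j = 0; j < p.N; ++j) tmp[j] = E[j] + 0.5 * h * k1[j];
    me_rhs(p, t + 0.5 * h, tmp, k2);
    for (int j = 0; j < p.N; ++j) tmp[j] = E[j] + 0.5 * h * k2[j];
    me_rhs(p, t + 0.5 * h, tmp, k3);
    for (int j = 0; j < p.N; ++j) tmp[j] = E[j] + h * k3[j];
    me_rhs(p, t + h, tmp, k4);
    for (int j = 0; j < p.N; ++j)
      E[j] += h / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    if (p.heater >= 0 && t + h < p.duration - 1e-12) E[p.heater] = p.E_pin;
    for (int j = 0; j < p.N; ++j) {
      if (!std::isfinite(E[j]) || E[j] > 1e6 * (Emax0 + 1.0))
        stop("master-equation integration unstable at t = %f ps (residue %d)",
             t + h, j + 1);
      if (E[j] < 0) E[j] = 0.0;  // guard against roundoff at hard zero
    }
    if ((s + 1) % rec_every == 0) {
      for (int j = 0; j < p.N; ++j) rec(j, ri) = E[j];
      rec_t[ri] = (s + 1) * h;
      ++ri;
    }
  }
  return List::create(_["times"] = rec_t, _["energies"] = rec);
}

// ---------------------------------------------------------------------------
// FPU-beta lattice surrogate: 1-D chain, harmonic + quartic nearest-neighbour
// potential, velocity-Verlet, optional Langevin thermostats (BAOAB splitting)
// on a heater segment and on the rest of the chain during a heating window.
// Internal units: u, nm, ps (kB = 8.31446e-3 u nm^2 ps^-2 K^-1).
// ---------------------------------------------------------------------------

static const double KB_INT = KB_EV / EV_PER_U_NM2_PS2;

// deterministic cross-platform normals: xorshift64* + Box-Muller
struct NormalRng {
  uint64_t s;
  bool have;
  double cached;
  explicit NormalRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL),
                                      have(false), cached(0) {}
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t r = s * 0x2545F4914F6CDD1DULL;
    return ((r >> 11) + 0.5) / 9007199254740992.0;  // (0,1)
  }
  double norm() {
    if (have) { have = false; return cached; }
    double u1 = unif(), u2 = unif();
    double rad = std::sqrt(-2.0 * std::log(u1));
    cached = rad * std::sin(2.0 * M_PI * u2);
    have = true;
    return rad * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export]]
List simulate_lattice_cpp(int n_sites, double mass, double k_harm_ev,
                          double beta_ev, double t_bath, double t_hot,
                          int heater_lo, int heater_hi, double heat_duration,
                          double friction, double dt, double t_total,
                          double record_interval, double seed,
                          bool thermostat_bath, bool thermostat_always,
                          double equil_time, NumericVector v0) {
  const double kk = k_harm_ev / EV_PER_U_NM2_PS2;   // u / ps^2
  const double bb = beta_ev / EV_PER_U_NM2_PS2;     // u nm^-2 ps^-2
  const double wmax = 2.0 * std::sqrt(kk / mass);
  if (dt >= 2.0 / wmax)
    stop("timestep exceeds the harmonic stability bound 2/omega_max");
  NormalRng rng((uint64_t)(seed));

  std::vector<double> u(n_sites, 0.0), v(n_sites, 0.0), F(n_sites, 0.0);
  if (v0.size() == n_sites) {
    for (int i = 0; i < n_sites; ++i) v[i] = v0[i];       // explicit start
  } else if (t_bath > 0) {
    const double sd = std::sqrt(KB_INT * t_bath / mass);  // Maxwell at T_bath
    for (int i = 0; i < n_sites; ++i) v[i] = sd * rng.norm();
  }

  auto forces = [&](void) {
    std::fill(F.begin(), F.end(), 0.0);
    for (int i = 0; i + 1 < n_sites; ++i) {
      const double d = u[i + 1] - u[i];
      const double fb = kk * d + bb * d * d * d;
      F[i] += fb;
      F[i + 1] -= fb;
    }
  };

  const long n_steps = (long)std::llround((t_total + equil_time) / dt);
  const long rec_every = (long)std::llround(record_interval / dt);
  if (rec_every < 1) stop("record_interval must be >= dt");
  std::vector<double> rt;
  std::vector<std::vector<double> > rv, ru;

  forces();
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt - equil_time;  // t < 0 is equilibration
    // B: half kick
    for (int i = 0; i < n_sites; ++i) v[i] += 0.5 * dt * F[i] / mass;
    // A: half drift
    for (int i = 0; i < n_sites; ++i) u[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck on thermostatted sites
    const bool heating = t >= 0 && t < heat_duration - 1e-12;
    for (int i = 0; i < n_sites; ++i) {
      const bool in_heater = (i >= heater_lo - 1 && i <= heater_hi - 1);
      double target = -1.0;
      if (t < 0) target = t_bath;                                    // equilibration
      else if (heating) target = in_heater ? t_hot
                                           : (thermostat_bath ? t_bath : -1.0);
      else if (thermostat_always) target = t_bath;                   // NVT throughout
      if (target >= 0 && friction > 0) {
        const double sd = std::sqrt(KB_INT * target / mass);
        v[i] = c1 * v[i] + c2 * sd * rng.norm();
      }
    }
    // A: half drift
    for (int i = 0; i < n_sites; ++i) u[i] += 0.5 * dt * v[i];
    forces();
    // B: half kick
    for (int i = 0; i < n_sites; ++i) v[i] += 0.5 * dt * F[i] / mass;

    for (int i = 0; i < n_sites; ++i)
      if (!std::isfinite(u[i]) || std::fabs(u[i]) > 1e6)
        stop("lattice integration unstable at t = %f ps", t);

    if (t >= -1e-12 && (s + 1) % rec_every == 0) {
      rt.push_back(t + dt);
      rv.push_back(v);
      ru.push_back(u);
    }
  }

  const int nr = (int)rt.size();
  NumericMatrix V(n_sites, nr), U(n_sites, nr);
  NumericVector T(nr);
  for (int c = 0; c < nr; ++c) {
    T[c] = rt[c];
    for (int i = 0; i < n_sites; ++i) { V(i, c) = rv[c][i]; U(i, c) = ru[c][i]; }
  }
  return List::create(_["times"] = T, _["velocities"] = V,
                      _["displacements"] = U);
}
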