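// Stochastic three-unit competition network: Heun (predictor-corrector)
// drift integration with exact Ornstein-Uhlenbeck noise updates.
// Per-trial, per-unit RNG streams derived deterministically from a master
// seed so that trials are reproducible and independent of batch layout.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoroshiro128+ uniforms with Box-Muller normals; fully specified so results
// are reproducible across platforms
struct GaussStream {
  uint64_t s0, s1;
  bool have_spare;
  double spare;
  explicit GaussStream(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t st = seed;
    s0 = splitmix64(st);
    s1 = splitmix64(st);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next_u64() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  inline double next_unif() {  // strictly inside (0, 1)
    return (static_cast<double>(next_u64() >> 11) + 0.5) *
           (1.0 / 9007199254740992.0);
  }
  inline double next_norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = next_unif();
    double u2 = next_unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925287 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

struct NetParams {
  double beta_i, alpha, g, tau_u, tau_a, gamma, tau_n, slope, thr, dt;
};

inline void drift(const double* u, const double* a, const double* n,
                  const double* I, const NetParams& p,
                  double* du, double* da) {
  const double usum = u[0] + u[1] + u[2];
  for (int j = 0; j < 3; ++j) {
    double arg = I[j] + p.alpha * u[j] - p.beta_i * (usum - u[j]) -
                 p.g * a[j] + n[j];
    double F = 1.0 / (1.0 + std::exp(-p.slope * (arg - p.thr)));
    du[j] = (-u[j] + F) / p.tau_u;
    da[j] = (-a[j] + u[j]) / p.tau_a;
  }
}

inline int percept_of(const double* u) {
  // integrated (0) iff AB strictly exceeds both A and B; ties -> segregated
  return (u[2] > u[0] && u[2] > u[1]) ? 0 : 1;
}

// Integrate one trial. percept: length-T buffer or nullptr. U/A/Nz: T x 3
// column-major buffers or nullptr.
void run_trial(const double* IA, const double* IB, const double* IAB,
               const int T, const NetParams& p, const uint64_t unit_seeds[3],
               int* percept, double* U, double* A_, double* Nz) {
  GaussStream g0(unit_seeds[0]), g1(unit_seeds[1]), g2(unit_seeds[2]);
  GaussStream* gs[3] = { &g0, &g1, &g2 };
  const double rho = std::exp(-p.dt / p.tau_n);
  const double sdn = p.gamma * std::sqrt(1.0 - rho * rho);
  const bool noisy = p.gamma > 0.0;

  double u[3] = {0, 0, 0}, a[3] = {0, 0, 0}, n[3] = {0, 0, 0};
  // units and adaptation start silent; the background noise is an ongoing
  // cortical process and starts from its stationary distribution
  if (noisy)
    for (int j = 0; j < 3; ++j) n[j] = p.gamma * gs[j]->next_norm();
  double du1[3], da1[3], du2[3], da2[3], up[3], ap[3], nn[3];
  double I0[3], I1[3];

  if (percept) percept[0] = percept_of(u);
  if (U) for (int j = 0; j < 3; ++j) { U[j * T] = 0; A_[j * T] = 0; Nz[j * T] = 0; }

  for (int i = 0; i < T - 1; ++i) {
    I0[0] = IA[i];     I0[1] = IB[i];     I0[2] = IAB[i];
    I1[0] = IA[i + 1]; I1[1] = IB[i + 1]; I1[2] = IAB[i + 1];
    if (noisy) {
      for (int j = 0; j < 3; ++j) nn[j] = n[j] * rho + sdn * gs[j]->next_norm();
    } else {
      nn[0] = nn[1] = nn[2] = 0.0;
    }
    drift(u, a, n, I0, p, du1, da1);
    for (int j = 0; j < 3; ++j) {
      up[j] = u[j] + p.dt * du1[j];
      ap[j] = a[j] + p.dt * da1[j];
    }
    drift(up, ap, nn, I1, p, du2, da2);
    for (int j = 0; j < 3; ++j) {
      u[j] += 0.5 * p.dt * (du1[j] + du2[j]);
      a[j] += 0.5 * p.dt * (da1[j] + da2[j]);
      if (u[j] < 0.0) u[j] = 0.0; else if (u[j] > 1.0) u[j] = 1.0;
      n[j] = nn[j];
    }
    if (!(std::isfinite(u[0]) && std::isfinite(u[1]) && std::isfinite(u[2])))
      stop("non-finite unit activity: integration unstable, reduce dt");
    const int k = i + 1;
    if (percept) percept[k] = percept_of(u);
    if (U) {
      for (int j = 0; j < 3; ++j) {
        U[j * T + k] = u[j];
        A_[j * T + k] = a[j];
        Nz[j * T + k] = n[j];
      }
    }
  }
}

NetParams unpack_params(const List& params) {
  NetParams p;
  p.beta_i = as<double>(params["beta_i"]);
  p.alpha = as<double>(params["alpha"]);
  p.g = as<double>(params["g"]);
  p.tau_u = as<double>(params["tau_u"]);
  p.tau_a = as<double>(params["tau_a"]);
  p.gamma = as<double>(params["gamma"]);
  p.tau_n = as<double>(params["tau_n"]);
  p.slope = as<double>(params["gain_slope"]);
  p.thr = as<double>(params["gain_threshold"]);
  p.dt = as<double>(params["dt"]);
  return p;
}

void derive_unit_seeds(uint64_t master, double trial_offset, int trial,
                       uint64_t out[3]) {
  uint64_t key = master +
      0x9E3779B97F4A7C15ULL *
          static_cast<uint64_t>(static_cast<int64_t>(trial_offset) + trial + 1);
  uint64_t st = key;
  uint64_t tseed = splitmix64(st);
  for (int j = 0; j < 3; ++j) {
    uint64_t s2 = tseed + static_cast<uint64_t>(j + 1) * 0xD1B54A32D192ED03ULL;
    out[j] = splitmix64(s2);
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP sim_trials_cpp(NumericMatrix I, List params, int n_trials,
                    double master_seed, double trial_offset,
                    std::string mode, int win_start, int win_end,
                    Nullable<NumericVector> unit_seeds = R_NilValue) {
  const int T = I.nrow();
  if (I.ncol() != 3) stop("current matrix must have 3 columns (A, B, AB)");
  if (T < 2) stop("need at least two time samples");
  NetParams p = unpack_params(params);
  if (!(p.tau_a > p.tau_u && p.tau_u > 0)) stop("require tau_a > tau_u > 0");
  const double* IA = &I(0, 0);
  const double* IB = &I(0, 1);
  const double* IAB = &I(0, 2);
  const uint64_t master = static_cast<uint64_t>(static_cast<int64_t>(master_seed));

  uint64_t useeds[3];
  bool override_seeds = unit_seeds.isNotNull();
  NumericVector us;
  if (override_seeds) {
    us = unit_seeds.get();
    if (us.size() != 3) stop("unit_seeds must have length 3");
    for (int j = 0; j < 3; ++j)
      useeds[j] = static_cast<uint64_t>(static_cast<int64_t>(us[j]));
  }

  if (mode == "trace") {
    if (n_trials != 1) stop("trace mode runs a single trial");
    if (!override_seeds) derive_unit_seeds(master, trial_offset, 0, useeds);
    NumericMatrix U(T, 3), A_(T, 3), Nz(T, 3);
    IntegerVector percept(T);
    run_trial(IA, IB, IAB, T, p, useeds, INTEGER(percept),
              U.begin(), A_.begin(), Nz.begin());
    return List::create(_["u"] = U, _["a"] = A_, _["n"] = Nz,
                        _["segregated"] = percept);
  }

  if (mode == "percept") {
    IntegerMatrix P(T, n_trials);
    for (int k = 0; k < n_trials; ++k) {
      if (!override_seeds) derive_unit_seeds(master, trial_offset, k, useeds);
      run_trial(IA, IB, IAB, T, p, useeds, &P(0, k), nullptr, nullptr, nullptr);
      if (k % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return P;
  }

  if (mode == "classify") {
    // win_start/win_end: 1-based sample indices, window [win_start, win_end)
    if (win_start < 1 || win_end <= win_start || win_end > T + 1)
      stop("invalid classification window");
    IntegerVector cls(n_trials);
    std::vector<int> percept(T);
    const int w0 = win_start - 1, w1 = win_end - 1;
    for (int k = 0; k < n_trials; ++k) {
      if (!override_seeds) derive_unit_seeds(master, trial_offset, k, useeds);
      run_trial(IA, IB, IAB, T, p, useeds, percept.data(),
                nullptr, nullptr, nullptr);
      int nseg = 0;
      for (int i = w0; i < w1; ++i) nseg += percept[i];
      cls[k] = (2 * nseg >= (w1 - w0)) ? 1 : 0;  // majority; ties segregated
      if (k % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return cls;
  }

  stop("unknown mode: " + mode);
}
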