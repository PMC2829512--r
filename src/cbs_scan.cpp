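// Circular-binary-segmentation arc scan.
//
// For a series x[1..n], find the contiguous arc [i..j] (1 <= length <= n-1)
// maximising the two-sample t-statistic (pooled variance) between the arc
// and its complement; every circular arc or its complement is contiguous, so
// scanning contiguous arcs covers the circle.
//
// With S the arc sum, m the arc length and m2 = n - m, the pooled
// within-group sum of squares is
//   SSW = sum(x^2) - S^2/m - (T-S)^2/m2 = V - a^2 * n/(m*m2),
// where a = S - m*T/n is the centred arc sum and V = sum(x^2) - T^2/n.
// Hence t^2 = (n-2) * U / (V - U) with U = a^2 * n/(m*m2): t^2 is monotone
// in a^2/(m*m2), so for each width only the extreme centred arc sums need
// be evaluated, and permutations (which leave V unchanged) compare U alone.
// The permutation test uses an internal deterministic RNG so segmentation
// never touches R's RNG state.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// centred prefix sums C[0..n]; C[j] = sum(x[1..j]) - j*T/n
void centred_prefix(const double* x, int n, double T, double* C) {
  const double mu = T / n;
  C[0] = 0.0;
  for (int j = 1; j <= n; ++j) C[j] = C[j - 1] + x[j - 1] - mu;
}

struct ArcBest {
  double u;   // a^2 * inv[m] * inv[m2] at the best arc (to scale by n)
  double a;   // centred arc sum there (its sign is the sign of the t)
  int i, j;
};

// full scan; when track_arg is false only the maximal u is needed
ArcBest scan(const double* C, int n, const double* inv, bool track_arg) {
  ArcBest best = {-1.0, 0.0, 0, 0};
  for (int m = 1; m <= n - 1; ++m) {
    const int m2 = n - m;
    double amax = -DBL_MAX, amin = DBL_MAX;
    int imax = 0, imin = 0;
    for (int i = 1; i <= n - m + 1; ++i) {
      const double a = C[i + m - 1] - C[i - 1];
      if (a > amax) { amax = a; imax = i; }
      if (a < amin) { amin = a; imin = i; }
    }
    const double w = inv[m] * inv[m2];
    // evaluate the two extremes; tie-break towards smallest (i, j)
    double cand_a[2] = {amax, amin};
    int cand_i[2] = {imax, imin};
    for (int k = 0; k < 2; ++k) {
      const double u = cand_a[k] * cand_a[k] * w;
      const int ci = cand_i[k], cj = cand_i[k] + m - 1;
      bool better = u > best.u;
      if (track_arg && u == best.u && best.i > 0)
        better = (ci < best.i) || (ci == best.i && cj < best.j);
      if (better) { best.u = u; best.a = cand_a[k]; best.i = ci; best.j = cj; }
    }
  }
  return best;
}

// splitmix64 -> xorshift128+ deterministic RNG
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9e3779b97f4a7c15ULL);
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
  }
  uint64_t next() {
    uint64_t x = s0; const uint64_t y = s1;
    s0 = y; x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  uint64_t bounded(uint64_t bound) {
    const uint64_t threshold = (~bound + 1) % bound;
    for (;;) { uint64_t r = next(); if (r >= threshold) return r % bound; }
  }
};

double t_from_u(double u_scaled, double V, int n) {
  // u_scaled = a^2 * n/(m*m2); perfect two-level fits exhaust V
  if (u_scaled >= V * (1.0 - 1e-12)) return R_PosInf;
  return std::sqrt((n - 2) * u_scaled / (V - u_scaled));
}

}  // namespace

// [[Rcpp::export(name = ".arc_max_t_cpp")]]
List arc_max_t_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 4) stop("series length must be >= 4");
  double T = 0.0, QT = 0.0;
  for (int k = 0; k < n; ++k) { T += x[k]; QT += x[k] * x[k]; }
  const double V = QT - T * T / n;
  if (V <= 1e-12 * std::max(1.0, QT))
    return List::create(_["start"] = 0, _["end"] = 0, _["t"] = 0.0,
                        _["flag_zero_variance"] = true);
  std::vector<double> inv(n + 1), C(n + 1);
  for (int m = 1; m <= n; ++m) inv[m] = 1.0 / m;
  centred_prefix(REAL(x), n, T, C.data());
  ArcBest b = scan(C.data(), n, inv.data(), true);
  const double t = t_from_u(b.u * n, V, n);
  const double sgn = (b.a > 0) - (b.a < 0);
  return List::create(_["start"] = b.i, _["end"] = b.j, _["t"] = sgn * t,
                      _["flag_zero_variance"] = false);
}

// [[Rcpp::export(name = ".arc_perm_test_cpp")]]
List arc_perm_test_cpp(NumericVector x, double t_obs_abs, int nperm,
                       double alpha, double seed) {
  const int n = x.size();
  if (n < 4) stop("series length must be >= 4");
  double T = 0.0, QT = 0.0;
  for (int k = 0; k < n; ++k) { T += x[k]; QT += x[k] * x[k]; }
  const double V = QT - T * T / n;  // permutation-invariant
  std::vector<double> inv(n + 1), C(n + 1);
  for (int m = 1; m <= n; ++m) inv[m] = 1.0 / m;
  std::vector<double> xp(REAL(x), REAL(x) + n);
  Rng rng(static_cast<uint64_t>(seed));

  // invert t_obs to the U scale (monotone): U_obs = V * t^2 / (n-2+t^2)
  double u_obs;
  if (t_obs_abs == R_PosInf) u_obs = V;
  else {
    const double t2 = t_obs_abs * t_obs_abs;
    u_obs = V * t2 / ((n - 2) + t2);
  }
  const int stop_count = static_cast<int>(std::floor(alpha * nperm));
  int exceed = 0, used = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int r = static_cast<int>(rng.bounded(static_cast<uint64_t>(k + 1)));
      std::swap(xp[k], xp[r]);
    }
    centred_prefix(xp.data(), n, T, C.data());
    ArcBest b = scan(C.data(), n, inv.data(), false);
    ++used;
    if (b.u * n >= u_obs * (1.0 - 1e-12)) ++exceed;
    if (exceed > stop_count) break;  // p-value already forced above alpha
  }
  return List::create(_["exceed"] = exceed, _["used"] = used,
                      _["significant"] = (exceed <= stop_count && used == nperm));
}
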