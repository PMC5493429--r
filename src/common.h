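#ifndef IKURSIM_COMMON_H
#define IKURSIM_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Voltage lookup table: all purely voltage-dependent factors of a cell model
// (steady-state gates, Rush-Larsen exponentials for a fixed dt, rectification
// and GHK driving-force factors) are tabulated once per (parameter set, dt)
// on a uniform grid and linearly interpolated during stepping.  Layout is
// [bin][table] so one membrane-voltage lookup touches a contiguous block.
struct Lut {
  double vmin, vmax, dv, inv_dv;
  int n, k;                 // n bins, k tables per bin
  std::vector<double> data; // (n+1) * k values

  void init(double vmin_, double vmax_, double dv_, int k_) {
    vmin = vmin_; vmax = vmax_; dv = dv_; inv_dv = 1.0 / dv_;
    n = (int)std::floor((vmax_ - vmin_) / dv_) + 1;
    k = k_;
    data.assign((size_t)(n + 1) * k, 0.0);
  }
  double* row(int i) { return data.data() + (size_t)i * k; }
  const double* row(int i) const { return data.data() + (size_t)i * k; }

  // interpolate all k tables at voltage v into out[]
  inline void lookup(double v, double* out) const {
    double u = (v - vmin) * inv_dv;
    if (u < 0) u = 0;
    if (u > n - 1) u = n - 1;
    int i0 = (int)u;
    double w = u - i0;
    const double* a = row(i0);
    const double* b = row(i0 + 1);
    for (int j = 0; j < k; ++j) out[j] = a[j] + w * (b[j] - a[j]);
  }
};

// guard against removable singularities of the form x/(1-exp(-x/s))
inline double safe_ratio(double num, double den) {
  if (std::fabs(den) < 1e-12) den = (den >= 0 ? 1e-12 : -1e-12);
  return num / den;
}

inline double rl_step(double y, double yinf, double e) {
  // Rush-Larsen: y <- yinf + (y - yinf) * exp(-dt/tau), e = exp(-dt/tau)
  return yinf + (y - yinf) * e;
}

#endif
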