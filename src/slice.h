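#pragma once

#include <cmath>
#include <functional>
#include <R.h>
#include <Rmath.h>

// Univariate slice sampler (Neal 2003): stepping out + shrinkage.
// g returns the log target (up to a constant); g0 = g(x0) must be finite.
// Caller is responsible for holding the R RNG state (RNGScope).
inline double slice_sample(double x0, double g0,
                           const std::function<double(double)> &g,
                           double w, int m) {
  const double logy = g0 - exp_rand();
  double u = unif_rand() * w;
  double L = x0 - u;
  double Rr = x0 + (w - u);
  int j = (int)std::floor(unif_rand() * m);
  int k = m - 1 - j;
  while (j > 0 && g(L) > logy) {
    L -= w;
    --j;
  }
  while (k > 0 && g(Rr) > logy) {
    Rr += w;
    --k;
  }
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + unif_rand() * (Rr - L);
    if (g(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;  // pathological shrinkage; keep current point
}
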