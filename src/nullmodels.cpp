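#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG so set.seed() governs draws.
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Repair step of the count quasiswap: starting from a matrix with the
// target row and column sums (a Patefield draw), perform random 2x2
// one-unit diagonal shifts that move the number of nonzero cells (fill)
// toward the target without overshooting it. Moves preserve all margins
// by construction. Fill-neutral moves are also accepted to keep mixing.
// [[Rcpp::export]]
IntegerMatrix quasiswap_count_repair(IntegerMatrix x, int target_fill,
                                     int max_trials) {
  IntegerMatrix m = clone(x);
  int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  int fill = 0;
  for (int i = 0; i < nr * nc; ++i) if (m[i] > 0) ++fill;
  int need = fill - target_fill; // >0: reduce fill, <0: increase
  long trials = 0;
  while (fill != target_fill && trials < (long)max_trials) {
    ++trials;
    int i1 = runif_int(nr), i2 = runif_int(nr - 1);
    if (i2 >= i1) ++i2;
    int j1 = runif_int(nc), j2 = runif_int(nc - 1);
    if (j2 >= j1) ++j2;
    int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    // candidate 1: a-1, b+1, c+1, d-1 ; candidate 2: the reverse
    int d1 = -999, d2 = -999;
    if (a > 0 && d > 0)
      d1 = (a == 1 ? -1 : 0) + (d == 1 ? -1 : 0) +
           (b == 0 ? 1 : 0) + (c == 0 ? 1 : 0);
    if (b > 0 && c > 0)
      d2 = (b == 1 ? -1 : 0) + (c == 1 ? -1 : 0) +
           (a == 0 ? 1 : 0) + (d == 0 ? 1 : 0);
    need = fill - target_fill;
    bool ok1 = d1 != -999, ok2 = d2 != -999;
    if (need > 0) { // want fill down, never below target
      ok1 = ok1 && d1 <= 0 && fill + d1 >= target_fill;
      ok2 = ok2 && d2 <= 0 && fill + d2 >= target_fill;
    } else {        // want fill up, never above target
      ok1 = ok1 && d1 >= 0 && fill + d1 <= target_fill;
      ok2 = ok2 && d2 >= 0 && fill + d2 <= target_fill;
    }
    int pick = 0;
    if (ok1 && ok2) pick = (unif_rand() < 0.5) ? 1 : 2;
    else if (ok1) pick = 1;
    else if (ok2) pick = 2;
    if (pick == 1) {
      m(i1, j1) = a - 1; m(i1, j2) = b + 1;
      m(i2, j1) = c + 1; m(i2, j2) = d - 1;
      fill += d1;
    } else if (pick == 2) {
      m(i1, j2) = b - 1; m(i1, j1) = a + 1;
      m(i2, j2) = d + 1; m(i2, j1) = c - 1;
      fill += d2;
    }
  }
  m.attr("fill_restored") = (fill == target_fill);
  return m;
}

// Sequential trial-swap chain on a binary incidence matrix: pick a random
// 2x2 submatrix and, when it is a checkerboard, swap its diagonal. Row and
// column sums are invariant; the chain's stationary distribution is uniform
// over fixed-margin binary matrices (symmetric proposal). The matrix is
// modified in place across calls by cloning once per call.
// [[Rcpp::export]]
IntegerMatrix trialswap_binary(IntegerMatrix x, int n_steps) {
  IntegerMatrix m = clone(x);
  int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  for (int s = 0; s < n_steps; ++s) {
    int i1 = runif_int(nr), i2 = runif_int(nr - 1);
    if (i2 >= i1) ++i2;
    int j1 = runif_int(nc), j2 = runif_int(nc - 1);
    if (j2 >= j1) ++j2;
    int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      m(i1, j1) = 0; m(i2, j2) = 0; m(i1, j2) = 1; m(i2, j1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      m(i1, j1) = 1; m(i2, j2) = 1; m(i1, j2) = 0; m(i2, j1) = 0;
    }
  }
  return m;
}

// Fill-preserving mixing phase run after fill restoration: random 2x2
// one-unit diagonal shifts accepted only when they leave the fill
// unchanged. Symmetric proposal + hard constraint => reversible chain,
// uniform over the reachable fixed-margin fixed-fill matrices.
// [[Rcpp::export]]
IntegerMatrix quasiswap_count_mix(IntegerMatrix x, int n_steps) {
  IntegerMatrix m = clone(x);
  int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  for (int s = 0; s < n_steps; ++s) {
    int i1 = (int)(unif_rand() * nr); if (i1 >= nr) i1 = nr - 1;
    int i2 = (int)(unif_rand() * (nr - 1)); if (i2 >= nr - 1) i2 = nr - 2;
    if (i2 >= i1) ++i2;
    int j1 = (int)(unif_rand() * nc); if (j1 >= nc) j1 = nc - 1;
    int j2 = (int)(unif_rand() * (nc - 1)); if (j2 >= nc - 1) j2 = nc - 2;
    if (j2 >= j1) ++j2;
    int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    int d1 = -999, d2 = -999;
    if (a > 0 && d > 0)
      d1 = (a == 1 ? -1 : 0) + (d == 1 ? -1 : 0) +
           (b == 0 ? 1 : 0) + (c == 0 ? 1 : 0);
    if (b > 0 && c > 0)
      d2 = (b == 1 ? -1 : 0) + (c == 1 ? -1 : 0) +
           (a == 0 ? 1 : 0) + (d == 0 ? 1 : 0);
    bool ok1 = (d1 == 0), ok2 = (d2 == 0);
    int pick = 0;
    if (ok1 && ok2) pick = (unif_rand() < 0.5) ? 1 : 2;
    else if (ok1) pick = 1;
    else if (ok2) pick = 2;
    if (pick == 1) {
      m(i1, j1) = a - 1; m(i1, j2) = b + 1;
      m(i2, j1) = c + 1; m(i2, j2) = d - 1;
    } else if (pick == 2) {
      m(i1, j2) = b - 1; m(i1, j1) = a + 1;
      m(i2, j2) = d + 1; m(i2, j1) = c - 1;
    }
  }
  return m;
}
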