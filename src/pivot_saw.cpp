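// Pivot-algorithm sampler for self-avoiding walks on the square / simple
// cubic lattice.  A pivot attempt picks an interior site and a random lattice
// symmetry (axis permutation + sign flips), applies it to the shorter arm of
// the walk and accepts if the result is self-avoiding.  Squared end-to-end
// distances are recorded every `thin` accepted pivots after thermalisation.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include "xrng.h"
using namespace Rcpp;

struct Site { int c[3]; };

static inline int64_t encode(const Site &p, int span) {
  // span: coordinates guaranteed within [-span, span]
  int64_t w = 2 * (int64_t)span + 1;
  return ((int64_t)p.c[0] + span) +
         w * (((int64_t)p.c[1] + span) + w * ((int64_t)p.c[2] + span));
}

// apply symmetry: permutation perm of axes then sign flips
static inline Site apply_sym(const Site &p, const int *perm, const int *sgn,
                             int dim) {
  Site q;
  q.c[0] = q.c[1] = q.c[2] = 0;
  for (int d = 0; d < dim; ++d) q.c[d] = sgn[d] * p.c[perm[d]];
  return q;
}

// [[Rcpp::export(name = ".cpp_saw_pivot_r2")]]
List cpp_saw_pivot_r2(int n_steps, int n_samples, int dim, int thin,
                      int n_therm, double seed, int max_attempt_factor) {
  if (dim != 2 && dim != 3) stop("dim must be 2 or 3");
  if (n_steps < 2) stop("n_steps must be >= 2");
  const int N = n_steps;            // walk has N+1 sites
  const int span = N + 1;
  XRng rng((uint64_t)seed);

  std::vector<Site> walk(N + 1), prop(N + 1);
  for (int i = 0; i <= N; ++i) { // straight rod start
    walk[i].c[0] = i; walk[i].c[1] = 0; walk[i].c[2] = 0;
  }

  const int perms2[2][2] = {{0, 1}, {1, 0}};
  const int perms3[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

  std::unordered_set<int64_t> occ;
  occ.reserve((size_t)(2 * N));

  long long accepted = 0, attempts = 0;
  long long target_accept = (long long)n_therm + (long long)thin * n_samples;
  long long max_attempts =
      (long long)max_attempt_factor * (target_accept + 100);
  int collected = 0;
  double sum_r2 = 0.0, sum_r4 = 0.0;
  NumericVector r2s(n_samples);

  while (collected < n_samples) {
    if (++attempts > max_attempts)
      stop("pivot acceptance collapsed: %lld accepts in %lld attempts",
           accepted, attempts);
    int p = 1 + (int)(rng.unif() * (N - 1)); // pivot site index in [1, N-1]
    int perm[3] = {0, 1, 2}, sgn[3] = {1, 1, 1};
    if (dim == 2) {
      int pi = (int)(rng.unif() * 2.0);
      perm[0] = perms2[pi][0]; perm[1] = perms2[pi][1];
      sgn[0] = (rng.unif() < 0.5) ? 1 : -1;
      sgn[1] = (rng.unif() < 0.5) ? 1 : -1;
    } else {
      int pi = (int)(rng.unif() * 6.0);
      for (int d = 0; d < 3; ++d) perm[d] = perms3[pi][d];
      for (int d = 0; d < 3; ++d) sgn[d] = (rng.unif() < 0.5) ? 1 : -1;
    }
    // transform the shorter arm about the pivot site
    bool tail = (N - p) <= p; // transform sites p+1..N if tail else 0..p-1
    occ.clear();
    int lo = tail ? 0 : p, hi = tail ? p : N; // fixed part
    for (int i = lo; i <= hi; ++i) occ.insert(encode(walk[i], span));
    bool ok = true;
    if (tail) {
      for (int i = p + 1; i <= N && ok; ++i) {
        Site rel; for (int d = 0; d < 3; ++d) rel.c[d] = walk[i].c[d] - walk[p].c[d];
        Site q = apply_sym(rel, perm, sgn, dim);
        for (int d = 0; d < 3; ++d) q.c[d] += walk[p].c[d];
        prop[i] = q;
        ok = occ.insert(encode(q, span)).second;
      }
      if (ok) for (int i = p + 1; i <= N; ++i) walk[i] = prop[i];
    } else {
      for (int i = p - 1; i >= 0 && ok; --i) {
        Site rel; for (int d = 0; d < 3; ++d) rel.c[d] = walk[i].c[d] - walk[p].c[d];
        Site q = apply_sym(rel, perm, sgn, dim);
        for (int d = 0; d < 3; ++d) q.c[d] += walk[p].c[d];
        prop[i] = q;
        ok = occ.insert(encode(q, span)).second;
      }
      if (ok) for (int i = 0; i < p; ++i) walk[i] = prop[i];
    }
    if (!ok) continue;
    ++accepted;
    if (accepted > n_therm && (accepted - n_therm) % thin == 0) {
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dx = (double)(walk[N].c[d] - walk[0].c[d]);
        r2 += dx * dx;
      }
      r2s[collected++] = r2;
      sum_r2 += r2; sum_r4 += r2 * r2;
    }
  }
  double mean = sum_r2 / n_samples;
  double var = sum_r4 / n_samples - mean * mean;
  return List::create(_["mean_r2"] = mean,
                      _["se_naive"] = std::sqrt(var / n_samples),
                      _["n_samples"] = n_samples,
                      _["acceptance"] = (double)accepted / (double)attempts,
                      _["r2"] = r2s);
}
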