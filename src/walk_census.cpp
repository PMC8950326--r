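// Exact census of 1-D +/-1 random walks that start at the origin and never
// go below it (the wall-tethered ideal-chain substrate for the partition
// exponent).  Counts overflow doubles long before m = 4096, so the dynamic
// programme accumulates arbitrary-precision integers: a minimal little-endian
// base-2^32 representation supporting only addition, which is all the DP
// needs.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <string>
#include <cmath>
using namespace Rcpp;

typedef std::vector<uint32_t> BigInt; // little-endian limbs, base 2^32

static void big_add(BigInt &a, const BigInt &b) { // a += b
  size_t n = a.size() > b.size() ? a.size() : b.size();
  a.resize(n, 0u);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = (uint64_t)a[i] + (i < b.size() ? (uint64_t)b[i] : 0u) + carry;
    a[i] = (uint32_t)(s & 0xffffffffULL);
    carry = s >> 32;
  }
  if (carry) a.push_back((uint32_t)carry);
}

static double big_log2(const BigInt &a) {
  int top = (int)a.size() - 1;
  while (top > 0 && a[top] == 0u) --top;
  // combine up to three top limbs for ~96 significant bits
  double mant = 0.0;
  int used = 0;
  for (int i = top; i >= 0 && used < 3; --i, ++used)
    mant = mant * 4294967296.0 + (double)a[i];
  int skipped = top + 1 - used;
  return std::log2(mant) + 32.0 * (double)skipped;
}

// decimal string via repeated division by 1e9
static std::string big_decimal(BigInt a) {
  std::string out;
  bool zero = true;
  for (uint32_t limb : a) if (limb) { zero = false; break; }
  if (zero) return "0";
  std::vector<uint32_t> chunks;
  while (true) {
    bool nonzero = false;
    uint64_t rem = 0;
    for (int i = (int)a.size() - 1; i >= 0; --i) {
      uint64_t cur = (rem << 32) | a[i];
      a[i] = (uint32_t)(cur / 1000000000ULL);
      rem = cur % 1000000000ULL;
      if (a[i]) nonzero = true;
    }
    chunks.push_back((uint32_t)rem);
    if (!nonzero) break;
  }
  char buf[16];
  snprintf(buf, sizeof(buf), "%u", chunks.back());
  out = buf;
  for (int i = (int)chunks.size() - 2; i >= 0; --i) {
    snprintf(buf, sizeof(buf), "%09u", chunks[i]);
    out += buf;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_halfspace_walk_count")]]
List cpp_halfspace_walk_count(int m) {
  if (m < 1 || m > 4096) stop("m must be in [1, 4096]");
  // counts[h] = number of walks of the current length ending at height h
  std::vector<BigInt> cur(m + 2), nxt(m + 2);
  cur[0] = BigInt(1, 1u);
  for (int step = 1; step <= m; ++step) {
    int hmax = step;
    for (int h = 0; h <= hmax; ++h) {
      nxt[h].clear();
      if (h > 0 && !cur[h - 1].empty()) big_add(nxt[h], cur[h - 1]);
      if (!cur[h + 1].empty()) big_add(nxt[h], cur[h + 1]);
    }
    for (int h = 0; h <= hmax; ++h) cur[h].swap(nxt[h]);
    for (int h = hmax + 1; h <= m + 1; ++h) cur[h].clear();
  }
  BigInt total;
  for (int h = 0; h <= m; ++h)
    if (!cur[h].empty()) big_add(total, cur[h]);
  double l2 = big_log2(total);
  double as_double = NA_REAL;
  if (l2 <= 52.9) { // fits a double exactly; at most two limbs occupied
    as_double = 0.0;
    for (int i = (int)total.size() - 1; i >= 0; --i)
      as_double = as_double * 4294967296.0 + (double)total[i];
  }
  return List::create(_["count_string"] = big_decimal(total),
                      _["log2_count"] = l2,
                      _["log_count"] = l2 * M_LN2,
                      _["count"] = as_double);
}
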