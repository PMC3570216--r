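// Bit-vector backend for strand cross-correlation.
//
// Profiles and mappability masks are packed into 64-bit words; for each
// shift d the four per-shift sufficient statistics
//   n_d   = sum_b m(b) * mg(b + d)        (doubly-mappable count)
//   sf_d  = sum_b [f*m](b) * mg(b + d)    (+ origins inside DM_d)
//   sg_d  = sum_b m(b) * [g*mg](b + d)    (- origins at DM_d + d)
//   sfg_d = sum_b [f*m](b) * [g*mg](b + d)
// are evaluated with shifted AND + popcount. Zero padding past the
// chromosome end enforces the b + d <= B - 1 clip automatically; the naive
// correlation uses all-ones masks, turning n_d into the overlap window
// length B - d.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static std::vector<uint64_t> pack_bits(const LogicalVector& x) {
  const R_xlen_t n = x.size();
  std::vector<uint64_t> w(static_cast<size_t>(n / 64) + 2, 0ULL);
  for (R_xlen_t i = 0; i < n; ++i)
    if (x[i] == TRUE) w[i >> 6] |= (1ULL << (i & 63));
  return w;
}

// sum over b of a(b) & bvec(b + d)
static double shifted_and_popcount(const std::vector<uint64_t>& a,
                                   const std::vector<uint64_t>& bvec,
                                   int d, size_t nw) {
  const size_t q = static_cast<size_t>(d) >> 6;
  const int r = d & 63;
  double total = 0.0;
  const size_t nb = bvec.size();
  for (size_t i = 0; i < nw; ++i) {
    if (a[i] == 0ULL) continue;
    uint64_t lo = (q + i < nb) ? bvec[q + i] : 0ULL;
    uint64_t sh;
    if (r == 0) {
      sh = lo;
    } else {
      uint64_t hi = (q + i + 1 < nb) ? bvec[q + i + 1] : 0ULL;
      sh = (lo >> r) | (hi << (64 - r));
    }
    total += static_cast<double>(__builtin_popcountll(a[i] & sh));
  }
  return total;
}

// [[Rcpp::export(name = ".cc_bit_stats")]]
NumericMatrix cc_bit_stats(LogicalVector f, LogicalVector g,
                           LogicalVector m, LogicalVector mg,
                           int d_min, int d_max) {
  const R_xlen_t B = f.size();
  if (g.size() != B || m.size() != B || mg.size() != B)
    stop("profile and mask vectors must share length");
  if (d_min < 0 || d_max < d_min) stop("invalid shift range");
  std::vector<uint64_t> mw = pack_bits(m);
  std::vector<uint64_t> mgw = pack_bits(mg);
  std::vector<uint64_t> fm = pack_bits(f);
  std::vector<uint64_t> gmg = pack_bits(g);
  const size_t nw = mw.size() - 1;  // last word is zero padding
  for (size_t i = 0; i < mw.size(); ++i) {
    fm[i] &= mw[i];
    gmg[i] &= mgw[i];
  }
  const int nd = d_max - d_min + 1;
  NumericMatrix out(nd, 4);
  colnames(out) = CharacterVector::create("n", "sf", "sg", "sfg");
  for (int j = 0; j < nd; ++j) {
    const int d = d_min + j;
    if (d >= B) { out(j, 0) = 0; continue; }
    out(j, 0) = shifted_and_popcount(mw, mgw, d, nw);
    out(j, 1) = shifted_and_popcount(fm, mgw, d, nw);
    out(j, 2) = shifted_and_popcount(mw, gmg, d, nw);
    out(j, 3) = shifted_and_popcount(fm, gmg, d, nw);
  }
  return out;
}
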