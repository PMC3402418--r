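#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

// Restricted Damerau-Levenshtein (optimal string alignment) between two
// complete strings of integer codes. Rolling three-row DP.
int osa_full(const int* a, int na, const int* b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> r0(nb + 1), r1(nb + 1), r2(nb + 1);
  for (int j = 0; j <= nb; ++j) r1[j] = j;
  for (int i = 1; i <= na; ++i) {
    r2[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(r1[j] + 1, r2[j - 1] + 1), r1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, r0[j - 2] + 1);
      r2[j] = v;
    }
    std::swap(r0, r1);
    std::swap(r1, r2);
  }
  return r1[nb];
}

// Free-end anchored distances for every start position in one pass.
//
// anchored(i) = min over e in {i-1, ..., l} of d(m, z[i..e]) (e = i-1 is the
// empty window, cost n). Running the OSA DP on the reversed strings with a
// free start row (row 0 all zeros) gives, in column c of the last row, the
// minimum distance of rev(m) to any window of rev(z) ending at c — i.e. any
// window of z starting at position l - c + 1. The pure-deletion path bounds
// every column by n, which covers the empty window, and windows longer than
// 2n can never beat it, so no explicit window cap is needed.
void anchored_profile_free(const std::vector<int>& rm, const std::vector<int>& rz,
                           std::vector<int>& r0, std::vector<int>& r1,
                           std::vector<int>& r2) {
  int n = (int)rm.size(), l = (int)rz.size();
  r0.assign(l + 1, 0);
  r1.assign(l + 1, 0);
  r2.assign(l + 1, 0);
  for (int i = 1; i <= n; ++i) {
    r2[0] = i;
    const int mi = rm[i - 1];
    const int mi1 = (i > 1) ? rm[i - 2] : -1;
    for (int c = 1; c <= l; ++c) {
      int cost = (mi == rz[c - 1]) ? 0 : 1;
      int v = std::min(std::min(r1[c] + 1, r2[c - 1] + 1), r1[c - 1] + cost);
      if (i > 1 && c > 1 && mi == rz[c - 2] && mi1 == rz[c - 1])
        v = std::min(v, r0[c - 2] + 1);
      r2[c] = v;
    }
    std::swap(r0, r1);
    std::swap(r1, r2);
  }
  // result lives in r1; anchored(i0, 0-based) = r1[l - i0]
}

inline double affinity_value(int d, int aff, double cap) {
  if (aff == 0) return 1.0 / (1.0 + (double)d);  // inv1p
  return d == 0 ? cap : 1.0 / (double)d;         // invcap
}

// Fixed-length-window variant: window is exactly z[i..i+n-1], truncated at
// the sequence end. Only used behind the `window = "fixed"` config switch.
double profile_sum_fixed(const std::vector<int>& pat, const std::vector<int>& z,
                         int aff, double cap) {
  int n = (int)pat.size(), l = (int)z.size();
  double s = 0.0;
  for (int i = 0; i < l; ++i) {
    int w = std::min(n, l - i);
    s += affinity_value(osa_full(pat.data(), n, z.data() + i, w), aff, cap);
  }
  return s;
}

std::vector<int> as_codes(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// One source sequence, stored reversed, with per-symbol match masks:
// eq[s][c] = 1 iff reversed-sequence symbol at column c equals s (c = 1..l).
struct SourceData {
  int len;
  std::vector<int> fwd;
  std::vector<uint8_t> eqmask;  // K rows of (len + 1)
  const uint8_t* eq(int s) const { return eqmask.data() + (size_t)s * (len + 1); }

  SourceData(std::vector<int> codes, int K) : len((int)codes.size()), fwd(codes) {
    eqmask.assign((size_t)K * (len + 1), 0);
    for (int c = 1; c <= len; ++c) {
      int sym = codes[len - c];  // reversed orientation
      eqmask[(size_t)sym * (len + 1) + c] = 1;
    }
  }
};

// Candidate scorer with per-history memoisation. Histories are encoded as
// base-K integers (h <= 10, K <= 9 fits comfortably in 64 bits).
//
// The hot path is the free-end anchored-distance DP over a whole source.
// It is organised for speed: uint8 rows (distances never exceed n + 1),
// a closed form for row 1, and each further row split into an elementwise
// pass with no intra-row dependence (auto-vectorisable) followed by a
// scalar prefix-min pass carrying the insertion recurrence. The affinity
// transform is applied through a lookup table over the 0..n distance range.
struct QEngine {
  std::vector<SourceData> srcs;
  int K, h, aff, tie;
  double cap;
  bool fixed;
  std::unordered_map<uint64_t, std::vector<double>> cache;
  std::vector<uint8_t> r0, r1, r2, tmp;

  QEngine(const List& sources, int K_, int h_, int aff_, double cap_,
          bool fixed_, int tie_)
      : K(K_), h(h_), aff(aff_), tie(tie_), cap(cap_), fixed(fixed_) {
    for (R_xlen_t s = 0; s < sources.size(); ++s) {
      srcs.emplace_back(as_codes(sources[s]), K);
    }
  }

  // Sum over all start positions of a(anchored distance) for the pattern
  // whose reversed form is rpat, against source sd.
  double profile_sum_free(const std::vector<int>& rpat, const SourceData& sd,
                          const double* atab) {
    int n = (int)rpat.size(), l = sd.len;
    r0.assign(l + 1, 0);
    r1.assign(l + 1, 0);
    // row 1: distance of the single symbol rpat[0] to windows ending at c is
    // 0 on a match and 1 otherwise (empty window or one substitution)
    {
      const uint8_t* e = sd.eq(rpat[0]);
      r1[0] = 1;
      for (int c = 1; c <= l; ++c) r1[c] = (uint8_t)(1 - e[c]);
    }
    if (n > 1) {
      r2.assign(l + 1, 0);
      tmp.assign(l + 1, 0);
      for (int i = 2; i <= n; ++i) {
        const uint8_t* e_mi = sd.eq(rpat[i - 1]);
        const uint8_t* e_mi1 = sd.eq(rpat[i - 2]);
        const uint8_t* p1 = r1.data();
        const uint8_t* p0 = r0.data();
        uint8_t* pt = tmp.data();
        // elementwise pass: deletion, substitution/match, transposition
        pt[1] = (uint8_t)std::min<int>(p1[1] + 1, p1[0] + 1 - e_mi[1]);
        for (int c = 2; c <= l; ++c) {
          uint8_t v = (uint8_t)std::min<int>(p1[c] + 1, p1[c - 1] + 1 - e_mi[c]);
          uint8_t t = (uint8_t)(e_mi[c - 1] & e_mi1[c]);
          uint8_t tv = (uint8_t)(p0[c - 2] + 1);
          v = (t && tv < v) ? tv : v;
          pt[c] = v;
        }
        // prefix-min pass: insertion recurrence r2[c] = min(tmp[c], r2[c-1]+1)
        uint8_t run = (uint8_t)i;
        r2[0] = run;
        uint8_t* p2 = r2.data();
        for (int c = 1; c <= l; ++c) {
          uint8_t x = pt[c];
          uint8_t rn = (uint8_t)(run + 1);
          run = (x < rn) ? x : rn;
          p2[c] = run;
        }
        std::swap(r0, r1);
        std::swap(r1, r2);
      }
    }
    double s = 0.0;
    const uint8_t* p1 = r1.data();
    for (int c = 1; c <= l; ++c) s += atab[p1[c]];
    return s;
  }

  const std::vector<double>& q(const int* hist) {
    uint64_t key = 0;
    for (int t = 0; t < h; ++t) key = key * (uint64_t)K + (uint64_t)hist[t];
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;

    int n = h + 1;
    double atab[16];
    for (int d = 0; d <= n + 1; ++d) atab[d] = affinity_value(d, aff, cap);
    std::vector<double> qv(K, 0.0);
    std::vector<int> rpat(n), pat(n);
    for (int t = 0; t < h; ++t) {
      rpat[n - 1 - t] = hist[t];
      pat[t] = hist[t];
    }
    for (int j = 0; j < K; ++j) {
      rpat[0] = j;
      pat[n - 1] = j;
      double acc = 0.0;
      for (size_t s = 0; s < srcs.size(); ++s) {
        double sum = fixed ? profile_sum_fixed(pat, srcs[s].fwd, aff, cap)
                           : profile_sum_free(rpat, srcs[s], atab);
        acc += sum / (double)srcs[s].len;
      }
      qv[j] = acc / (double)srcs.size();
    }
    return cache.emplace(key, std::move(qv)).first->second;
  }

  int pick(const std::vector<double>& qv) {
    double best = qv[0];
    int arg = 0, nbest = 1;
    for (int j = 1; j < K; ++j) {
      if (qv[j] > best) {
        best = qv[j];
        arg = j;
        nbest = 1;
      } else if (qv[j] == best) {
        ++nbest;
      }
    }
    if (tie == 0 || nbest == 1) return arg;  // lowest symbol wins
    int wanted = (int)std::floor(unif_rand() * nbest);
    if (wanted >= nbest) wanted = nbest - 1;
    for (int j = 0; j < K; ++j) {
      if (qv[j] == best && wanted-- == 0) return j;
    }
    return arg;  // unreachable
  }
};

}  // namespace

// [[Rcpp::export]]
int cpp_osa(IntegerVector a, IntegerVector b) {
  std::vector<int> va = as_codes(a), vb = as_codes(b);
  return osa_full(va.data(), (int)va.size(), vb.data(), (int)vb.size());
}

// [[Rcpp::export]]
IntegerVector cpp_anchored_profile(IntegerVector m, IntegerVector z, bool fixed) {
  std::vector<int> vm = as_codes(m), vz = as_codes(z);
  int n = (int)vm.size(), l = (int)vz.size();
  IntegerVector out(l);
  if (!fixed) {
    std::vector<int> rm(vm.rbegin(), vm.rend()), rz(vz.rbegin(), vz.rend());
    std::vector<int> b0, b1, b2;
    anchored_profile_free(rm, rz, b0, b1, b2);
    for (int i = 0; i < l; ++i) out[i] = b1[l - i];
  } else {
    for (int i = 0; i < l; ++i) {
      int w = std::min(n, l - i);
      out[i] = osa_full(vm.data(), n, vz.data() + i, w);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_candidate_q(List sources, IntegerVector history, int K,
                              int aff, double cap, bool fixed) {
  int h = (int)history.size();
  QEngine eng(sources, K, h, aff, cap, fixed, 0);
  std::vector<int> hist = as_codes(history);
  const std::vector<double>& qv = eng.q(hist.data());
  return NumericVector(qv.begin(), qv.end());
}

// [[Rcpp::export]]
List cpp_predict(List sources, IntegerVector target, int h, int K, int aff,
                 double cap, bool fixed, int tie, bool want_q) {
  QEngine eng(sources, K, h, aff, cap, fixed, tie);
  std::vector<int> tgt = as_codes(target);
  int lt = (int)tgt.size(), evaluated = lt - h, hits = 0;
  IntegerVector predicted(evaluated);
  NumericMatrix qmat = want_q ? NumericMatrix(evaluated, K) : NumericMatrix(0, 0);
  for (int k = h; k < lt; ++k) {
    const std::vector<double>& qv = eng.q(tgt.data() + (k - h));
    int jhat = eng.pick(qv);
    predicted[k - h] = jhat;
    if (jhat == tgt[k]) ++hits;
    if (want_q)
      for (int j = 0; j < K; ++j) qmat(k - h, j) = qv[j];
  }
  return List::create(_["hits"] = hits, _["evaluated"] = evaluated,
                      _["predicted"] = predicted,
                      _["q"] = want_q ? (RObject)qmat : (RObject)R_NilValue);
}

// [[Rcpp::export]]
NumericVector cpp_zeta_block(List sources, List targets, int h, int K, int aff,
                             double cap, bool fixed, int tie) {
  QEngine eng(sources, K, h, aff, cap, fixed, tie);
  R_xlen_t nt = targets.size();
  NumericVector out(nt);
  for (R_xlen_t t = 0; t < nt; ++t) {
    std::vector<int> tgt = as_codes(targets[t]);
    int lt = (int)tgt.size(), hits = 0;
    for (int k = h; k < lt; ++k) {
      const std::vector<double>& qv = eng.q(tgt.data() + (k - h));
      if (eng.pick(qv) == tgt[k]) ++hits;
    }
    out[t] = (double)hits / (double)(lt - h);
  }
  return out;
}
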