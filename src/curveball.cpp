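#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Self-contained xoshiro256++ PRNG so that ensembles are bit-reproducible
// from an integer seed, independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform integer in [0, n)
  inline int unif_int(int n) {
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do { x = next(); } while (x >= lim);
    return (int)(x % (uint64_t)n);
  }
};

// One curveball trade: pick two distinct rows, pool the columns held by
// exactly one of them, and reassign that pool uniformly at random while
// keeping each row's share. Row and column sums are invariant.
static inline void curveball_trade(std::vector<uint8_t>& x, int n, int m,
                                   std::vector<int>& diff, Xoshiro& rng) {
  int r1 = rng.unif_int(n);
  int r2 = rng.unif_int(n - 1);
  if (r2 >= r1) ++r2;
  uint8_t* row1 = &x[(size_t)r1 * m];
  uint8_t* row2 = &x[(size_t)r2 * m];
  int nd = 0, k1 = 0;
  for (int j = 0; j < m; ++j) {
    if (row1[j] != row2[j]) {
      diff[nd++] = j;
      k1 += row1[j];
    }
  }
  if (k1 == 0 || k1 == nd) return;  // nothing tradeable
  // partial Fisher-Yates: first k1 entries of diff become row1's columns
  for (int t = 0; t < k1; ++t) {
    int pick = t + rng.unif_int(nd - t);
    int tmp = diff[t]; diff[t] = diff[pick]; diff[pick] = tmp;
  }
  for (int t = 0; t < nd; ++t) {
    row1[diff[t]] = (t < k1) ? 1 : 0;
    row2[diff[t]] = (t < k1) ? 0 : 1;
  }
}

static std::vector<uint8_t> to_bytes(const IntegerMatrix& x) {
  int n = x.nrow(), m = x.ncol();
  std::vector<uint8_t> out((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int v = x(i, j);
      if (v != 0 && v != 1) stop("matrix must be binary (0/1)");
      out[(size_t)i * m + j] = (uint8_t)v;
    }
  return out;
}

static IntegerMatrix from_bytes(const std::vector<uint8_t>& x, int n, int m) {
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = x[(size_t)i * m + j];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_curveball(IntegerMatrix x, int steps, double seed) {
  int n = x.nrow(), m = x.ncol();
  std::vector<uint8_t> b = to_bytes(x);
  std::vector<int> diff(m);
  Xoshiro rng((uint64_t)seed);
  for (int s = 0; s < steps; ++s) curveball_trade(b, n, m, diff, rng);
  return from_bytes(b, n, m);
}

// Pack current state into per-column bitsets for fast pairwise popcounts.
static inline void pack_columns(const std::vector<uint8_t>& x, int n, int m,
                                int words, std::vector<uint64_t>& packed) {
  std::fill(packed.begin(), packed.end(), 0ULL);
  for (int i = 0; i < n; ++i) {
    const uint8_t* row = &x[(size_t)i * m];
    int w = i >> 6;
    uint64_t bit = 1ULL << (i & 63);
    for (int j = 0; j < m; ++j)
      if (row[j]) packed[(size_t)j * words + w] |= bit;
  }
}

#if defined(__GNUC__) || defined(__clang__)
static inline int popcount64(uint64_t v) { return __builtin_popcountll(v); }
#else
static inline int popcount64(uint64_t v) {
  int c = 0;
  while (v) { v &= v - 1; ++c; }
  return c;
}
#endif

// Streaming fixed-fixed randomization: run one curveball chain, and at each
// of M saved states compute per-pair raw C = (Ri-S)(Rj-S) and
// T = S(N+S-Ri-Rj).  Margins are invariant along the chain, so per-pair
// normalizers are precomputed once.  Tail counts compare integer raw scores
// (exactly equivalent to comparing standardized scores, which share the
// fixed normalizer).
// [[Rcpp::export]]
List cpp_cb_stream(IntegerMatrix x, IntegerMatrix pairs, int M, int burn_in,
                   int thin, double seed, bool product_norm,
                   bool return_scores) {
  int n = x.nrow(), m = x.ncol(), P = pairs.nrow();
  if (thin < 1) stop("thin must be >= 1");
  std::vector<uint8_t> b = to_bytes(x);
  std::vector<int> diff(m);
  Xoshiro rng((uint64_t)seed);

  // column margins (invariant)
  std::vector<int> colsum(m, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) colsum[j] += b[(size_t)i * m + j];

  std::vector<int> pi(P), pj(P), Ri(P), Rj(P);
  std::vector<double> cmax(P), tmax(P);
  for (int p = 0; p < P; ++p) {
    pi[p] = pairs(p, 0); pj[p] = pairs(p, 1);
    if (pi[p] < 0 || pi[p] >= m || pj[p] < 0 || pj[p] >= m || pi[p] == pj[p])
      stop("invalid pair indices");
    Ri[p] = colsum[pi[p]]; Rj[p] = colsum[pj[p]];
    int smin = Ri[p] + Rj[p] - n; if (smin < 0) smin = 0;
    int smax = Ri[p] < Rj[p] ? Ri[p] : Rj[p];
    if (product_norm) {
      cmax[p] = (double)Ri[p] * Rj[p];
      tmax[p] = (double)Ri[p] * Rj[p];
    } else {
      cmax[p] = (double)(Ri[p] - smin) * (Rj[p] - smin);
      tmax[p] = (double)smax * (n + smax - Ri[p] - Rj[p]);
    }
  }

  int words = (n + 63) / 64;
  std::vector<uint64_t> packed((size_t)m * words);

  // observed scores
  pack_columns(b, n, m, words, packed);
  std::vector<long long> obsC(P), obsT(P);
  NumericVector obsCstd(P), obsTstd(P);
  for (int p = 0; p < P; ++p) {
    const uint64_t* ci = &packed[(size_t)pi[p] * words];
    const uint64_t* cj = &packed[(size_t)pj[p] * words];
    int S = 0;
    for (int w = 0; w < words; ++w) S += popcount64(ci[w] & cj[w]);
    obsC[p] = (long long)(Ri[p] - S) * (Rj[p] - S);
    obsT[p] = (long long)S * (n + S - Ri[p] - Rj[p]);
    obsCstd[p] = cmax[p] > 0 ? obsC[p] / cmax[p] : 0.0;
    obsTstd[p] = tmax[p] > 0 ? obsT[p] / tmax[p] : 0.0;
  }

  std::vector<int> cge(P, 0), tge(P, 0);
  std::vector<double> csum(P, 0), csum2(P, 0), tsum(P, 0), tsum2(P, 0);
  NumericVector commC(M), commT(M);
  NumericMatrix scC, scT;
  if (return_scores) { scC = NumericMatrix(M, P); scT = NumericMatrix(M, P); }

  for (int s = 0; s < burn_in; ++s) curveball_trade(b, n, m, diff, rng);
  for (int k = 0; k < M; ++k) {
    for (int s = 0; s < thin; ++s) curveball_trade(b, n, m, diff, rng);
    pack_columns(b, n, m, words, packed);
    double accC = 0, accT = 0;
    for (int p = 0; p < P; ++p) {
      const uint64_t* ci = &packed[(size_t)pi[p] * words];
      const uint64_t* cj = &packed[(size_t)pj[p] * words];
      int S = 0;
      for (int w = 0; w < words; ++w) S += popcount64(ci[w] & cj[w]);
      long long C = (long long)(Ri[p] - S) * (Rj[p] - S);
      long long T = (long long)S * (n + S - Ri[p] - Rj[p]);
      double Cs = cmax[p] > 0 ? C / cmax[p] : 0.0;
      double Ts = tmax[p] > 0 ? T / tmax[p] : 0.0;
      if (C >= obsC[p]) ++cge[p];
      if (T >= obsT[p]) ++tge[p];
      csum[p] += Cs; csum2[p] += Cs * Cs;
      tsum[p] += Ts; tsum2[p] += Ts * Ts;
      accC += Cs; accT += Ts;
      if (return_scores) { scC(k, p) = Cs; scT(k, p) = Ts; }
    }
    commC[k] = P > 0 ? accC / P : 0.0;
    commT[k] = P > 0 ? accT / P : 0.0;
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["obs_C_std"] = obsCstd, _["obs_T_std"] = obsTstd,
    _["c_ge"] = IntegerVector(cge.begin(), cge.end()),
    _["t_ge"] = IntegerVector(tge.begin(), tge.end()),
    _["c_sum"] = NumericVector(csum.begin(), csum.end()),
    _["c_sum2"] = NumericVector(csum2.begin(), csum2.end()),
    _["t_sum"] = NumericVector(tsum.begin(), tsum.end()),
    _["t_sum2"] = NumericVector(tsum2.begin(), tsum2.end()),
    _["comm_C"] = commC, _["comm_T"] = commT);
  if (return_scores) { out["C_std"] = scC; out["T_std"] = scT; }
  return out;
}

// Materialize an ensemble from the identical chain as cpp_cb_stream
// (same seed => state k here equals the state scored at step k there).
// [[Rcpp::export]]
List cpp_cb_ensemble(IntegerMatrix x, int M, int burn_in, int thin,
                     double seed) {
  int n = x.nrow(), m = x.ncol();
  if (thin < 1) stop("thin must be >= 1");
  std::vector<uint8_t> b = to_bytes(x);
  std::vector<int> diff(m);
  Xoshiro rng((uint64_t)seed);
  List out(M);
  for (int s = 0; s < burn_in; ++s) curveball_trade(b, n, m, diff, rng);
  for (int k = 0; k < M; ++k) {
    for (int s = 0; s < thin; ++s) curveball_trade(b, n, m, diff, rng);
    out[k] = from_bytes(b, n, m);
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Per-pair (Ri, Rj, S) for an arbitrary binary matrix.
// [[Rcpp::export]]
List cpp_pair_stats(IntegerMatrix x, IntegerMatrix pairs) {
  int n = x.nrow(), m = x.ncol(), P = pairs.nrow();
  std::vector<uint8_t> b = to_bytes(x);
  int words = (n + 63) / 64;
  std::vector<uint64_t> packed((size_t)m * words);
  pack_columns(b, n, m, words, packed);
  std::vector<int> colsum(m, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) colsum[j] += b[(size_t)i * m + j];
  IntegerVector Ri(P), Rj(P), S(P);
  for (int p = 0; p < P; ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    if (i < 0 || i >= m || j < 0 || j >= m) stop("invalid pair indices");
    const uint64_t* ci = &packed[(size_t)i * words];
    const uint64_t* cj = &packed[(size_t)j * words];
    int s = 0;
    for (int w = 0; w < words; ++w) s += popcount64(ci[w] & cj[w]);
    Ri[p] = colsum[i]; Rj[p] = colsum[j]; S[p] = s;
  }
  return List::create(_["R_i"] = Ri, _["R_j"] = Rj, _["S"] = S, _["N"] = n);
}
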