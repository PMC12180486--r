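#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Version-pinned FNV-1a 64-bit feature hashing. Stable across platforms and
// R sessions by construction (no runtime salting), which makes embeddings
// reproducible byte-for-byte.

static inline uint64_t fnv1a64(const char *s, size_t len, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ (seed * 0x9E3779B97F4A7C15ULL);
  for (size_t i = 0; i < len; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline void accumulate(const char *s, size_t len, uint64_t seed,
                              int dim, std::vector<double> &acc) {
  uint64_t h = fnv1a64(s, len, seed);
  int idx = (int)(h % (uint64_t)dim);
  double sign = ((h >> 32) & 1ULL) ? 1.0 : -1.0;
  acc[idx] += sign;
}

// Hashed k-mer composition embedding; L2-normalized. Sequences shorter than
// k fall back to all j-mers, j = 1..length.
// [[Rcpp::export(name = ".embed_kmers_cpp")]]
NumericVector embed_kmers_cpp(std::string seq, int dim, int k, int seed) {
  std::vector<double> acc(dim, 0.0);
  const int L = (int)seq.size();
  if (L == 0) stop("cannot embed an empty sequence");
  const uint64_t sd = (uint64_t)seed;
  if (L >= k) {
    for (int i = 0; i + k <= L; ++i) accumulate(seq.data() + i, k, sd, dim, acc);
  } else {
    for (int j = 1; j <= L; ++j)
      for (int i = 0; i + j <= L; ++i) accumulate(seq.data() + i, j, sd, dim, acc);
  }
  double nrm = 0.0;
  for (int d = 0; d < dim; ++d) nrm += acc[d] * acc[d];
  nrm = std::sqrt(nrm);
  NumericVector out(dim);
  if (nrm == 0.0) stop("degenerate embedding (zero norm)");
  for (int d = 0; d < dim; ++d) out[d] = acc[d] / nrm;
  return out;
}

// Signed hashed bag-of-tokens (text featurizer); returned unnormalized.
// [[Rcpp::export(name = ".hash_tokens_cpp")]]
NumericVector hash_tokens_cpp(CharacterVector tokens, int dim, int seed) {
  std::vector<double> acc(dim, 0.0);
  const uint64_t sd = (uint64_t)seed;
  for (R_xlen_t t = 0; t < tokens.size(); ++t) {
    const char *s = CHAR(STRING_ELT(tokens, t));
    accumulate(s, strlen(s), sd, dim, acc);
  }
  return wrap(acc);
}
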