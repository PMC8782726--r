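#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// FNV-1a 32-bit hash of each input string, returned as 8-char lowercase hex.
// Used for substructure-environment identifiers and fingerprint folding:
// stable across platforms and sessions (unlike R's internal hashing).
// [[Rcpp::export(name = ".fnv1a32")]]
CharacterVector fnv1a32(CharacterVector x) {
  const uint32_t prime = 16777619u;
  CharacterVector out(x.size());
  char buf[9];
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint32_t)(*p);
      h *= prime;
    }
    snprintf(buf, sizeof(buf), "%08x", h);
    out[i] = buf;
  }
  return out;
}

// FNV-1a 32-bit reduced modulo `size` (for fingerprint folding).
// [[Rcpp::export(name = ".fnv1a32_mod")]]
IntegerVector fnv1a32_mod(CharacterVector x, int size) {
  const uint32_t prime = 16777619u;
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint32_t)(*p);
      h *= prime;
    }
    out[i] = (int)(h % (uint32_t)size);
  }
  return out;
}

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG.
static inline uint64_t xs_next(uint64_t &state) {
  state ^= state >> 12;
  state ^= state << 25;
  state ^= state >> 27;
  return state * 2685821657736338717ULL;
}

static inline double xs_unif(uint64_t &state) {
  return (double)(xs_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

// Skip-gram with negative sampling over tokenised sentences.
//
// sentences: list of integer vectors, 1-based token ids in [1, vocab_size];
// counts:    token frequencies (for the 0.75-power negative-sampling table);
// Training is strictly sequential (single worker) so a fixed seed gives a
// bit-reproducible vector matrix. Learning rate decays linearly per epoch.
// Returns a vocab_size x dim matrix of input vectors.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha, double seed) {
  if (vocab_size < 1) stop("empty vocabulary");
  if (dim < 2) stop("embedding dimension must be >= 2");

  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (xs_unif(rng) - 0.5) / dim;

  // unigram^0.75 sampling table
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int i = 0; i < vocab_size; ++i) total += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((double)(t + 1) / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / total;
      }
    }
  }

  const double min_alpha_frac = 1e-4;
  std::vector<double> grad(dim);
  int n_sent = sentences.size();

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = alpha * (1.0 - (double)ep / epochs);
    if (lr < alpha * min_alpha_frac) lr = alpha * min_alpha_frac;

    for (int si = 0; si < n_sent; ++si) {
      IntegerVector sent = sentences[si];
      int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        int center = sent[pos] - 1;
        // dynamic window, as in word2vec
        int b = (int)(xs_next(rng) % (uint64_t)window);
        int lo = pos - (window - b); if (lo < 0) lo = 0;
        int hi = pos + (window - b); if (hi >= len) hi = len - 1;
        for (int cp = lo; cp <= hi; ++cp) {
          if (cp == pos) continue;
          int context = sent[cp] - 1;
          double *v = &syn0[(size_t)context * dim];
          for (int k = 0; k < dim; ++k) grad[k] = 0.0;
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = table[xs_next(rng) % (uint64_t)table_size];
              if (target == center) continue;
              label = 0.0;
            }
            double *w = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * w[k];
            double sig = 1.0 / (1.0 + std::exp(-dot));
            double g = lr * (label - sig);
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * w[k];
              w[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
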