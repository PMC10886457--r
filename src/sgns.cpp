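#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic xorshift64* generator: training must be bit-reproducible
// across runs and platforms, so R's RNG (whose state the caller owns) is not
// used here.
static inline uint64_t xorshift(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double unif01(uint64_t &s) {
  return (xorshift(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline int randint(uint64_t &s, int n) {
  return (int)(xorshift(s) % (uint64_t)n);
}

// Skip-gram with negative sampling. Sentences hold 1-based vocabulary ids;
// counts are the corpus frequencies used for the 0.75-power unigram noise
// distribution. Single-threaded, seeded, linear learning-rate decay.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int epochs, int negative,
                         double alpha, double min_alpha, int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  if (dim < 2) stop("embedding dimension must be >= 2");

  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double Z = 0.0;
    for (int i = 0; i < vocab_size; i++) Z += std::pow(counts[i], 0.75);
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / Z;
    for (int a = 0; a < table_size; a++) {
      table[a] = i;
      if ((double)(a + 1) / table_size > cum && i < vocab_size - 1) {
        i++;
        cum += std::pow(counts[i], 0.75) / Z;
      }
    }
  }

  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL +
                 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); k++)
    syn0[k] = (unif01(rng) - 0.5) / dim;

  int S = sentences.size();
  std::vector<std::vector<int> > sents(S);
  long long total = 0;
  for (int s = 0; s < S; s++) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    for (size_t j = 0; j < sents[s].size(); j++) {
      if (sents[s][j] < 1 || sents[s][j] > vocab_size)
        stop("token id out of range");
    }
    total += iv.size();
  }
  if (total == 0) stop("empty corpus");

  long long train_total = total * (long long)epochs;
  long long processed = 0;
  std::vector<double> neu1e(dim);

  for (int ep = 0; ep < epochs; ep++) {
    for (int s = 0; s < S; s++) {
      const std::vector<int> &sent = sents[s];
      int n = (int)sent.size();
      for (int pos = 0; pos < n; pos++) {
        double lr = alpha * (1.0 - (double)processed / (double)train_total);
        if (lr < min_alpha) lr = min_alpha;
        processed++;
        int w = sent[pos] - 1;
        int shrink = randint(rng, window);  // dynamic window, as in word2vec
        for (int off = shrink - window; off <= window - shrink; off++) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          int c = sent[cpos] - 1;
          double *v = &syn0[(size_t)c * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d < negative + 1; d++) {
            int target;
            double label;
            if (d == 0) {
              target = w;
              label = 1.0;
            } else {
              target = table[randint(rng, table_size)];
              if (target == w) continue;
              label = 0.0;
            }
            double *u = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; k++) f += v[k] * u[k];
            double g;
            if (f > 6.0) g = (label - 1.0) * lr;
            else if (f < -6.0) g = label * lr;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
            for (int k = 0; k < dim; k++) {
              neu1e[k] += g * u[k];
              u[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; k++) v[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; i++)
    for (int k = 0; k < dim; k++)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
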