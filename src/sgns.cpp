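#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic single-threaded skip-gram with negative sampling.
//
// The update scheme follows the classic word2vec reference trainer:
// frequency^0.75 unigram table for negative sampling, per-position
// reduced window, linear learning-rate decay, and a 64-bit LCG so that
// a fixed seed reproduces the weight matrix bit for bit.
//
// docs:   list of integer vectors, 0-based in-vocabulary token ids
//         (out-of-vocabulary tokens already removed by the caller)
// counts: token frequencies, one per vocabulary row

static const int TABLE_SIZE = 1000000;
static const double MAX_EXP = 6.0;

static inline uint64_t lcg_next(uint64_t x) {
  return x * 25214903917ULL + 11ULL;
}

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List docs, IntegerVector counts, int dim,
                             int window, int epochs, int negative,
                             double alpha0, int seed) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");

  // unigram table over counts^0.75
  std::vector<int> table(TABLE_SIZE);
  double z = 0.0;
  for (int a = 0; a < V; ++a) z += std::pow((double)counts[a], 0.75);
  {
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / z;
    for (int a = 0; a < TABLE_SIZE; ++a) {
      table[a] = i;
      if ((double)a / TABLE_SIZE > cum && i < V - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / z;
      }
    }
  }

  uint64_t rng = (uint64_t)(uint32_t)seed;

  // input vectors: deterministic uniform init in (-0.5, 0.5)/dim;
  // output (context) vectors start at zero
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t a = 0; a < (size_t)V * dim; ++a) {
    rng = lcg_next(rng);
    syn0[a] = (((rng & 0xFFFFULL) / 65536.0) - 0.5) / dim;
  }

  long long train_words = 0;
  const int n_docs = docs.size();
  std::vector<std::vector<int> > sen(n_docs);
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    sen[d].assign(v.begin(), v.end());
    train_words += v.size();
  }
  if (train_words == 0) stop("empty corpus");

  std::vector<double> neu1e_v(dim);
  double* __restrict s0 = syn0.data();
  double* __restrict s1 = syn1.data();
  double* __restrict neu1e = neu1e_v.data();
  const int* __restrict tab = table.data();
  double lr = alpha0;
  long long processed = 0;
  const double total = (double)train_words * epochs + 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      const std::vector<int>& s = sen[d];
      const int n = (int)s.size();
      for (int pos = 0; pos < n; ++pos) {
        if ((processed % 10000) == 0) {
          lr = alpha0 * (1.0 - processed / total);
          if (lr < alpha0 * 1e-4) lr = alpha0 * 1e-4;
          Rcpp::checkUserInterrupt();
        }
        ++processed;
        const int word = s[pos];
        rng = lcg_next(rng);
        const int b = (int)(rng % (uint64_t)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          const int c = pos - window + a;
          if (c < 0 || c >= n) continue;
          const int last_word = s[c];
          const double* __restrict p1 = s0 + (size_t)last_word * dim;
          for (int j = 0; j < dim; ++j) neu1e[j] = 0.0;
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = word;
              label = 1.0;
            } else {
              rng = lcg_next(rng);
              target = tab[(rng >> 16) % TABLE_SIZE];
              if (target == word) continue;
              label = 0.0;
            }
            double* __restrict p2 = s1 + (size_t)target * dim;
            double f = 0.0;
            for (int j = 0; j < dim; ++j) f += p1[j] * p2[j];
            double g;
            if (f > MAX_EXP) g = (label - 1.0) * lr;
            else if (f < -MAX_EXP) g = label * lr;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
            for (int j = 0; j < dim; ++j) neu1e[j] += g * p2[j];
            for (int j = 0; j < dim; ++j) p2[j] += g * p1[j];
          }
          double* __restrict q1 = s0 + (size_t)last_word * dim;
          for (int j = 0; j < dim; ++j) q1[j] += neu1e[j];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int a = 0; a < V; ++a)
    for (int j = 0; j < dim; ++j) out(a, j) = syn0[(size_t)a * dim + j];
  return out;
}
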