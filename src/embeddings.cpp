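// Negative-sampling SGD trainers for PV-DBOW paragraph vectors and CBOW
// word vectors. Single-threaded and seeded, so runs are bitwise
// reproducible for a fixed seed.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t below(uint64_t n) { return next() % n; }
};

// precomputed logistic table over [-6, 6], word2vec style
struct SigmoidTable {
  static const int N = 4096;
  double t[N];
  SigmoidTable() {
    for (int i = 0; i < N; ++i) {
      double x = (i / (double)(N - 1)) * 12.0 - 6.0;
      t[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
};
static const SigmoidTable SIG;

inline double sigmoid(double x) {
  if (x >= 6.0) return 1.0;
  if (x <= -6.0) return 0.0;
  return SIG.t[(int)((x + 6.0) / 12.0 * (SigmoidTable::N - 1))];
}

// unigram^0.75 sampling table
std::vector<int> build_table(const std::vector<double>& freq, int size) {
  std::vector<int> table(size);
  double total = 0.0;
  for (double f : freq) total += std::pow(f, 0.75);
  int i = 0;
  double cum = std::pow(freq[0], 0.75) / total;
  for (int a = 0; a < size; ++a) {
    table[a] = i;
    if ((a + 1.0) / size > cum && i < (int)freq.size() - 1) {
      ++i;
      cum += std::pow(freq[i], 0.75) / total;
    }
  }
  return table;
}

// one positive + `negative` sampled negative updates between a context
// vector `v` (updated in place via grad accumulation) and output rows
inline void ns_update(double* __restrict v, std::vector<double>& syn1,
                      int dim, int target, int negative,
                      const std::vector<int>& table, XorShift& rng,
                      double alpha, std::vector<double>& grad_buf,
                      bool update_output) {
  double* __restrict grad = grad_buf.data();
  std::fill(grad, grad + dim, 0.0);
  for (int k = 0; k <= negative; ++k) {
    int w;
    double label;
    if (k == 0) {
      w = target;
      label = 1.0;
    } else {
      w = table[rng.below(table.size())];
      if (w == target) continue;
      label = 0.0;
    }
    double* __restrict o = &syn1[(size_t)w * dim];
    double f = 0.0;
    for (int c = 0; c < dim; ++c) f += v[c] * o[c];
    double g = (label - sigmoid(f)) * alpha;
    if (update_output) {
      for (int c = 0; c < dim; ++c) {
        grad[c] += g * o[c];
        o[c] += g * v[c];
      }
    } else {
      for (int c = 0; c < dim; ++c) grad[c] += g * o[c];
    }
  }
  for (int c = 0; c < dim; ++c) v[c] += grad[c];
}

} // namespace

// [[Rcpp::export]]
List cpp_pvdbow_train(IntegerVector words, IntegerVector doc_start,
                      int n_words, NumericVector word_freq, int dim,
                      int epochs, double alpha, int negative, int seed) {
  const int n_docs = doc_start.size() - 1;
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> docv((size_t)n_docs * dim);
  for (size_t i = 0; i < docv.size(); ++i)
    docv[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> syn1((size_t)n_words * dim, 0.0);

  std::vector<double> freq(word_freq.begin(), word_freq.end());
  std::vector<int> table = build_table(freq, 1000000);
  std::vector<double> grad(dim);

  const double alpha0 = alpha, alpha_min = alpha * 1e-4;
  const double total = (double)epochs * words.size();
  double processed = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      double* v = &docv[(size_t)d * dim];
      for (int pos = doc_start[d]; pos < doc_start[d + 1]; ++pos) {
        double lr = alpha0 * (1.0 - processed / total);
        if (lr < alpha_min) lr = alpha_min;
        ns_update(v, syn1, dim, words[pos], negative, table, rng, lr,
                  grad, true);
        processed += 1.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix dv(n_docs, dim), ov(n_words, dim);
  for (int d = 0; d < n_docs; ++d)
    for (int c = 0; c < dim; ++c) dv(d, c) = docv[(size_t)d * dim + c];
  for (int w = 0; w < n_words; ++w)
    for (int c = 0; c < dim; ++c) ov(w, c) = syn1[(size_t)w * dim + c];
  return List::create(_["doc_vectors"] = dv, _["output_vectors"] = ov);
}

// [[Rcpp::export]]
NumericMatrix cpp_pvdbow_infer(IntegerVector words, IntegerVector doc_start,
                               NumericMatrix output_vectors,
                               NumericVector word_freq, int dim, int epochs,
                               double alpha, int negative, int seed) {
  const int n_docs = doc_start.size() - 1;
  const int n_words = output_vectors.nrow();
  XorShift rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);

  std::vector<double> syn1((size_t)n_words * dim);
  for (int w = 0; w < n_words; ++w)
    for (int c = 0; c < dim; ++c) syn1[(size_t)w * dim + c] = output_vectors(w, c);
  std::vector<double> freq(word_freq.begin(), word_freq.end());
  std::vector<int> table = build_table(freq, 1000000);
  std::vector<double> grad(dim);

  NumericMatrix dv(n_docs, dim);
  std::vector<double> v(dim);
  for (int d = 0; d < n_docs; ++d) {
    for (int c = 0; c < dim; ++c) v[c] = (rng.unif() - 0.5) / dim;
    int len = doc_start[d + 1] - doc_start[d];
    double steps = std::max(1, len * epochs);
    double done = 0.0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int pos = doc_start[d]; pos < doc_start[d + 1]; ++pos) {
        double lr = alpha * (1.0 - done / steps);
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        // output vectors stay frozen at inference
        ns_update(v.data(), syn1, dim, words[pos], negative, table, rng,
                  lr, grad, false);
        done += 1.0;
      }
    }
    for (int c = 0; c < dim; ++c) dv(d, c) = v[c];
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return dv;
}

// [[Rcpp::export]]
NumericMatrix cpp_cbow_train(IntegerVector words, IntegerVector doc_start,
                             int n_words, NumericVector word_freq, int dim,
                             int epochs, double alpha, int window,
                             int negative, int seed) {
  const int n_docs = doc_start.size() - 1;
  XorShift rng((uint64_t)seed * 6364136223846793005ULL + 3ULL);

  std::vector<double> syn0((size_t)n_words * dim);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;
  std::vector<double> syn1((size_t)n_words * dim, 0.0);
  std::vector<double> freq(word_freq.begin(), word_freq.end());
  std::vector<int> table = build_table(freq, 1000000);
  std::vector<double> h(dim), grad(dim);

  const double total = (double)epochs * words.size();
  double processed = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      for (int pos = doc_start[d]; pos < doc_start[d + 1]; ++pos) {
        double lr = alpha * (1.0 - processed / total);
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        processed += 1.0;
        int b = (int)rng.below((uint64_t)window) ; // shrunk window
        int lo = pos - (window - b), hi = pos + (window - b);
        if (lo < doc_start[d]) lo = doc_start[d];
        if (hi > doc_start[d + 1] - 1) hi = doc_start[d + 1] - 1;
        int cw = 0;
        std::fill(h.begin(), h.end(), 0.0);
        for (int p = lo; p <= hi; ++p) {
          if (p == pos) continue;
          double* in = &syn0[(size_t)words[p] * dim];
          for (int c = 0; c < dim; ++c) h[c] += in[c];
          ++cw;
        }
        if (!cw) continue;
        for (int c = 0; c < dim; ++c) h[c] /= cw;
        ns_update(h.data(), syn1, dim, words[pos], negative, table, rng,
                  lr, grad, true);
        // h was updated in place by the accumulated gradient; recover it
        // and spread over the context words
        for (int p = lo; p <= hi; ++p) {
          if (p == pos) continue;
          double* in = &syn0[(size_t)words[p] * dim];
          for (int c = 0; c < dim; ++c) in[c] += grad[c];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix wv(n_words, dim);
  for (int w = 0; w < n_words; ++w)
    for (int c = 0; c < dim; ++c) wv(w, c) = syn0[(size_t)w * dim + c];
  return wv;
}
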