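// Skip-gram with negative sampling (SGNS), single-threaded and fully
// deterministic given the seed. Follows the reference word2vec training
// scheme: dynamic window shrinking, unigram^0.75 negative-sampling
// distribution, frequent-word subsampling, and linear learning-rate decay.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoidd(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
arma::mat cpp_sgns_train(List sentences, arma::vec counts, int dim,
                         int window, int epochs, int negative,
                         double alpha0, double sample, int seed) {
  const int V = counts.n_elem;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // init: input vectors uniform in (-0.5/dim, 0.5/dim), output vectors zero
  arma::mat syn0(dim, V), syn1(dim, V, arma::fill::zeros);
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < dim; ++k)
      syn0(k, w) = (unif(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  arma::vec cum(V);
  double acc = 0.0;
  for (int w = 0; w < V; ++w) { acc += std::pow(counts[w], 0.75); cum[w] = acc; }
  auto sample_neg = [&](void) -> int {
    double r = unif(rng) * acc;
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  const double total_words = arma::accu(counts);
  const double train_total = total_words * std::max(1, epochs) + 1.0;
  double processed = 0.0;
  arma::vec neu1e(dim);
  const int S = sentences.size();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sen0 = sentences[s];
      // frequent-word subsampling
      std::vector<int> sen;
      sen.reserve(sen0.size());
      for (int j = 0; j < sen0.size(); ++j) {
        int w = sen0[j];
        if (w < 0 || w >= V) continue;
        processed += 1.0;
        if (sample > 0) {
          double f = counts[w] / total_words;
          double keep = (std::sqrt(f / sample) + 1.0) * sample / f;
          if (keep < 1.0 && unif(rng) > keep) continue;
        }
        sen.push_back(w);
      }
      const int n = static_cast<int>(sen.size());
      if (n < 2) continue;
      double alpha = alpha0 * std::max(1e-4, 1.0 - processed / train_total);

      for (int pos = 0; pos < n; ++pos) {
        int word = sen[pos];
        int b = static_cast<int>(unif(rng) * window); // shrink window
        for (int a = b; a < 2 * window + 1 - b; ++a) {
          if (a == window) continue;
          int cpos = pos - window + a;
          if (cpos < 0 || cpos >= n) continue;
          int last = sen[cpos];
          neu1e.zeros();
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = word; label = 1.0; }
            else {
              target = sample_neg();
              if (target == word) continue;
              label = 0.0;
            }
            double f = arma::dot(syn0.col(last), syn1.col(target));
            double g = (label - sigmoidd(f)) * alpha;
            neu1e += g * syn1.col(target);
            syn1.col(target) += g * syn0.col(last);
          }
          syn0.col(last) += neu1e;
        }
      }
    }
  }
  return syn0.t(); // V x dim
}
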