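#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

// Self-contained PRNG (xorshift128+ seeded by splitmix64) so that training
// is bit-reproducible from the integer seed alone, independent of R's RNG
// state.
namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t; else s1 = t;
    }
    if (!(s0 | s1)) s0 = 0x1ULL;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// CBOW with negative sampling over whole-scene context windows: for each
// object in a scene the context is the set of all other objects in that
// scene, equally weighted (the hidden vector is the mean of the context
// input vectors).  Negatives are drawn from the unigram distribution raised
// to `noise_power`, excluding the current target.  The learning rate decays
// linearly from `lr0` to lr0 * 1e-4 across all training steps.
//
// scenes: list of 0-based integer vectors (label indices); counts: per-label
// scene-containing counts used for the noise distribution.  Returns the
// input-side embedding matrix (vocab x dim).
// [[Rcpp::export(name = ".cbow_train")]]
Rcpp::NumericMatrix cbow_train(Rcpp::List scenes,
                               Rcpp::NumericVector counts,
                               int dim, int epochs, int negatives,
                               double lr0, double noise_power,
                               double seed) {
  const int V = counts.size();
  const int S = scenes.size();
  std::vector<std::vector<int>> sc(S);
  long long total_pairs = 0;
  for (int i = 0; i < S; ++i) {
    Rcpp::IntegerVector v = scenes[i];
    sc[i] = std::vector<int>(v.begin(), v.end());
    if (sc[i].size() >= 2) total_pairs += sc[i].size();
  }
  if (total_pairs == 0)
    Rcpp::stop("no scene with at least 2 labels; nothing to train on");

  Rng rng(static_cast<uint64_t>(seed));

  // cumulative noise distribution ~ counts^noise_power
  std::vector<double> cum(V);
  double acc = 0.0;
  for (int i = 0; i < V; ++i) {
    acc += std::pow(counts[i], noise_power);
    cum[i] = acc;
  }

  // input vectors uniform in (-0.5/dim, 0.5/dim); output vectors zero
  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<int> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;
  std::vector<double> h(dim), grad(dim);

  const double total_steps = static_cast<double>(epochs) * total_pairs;
  const double lr_floor = lr0 * 1e-4;
  long long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle of the scene order
    for (int i = S - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < S; ++oi) {
      const std::vector<int>& scene = sc[order[oi]];
      const int n = static_cast<int>(scene.size());
      if (n < 2) continue;
      for (int ti = 0; ti < n; ++ti) {
        const double lr =
            std::max(lr0 * (1.0 - step / total_steps), lr_floor);
        ++step;
        const int target = scene[ti];
        const int nctx = n - 1;
        // h = mean of context input vectors
        std::fill(h.begin(), h.end(), 0.0);
        for (int ci = 0; ci < n; ++ci) {
          if (ci == ti) continue;
          const double* v = &syn0[static_cast<size_t>(scene[ci]) * dim];
          for (int d = 0; d < dim; ++d) h[d] += v[d];
        }
        for (int d = 0; d < dim; ++d) h[d] /= nctx;

        std::fill(grad.begin(), grad.end(), 0.0);
        for (int k = 0; k <= negatives; ++k) {
          int label;
          double y;
          if (k == 0) {
            label = target;
            y = 1.0;
          } else {
            // draw from the noise distribution, excluding the target
            int tries = 0;
            do {
              const double u = rng.unif() * acc;
              int lo = 0, hi = V - 1;
              while (lo < hi) {
                const int mid = (lo + hi) / 2;
                if (cum[mid] < u) lo = mid + 1; else hi = mid;
              }
              label = lo;
            } while (label == target && ++tries < 100);
            if (label == target) continue;
            y = 0.0;
          }
          double* w = &syn1[static_cast<size_t>(label) * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += h[d] * w[d];
          const double g = (y - sigmoid(f)) * lr;
          for (int d = 0; d < dim; ++d) {
            grad[d] += g * w[d];
            w[d] += g * h[d];
          }
        }
        // distribute the hidden-layer gradient to the context vectors
        for (int ci = 0; ci < n; ++ci) {
          if (ci == ti) continue;
          double* v = &syn0[static_cast<size_t>(scene[ci]) * dim];
          for (int d = 0; d < dim; ++d) v[d] += grad[d] / nctx;
        }
      }
    }
    if (ep % 64 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  return out;
}
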