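#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Feature hashing (FNV-1a, 64-bit) over token byte strings.
// Tokens are separated by a 0x1F unit-separator byte so that ("ab","c") and
// ("a","bc") hash differently.  Hashing token strings (not vocabulary ids)
// keeps bucket assignments identical across models that share a bucket
// count, which is what makes pre-trained n-gram vectors transferable.
// ---------------------------------------------------------------------------

static inline uint64_t fnv1a_update(uint64_t h, const char *s, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline int hash_tokens(const std::vector<std::string> &toks,
                              int from, int len, int buckets) {
  uint64_t h = 14695981039346656037ULL;
  for (int i = 0; i < len; ++i) {
    if (i > 0) {
      const char sep = 0x1F;
      h = fnv1a_update(h, &sep, 1);
    }
    const std::string &t = toks[from + i];
    h = fnv1a_update(h, t.data(), t.size());
  }
  return (int)(h % (uint64_t)buckets);
}

// [[Rcpp::export]]
int hash_ngram_cpp(CharacterVector tokens, int buckets) {
  std::vector<std::string> toks(tokens.size());
  for (int i = 0; i < tokens.size(); ++i) toks[i] = as<std::string>(tokens[i]);
  return hash_tokens(toks, 0, (int)toks.size(), buckets);
}

// Occurrence-level feature ids (1-based): in-vocabulary unigrams get their
// vocabulary id; every n-gram (2..n_max) of consecutive tokens -- vocabulary
// membership of the constituents notwithstanding -- gets vocab_size + bucket
// + 1.  Out-of-vocabulary unigrams contribute no unigram feature but still
// occupy their positions inside n-grams.
// [[Rcpp::export]]
IntegerVector encode_features_cpp(CharacterVector tokens, IntegerVector uni_ids,
                                  int n_max, int buckets, int vocab_size) {
  int L = tokens.size();
  std::vector<std::string> toks(L);
  for (int i = 0; i < L; ++i) toks[i] = as<std::string>(tokens[i]);
  std::vector<int> out;
  out.reserve(L * n_max);
  for (int i = 0; i < L; ++i)
    if (uni_ids[i] != NA_INTEGER) out.push_back(uni_ids[i]);
  for (int n = 2; n <= n_max; ++n)
    for (int i = 0; i + n <= L; ++i)
      out.push_back(vocab_size + hash_tokens(toks, i, n, buckets) + 1);
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Shared numerics
// ---------------------------------------------------------------------------

static inline void softmax_inplace(std::vector<double> &z) {
  double m = z[0];
  for (size_t i = 1; i < z.size(); ++i) m = std::max(m, z[i]);
  double s = 0.0;
  for (size_t i = 0; i < z.size(); ++i) { z[i] = std::exp(z[i] - m); s += z[i]; }
  for (size_t i = 0; i < z.size(); ++i) z[i] /= s;
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  return std::log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// Supervised training: per-example SGD on the softmax negative log-likelihood
// with linearly decaying learning rate.  V is h x n_features (one column per
// feature), U is k x h.  Only the feature columns of the current example are
// touched -- the sparse-update contract that keeps cost linear in sentence
// length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List train_supervised_cpp(List feats, IntegerVector labels, int h, int k,
                          int epochs, double lr0, int seed,
                          NumericMatrix V_init, NumericMatrix U_init) {
  int N = feats.size();
  NumericMatrix V = clone(V_init);   // h x n_features
  NumericMatrix U = clone(U_init);   // k x h
  double *Vp = REAL(V);
  double *Up = REAL(U);

  std::vector<std::vector<int>> ex(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector f = feats[i];
    ex[i].assign(f.begin(), f.end());
  }

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> hidden(h), scores(k), ghid(h);
  NumericVector epoch_loss(epochs);
  double total = (double)N * epochs;
  long long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with explicit draws, reproducible for a fixed seed
    for (int i = N - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order[i], order[d(rng)]);
    }
    double loss = 0.0;
    for (int ii = 0; ii < N; ++ii) {
      const std::vector<int> &f = ex[order[ii]];
      int y = labels[order[ii]] - 1;
      double lr = lr0 * (1.0 - (double)t / total);
      ++t;
      int m = (int)f.size();
      if (m == 0) { loss += std::log((double)k); continue; }
      double inv = 1.0 / m;
      std::fill(hidden.begin(), hidden.end(), 0.0);
      for (int j = 0; j < m; ++j) {
        const double *col = Vp + (size_t)(f[j] - 1) * h;
        for (int d = 0; d < h; ++d) hidden[d] += col[d];
      }
      for (int d = 0; d < h; ++d) hidden[d] *= inv;
      for (int c = 0; c < k; ++c) {
        double s = 0.0;
        for (int d = 0; d < h; ++d) s += Up[c + (size_t)d * k] * hidden[d];
        scores[c] = s;
      }
      softmax_inplace(scores);
      loss -= std::log(std::max(scores[y], 1e-300));
      // scores now holds p; gradient wrt logits is p - onehot(y)
      scores[y] -= 1.0;
      std::fill(ghid.begin(), ghid.end(), 0.0);
      for (int c = 0; c < k; ++c) {
        double g = scores[c];
        if (g == 0.0) continue;
        for (int d = 0; d < h; ++d) {
          ghid[d] += Up[c + (size_t)d * k] * g;
          Up[c + (size_t)d * k] -= lr * g * hidden[d];
        }
      }
      for (int d = 0; d < h; ++d) ghid[d] *= lr * inv;
      for (int j = 0; j < m; ++j) {
        double *col = Vp + (size_t)(f[j] - 1) * h;
        for (int d = 0; d < h; ++d) col[d] -= ghid[d];
      }
    }
    epoch_loss[ep] = loss / N;
  }
  return List::create(_["V"] = V, _["U"] = U, _["epoch_loss"] = epoch_loss);
}

// Class probabilities for a list of encoded sentences (rows) -- the batched
// counterpart of predict_proba used by the evaluation harness.
// [[Rcpp::export]]
NumericMatrix predict_proba_cpp(List feats, NumericMatrix V, NumericMatrix U) {
  int N = feats.size(), h = V.nrow(), k = U.nrow();
  const double *Vp = REAL(V);
  const double *Up = REAL(U);
  NumericMatrix out(N, k);
  std::vector<double> hidden(h), scores(k);
  for (int i = 0; i < N; ++i) {
    IntegerVector f = feats[i];
    int m = f.size();
    std::fill(hidden.begin(), hidden.end(), 0.0);
    if (m > 0) {
      for (int j = 0; j < m; ++j) {
        const double *col = Vp + (size_t)(f[j] - 1) * h;
        for (int d = 0; d < h; ++d) hidden[d] += col[d];
      }
      for (int d = 0; d < h; ++d) hidden[d] /= m;
    }
    for (int c = 0; c < k; ++c) {
      double s = 0.0;
      for (int d = 0; d < h; ++d) s += Up[c + (size_t)d * k] * hidden[d];
      scores[c] = s;
    }
    softmax_inplace(scores);
    for (int c = 0; c < k; ++c) out(i, c) = scores[c];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Unsupervised pre-training with negative sampling.
//
// mode 0 (fixed window, CBOW-style): the context of a target position is the
//   unigrams within `window` positions on each side.
// mode 1 (whole sentence, sent2vec-style): the context is every other
//   unigram of the sentence plus the n-grams (2..n_max) of the sentence with
//   the target position spliced out; n-grams are hashed into the same bucket
//   space the supervised encoder uses.
//
// Sentences arrive with out-of-vocabulary tokens already removed.  V is
// h x (vocab + buckets) (mode 1) or h x vocab (mode 0); U is h x vocab and
// holds the output ("negative") vectors, one column per vocabulary word.
// ---------------------------------------------------------------------------

static int sample_word(const std::vector<double> &cum, std::mt19937 &rng,
                       std::uniform_real_distribution<double> &unif) {
  double u = unif(rng);
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo; // 0-based vocab index
}

// [[Rcpp::export]]
List pretrain_cpp(List sents, List sent_tokens, int mode, int window, int n_max,
                  int buckets, int vocab_size, int h, int epochs, double lr0,
                  int negatives, NumericVector noise_cum, int seed,
                  NumericMatrix V_init, NumericMatrix U_init) {
  int S = sents.size();
  NumericMatrix V = clone(V_init);
  NumericMatrix U = clone(U_init);
  double *Vp = REAL(V);
  double *Up = REAL(U);

  std::vector<std::vector<int>> ids(S);
  std::vector<std::vector<std::string>> toks(S);
  long long npairs = 0;
  for (int i = 0; i < S; ++i) {
    IntegerVector v = sents[i];
    ids[i].assign(v.begin(), v.end());
    npairs += v.size();
    if (mode == 1 && n_max >= 2) {
      CharacterVector tv = sent_tokens[i];
      toks[i].resize(tv.size());
      for (int j = 0; j < tv.size(); ++j) toks[i][j] = as<std::string>(tv[j]);
    }
  }

  // Pre-compute per-target context feature lists once; reused every epoch.
  std::vector<std::vector<std::vector<int>>> ctx(S);
  std::vector<std::string> spl;
  for (int i = 0; i < S; ++i) {
    int L = (int)ids[i].size();
    ctx[i].resize(L);
    for (int t = 0; t < L; ++t) {
      std::vector<int> &c = ctx[i][t];
      if (mode == 0) {
        for (int j = std::max(0, t - window); j <= std::min(L - 1, t + window); ++j)
          if (j != t) c.push_back(ids[i][j]);
      } else {
        for (int j = 0; j < L; ++j)
          if (j != t) c.push_back(ids[i][j]);
        if (n_max >= 2 && L >= 3) {
          spl.clear();
          for (int j = 0; j < L; ++j)
            if (j != t) spl.push_back(toks[i][j]);
          for (int n = 2; n <= n_max; ++n)
            for (int j = 0; j + n <= (int)spl.size(); ++j)
              c.push_back(vocab_size + hash_tokens(spl, j, n, buckets) + 1);
        }
      }
    }
  }

  std::vector<double> cum(noise_cum.begin(), noise_cum.end());
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;

  std::vector<double> vctx(h), gctx(h);
  NumericVector epoch_loss(epochs);
  double total = (double)npairs * epochs;
  long long t_done = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = S - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order[i], order[d(rng)]);
    }
    double loss = 0.0;
    for (int si = 0; si < S; ++si) {
      int s = order[si];
      int L = (int)ids[s].size();
      for (int t = 0; t < L; ++t) {
        double lr = lr0 * (1.0 - (double)t_done / total);
        ++t_done;
        const std::vector<int> &c = ctx[s][t];
        int m = (int)c.size();
        if (m == 0) continue;
        int target = ids[s][t] - 1; // 0-based vocab index
        double inv = 1.0 / m;
        std::fill(vctx.begin(), vctx.end(), 0.0);
        for (int j = 0; j < m; ++j) {
          const double *col = Vp + (size_t)(c[j] - 1) * h;
          for (int d = 0; d < h; ++d) vctx[d] += col[d];
        }
        for (int d = 0; d < h; ++d) vctx[d] *= inv;
        std::fill(gctx.begin(), gctx.end(), 0.0);
        // positive example
        {
          double *ucol = Up + (size_t)target * h;
          double score = 0.0;
          for (int d = 0; d < h; ++d) score += ucol[d] * vctx[d];
          loss += softplus(-score);
          double g = sigmoid(score) - 1.0; // d loss / d score
          for (int d = 0; d < h; ++d) {
            gctx[d] += g * ucol[d];
            ucol[d] -= lr * g * vctx[d];
          }
        }
        // negative examples, resampling draws equal to the target
        for (int neg = 0; neg < negatives; ++neg) {
          int w = sample_word(cum, rng, unif);
          while (w == target) w = sample_word(cum, rng, unif);
          double *ucol = Up + (size_t)w * h;
          double score = 0.0;
          for (int d = 0; d < h; ++d) score += ucol[d] * vctx[d];
          loss += softplus(score);
          double g = sigmoid(score);
          for (int d = 0; d < h; ++d) {
            gctx[d] += g * ucol[d];
            ucol[d] -= lr * g * vctx[d];
          }
        }
        for (int d = 0; d < h; ++d) gctx[d] *= lr * inv;
        for (int j = 0; j < m; ++j) {
          double *col = Vp + (size_t)(c[j] - 1) * h;
          for (int d = 0; d < h; ++d) col[d] -= gctx[d];
        }
      }
    }
    epoch_loss[ep] = loss / npairs;
  }
  return List::create(_["V"] = V, _["U"] = U, _["epoch_loss"] = epoch_loss);
}
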