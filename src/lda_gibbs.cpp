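#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// tokens: 0-based vocabulary index per token position (all docs concatenated)
// doc:    0-based document index per token position
// Each sweep resamples every token's topic from
//   p(z = k | .) ~ (n_dk + alpha) * (n_kw + beta) / (n_k + V * beta)
// with the counts excluding the current token. Draws use R's RNG (unif_rand)
// so a set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export]]
List lda_gibbs(IntegerVector tokens, IntegerVector doc, int n_docs,
               int vocab_size, int K, double alpha, double beta,
               int n_iters, IntegerVector init_z) {
  const int N = tokens.size();
  IntegerVector z = clone(init_z);
  IntegerMatrix ndk(n_docs, K);
  IntegerMatrix nkw(K, vocab_size);
  IntegerVector nk(K);

  for (int i = 0; i < N; ++i) {
    ndk(doc[i], z[i])++;
    nkw(z[i], tokens[i])++;
    nk[z[i]]++;
  }

  std::vector<double> p(K);
  const double Vbeta = vocab_size * beta;
  for (int it = 0; it < n_iters; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = tokens[i];
      int k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + Vbeta);
        total += p[t];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int t = 0; t < K; ++t) {
        cum += p[t];
        if (u <= cum) { k = t; break; }
      }
      z[i] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }
  }
  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk);
}
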