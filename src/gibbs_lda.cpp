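#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs: list of integer vectors of 0-based word ids; V: vocabulary size;
// K topics; symmetric priors alpha (doc-topic) and beta (topic-word).
// Topic assignments are resampled token by token from the standard
// collapsed conditional
//   p(z = k) propto (n_dk + alpha) * (n_kw + beta) / (n_k + V beta).
// After burn_in sweeps, every thin-th sweep contributes one sample of
// the topic-word counts and topic totals; posterior means are formed
// over those samples. Randomness comes from R's RNG, so results are
// reproducible under set.seed().
//
// Returns: phi (K x V posterior-mean topic-word distributions),
// topic_weights (posterior-mean corpus topic proportions), loglik
// (per-sweep in-sample token log-likelihood), n_samples.
// [[Rcpp::export]]
List gibbs_lda_cpp(List docs, int V, int K, double alpha, double beta,
                   int iterations, int burn_in, int thin) {
  RNGScope scope;
  const int D = docs.size();

  std::vector<std::vector<int>> w(D), z(D);
  long total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
    total_tokens += dv.size();
  }

  std::vector<double> n_kw((size_t)K * V, 0.0);
  std::vector<double> n_dk((size_t)D * K, 0.0);
  std::vector<double> n_k(K, 0.0);

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      n_kw[(size_t)k * V + w[d][i]] += 1.0;
      n_dk[(size_t)d * K + k] += 1.0;
      n_k[k] += 1.0;
    }
  }

  std::vector<double> phi_acc((size_t)K * V, 0.0);
  std::vector<double> nk_acc(K, 0.0);
  std::vector<double> prob(K);
  NumericVector loglik(iterations);
  int n_samples = 0;
  const double Vbeta = V * beta;

  for (int it = 0; it < iterations; ++it) {
    for (int d = 0; d < D; ++d) {
      double *nd = &n_dk[(size_t)d * K];
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int wi = w[d][i];
        const int old_k = z[d][i];
        n_kw[(size_t)old_k * V + wi] -= 1.0;
        nd[old_k] -= 1.0;
        n_k[old_k] -= 1.0;

        double sum = 0.0;
        for (int k = 0; k < K; ++k) {
          sum += (nd[k] + alpha) *
                 (n_kw[(size_t)k * V + wi] + beta) / (n_k[k] + Vbeta);
          prob[k] = sum;
        }
        const double u = unif_rand() * sum;
        int new_k = 0;
        while (new_k < K - 1 && prob[new_k] < u) ++new_k;

        z[d][i] = new_k;
        n_kw[(size_t)new_k * V + wi] += 1.0;
        nd[new_k] += 1.0;
        n_k[new_k] += 1.0;
      }
    }

    // in-sample log-likelihood under current-count estimates
    double ll = 0.0;
    for (int d = 0; d < D; ++d) {
      const double *nd = &n_dk[(size_t)d * K];
      const double denom_d = (double)w[d].size() + K * alpha;
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int wi = w[d][i];
        double p = 0.0;
        for (int k = 0; k < K; ++k) {
          p += ((nd[k] + alpha) / denom_d) *
               ((n_kw[(size_t)k * V + wi] + beta) / (n_k[k] + Vbeta));
        }
        ll += std::log(p);
      }
    }
    loglik[it] = ll;

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_samples;
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + Vbeta;
        for (int v = 0; v < V; ++v)
          phi_acc[(size_t)k * V + v] +=
            (n_kw[(size_t)k * V + v] + beta) / denom;
        nk_acc[k] += n_k[k];
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  if (n_samples == 0) stop("no post-burn-in samples retained");

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      phi(k, v) = phi_acc[(size_t)k * V + v] / n_samples;

  NumericVector topic_weights(K);
  double nk_total = 0.0;
  for (int k = 0; k < K; ++k) nk_total += nk_acc[k];
  for (int k = 0; k < K; ++k) topic_weights[k] = nk_acc[k] / nk_total;

  return List::create(_["phi"] = phi,
                      _["topic_weights"] = topic_weights,
                      _["loglik"] = loglik,
                      _["n_samples"] = n_samples);
}
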