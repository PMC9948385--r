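#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// word, doc: parallel 0-based token vectors (doc-major, the canonical scan
// order). z_init: 0-based initial topic per token. Uses R's RNG so runs are
// reproducible with set.seed() from the calling R code.
//
// theta/phi are the smoothed conditional estimates averaged over retained
// samples (every `thin` sweeps after `burnin`). When collect_coassign is
// true (small corpora only) the token-by-token co-assignment frequency
// matrix over retained samples is returned as well.

static double collapsed_loglik(const IntegerMatrix &Cwk,
                               const IntegerMatrix &Cdk,
                               const IntegerVector &topic_tot,
                               const IntegerVector &doc_tot,
                               double alpha, double beta) {
  const int W = Cwk.nrow(), K = Cwk.ncol(), D = Cdk.nrow();
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    ll += R::lgammafn(W * beta) - W * R::lgammafn(beta);
    for (int w = 0; w < W; ++w) ll += R::lgammafn(Cwk(w, k) + beta);
    ll -= R::lgammafn(topic_tot[k] + W * beta);
  }
  for (int d = 0; d < D; ++d) {
    ll += R::lgammafn(K * alpha) - K * R::lgammafn(alpha);
    for (int k = 0; k < K; ++k) ll += R::lgammafn(Cdk(d, k) + alpha);
    ll -= R::lgammafn(doc_tot[d] + K * alpha);
  }
  return ll;
}

// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector word, IntegerVector doc, int D, int W,
                   int K, double alpha, double beta, int n_iter, int burnin,
                   int thin, IntegerVector z_init, bool collect_coassign) {
  const int T = word.size();
  IntegerVector z = clone(z_init);
  IntegerMatrix Cwk(W, K), Cdk(D, K);
  IntegerVector topic_tot(K), doc_tot(D);
  for (int i = 0; i < T; ++i) {
    Cwk(word[i], z[i])++;
    Cdk(doc[i], z[i])++;
    topic_tot[z[i]]++;
    doc_tot[doc[i]]++;
  }

  NumericMatrix theta_sum(D, K), phi_sum(K, W);
  NumericMatrix coassign;
  if (collect_coassign) coassign = NumericMatrix(T, T);
  NumericVector loglik(n_iter);
  std::vector<double> p(K);
  int n_samples = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < T; ++i) {
      const int w = word[i], d = doc[i], k_old = z[i];
      Cwk(w, k_old)--;
      Cdk(d, k_old)--;
      topic_tot[k_old]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (Cwk(w, k) + beta) / (topic_tot[k] + W * beta) *
               (Cdk(d, k) + alpha);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int k_new = 0;
      double cum = p[0];
      while (k_new < K - 1 && u > cum) cum += p[++k_new];
      z[i] = k_new;
      Cwk(w, k_new)++;
      Cdk(d, k_new)++;
      topic_tot[k_new]++;
    }
    loglik[it] = collapsed_loglik(Cwk, Cdk, topic_tot, doc_tot, alpha, beta);
    if (it >= burnin && (it - burnin) % thin == 0) {
      ++n_samples;
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) +=
              (Cdk(d, k) + alpha) / (doc_tot[d] + K * alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < W; ++w)
          phi_sum(k, w) += (Cwk(w, k) + beta) / (topic_tot[k] + W * beta);
      if (collect_coassign) {
        for (int i = 0; i < T; ++i)
          for (int j = 0; j < T; ++j)
            if (z[i] == z[j]) coassign(i, j) += 1.0;
      }
    }
  }

  NumericMatrix theta(D, K), phi(K, W);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = theta_sum(d, k) / n_samples;
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < W; ++w) phi(k, w) = phi_sum(k, w) / n_samples;
  if (collect_coassign && n_samples > 0)
    for (int i = 0; i < T; ++i)
      for (int j = 0; j < T; ++j) coassign(i, j) /= n_samples;

  List out = List::create(Named("theta") = theta, Named("phi") = phi,
                          Named("z") = z, Named("loglik") = loglik,
                          Named("n_samples") = n_samples);
  if (collect_coassign) out["coassign"] = coassign;
  return out;
}
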