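#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// docs: list of integer vectors of 0-based term ids (one per document).
// Uses R's RNG so chains are reproducible from set.seed(); the scan order is
// fixed (documents in index order, positions left to right) for the same
// reason. After burn_in sweeps the per-sweep count tables n_{d,t} and
// n_{t,w} are accumulated; point estimates are formed in R from the
// averaged tables.
//
// check_counts: when true, verify after every sweep that
// sum_t n_{d,t} == l_d for every d and sum_{t,w} n_{t,w} == sum_d l_d
// (count conservation), aborting on violation.
// [[Rcpp::export]]
List gibbs_lda_cpp(List docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in, bool check_counts = false) {
  const int D = docs.size();
  if (K < 1) stop("K must be >= 1");
  if (V < 1) stop("vocabulary is empty");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");

  std::vector<IntegerVector> w(D);
  long total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    w[d] = as<IntegerVector>(docs[d]);
    total_tokens += w[d].size();
    for (int j = 0; j < w[d].size(); ++j) {
      if (w[d][j] < 0 || w[d][j] >= V) stop("term id out of range in document %d", d + 1);
    }
  }
  if (total_tokens == 0) stop("all documents are empty");

  IntegerMatrix nd(D, K);      // n_{d,t}
  IntegerMatrix nw(K, V);      // n_{t,w}
  IntegerVector nt(K);         // n_t
  std::vector<std::vector<int> > z(D);

  // initialize assignments uniformly at random
  for (int d = 0; d < D; ++d) {
    const int ld = w[d].size();
    z[d].resize(ld);
    for (int j = 0; j < ld; ++j) {
      int t = (int)(unif_rand() * K);
      if (t == K) t = K - 1;
      z[d][j] = t;
      nd(d, t) += 1;
      nw(t, w[d][j]) += 1;
      nt[t] += 1;
    }
  }

  NumericMatrix sum_nd(D, K);
  NumericMatrix sum_nw(K, V);
  std::vector<double> p(K);
  const double Vbeta = V * beta;
  int retained = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      const int ld = w[d].size();
      for (int j = 0; j < ld; ++j) {
        const int wi = w[d][j];
        int t = z[d][j];
        nd(d, t) -= 1; nw(t, wi) -= 1; nt[t] -= 1;

        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          total += (nd(d, k) + alpha) * (nw(k, wi) + beta) / (nt[k] + Vbeta);
          p[k] = total;
        }
        const double u = unif_rand() * total;
        int tnew = 0;
        while (tnew < K - 1 && p[tnew] < u) ++tnew;

        z[d][j] = tnew;
        nd(d, tnew) += 1; nw(tnew, wi) += 1; nt[tnew] += 1;
      }
    }

    if (check_counts) {
      long tot = 0;
      for (int d = 0; d < D; ++d) {
        long s = 0;
        for (int k = 0; k < K; ++k) s += nd(d, k);
        if (s != (long)w[d].size()) stop("count conservation violated for document %d", d + 1);
      }
      for (int k = 0; k < K; ++k) {
        long s = 0;
        for (int v = 0; v < V; ++v) s += nw(k, v);
        if (s != (long)nt[k]) stop("topic count table inconsistent for topic %d", k + 1);
        tot += s;
      }
      if (tot != total_tokens) stop("global count conservation violated");
    }

    if (iter >= burn_in) {
      ++retained;
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k) sum_nd(d, k) += nd(d, k);
      for (int k = 0; k < K; ++k)
        for (int v = 0; v < V; ++v) sum_nw(k, v) += nw(k, v);
    }

    if (iter % 64 == 0) checkUserInterrupt();
  }

  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) sum_nd(d, k) /= retained;
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) sum_nw(k, v) /= retained;

  List zz(D);
  for (int d = 0; d < D; ++d) zz[d] = IntegerVector(z[d].begin(), z[d].end());

  return List::create(_["avg_nd"] = sum_nd, _["avg_nw"] = sum_nw,
                      _["z"] = zz, _["retained"] = retained);
}
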