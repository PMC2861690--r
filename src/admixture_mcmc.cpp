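// Gibbs sampler for the admixture model of population structure:
// latent origin Z for every allele copy, Dirichlet conditional updates for
// cluster allele frequencies P and individual memberships Q, and a
// Metropolis random walk for the shared Dirichlet concentration alpha with
// a Uniform(0, alphaMax] prior.  Uses R's RNG so set.seed() on the R side
// fixes the draws.
#include <Rcpp.h>
using namespace Rcpp;

static inline void rdirichlet_row(std::vector<double>& out,
                                  const std::vector<double>& shape) {
  double s = 0.0;
  for (size_t j = 0; j < shape.size(); ++j) {
    out[j] = R::rgamma(shape[j], 1.0);
    s += out[j];
  }
  if (s <= 0.0) {  // numerically degenerate; fall back to uniform
    for (size_t j = 0; j < shape.size(); ++j) out[j] = 1.0 / shape.size();
  } else {
    for (size_t j = 0; j < shape.size(); ++j) out[j] /= s;
  }
}

// alleles: nInd x (2*nLoci) integer matrix, entries 1..nAlleles[l], 0 = missing
// [[Rcpp::export(name = ".admixtureMcmcCpp")]]
List admixtureMcmcCpp(IntegerMatrix alleles, IntegerVector nAlleles,
                      int K, int burnin, int iters, int thin,
                      double lambda, double alphaMax, double alphaSd,
                      double alphaInit) {
  const int N = alleles.nrow();
  const int L = nAlleles.size();
  RNGScope scope;

  // state
  std::vector<std::vector<double>> P(L);           // P[l]: K x A_l row-major
  std::vector<double> Q(N * K, 1.0 / K);
  std::vector<int> Z(N * L * 2, 0);
  double alpha = alphaInit;

  for (int l = 0; l < L; ++l) P[l].assign(K * nAlleles[l], 1.0 / nAlleles[l]);

  // accumulators
  std::vector<double> Qsum(N * K, 0.0);
  std::vector<std::vector<double>> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l].assign(K * nAlleles[l], 0.0);
  std::vector<double> trace;
  double alphaSum = 0.0;
  int nSaved = 0;

  std::vector<double> prob(K), qrow(K), shape;
  std::vector<int> mcount(N * K), ncount;

  const int total = burnin + iters;
  for (int it = 0; it < total; ++it) {
    // --- Z update (and membership counts) ---
    std::fill(mcount.begin(), mcount.end(), 0);
    for (int l = 0; l < L; ++l) {
      const int A = nAlleles[l];
      for (int c = 0; c < 2; ++c) {
        for (int i = 0; i < N; ++i) {
          const int a = alleles(i, 2 * l + c);
          if (a == 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q[i * K + k] * P[l][k * A + (a - 1)];
            s += prob[k];
          }
          int k = K - 1;
          if (s > 0.0) {
            double u = R::runif(0.0, s), acc = 0.0;
            for (int j = 0; j < K; ++j) {
              acc += prob[j];
              if (u <= acc) { k = j; break; }
            }
          } else {
            k = (int)(R::unif_rand() * K); if (k == K) k = K - 1;
          }
          Z[(i * L + l) * 2 + c] = k;
          mcount[i * K + k] += 1;
        }
      }
    }

    // --- P update ---
    for (int l = 0; l < L; ++l) {
      const int A = nAlleles[l];
      ncount.assign(K * A, 0);
      for (int c = 0; c < 2; ++c)
        for (int i = 0; i < N; ++i) {
          const int a = alleles(i, 2 * l + c);
          if (a == 0) continue;
          ncount[Z[(i * L + l) * 2 + c] * A + (a - 1)] += 1;
        }
      shape.resize(A);
      std::vector<double> row(A);
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a) shape[a] = lambda + ncount[k * A + a];
        rdirichlet_row(row, shape);
        for (int a = 0; a < A; ++a) P[l][k * A + a] = row[a];
      }
    }

    // --- Q update ---
    if (K == 1) {
      std::fill(Q.begin(), Q.end(), 1.0);
    } else {
      shape.resize(K);
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < K; ++k) shape[k] = alpha + mcount[i * K + k];
        rdirichlet_row(qrow, shape);
        for (int k = 0; k < K; ++k) Q[i * K + k] = qrow[k];
      }
    }

    // --- alpha Metropolis update ---
    if (K > 1) {
      double aprop = alpha + R::rnorm(0.0, alphaSd);
      if (aprop > 0.0 && aprop <= alphaMax) {
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(Q[i * K + k], 1e-300));
        double logr =
          N * (R::lgammafn(K * aprop) - K * R::lgammafn(aprop)) -
          N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
          (aprop - alpha) * slq;
        if (std::log(R::unif_rand()) < logr) alpha = aprop;
      }
    }

    // --- log-likelihood and accumulation ---
    if (it >= burnin) {
      double ll = 0.0;
      for (int l = 0; l < L; ++l) {
        const int A = nAlleles[l];
        for (int c = 0; c < 2; ++c)
          for (int i = 0; i < N; ++i) {
            const int a = alleles(i, 2 * l + c);
            if (a == 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += Q[i * K + k] * P[l][k * A + (a - 1)];
            ll += std::log(std::max(s, 1e-300));
          }
      }
      trace.push_back(ll);
      if ((it - burnin) % thin == 0) {
        for (int j = 0; j < N * K; ++j) Qsum[j] += Q[j];
        for (int l = 0; l < L; ++l)
          for (size_t j = 0; j < P[l].size(); ++j) Psum[l][j] += P[l][j];
        alphaSum += alpha;
        ++nSaved;
      }
    }
  }

  NumericMatrix Qmean(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum[i * K + k] / nSaved;
  List Pmean(L);
  for (int l = 0; l < L; ++l) {
    const int A = nAlleles[l];
    NumericMatrix pm(K, A);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < A; ++a) pm(k, a) = Psum[l][k * A + a] / nSaved;
    // renormalise posterior means to exact simplices
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) s += pm(k, a);
      for (int a = 0; a < A; ++a) pm(k, a) /= s;
    }
    Pmean[l] = pm;
  }
  // exact simplex for Q rows too
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qmean(i, k);
    for (int k = 0; k < K; ++k) Qmean(i, k) /= s;
  }

  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["alpha"] = alphaSum / nSaved,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
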