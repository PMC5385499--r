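#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent Dirichlet(1)
// priors on per-cluster allele frequencies. Genotypes are integer allele
// codes 1..J[l] per locus (0 = missing). Allele-copy assignments z are
// sampled conditional on cluster frequencies phi and individual ancestry q;
// q ~ Dirichlet(alpha + counts); alpha gets a Metropolis random-walk update
// with a uniform(0, 10) prior. The no-admixture variant assigns whole
// individuals to one cluster and reports posterior membership frequencies.
//
// Uses R's RNG throughout, so results are reproducible under set.seed().

static int sample_cat(const std::vector<double> &w) {
  double tot = 0.0;
  for (double v : w) tot += v;
  double u = R::runif(0.0, tot);
  double acc = 0.0;
  for (int k = 0; k < (int)w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return (int)w.size() - 1;
}

static void rdirichlet(std::vector<double> &out, const std::vector<double> &a) {
  double tot = 0.0;
  for (size_t k = 0; k < a.size(); ++k) {
    out[k] = R::rgamma(a[k], 1.0);
    if (out[k] < 1e-300) out[k] = 1e-300;
    tot += out[k];
  }
  for (size_t k = 0; k < a.size(); ++k) out[k] /= tot;
}

// [[Rcpp::export(name = ".gibbs_admixture")]]
List gibbs_admixture(IntegerMatrix geno, IntegerVector nalleles, int K,
                     int burnin, int iters, double alpha_init,
                     bool admixture, int thin) {
  const int n = geno.nrow();
  const int L = nalleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");

  // state
  std::vector<std::vector<double>> phi(L); // phi[l][k * J + j]
  for (int l = 0; l < L; ++l) phi[l].assign(K * nalleles[l], 1.0 / nalleles[l]);
  NumericMatrix q(n, K);
  std::fill(q.begin(), q.end(), 1.0 / K);
  IntegerMatrix z(n, 2 * L);
  double alpha = alpha_init;

  // workspaces
  std::vector<double> w(K), qa(K), qtmp(K);
  std::vector<std::vector<double>> counts(L);
  for (int l = 0; l < L; ++l) counts[l].assign(K * nalleles[l], 0.0);
  std::vector<double> nz(n * K, 0.0);

  // init z uniformly
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c)
      z(i, c) = (geno(i, c) > 0) ? (int)(R::unif_rand() * K) : -1;

  NumericMatrix qsum(n, K);
  int nrec = 0;
  std::vector<double> ll_trace;
  int total = burnin + iters;
  double accept_alpha = 0.0; int prop_alpha = 0;

  for (int t = 0; t < total; ++t) {
    // --- phi | z ---
    for (int l = 0; l < L; ++l)
      std::fill(counts[l].begin(), counts[l].end(), 1.0); // Dirichlet(1) prior
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a > 0) counts[l][z(i, 2 * l + c) * nalleles[l] + (a - 1)] += 1.0;
        }
    for (int l = 0; l < L; ++l) {
      int J = nalleles[l];
      std::vector<double> par(J), out(J);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < J; ++j) par[j] = counts[l][k * J + j];
        rdirichlet(out, par);
        for (int j = 0; j < J; ++j) phi[l][k * J + j] = out[j];
      }
    }

    if (admixture) {
      // --- z | phi, q ---
      std::fill(nz.begin(), nz.end(), 0.0);
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            for (int k = 0; k < K; ++k)
              w[k] = q(i, k) * phi[l][k * nalleles[l] + (a - 1)];
            int k = sample_cat(w);
            z(i, 2 * l + c) = k;
            nz[i * K + k] += 1.0;
          }
      // --- q | z, alpha ---
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) qa[k] = alpha + nz[i * K + k];
        rdirichlet(qtmp, qa);
        for (int k = 0; k < K; ++k) q(i, k) = qtmp[k];
      }
      // --- alpha Metropolis (uniform(0,10) prior) ---
      if (K > 1) {
        double prop = alpha + R::norm_rand() * 0.05;
        ++prop_alpha;
        if (prop > 0.0 && prop < 10.0) {
          double logr = 0.0;
          logr += n * (R::lgammafn(K * prop) - K * R::lgammafn(prop));
          logr -= n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
          double slog = 0.0;
          for (int i = 0; i < n; ++i)
            for (int k = 0; k < K; ++k) slog += std::log(q(i, k));
          logr += (prop - alpha) * slog;
          if (std::log(R::unif_rand()) < logr) { alpha = prop; accept_alpha += 1.0; }
        }
      }
    } else {
      // --- whole-individual assignment; q holds membership indicators ---
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) w[k] = 0.0;
        for (int k = 0; k < K; ++k) {
          double lp = 0.0;
          for (int l = 0; l < L; ++l)
            for (int c = 0; c < 2; ++c) {
              int a = geno(i, 2 * l + c);
              if (a > 0) lp += std::log(phi[l][k * nalleles[l] + (a - 1)]);
            }
          w[k] = lp;
        }
        double mx = w[0];
        for (int k = 1; k < K; ++k) if (w[k] > mx) mx = w[k];
        for (int k = 0; k < K; ++k) w[k] = std::exp(w[k] - mx);
        int k = sample_cat(w);
        for (int kk = 0; kk < K; ++kk) q(i, kk) = (kk == k) ? 1.0 : 0.0;
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c)
            if (geno(i, 2 * l + c) > 0) z(i, 2 * l + c) = k;
      }
    }

    // --- record ---
    if (t >= burnin && ((t - burnin) % thin == 0)) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += q(i, k) * phi[l][k * nalleles[l] + (a - 1)];
            ll += std::log(s);
          }
      ll_trace.push_back(ll);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q(i, k);
      ++nrec;
    }
  }

  NumericMatrix Q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = qsum(i, k) / std::max(nrec, 1);
  return List::create(
    _["Q"] = Q,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["mean_loglik"] = ll_trace.empty() ? NA_REAL :
      std::accumulate(ll_trace.begin(), ll_trace.end(), 0.0) / ll_trace.size(),
    _["alpha"] = alpha,
    _["alpha_accept"] = prop_alpha > 0 ? accept_alpha / prop_alpha : NA_REAL);
}
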