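#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batch Monte Carlo for the sequential Wald test on one SNP, sampling the
// sufficient statistics (x'x, beta-hat, S) directly rather than raw data.
//
// For a centered genotype x with sum of squares x'x and Gaussian errors with
// covariance Sigma, the joint law of the statistics the test consumes is
//   z = u'E ~ MVN(0, Sigma),  u = x_c / ||x_c||
//   (n-1) S = x'x bb' + sqrt(x'x) (b z' + z b') + z z' + M,
//   M ~ Wishart(Sigma, n - 2)  independent of z (Bartlett decomposition)
//   beta_hat = b + z / sqrt(x'x)
// where b is the true effect vector. Genotype class counts (n0, n1, n2) are
// multinomial, which fixes x'x exactly without materializing x. All draws use
// R's RNG so results are reproducible under set.seed().
//
// zero_sets: list (one element per stage) of 0-based integer matrices,
// columns = trait subsets constrained to zero under each component null.
// Returns a B x n_stage matrix of stage-wise IU p-values.

// [[Rcpp::export(name = ".mc_seq_batch_cpp")]]
NumericMatrix mc_seq_batch_cpp(int n, int B, int p,
                               double rho, double h2,
                               NumericVector effect_profile,
                               double maf_lo, double maf_hi,
                               List zero_sets) {
  const int n_stage = zero_sets.size();
  NumericMatrix out(B, n_stage);

  arma::vec prof(effect_profile.begin(), p);
  // error covariance: per-trait error variance 1 - h2_j keeps total
  // phenotypic variance at 1, h2_j = h2 * profile_j^2
  arma::vec d(p);
  for (int j = 0; j < p; ++j) d(j) = 1.0 - h2 * prof(j) * prof(j);
  arma::mat Sigma(p, p);
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < p; ++k)
      Sigma(j, k) = (j == k) ? d(j) : rho * std::sqrt(d(j) * d(k));
  arma::mat L = arma::chol(Sigma, "lower");

  // pre-extract subset index vectors
  std::vector< std::vector<arma::uvec> > subs(n_stage);
  std::vector<double> stage_df(n_stage);
  for (int s = 0; s < n_stage; ++s) {
    IntegerMatrix zm = zero_sets[s];
    stage_df[s] = zm.nrow();
    subs[s].resize(zm.ncol());
    for (int c = 0; c < zm.ncol(); ++c) {
      arma::uvec idx(zm.nrow());
      for (int r = 0; r < zm.nrow(); ++r) idx(r) = (arma::uword) zm(r, c);
      subs[s][c] = idx;
    }
  }

  arma::vec z(p), b(p), bhat(p);
  arma::mat A(p, p), M(p, p), S(p, p);

  for (int rep = 0; rep < B; ++rep) {
    // genotype class counts and centered sum of squares
    double xtx = 0.0, f = 0.0;
    while (xtx <= 0.0) {
      f = R::runif(maf_lo, maf_hi);
      double p2 = f * f;
      double n2 = R::rbinom(n, p2);
      double n1 = R::rbinom(n - n2, (2.0 * f * (1.0 - f)) / (1.0 - p2));
      double n0 = n - n1 - n2;
      double m = (n1 + 2.0 * n2) / n;
      xtx = n0 * m * m + n1 * (1.0 - m) * (1.0 - m) + n2 * (2.0 - m) * (2.0 - m);
    }
    double varx = 2.0 * f * (1.0 - f);
    double b1 = (h2 > 0.0) ? std::sqrt(h2 / varx) : 0.0;
    b = b1 * prof;

    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    z = L * z;

    // Wishart(Sigma, n - 2) via Bartlett
    A.zeros();
    for (int j = 0; j < p; ++j) {
      A(j, j) = std::sqrt(R::rchisq((double)(n - 2 - j)));
      for (int k = 0; k < j; ++k) A(j, k) = norm_rand();
    }
    M = L * A;
    M = M * M.t();

    double sx = std::sqrt(xtx);
    S = (xtx * (b * b.t()) + sx * (b * z.t() + z * b.t()) + z * z.t() + M) /
        (double)(n - 1);
    bhat = b + z / sx;

    for (int s = 0; s < n_stage; ++s) {
      double wmin = R_PosInf;
      for (size_t c = 0; c < subs[s].size(); ++c) {
        const arma::uvec& K = subs[s][c];
        arma::vec bK = bhat(K);
        arma::vec sol = arma::solve(S.submat(K, K), bK,
                                    arma::solve_opts::likely_sympd);
        double w = xtx * arma::dot(bK, sol);
        if (w < wmin) wmin = w;
      }
      out(rep, s) = R::pchisq(wmin, stage_df[s], 0, 0);
    }
  }
  return out;
}
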