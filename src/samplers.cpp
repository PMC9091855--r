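#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// draw from a scaled inverse chi-squared distribution with df nu and scale s2
static inline double rscinvchisq(double nu, double s2) {
  double chi = R::rchisq(nu);
  if (chi <= 0) chi = 1e-300;
  return nu * s2 / chi;
}

// Gibbs sampler for the four-component normal-mixture SNP-effect model
// (BayesR-style). X is the centered, imputed genotype matrix (n x m),
// y the adjusted phenotype. Component k has effect variance gamma[k] times a
// reference variance: either the (fixed) phenotypic variance of y or the
// current genetic variance parameter, selected by ref_genetic.
// keep_iters: sorted 1-based iteration indices to retain.
// [[Rcpp::export]]
List bayesr_gibbs(const NumericMatrix X, const NumericVector y,
                  const NumericVector gamma_frac, const NumericVector alpha,
                  const bool ref_genetic,
                  const double df_g, const double scale_g,
                  const double df_e, const double scale_e,
                  const int n_iter, const IntegerVector keep_iters) {
  const int n = X.nrow(), m = X.ncol(), K = gamma_frac.size();
  const int n_out = keep_iters.size();

  // precompute x_j' x_j
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    const double* xj = X.begin() + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double ybar = mean(y);
  double vary = var(y);
  if (!(vary > 0)) stop("phenotype variance is zero; nothing to fit");

  std::vector<double> beta(m, 0.0), e(n);
  std::vector<int> comp(m, 0);               // 0-based class index, 0 = null
  double mu = ybar;
  double sigma2_e = 0.5 * vary;
  double sigma2_g = 0.5 * vary;
  std::vector<double> pi(K);
  double asum = sum(alpha);
  for (int k = 0; k < K; ++k) pi[k] = alpha[k] / asum;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  NumericMatrix out_beta(n_out, m);
  IntegerMatrix out_comp(n_out, m);
  NumericMatrix out_pi(n_out, K);
  NumericVector out_mu(n_out), out_s2e(n_out), out_s2g(n_out);

  std::vector<double> logl(K), prob(K);
  std::vector<int> ord(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  int keep_ptr = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + std::sqrt(sigma2_e / n) * R::norm_rand();
    double shift = mu - mu_new;
    for (int i = 0; i < n; ++i) e[i] += shift;
    mu = mu_new;

    const double sigma2_ref = ref_genetic ? sigma2_g : vary;

    // random SNP update order
    for (int j = m - 1; j > 0; --j) {
      int k = (int)std::floor(R::unif_rand() * (j + 1));
      std::swap(ord[j], ord[k]);
    }

    std::vector<int> cls_count(K, 0);
    for (int jj = 0; jj < m; ++jj) {
      const int j = ord[jj];
      const double* xj = X.begin() + (size_t)j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xtx[j] * beta[j];

      double lmax = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double v = gamma_frac[k] * sigma2_ref;
        double ll;
        if (v <= 0.0) {
          ll = std::log(pi[k] + 1e-300);
        } else {
          double c = xtx[j] * v + sigma2_e;
          ll = std::log(pi[k] + 1e-300) - 0.5 * std::log(c / sigma2_e) +
               0.5 * rhs * rhs * v / (sigma2_e * c);
        }
        logl[k] = ll;
        if (ll > lmax) lmax = ll;
      }
      double psum = 0.0;
      for (int k = 0; k < K; ++k) { prob[k] = std::exp(logl[k] - lmax); psum += prob[k]; }
      double u = R::unif_rand() * psum, acc = 0.0;
      int knew = K - 1;
      for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { knew = k; break; } }

      double beta_new = 0.0;
      double v = gamma_frac[knew] * sigma2_ref;
      if (v > 0.0) {
        double c = xtx[j] * v + sigma2_e;
        double mean_post = rhs * v / c;
        double sd_post = std::sqrt(sigma2_e * v / c);
        beta_new = mean_post + sd_post * R::norm_rand();
      }
      if (beta_new != beta[j]) {
        double d = beta[j] - beta_new;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * d;
      }
      beta[j] = beta_new;
      comp[j] = knew;
      ++cls_count[knew];
    }

    // mixture proportions ~ Dirichlet(alpha + counts)
    double gsum = 0.0;
    for (int k = 0; k < K; ++k) {
      pi[k] = R::rgamma(alpha[k] + cls_count[k], 1.0);
      gsum += pi[k];
    }
    for (int k = 0; k < K; ++k) pi[k] /= gsum;

    // genetic variance (scale parameter of the mixture) if tracked
    if (ref_genetic) {
      double ss = 0.0; int m_nz = 0;
      for (int j = 0; j < m; ++j) {
        if (comp[j] > 0) { ss += beta[j] * beta[j] / gamma_frac[comp[j]]; ++m_nz; }
      }
      sigma2_g = rscinvchisq(df_g + m_nz, (df_g * scale_g + ss) / (df_g + m_nz));
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = rscinvchisq(df_e + n, (df_e * scale_e + sse) / (df_e + n));

    if (!std::isfinite(sigma2_e) || !std::isfinite(mu)) {
      stop("sampler diverged (non-finite state) at iteration %d", it);
    }

    if (keep_ptr < n_out && it == keep_iters[keep_ptr]) {
      for (int j = 0; j < m; ++j) {
        out_beta(keep_ptr, j) = beta[j];
        out_comp(keep_ptr, j) = comp[j] + 1;
      }
      for (int k = 0; k < K; ++k) out_pi(keep_ptr, k) = pi[k];
      out_mu[keep_ptr] = mu;
      out_s2e[keep_ptr] = sigma2_e;
      if (ref_genetic) {
        out_s2g[keep_ptr] = sigma2_g;
      } else {
        // realized genetic variance var(X beta) = var(y - mu - e)
        double sm = 0.0, sq = 0.0;
        for (int i = 0; i < n; ++i) {
          double g = y[i] - mu - e[i];
          sm += g; sq += g * g;
        }
        out_s2g[keep_ptr] = (sq - sm * sm / n) / (n - 1);
      }
      ++keep_ptr;
    }
  }

  return List::create(_["beta"] = out_beta, _["comp"] = out_comp,
                      _["pi"] = out_pi, _["mu"] = out_mu,
                      _["sigma2_e"] = out_s2e, _["sigma2_g"] = out_s2g);
}

// walk along SNPs copying from one of the two parental haplotype columns,
// switching template between SNP j-1 and j with probability sw[j]
static inline void make_gamete(const int* hA, const int* hB, const double* sw,
                               int m, int* child) {
  int t = (R::unif_rand() < 0.5) ? 0 : 1;
  for (int j = 0; j < m; ++j) {
    if (j > 0 && R::unif_rand() < sw[j]) t = 1 - t;
    child[j] = t ? hB[j] : hA[j];
  }
}

// Transmit haplotypes to a batch of offspring, in place. hap1/hap2 are
// m x N matrices (column = individual); children receive a recombinant
// paternal gamete into hap1 and maternal gamete into hap2. Parents must
// already carry haplotypes. Indices are 1-based.
// [[Rcpp::export]]
void transmit_inplace(IntegerMatrix hap1, IntegerMatrix hap2,
                      const IntegerVector child, const IntegerVector sire,
                      const IntegerVector dam, const NumericVector sw) {
  const int m = hap1.nrow();
  for (int i = 0; i < child.size(); ++i) {
    int c = child[i] - 1, s = sire[i] - 1, d = dam[i] - 1;
    int* h1 = hap1.begin(); int* h2 = hap2.begin();
    make_gamete(h1 + (size_t)s * m, h2 + (size_t)s * m, sw.begin(), m, h1 + (size_t)c * m);
    make_gamete(h1 + (size_t)d * m, h2 + (size_t)d * m, sw.begin(), m, h2 + (size_t)c * m);
  }
}

// Full gene-drop through a pedigree sorted so parents and donors precede
// their users. pool is m x H (column = founder haplotype). founder[i] TRUE:
// individual i draws two pool columns with replacement. Otherwise each
// parental slot yields a recombinant gamete if the parent index is > 0; a
// missing parent is replaced by one haplotype (chosen at random) of a random
// donor from donors_sire/donors_dam[i] (1-based individual indices), falling
// back to a random pool column when the donor list is empty.
// Returns the m x n matrix of genotype counts.
// [[Rcpp::export]]
IntegerMatrix gene_drop_cpp(const IntegerMatrix pool, const NumericVector sw,
                            const IntegerVector sire, const IntegerVector dam,
                            const LogicalVector founder,
                            const List donors_sire, const List donors_dam) {
  const int m = pool.nrow(), H = pool.ncol(), n = sire.size();
  IntegerMatrix hap1(m, n), hap2(m, n), geno(m, n);
  int* h1 = hap1.begin(); int* h2 = hap2.begin();
  const int* pl = pool.begin();

  for (int i = 0; i < n; ++i) {
    int* c1 = h1 + (size_t)i * m;
    int* c2 = h2 + (size_t)i * m;
    if (founder[i]) {
      int a = (int)std::floor(R::unif_rand() * H);
      int b = (int)std::floor(R::unif_rand() * H);
      std::copy(pl + (size_t)a * m, pl + (size_t)a * m + m, c1);
      std::copy(pl + (size_t)b * m, pl + (size_t)b * m + m, c2);
    } else {
      // paternal slot -> hap1
      if (sire[i] > 0) {
        size_t s = sire[i] - 1;
        make_gamete(h1 + s * m, h2 + s * m, sw.begin(), m, c1);
      } else {
        IntegerVector cand = donors_sire[i];
        if (cand.size() > 0) {
          size_t d = cand[(int)std::floor(R::unif_rand() * cand.size())] - 1;
          const int* src = (R::unif_rand() < 0.5) ? h1 + d * m : h2 + d * m;
          std::copy(src, src + m, c1);
        } else {
          size_t a = (size_t)std::floor(R::unif_rand() * H);
          std::copy(pl + a * m, pl + a * m + m, c1);
        }
      }
      // maternal slot -> hap2
      if (dam[i] > 0) {
        size_t d = dam[i] - 1;
        make_gamete(h1 + d * m, h2 + d * m, sw.begin(), m, c2);
      } else {
        IntegerVector cand = donors_dam[i];
        if (cand.size() > 0) {
          size_t dd = cand[(int)std::floor(R::unif_rand() * cand.size())] - 1;
          const int* src = (R::unif_rand() < 0.5) ? h1 + dd * m : h2 + dd * m;
          std::copy(src, src + m, c2);
        } else {
          size_t a = (size_t)std::floor(R::unif_rand() * H);
          std::copy(pl + a * m, pl + a * m + m, c2);
        }
      }
    }
    for (int j = 0; j < m; ++j) geno(j, i) = c1[j] + c2[j];
  }
  return geno;
}

// Single meiosis, exposed for the forward simulator and for tests.
// [[Rcpp::export]]
IntegerVector meiosis_cpp(const IntegerVector hapA, const IntegerVector hapB,
                          const NumericVector sw) {
  const int m = hapA.size();
  IntegerVector child(m);
  make_gamete(hapA.begin(), hapB.begin(), sw.begin(), m, child.begin());
  return child;
}
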