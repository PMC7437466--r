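// Variable-rates multivariate Brownian motion: matrix-normal likelihood via
// the postorder pruning algorithm (linear in the number of tips per
// evaluation) and a reversible-jump Metropolis-Hastings sampler over the set
// of rate-scaled branches, their scalars, and the trait covariance R
// (parameterised by its Cholesky factor).
//
// The trait covariance enters the likelihood only through c' R^-1 c terms
// over independent contrasts, so traits are whitened once per R update
// (Z = Y L^-T with R = L L') and the pruning pass runs with an identity
// trait covariance; per-iteration cost is then O(nodes x q).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct PruneWork {
  arma::mat val;   // q x nnode partial means (whitened traits, col per node)
  arma::vec vv;    // nnode accumulated variances
  std::vector<char> has;
  void resize(int q, int nnode) {
    val.set_size(q, nnode);
    vv.set_size(nnode);
    has.assign(nnode, 0);
  }
};

// Profile (GLS-mean) log-likelihood of whitened traits Zt (q x N) under BM
// with per-edge variances elen[e] * rates[e]. Edges must be in postorder.
static double prune_loglik_white(const arma::mat& Zt, const arma::imat& edge,
                                 const arma::vec& elen, const arma::vec& rates,
                                 int ntip, double logdetR, PruneWork& w) {
  const int q = Zt.n_rows, N = Zt.n_cols, E = edge.n_rows;
  std::fill(w.has.begin(), w.has.end(), 0);
  std::memcpy(w.val.memptr(), Zt.memptr(), sizeof(double) * q * ntip);
  for (int i = 0; i < ntip; ++i) { w.vv(i) = 0.0; w.has[i] = 1; }
  double logdetC = 0.0, quad = 0.0;
  for (int e = 0; e < E; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double u = w.vv(c) + elen(e) * rates(e);
    double* vp = w.val.colptr(p);
    const double* vc = w.val.colptr(c);
    if (!w.has[p]) {
      std::memcpy(vp, vc, sizeof(double) * q);
      w.vv(p) = u;
      w.has[p] = 1;
    } else {
      const double vvp = w.vv(p);
      const double varc = vvp + u;
      const double inv = 1.0 / varc;
      double s = 0.0;
      for (int j = 0; j < q; ++j) {
        const double d = vp[j] - vc[j];
        s += d * d;
        vp[j] = (u * vp[j] + vvp * vc[j]) * inv;
      }
      logdetC += std::log(varc);
      quad += s * inv;
      w.vv(p) = vvp * u * inv;
    }
  }
  const int root = ntip;  // ape root id = ntip + 1
  if (w.vv(root) <= 0.0) return -arma::datum::inf;
  logdetC += std::log(w.vv(root));
  return -0.5 * (q * logdetC + N * logdetR + quad +
                 N * q * std::log(2.0 * M_PI));
}

// whitened traits, one column per tip: Zt = L^-1 Y'
static arma::mat whiten_t(const arma::mat& Yt, const arma::mat& L) {
  return arma::solve(arma::trimatl(L), Yt);
}

// [[Rcpp::export]]
double prune_loglik_cpp(const arma::mat& Y, const arma::imat& edge,
                        const arma::vec& elen, const arma::vec& rates,
                        int ntip, int nnode, const arma::mat& R) {
  PruneWork w;
  w.resize(Y.n_cols, nnode);
  arma::mat L = arma::chol(R, "lower");
  const double logdetR = 2.0 * arma::accu(arma::log(L.diag()));
  return prune_loglik_white(whiten_t(Y.t(), L), edge, elen, rates, ntip,
                            logdetR, w);
}

static double lnorm_logpdf_on_log(double logr, double m, double s) {
  const double z = (logr - m) / s;
  return -0.5 * z * z - std::log(s) - 0.5 * std::log(2.0 * M_PI);
}

// [[Rcpp::export]]
List vr_mcmc_cpp(const arma::mat& Y, const arma::imat& edge,
                 const arma::vec& elen, int ntip, int nnode, List cfg) {
  const int q = Y.n_cols, E = edge.n_rows;
  const int iterations = as<int>(cfg["iterations"]);
  const int burnin = as<int>(cfg["burnin"]);
  const int thin = as<int>(cfg["thin"]);
  const double beta = as<double>(cfg["beta"]);
  const bool fix_scalars = as<bool>(cfg["fix_scalars"]);
  const double geom_p = as<double>(cfg["geom_p"]);
  const double r_meanlog = as<double>(cfg["r_meanlog"]);
  const double r_sdlog = as<double>(cfg["r_sdlog"]);
  const double eps_sd = as<double>(cfg["eps_sd"]);
  const double L_step = as<double>(cfg["L_step"]);
  const arma::mat Linit = as<arma::mat>(cfg["Linit"]);
  const double Ldiag_prior_sd = as<double>(cfg["Ldiag_prior_sd"]);
  const double Loff_prior_sd = as<double>(cfg["Loff_prior_sd"]);

  PruneWork w;
  w.resize(q, nnode);
  const arma::mat Yt = Y.t();

  arma::vec rates(E, arma::fill::ones);
  std::vector<int> scaled;            // edges currently carrying a scalar
  std::vector<char> is_scaled(E, 0);
  arma::mat L = Linit;                // lower Cholesky of R
  const arma::vec Ldiag_mu = arma::log(L.diag());
  arma::mat Zt = whiten_t(Yt, L);
  double logdetR = 2.0 * arma::accu(arma::log(L.diag()));

  double curll = prune_loglik_white(Zt, edge, elen, rates, ntip, logdetR, w);
  const double log1mp = std::log(1.0 - geom_p);

  const int nsave = (iterations - burnin) / thin;
  arma::mat save_r(nsave, E);
  arma::vec save_ll(nsave), save_k(nsave);
  arma::mat save_R(nsave, q * (q + 1) / 2);
  IntegerVector acc(4), tries(4);  // birth, death, perturb, covupdate

  double pb = 0.2, pd = 0.2, pp = 0.4;  // remainder: covariance update
  if (fix_scalars) { pb = pd = pp = 0.0; }

  int isave = 0;
  for (int it = 1; it <= iterations; ++it) {
    const double u = R::runif(0.0, 1.0);
    const int k = (int)scaled.size();
    if (u < pb) {                               // birth
      tries[0]++;
      if (k < E) {
        int pick = (int)std::floor(R::runif(0.0, 1.0) * (E - k));
        int e = -1, seen = 0;
        for (int j = 0; j < E; ++j)
          if (!is_scaled[j] && seen++ == pick) { e = j; break; }
        const double logr = R::rnorm(r_meanlog, r_sdlog);
        const double old = rates(e);
        rates(e) = std::exp(logr);
        const double newll =
            prune_loglik_white(Zt, edge, elen, rates, ntip, logdetR, w);
        // prior/proposal terms cancel except the set-size prior ratio
        if (std::log(R::runif(0.0, 1.0)) < beta * (newll - curll) + log1mp) {
          curll = newll;
          is_scaled[e] = 1;
          scaled.push_back(e);
          acc[0]++;
        } else rates(e) = old;
      }
    } else if (u < pb + pd) {                   // death
      tries[1]++;
      if (k > 0) {
        const int pos = (int)std::floor(R::runif(0.0, 1.0) * k);
        const int e = scaled[pos];
        const double old = rates(e);
        rates(e) = 1.0;
        const double newll =
            prune_loglik_white(Zt, edge, elen, rates, ntip, logdetR, w);
        if (std::log(R::runif(0.0, 1.0)) < beta * (newll - curll) - log1mp) {
          curll = newll;
          is_scaled[e] = 0;
          scaled[pos] = scaled.back();
          scaled.pop_back();
          acc[1]++;
        } else rates(e) = old;
      }
    } else if (u < pb + pd + pp) {              // perturb a scalar
      tries[2]++;
      if (k > 0) {
        const int pos = (int)std::floor(R::runif(0.0, 1.0) * k);
        const int e = scaled[pos];
        const double old = rates(e);
        const double logr_old = std::log(old);
        const double logr_new = logr_old + R::rnorm(0.0, eps_sd);
        rates(e) = std::exp(logr_new);
        const double newll =
            prune_loglik_white(Zt, edge, elen, rates, ntip, logdetR, w);
        // symmetric walk in log space; log-normal prior + Jacobian reduce to
        // a normal-density ratio on log r
        const double dprior =
            lnorm_logpdf_on_log(logr_new, r_meanlog, r_sdlog) -
            lnorm_logpdf_on_log(logr_old, r_meanlog, r_sdlog);
        if (std::log(R::runif(0.0, 1.0)) < beta * (newll - curll) + dprior) {
          curll = newll;
          acc[2]++;
        } else rates(e) = old;
      }
    } else {                                    // update R via its Cholesky
      tries[3]++;
      const int nel = q * (q + 1) / 2;
      int pick = (int)std::floor(R::runif(0.0, 1.0) * nel);
      int row = 0, col = 0, seen = 0;
      for (int i = 0; i < q && seen <= pick; ++i)
        for (int j = 0; j <= i && seen <= pick; ++j)
          if (seen++ == pick) { row = i; col = j; }
      const double old = L(row, col);
      double dprior;
      if (row == col) {
        const double lo = std::log(old);
        const double ln = lo + R::rnorm(0.0, L_step);
        L(row, col) = std::exp(ln);
        dprior = R::dnorm(ln, Ldiag_mu(row), Ldiag_prior_sd, 1) -
                 R::dnorm(lo, Ldiag_mu(row), Ldiag_prior_sd, 1);
      } else {
        const double step = L_step * std::exp(Ldiag_mu(row));
        L(row, col) = old + R::rnorm(0.0, step);
        dprior = R::dnorm(L(row, col), 0.0, Loff_prior_sd, 1) -
                 R::dnorm(old, 0.0, Loff_prior_sd, 1);
      }
      const arma::mat Znew = whiten_t(Yt, L);
      const double ldnew = 2.0 * arma::accu(arma::log(L.diag()));
      const double newll =
          prune_loglik_white(Znew, edge, elen, rates, ntip, ldnew, w);
      if (std::log(R::runif(0.0, 1.0)) < beta * (newll - curll) + dprior) {
        curll = newll;
        Zt = Znew;
        logdetR = ldnew;
        acc[3]++;
      } else L(row, col) = old;
    }

    if (it > burnin && (it - burnin) % thin == 0 && isave < nsave) {
      save_r.row(isave) = rates.t();
      save_ll(isave) = curll;
      save_k(isave) = (double)scaled.size();
      const arma::mat R = L * L.t();
      int s = 0;
      for (int i = 0; i < q; ++i)
        for (int j = 0; j <= i; ++j) save_R(isave, s++) = R(i, j);
      isave++;
    }
  }

  return List::create(
      _["r"] = save_r, _["loglik"] = save_ll, _["k"] = save_k,
      _["R_vech"] = save_R, _["accept"] = acc, _["tries"] = tries);
}
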