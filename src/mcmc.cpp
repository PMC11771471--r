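#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Four Gumbel-joined cell probabilities for Bernoulli margins (gA, gT) with
// association psi.  Cells are floored at `floor_at` and renormalised: the
// correction term can push a cell slightly negative for extreme margins.
static inline double log_cell_prob(double gA, double gT, double psi,
                                   int a, int b, double floor_at = 1e-12) {
  double g = std::tanh(psi / 2.0); // (e^psi - 1)/(e^psi + 1)
  double corr = gA * (1.0 - gA) * gT * (1.0 - gT) * g;
  double c11 = gA * gT + corr;
  double c10 = gA * (1.0 - gT) - corr;
  double c01 = (1.0 - gA) * gT - corr;
  double c00 = (1.0 - gA) * (1.0 - gT) + corr;
  if (c11 < floor_at) c11 = floor_at;
  if (c10 < floor_at) c10 = floor_at;
  if (c01 < floor_at) c01 = floor_at;
  if (c00 < floor_at) c00 = floor_at;
  double s = c11 + c10 + c01 + c00;
  double cell = a ? (b ? c11 : c10) : (b ? c01 : c00);
  return std::log(cell) - std::log(s);
}

// th = (betaT0, log betaT1, betaA0, log betaA1, psi)
// [[Rcpp::export]]
double cpp_joint_loglik(const arma::vec& th, const arma::vec& dose,
                        const arma::ivec& y_act, const arma::ivec& y_tox,
                        const arma::vec& w_act, const arma::vec& w_tox) {
  double bT0 = th(0), bT1 = std::exp(th(1));
  double bA0 = th(2), bA1 = std::exp(th(3));
  double psi = th(4);
  double ll = 0.0;
  for (arma::uword i = 0; i < dose.n_elem; ++i) {
    double gT = w_tox(i) * logistic(bT0 + bT1 * dose(i));
    double gA = w_act(i) * logistic(bA0 + bA1 * dose(i));
    ll += log_cell_prob(gA, gT, psi, y_act(i), y_tox(i));
  }
  return ll;
}

// Dynamic-Beta model: increments b in (0,1) per dose level induce monotone
// cumulative probabilities p_j = p_{j-1} + (1 - p_{j-1}) b_j.
static inline void induced(const arma::vec& b, arma::vec& p) {
  double c = 0.0;
  for (arma::uword j = 0; j < b.n_elem; ++j) {
    c = c + (1.0 - c) * b(j);
    p(j) = c;
  }
}

// [[Rcpp::export]]
double cpp_ma_loglik(const arma::vec& b_tox, const arma::vec& b_act,
                     const arma::ivec& level,
                     const arma::ivec& y_act, const arma::ivec& y_tox,
                     const arma::vec& w_act, const arma::vec& w_tox) {
  arma::vec pT(b_tox.n_elem), pA(b_act.n_elem);
  induced(b_tox, pT);
  induced(b_act, pA);
  double ll = 0.0;
  for (arma::uword i = 0; i < level.n_elem; ++i) {
    int j = level(i) - 1;
    double pt = w_tox(i) * pT(j);
    double pa = w_act(i) * pA(j);
    ll += y_tox(i) ? std::log(pt) : std::log1p(-pt);
    ll += y_act(i) ? std::log(pa) : std::log1p(-pa);
  }
  return ll;
}

struct JointTarget {
  const arma::vec &dose, &w_act, &w_tox, &pm, &pv;
  const arma::ivec &y_act, &y_tox;
  double operator()(const arma::vec& th) const {
    double lp = 0.0;
    for (arma::uword k = 0; k < th.n_elem; ++k) {
      double z = th(k) - pm(k);
      lp -= 0.5 * z * z / pv(k);
    }
    if (dose.n_elem > 0)
      lp += cpp_joint_loglik(th, dose, y_act, y_tox, w_act, w_tox);
    return lp;
  }
};

struct MaTarget {
  const arma::vec &a_tox, &b_tox, &a_act, &b_act, &w_act, &w_tox;
  const arma::ivec &level, &y_act, &y_tox;
  // th holds probit-uniforms of the 2J increments (toxicity first): each
  // increment is qbeta(pnorm(th), a, b), so the prior reduces to a
  // standard normal on th.  This keeps the sampler well scaled even for
  // the strongly U-shaped Beta priors used here.
  double operator()(const arma::vec& th) const {
    arma::uword J = a_tox.n_elem;
    arma::vec bt(J), ba(J);
    double lp = 0.0;
    for (arma::uword j = 0; j < J; ++j) {
      bt(j) = R::qbeta(R::pnorm(th(j), 0.0, 1.0, 1, 0),
                       a_tox(j), b_tox(j), 1, 0);
      ba(j) = R::qbeta(R::pnorm(th(J + j), 0.0, 1.0, 1, 0),
                       a_act(j), b_act(j), 1, 0);
      lp -= 0.5 * (th(j) * th(j) + th(J + j) * th(J + j));
    }
    if (level.n_elem > 0)
      lp += cpp_ma_loglik(bt, ba, level, y_act, y_tox, w_act, w_tox);
    return lp;
  }
};

// Adaptive random-walk Metropolis: Haario-type covariance adaptation with
// Robbins-Monro scaling toward 0.234 acceptance.  Adaptation continues
// throughout with a diminishing rate (which preserves ergodicity); draws
// are collected after warmup.  Uses R's RNG so that set.seed() in R makes
// runs reproducible.
template <class Target>
static List amh(const Target& target, arma::vec init,
                int warmup, int iter, int thin, const arma::vec& init_diag) {
  const int d = init.n_elem;
  if (thin < 1) thin = 1;
  arma::vec x = init;
  double lpx = target(x);
  if (!std::isfinite(lpx)) stop("non-finite log-posterior at initial value");

  double lscale = std::log(2.38 / std::sqrt((double)d));
  arma::vec mu = x;
  arma::mat cov = arma::diagmat(init_diag);
  arma::mat L = arma::chol(cov, "lower");
  arma::mat out(iter, d);
  int n_acc = 0;

  const int total = warmup + iter * thin;
  for (int t = 0; t < total; ++t) {
    arma::vec z(d);
    for (int k = 0; k < d; ++k) z(k) = R::norm_rand();
    arma::vec prop = x + std::exp(lscale) * (L * z);
    double lpp = target(prop);
    double alpha = std::isfinite(lpp) ? std::min(1.0, std::exp(lpp - lpx)) : 0.0;
    if (R::unif_rand() < alpha) {
      x = prop;
      lpx = lpp;
      if (t >= warmup) ++n_acc;
    }
    {
      double g = 1.0 / std::pow(t + 2.0, 0.6);
      lscale += g * (alpha - 0.234);
      arma::vec dx = x - mu;
      mu += g * dx;
      cov = (1.0 - g) * cov + g * (dx * dx.t());
      if ((t + 1) % 50 == 0 || t == warmup - 1) {
        arma::mat C = cov + arma::eye(d, d) * 1e-9;
        if (!arma::chol(L, C, "lower")) L = arma::eye(d, d) * 0.05;
      }
    }
    if (t >= warmup && (t - warmup) % thin == thin - 1) {
      out.row((t - warmup) / thin) = x.t();
    }
  }
  return List::create(_["draws"] = out,
                      _["accept_rate"] =
                        (double)n_acc / std::max(iter * thin, 1));
}

// [[Rcpp::export]]
List cpp_mcmc_joint(const arma::vec& dose, const arma::ivec& y_act,
                    const arma::ivec& y_tox, const arma::vec& w_act,
                    const arma::vec& w_tox, const arma::vec& prior_mean,
                    const arma::vec& prior_var, const arma::vec& init,
                    int warmup, int iter, int thin) {
  JointTarget tgt{dose, w_act, w_tox, prior_mean, prior_var, y_act, y_tox};
  return amh(tgt, init, warmup, iter, thin, prior_var);
}

// [[Rcpp::export]]
List cpp_mcmc_ma(const arma::ivec& level, const arma::ivec& y_act,
                 const arma::ivec& y_tox, const arma::vec& w_act,
                 const arma::vec& w_tox, const arma::vec& a_tox,
                 const arma::vec& b_tox, const arma::vec& a_act,
                 const arma::vec& b_act, const arma::vec& init,
                 int warmup, int iter, int thin) {
  MaTarget tgt{a_tox, b_tox, a_act, b_act, w_act, w_tox, level, y_act, y_tox};
  arma::vec init_diag(init.n_elem, arma::fill::ones);
  return amh(tgt, init, warmup, iter, thin, init_diag);
}
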