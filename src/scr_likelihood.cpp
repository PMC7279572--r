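// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Negative log-likelihood of the closed-population SCR model for proximity
// detectors with half-normal detection and Poisson-distributed n, evaluated
// on the link scale (log D, logit g0, log sigma).
//
//   log L = n log(D a) + sum_i log( sum_m Pr(omega_i | s_m) )
//           - D a sum_m p.(s_m)                      [log n! dropped]
//   Pr(omega_i | s) = prod_k p_k(s)^{n_ik} (1 - p_k(s))^{T - n_ik}
//   p_k(s) = g0 exp(-d_k(s)^2 / (2 sigma^2)),  p.(s) = 1 - prod_k (1-p_k)^T
//
// counts: n x K collapsed detection counts; d2: K x M squared distances (m^2)
// between detectors and mask points; a: mask cell area in km^2; D in /km^2.
// [[Rcpp::export]]
double scr_nll_cpp(const arma::vec& par, const arma::mat& counts,
                   const arma::mat& d2, double T, double a) {
  const double D = std::exp(par[0]);
  const double g0 = 1.0 / (1.0 + std::exp(-par[1]));
  const double sigma = std::exp(par[2]);
  const arma::uword n = counts.n_rows;

  // log p_k(s_m) computed directly so large distances stay finite
  arma::mat logP = std::log(g0) - d2 / (2.0 * sigma * sigma);
  arma::mat P = arma::exp(logP);
  // guard logit overflow: keep 1 - p away from exactly zero
  P.transform([](double v) { return v > 1.0 - 1e-12 ? 1.0 - 1e-12 : v; });
  arma::mat log1mP = arma::log1p(-P);

  arma::rowvec lognull = T * arma::sum(log1mP, 0);   // log Pr(never | s_m)
  double esa_sum = arma::accu(1.0 - arma::exp(lognull)); // sum_m p.(s_m)

  double ll = -D * a * esa_sum;
  if (n > 0) {
    arma::mat logPr = counts * logP + (T - counts) * log1mP; // n x M
    for (arma::uword i = 0; i < n; ++i) {
      double mx = logPr.row(i).max();
      if (!std::isfinite(mx)) return std::numeric_limits<double>::infinity();
      ll += mx + std::log(arma::accu(arma::exp(logPr.row(i) - mx)));
    }
    ll += n * std::log(D * a);
  }
  if (!std::isfinite(ll)) return std::numeric_limits<double>::infinity();
  return -ll;
}

// Negative log-likelihood and its analytic gradient on the link scale.
// Gradient pieces, with u1 = log D, u2 = logit g0, u3 = log sigma:
//   dp/du2 = p (1 - g0),  dp/du3 = p d^2 / sigma^2,
//   d logPr_i(s)/du = sum_k (n_ik / p - (T - n_ik) / (1 - p)) dp/du,
//   d log L/du = sum_i sum_m softmax_im d logPr_im/du - D a dE/du,
//   dE/du = T sum_m exp(log Q_m) sum_k (dp/du) / (1 - p).
// [[Rcpp::export]]
List scr_nll_grad_cpp(const arma::vec& par, const arma::mat& counts,
                      const arma::mat& d2, double T, double a) {
  const double D = std::exp(par[0]);
  const double g0 = 1.0 / (1.0 + std::exp(-par[1]));
  const double sigma = std::exp(par[2]);
  const arma::uword n = counts.n_rows;
  const double inf = std::numeric_limits<double>::infinity();
  arma::vec grad(3, arma::fill::zeros);

  arma::mat logP = std::log(g0) - d2 / (2.0 * sigma * sigma);
  arma::mat P = arma::exp(logP);
  P.transform([](double v) { return v > 1.0 - 1e-12 ? 1.0 - 1e-12 : v; });
  arma::mat log1mP = arma::log1p(-P);
  arma::mat Pratio = P / (1.0 - P);          // p / (1-p)
  arma::mat D2s = d2 / (sigma * sigma);      // dp/du3 = P % D2s

  arma::rowvec lognull = T * arma::sum(log1mP, 0);
  arma::rowvec qnull = arma::exp(lognull);
  double E = arma::accu(1.0 - qnull);

  // dE/du = T sum_m qnull_m sum_k dp_km/du / (1 - p_km)
  arma::rowvec c2 = arma::sum(Pratio, 0) * (1.0 - g0);
  arma::rowvec c3 = arma::sum(Pratio % D2s, 0);
  double dE2 = T * arma::dot(qnull, c2);
  double dE3 = T * arma::dot(qnull, c3);

  double ll = -D * a * E;
  grad[0] = -D * a * E;                      // d ll / d log D (density part)
  grad[1] = -D * a * dE2;
  grad[2] = -D * a * dE3;

  if (n > 0) {
    arma::mat logPr = counts * logP + (T - counts) * log1mP;
    arma::vec totcap = arma::sum(counts, 1);  // total detections per animal
    // d logPr/du2 = (1-g0) (totcap_i - [(T - counts) * Pratio]_im)
    arma::mat B = (T - counts) * Pratio;      // n x M
    // d logPr/du3 = [counts * D2s]_im - [(T - counts) * (Pratio % D2s)]_im
    arma::mat G3 = counts * D2s - (T - counts) * (Pratio % D2s);
    for (arma::uword i = 0; i < n; ++i) {
      double mx = logPr.row(i).max();
      if (!std::isfinite(mx))
        return List::create(Named("value") = inf,
                            Named("gradient") = NumericVector(3));
      arma::rowvec w = arma::exp(logPr.row(i) - mx);
      double sw = arma::accu(w);
      ll += mx + std::log(sw);
      w /= sw;                                // softmax over mask cells
      grad[1] += (1.0 - g0) * (totcap[i] - arma::dot(w, B.row(i)));
      grad[2] += arma::dot(w, G3.row(i));
    }
    ll += n * std::log(D * a);
    grad[0] += n;
  }
  if (!std::isfinite(ll))
    return List::create(Named("value") = inf,
                        Named("gradient") = NumericVector(3));
  return List::create(Named("value") = -ll,
                      Named("gradient") = NumericVector::create(
                        -grad[0], -grad[1], -grad[2]));
}
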