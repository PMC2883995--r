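// Annealed gradient descent on the signed-graph configuration energy.
// Kept in C++ because the embedding is re-fitted many times (null maps
// for dimension significance, parameter sweeps); R-side reference
// implementations of the energy and gradient are cross-checked against
// this path in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double energy_of(const arma::mat& X, const arma::sp_mat& W,
                        double pair_c, double quart_c) {
  arma::vec rs = arma::sum(X % X, 1);
  double pair = -0.5 * arma::accu(X % (W * X));
  return pair_c * pair + quart_c * arma::accu(rs % rs);
}

static arma::mat grad_of(const arma::mat& X, const arma::sp_mat& W,
                         double pair_c, double quart_c) {
  arma::vec rs = arma::sum(X % X, 1);
  arma::mat G = -pair_c * (W * X);
  G += (4.0 * quart_c) * (X.each_col() % rs);
  return G;
}

// [[Rcpp::export(name = ".energy_cpp")]]
double energy_cpp(const arma::mat& X, const arma::sp_mat& W,
                  double pair_c, double quart_c) {
  return energy_of(X, W, pair_c, quart_c);
}

// [[Rcpp::export(name = ".gradient_cpp")]]
arma::mat gradient_cpp(const arma::mat& X, const arma::sp_mat& W,
                       double pair_c, double quart_c) {
  return grad_of(X, W, pair_c, quart_c);
}

// Annealed phase: plain gradient steps plus Gaussian noise of
// geometrically decaying scale (noise drawn from the R RNG so runs are
// reproducible under set.seed). Deterministic phase: backtracking line
// search with an adaptively grown step; convergence is declared when the
// gradient infinity-norm, the relative energy change, or the relative
// maximum row displacement falls below `tol`.
// [[Rcpp::export(name = ".descend_cpp")]]
List descend_cpp(const arma::mat& X0, const arma::sp_mat& W,
                 double pair_c, double quart_c,
                 double tol, int max_steps,
                 double noise0, double noise_decay, double noise_floor) {
  const double eps = 1e-12;
  arma::mat X = X0;
  double E = energy_of(X, W, pair_c, quart_c);
  double step = 0.1;
  double noise = noise0;
  bool converged = false;
  std::string monitor = "max_steps";
  int it = 0;

  for (it = 1; it <= max_steps; ++it) {
    arma::mat G = grad_of(X, W, pair_c, quart_c);

    if (noise > noise_floor) {
      // line-search the gradient part for stability, then superimpose
      // the thermal noise (accepted unconditionally)
      arma::mat Xd;
      double Ed;
      while (true) {
        Xd = X - step * G;
        Ed = energy_of(Xd, W, pair_c, quart_c);
        if (std::isfinite(Ed) && Ed <= E + 1e-14) break;
        step *= 0.5;
        if (step < 1e-14) { Xd = X; break; }
      }
      arma::mat N(X.n_rows, X.n_cols);
      for (arma::uword k = 0; k < N.n_elem; ++k) N(k) = R::norm_rand();
      arma::mat Xn = Xd + noise * N;
      double En = energy_of(Xn, W, pair_c, quart_c);
      if (!std::isfinite(En))
        stop("optimization diverged at step %d (non-finite energy)", it);
      X = Xn;
      E = En;
      step *= 1.2;
      noise *= noise_decay;
      continue;
    }

    // backtracking line search
    arma::mat Xn;
    double En = E;
    while (true) {
      Xn = X - step * G;
      En = energy_of(Xn, W, pair_c, quart_c);
      if (std::isfinite(En) && En <= E - 1e-14) break;
      step *= 0.5;
      if (step < 1e-14) { Xn = X; En = E; break; }
    }

    double ginf = arma::abs(G).max();
    double rel_e = std::fabs(En - E) / (std::fabs(E) + eps);
    double max_disp = arma::abs(Xn - X).max();
    arma::vec rn = arma::sqrt(arma::sum(Xn % Xn, 1));
    double rel_x = max_disp / (rn.max() + eps);

    X = Xn;
    E = En;
    step *= 1.5;

    if (!std::isfinite(E))
      stop("optimization diverged at step %d (non-finite energy)", it);

    if (ginf < tol) { converged = true; monitor = "gradient"; break; }
    if (rel_e < tol) { converged = true; monitor = "energy"; break; }
    if (rel_x < tol) { converged = true; monitor = "coordinates"; break; }
  }
  if (it > max_steps) it = max_steps;

  return List::create(_["config"] = X,
                      _["converged"] = converged,
                      _["steps"] = it,
                      _["final_energy"] = E,
                      _["monitor"] = monitor);
}
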