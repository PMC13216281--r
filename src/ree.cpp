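// Relative entropy of entanglement by away-step Frank-Wolfe over the
// separable set.  Extreme points are pure product states x = a (x) b with
// complex factors; for a real symmetric rho the optimal separable state
// can be taken real, so atoms are stored as Re(x x^dag), which is again
// separable.  The linear subproblem (best product state against the
// gradient) is solved by alternating smallest-eigenvector iterations over
// the two factors with random restarts; away steps over the active atoms
// give linear local convergence and the Frank-Wolfe gap certifies the
// returned upper bound.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
using namespace arma;

static double ree_f(const mat& rho, const mat& sigma, double s_rho) {
  vec w; mat V;
  eig_sym(w, V, sigma);
  w = clamp(w, 1e-300, datum::inf);
  mat logs = V * diagmat(log(w)) * V.t();
  return -accu(rho % logs) - s_rho;
}

static mat ree_grad(const mat& rho, const mat& sigma) {
  vec w; mat V;
  eig_sym(w, V, sigma);
  w = clamp(w, 1e-300, datum::inf);
  mat rt = V.t() * rho * V;
  int d = w.n_elem;
  mat phi(d, d);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      double num = std::log(w[i]) - std::log(w[j]);
      double den = w[i] - w[j];
      phi(i, j) = (std::abs(den) > 1e-13) ? num / den : 1.0 / w[i];
    }
  return -(V * (rt % phi) * V.t());
}

// min over complex product states x = a (x) b of x^dag G x (G real sym)
static cx_vec best_product(const mat& G, int dA, int dB, std::mt19937& rng,
                           int tries, double* valout, bool complex_factors) {
  std::normal_distribution<double> N(0.0, 1.0);
  cx_vec best; double bestval = datum::inf;
  for (int t = 0; t < tries; ++t) {
    cx_vec b(dB);
    for (int i = 0; i < dB; ++i)
      b[i] = std::complex<double>(N(rng),
               (complex_factors && t > 0) ? N(rng) : 0.0);
    b /= norm(b);
    cx_vec a(dA, fill::zeros);
    for (int it = 0; it < 100; ++it) {
      cx_mat MA(dA, dA, fill::zeros);
      for (int p = 0; p < dB; ++p)
        for (int q = 0; q < dB; ++q) {
          std::complex<double> w = std::conj(b[p]) * b[q];
          for (int x = 0; x < dA; ++x)
            for (int y = 0; y < dA; ++y)
              MA(x, y) += w * G(p + dB * x, q + dB * y);
        }
      vec wA; cx_mat VA;
      eig_sym(wA, VA, 0.5 * (MA + MA.t()));
      a = VA.col(0);
      cx_mat MB(dB, dB, fill::zeros);
      for (int x = 0; x < dA; ++x)
        for (int y = 0; y < dA; ++y) {
          std::complex<double> w = std::conj(a[x]) * a[y];
          for (int p = 0; p < dB; ++p)
            for (int q = 0; q < dB; ++q)
              MB(p, q) += w * G(p + dB * x, q + dB * y);
        }
      vec wB; cx_mat VB;
      eig_sym(wB, VB, 0.5 * (MB + MB.t()));
      cx_vec bn = VB.col(0);
      double diff = std::abs(1.0 - std::abs(cdot(b, bn)));
      b = bn;
      if (diff < 1e-14) break;
    }
    cx_vec x(dA * dB);
    for (int xa = 0; xa < dA; ++xa)
      for (int p = 0; p < dB; ++p) x[p + dB * xa] = a[xa] * b[p];
    double v = std::real(cdot(x, cx_mat(G, mat(G.n_rows, G.n_cols, fill::zeros)) * x));
    if (v < bestval) { bestval = v; best = x; }
  }
  *valout = bestval;
  return best;
}

static double golden(const mat& rho, const mat& sigma, const mat& Dir,
                     double s_rho, double tmax) {
  const double gr = 0.6180339887498949;
  double a = 0.0, b = tmax;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = ree_f(rho, sigma + c * Dir, s_rho);
  double fd = ree_f(rho, sigma + d * Dir, s_rho);
  for (int it = 0; it < 80 && (b - a) > 1e-13 * std::max(1.0, tmax); ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = ree_f(rho, sigma + c * Dir, s_rho);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = ree_f(rho, sigma + d * Dir, s_rho);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
Rcpp::List cpp_ree(const arma::mat& rho, int dA, int dB, double tol,
                   int maxit, int seed, int tries,
                   bool complex_factors = true) {
  int d = dA * dB;
  std::mt19937 rng(seed);
  vec wr = eig_sym(rho);
  double s_rho = 0.0;
  for (double x : wr) if (x > 1e-14) s_rho -= x * std::log(x);
  mat sigma = eye(d, d) / d;
  std::vector<mat> atoms;
  std::vector<double> wts;
  atoms.push_back(eye(d, d) / d); // maximally mixed start is separable
  wts.push_back(1.0);
  double gap = datum::inf;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    mat G = ree_grad(rho, sigma);
    double xval;
    cx_vec x = best_product(G, dA, dB, rng, tries, &xval, complex_factors);
    double sval = accu(G % sigma);
    gap = sval - xval;
    if (gap < tol) {
      // confirm with a deeper product-state search before terminating
      double xv2;
      cx_vec x2 = best_product(G, dA, dB, rng, 4 * tries, &xv2, complex_factors);
      if (xv2 < xval) { xval = xv2; x = x2; gap = sval - xval; }
      if (gap < tol) break;
    }
    mat X = real(x * x.t()); // Re(x x^dag): separable for real-sym targets
    // away atom: active atom with largest <G, atom>
    int away = -1; double aval = -datum::inf;
    for (size_t k = 0; k < atoms.size(); ++k) {
      if (wts[k] < 1e-12) continue;
      double v = accu(G % atoms[k]);
      if (v > aval) { aval = v; away = (int)k; }
    }
    if (away >= 0 && (aval - sval) > (sval - xval) && wts[away] < 1.0 - 1e-12) {
      double tmax = wts[away] / (1.0 - wts[away]);
      mat Dir = sigma - atoms[away];
      double t = golden(rho, sigma, Dir, s_rho, tmax);
      sigma = sigma + t * Dir;
      double scale = 1.0 + t;
      for (auto& w : wts) w *= scale;
      wts[away] -= t;
    } else {
      mat Dir = X - sigma;
      double t = golden(rho, sigma, Dir, s_rho, 1.0);
      sigma = sigma + t * Dir;
      for (auto& w : wts) w *= (1.0 - t);
      atoms.push_back(X);
      wts.push_back(t);
    }
    if ((int)atoms.size() > 6 * d) { // prune dead atoms
      std::vector<mat> a2; std::vector<double> w2;
      for (size_t k = 0; k < atoms.size(); ++k)
        if (wts[k] > 1e-12) { a2.push_back(atoms[k]); w2.push_back(wts[k]); }
      atoms.swap(a2); wts.swap(w2);
    }
  }
  double value = ree_f(rho, sigma, s_rho);
  if (value < 0) value = 0;
  return Rcpp::List::create(Rcpp::_["value"] = value, Rcpp::_["gap"] = gap,
                            Rcpp::_["iterations"] = it,
                            Rcpp::_["sigma"] = sigma);
}
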