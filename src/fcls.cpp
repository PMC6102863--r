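// Fully constrained least-squares unmixing.
//
// The per-pixel inversion solves
//   min ||r - M a||^2   s.t.  a >= 0,  sum(a) = 1
// via Lawson-Hanson NNLS on the sum-to-one-augmented system
// [M; delta * 1'] a ~ [r; delta] with delta = 1e3, followed by
// renormalisation and, when the augmented sum still deviates, an exact
// equality-constrained refinement on the positive support (KKT system).
//
// grid_search_cpp is a deliberately separate brute-force enumerator over
// the whole 0.01-step simplex, used only as a reference oracle in tests;
// it shares no code with the solver.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS for small dense systems.
// Ties in the gradient selection break toward the smallest index so the
// solver is deterministic for collinear columns.
static vec nnls_small(const mat& A, const vec& b,
                      double tol = 1e-12, int maxit = 300) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);
  int it = 0;

  while (true) {
    double wmax = tol;
    sword t = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (sword) j; }
    }
    if (t < 0) break;
    passive[(uword) t] = true;

    while (true) {
      if (++it > maxit) return x;
      uvec idx(n);
      uword k = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) idx(k++) = j;
      idx.resize(k);

      vec z;
      bool ok = solve(z, A.cols(idx), b, solve_opts::no_approx);
      if (!ok) z = pinv(A.cols(idx)) * b;

      if (k == 0 || z.min() > tol) {
        x.zeros();
        for (uword j = 0; j < k; ++j) x(idx(j)) = z(j);
        break;
      }
      double alpha = datum::inf;
      for (uword j = 0; j < k; ++j) {
        if (z(j) <= tol) {
          double denom = x(idx(j)) - z(j);
          double a = denom > 0 ? x(idx(j)) / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      vec xi(k);
      for (uword j = 0; j < k; ++j) xi(j) = x(idx(j));
      xi += alpha * (z - xi);
      x.zeros();
      for (uword j = 0; j < k; ++j) {
        if (xi(j) <= tol) {
          passive[idx(j)] = false;
        } else {
          x(idx(j)) = xi(j);
        }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// Equality-constrained LS refinement on a fixed support: solve
// min ||r - Ms a||^2 s.t. 1'a = 1 through the KKT system. Returns false if
// the KKT solve fails or produces a negative component.
static bool refine_sum1(const mat& Ms, const vec& r, vec& out) {
  const uword k = Ms.n_cols;
  mat K(k + 1, k + 1, fill::zeros);
  K.submat(0, 0, k - 1, k - 1) = Ms.t() * Ms;
  for (uword j = 0; j < k; ++j) { K(j, k) = 1.0; K(k, j) = 1.0; }
  vec rhs(k + 1);
  rhs.subvec(0, k - 1) = Ms.t() * r;
  rhs(k) = 1.0;
  vec sol;
  if (!solve(sol, K, rhs, solve_opts::no_approx)) return false;
  vec a = sol.subvec(0, k - 1);
  if (a.min() < -1e-12) return false;
  a.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  out = a / accu(a);
  return true;
}

// R: npix x nbands reflectance, M: nbands x nem endmember matrix.
// Returns npix x (nem + 1): abundances plus per-pixel RMS residual.
// [[Rcpp::export(name = ".fclsCpp")]]
arma::mat fcls_cpp(const arma::mat& R, const arma::mat& M,
                   double delta = 1e3) {
  const uword npix = R.n_rows, nb = M.n_rows, nem = M.n_cols;
  if (R.n_cols != nb) Rcpp::stop("reflectance/library band mismatch");

  mat A(nb + 1, nem);
  A.rows(0, nb - 1) = M;
  A.row(nb).fill(delta);

  mat out(npix, nem + 1);
  vec b(nb + 1);
  b(nb) = delta;

  for (uword i = 0; i < npix; ++i) {
    b.subvec(0, nb - 1) = R.row(i).t();
    vec x = nnls_small(A, b);
    double s = accu(x);
    if (s <= 0) {
      // degenerate: fall back to uniform abundances
      x.fill(1.0 / nem);
    } else if (std::abs(s - 1.0) > 1e-8) {
      uvec idx = find(x > 1e-12);
      vec ref;
      if (idx.n_elem > 0 && refine_sum1(M.cols(idx), R.row(i).t(), ref)) {
        x.zeros();
        x(idx) = ref;
      } else {
        x /= s;
      }
    } else {
      x /= s;
    }
    vec res = R.row(i).t() - M * x;
    for (uword j = 0; j < nem; ++j) out(i, j) = x(j);
    out(i, nem) = std::sqrt(accu(square(res)) / nb);
  }
  return out;
}

// Exhaustive enumeration of the abundance simplex at resolution 1/steps.
// For every composition (k1..knem) with sum = steps, evaluates
// ||r - M a||^2 for all pixels and tracks the minimum. Reference oracle.
// [[Rcpp::export(name = ".gridSearchCpp")]]
Rcpp::List grid_search_cpp(const arma::mat& R, const arma::mat& M,
                           int steps = 100) {
  const uword npix = R.n_rows, nem = M.n_cols;
  if (R.n_cols != M.n_rows) Rcpp::stop("reflectance/library band mismatch");

  mat Q = M.t() * M;
  mat Bt = M.t() * R.t();                 // nem x npix
  vec cst(npix);
  for (uword i = 0; i < npix; ++i) cst(i) = dot(R.row(i), R.row(i));

  vec best(npix);
  best.fill(datum::inf);
  mat bestA(npix, nem, fill::zeros);

  std::vector<int> k(nem, 0);
  vec a(nem);
  std::function<void(uword, int)> rec = [&](uword d, int rem) {
    if (d == nem - 1) {
      k[d] = rem;
      for (uword j = 0; j < nem; ++j) a(j) = (double) k[j] / steps;
      double q = as_scalar(a.t() * Q * a);
      for (uword i = 0; i < npix; ++i) {
        double obj = cst(i) + q - 2.0 * dot(a, Bt.col(i));
        if (obj < best(i)) { best(i) = obj; bestA.row(i) = a.t(); }
      }
      return;
    }
    for (int v = 0; v <= rem; ++v) { k[d] = v; rec(d + 1, rem - v); }
  };
  rec(0, steps);

  return Rcpp::List::create(Rcpp::Named("objective") = best,
                            Rcpp::Named("abundance") = bestA);
}
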