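// ADMM solver for the sum-to-zero-constrained sparse group lasso with
// tree-nested (laminar) groups, and the exact hierarchical proximal operator.
//
// Problem:
//   min_b  (1/2n) ||y - D b||_2^2
//          + lambda * ( sum_j l1w_j |b_j| + sum_v ||b[g_v]||_2 / w_v )
//   s.t.   sum_{j in block_k} b_j = 0  for each constraint block k.
//
// Two-block splitting: the x-block holds the smooth loss plus the affine
// zero-sum constraints (KKT linear solve); the z-block is the penalty,
// handled by composing group soft-thresholding leaf-to-root, which is the
// exact prox when the groups form a laminar family.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact prox of tau * (sum_j l1w_j |b_j| + sum_v ||b[g_v]||/w_v) at v,
// for groups ordered children-before-parents (ascending leaf-set size).
static vec hier_prox_impl(const vec& v,
                          const std::vector<uvec>& groups,
                          const vec& group_w,
                          const vec& l1w,
                          double tau) {
  vec z = v;
  // leaf level: elementwise soft-thresholding
  for (uword j = 0; j < z.n_elem; ++j) {
    double t = tau * l1w(j);
    double a = std::fabs(z(j)) - t;
    z(j) = (a > 0.0) ? ((z(j) > 0.0) ? a : -a) : 0.0;
  }
  // internal nodes, leaf-to-root: group soft-thresholding
  for (size_t g = 0; g < groups.size(); ++g) {
    const uvec& idx = groups[g];
    double nrm = norm(z.elem(idx), 2);
    double t = tau / group_w(g);
    if (nrm <= t) {
      z.elem(idx).zeros();
    } else {
      z.elem(idx) *= (1.0 - t / nrm);
    }
  }
  return z;
}

static double objective_impl(const mat& D, const vec& y, const vec& b,
                             const std::vector<uvec>& groups,
                             const vec& group_w, const vec& l1w,
                             double lambda) {
  double n = (double) D.n_rows;
  vec r = y - D * b;
  double obj = 0.5 * dot(r, r) / n;
  double pen = dot(l1w, abs(b));
  for (size_t g = 0; g < groups.size(); ++g)
    pen += norm(b.elem(groups[g]), 2) / group_w(g);
  return obj + lambda * pen;
}

static std::vector<uvec> as_uvec_list(const Rcpp::List& lst) {
  std::vector<uvec> out;
  out.reserve(lst.size());
  for (int i = 0; i < lst.size(); ++i) {
    Rcpp::IntegerVector v = lst[i];
    uvec idx(v.size());
    for (int j = 0; j < v.size(); ++j) idx(j) = (uword) v[j];
    out.push_back(idx);
  }
  return out;
}

// [[Rcpp::export(name = ".hier_prox_cpp")]]
arma::vec hier_prox_cpp(const arma::vec& v, const Rcpp::List& group_idx,
                        const arma::vec& group_w, const arma::vec& l1w,
                        double tau) {
  std::vector<uvec> groups = as_uvec_list(group_idx);
  return hier_prox_impl(v, groups, group_w, l1w, tau);
}

// [[Rcpp::export(name = ".objective_cpp")]]
double objective_cpp(const arma::mat& D, const arma::vec& y,
                     const arma::vec& b, const Rcpp::List& group_idx,
                     const arma::vec& group_w, const arma::vec& l1w,
                     double lambda) {
  std::vector<uvec> groups = as_uvec_list(group_idx);
  return objective_impl(D, y, b, groups, group_w, l1w, lambda);
}

// [[Rcpp::export(name = ".admm_solve_cpp")]]
Rcpp::List admm_solve_cpp(const arma::mat& D, const arma::vec& y,
                          const Rcpp::List& group_idx,
                          const arma::vec& group_w,
                          const arma::vec& l1w,
                          const Rcpp::List& block_idx,
                          double lambda, double rho, int maxit,
                          double abstol, double reltol,
                          arma::vec z, arma::vec u,
                          bool trace_objective) {
  const uword n = D.n_rows, d = D.n_cols;
  std::vector<uvec> groups = as_uvec_list(group_idx);
  std::vector<uvec> blocks = as_uvec_list(block_idx);
  const uword k = blocks.size();

  mat DtD = D.t() * D / (double) n;
  vec Dty = D.t() * y / (double) n;
  mat A(k, d, fill::zeros);
  for (uword b = 0; b < k; ++b)
    for (uword j = 0; j < blocks[b].n_elem; ++j) A(b, blocks[b](j)) = 1.0;

  mat R;                 // chol factor of DtD + rho I
  mat MinvAt;            // (DtD + rho I)^{-1} A'
  mat Schur;             // A (DtD+rho I)^{-1} A'
  auto refactor = [&]() {
    mat M = DtD;
    M.diag() += rho;
    R = chol(M);
    if (k > 0) {
      MinvAt = solve(trimatu(R), solve(trimatl(R.t()), A.t()));
      Schur = A * MinvAt;
    }
  };
  refactor();

  vec x(d, fill::zeros), zold;
  std::vector<double> trace;
  bool converged = false;
  int iter = 0;
  const double sqd = std::sqrt((double) d);

  for (iter = 0; iter < maxit; ++iter) {
    // x-update: equality-constrained quadratic, via KKT / Schur complement
    vec q = Dty + rho * (z - u);
    vec t1 = solve(trimatu(R), solve(trimatl(R.t()), q));
    if (k > 0) {
      vec nu = solve(Schur, A * t1);
      x = t1 - MinvAt * nu;
    } else {
      x = t1;
    }
    // z-update: exact hierarchical prox
    zold = z;
    z = hier_prox_impl(x + u, groups, group_w, l1w, lambda / rho);
    u += x - z;

    if (trace_objective) {
      // evaluate at a feasibility-restored copy (active coefficients of each
      // block re-centered) so the trace is bounded below by the constrained
      // optimum
      vec zf = z;
      for (size_t bk = 0; bk < blocks.size(); ++bk) {
        const uvec& ix = blocks[bk];
        double tot = 0.0;
        uword nact = 0;
        for (uword j = 0; j < ix.n_elem; ++j) {
          if (zf(ix(j)) != 0.0) { tot += zf(ix(j)); ++nact; }
        }
        if (nact > 0) {
          double shift = tot / (double) nact;
          for (uword j = 0; j < ix.n_elem; ++j) {
            if (zf(ix(j)) != 0.0) zf(ix(j)) -= shift;
          }
        }
      }
      trace.push_back(objective_impl(D, y, zf, groups, group_w, l1w, lambda));
    }

    double rnorm = norm(x - z, 2);
    double snorm = rho * norm(z - zold, 2);
    double eps_pri = sqd * abstol +
      reltol * std::max(norm(x, 2), norm(z, 2));
    double eps_dual = sqd * abstol + reltol * rho * norm(u, 2);
    if (rnorm <= eps_pri && snorm <= eps_dual) {
      converged = true;
      ++iter;
      break;
    }
    // residual balancing every 10 iterations
    if ((iter + 1) % 10 == 0) {
      if (rnorm > 10.0 * snorm) {
        rho *= 2.0; u /= 2.0; refactor();
      } else if (snorm > 10.0 * rnorm) {
        rho /= 2.0; u *= 2.0; refactor();
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("z") = z,
    Rcpp::Named("u") = u,
    Rcpp::Named("rho") = rho,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective_trace") = trace);
}
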