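// Post-order pruning of the Gaussian likelihood of tip traits on a tree.
//
// The log-density of the data in the subtree below a node, viewed as a
// function of the (unobserved) node state x and of the stacked linear mean
// parameters z (optima per regime and, depending on the root policy, the
// root state), is an exact quadratic
//
//   log f(subtree | x, z) = x' L x + (M z + m0)' x + z' R z + r1' z + r0 .
//
// Each branch contributes the OU transition  child | parent ~ N(F par + W z, V)
// with F = expm(-A t) and W = (I - F) T_r  (T_r selects the regime's
// optimum out of z); integrating the child state out propagates the
// quadratic to the parent in closed form.  One pass yields the exact
// likelihood and, because the form is jointly quadratic in z, the GLS
// profile of all mean parameters.  Cost is linear in the number of tips.
//
// Branch moments come from the eigendecomposition A = P diag(lambda) P^-1
// (complex-valued in general; the results are real up to rounding and the
// transpose in the V formula is the plain transpose, not the conjugate
// one), or from per-edge precomputed (F, V) arrays when A is defective.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double LOG2PI = 1.8378770664093454836;

// symmetric inverse with log-determinant; false on (numerical) singularity
static bool sym_inv_logdet(const arma::mat& S, arma::mat& Sinv,
                           double& logdet) {
  arma::mat Ss = 0.5 * (S + S.t());
  arma::mat U;
  if (!arma::chol(U, Ss)) return false;
  double ld = 0.0;
  for (arma::uword i = 0; i < U.n_rows; ++i) {
    if (U(i, i) <= 0.0) return false;
    ld += std::log(U(i, i));
  }
  logdet = 2.0 * ld;
  arma::mat Uinv;
  if (!arma::inv(Uinv, arma::trimatu(U))) return false;
  Sinv = Uinv * Uinv.t();
  return true;
}

// [[Rcpp::export]]
Rcpp::List prune_tree_cpp(const int k, const int p,
                          const arma::imat& edge,       // E x 2 (parent, child), postorder
                          const arma::vec& edge_len,
                          const arma::ivec& edge_regime, // 1-based
                          const int n_tip, const int n_node, const int root,
                          const arma::mat& Y,            // k x n_tip
                          const arma::cube& ME,          // k x k x n_tip
                          const arma::cube& Tsel,        // k x p x n_regime
                          const bool use_eigen,
                          const arma::cx_mat& P, const arma::cx_mat& Pinv,
                          const arma::cx_vec& lambda,
                          const arma::cx_mat& Stilde,
                          const arma::cube& Farr, const arma::cube& Varr) {
  const int E = edge.n_rows;
  arma::cube Lc(k, k, n_node, arma::fill::zeros);
  arma::cube Mc(k, p, n_node, arma::fill::zeros);
  arma::mat m0c(k, n_node, arma::fill::zeros);
  arma::cube Rc(p, p, n_node, arma::fill::zeros);
  arma::mat r1c(p, n_node, arma::fill::zeros);
  arma::vec r0c(n_node, arma::fill::zeros);

  const arma::mat Ik = arma::eye(k, k);
  arma::cx_mat lam_sum(k, k);
  if (use_eigen) {
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) lam_sum(i, j) = lambda(i) + lambda(j);
  }

  arma::mat F(k, k), V(k, k);
  arma::cx_mat intf(k, k);
  for (int e = 0; e < E; ++e) {
    const int par = edge(e, 0) - 1;
    const int chl = edge(e, 1) - 1;
    const double t = edge_len(e);
    if (use_eigen) {
      arma::cx_vec El = arma::exp(-lambda * t);
      F = arma::real(P * arma::diagmat(El) * Pinv);
      for (int i = 0; i < k; ++i) {
        for (int j = 0; j < k; ++j) {
          const std::complex<double> s = lam_sum(i, j);
          intf(i, j) = (std::abs(s) * t < 1e-10)
            ? std::complex<double>(t, 0.0)
            : (1.0 - std::exp(-s * t)) / s;
        }
      }
      // plain transpose .st(): e^{-A' s} = P^-T e^{-Lambda s} P^T
      V = arma::real(P * (Stilde % intf) * P.st());
      V = 0.5 * (V + V.t());
    } else {
      F = Farr.slice(e);
      V = Varr.slice(e);
    }
    const arma::mat W = (Ik - F) * Tsel.slice(edge_regime(e) - 1);

    if (chl < n_tip) {  // terminal branch: child state observed (plus ME)
      arma::mat Vt = V + ME.slice(chl);
      arma::mat Lam;
      double logdet;
      if (!sym_inv_logdet(Vt, Lam, logdet)) {
        Rcpp::stop("singular covariance on the terminal branch of tip %d; "
                   "adding measurement error removes this singularity",
                   chl + 1);
      }
      const arma::vec y = Y.col(chl);
      const arma::mat FtL = F.t() * Lam;
      Lc.slice(par) += -0.5 * FtL * F;
      Mc.slice(par) += -FtL * W;
      m0c.col(par) += FtL * y;
      Rc.slice(par) += -0.5 * W.t() * Lam * W;
      r1c.col(par) += W.t() * Lam * y;
      r0c(par) += -0.5 * arma::dot(y, Lam * y) -
        0.5 * (k * LOG2PI + logdet);
    } else {            // internal branch: integrate the child state out
      const arma::mat& Lch = Lc.slice(chl);
      const arma::mat& Mch = Mc.slice(chl);
      const arma::vec m0ch = m0c.col(chl);
      if (V.max() < 1e-14 && (-V).max() < 1e-14) {
        // (numerically) deterministic branch: substitute x_child = F x + W z
        Lc.slice(par) += F.t() * Lch * F;
        Mc.slice(par) += 2.0 * F.t() * Lch * W + F.t() * Mch;
        m0c.col(par) += F.t() * m0ch;
        Rc.slice(par) += Rc.slice(chl) + W.t() * Lch * W +
          0.5 * (Mch.t() * W + W.t() * Mch);
        r1c.col(par) += r1c.col(chl) + W.t() * m0ch;
        r0c(par) += r0c(chl);
      } else {
        arma::mat Lam;
        double logdetV;
        if (!sym_inv_logdet(V, Lam, logdetV)) {
          Rcpp::stop("singular covariance on the branch above internal "
                     "node %d", chl + 1);
        }
        arma::mat C = 0.5 * Lam - Lch;
        arma::mat Cinv;
        double logdetC;
        if (!sym_inv_logdet(C, Cinv, logdetC)) {
          Rcpp::stop("non-positive-definite integration step at internal "
                     "node %d", chl + 1);
        }
        const arma::mat B = Lam * F;
        const arma::mat G = Lam * W + Mch;
        const arma::mat BtC = B.t() * Cinv;
        Lc.slice(par) += 0.25 * BtC * B - 0.5 * F.t() * Lam * F;
        Mc.slice(par) += 0.5 * BtC * G - F.t() * Lam * W;
        m0c.col(par) += 0.5 * BtC * m0ch;
        Rc.slice(par) += Rc.slice(chl) + 0.25 * G.t() * Cinv * G -
          0.5 * W.t() * Lam * W;
        r1c.col(par) += r1c.col(chl) + 0.5 * G.t() * Cinv * m0ch;
        r0c(par) += r0c(chl) + 0.25 * arma::dot(m0ch, Cinv * m0ch) -
          0.5 * k * std::log(2.0) - 0.5 * logdetV - 0.5 * logdetC;
      }
    }
  }

  const int r = root - 1;
  return Rcpp::List::create(
      Rcpp::Named("L") = Lc.slice(r),
      Rcpp::Named("M") = Mc.slice(r),
      Rcpp::Named("m0") = m0c.col(r),
      Rcpp::Named("R") = Rc.slice(r),
      Rcpp::Named("r1") = r1c.col(r),
      Rcpp::Named("r0") = r0c(r));
  }
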