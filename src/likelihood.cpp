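// Pruning-algorithm likelihood for reversible CTMC generators, generic over
// the number of states (61 for codon models, 4 for positional GTR fits).
//
// The generator Q with stationary distribution pi satisfies detailed balance,
// so S = D^{1/2} Q D^{-1/2} (D = diag(pi)) is symmetric and
// P(t) = exp(Qt) = D^{-1/2} V exp(Lambda t) V' D^{1/2}
// with S = V Lambda V'.  One eigendecomposition per likelihood evaluation
// serves every branch of the tree.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double SCALE_THRESHOLD = 1e-80;

// Decompose a reversible generator. Returns false if eig_sym fails.
static bool rev_decompose(const arma::mat& Q, const arma::vec& pi,
                          arma::mat& A, arma::mat& B, arma::vec& lambda) {
  arma::vec sq = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= sq;         // D^{1/2} Q
  S.each_row() /= sq.t();     // D^{1/2} Q D^{-1/2}
  S = 0.5 * (S + S.t());      // symmetrize against rounding
  arma::mat V;
  if (!arma::eig_sym(lambda, V, S)) return false;
  A = V;
  A.each_col() /= sq;         // D^{-1/2} V
  B = V.t();
  B.each_row() %= sq.t();     // V' D^{1/2}
  return true;
}

static arma::mat trans_prob(const arma::mat& A, const arma::mat& B,
                            const arma::vec& lambda, double t) {
  arma::mat As = A;
  As.each_row() %= arma::exp(lambda * t).t();
  arma::mat P = As * B;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Q * P(t): same eigenbasis with lambda * exp(lambda t) weights.
static arma::mat trans_prob_deriv(const arma::mat& A, const arma::mat& B,
                                  const arma::vec& lambda, double t) {
  arma::mat As = A;
  As.each_row() %= (lambda % arma::exp(lambda * t)).t();
  return As * B;
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat& Q, const arma::vec& pi,
                                double t) {
  arma::mat A, B;
  arma::vec lambda;
  if (!rev_decompose(Q, pi, A, B, lambda))
    stop("eigendecomposition of the scaled generator failed");
  return trans_prob(A, B, lambda, t);
}

// Felsenstein pruning over compressed site patterns.
//
// edge:      (2N-2) x 2 matrix of (parent, child) node ids, 1-based ape
//            numbering (tips 1..ntip), in postorder (children before parents).
// edge_len:  branch lengths, same order.
// tip_pat:   ntip x npat integer matrix, 1-based states; NA/<=0 = missing.
// pat_w:     pattern multiplicities.
// [[Rcpp::export]]
double cpp_loglik(const arma::mat& Q, const arma::vec& pi,
                  const IntegerMatrix& edge, const NumericVector& edge_len,
                  const IntegerMatrix& tip_pat, const NumericVector& pat_w,
                  int n_node) {
  const int ns = Q.n_rows;
  const int ntip = tip_pat.nrow();
  const int npat = tip_pat.ncol();
  const int nedge = edge.nrow();
  const int ntot = ntip + n_node;

  arma::mat A, B;
  arma::vec lambda;
  if (!rev_decompose(Q, pi, A, B, lambda)) return R_NegInf;

  // conditional likelihoods, one ns x npat matrix per node (lazily allocated)
  std::vector<arma::mat> L(ntot);
  arma::rowvec logscale(npat, arma::fill::zeros);

  // number of child edges below each internal node, to know when complete
  std::vector<int> n_children(ntot, 0), seen(ntot, 0);
  for (int e = 0; e < nedge; ++e) n_children[edge(e, 0) - 1]++;

  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    arma::mat P = trans_prob(A, B, lambda, edge_len[e]);

    arma::mat down(ns, npat);
    if (chi < ntip) {
      // P * indicator column = column of P
      for (int p = 0; p < npat; ++p) {
        int s = tip_pat(chi, p);
        if (s == NA_INTEGER || s <= 0)
          down.col(p).ones();
        else
          down.col(p) = P.col(s - 1);
      }
    } else {
      down = P * L[chi];
      L[chi].reset();
    }
    if (L[par].n_elem == 0)
      L[par] = down;
    else
      L[par] %= down;

    if (++seen[par] == n_children[par] && par >= ntip) {
      // node complete: rescale patterns that have drifted small
      for (int p = 0; p < npat; ++p) {
        double m = L[par].col(p).max();
        if (m < SCALE_THRESHOLD && m > 0.0) {
          L[par].col(p) /= m;
          logscale[p] += std::log(m);
        }
      }
    }
  }

  const int root = edge(nedge - 1, 0) - 1;
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double site = arma::dot(pi, L[root].col(p));
    if (!(site > 0.0) || !std::isfinite(site)) return R_NegInf;
    ll += pat_w[p] * (std::log(site) + logscale[p]);
  }
  return ll;
}

// Log-likelihood plus its analytic gradient in the branch lengths, via a
// post-order pass (conditional likelihoods below each node) and a pre-order
// pass (partial likelihoods above each node).  For edge e = (p -> c),
// d lnL / d t_e = sum_pat w * W_e' (Q P_e) L_c / sitelik, where
// W_e = U_p o prod_{siblings} down_sib and U is the above-partial.
// No rescaling: intended for the tree sizes this package fits, where site
// likelihoods stay comfortably within double range; returns loglik = -Inf
// if a site underflows (caller falls back to the rescaled evaluator).
// [[Rcpp::export]]
List cpp_loglik_grad(const arma::mat& Q, const arma::vec& pi,
                     const IntegerMatrix& edge, const NumericVector& edge_len,
                     const IntegerMatrix& tip_pat, const NumericVector& pat_w,
                     int n_node) {
  const int ns = Q.n_rows;
  const int ntip = tip_pat.nrow();
  const int npat = tip_pat.ncol();
  const int nedge = edge.nrow();
  const int ntot = ntip + n_node;

  arma::mat A, B;
  arma::vec lambda;
  NumericVector grad(nedge);
  if (!rev_decompose(Q, pi, A, B, lambda))
    return List::create(_["loglik"] = R_NegInf, _["grad"] = grad);

  std::vector<arma::mat> L(ntot), down(nedge);
  std::vector<arma::mat> P(nedge);
  std::vector<std::vector<int>> child_edges(ntot);

  // post-order: conditional likelihoods
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    child_edges[par].push_back(e);
    P[e] = trans_prob(A, B, lambda, edge_len[e]);
    arma::mat& d = down[e];
    if (chi < ntip) {
      d.set_size(ns, npat);
      for (int p = 0; p < npat; ++p) {
        int s = tip_pat(chi, p);
        if (s == NA_INTEGER || s <= 0)
          d.col(p) = arma::sum(P[e], 1);
        else
          d.col(p) = P[e].col(s - 1);
      }
    } else {
      d = P[e] * L[chi];
    }
    if (L[par].n_elem == 0)
      L[par] = d;
    else
      L[par] %= d;
  }

  const int root = edge(nedge - 1, 0) - 1;
  arma::rowvec sitelik(npat);
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double s = arma::dot(pi, L[root].col(p));
    if (!(s > 0.0) || !std::isfinite(s))
      return List::create(_["loglik"] = R_NegInf, _["grad"] = grad);
    sitelik[p] = s;
    ll += pat_w[p] * std::log(s);
  }

  // pre-order: U[node] = above-partial; root's U is pi at every pattern
  std::vector<arma::mat> U(ntot);
  U[root] = arma::repmat(pi, 1, npat);
  for (int e = nedge - 1; e >= 0; --e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    // W = U[par] o product of sibling downs
    arma::mat W = U[par];
    for (int se : child_edges[par])
      if (se != e) W %= down[se];

    // derivative contribution of this edge
    arma::mat QP = trans_prob_deriv(A, B, lambda, edge_len[e]);
    arma::mat D(ns, npat);
    if (chi < ntip) {
      for (int p = 0; p < npat; ++p) {
        int s = tip_pat(chi, p);
        if (s == NA_INTEGER || s <= 0)
          D.col(p) = arma::sum(QP, 1);
        else
          D.col(p) = QP.col(s - 1);
      }
    } else {
      D = QP * L[chi];
    }
    double g = 0.0;
    arma::rowvec num = arma::sum(W % D, 0);
    for (int p = 0; p < npat; ++p) g += pat_w[p] * num[p] / sitelik[p];
    grad[e] = g;

    if (chi >= ntip) U[chi] = P[e].t() * W;
  }

  return List::create(_["loglik"] = ll, _["grad"] = grad);
}
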