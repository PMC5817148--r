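// Pruning-algorithm kernels for a k-state continuous-time Markov trait on a
// rooted tree (polytomies allowed).  Trees arrive in ape's postorder edge
// encoding: tips are nodes 1..ntip, the root is ntip+1, and edge rows are
// ordered so every child edge precedes the edge above it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// One-off spectral factorization of Q so P(t) = exp(Qt) is cheap per edge.
// Reduced models zero out rates and can make Q defective; the reconstruction
// check drops such cases to scaling-and-squaring (arma::expmat).
struct QExp {
  arma::mat Q;
  bool use_eig;
  arma::cx_vec eval;
  arma::cx_mat evec, evinv;

  explicit QExp(const arma::mat& Qin) : Q(Qin), use_eig(false) {
    arma::cx_vec ev;
    arma::cx_mat V;
    if (arma::eig_gen(ev, V, Q)) {
      arma::cx_mat Vi;
      if (arma::inv(Vi, V)) {
        arma::mat rec = arma::real(V * arma::diagmat(ev) * Vi);
        double scale = 1.0 + arma::norm(Q, "inf");
        if (arma::norm(rec - Q, "inf") < 1e-9 * scale) {
          use_eig = true;
          eval = ev;
          evec = V;
          evinv = Vi;
        }
      }
    }
  }

  arma::mat P(double t) const {
    const arma::uword k = Q.n_rows;
    if (t < 0.0) stop("branch length must be >= 0");
    if (t == 0.0) return arma::eye(k, k);
    arma::mat out;
    bool ok = false;
    if (use_eig) {
      out = arma::real(evec * arma::diagmat(arma::exp(eval * t)) * evinv);
      ok = out.is_finite() && out.min() > -1e-12;
    }
    if (!ok) {
      out = arma::expmat(Q * t);
      if (!out.is_finite() || out.min() < -1e-12)
        stop("transition probability matrix has entries below -1e-12");
    }
    out.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return out;
  }
};

// Scaled post-order pass.  L holds per-node conditional likelihood vectors
// (tips: indicator or all-ones for ambiguous); msgs holds the scaled
// per-edge messages P(t) %*% L[child] needed by the down pass.
struct UpPass {
  arma::mat L;       // k x (ntip + nnode)
  arma::mat msgs;    // k x nedge
  double logscale;
  bool impossible;   // data probability exactly 0

  UpPass(const arma::imat& edge, const arma::vec& elen, int ntip, int nnode,
         const arma::ivec& tipstate, const QExp& qe, arma::uword k)
      : L(k, ntip + nnode, arma::fill::ones),
        msgs(k, edge.n_rows, arma::fill::zeros),
        logscale(0.0),
        impossible(false) {
    for (int i = 0; i < ntip; ++i) {
      if (tipstate[i] >= 0) {
        L.col(i).zeros();
        L(tipstate[i], i) = 1.0;
      }
    }
    for (arma::uword e = 0; e < edge.n_rows; ++e) {
      int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      arma::vec msg = qe.P(elen[e]) * L.col(c);
      double m = msg.max();
      if (m <= 0.0 || !std::isfinite(m)) {
        impossible = true;
        return;
      }
      msg /= m;
      logscale += std::log(m);
      msgs.col(e) = msg;
      L.col(p) %= msg;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat& Q, double t) {
  QExp qe(Q);
  return qe.P(t);
}

// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge, const arma::vec& elen, int ntip,
                     int nnode, const arma::ivec& tipstate, const arma::mat& Q,
                     const arma::vec& pi) {
  QExp qe(Q);
  UpPass up(edge, elen, ntip, nnode, tipstate, qe, Q.n_rows);
  if (up.impossible) return R_NegInf;
  double lik = arma::dot(pi, up.L.col(ntip));
  if (lik <= 0.0 || !std::isfinite(lik)) return R_NegInf;
  return std::log(lik) + up.logscale;
}

// Marginal posterior state probabilities at every node, via the standard
// up-pass/down-pass.  Sibling contributions are recomputed by explicit
// exclusion products (no division), so zero messages are handled exactly.
// [[Rcpp::export]]
arma::mat cpp_mk_marginals(const arma::imat& edge, const arma::vec& elen,
                           int ntip, int nnode, const arma::ivec& tipstate,
                           const arma::mat& Q, const arma::vec& pi) {
  const arma::uword k = Q.n_rows;
  const int nnodes_total = ntip + nnode;
  QExp qe(Q);
  UpPass up(edge, elen, ntip, nnode, tipstate, qe, k);
  if (up.impossible || arma::dot(pi, up.L.col(ntip)) <= 0.0)
    stop("data have probability 0 under (Q, pi); marginals undefined");

  // child-edge lists per parent
  std::vector<std::vector<arma::uword>> kids(nnodes_total);
  for (arma::uword e = 0; e < edge.n_rows; ++e) kids[edge(e, 0) - 1].push_back(e);

  arma::mat D(k, nnodes_total, arma::fill::zeros);
  D.col(ntip) = pi;  // root
  for (arma::uword r = edge.n_rows; r-- > 0;) {  // reverse postorder = parents first
    int p = edge(r, 0) - 1, c = edge(r, 1) - 1;
    arma::vec excl = D.col(p);
    for (arma::uword f : kids[p])
      if (f != r) excl %= up.msgs.col(f);
    arma::vec dc = qe.P(elen[r]).t() * excl;
    double m = dc.max();
    if (m > 0.0) dc /= m;  // rescale; marginals are normalized below
    D.col(c) = dc;
  }

  arma::mat marg(k, nnodes_total);
  for (int v = 0; v < nnodes_total; ++v) {
    arma::vec w = D.col(v) % up.L.col(v);
    double s = arma::accu(w);
    if (s <= 0.0) stop("marginal normalization failed (zero posterior mass at a node)");
    marg.col(v) = w / s;
  }
  return marg;
}
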