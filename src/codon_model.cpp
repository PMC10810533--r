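// Codon substitution model core: MG94/GTR-style rate matrices over the
// sense codons of an arbitrary genetic code, branch-site random-effects
// mixtures, and Felsenstein pruning. Rate matrices are reversible
// (pi_i q_ij = pi_j q_ji), so transition probabilities come from a
// symmetric eigendecomposition, which is also what makes per-branch
// omega-category mixtures cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the scaled rate matrix Q(omega). Transitions are single-nucleotide
// codon changes i->j with rate rho[pair] * pi[j], multiplied by omega when
// the change is nonsynonymous. 'scale' divides Q so that branch lengths are
// expected substitutions per codon under the neutral (omega = 1) matrix;
// the same factor is shared by all omega categories so that relative rates
// across categories are preserved.
static arma::mat build_Q(const arma::vec& pi, const arma::vec& rho,
                         const IntegerVector& tr_i, const IntegerVector& tr_j,
                         const IntegerVector& tr_pair, const IntegerVector& tr_nonsyn,
                         double omega, double scale) {
  const int S = pi.n_elem;
  arma::mat Q(S, S, arma::fill::zeros);
  const int nt = tr_i.size();
  for (int k = 0; k < nt; ++k) {
    double r = rho[tr_pair[k]] * pi[tr_j[k]];
    if (tr_nonsyn[k]) r *= omega;
    Q(tr_i[k], tr_j[k]) = r;
  }
  Q.diag() = -arma::sum(Q, 1);
  if (scale > 0) Q /= scale;
  return Q;
}

// neutral mean rate used as the common scaling factor
static double neutral_rate(const arma::vec& pi, const arma::vec& rho,
                           const IntegerVector& tr_i, const IntegerVector& tr_j,
                           const IntegerVector& tr_pair, const IntegerVector& tr_nonsyn) {
  arma::mat Q1 = build_Q(pi, rho, tr_i, tr_j, tr_pair, tr_nonsyn, 1.0, -1.0);
  return -arma::dot(pi, Q1.diag());
}

struct Eigensystem {
  arma::vec lam;
  arma::mat U;       // columns: eigenvectors of the symmetrised matrix
  arma::vec d, dinv; // sqrt(pi) and its inverse
};

static Eigensystem eigen_Q(const arma::mat& Q, const arma::vec& pi) {
  Eigensystem es;
  es.d = arma::sqrt(pi);
  es.dinv = 1.0 / es.d;
  arma::mat B = arma::diagmat(es.d) * Q * arma::diagmat(es.dinv);
  B = 0.5 * (B + B.t());
  arma::eig_sym(es.lam, es.U, B);
  return es;
}

static arma::mat pmat_from_eigen(const Eigensystem& es, double t) {
  arma::mat P = arma::diagmat(es.dinv) * es.U *
                arma::diagmat(arma::exp(es.lam * t)) * es.U.t() *
                arma::diagmat(es.d);
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmatrix(const arma::vec& pi, const arma::vec& rho,
                      const IntegerVector& tr_i, const IntegerVector& tr_j,
                      const IntegerVector& tr_pair, const IntegerVector& tr_nonsyn,
                      double omega, double t) {
  double mu = neutral_rate(pi, rho, tr_i, tr_j, tr_pair, tr_nonsyn);
  arma::mat Q = build_Q(pi, rho, tr_i, tr_j, tr_pair, tr_nonsyn, omega, mu);
  return pmat_from_eigen(eigen_Q(Q, pi), t);
}

// Total and per-site log-likelihood by pruning with per-branch mixture
// transition matrices P_b = sum_k w_k P(omega_k, t_b). Mixing collapses to
// the branch level because each branch x site draws its omega category
// independently of every other branch.
//
// tip_states: ntips x nsites, 0-based sense-codon index, -1 = missing.
// edge: nedges x 2 (1-based ape node numbers), ordered children-first.
// edge_dist: 1-based index into dists for each edge.
// dists: list of list(omega = numeric, weight = numeric).
// [[Rcpp::export]]
List cpp_codon_loglik(const IntegerMatrix& tip_states,
                      const IntegerMatrix& edge,
                      int n_nodes,
                      const NumericVector& edge_len,
                      const IntegerVector& edge_dist,
                      const List& dists,
                      const arma::vec& pi, const arma::vec& rho,
                      const IntegerVector& tr_i, const IntegerVector& tr_j,
                      const IntegerVector& tr_pair, const IntegerVector& tr_nonsyn) {
  const int S = pi.n_elem;
  const int ntips = tip_states.nrow();
  const int nsites = tip_states.ncol();
  const int nedges = edge.nrow();
  const int root = ntips + 1;

  double mu = neutral_rate(pi, rho, tr_i, tr_j, tr_pair, tr_nonsyn);

  // eigendecompositions per (distribution, category)
  std::vector<std::vector<Eigensystem>> eigs(dists.size());
  std::vector<arma::vec> weights(dists.size());
  for (int d = 0; d < dists.size(); ++d) {
    List dd = dists[d];
    arma::vec om = as<arma::vec>(dd["omega"]);
    weights[d] = as<arma::vec>(dd["weight"]);
    eigs[d].resize(om.n_elem);
    for (arma::uword k = 0; k < om.n_elem; ++k) {
      arma::mat Q = build_Q(pi, rho, tr_i, tr_j, tr_pair, tr_nonsyn, om[k], mu);
      eigs[d][k] = eigen_Q(Q, pi);
    }
  }

  std::vector<arma::mat> partial(n_nodes + 1);
  arma::rowvec logscale(nsites, arma::fill::zeros);

  for (int e = 0; e < nedges; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    int d = edge_dist[e] - 1;
    arma::mat P(S, S, arma::fill::zeros);
    for (arma::uword k = 0; k < weights[d].n_elem; ++k) {
      P += weights[d][k] * pmat_from_eigen(eigs[d][k], edge_len[e]);
    }
    arma::mat C;
    if (c <= ntips) {
      C.set_size(S, nsites);
      for (int s = 0; s < nsites; ++s) {
        int st = tip_states(c - 1, s);
        if (st >= 0) C.col(s) = P.col(st);
        else C.col(s).ones();
      }
    } else {
      C = P * partial[c];
      partial[c].reset();
    }
    if (partial[p].is_empty()) partial[p] = arma::mat(S, nsites, arma::fill::ones);
    partial[p] %= C;
    // per-site rescale to avoid underflow on deep trees
    arma::rowvec mx = arma::max(partial[p], 0);
    mx.elem(arma::find(mx <= 0)).ones();
    partial[p].each_row() /= mx;
    logscale += arma::log(mx);
  }

  arma::rowvec site_l = pi.t() * partial[root];
  arma::rowvec site_ll = arma::log(site_l) + logscale;
  return List::create(_["loglik"] = arma::accu(site_ll),
                      _["site_loglik"] = NumericVector(site_ll.begin(), site_ll.end()));
}
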