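#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Felsenstein pruning over a k-state CTMC, generic fallback path: one matrix
// exponential per edge (Pade scaling-and-squaring via arma::expmat).
// [[Rcpp::export]]
double pruning_loglik_cpp(const IntegerMatrix edge, const NumericVector elen,
                          const int ntip, const int nnode,
                          const IntegerVector tip_state, const arma::mat Q,
                          const arma::vec root_p) {
  const int k = Q.n_rows;
  const int ntot = ntip + nnode;
  arma::mat L(ntot, k, arma::fill::ones);
  arma::vec lscale(ntot, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) {
    L.row(i).zeros();
    L(i, tip_state[i] - 1) = 1.0;
  }
  const int nedge = edge.nrow();
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    arma::mat P = arma::expmat(Q * elen[e]);
    arma::vec v = P * L.row(chi).t();
    double mx = v.max();
    if (!(mx > 0.0)) return R_NegInf;
    v /= mx;
    L.row(par) %= v.t();
    lscale[par] += lscale[chi] + std::log(mx);
  }
  const int root = ntip;  // ape numbers the root ntip + 1
  double lik = arma::dot(root_p, L.row(root).t());
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + lscale[root];
}

// Build the 4x4 generator of the joint chain from the eight permitted rates
// in the package order q12, q21, q13, q31, q24, q42, q34, q43 (0-based cells).
static arma::mat joint_generator(const arma::vec& rates) {
  arma::mat Q(4, 4, arma::fill::zeros);
  Q(0, 1) = rates[0];  Q(1, 0) = rates[1];
  Q(0, 2) = rates[2];  Q(2, 0) = rates[3];
  Q(1, 3) = rates[4];  Q(3, 1) = rates[5];
  Q(2, 3) = rates[6];  Q(3, 2) = rates[7];
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Fast pruning for the 4-state joint chain: eigen-decompose Q once and
// propagate partial likelihoods as V exp(lambda t) V^{-1} x (two complex
// 4x4 mat-vec products per edge). Falls back to per-edge expmat when the
// decomposition is unusable (defective or ill-conditioned Q).
// [[Rcpp::export]]
double pruning_loglik_rates_cpp(const IntegerMatrix edge, const NumericVector elen,
                                const int ntip, const int nnode,
                                const IntegerVector tip_state,
                                const arma::vec rates, const arma::vec root_p) {
  arma::mat Q = joint_generator(rates);
  arma::cx_vec lam;
  arma::cx_mat V;
  bool have_eig = arma::eig_gen(lam, V, Q);
  arma::cx_mat Vinv;
  if (have_eig) have_eig = arma::inv(Vinv, V);
  if (have_eig) {
    // sanity: propagator at the first edge must be a stochastic row map
    arma::cx_vec el = arma::exp(lam * elen[0]);
    arma::cx_mat P = V * arma::diagmat(el) * Vinv;
    if (arma::norm(arma::imag(P), "inf") > 1e-8 ||
        arma::any(arma::vectorise(arma::real(P)) < -1e-8))
      have_eig = false;
  }
  const int ntot = ntip + nnode;
  arma::mat L(ntot, 4, arma::fill::ones);
  arma::vec lscale(ntot, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) {
    L.row(i).zeros();
    L(i, tip_state[i] - 1) = 1.0;
  }
  const int nedge = edge.nrow();
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    arma::vec v(4);
    if (have_eig) {
      arma::cx_vec tmp = Vinv * arma::cx_vec(L.row(chi).t(), arma::vec(4, arma::fill::zeros));
      tmp %= arma::exp(lam * elen[e]);
      v = arma::real(V * tmp);
      v.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    } else {
      v = arma::expmat(Q * elen[e]) * L.row(chi).t();
    }
    double mx = v.max();
    if (!(mx > 0.0)) return R_NegInf;
    v /= mx;
    L.row(par) %= v.t();
    lscale[par] += lscale[chi] + std::log(mx);
  }
  const int root = ntip;
  double lik = arma::dot(root_p, L.row(root).t());
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + lscale[root];
}
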