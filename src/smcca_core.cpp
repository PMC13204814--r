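// Penalized-matrix-decomposition core for sparse multiple CCA.
//
// The hot paths (coordinate-ascent component fits inside permutation and
// leave-one-out loops) live here; all RNG stays on the R side, which passes
// pre-drawn permutation indices down.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static vec soft_thr(const vec& x, double d) {
  return arma::sign(x) % arma::max(arma::abs(x) - d, arma::zeros<vec>(x.n_elem));
}

// w = S(x, d)/||S(x, d)||_2 with the smallest d >= 0 s.t. ||w||_1 <= c.
// Feasible for any c >= 1 because the one-hot limit has L1 norm 1.
static vec l1_project(const vec& x, double c) {
  const double nx2 = arma::norm(x, 2);
  if (nx2 == 0.0) return arma::zeros<vec>(x.n_elem);
  vec w = x / nx2;
  if (arma::accu(arma::abs(w)) <= c + 1e-12) return w;
  double lo = 0.0, hi = arma::abs(x).max();
  for (int it = 0; it < 200 && (hi - lo) > 1e-15 * (1.0 + hi); ++it) {
    const double mid = 0.5 * (lo + hi);
    const vec s = soft_thr(x, mid);
    const double n2 = arma::norm(s, 2);
    const double ratio = (n2 > 0.0) ? arma::accu(arma::abs(s)) / n2 : 0.0;
    if (ratio > c) lo = mid; else hi = mid;
  }
  vec s = soft_thr(x, hi);
  double n2 = arma::norm(s, 2);
  if (n2 == 0.0 || arma::accu(arma::abs(s)) / n2 > c + 1e-8) {
    // exact ties at the maximum: degenerate bracket, return one-hot optimum
    uword i = arma::abs(x).index_max();
    vec w1 = arma::zeros<vec>(x.n_elem);
    w1(i) = (x(i) >= 0.0) ? 1.0 : -1.0;
    return w1;
  }
  return s / n2;
}

// [[Rcpp::export]]
NumericVector cpp_soft_threshold(NumericVector x, double d) {
  vec xx(x.begin(), x.size(), false);
  vec out = soft_thr(xx, d);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericVector cpp_l1_project(NumericVector x, double c) {
  vec xx(x.begin(), x.size(), false);
  vec out = l1_project(xx, c);
  return NumericVector(out.begin(), out.end());
}

static double objective(const arma::field<mat>& C,
                        const arma::field<vec>& w, int K) {
  double o = 0.0;
  for (int i = 0; i < K; ++i)
    for (int j = i + 1; j < K; ++j)
      o += arma::dot(w(i), C(i, j) * w(j));
  return o;
}

struct ComponentFit {
  arma::field<vec> w;
  std::vector<double> trace;
  int iters = 0;
  bool converged = false;
  bool degenerate = false;
  double obj = 0.0;
};

// Cyclic block coordinate ascent from a given initialization.
static ComponentFit ascend(const arma::field<mat>& C, const vec& pen,
                           arma::field<vec> w, int K, double tol, int maxit) {
  ComponentFit fit;
  for (int it = 1; it <= maxit; ++it) {
    double maxchg = 0.0;
    for (int i = 0; i < K; ++i) {
      vec v = arma::zeros<vec>(w(i).n_elem);
      for (int j = 0; j < K; ++j) {
        if (j == i) continue;
        v += (j > i) ? C(i, j) * w(j) : mat(C(j, i).t()) * w(j);
      }
      vec wn = (arma::norm(v, 2) == 0.0) ? arma::zeros<vec>(v.n_elem)
                                         : l1_project(v, pen(i));
      const double chg = arma::abs(wn - w(i)).max();
      if (chg > maxchg) maxchg = chg;
      w(i) = wn;
    }
    fit.trace.push_back(objective(C, w, K));
    fit.iters = it;
    if (maxchg < tol) { fit.converged = true; break; }
  }
  fit.obj = objective(C, w, K);
  for (int i = 0; i < K; ++i)
    if (arma::norm(w(i), 2) == 0.0) fit.degenerate = true;
  fit.w = w;
  return fit;
}

static double pearson(const vec& a, const vec& b) {
  const double sa = arma::stddev(a), sb = arma::stddev(b);
  if (sa == 0.0 || sb == 0.0) return 0.0;
  mat r = arma::cor(a, b);
  return r(0, 0);
}

struct MultiFit {
  std::vector<mat> W;          // per block: p_i x ndims
  mat corr;                    // npairs x ndims
  vec obj;                     // ndims
  std::vector<std::vector<double>> traces;
  std::vector<int> iters;
  std::vector<bool> conv;
  std::vector<bool> degen;
};

// Full multi-dimension fit: multi-start coordinate ascent + sign convention
// + deflation. X matrices are assumed standardized upstream.
static MultiFit fit_multi_core(const std::vector<mat>& X, const vec& pen,
                               int ndims, double tol, int maxit,
                               int extra_starts) {
  const int K = (int)X.size();
  const int npairs = K * (K - 1) / 2;
  arma::field<mat> C(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = i + 1; j < K; ++j)
      C(i, j) = X[i].t() * X[j];

  // deterministic SVD initialization, sign-fixed
  arma::field<vec> w0(K);
  for (int i = 0; i < K; ++i) {
    mat U, V;
    vec s;
    arma::svd_econ(U, s, V, X[i]);
    vec v = V.col(0);
    if (v(arma::abs(v).index_max()) < 0) v = -v;
    w0(i) = v;
  }

  MultiFit out;
  out.W.resize(K);
  for (int i = 0; i < K; ++i) out.W[i].set_size(X[i].n_cols, ndims);
  out.corr.set_size(npairs, ndims);
  out.obj.set_size(ndims);

  for (int d = 0; d < ndims; ++d) {
    // starts: SVD init, plus one-hot inits of blocks 2..K at their strongest
    // coordinates (by combined squared cross-covariance)
    std::vector<arma::field<vec>> starts;
    starts.push_back(w0);
    for (int i = 1; i < K; ++i) {
      const int pi = (int)X[i].n_cols;
      vec m = arma::zeros<vec>(pi);
      for (int j = 0; j < K; ++j) {
        if (j == i) continue;
        const mat& Cij = (j < i) ? C(j, i) : C(i, j);
        m += (j < i) ? vec(arma::sum(arma::square(Cij), 0).t())
                     : vec(arma::sum(arma::square(Cij), 1));
      }
      arma::uvec ord = arma::sort_index(m, "descend");
      const int q = std::min(extra_starts, pi);
      for (int t = 0; t < q; ++t) {
        arma::field<vec> ws = w0;
        vec oh = arma::zeros<vec>(pi);
        oh(ord(t)) = 1.0;
        ws(i) = oh;
        starts.push_back(ws);
      }
    }

    ComponentFit best;
    bool have = false;
    for (size_t s = 0; s < starts.size(); ++s) {
      ComponentFit f = ascend(C, pen, starts[s], K, tol, maxit);
      if (!have || f.obj > best.obj) { best = f; have = true; }
    }

    // score correlations and sign convention
    std::vector<vec> z(K);
    for (int i = 0; i < K; ++i) z[i] = X[i] * best.w(i);
    mat rmat(K, K, arma::fill::zeros);
    for (int i = 0; i < K; ++i)
      for (int j = i + 1; j < K; ++j)
        rmat(i, j) = pearson(z[i], z[j]);
    // exhaustive sign flips (s_0 = +1) maximizing sum of pairwise r
    std::vector<int> bestsign(K, 1);
    double bestsum = -1e300;
    const int ncfg = 1 << (K - 1);
    for (int cfg = 0; cfg < ncfg; ++cfg) {
      std::vector<int> sg(K, 1);
      for (int i = 1; i < K; ++i) sg[i] = (cfg >> (i - 1)) & 1 ? -1 : 1;
      double tot = 0.0;
      for (int i = 0; i < K; ++i)
        for (int j = i + 1; j < K; ++j)
          tot += sg[i] * sg[j] * rmat(i, j);
      if (tot > bestsum + 1e-15) { bestsum = tot; bestsign = sg; }
    }
    for (int i = 0; i < K; ++i) best.w(i) *= bestsign[i];
    // largest-|weight| entry of block 1 positive (global flip, r preserved)
    if (arma::norm(best.w(0), 2) > 0.0) {
      const vec& w1 = best.w(0);
      if (w1(arma::abs(w1).index_max()) < 0)
        for (int i = 0; i < K; ++i) best.w(i) = -best.w(i);
    }
    for (int i = 0; i < K; ++i) z[i] = X[i] * best.w(i);
    int pr = 0;
    for (int i = 0; i < K; ++i)
      for (int j = i + 1; j < K; ++j)
        out.corr(pr++, d) = pearson(z[i], z[j]);

    out.obj(d) = objective(C, best.w, K);
    for (int i = 0; i < K; ++i) out.W[i].col(d) = best.w(i);
    out.traces.push_back(best.trace);
    out.iters.push_back(best.iters);
    out.conv.push_back(best.converged);
    out.degen.push_back(best.degenerate);

    // deflate: C_ij <- C_ij - (w_i' C_ij w_j) w_i w_j'
    for (int i = 0; i < K; ++i)
      for (int j = i + 1; j < K; ++j) {
        const double dij = arma::dot(best.w(i), C(i, j) * best.w(j));
        C(i, j) -= dij * (best.w(i) * best.w(j).t());
      }
  }
  return out;
}

static List multifit_to_list(const MultiFit& f, int K) {
  List W(K);
  for (int i = 0; i < K; ++i) W[i] = wrap(f.W[i]);
  List traces(f.traces.size());
  for (size_t d = 0; d < f.traces.size(); ++d) traces[d] = wrap(f.traces[d]);
  return List::create(_["weights"] = W,
                      _["corr"] = wrap(f.corr),
                      _["objective"] = wrap(f.obj),
                      _["trace"] = traces,
                      _["iterations"] = wrap(f.iters),
                      _["converged"] = wrap(f.conv),
                      _["degenerate"] = wrap(f.degen));
}

// [[Rcpp::export]]
List cpp_fit_multi(List Xs, NumericVector penalties, int ndims, double tol,
                   int maxit, int extra_starts) {
  const int K = Xs.size();
  std::vector<mat> X(K);
  for (int i = 0; i < K; ++i) X[i] = as<mat>(Xs[i]);
  vec pen(penalties.begin(), penalties.size());
  MultiFit f = fit_multi_core(X, pen, ndims, tol, maxit, extra_starts);
  return multifit_to_list(f, K);
}

// Permutation null engine: for each of B permutations (indices pre-drawn in
// R, 1-based, one B x n matrix per block), row-shuffle every block
// independently, refit, and record pairwise score correlations and weights.
// Weights keep the solver's own canonical sign convention (a deterministic
// function of each fit, independent of the observed solution) so that the
// recorded null is exchangeable with the observed statistics.
// [[Rcpp::export]]
List cpp_perm_null(List Xs, NumericVector penalties, int ndims, List permIdx,
                   double tol, int maxit, int extra_starts) {
  const int K = Xs.size();
  std::vector<mat> X(K);
  for (int i = 0; i < K; ++i) X[i] = as<mat>(Xs[i]);
  vec pen(penalties.begin(), penalties.size());
  std::vector<arma::imat> perms(K);
  for (int i = 0; i < K; ++i) perms[i] = as<arma::imat>(permIdx[i]);

  const int B = (int)perms[0].n_rows;
  const int npairs = K * (K - 1) / 2;
  arma::cube nullCorr(B, npairs, ndims, arma::fill::zeros);
  std::vector<arma::cube> nullW(K);
  for (int i = 0; i < K; ++i)
    nullW[i].set_size(X[i].n_cols, ndims, B);

  std::vector<mat> Xp(K);
  for (int b = 0; b < B; ++b) {
    if (b % 50 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < K; ++i) {
      arma::uvec idx(X[i].n_rows);
      for (uword r = 0; r < idx.n_elem; ++r)
        idx(r) = (uword)(perms[i](b, r) - 1);
      Xp[i] = X[i].rows(idx);
    }
    MultiFit f = fit_multi_core(Xp, pen, ndims, tol, maxit, extra_starts);
    for (int d = 0; d < ndims; ++d)
      for (int p = 0; p < npairs; ++p)
        nullCorr(b, p, d) = f.corr(p, d);
    for (int i = 0; i < K; ++i) nullW[i].slice(b) = f.W[i];
  }
  List Wout(K);
  for (int i = 0; i < K; ++i) Wout[i] = wrap(nullW[i]);
  return List::create(_["corr"] = wrap(nullCorr), _["weights"] = Wout);
}
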