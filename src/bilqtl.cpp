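#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the 3-state genotype HMM with a
// distance-heterogeneous transition matrix. `emit` holds per-marker emission
// likelihoods (rows = markers, cols = states), `d` the cM distance of each
// marker to its predecessor (d[0] ignored). The transition matrix at distance
// d has diagonal exp(-d^2 / (2 sigma^2)); the off-diagonal mass is split
// between the two alternative states either equally or proportionally to the
// stationary priors.
// [[Rcpp::export(name = ".fb_cpp")]]
NumericMatrix fb_cpp(NumericMatrix emit, NumericVector d, double sigma,
                     NumericVector prior, int prior_weighted) {
  const int n = emit.nrow();
  const int S = 3;
  NumericMatrix post(n, S);
  if (n == 0) return post;

  NumericMatrix alpha(n, S), beta(n, S);
  NumericVector scale(n);

  // per-step transition matrices
  std::vector<double> T(static_cast<size_t>(n) * S * S);
  for (int t = 1; t < n; ++t) {
    double stay = std::exp(-(d[t] * d[t]) / (2.0 * sigma * sigma));
    double change = 1.0 - stay;
    for (int i = 0; i < S; ++i) {
      double wsum = 0.0;
      for (int j = 0; j < S; ++j) if (j != i) {
        wsum += prior_weighted ? prior[j] : 1.0;
      }
      for (int j = 0; j < S; ++j) {
        double v;
        if (i == j) v = stay;
        else v = change * (prior_weighted ? prior[j] : 1.0) / wsum;
        T[(static_cast<size_t>(t) * S + i) * S + j] = v;
      }
    }
  }

  // forward
  double c0 = 0.0;
  for (int j = 0; j < S; ++j) {
    alpha(0, j) = prior[j] * emit(0, j);
    c0 += alpha(0, j);
  }
  if (c0 <= 0) stop("zero forward mass at marker 1");
  for (int j = 0; j < S; ++j) alpha(0, j) /= c0;
  scale[0] = c0;
  for (int t = 1; t < n; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) {
        s += alpha(t - 1, i) * T[(static_cast<size_t>(t) * S + i) * S + j];
      }
      alpha(t, j) = s * emit(t, j);
      ct += alpha(t, j);
    }
    if (ct <= 0) stop("zero forward mass at marker %d", t + 1);
    for (int j = 0; j < S; ++j) alpha(t, j) /= ct;
    scale[t] = ct;
  }

  // backward (scaled by the forward constants)
  for (int j = 0; j < S; ++j) beta(n - 1, j) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j) {
        s += T[(static_cast<size_t>(t + 1) * S + i) * S + j] *
             emit(t + 1, j) * beta(t + 1, j);
      }
      beta(t, i) = s / scale[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double tot = 0.0;
    for (int j = 0; j < S; ++j) {
      post(t, j) = alpha(t, j) * beta(t, j);
      tot += post(t, j);
    }
    for (int j = 0; j < S; ++j) post(t, j) /= tot;
  }
  return post;
}

static inline double mcplus(double bt, double alpha, double gamma) {
  double a = std::fabs(bt);
  if (a <= alpha) return 0.0;
  if (a <= alpha * gamma) {
    return ((bt > 0) - (bt < 0)) * (a - alpha) / (1.0 - 1.0 / gamma);
  }
  return bt;
}

// one coordinate-descent solve at fixed (alpha, gamma), warm-started from
// the beta/residual passed in; alternates full sweeps with active-set
// iterations until no coordinate moves more than tol
static bool cd_solve(const NumericMatrix &X, std::vector<double> &beta,
                     std::vector<double> &r, double alpha, double gamma,
                     double tol, int max_sweeps, int &sweeps) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> active;
  active.reserve(256);
  while (sweeps < max_sweeps) {
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      double g = 0.0;
      const double *xj = X.begin() + static_cast<size_t>(j) * n;
      for (int i = 0; i < n; ++i) g += xj[i] * r[i];
      double bt = beta[j] + g / n;
      double bn = mcplus(bt, alpha, gamma);
      double dlt = bn - beta[j];
      if (dlt != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * dlt;
        beta[j] = bn;
      }
      if (std::fabs(dlt) > maxd) maxd = std::fabs(dlt);
    }
    ++sweeps;
    if (maxd < tol) return true;
    active.clear();
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (sweeps < max_sweeps) {
      double amax = 0.0;
      for (size_t k = 0; k < active.size(); ++k) {
        int j = active[k];
        double g = 0.0;
        const double *xj = X.begin() + static_cast<size_t>(j) * n;
        for (int i = 0; i < n; ++i) g += xj[i] * r[i];
        double bt = beta[j] + g / n;
        double bn = mcplus(bt, alpha, gamma);
        double dlt = bn - beta[j];
        if (dlt != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * dlt;
          beta[j] = bn;
        }
        if (std::fabs(dlt) > amax) amax = std::fabs(dlt);
      }
      ++sweeps;
      if (amax < tol) break;
    }
  }
  return false;
}

// Coordinate-descent MC+ (SparseNet-style) surface over an (alpha, gamma)
// grid. X must be standardized so that each column has mean 0 and mean
// square 1; y must be centered. Double warm starts: the alpha path runs from
// sparse (large alpha) to dense, and at each alpha the gamma sequence is
// relaxed from most convex (lasso-like, largest gamma) to most concave, each
// gamma solve starting from the previous gamma's solution at the same alpha
// -- the recalibration scheme of the original SparseNet algorithm, which
// keeps the nonconvex solves on the solution branch reached from the convex
// end rather than in arbitrary local minima.
// Returns, per (gamma, alpha), the nonzero indices (1-based) and values.
// [[Rcpp::export(name = ".mcplus_path_cpp")]]
List mcplus_path_cpp(NumericMatrix X, NumericVector y, NumericVector alphas,
                     NumericVector gammas, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  const int na = alphas.size(), ng = gammas.size();

  // persistent state for the most-convex gamma's alpha path
  std::vector<double> beta0(p, 0.0), r0(y.begin(), y.end());
  std::vector<double> beta(p), r(n);

  // results[gi][ai]
  std::vector<List> results(static_cast<size_t>(ng) * na);

  for (int ai = 0; ai < na; ++ai) {
    double alpha = alphas[ai];
    for (int gi = 0; gi < ng; ++gi) {
      double gamma = gammas[gi];
      int sweeps = 0;
      bool converged;
      if (gi == 0) {
        converged = cd_solve(X, beta0, r0, alpha, gamma, tol, max_sweeps,
                             sweeps);
        beta = beta0;
        r = r0;
      } else {
        // relax the previous (more convex) solution at this alpha
        converged = cd_solve(X, beta, r, alpha, gamma, tol, max_sweeps,
                             sweeps);
      }
      std::vector<int> idx;
      std::vector<double> val;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) {
        idx.push_back(j + 1);
        val.push_back(beta[j]);
      }
      results[static_cast<size_t>(gi) * na + ai] =
        List::create(_["index"] = wrap(idx), _["beta"] = wrap(val),
                     _["converged"] = converged, _["sweeps"] = sweeps);
    }
  }

  List out(ng);
  for (int gi = 0; gi < ng; ++gi) {
    List per_alpha(na);
    for (int ai = 0; ai < na; ++ai) {
      per_alpha[ai] = results[static_cast<size_t>(gi) * na + ai];
    }
    out[gi] = per_alpha;
  }
  return out;
}
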