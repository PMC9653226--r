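#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fill the closed-form transition matrix for a window-homogeneous segment
// [a, b]. States (row-major, k = S + 2): 0 unedited, 1 silenced, 2.. scars.
static void seg_P(double a, double b, double t1, double t2, double r,
                  const double* s, double sigma, double l, int S, double* P) {
  const int k = S + 2;
  const double d = b - a;
  const double surv = std::exp(-l * d);
  const double sil = -std::expm1(-l * d);
  std::fill(P, P + k * k, 0.0);
  P[1 * k + 1] = 1.0;
  for (int i = 0; i < S; ++i) {
    P[(2 + i) * k + (2 + i)] = surv;
    P[(2 + i) * k + 1] = sil;
  }
  const double mid = 0.5 * (a + b);
  const bool inside = (mid >= t1) && (mid <= t2) && d > 0;
  if (inside) {
    const double rs = r * sigma;
    P[0] = std::exp(-(l + rs) * d);
    if (sigma > 0) {
      const double edited = -std::expm1(-rs * d);
      for (int i = 0; i < S; ++i)
        P[0 * k + 2 + i] = (s[i] / sigma) * surv * edited;
    }
    P[0 * k + 1] = sil;
  } else {
    P[0] = surv;
    P[0 * k + 1] = sil;
  }
}

// P over an arbitrary branch [ta, tb]: ordered product of the <= 3
// window-homogeneous segments cut at t1 and t2.
static void branch_P(double ta, double tb, double t1, double t2, double r,
                     const double* s, double sigma, double l, int S,
                     double* P, double* tmpA, double* tmpB) {
  const int k = S + 2;
  double cuts[4];
  int nc = 0;
  cuts[nc++] = ta;
  if (t1 > ta && t1 < tb) cuts[nc++] = t1;
  if (t2 > ta && t2 < tb && t2 != t1) cuts[nc++] = t2;
  cuts[nc++] = tb;
  // identity
  std::fill(P, P + k * k, 0.0);
  for (int i = 0; i < k; ++i) P[i * k + i] = 1.0;
  for (int c = 0; c + 1 < nc; ++c) {
    seg_P(cuts[c], cuts[c + 1], t1, t2, r, s, sigma, l, S, tmpA);
    // tmpB = P * tmpA
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) {
        double acc = 0.0;
        for (int h = 0; h < k; ++h) acc += P[i * k + h] * tmpA[h * k + j];
        tmpB[i * k + j] = acc;
      }
    std::copy(tmpB, tmpB + k * k, P);
  }
}

//' @title Pruning log-likelihood core (internal)
//' @description Felsenstein pruning over a node-table tree with per-branch
//'   closed-form transition matrices and per-site scaling. Internal; called
//'   by tree_log_likelihood().
//' @param parent 0-based parent index per node, -1 for the origin.
//' @param porder node indices (0-based) in postorder (children first).
//' @param node_time forward node times.
//' @param tip_row per node: 0-based row into states, -1 for internal nodes.
//' @param states tips x sites integer matrix (0 unedited, 1 silenced,
//'   2.. scars), NA = missing.
//' @param r,l per-group edit and silencing rates.
//' @param smat scar-multiplier matrix, S x groups.
//' @param group 0-based group index per site.
//' @param t1,t2 scarring window.
//' @return numeric vector of per-site log-likelihoods.
//' @keywords internal
// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerVector parent, IntegerVector porder,
                               NumericVector node_time, IntegerVector tip_row,
                               IntegerMatrix states, NumericVector r,
                               NumericVector l, NumericMatrix smat,
                               IntegerVector group, double t1, double t2) {
  const int nn = parent.size();
  const int m = states.ncol();
  const int S = smat.nrow();
  const int G = r.size();
  const int k = S + 2;

  std::vector<double> part((size_t)nn * k * m);
  std::vector<double> logscale(m, 0.0);
  std::vector<double> sigma(G);
  for (int g = 0; g < G; ++g) {
    double acc = 0.0;
    for (int i = 0; i < S; ++i) acc += smat(i, g);
    sigma[g] = acc;
  }

  // initialize partials: ones for internal, indicator (or ones) for tips
  for (int nd = 0; nd < nn; ++nd) {
    double* p = &part[(size_t)nd * k * m];
    if (tip_row[nd] < 0) {
      std::fill(p, p + k * m, 1.0);
    } else {
      std::fill(p, p + k * m, 0.0);
      for (int j = 0; j < m; ++j) {
        int st = states(tip_row[nd], j);
        if (st == NA_INTEGER) {
          for (int a = 0; a < k; ++a) p[j * k + a] = 1.0;
        } else {
          p[j * k + st] = 1.0;
        }
      }
    }
  }

  std::vector<double> P((size_t)G * k * k), tmpA(k * k), tmpB(k * k);
  std::vector<double> msg(k);
  int origin = -1;

  for (int oi = 0; oi < nn; ++oi) {
    const int nd = porder[oi];
    const int pa = parent[nd];
    if (pa < 0) { origin = nd; continue; }
    // per-site scaling of the completed partial at nd (internal nodes only)
    double* pnd = &part[(size_t)nd * k * m];
    if (tip_row[nd] < 0) {
      for (int j = 0; j < m; ++j) {
        double mx = 0.0;
        for (int a = 0; a < k; ++a) if (pnd[j * k + a] > mx) mx = pnd[j * k + a];
        if (mx > 0.0 && mx != 1.0) {
          for (int a = 0; a < k; ++a) pnd[j * k + a] /= mx;
          logscale[j] += std::log(mx);
        } else if (mx == 0.0) {
          logscale[j] = R_NegInf;  // impossible data under the model
        }
      }
    }
    // transition matrices for the branch above nd, one per site group
    for (int g = 0; g < G; ++g)
      branch_P(node_time[pa], node_time[nd], t1, t2, r[g], &smat(0, g),
               sigma[g], l[g], S, &P[(size_t)g * k * k], tmpA.data(), tmpB.data());
    // push message into the parent partial
    double* ppa = &part[(size_t)pa * k * m];
    for (int j = 0; j < m; ++j) {
      const double* Pg = &P[(size_t)group[j] * k * k];
      const double* cj = &pnd[j * k];
      for (int a = 0; a < k; ++a) {
        double acc = 0.0;
        for (int b = 0; b < k; ++b) acc += Pg[a * k + b] * cj[b];
        msg[a] = acc;
      }
      for (int a = 0; a < k; ++a) ppa[j * k + a] *= msg[a];
    }
  }

  NumericVector out(m);
  const double* po = &part[(size_t)origin * k * m];
  for (int j = 0; j < m; ++j)
    out[j] = (R_finite(logscale[j])) ? std::log(po[j * k + 0]) + logscale[j]
                                     : R_NegInf;
  return out;
}

//' @title Closed-form branch transition matrix (internal)
//' @description Product of window-homogeneous closed-form segments over
//'   one branch; used by the simulator.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix branch_matrix_cpp(double ta, double tb, double t1, double t2,
                                double r, NumericVector s, double l) {
  const int S = s.size();
  const int k = S + 2;
  double sigma = 0.0;
  for (int i = 0; i < S; ++i) sigma += s[i];
  std::vector<double> P(k * k), tmpA(k * k), tmpB(k * k);
  branch_P(ta, tb, t1, t2, r, s.begin(), sigma, l, S, P.data(),
           tmpA.data(), tmpB.data());
  NumericMatrix out(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) out(i, j) = P[i * k + j];
  return out;
}
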