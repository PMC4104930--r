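// Dual coordinate descent for linear epsilon-insensitive SVR,
// LIBLINEAR-style (Ho & Lin style updates), extended with
//  * custom per-instance linear terms (top-down multi-task pull), and
//  * a task-coupled variant whose effective kernel is
//    Q_ij = M[t_i, t_j] * x_i' x_j with M = (I_T + L)^{-1}
//    (graph-regularized multi-task SVR).
//
// Instances are the *columns* of a dgCMatrix X (features x instances).
// Coordinate order is a fresh random permutation each epoch, driven by an
// explicit integer seed so runs are reproducible.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Csc {
  // keeps the slot vectors alive while pointers are borrowed
  IntegerVector pp, ii;
  NumericVector xx;
  const int *p;
  const int *i;
  const double *x;
  int ncol;

  explicit Csc(const S4 &X)
      : pp(X.slot("p")), ii(X.slot("i")), xx(X.slot("x")) {
    p = INTEGER(pp);
    i = INTEGER(ii);
    x = REAL(xx);
    IntegerVector dim = X.slot("Dim");
    ncol = dim[1];
  }
};

inline double col_dot_dense(const Csc &m, int j, const double *w) {
  double s = 0.0;
  for (int k = m.p[j]; k < m.p[j + 1]; ++k) s += m.x[k] * w[m.i[k]];
  return s;
}

inline double col_sqnorm(const Csc &m, int j) {
  double s = 0.0;
  for (int k = m.p[j]; k < m.p[j + 1]; ++k) s += m.x[k] * m.x[k];
  return s;
}

inline void axpy_col(const Csc &m, int j, double d, double *w) {
  for (int k = m.p[j]; k < m.p[j + 1]; ++k) w[m.i[k]] += d * m.x[k];
}

}  // namespace

// [[Rcpp::export(name = ".cd_svr")]]
List cd_svr(S4 X, NumericVector y, double C, double epsilon,
            NumericVector linear_terms, int loss_order, double tol,
            int max_iter, int seed) {
  Csc m(X);
  const int l = m.ncol;
  IntegerVector dim = X.slot("Dim");
  const int n = dim[0];

  // effective labels: minimizing f_D(beta) - sum_i beta_i p_i is the standard
  // dual with labels y_i + p_i
  std::vector<double> yy(l);
  for (int i = 0; i < l; ++i) yy[i] = y[i] + linear_terms[i];

  const double lambda = (loss_order == 2) ? 1.0 / (2.0 * C) : 0.0;
  std::vector<double> w(n, 0.0), beta(l, 0.0), qii(l);
  for (int i = 0; i < l; ++i) qii[i] = col_sqnorm(m, i);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> order(l);
  for (int i = 0; i < l; ++i) order[i] = i;

  int iter = 0;
  bool converged = false;
  double maxviol = R_PosInf;
  double stop_at = tol;  // rescaled after the first epoch
  for (iter = 0; iter < max_iter; ++iter) {
    std::shuffle(order.begin(), order.end(), rng);
    maxviol = 0.0;
    for (int s = 0; s < l; ++s) {
      const int i = order[s];
      const double H = qii[i] + lambda;
      if (H <= 0.0) continue;  // all-zero instance: beta_i stays 0
      const double G = col_dot_dense(m, i, w.data()) - yy[i] + lambda * beta[i];
      const double Gp = G + epsilon;
      const double Gn = G - epsilon;
      double viol = 0.0;
      if (beta[i] == 0.0) {
        if (Gp < 0.0) viol = -Gp;
        else if (Gn > 0.0) viol = Gn;
      } else if (beta[i] > 0.0) {
        viol = std::fabs(Gp);
        if (loss_order == 1 && beta[i] >= C && Gp < 0.0) viol = 0.0;
      } else {
        viol = std::fabs(Gn);
        if (loss_order == 1 && beta[i] <= -C && Gn > 0.0) viol = 0.0;
      }
      if (viol > maxviol) maxviol = viol;

      double d;
      if (Gp < H * beta[i]) d = -Gp / H;
      else if (Gn > H * beta[i]) d = -Gn / H;
      else d = -beta[i];
      if (loss_order == 1) {
        double nb = beta[i] + d;
        if (nb > C) nb = C;
        if (nb < -C) nb = -C;
        d = nb - beta[i];
      }
      if (d != 0.0) {
        beta[i] += d;
        axpy_col(m, i, d, w.data());
      }
    }
    if (iter == 0) stop_at = tol * std::max(1.0, maxviol);
    if (maxviol < stop_at) {
      converged = true;
      ++iter;
      break;
    }
  }

  // dual objective: 1/2 ||w||^2 + sum eps|b| - (y+p) b [+ b^2/(4C) for L2]
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += 0.5 * w[j] * w[j];
  for (int i = 0; i < l; ++i) {
    obj += epsilon * std::fabs(beta[i]) - yy[i] * beta[i];
    if (loss_order == 2) obj += beta[i] * beta[i] / (4.0 * C);
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iterations"] = iter, _["converged"] = converged,
                      _["max_violation"] = maxviol, _["dual_objective"] = obj);
}

// [[Rcpp::export(name = ".cd_grmt")]]
List cd_grmt(S4 X, NumericVector y, IntegerVector task0, NumericMatrix M,
             double C, double epsilon, double tol, int max_iter, int seed) {
  Csc m(X);
  const int l = m.ncol;
  IntegerVector dim = X.slot("Dim");
  const int n = dim[0];
  const int T = M.nrow();

  const double lambda = 1.0 / (2.0 * C);  // L2 loss only
  // U: block components u_t = sum_{i: t_i = t} beta_i x_i
  // Z: effective weights z_t = sum_s M[t, s] u_s (the primal w_t)
  NumericMatrix U(n, T), Z(n, T);
  std::vector<double> beta(l, 0.0), qii(l);
  for (int i = 0; i < l; ++i) qii[i] = M(task0[i], task0[i]) * col_sqnorm(m, i);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> order(l);
  for (int i = 0; i < l; ++i) order[i] = i;

  int iter = 0;
  bool converged = false;
  double maxviol = R_PosInf;
  double stop_at = tol;  // rescaled after the first epoch
  for (iter = 0; iter < max_iter; ++iter) {
    std::shuffle(order.begin(), order.end(), rng);
    maxviol = 0.0;
    for (int s = 0; s < l; ++s) {
      const int i = order[s];
      const int ti = task0[i];
      const double H = qii[i] + lambda;
      if (H <= 0.0) continue;
      const double G =
          col_dot_dense(m, i, &Z(0, ti)) - y[i] + lambda * beta[i];
      const double Gp = G + epsilon;
      const double Gn = G - epsilon;
      double viol = 0.0;
      if (beta[i] == 0.0) {
        if (Gp < 0.0) viol = -Gp;
        else if (Gn > 0.0) viol = Gn;
      } else if (beta[i] > 0.0) {
        viol = std::fabs(Gp);
      } else {
        viol = std::fabs(Gn);
      }
      if (viol > maxviol) maxviol = viol;

      double d;
      if (Gp < H * beta[i]) d = -Gp / H;
      else if (Gn > H * beta[i]) d = -Gn / H;
      else d = -beta[i];
      if (d != 0.0) {
        beta[i] += d;
        axpy_col(m, i, d, &U(0, ti));
        for (int t = 0; t < T; ++t) {
          const double f = d * M(t, ti);
          if (f != 0.0) axpy_col(m, i, f, &Z(0, t));
        }
      }
    }
    if (iter == 0) stop_at = tol * std::max(1.0, maxviol);
    if (maxviol < stop_at) {
      converged = true;
      ++iter;
      break;
    }
  }

  // dual objective: 1/2 sum_t u_t' z_t + sum eps|b| - y b + b^2/(4C)
  double obj = 0.0;
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < n; ++j) obj += 0.5 * U(j, t) * Z(j, t);
  for (int i = 0; i < l; ++i)
    obj += epsilon * std::fabs(beta[i]) - y[i] * beta[i] +
           beta[i] * beta[i] / (4.0 * C);

  return List::create(_["W"] = Z, _["U"] = U,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iterations"] = iter, _["converged"] = converged,
                      _["max_violation"] = maxviol, _["dual_objective"] = obj);
}
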