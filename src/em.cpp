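#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Internal bin-major layout for cache-friendly traversal:
//   X[i + I*(n + N*m)]  input counts
//   Y[i + I*(t + T*m)]  reference counts
//   B[i + I*(t + T*m)]  bin probabilities
// R passes column-major (first axis fastest) arrays x: (N, M, I), y/beta:
// (T, M, I); converted once per call.

static std::vector<double> to_bin_major_x(const double* x, int N, int M,
                                          int I) {
  std::vector<double> out((size_t)N * M * I);
  for (int i = 0; i < I; ++i)
    for (int m = 0; m < M; ++m)
      for (int n = 0; n < N; ++n)
        out[i + (size_t)I * (n + (size_t)N * m)] =
            x[n + (size_t)N * (m + (size_t)M * i)];
  return out;
}

static std::vector<double> to_bin_major_y(const double* y, int T, int M,
                                          int I) {
  std::vector<double> out((size_t)T * M * I);
  for (int i = 0; i < I; ++i)
    for (int m = 0; m < M; ++m)
      for (int t = 0; t < T; ++t)
        out[i + (size_t)I * (t + (size_t)T * m)] =
            y[t + (size_t)T * (m + (size_t)M * i)];
  return out;
}

// Marginal observed-data log-likelihood without the data-only multinomial
// coefficient term (added once in R). The reference term is weighted N-fold,
// matching the beta update in which the sum over individuals runs over the
// reference counts as well.
static double marginal_loglik(const std::vector<double>& alpha,
                              const std::vector<double>& B,
                              const std::vector<double>& X,
                              const std::vector<double>& Y, int N, int T,
                              int M, int I) {
  double ll = 0.0;
  std::vector<double> denom(I);
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      const double* xm = X.data() + (size_t)I * (n + (size_t)N * m);
      std::fill(denom.begin(), denom.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        const double at = alpha[n + (size_t)N * t];
        const double* b = B.data() + (size_t)I * (t + (size_t)T * m);
        for (int i = 0; i < I; ++i) denom[i] += at * b[i];
      }
      for (int i = 0; i < I; ++i)
        if (xm[i] > 0.0 && denom[i] > 0.0) ll += xm[i] * std::log(denom[i]);
    }
    for (int t = 0; t < T; ++t) {
      const double* b = B.data() + (size_t)I * (t + (size_t)T * m);
      const double* yv = Y.data() + (size_t)I * (t + (size_t)T * m);
      for (int i = 0; i < I; ++i)
        if (yv[i] > 0.0) ll += (double)N * yv[i] * std::log(b[i]);
    }
  }
  return ll;
}

// floor each (t, m) simplex at eps and renormalise over bins
static void floor_beta(std::vector<double>& B, int T, int M, int I,
                       double eps) {
  for (size_t k = 0; k < (size_t)T * M; ++k) {
    double* b = B.data() + I * k;
    double s = 0.0;
    for (int i = 0; i < I; ++i) {
      if (b[i] < eps) b[i] = eps;
      s += b[i];
    }
    for (int i = 0; i < I; ++i) b[i] /= s;
  }
}

// E step fused with the sufficient statistics of the M step; templated on
// the bin count so the bin loops unroll (IB = 0 keeps it runtime-sized)
template <int IB>
static void em_sweep(const std::vector<double>& alpha,
                     const std::vector<double>& B,
                     const std::vector<double>& X,
                     std::vector<double>& alpha_num,
                     std::vector<double>& B_num, int N, int T, int M, int I) {
  const int nb = IB > 0 ? IB : I;
  std::vector<double> buf(2 * nb);
  double* denom = buf.data();
  double* scale = buf.data() + nb;
  for (int m = 0; m < M; ++m) {
    const size_t moff = (size_t)nb * (size_t)T * m;
    for (int n = 0; n < N; ++n) {
      const double* xm = X.data() + (size_t)nb * (n + (size_t)N * m);
      bool any = false;
      for (int i = 0; i < nb; ++i)
        if (xm[i] > 0.0) any = true;
      if (!any) continue;
      for (int i = 0; i < nb; ++i) denom[i] = 0.0;
      for (int t = 0; t < T; ++t) {
        const double at = alpha[n + (size_t)N * t];
        const double* b = B.data() + moff + (size_t)nb * t;
        for (int i = 0; i < nb; ++i) denom[i] += at * b[i];
      }
      for (int i = 0; i < nb; ++i)
        scale[i] = (xm[i] > 0.0 && denom[i] > 0.0) ? xm[i] / denom[i] : 0.0;
      for (int t = 0; t < T; ++t) {
        const double at = alpha[n + (size_t)N * t];
        const double* b = B.data() + moff + (size_t)nb * t;
        double* bn = B_num.data() + moff + (size_t)nb * t;
        double acc = 0.0;
        for (int i = 0; i < nb; ++i) {
          const double w = at * b[i] * scale[i];
          acc += w;
          bn[i] += w;
        }
        alpha_num[n + (size_t)N * t] += acc;
      }
    }
  }
}

// One complete EM run from the supplied initialisation. Convergence is
// declared when max |delta alpha| < tol between consecutive iterations.
// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericVector x, NumericVector y, NumericMatrix alpha0,
             NumericVector beta0, int max_iter, double tol, double eps,
             bool freeze_beta, bool track_loglik) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = y.attr("dim");
  const int N = xd[0], M = xd[1], I = xd[2], T = yd[0];

  std::vector<double> X = to_bin_major_x(x.begin(), N, M, I);
  std::vector<double> Y = to_bin_major_y(y.begin(), T, M, I);
  std::vector<double> B = to_bin_major_y(beta0.begin(), T, M, I);
  std::vector<double> alpha((size_t)N * T);
  for (int t = 0; t < T; ++t)
    for (int n = 0; n < N; ++n) alpha[n + (size_t)N * t] = alpha0(n, t);
  floor_beta(B, T, M, I, eps);

  std::vector<double> alpha_num((size_t)N * T), B_num((size_t)T * M * I);
  std::vector<double> ll_trace;

  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    std::fill(alpha_num.begin(), alpha_num.end(), 0.0);
    std::fill(B_num.begin(), B_num.end(), 0.0);

    if (I == 5)
      em_sweep<5>(alpha, B, X, alpha_num, B_num, N, T, M, I);
    else if (I == 2)
      em_sweep<2>(alpha, B, X, alpha_num, B_num, N, T, M, I);
    else
      em_sweep<0>(alpha, B, X, alpha_num, B_num, N, T, M, I);

    if (!freeze_beta) {
      for (size_t k = 0; k < (size_t)T * M; ++k) {
        double* b = B.data() + I * k;
        const double* bn = B_num.data() + I * k;
        const double* yv = Y.data() + I * k;
        double s = 0.0;
        for (int i = 0; i < I; ++i) {
          const double v = bn[i] + (double)N * yv[i];
          b[i] = v;
          s += v;
        }
        if (s > 0.0) {
          for (int i = 0; i < I; ++i) {
            b[i] /= s;
            if (b[i] < eps) b[i] = eps;
          }
        } else {
          for (int i = 0; i < I; ++i) b[i] = 1.0 / I;
        }
        // renormalise after flooring
        s = 0.0;
        for (int i = 0; i < I; ++i) s += b[i];
        for (int i = 0; i < I; ++i) b[i] /= s;
      }
    }

    double max_diff = 0.0;
    for (int n = 0; n < N; ++n) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) s += alpha_num[n + (size_t)N * t];
      for (int t = 0; t < T; ++t) {
        const double a_new =
            (s > 0.0) ? alpha_num[n + (size_t)N * t] / s : 1.0 / T;
        const double d = std::fabs(a_new - alpha[n + (size_t)N * t]);
        if (d > max_diff) max_diff = d;
        alpha[n + (size_t)N * t] = a_new;
      }
    }

    if (track_loglik)
      ll_trace.push_back(marginal_loglik(alpha, B, X, Y, N, T, M, I));
    if (max_diff < tol) {
      converged = true;
      break;
    }
  }

  const double ll = marginal_loglik(alpha, B, X, Y, N, T, M, I);

  NumericMatrix alpha_out(N, T);
  for (int t = 0; t < T; ++t)
    for (int n = 0; n < N; ++n) alpha_out(n, t) = alpha[n + (size_t)N * t];
  NumericVector beta_out((size_t)T * M * I);
  for (int i = 0; i < I; ++i)
    for (int m = 0; m < M; ++m)
      for (int t = 0; t < T; ++t)
        beta_out[t + (size_t)T * (m + (size_t)M * i)] =
            B[i + (size_t)I * (t + (size_t)T * m)];
  beta_out.attr("dim") = IntegerVector::create(T, M, I);

  return List::create(_["alpha"] = alpha_out, _["beta"] = beta_out,
                      _["loglik"] = ll, _["ll_trace"] = wrap(ll_trace),
                      _["n_iter"] = iter, _["converged"] = converged);
}
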