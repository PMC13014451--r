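// WHAM self-consistency loop: given per-bin total counts, the bias Boltzmann
// factors exp(-beta w_i(z_b)) and per-window sample counts, iterate the
// standard coupled equations for the unnormalized density p(z_b) and the
// window shift constants f_i until the f's move less than tol (kcal/mol).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_wham_iterate(NumericVector n_b, NumericMatrix expw, NumericVector N,
                      NumericVector f_init, double beta, double tol,
                      int max_iter) {
  int B = expw.nrow(), W = expw.ncol();
  std::vector<double> f(f_init.begin(), f_init.end());
  std::vector<double> a(W), p(B), fnew(W);
  double delta = R_PosInf;
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    ++iter;
    for (int i = 0; i < W; ++i) a[i] = N[i] * std::exp(beta * f[i]);
    for (int b = 0; b < B; ++b) {
      if (n_b[b] <= 0.0) { p[b] = 0.0; continue; }
      double denom = 0.0;
      for (int i = 0; i < W; ++i) denom += expw(b, i) * a[i];
      p[b] = denom > 0.0 ? n_b[b] / denom : 0.0;
    }
    for (int i = 0; i < W; ++i) {
      double s = 0.0;
      for (int b = 0; b < B; ++b) s += p[b] * expw(b, i);
      fnew[i] = -std::log(s) / beta;
    }
    double f0 = fnew[0];  // gauge: pin the first window's shift to zero
    delta = 0.0;
    for (int i = 0; i < W; ++i) {
      fnew[i] -= f0;
      double d = std::fabs(fnew[i] - f[i]);
      if (d > delta) delta = d;
      f[i] = fnew[i];
    }
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["delta"] = delta);
}
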