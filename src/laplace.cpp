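#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gauss-Seidel/SOR relaxation of the Laplace equation on a labelled grid.
// region codes: 0 outside (insulated), 1 interior, 2 Dirichlet psi=0,
// 3 Dirichlet psi=1.  Faces to code-0 voxels carry a zero-flux condition
// (the neighbour is simply dropped from the stencil).

// [[Rcpp::export]]
List cpp_laplace_sor(IntegerVector region, IntegerVector dim,
                     double omega, double tol, int max_sweeps) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  NumericVector psi(nvox);
  const int *reg = region.begin();
  double *p = psi.begin();

  std::vector<R_xlen_t> interior;
  interior.reserve(nvox / 8);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (reg[v] == 1) { interior.push_back(v); p[v] = 0.5; }
    else if (reg[v] == 3) p[v] = 1.0;
  }
  if (interior.empty())
    stop("Laplace domain has no interior voxels");

  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  double maxdelta = R_PosInf;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps && maxdelta > tol; ++sweep) {
    maxdelta = 0.0;
    for (size_t t = 0; t < interior.size(); ++t) {
      R_xlen_t v = interior[t];
      int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / s3);
      double sum = 0.0; int cnt = 0;
      if (i > 0      && reg[v - s1]) { sum += p[v - s1]; ++cnt; }
      if (i < d1 - 1 && reg[v + s1]) { sum += p[v + s1]; ++cnt; }
      if (j > 0      && reg[v - s2]) { sum += p[v - s2]; ++cnt; }
      if (j < d2 - 1 && reg[v + s2]) { sum += p[v + s2]; ++cnt; }
      if (k > 0      && reg[v - s3]) { sum += p[v - s3]; ++cnt; }
      if (k < d3 - 1 && reg[v + s3]) { sum += p[v + s3]; ++cnt; }
      if (cnt == 0) continue;
      double newv = p[v] + omega * (sum / cnt - p[v]);
      double delta = std::fabs(newv - p[v]);
      if (delta > maxdelta) maxdelta = delta;
      p[v] = newv;
    }
  }
  return List::create(_["psi"] = psi, _["sweeps"] = sweep,
                      _["max_delta"] = maxdelta,
                      _["converged"] = maxdelta <= tol);
}
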