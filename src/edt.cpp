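// Exact squared Euclidean distance transform for 2D/3D integer grids,
// separable lower-envelope algorithm (one 1D pass per axis).
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double DINF = 1e20;

// 1D squared distance transform of sampled function f, in place.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0; z[0] = -DINF; z[1] = DINF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = DINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".sqedt_cpp")]]
NumericVector sqedt_cpp(LogicalVector feature, IntegerVector dims) {
  int nd = dims.size();
  std::vector<int> dim(nd);
  R_xlen_t total = 1;
  for (int i = 0; i < nd; ++i) { dim[i] = dims[i]; total *= dims[i]; }
  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i)
    out[i] = (feature[i] == TRUE) ? 0.0 : DINF;

  // iterate axes; for axis a with stride s, lines run over dim[a]
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int i = 1; i < nd; ++i) stride[i] = stride[i - 1] * dim[i - 1];

  int nmax = 0;
  for (int i = 0; i < nd; ++i) nmax = std::max(nmax, dim[i]);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int a = 0; a < nd; ++a) {
    int n = dim[a];
    if (n == 1) continue;
    R_xlen_t s = stride[a];
    R_xlen_t nlines = total / n;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line: decompose 'line' over the other axes
      R_xlen_t rem = line, base = 0;
      for (int i = 0; i < nd; ++i) {
        if (i == a) continue;
        R_xlen_t idx = rem % dim[i];
        rem /= dim[i];
        base += idx * stride[i];
      }
      for (int q = 0; q < n; ++q) f[q] = out[base + q * s];
      dt1d(f, d, v, z, n);
      for (int q = 0; q < n; ++q) out[base + q * s] = d[q];
    }
  }
  out.attr("dim") = dims;
  return out;
}
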