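#include <Rcpp.h>
using namespace Rcpp;

// Rasterize point observations with a truncated isotropic Gaussian kernel.
// Returns an N x (n_rows * n_cols) matrix; cell (j, k) (0-based column j,
// row k, y increasing with k) maps to flat index k + n_rows * j, so a
// length-M row reshapes to an n_rows x n_cols matrix in R's column-major
// order with rows indexing y.
// [[Rcpp::export]]
NumericMatrix rasterize_points_cpp(NumericVector x, NumericVector y,
                                   double sigma, double trunc_radius,
                                   double origin_x, double origin_y,
                                   double cell_size,
                                   int n_rows, int n_cols) {
  const int n = x.size();
  const int m = n_rows * n_cols;
  NumericMatrix out(n, m);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = cell_size * cell_size / (2.0 * M_PI * sigma * sigma);
  const double tr2 = trunc_radius * trunc_radius;

  for (int i = 0; i < n; ++i) {
    // bounding window of cells possibly within the truncation radius
    int j_lo = (int)std::floor((x[i] - trunc_radius - origin_x) / cell_size - 0.5);
    int j_hi = (int)std::ceil((x[i] + trunc_radius - origin_x) / cell_size - 0.5);
    int k_lo = (int)std::floor((y[i] - trunc_radius - origin_y) / cell_size - 0.5);
    int k_hi = (int)std::ceil((y[i] + trunc_radius - origin_y) / cell_size - 0.5);
    if (j_lo < 0) j_lo = 0;
    if (k_lo < 0) k_lo = 0;
    if (j_hi > n_cols - 1) j_hi = n_cols - 1;
    if (k_hi > n_rows - 1) k_hi = n_rows - 1;
    for (int j = j_lo; j <= j_hi; ++j) {
      const double dx = origin_x + (j + 0.5) * cell_size - x[i];
      for (int k = k_lo; k <= k_hi; ++k) {
        const double dy = origin_y + (k + 0.5) * cell_size - y[i];
        const double d2 = dx * dx + dy * dy;
        if (d2 <= tr2)
          out(i, k + n_rows * j) = norm * std::exp(-d2 * inv2s2);
      }
    }
  }
  return out;
}

// Accumulate, over the observations (rows) of a response chunk, the
// per-cell sum of squares and the products of responses at axis-adjacent
// cells. Cell (j, k) has flat index k + n_rows * j; x-adjacent pair p
// (cells (j, k) and (j + 1, k)) has index k + n_rows * j, y-adjacent
// pair p (cells (j, k) and (j, k + 1)) has index k + (n_rows - 1) * j.
// [[Rcpp::export]]
List cell_cross_products_cpp(NumericMatrix y, int n_rows, int n_cols) {
  const int n = y.nrow();
  const int m = n_rows * n_cols;
  if (y.ncol() != m) stop("response chunk does not match the grid");
  NumericVector d0(m), dx(n_rows * (n_cols - 1)), dy((n_rows - 1) * n_cols);
  const double *py = y.begin();
  for (int c = 0; c < m; ++c) {
    const double *col = py + (R_xlen_t)c * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    d0[c] = s;
  }
  for (int j = 0; j < n_cols - 1; ++j) {
    for (int k = 0; k < n_rows; ++k) {
      const double *a = py + (R_xlen_t)(k + n_rows * j) * n;
      const double *b = py + (R_xlen_t)(k + n_rows * (j + 1)) * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += a[i] * b[i];
      dx[k + n_rows * j] = s;
    }
  }
  for (int j = 0; j < n_cols; ++j) {
    for (int k = 0; k < n_rows - 1; ++k) {
      const double *a = py + (R_xlen_t)(k + n_rows * j) * n;
      const double *b = py + (R_xlen_t)(k + 1 + n_rows * j) * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += a[i] * b[i];
      dy[k + (n_rows - 1) * j] = s;
    }
  }
  return List::create(_["d0"] = d0, _["dx"] = dx, _["dy"] = dy);
}

// For every point in A, the Euclidean distance to its nearest point in B.
// Brute force; used for the modified Hausdorff distance between cell sets.
// [[Rcpp::export]]
NumericVector nn_min_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
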