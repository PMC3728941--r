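// Bathymetry-constrained random walk used by the foraging-area fidelity test.
// The replicate keeps the observed step lengths in order, draws each heading
// uniformly, and redraws any step whose endpoint falls outside the permitted
// depth band (default -100..0 m); after max_attempts redraws the step is
// reflected back along the incoming direction.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double bilin(const NumericMatrix& m, double gx0, double gy0,
                           double cell, double x, double y) {
  double fx = (x - gx0) / cell, fy = (y - gy0) / cell;
  int nx = m.nrow(), ny = m.ncol();
  if (fx < 0 || fy < 0 || fx > nx - 1 || fy > ny - 1) return NA_REAL;
  int i0 = std::min(int(fx), nx - 2), j0 = std::min(int(fy), ny - 2);
  double wx = fx - i0, wy = fy - j0;
  return m(i0, j0) * (1 - wx) * (1 - wy) + m(i0 + 1, j0) * wx * (1 - wy) +
         m(i0, j0 + 1) * (1 - wx) * wy + m(i0 + 1, j0 + 1) * wx * wy;
}

// [[Rcpp::export]]
List constrained_rw_cpp(double start_x, double start_y, NumericVector steps,
                        NumericMatrix bathy, double grid_x0, double grid_y0,
                        double cell_km, double depth_min, double depth_max,
                        int max_attempts) {
  int n = steps.size();
  NumericVector X(n + 1), Y(n + 1);
  X[0] = start_x; Y[0] = start_y;
  int violations = 0;
  RNGScope scope;
  double b0 = bilin(bathy, grid_x0, grid_y0, cell_km, start_x, start_y);
  if (ISNA(b0) || b0 < depth_min || b0 > depth_max)
    stop("random-walk start point lies outside the permitted depth band");
  for (int t = 0; t < n; ++t) {
    double cx = X[t], cy = Y[t], nx = cx, ny = cy;
    bool ok = false;
    for (int a = 0; a < max_attempts; ++a) {
      double th = R::unif_rand() * 2.0 * M_PI;
      nx = cx + steps[t] * std::cos(th);
      ny = cy + steps[t] * std::sin(th);
      double b = bilin(bathy, grid_x0, grid_y0, cell_km, nx, ny);
      if (!ISNA(b) && b >= depth_min && b <= depth_max) { ok = true; break; }
    }
    if (!ok) {
      // reflect back along the incoming direction
      double bx = (t > 0) ? X[t - 1] - cx : -1.0, by = (t > 0) ? Y[t - 1] - cy : 0.0;
      double len = std::sqrt(bx * bx + by * by);
      if (len < 1e-12) { bx = 1.0; by = 0.0; len = 1.0; }
      nx = cx + steps[t] * bx / len;
      ny = cy + steps[t] * by / len;
      double b = bilin(bathy, grid_x0, grid_y0, cell_km, nx, ny);
      if (ISNA(b) || b < depth_min || b > depth_max) violations++;
    }
    X[t + 1] = nx; Y[t + 1] = ny;
  }
  return List::create(_["x"] = X, _["y"] = Y, _["violations"] = violations);
}
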