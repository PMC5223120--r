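#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbour distances of a planar point set via grid bucketing with
// an expanding ring search. Expected O(n) for roughly homogeneous patterns;
// correct for any pattern (the ring search only stops once no unexplored
// cell can contain a closer point).
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  if (n < 2) stop("need >=2 points");

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double w = xmax - xmin, h = ymax - ymin;
  double area = w * h;
  double cell = area > 0 ? std::sqrt(area / n) : 1.0;
  if (cell <= 0) cell = 1.0;
  int nx = std::max(1, (int)std::floor(w / cell) + 1);
  int ny = std::max(1, (int)std::floor(h / cell) + 1);

  std::vector<std::vector<int> > buckets((size_t)nx * ny);
  std::vector<int> cxs(n), cys(n);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(nx - 1, (int)((x[i] - xmin) / cell));
    int cy = std::min(ny - 1, (int)((y[i] - ymin) / cell));
    cxs[i] = cx; cys[i] = cy;
    buckets[(size_t)cy * nx + cx].push_back(i);
  }

  const int maxRing = std::max(nx, ny);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const int cx = cxs[i], cy = cys[i];
    for (int k = 0; k <= maxRing; ++k) {
      if (k > 0 && best <= (double)(k - 1) * cell * (double)(k - 1) * cell)
        break;
      int x0 = cx - k, x1 = cx + k, y0 = cy - k, y1 = cy + k;
      for (int gy = y0; gy <= y1; ++gy) {
        if (gy < 0 || gy >= ny) continue;
        for (int gx = x0; gx <= x1; ++gx) {
          if (gx < 0 || gx >= nx) continue;
          // ring only: skip interior cells already visited
          if (k > 0 && gx > x0 && gx < x1 && gy > y0 && gy < y1) continue;
          const std::vector<int>& b = buckets[(size_t)gy * nx + gx];
          for (size_t t = 0; t < b.size(); ++t) {
            int j = b[t];
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
          }
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
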