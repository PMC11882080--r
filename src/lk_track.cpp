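#include <Rcpp.h>
using namespace Rcpp;

// Pyramidal Lucas-Kanade step for a set of tracked points.
//
// Coordinates are 0-based with x = column, y = row (y increases downward).
// pyrA/pyrB are Gaussian pyramids (element 1 = full resolution, each further
// level decimated by 2). For each point the 2x2 normal equations of the
// window-summed brightness-constancy residual are solved iteratively,
// coarse-to-fine. A point dies (status 0) when its window leaves the image at
// full resolution, the window structure tensor is near-singular, or the
// refinement fails to converge.

static inline double bilin(const NumericMatrix& I, double x, double y) {
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const double fx = x - x0, fy = y - y0;
  const double v00 = I(y0, x0),     v01 = I(y0, x0 + 1);
  const double v10 = I(y0 + 1, x0), v11 = I(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy       * ((1 - fx) * v10 + fx * v11);
}

// window fully inside sampling-safe region (1 px margin for gradients)?
static inline bool windowOk(const NumericMatrix& I, double cx, double cy, int h) {
  const int nc = I.ncol(), nr = I.nrow();
  return (cx - h >= 1.0) && (cy - h >= 1.0) &&
         (cx + h <= nc - 3.0) && (cy + h <= nr - 3.0);
}

// [[Rcpp::export]]
List lk_track_cpp(List pyrA, List pyrB, NumericMatrix pts,
                  int winHalf, int maxIter, double eps, double minEigFloor) {
  const int nLev = pyrA.size();
  const int n = pts.nrow();
  const int W = 2 * winHalf + 1;
  const double winArea = (double)W * W;
  NumericMatrix out(n, 2);
  IntegerVector status(n);

  std::vector<double> Aw(W * W), Ax(W * W), Ay(W * W);

  for (int i = 0; i < n; ++i) {
    const double px0 = pts(i, 0), py0 = pts(i, 1);
    double gx = 0.0, gy = 0.0;     // displacement guess, current-level units
    int st = 1;

    for (int L = nLev - 1; L >= 0; --L) {
      const NumericMatrix A = pyrA[L], B = pyrB[L];
      const double sc = std::pow(2.0, L);
      const double px = px0 / sc, py = py0 / sc;

      if (!windowOk(A, px, py, winHalf)) {
        if (L == 0) { st = 0; }       // cannot even form the template window
        else { gx *= 2.0; gy *= 2.0; }
        continue;
      }

      // template window and spatial gradients (central differences)
      double gxx = 0.0, gxy = 0.0, gyy = 0.0;
      int k = 0;
      for (int oy = -winHalf; oy <= winHalf; ++oy) {
        for (int ox = -winHalf; ox <= winHalf; ++ox, ++k) {
          const double sx = px + ox, sy = py + oy;
          Aw[k] = bilin(A, sx, sy);
          Ax[k] = 0.5 * (bilin(A, sx + 1, sy) - bilin(A, sx - 1, sy));
          Ay[k] = 0.5 * (bilin(A, sx, sy + 1) - bilin(A, sx, sy - 1));
          gxx += Ax[k] * Ax[k];
          gxy += Ax[k] * Ay[k];
          gyy += Ay[k] * Ay[k];
        }
      }
      const double tr = gxx + gyy;
      const double det = gxx * gyy - gxy * gxy;
      const double minEig = 0.5 * (tr - std::sqrt(std::max(0.0, tr * tr - 4.0 * det)));
      if (minEig < minEigFloor * winArea || det <= 0.0) {
        if (L == 0) { st = 0; }
        else { gx *= 2.0; gy *= 2.0; }
        continue;
      }

      double vx = 0.0, vy = 0.0;
      bool converged = false, lost = false;
      for (int it = 0; it < maxIter; ++it) {
        const double cx = px + gx + vx, cy = py + gy + vy;
        if (!windowOk(B, cx, cy, winHalf)) { lost = true; break; }
        double bx = 0.0, by = 0.0;
        k = 0;
        for (int oy = -winHalf; oy <= winHalf; ++oy) {
          for (int ox = -winHalf; ox <= winHalf; ++ox, ++k) {
            const double r = bilin(B, cx + ox, cy + oy) - Aw[k];
            bx += r * Ax[k];
            by += r * Ay[k];
          }
        }
        const double dx = -( gyy * bx - gxy * by) / det;
        const double dy = -(-gxy * bx + gxx * by) / det;
        vx += dx; vy += dy;
        if (std::sqrt(dx * dx + dy * dy) < eps) { converged = true; break; }
      }
      if (L == 0) {
        if (lost || !converged) st = 0;
        gx += vx; gy += vy;
      } else {
        if (!lost) { gx += vx; gy += vy; }
        gx *= 2.0; gy *= 2.0;
      }
    }

    const NumericMatrix base = pyrA[0];
    const double nx = px0 + gx, ny = py0 + gy;
    if (nx < 0.0 || ny < 0.0 || nx > base.ncol() - 1.0 || ny > base.nrow() - 1.0)
      st = 0;
    out(i, 0) = nx; out(i, 1) = ny;
    status[i] = st;
  }
  return List::create(_["points"] = out, _["status"] = status);
}
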