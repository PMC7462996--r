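#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Anisotropic nearest-seed rasterization. Pixel centers sit at integer
// coordinates (x = column, y = row, 0-based). Each seed i may carry an
// anisotropic metric: distances measured in a frame rotated by theta[i],
// with the axis along theta divided by stretch[i] and the orthogonal axis
// multiplied by stretch[i] (area-preserving elongation of the cell).
// A per-seed window bounded by win_r keeps the scan local; pixels missed by
// every window fall back to a full scan, so the assignment is exact.
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_labels(NumericVector sx, NumericVector sy,
                                 NumericVector theta, NumericVector stretch,
                                 NumericVector weight,
                                 int width, int height, double win_r) {
  const int n = sx.size();
  IntegerMatrix lab(height, width);
  std::vector<double> best(static_cast<size_t>(width) * height,
                           std::numeric_limits<double>::infinity());

  std::vector<double> ct(n), st(n), inv2(n), sq2(n), iw2(n);
  for (int i = 0; i < n; ++i) {
    ct[i] = std::cos(theta[i]);
    st[i] = std::sin(theta[i]);
    inv2[i] = 1.0 / (stretch[i] * stretch[i]);
    sq2[i] = stretch[i] * stretch[i];
    iw2[i] = 1.0 / (weight[i] * weight[i]);
  }

  for (int i = 0; i < n; ++i) {
    bool iso = stretch[i] == 1.0;
    // bounding box of the metric ball {d_i <= win_r} (an ellipse with
    // semi-axes win_r*weight*stretch along theta and win_r*weight/stretch)
    double wr = win_r * weight[i];
    double a = wr * stretch[i], b = wr / stretch[i];
    double hx = iso ? wr : std::sqrt(a * a * ct[i] * ct[i] + b * b * st[i] * st[i]);
    double hy = iso ? wr : std::sqrt(a * a * st[i] * st[i] + b * b * ct[i] * ct[i]);
    int x0 = std::max(0, (int)std::floor(sx[i] - hx));
    int x1 = std::min(width - 1, (int)std::ceil(sx[i] + hx));
    int y0 = std::max(0, (int)std::floor(sy[i] - hy));
    int y1 = std::min(height - 1, (int)std::ceil(sy[i] + hy));
    for (int x = x0; x <= x1; ++x) {
      double dx = x - sx[i];
      size_t col = static_cast<size_t>(x) * height;
      if (iso) {
        double dx2 = dx * dx;
        for (int y = y0; y <= y1; ++y) {
          double dy = y - sy[i];
          double d2 = (dx2 + dy * dy) * iw2[i];
          if (d2 < best[col + y]) {
            best[col + y] = d2;
            lab(y, x) = i + 1;
          }
        }
      } else {
        for (int y = y0; y <= y1; ++y) {
          double dy = y - sy[i];
          double u = dx * ct[i] + dy * st[i];
          double v = -dx * st[i] + dy * ct[i];
          double d2 = (u * u * inv2[i] + v * v * sq2[i]) * iw2[i];
          if (d2 < best[col + y]) {
            best[col + y] = d2;
            lab(y, x) = i + 1;
          }
        }
      }
    }
  }

  // exact fallback for pixels outside every window
  for (int x = 0; x < width; ++x) {
    size_t col = static_cast<size_t>(x) * height;
    for (int y = 0; y < height; ++y) {
      if (!std::isinf(best[col + y])) continue;
      double bd = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x - sx[i], dy = y - sy[i];
        double u = dx * ct[i] + dy * st[i];
        double v = -dx * st[i] + dy * ct[i];
        double d2 = (u * u * inv2[i] + v * v * sq2[i]) * iw2[i];
        if (d2 < bd) { bd = d2; bi = i + 1; }
      }
      lab(y, x) = bi;
    }
  }
  return lab;
}

// Lloyd relaxation of seed points on a strided pixel grid (isotropic
// metric). Each iteration assigns grid points to their nearest seed and
// moves every seed to the centroid of its region; seeds with an empty
// region stay put.
// [[Rcpp::export]]
NumericMatrix cpp_lloyd(NumericVector sx, NumericVector sy,
                        int width, int height, int iters, int stride,
                        double win_r) {
  const int n = sx.size();
  std::vector<double> px(sx.begin(), sx.end()), py(sy.begin(), sy.end());

  for (int it = 0; it < iters; ++it) {
    std::vector<double> sumx(n, 0.0), sumy(n, 0.0);
    std::vector<int> cnt(n, 0);
    for (int x = 0; x < width; x += stride) {
      for (int y = 0; y < height; y += stride) {
        double bd = std::numeric_limits<double>::infinity();
        int bi = -1;
        for (int i = 0; i < n; ++i) {
          double dx = x - px[i], dy = y - py[i];
          if (std::fabs(dx) > win_r || std::fabs(dy) > win_r) continue;
          double d2 = dx * dx + dy * dy;
          if (d2 < bd) { bd = d2; bi = i; }
        }
        if (bi < 0) { // no seed within the window: full scan
          for (int i = 0; i < n; ++i) {
            double dx = x - px[i], dy = y - py[i];
            double d2 = dx * dx + dy * dy;
            if (d2 < bd) { bd = d2; bi = i; }
          }
        }
        sumx[bi] += x; sumy[bi] += y; cnt[bi]++;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (cnt[i] > 0) {
        px[i] = sumx[i] / cnt[i];
        py[i] = sumy[i] / cnt[i];
      }
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform: for every true pixel, the
// squared distance from its center to the nearest false pixel center.
// False pixels get 0. Distances are measured to background pixels inside
// the matrix only; callers pad the mask when the matrix edge should count
// as background.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e30;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = mask(i, j) ? INF : 0.0;

  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int j = 0; j < nc; ++j) { // columns
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    edt_1d(f, d, v, z, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) { // rows
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    edt_1d(f, d, v, z, nc);
    for (int j = 0; j < nc; ++j) g(i, j) = d[j];
  }
  return g;
}

// Split every label into 4-connected components; keep the largest component
// of each label (ties by first encounter in column-major scan), clear the
// rest to background. Returns the cleaned label matrix and the number of
// components each input label had.
// [[Rcpp::export]]
List cpp_keep_largest_component(IntegerMatrix labels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > maxlab) maxlab = labels(i, j);

  IntegerMatrix comp(nr, nc); // component id per pixel (1-based)
  std::vector<int> comp_label, comp_size;
  std::vector<int> stack;
  int ncomp = 0;

  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (labels(i0, j0) == 0 || comp(i0, j0) != 0) continue;
      int lab = labels(i0, j0);
      ++ncomp;
      comp_label.push_back(lab);
      comp_size.push_back(0);
      stack.clear();
      stack.push_back(i0 + j0 * nr);
      comp(i0, j0) = ncomp;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % nr, j = p / nr;
        comp_size[ncomp - 1]++;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (labels(ii, jj) == lab && comp(ii, jj) == 0) {
            comp(ii, jj) = ncomp;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }

  std::vector<int> n_comp_per_label(maxlab, 0);
  std::vector<int> best_comp(maxlab, 0); // component id kept per label
  for (int c = 0; c < ncomp; ++c) {
    int lab = comp_label[c];
    n_comp_per_label[lab - 1]++;
    int b = best_comp[lab - 1];
    if (b == 0 || comp_size[c] > comp_size[b - 1]) best_comp[lab - 1] = c + 1;
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int lab = labels(i, j);
      if (lab > 0 && comp(i, j) == best_comp[lab - 1]) out(i, j) = lab;
    }

  return List::create(_["labels"] = out,
                      _["n_components"] = IntegerVector(n_comp_per_label.begin(),
                                                        n_comp_per_label.end()));
}
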