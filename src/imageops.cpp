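#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Binary dilation/erosion with an arbitrary structuring element given as
// (drow, dcol) offsets. Pixels outside the image count as background, so
// erosion eats border-touching objects and dilation is clipped at borders.
// [[Rcpp::export]]
LogicalMatrix cpp_binary_morph(const LogicalMatrix& m, const IntegerMatrix& se,
                               bool dilate) {
  int nr = m.nrow(), nc = m.ncol(), k = se.nrow();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool acc = !dilate; // erosion: AND-accumulator, dilation: OR
      for (int s = 0; s < k; ++s) {
        int ii = i + se(s, 0), jj = j + se(s, 1);
        bool v = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? (bool)m(ii, jj)
                                                            : false;
        if (dilate) { if (v) { acc = true; break; } }
        else        { if (!v) { acc = false; break; } }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Grayscale erosion/dilation (min/max filter) over an offset set; values
// outside the image are ignored (border-clipped neighbourhood).
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(const NumericMatrix& m, const IntegerMatrix& se,
                             bool dilate) {
  int nr = m.nrow(), nc = m.ncol(), k = se.nrow();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = dilate ? -std::numeric_limits<double>::infinity()
                          :  std::numeric_limits<double>::infinity();
      for (int s = 0; s < k; ++s) {
        int ii = i + se(s, 0), jj = j + se(s, 1);
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = m(ii, jj);
        if (dilate) { if (v > acc) acc = v; }
        else        { if (v < acc) acc = v; }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Connected-component labelling of a boolean foreground. Labels are
// consecutive from 1 in raster order (column-major, matching R's layout is
// irrelevant for label ORDER as long as it is deterministic; we scan in
// row-major order so "first pixel" means first in reading order).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& m, int connectivity) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > nb;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      if (connectivity == 4 && di != 0 && dj != 0) continue;
      nb.push_back(std::make_pair(di, dj));
    }
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int i = 0; i < nr; ++i) {       // row-major scan: reading order
    for (int j = 0; j < nc; ++j) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (size_t s = 0; s < nb.size(); ++s) {
          int ii = p.first + nb[s].first, jj = p.second + nb[s].second;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (m(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher (2004). Unreachable sites carry DT_BIG, a
// large finite sentinel: true infinities break the intersection formula.
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] =  std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    if (k == 0 && s <= z[0]) { // new parabola dominates everywhere
      v[0] = q;
      z[0] = -std::numeric_limits<double>::infinity();
      z[1] =  std::numeric_limits<double>::infinity();
      continue;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  int k2 = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k2 + 1] < q) ++k2;
    double dq = q - (double)v[k2];
    d[q] = dq * dq + f[v[k2]];
  }
}

// Exact squared Euclidean distance to the nearest TRUE pixel. Pixels in
// images with no TRUE pixel anywhere get Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& m) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix g(nr, nc);
  // columns first
  for (int j = 0; j < nc; ++j) {
    std::vector<double> fc(nr), dc(nr);
    for (int i = 0; i < nr; ++i) fc[i] = m(i, j) ? 0.0 : DT_BIG;
    dt1d(fc, dc);
    for (int i = 0; i < nr; ++i) g(i, j) = dc[i];
  }
  // then rows
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    std::vector<double> fr(nc), dr(nc);
    for (int j = 0; j < nc; ++j) fr[j] = g(i, j);
    dt1d(fr, dr);
    for (int j = 0; j < nc; ++j)
      out(i, j) = dr[j] >= DT_BIG ? R_PosInf : dr[j];
  }
  return out;
}

// Bilinear sampling of img at fractional (row, col) positions; coordinates
// are clamped to the image domain (replicate-border behaviour).
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img, const NumericVector& rows,
                           const NumericVector& cols) {
  int nr = img.nrow(), nc = img.ncol(), n = rows.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    double r = rows[s], c = cols[s];
    if (r < 0) r = 0; if (r > nr - 1) r = nr - 1;
    if (c < 0) c = 0; if (c > nc - 1) c = nc - 1;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
    double fr = r - r0, fc = c - c0;
    out[s] = (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c1) +
             fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
  }
  return out;
}
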