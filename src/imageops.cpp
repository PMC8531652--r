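#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Stacks are numeric 3D arrays laid out (y, x, z), column-major:
// linear index = y + ny*(x + nx*z).

static inline int reflect_index(int i, int n) {
  // scipy-style 'reflect' (edge repeated): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector conv3d_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dims = vol.attr("dim");
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int klen = kernel.size();
  int kr = (klen - 1) / 2;          // kernels are odd-length, centered
  NumericVector out(vol.size());
  out.attr("dim") = dims;

  int n = (axis == 0) ? ny : (axis == 1) ? nx : nz;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)ny : (R_xlen_t)ny * nx;
  const double *src = REAL(vol);
  double *dst = REAL(out);
  const double *kw = REAL(kernel);

  // pad each 1D line once (reflected edges), then straight multiply-add
  std::vector<double> buf(n + 2 * kr);
  int n1 = (axis == 0) ? nx : ny;
  int n2 = (axis == 0) ? nz : (axis == 1) ? nz : nx;
  R_xlen_t s1 = (axis == 0) ? (R_xlen_t)ny : 1;
  R_xlen_t s2 = (axis == 0) ? (R_xlen_t)ny * nx
                            : (axis == 1) ? (R_xlen_t)ny * nx : (R_xlen_t)ny;

  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t line0 = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) buf[kr + i] = src[line0 + (R_xlen_t)i * stride];
      for (int i = 0; i < kr; ++i) {
        buf[kr - 1 - i] = buf[kr + reflect_index(-1 - i, n)];
        buf[kr + n + i] = buf[kr + reflect_index(n + i, n)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *b = &buf[i];
        for (int k = 0; k < klen; ++k) acc += kw[k] * b[k];
        dst[line0 + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}

// Morphological grayscale reconstruction by dilation (Vincent's hybrid
// algorithm), 6-connectivity in 3D. marker <= mask is assumed (checked in R).
// [[Rcpp::export]]
NumericVector reconstruct_dilate3d(NumericVector marker, NumericVector mask) {
  IntegerVector dims = marker.attr("dim");
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = marker.size();
  NumericVector J(n);
  for (R_xlen_t i = 0; i < n; ++i) J[i] = marker[i];
  J.attr("dim") = dims;

  R_xlen_t sy = 1, sx = ny, sz = (R_xlen_t)ny * nx;

  // raster scan: N+ = neighbors already visited in raster order
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = y * sy + x * sx + z * sz;
        double v = J[i];
        if (y > 0 && J[i - sy] > v) v = J[i - sy];
        if (x > 0 && J[i - sx] > v) v = J[i - sx];
        if (z > 0 && J[i - sz] > v) v = J[i - sz];
        if (v > mask[i]) v = mask[i];
        J[i] = v;
      }

  std::queue<R_xlen_t> fifo;
  // anti-raster scan with N-
  for (int z = nz - 1; z >= 0; --z)
    for (int x = nx - 1; x >= 0; --x)
      for (int y = ny - 1; y >= 0; --y) {
        R_xlen_t i = y * sy + x * sx + z * sz;
        double v = J[i];
        if (y < ny - 1 && J[i + sy] > v) v = J[i + sy];
        if (x < nx - 1 && J[i + sx] > v) v = J[i + sx];
        if (z < nz - 1 && J[i + sz] > v) v = J[i + sz];
        if (v > mask[i]) v = mask[i];
        J[i] = v;
        // enqueue if some N- neighbor could still grow
        bool push = false;
        if (y < ny - 1 && J[i + sy] < J[i] && J[i + sy] < mask[i + sy]) push = true;
        if (!push && x < nx - 1 && J[i + sx] < J[i] && J[i + sx] < mask[i + sx]) push = true;
        if (!push && z < nz - 1 && J[i + sz] < J[i] && J[i + sz] < mask[i + sz]) push = true;
        if (push) fifo.push(i);
      }

  const int noff = 6;
  while (!fifo.empty()) {
    R_xlen_t i = fifo.front();
    fifo.pop();
    int y = (int)(i % ny);
    int x = (int)((i / ny) % nx);
    int z = (int)(i / sz);
    for (int k = 0; k < noff; ++k) {
      int yy = y, xx = x, zz = z;
      switch (k) {
        case 0: yy = y - 1; break;
        case 1: yy = y + 1; break;
        case 2: xx = x - 1; break;
        case 3: xx = x + 1; break;
        case 4: zz = z - 1; break;
        case 5: zz = z + 1; break;
      }
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t j = yy * sy + xx * sx + zz * sz;
      if (J[j] < J[i] && mask[j] != J[j]) {
        double v = (J[i] < mask[j]) ? J[i] : mask[j];
        if (v > J[j]) {
          J[j] = v;
          fifo.push(j);
        }
      }
    }
  }
  return J;
}

// 3D connected-component labeling of a logical/numeric mask, 26-connectivity
// (8-connectivity per slice when nz == 1). Returns integer labels, 0 = bg.
// [[Rcpp::export]]
IntegerVector label_components3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  R_xlen_t sy = 1, sx = ny, sz = (R_xlen_t)ny * nx;
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int y = (int)(i % ny);
      int x = (int)((i / ny) % nx);
      int z = (int)(i / sz);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (dy == 0 && dx == 0 && dz == 0) continue;
            int yy = y + dy, xx = x + dx, zz = z + dz;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
            R_xlen_t j = yy * sy + xx * sx + zz * sz;
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// Local Shannon entropy (bits) over a square window on an integer-quantized
// image (values in 0..nlevels-1). Windows are clipped at the image border.
// [[Rcpp::export]]
NumericMatrix local_entropy2d(IntegerMatrix img, int size, int nlevels) {
  int ny = img.nrow(), nx = img.ncol();
  int r = size / 2;
  NumericMatrix out(ny, nx);
  std::vector<int> hist(nlevels);

  for (int x = 0; x < nx; ++x) {
    int x0 = std::max(0, x - r), x1 = std::min(nx - 1, x + r);
    std::fill(hist.begin(), hist.end(), 0);
    int cnt = 0;
    // initial window for y = 0
    for (int yy = 0; yy <= std::min(ny - 1, r); ++yy)
      for (int xx = x0; xx <= x1; ++xx) {
        ++hist[img(yy, xx)];
        ++cnt;
      }
    for (int y = 0; y < ny; ++y) {
      if (y > 0) {
        int yadd = y + r, yrm = y - r - 1;
        if (yadd < ny)
          for (int xx = x0; xx <= x1; ++xx) { ++hist[img(yadd, xx)]; ++cnt; }
        if (yrm >= 0)
          for (int xx = x0; xx <= x1; ++xx) { --hist[img(yrm, xx)]; --cnt; }
      }
      double h = 0.0;
      for (int b = 0; b < nlevels; ++b) {
        if (hist[b] > 0) {
          double p = (double)hist[b] / cnt;
          h -= p * std::log2(p);
        }
      }
      out(y, x) = h;
    }
  }
  return out;
}
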