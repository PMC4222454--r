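#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DT_INF = 1e30;

// 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher),
// weighted by the squared voxel spacing w2 along this axis. Propagates the
// identity of the nearest site through `id` so the full 3D pass can report,
// for every voxel, which seed voxel is closest in physical units.
static void dt1d(const double* f, const int* fid, int n, double w2,
                 double* d, int* did,
                 std::vector<int>& v, std::vector<double>& z) {
  const double NINF = -std::numeric_limits<double>::infinity();
  const double PINF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = NINF;
  z[1] = PINF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = PINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
    did[q] = fid[p];
  }
}

// Anisotropic Euclidean distance transform on a 3D grid stored in R array
// order: dim = (nz, ny, nx), linear index = z + nz*(y + ny*x). Distances are
// measured in physical units given per-axis spacings. Returns squared distance
// to the nearest TRUE voxel of `sites` and that voxel's 1-based linear index.
// [[Rcpp::export]]
List edt3d_cpp(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];

  NumericVector dist(n);
  IntegerVector near(n);
  std::vector<double> f(n);
  std::vector<int> fid(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (sites[i]) { f[i] = 0.0; fid[i] = (int)i; }
    else          { f[i] = DT_INF; fid[i] = -1; }
  }

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> line(nmax), dline(nmax), zbuf(nmax + 1);
  std::vector<int> lid(nmax), dlid(nmax), vbuf(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) { line[z] = f[base + z]; lid[z] = fid[base + z]; }
      dt1d(line.data(), lid.data(), nz, dz * dz, dline.data(), dlid.data(), vbuf, zbuf);
      for (int z = 0; z < nz; ++z) { f[base + z] = dline[z]; fid[base + z] = dlid[z]; }
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) { line[y] = f[base + (R_xlen_t)nz * y]; lid[y] = fid[base + (R_xlen_t)nz * y]; }
      dt1d(line.data(), lid.data(), ny, dy * dy, dline.data(), dlid.data(), vbuf, zbuf);
      for (int y = 0; y < ny; ++y) { f[base + (R_xlen_t)nz * y] = dline[y]; fid[base + (R_xlen_t)nz * y] = dlid[y]; }
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) { line[x] = f[base + sx * x]; lid[x] = fid[base + sx * x]; }
      dt1d(line.data(), lid.data(), nx, dx * dx, dline.data(), dlid.data(), vbuf, zbuf);
      for (int x = 0; x < nx; ++x) { f[base + sx * x] = dline[x]; fid[base + sx * x] = dlid[x]; }
    }

  for (R_xlen_t i = 0; i < n; ++i) {
    dist[i] = (f[i] >= DT_INF) ? R_PosInf : f[i];
    near[i] = (fid[i] < 0) ? 0 : fid[i] + 1;
  }
  return List::create(_["dist2"] = dist, _["nearest"] = near);
}

// 3D connected-component labeling of a logical array (R order, dim = nz,ny,nx)
// with 6- or 26-connectivity. Labels are assigned in raster-scan discovery
// order starting at 1; background is 0.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);

  std::vector<std::array<int,3>> offs;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        if (oz == 0 && oy == 0 && ox == 0) continue;
        int manh = std::abs(oz) + std::abs(oy) + std::abs(ox);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({oz, oy, ox});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Square-window median filter on a matrix (used slice-wise for background
// estimation). Window is clamped at the image border.
// [[Rcpp::export]]
NumericMatrix medfilt2d_cpp(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      win.clear();
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          win.push_back(img(rr, cc));
      size_t m = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + m, win.end());
      double med = win[m];
      if (win.size() % 2 == 0) {
        double lo = *std::max_element(win.begin(), win.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Separable convolution along one axis of a 3D array (R order), with
// reflective boundary handling. kernel has odd length.
// [[Rcpp::export]]
NumericVector convaxis3d_cpp(NumericVector data, IntegerVector dims,
                             NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int kl = kernel.size();
  const int kr = kl / 2;
  NumericVector out(n);

  int alen, nlines_a, nlines_b;
  R_xlen_t stride, sa, sb;
  if (axis == 1) { alen = nz; stride = 1; sa = nz; sb = (R_xlen_t)nz * ny; nlines_a = ny; nlines_b = nx; }
  else if (axis == 2) { alen = ny; stride = nz; sa = 1; sb = (R_xlen_t)nz * ny; nlines_a = nz; nlines_b = nx; }
  else { alen = nx; stride = (R_xlen_t)nz * ny; sa = 1; sb = nz; nlines_a = nz; nlines_b = ny; }

  std::vector<double> line(alen), res(alen);
  for (int b = 0; b < nlines_b; ++b)
    for (int a = 0; a < nlines_a; ++a) {
      R_xlen_t base = sa * a + sb * b;
      for (int i = 0; i < alen; ++i) line[i] = data[base + stride * i];
      for (int i = 0; i < alen; ++i) {
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k) {
          int j = i + k;
          if (j < 0) j = -j - 1;               // reflect about the edge
          else if (j >= alen) j = 2 * alen - j - 1;
          if (j < 0) j = 0; if (j >= alen) j = alen - 1;  // tiny arrays
          acc += kernel[k + kr] * line[j];
        }
        res[i] = acc;
      }
      for (int i = 0; i < alen; ++i) out[base + stride * i] = res[i];
    }
  return out;
}

// Sliding-histogram median filter for integer-valued images (16-bit camera
// data): coarse/fine histograms give O(w) updates per pixel instead of the
// O(w^2) of the generic path. Window clamped at borders; with cap = 65535
// the output is identical to medfilt2d_cpp. Values above `cap` are excluded
// from the window (sigma-clipped background: bright particle pixels must
// not bias their own background estimate).
// [[Rcpp::export]]
NumericMatrix medfilt2d_hist_cpp(IntegerMatrix img, int radius, int cap = 65535) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> fine(65536), coarse(256);

  auto kth = [&](int k) {             // k is 1-based rank
    int acc = 0, cb = 0;
    while (acc + coarse[cb] < k) acc += coarse[cb++];
    int v = cb << 8;
    while (acc + fine[v] < k) acc += fine[v++];
    return v;
  };

  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
    std::fill(fine.begin(), fine.end(), 0);
    std::fill(coarse.begin(), coarse.end(), 0);
    int nwin = 0;
    int top = std::min(nr - 1, radius);
    for (int cc = c0; cc <= c1; ++cc)
      for (int rr = 0; rr <= top; ++rr) {
        int v = img(rr, cc);
        if (v > cap) continue;
        ++fine[v]; ++coarse[v >> 8]; ++nwin;
      }
    for (int r = 0; r < nr; ++r) {
      if (r > 0) {
        int add = r + radius, rem = r - radius - 1;
        if (add < nr)
          for (int cc = c0; cc <= c1; ++cc) {
            int v = img(add, cc);
            if (v > cap) continue;
            ++fine[v]; ++coarse[v >> 8]; ++nwin;
          }
        if (rem >= 0)
          for (int cc = c0; cc <= c1; ++cc) {
            int v = img(rem, cc);
            if (v > cap) continue;
            --fine[v]; --coarse[v >> 8]; --nwin;
          }
      }
      if (nwin == 0) { out(r, c) = img(r, c); continue; }
      int v1 = kth(nwin / 2 + 1);
      out(r, c) = (nwin % 2 == 0) ? 0.5 * (v1 + kth(nwin / 2)) : v1;
    }
  }
  return out;
}
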