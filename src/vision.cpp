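#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Separable Gaussian blur with replicate padding. Kernel radius = ceil(3*sigma),
// renormalised at the borders so flat regions stay flat. Both passes walk
// memory column-wise (R matrices are column-major).
static void gauss_blur_impl(const double* img, double* out, double* tmp,
                            int nr, int nc, double sigma) {
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int j = -r; j <= r; ++j) {
    k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
    ks += k[j + r];
  }
  for (double& v : k) v /= ks;

  // pass 1: along rows within each column (contiguous)
  for (int c = 0; c < nc; ++c) {
    const double* col = img + (size_t)c * nr;
    double* tcol = tmp + (size_t)c * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      if (i >= r && i < nr - r) {
        const double* p = col + i - r;
        for (int j = 0; j <= 2 * r; ++j) acc += k[j] * p[j];
      } else {
        for (int j = -r; j <= r; ++j) {
          int ii = i + j;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          acc += k[j + r] * col[ii];
        }
      }
      tcol[i] = acc;
    }
  }
  // pass 2: per output column, accumulate neighbouring columns (axpy-style)
  std::fill(out, out + (size_t)nr * nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    double* ocol = out + (size_t)c * nr;
    for (int j = -r; j <= r; ++j) {
      int cc = c + j;
      if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
      const double* tcol = tmp + (size_t)cc * nr;
      const double kj = k[j + r];
      for (int i = 0; i < nr; ++i) ocol[i] += kj * tcol[i];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  NumericMatrix out(nr, nc);
  std::vector<double> tmp((size_t)nr * nc);
  gauss_blur_impl(img.begin(), out.begin(), tmp.data(), nr, nc, sigma);
  return out;
}

// Local mean over a (2*radius+1)^2 box via integral image; the box is clipped
// at the borders and the mean taken over the clipped support.
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  // integral image with a zero row/col at index 0
  std::vector<double> I((nr + 1) * (nc + 1), 0.0);
  const int stride = nr + 1;
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i)
      I[(i + 1) + (c + 1) * stride] =
        img(i, c) + I[i + (c + 1) * stride] + I[(i + 1) + c * stride] -
        I[i + c * stride];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      double s = I[(i1 + 1) + (c1 + 1) * stride] - I[i0 + (c1 + 1) * stride] -
                 I[(i1 + 1) + c0 * stride] + I[i0 + c0 * stride];
      out(i, c) = s / ((double)(i1 - i0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// Otsu threshold over a 256-bin histogram of values in [0, maxval].
// Returns the bin upper edge maximising between-class variance.
// [[Rcpp::export]]
double cpp_otsu(const NumericMatrix& img, double maxval) {
  const int nb = 256;
  std::vector<double> h(nb, 0.0);
  const R_xlen_t n = (R_xlen_t)img.nrow() * img.ncol();
  if (n == 0 || maxval <= 0) return 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = img[i] / maxval;
    int b = (int)(v * (nb - 1) + 0.5);
    if (b < 0) b = 0; else if (b >= nb) b = nb - 1;
    h[b] += 1.0;
  }
  double total = (double)n, sum = 0.0;
  for (int b = 0; b < nb; ++b) sum += b * h[b];
  double sumB = 0.0, wB = 0.0, best = -1.0;
  int thr = 0;
  for (int b = 0; b < nb; ++b) {
    wB += h[b];
    if (wB == 0) continue;
    double wF = total - wB;
    if (wF == 0) break;
    sumB += b * h[b];
    double mB = sumB / wB, mF = (sum - sumB) / wF;
    double between = wB * wF * (mB - mF) * (mB - mF);
    if (between > best) { best = between; thr = b; }
  }
  return (thr + 0.5) / (nb - 1) * maxval;
}

// 8-connected component labelling of a logical mask; labels 1..n in scan order
// of the first-encountered pixel (column-major, matching R storage).
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, c) || lab(i, c)) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, c);
      lab(i, c) = next;
      while (!stack.empty()) {
        auto [pi, pc] = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dc) continue;
            int qi = pi + di, qc = pc + dc;
            if (qi < 0 || qi >= nr || qc < 0 || qc >= nc) continue;
            if (mask(qi, qc) && !lab(qi, qc)) {
              lab(qi, qc) = next;
              stack.emplace_back(qi, qc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-component area, centroid (1-based, sub-pixel), mean gray over the
// original frame, inclusive bounding box, and 1-based linear pixel indices.
// [[Rcpp::export]]
List cpp_component_stats(const IntegerMatrix& lab, const NumericMatrix& frame) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int n = 0;
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i)
      if (lab(i, c) > n) n = lab(i, c);
  IntegerVector area(n), rmin(n, nr + 1), rmax(n, 0), cmin(n, nc + 1), cmax(n, 0);
  NumericVector srow(n), scol(n), sgray(n);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, c);
      if (!l) continue;
      int j = l - 1;
      area[j]++;
      srow[j] += i + 1;
      scol[j] += c + 1;
      sgray[j] += frame(i, c);
      if (i + 1 < rmin[j]) rmin[j] = i + 1;
      if (i + 1 > rmax[j]) rmax[j] = i + 1;
      if (c + 1 < cmin[j]) cmin[j] = c + 1;
      if (c + 1 > cmax[j]) cmax[j] = c + 1;
    }
  }
  List pix(n);
  {
    std::vector<std::vector<int>> acc(n);
    for (int j = 0; j < n; ++j) acc[j].reserve(area[j]);
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < nr; ++i)
        if (lab(i, c)) acc[lab(i, c) - 1].push_back(i + 1 + c * nr);
    for (int j = 0; j < n; ++j) pix[j] = wrap(acc[j]);
  }
  NumericVector crow(n), ccol(n), mgray(n);
  for (int j = 0; j < n; ++j) {
    crow[j] = srow[j] / area[j];
    ccol[j] = scol[j] / area[j];
    mgray[j] = sgray[j] / area[j];
  }
  return List::create(
    _["area"] = area, _["row"] = crow, _["col"] = ccol, _["gray"] = mgray,
    _["rmin"] = rmin, _["rmax"] = rmax, _["cmin"] = cmin, _["cmax"] = cmax,
    _["pixels"] = pix);
}

// Size of the intersection of two sorted integer vectors (mask pixel indices).
// [[Rcpp::export]]
int cpp_intersect_size(const IntegerVector& a, const IntegerVector& b) {
  int i = 0, j = 0, n = 0;
  const int na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Fused hot path for per-frame candidate extraction: Gaussian blur,
// median-centred absolute deviation, adaptive (local mean + offset) and
// global (Otsu floored at the offset) thresholds, union, 8-connected
// labelling and component stats with a minimum-area filter. Returns NULL
// when nothing qualifies. Semantically identical to composing the exported
// primitives, which the R wrapper and the tests still do.
// [[Rcpp::export]]
SEXP cpp_roi_candidates(const NumericMatrix& frame, double sigma,
                        int block_radius, double offset, double min_area) {
  const int nr = frame.nrow(), nc = frame.ncol();
  const size_t n = (size_t)nr * nc;
  NumericMatrix dev(nr, nc);
  {
    std::vector<double> tmp(n);
    gauss_blur_impl(frame.begin(), dev.begin(), tmp.data(), nr, nc, sigma);
    std::copy(dev.begin(), dev.end(), tmp.begin());
    const size_t k = n / 2;
    std::nth_element(tmp.begin(), tmp.begin() + k, tmp.end());
    double med = tmp[k];
    if (n % 2 == 0) {
      med = (med + *std::max_element(tmp.begin(), tmp.begin() + k)) / 2.0;
    }
    for (size_t i = 0; i < n; ++i) dev[i] = std::fabs(dev[i] - med);
  }
  NumericMatrix loc = cpp_box_mean(dev, block_radius);
  double thr = cpp_otsu(dev, 255.0);
  if (thr < offset) thr = offset;
  LogicalMatrix fg(nr, nc);
  bool anyfg = false;
  for (size_t i = 0; i < n; ++i) {
    fg[i] = dev[i] > loc[i] + offset || dev[i] > thr;
    anyfg = anyfg || fg[i];
  }
  if (!anyfg) return R_NilValue;
  IntegerMatrix lab = cpp_label(fg);
  List st = cpp_component_stats(lab, frame);
  IntegerVector area = st["area"];
  std::vector<int> keep;
  for (int j = 0; j < area.size(); ++j)
    if (area[j] >= min_area) keep.push_back(j);
  if (keep.empty()) return R_NilValue;
  const int m = (int)keep.size();
  IntegerVector a(m), rmn(m), rmx(m), cmn(m), cmx(m);
  NumericVector rw(m), cl(m), gy(m);
  List px(m);
  NumericVector row = st["row"], col = st["col"], gray = st["gray"];
  IntegerVector rmin = st["rmin"], rmax = st["rmax"],
                cmin = st["cmin"], cmax = st["cmax"];
  List pixels = st["pixels"];
  for (int j = 0; j < m; ++j) {
    int k = keep[j];
    a[j] = area[k]; rw[j] = row[k]; cl[j] = col[k]; gy[j] = gray[k];
    rmn[j] = rmin[k]; rmx[j] = rmax[k]; cmn[j] = cmin[k]; cmx[j] = cmax[k];
    px[j] = pixels[k];
  }
  return List::create(
    _["area"] = a, _["row"] = rw, _["col"] = cl, _["gray"] = gy,
    _["rmin"] = rmn, _["rmax"] = rmx, _["cmin"] = cmn, _["cmax"] = cmx,
    _["pixels"] = px);
}

// Median of all matrix entries via nth_element (O(n)).
// [[Rcpp::export]]
double cpp_median(const NumericMatrix& img) {
  const R_xlen_t n = (R_xlen_t)img.nrow() * img.ncol();
  if (n == 0) return NA_REAL;
  std::vector<double> v(img.begin(), img.end());
  const R_xlen_t k = n / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  double hi = v[k];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + k);
  return (lo + hi) / 2.0;
}
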