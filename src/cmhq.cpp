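#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a binary matrix, 4- or 8-connectivity.
// Iterative flood fill (explicit stack) so deep components cannot overflow
// the C stack. Labels are 1..k in raster order of each component's first
// pixel, which makes the output deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 3-D 6-connected labeling of a logical array given as a vector with dims
// (nz, nr, nc) flattened in R's column-major order dim = c(nz, nr, nc).
// [[Rcpp::export]]
IntegerVector cpp_label_components_3d(const LogicalVector arr, const int nz,
                                      const int nr, const int nc) {
  IntegerVector lab(arr.size());
  const long strz = 1, strr = nz, strc = (long)nz * nr;
  int next = 0;
  std::vector<long> stack;
  for (long c = 0; c < nc; ++c) {
    for (long r = 0; r < nr; ++r) {
      for (long z = 0; z < nz; ++z) {
        const long idx = z * strz + r * strr + c * strc;
        if (!arr[idx] || lab[idx] != 0) continue;
        ++next;
        stack.clear();
        stack.push_back(idx);
        lab[idx] = next;
        while (!stack.empty()) {
          const long i = stack.back();
          stack.pop_back();
          const long zz = i % nz, rr = (i / nz) % nr, cc = i / ((long)nz * nr);
          const long zs[6] = {zz - 1, zz + 1, zz, zz, zz, zz};
          const long rs[6] = {rr, rr, rr - 1, rr + 1, rr, rr};
          const long cs[6] = {cc, cc, cc, cc, cc - 1, cc + 1};
          for (int k = 0; k < 6; ++k) {
            if (zs[k] < 0 || zs[k] >= nz || rs[k] < 0 || rs[k] >= nr ||
                cs[k] < 0 || cs[k] >= nc) continue;
            const long j = zs[k] * strz + rs[k] * strr + cs[k] * strc;
            if (arr[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Rigid resampling by inverse mapping: the transform rotates the source by
// `angle_deg` about the canvas center and then translates by (drow, dcol);
// out-of-canvas samples take `fill`. interp: 0 = nearest, 1 = bilinear.
// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(const NumericMatrix img, const double angle_deg,
                             const double drow, const double dcol,
                             const int interp, const double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double a = angle_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double yr = r - drow - cr, yc = c - dcol - cc;
      // inverse rotation
      const double sr = ca * yr + sa * yc + cr;
      const double sc = -sa * yr + ca * yc + cc;
      double v = fill;
      if (interp == 0) {
        const int ir = (int)std::lround(sr), ic = (int)std::lround(sc);
        if (ir >= 0 && ir < nr && ic >= 0 && ic < nc) v = img(ir, ic);
      } else {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        double acc = 0.0;
        const double w[4] = {(1 - fr) * (1 - fc), (1 - fr) * fc,
                             fr * (1 - fc), fr * fc};
        const int rr[4] = {r0, r0, r0 + 1, r0 + 1};
        const int cc2[4] = {c0, c0 + 1, c0, c0 + 1};
        for (int k = 0; k < 4; ++k) {
          const double vk = (rr[k] >= 0 && rr[k] < nr && cc2[k] >= 0 && cc2[k] < nc)
                              ? img(rr[k], cc2[k])
                              : fill;
          acc += w[k] * vk;
        }
        v = acc;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// Mean squared difference between two equal-size matrices (registration cost).
// [[Rcpp::export]]
double cpp_mse(const NumericMatrix a, const NumericMatrix b) {
  const long n = (long)a.nrow() * a.ncol();
  double s = 0.0;
  for (long i = 0; i < n; ++i) s += (a[i] - b[i]) * (a[i] - b[i]);
  return s / (double)n;
}
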