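#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Images are R matrices indexed [row, col] = [y + 1, x + 1]; coordinates
// handed across the interface are 0-based pixel centers (x = col, y = row).

// Additively render isotropic 2-D Gaussian spots. 'total' is the integrated
// intensity of each spot; the kernel is truncated at 5 sigma.
// [[Rcpp::export(name = ".renderSpots")]]
NumericMatrix renderSpots(NumericMatrix img, NumericVector x, NumericVector y,
                          NumericVector total, double sigma) {
  int nr = img.nrow(), nc = img.ncol(), n = x.size();
  double s2 = 2.0 * sigma * sigma;
  double norm = 1.0 / (2.0 * M_PI * sigma * sigma);
  int ext = (int)std::ceil(5.0 * sigma);
  for (int i = 0; i < n; i++) {
    double cx = x[i], cy = y[i], amp = total[i] * norm;
    int x0 = std::max(0, (int)std::floor(cx) - ext);
    int x1 = std::min(nc - 1, (int)std::ceil(cx) + ext);
    int y0 = std::max(0, (int)std::floor(cy) - ext);
    int y1 = std::min(nr - 1, (int)std::ceil(cy) + ext);
    for (int xx = x0; xx <= x1; xx++) {
      double dx = xx - cx;
      for (int yy = y0; yy <= y1; yy++) {
        double dy = yy - cy;
        img(yy, xx) += amp * std::exp(-(dx * dx + dy * dy) / s2);
      }
    }
  }
  return img;
}

// Additively render anti-aliased disks of per-pixel level 'level'; the edge
// ramps linearly over one pixel so that threshold-based masks are stable.
// [[Rcpp::export(name = ".renderDisks")]]
NumericMatrix renderDisks(NumericMatrix img, NumericVector x, NumericVector y,
                          NumericVector radius, NumericVector level) {
  int nr = img.nrow(), nc = img.ncol(), n = x.size();
  for (int i = 0; i < n; i++) {
    double cx = x[i], cy = y[i], r = radius[i], lev = level[i];
    int ext = (int)std::ceil(r) + 1;
    int x0 = std::max(0, (int)std::floor(cx) - ext);
    int x1 = std::min(nc - 1, (int)std::ceil(cx) + ext);
    int y0 = std::max(0, (int)std::floor(cy) - ext);
    int y1 = std::min(nr - 1, (int)std::ceil(cy) + ext);
    for (int xx = x0; xx <= x1; xx++) {
      for (int yy = y0; yy <= y1; yy++) {
        double d = std::sqrt((xx - cx) * (xx - cx) + (yy - cy) * (yy - cy));
        double cov = r + 0.5 - d;
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        img(yy, xx) += lev * cov;
      }
    }
  }
  return img;
}

// 8-connected components of a logical mask, labelled in raster order.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qy, qx;
  for (int yy = 0; yy < nr; yy++) {
    for (int xx = 0; xx < nc; xx++) {
      if (!mask(yy, xx) || lab(yy, xx) != 0) continue;
      next++;
      qy.clear(); qx.clear();
      qy.push_back(yy); qx.push_back(xx);
      lab(yy, xx) = next;
      size_t head = 0;
      while (head < qy.size()) {
        int py = qy[head], px = qx[head]; head++;
        for (int dy = -1; dy <= 1; dy++) {
          for (int dx = -1; dx <= 1; dx++) {
            if (dy == 0 && dx == 0) continue;
            int ny = py + dy, nx = px + dx;
            if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
            if (mask(ny, nx) && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              qy.push_back(ny); qx.push_back(nx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Assign every pixel to the nucleus whose mask it is nearest to (Euclidean,
// pixel centre to pixel centre), capped at capPx. Ties go to the lower label
// because labels are processed in ascending order with a strict '<'.
// Returns the assignment and the distance to the owning mask (0 inside it).
// [[Rcpp::export(name = ".voronoiAssign")]]
List voronoiAssign(IntegerMatrix lab, double capPx) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix assign(nr, nc);
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  int L = 0;
  for (int i = 0; i < nr * nc; i++) if (lab[i] > L) L = lab[i];
  if (L == 0) return List::create(_["label"] = assign, _["dist"] = dist);

  // mask pixels own themselves at distance 0
  for (int xx = 0; xx < nc; xx++)
    for (int yy = 0; yy < nr; yy++)
      if (lab(yy, xx) > 0) { assign(yy, xx) = lab(yy, xx); dist(yy, xx) = 0.0; }

  // boundary pixels and bounding box per label
  std::vector< std::vector<int> > by(L + 1), bx(L + 1);
  std::vector<int> x0(L + 1, nc), x1(L + 1, -1), y0(L + 1, nr), y1(L + 1, -1);
  for (int xx = 0; xx < nc; xx++) {
    for (int yy = 0; yy < nr; yy++) {
      int l = lab(yy, xx);
      if (l == 0) continue;
      if (xx < x0[l]) x0[l] = xx;
      if (xx > x1[l]) x1[l] = xx;
      if (yy < y0[l]) y0[l] = yy;
      if (yy > y1[l]) y1[l] = yy;
      bool edge = (yy == 0 || yy == nr - 1 || xx == 0 || xx == nc - 1);
      if (!edge) {
        edge = (lab(yy - 1, xx) == 0 || lab(yy + 1, xx) == 0 ||
                lab(yy, xx - 1) == 0 || lab(yy, xx + 1) == 0);
      }
      if (edge) { by[l].push_back(yy); bx[l].push_back(xx); }
    }
  }

  double cap2 = capPx * capPx;
  int ext = (int)std::ceil(capPx);
  for (int l = 1; l <= L; l++) {
    if (by[l].empty()) continue;
    int wx0 = std::max(0, x0[l] - ext), wx1 = std::min(nc - 1, x1[l] + ext);
    int wy0 = std::max(0, y0[l] - ext), wy1 = std::min(nr - 1, y1[l] + ext);
    size_t nb = by[l].size();
    for (int xx = wx0; xx <= wx1; xx++) {
      for (int yy = wy0; yy <= wy1; yy++) {
        if (lab(yy, xx) > 0) continue;          // inside some nucleus
        double best = dist(yy, xx);
        double b2 = best * best;
        // cheap reject: distance to the label's bounding box already beats
        // neither the cap nor the current best
        double bdx = (xx < x0[l]) ? x0[l] - xx : ((xx > x1[l]) ? xx - x1[l] : 0);
        double bdy = (yy < y0[l]) ? y0[l] - yy : ((yy > y1[l]) ? yy - y1[l] : 0);
        double d2box = bdx * bdx + bdy * bdy;
        if (d2box > cap2 || d2box >= b2 - 1e-12) continue;
        double d2min = R_PosInf;
        for (size_t j = 0; j < nb; j++) {
          double dx = xx - bx[l][j], dy = yy - by[l][j];
          double d2 = dx * dx + dy * dy;
          if (d2 < d2min) {
            d2min = d2;
            if (d2min < 1e-12) break;
          }
        }
        if (d2min <= cap2 && d2min < b2 - 1e-12) {
          assign(yy, xx) = l;
          dist(yy, xx) = std::sqrt(d2min);
        }
      }
    }
  }
  // pixels never reached stay label 0, distance Inf
  return List::create(_["label"] = assign, _["dist"] = dist);
}

// Strict local maxima in a (2*winR+1)^2 Chebyshev window, above peakMin.
// On plateaus the pixel that comes first in (row, col) lexicographic order
// wins. NA pixels never qualify and never suppress.
// [[Rcpp::export(name = ".localMaxima")]]
DataFrame localMaxima(NumericMatrix img, int winR, double peakMin) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> outx, outy;
  std::vector<double> outv;
  for (int yy = 0; yy < nr; yy++) {
    for (int xx = 0; xx < nc; xx++) {
      double v = img(yy, xx);
      if (ISNAN(v) || v <= peakMin) continue;
      bool ok = true;
      for (int dy = -winR; dy <= winR && ok; dy++) {
        int ny = yy + dy;
        if (ny < 0 || ny >= nr) continue;
        for (int dx = -winR; dx <= winR; dx++) {
          if (dy == 0 && dx == 0) continue;
          int nx = xx + dx;
          if (nx < 0 || nx >= nc) continue;
          double u = img(ny, nx);
          if (ISNAN(u)) continue;
          if (u > v) { ok = false; break; }
          if (u == v) {
            // neighbour earlier in (row, col) order suppresses this pixel
            if (ny < yy || (ny == yy && nx < xx)) { ok = false; break; }
          }
        }
      }
      if (ok) { outx.push_back(xx); outy.push_back(yy); outv.push_back(v); }
    }
  }
  return DataFrame::create(_["x"] = outx, _["y"] = outy, _["peak"] = outv);
}

// Integrate puncta over a fixed (2*patchR+1)^2 patch with an optional local
// background correction: the median of the square ring at Chebyshev radii
// (patchR, patchR + ringW] is subtracted from every patch pixel. NA pixels
// are excluded from the patch sum and the ring.
// [[Rcpp::export(name = ".patchIntegrate")]]
DataFrame patchIntegrate(NumericMatrix img, IntegerVector x, IntegerVector y,
                         int patchR, int ringW) {
  int nr = img.nrow(), nc = img.ncol(), n = x.size();
  NumericVector integ(n), localBg(n);
  int outR = patchR + ringW;
  std::vector<double> ring;
  for (int i = 0; i < n; i++) {
    int cx = x[i], cy = y[i];
    double s = 0.0; int npx = 0;
    for (int xx = std::max(0, cx - patchR); xx <= std::min(nc - 1, cx + patchR); xx++)
      for (int yy = std::max(0, cy - patchR); yy <= std::min(nr - 1, cy + patchR); yy++) {
        double v = img(yy, xx);
        if (!ISNAN(v)) { s += v; npx++; }
      }
    double bg = 0.0;
    if (ringW > 0) {
      ring.clear();
      for (int xx = std::max(0, cx - outR); xx <= std::min(nc - 1, cx + outR); xx++)
        for (int yy = std::max(0, cy - outR); yy <= std::min(nr - 1, cy + outR); yy++) {
          int cheb = std::max(std::abs(xx - cx), std::abs(yy - cy));
          if (cheb <= patchR) continue;
          double v = img(yy, xx);
          if (!ISNAN(v)) ring.push_back(v);
        }
      if (!ring.empty()) {
        size_t mid = ring.size() / 2;
        std::nth_element(ring.begin(), ring.begin() + mid, ring.end());
        bg = ring[mid];
        if (ring.size() % 2 == 0) {
          double lo = *std::max_element(ring.begin(), ring.begin() + mid);
          bg = 0.5 * (bg + lo);
        }
      }
    }
    localBg[i] = bg;
    integ[i] = s - bg * npx;
  }
  return DataFrame::create(_["intensity"] = integ, _["localBg"] = localBg);
}
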