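#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>
using namespace Rcpp;

// Neighbourhood offsets with linear spatial falloff between
// (radius - falloff) and radius. Excludes the focal pixel (weight 1, added
// separately).
struct Off { int di, dj; double w; };

static std::vector<Off> make_offsets(double radius, double falloff) {
  std::vector<Off> off;
  int r = (int)std::floor(radius);
  double inner = radius - falloff;
  for (int dj = -r; dj <= r; ++dj) {
    for (int di = -r; di <= r; ++di) {
      if (di == 0 && dj == 0) continue;
      double d = std::sqrt((double)(di * di + dj * dj));
      if (d > radius) continue;
      double w = 1.0;
      if (falloff > 0 && d > inner) w = (radius - d) / falloff;
      if (w <= 0) continue;
      Off o; o.di = di; o.dj = dj; o.w = w;
      off.push_back(o);
    }
  }
  return off;
}

// separable running min/max of a matrix over a (2r+1) square window,
// used to skip pixels whose whole neighbourhood is numerically constant
static void window_range(const NumericMatrix &x, int r,
                         NumericMatrix &wmin, NumericMatrix &wmax,
                         NumericMatrix &tmin, NumericMatrix &tmax) {
  int nr = x.nrow(), nc = x.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int lo = std::max(0, i - r), hi = std::min(nr - 1, i + r);
      double mn = x(lo, j), mx = mn;
      for (int k = lo + 1; k <= hi; ++k) {
        double v = x(k, j);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      tmin(i, j) = mn; tmax(i, j) = mx;
    }
  }
  for (int j = 0; j < nc; ++j) {
    int lo = std::max(0, j - r), hi = std::min(nc - 1, j + r);
    for (int i = 0; i < nr; ++i) {
      double mn = tmin(i, lo), mx = tmax(i, lo);
      for (int k = lo + 1; k <= hi; ++k) {
        if (tmin(i, k) < mn) mn = tmin(i, k);
        if (tmax(i, k) > mx) mx = tmax(i, k);
      }
      wmin(i, j) = mn; wmax(i, j) = mx;
    }
  }
}

// weighted quantile of sorted (value, weight) pairs
static double weighted_quantile(const std::vector<std::pair<double, double> > &vw,
                                double wtot, double p) {
  double acc = 0.0;
  for (size_t k = 0; k < vw.size(); ++k) {
    acc += vw[k].second;
    if (acc >= p * wtot) return vw[k].first;
  }
  return vw.back().first;
}

// Shock-style snap target for a minority pixel: the nearer (in log
// luminance) of the kernel's two dominant extreme clusters, located by the
// weighted 0.15 and 0.85 quantiles.
static double snap_target(std::vector<std::pair<double, double> > &vw,
                          double lf) {
  std::sort(vw.begin(), vw.end());
  double wtot = 0.0;
  for (size_t k = 0; k < vw.size(); ++k) wtot += vw[k].second;
  double q_lo = weighted_quantile(vw, wtot, 0.15);
  double q_hi = weighted_quantile(vw, wtot, 0.85);
  return (std::fabs(lf - q_hi) <= std::fabs(lf - q_lo)) ? q_hi : q_lo;
}

// One pixel of the rank-augmented RNL step, luminance only. If the focal
// pixel's own sub-threshold cluster carries at least min_cluster_frac of the
// kernel weight, the pixel is replaced by the weighted mean of that cluster
// (plain edge-preserving smoothing). Otherwise the pixel is a minority level
// (e.g. on the flank of a blurred suprathreshold boundary) and is snapped to
// the nearer dominant extreme cluster: the weighted mean of the neighbours
// within the gate of the snap target (see snap_target above).
static inline double rnl_pixel_lum(const NumericMatrix &cur,
                                   const NumericMatrix &L,
                                   const std::vector<Off> &off,
                                   int i, int j, int nr, int nc,
                                   double gate, double min_cluster_frac) {
  double lf = L(i, j);
  double w_own = 1.0, v_own = cur(i, j);
  double w_tot = 1.0;
  for (size_t k = 0; k < off.size(); ++k) {
    int ii = i + off[k].di, jj = j + off[k].dj;
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    w_tot += off[k].w;
    if (std::fabs(L(ii, jj) - lf) < gate) {
      w_own += off[k].w;
      v_own += off[k].w * cur(ii, jj);
    }
  }
  if (w_own >= min_cluster_frac * w_tot) return v_own / w_own;
  // minority pixel: snap to the nearer dominant extreme cluster
  std::vector<std::pair<double, double> > vw;
  vw.reserve(off.size() + 1);
  vw.push_back(std::make_pair(lf, 1.0));
  for (size_t k = 0; k < off.size(); ++k) {
    int ii = i + off[k].di, jj = j + off[k].dj;
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    vw.push_back(std::make_pair(L(ii, jj), off[k].w));
  }
  double tgt = snap_target(vw, lf);
  double vsum = 0.0, wsum = 0.0;
  if (std::fabs(lf - tgt) < gate) { vsum += cur(i, j); wsum += 1.0; }
  for (size_t k = 0; k < off.size(); ++k) {
    int ii = i + off[k].di, jj = j + off[k].dj;
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    if (std::fabs(L(ii, jj) - tgt) < gate) {
      vsum += off[k].w * cur(ii, jj);
      wsum += off[k].w;
    }
  }
  return wsum > 0.0 ? vsum / wsum : cur(i, j);
}

// [[Rcpp::export]]
NumericMatrix rnl_filter_lum_cpp(NumericMatrix img, int iterations,
                                 double radius, double falloff,
                                 double threshold, double weber_lum,
                                 double min_cluster_frac = 0.3) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<Off> off = make_offsets(radius, falloff);
  NumericMatrix cur = clone(img);
  NumericMatrix nxt(nr, nc);
  NumericMatrix L(nr, nc);
  NumericMatrix wmin(nr, nc), wmax(nr, nc), tmin(nr, nc), tmax(nr, nc);
  int r = (int)std::floor(radius);
  double gate = threshold * weber_lum;  // gate on |log difference| directly
  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) L(i, j) = std::log(cur(i, j));
    window_range(L, r, wmin, wmax, tmin, tmax);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (wmax(i, j) - wmin(i, j) < 1e-12) {  // constant neighbourhood
          nxt(i, j) = cur(i, j);
          continue;
        }
        nxt(i, j) = rnl_pixel_lum(cur, L, off, i, j, nr, nc, gate,
                                  min_cluster_frac);
      }
    }
    NumericMatrix tmp = cur; cur = nxt; nxt = tmp;
  }
  return cur;
}

// [[Rcpp::export]]
List rnl_filter_cpp(NumericMatrix lw, NumericMatrix mw, NumericMatrix sw,
                    int iterations, double radius, double falloff,
                    double threshold, double weber_lum,
                    double weber_lw, double weber_mw, double weber_sw,
                    double min_cluster_frac = 0.3) {
  int nr = lw.nrow(), nc = lw.ncol();
  std::vector<Off> off = make_offsets(radius, falloff);
  NumericMatrix cl = clone(lw), cm = clone(mw), cs = clone(sw);
  NumericMatrix nl(nr, nc), nm(nr, nc), ns(nr, nc);
  NumericMatrix Ll(nr, nc), Lm(nr, nc), Ls(nr, nc), Lu(nr, nc);
  double el2 = weber_lw * weber_lw, em2 = weber_mw * weber_mw,
         es2 = weber_sw * weber_sw;
  double den = el2 * em2 + el2 * es2 + em2 * es2;
  double thr2 = threshold * threshold;
  double gate = threshold * weber_lum;
  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        Ll(i, j) = std::log(cl(i, j));
        Lm(i, j) = std::log(cm(i, j));
        Ls(i, j) = std::log(cs(i, j));
        Lu(i, j) = std::log(0.5 * (cl(i, j) + cm(i, j)));
      }
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double fl = Ll(i, j), fm = Lm(i, j), fs = Ls(i, j);
        // reference luminance level: own value, or the kernel's weighted
        // median when the focal pixel's own cluster is a minority
        double m = Lu(i, j);
        double w_own = 1.0, w_tot = 1.0;
        for (size_t k = 0; k < off.size(); ++k) {
          int ii = i + off[k].di, jj = j + off[k].dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          w_tot += off[k].w;
          if (std::fabs(Lu(ii, jj) - m) < gate) w_own += off[k].w;
        }
        if (w_own < min_cluster_frac * w_tot) {
          std::vector<std::pair<double, double> > vw;
          vw.reserve(off.size() + 1);
          vw.push_back(std::make_pair(m, 1.0));
          for (size_t k = 0; k < off.size(); ++k) {
            int ii = i + off[k].di, jj = j + off[k].dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            vw.push_back(std::make_pair(Lu(ii, jj), off[k].w));
          }
          m = snap_target(vw, Lu(i, j));
        }
        double wsum = 0.0, vl = 0.0, vm = 0.0, vs = 0.0;
        if (std::fabs(Lu(i, j) - m) < gate) {
          wsum += 1.0; vl += cl(i, j); vm += cm(i, j); vs += cs(i, j);
        }
        for (size_t k = 0; k < off.size(); ++k) {
          int ii = i + off[k].di, jj = j + off[k].dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (std::fabs(Lu(ii, jj) - m) >= gate) continue;
          double dl = Ll(ii, jj) - fl, dm = Lm(ii, jj) - fm,
                 ds = Ls(ii, jj) - fs;
          double num = es2 * (dl - dm) * (dl - dm) +
                       em2 * (dl - ds) * (dl - ds) +
                       el2 * (dm - ds) * (dm - ds);
          if (num / den >= thr2) continue;  // chromatic Delta-S >= threshold
          wsum += off[k].w;
          vl += off[k].w * cl(ii, jj);
          vm += off[k].w * cm(ii, jj);
          vs += off[k].w * cs(ii, jj);
        }
        if (wsum > 0.0) {
          nl(i, j) = vl / wsum; nm(i, j) = vm / wsum; ns(i, j) = vs / wsum;
        } else {
          nl(i, j) = cl(i, j); nm(i, j) = cm(i, j); ns(i, j) = cs(i, j);
        }
      }
    }
    NumericMatrix t;
    t = cl; cl = nl; nl = t;
    t = cm; cm = nm; nm = t;
    t = cs; cs = ns; ns = t;
  }
  return List::create(cl, cm, cs);
}
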