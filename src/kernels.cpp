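#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// half-sample mirror: -1 -> 0, -2 -> 1, n -> n-1, ...
inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// matches stats::median(): mean of the two middle order statistics when even
double median_inplace(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  const size_t n = v.size();
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// triangular membership centred on the clean-neighbour median, floored so the
// aggregate is always defined
double fuzzy_weighted(const std::vector<double>& clean, double centre,
                      double spread, double weight_floor) {
  double sw = 0.0, swv = 0.0;
  for (double v : clean) {
    double w = 1.0 - std::fabs(v - centre) / spread;
    if (w < weight_floor) w = weight_floor;
    sw += w;
    swv += w * v;
  }
  return swv / sw;
}

double afm_pixel_impl(const NumericMatrix& img, const LogicalMatrix& mask,
                      int r, int c, int init_w, int max_w, double spread,
                      int min_clean, double weight_floor) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<double> all, clean, tmp;
  for (int w = init_w; w <= max_w; w += 2) {
    const bool last = (w + 2 > max_w);
    const int k = w / 2;
    all.clear();
    clean.clear();
    for (int dc = -k; dc <= k; ++dc) {
      for (int dr = -k; dr <= k; ++dr) {
        const int rr = reflect_index(r + dr, nr);
        const int cc = reflect_index(c + dc, nc);
        const double v = img(rr, cc);
        all.push_back(v);
        if (!mask(rr, cc)) clean.push_back(v);
      }
    }
    if (static_cast<int>(clean.size()) >= min_clean) {
      tmp = clean;
      const double med = median_inplace(tmp);
      const double mn = *std::min_element(all.begin(), all.end());
      const double mx = *std::max_element(all.begin(), all.end());
      // the adaptive-median trigger: a median sitting at a window extreme is
      // itself suspect, so grow the window and retry
      if ((med > mn && med < mx) || last)
        return fuzzy_weighted(clean, med, spread, weight_floor);
    } else if (last) {
      if (!clean.empty()) {
        tmp = clean;
        const double med = median_inplace(tmp);
        return fuzzy_weighted(clean, med, spread, weight_floor);
      }
      tmp = all;
      return median_inplace(tmp);  // no usable neighbours at the largest window
    }
  }
  return img(r, c);  // unreachable: the last iteration always returns
}

}  // namespace

// [[Rcpp::export]]
List cpp_amed_amad(const NumericMatrix img, const int window,
                   const bool reflect) {
  const int nr = img.nrow(), nc = img.ncol(), k = window / 2;
  NumericMatrix amed(nr, nc), amad(nr, nc);
  std::vector<double> vals, devs;
  vals.reserve(window * window);
  devs.reserve(window * window);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      vals.clear();
      for (int dc = -k; dc <= k; ++dc) {
        for (int dr = -k; dr <= k; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (reflect) {
            rr = reflect_index(rr, nr);
            cc = reflect_index(cc, nc);
          } else if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) {
            continue;  // exclude_partial: clipped window
          }
          vals.push_back(img(rr, cc));
        }
      }
      devs.clear();
      const double med = median_inplace(vals);
      for (double v : vals) devs.push_back(std::fabs(v - med));
      amed(r, c) = med;
      amad(r, c) = median_inplace(devs);
    }
  }
  return List::create(_["amed"] = amed, _["amad"] = amad);
}

// [[Rcpp::export]]
NumericMatrix cpp_sliding_median(const NumericMatrix img, const int window) {
  const int nr = img.nrow(), nc = img.ncol(), k = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> vals;
  vals.reserve(window * window);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      vals.clear();
      for (int dc = -k; dc <= k; ++dc)
        for (int dr = -k; dr <= k; ++dr)
          vals.push_back(
              img(reflect_index(r + dr, nr), reflect_index(c + dc, nc)));
      out(r, c) = median_inplace(vals);
    }
  }
  return out;
}

// classic two-level adaptive median: grow the window while its median is an
// extreme; replace the pixel only if the pixel itself is an extreme of the
// final window
// [[Rcpp::export]]
NumericMatrix cpp_adaptive_median(const NumericMatrix img,
                                  const int max_window) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  std::vector<double> vals;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int w = 3; w <= max_window; w += 2) {
        const int k = w / 2;
        vals.clear();
        for (int dc = -k; dc <= k; ++dc)
          for (int dr = -k; dr <= k; ++dr)
            vals.push_back(
                img(reflect_index(r + dr, nr), reflect_index(c + dc, nc)));
        const double mn = *std::min_element(vals.begin(), vals.end());
        const double mx = *std::max_element(vals.begin(), vals.end());
        const double med = median_inplace(vals);
        const bool med_ok = (med > mn && med < mx);
        if (med_ok || w + 2 > max_window) {
          const double x = img(r, c);
          out(r, c) = (x <= mn || x >= mx) ? med : x;
          break;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_afm_pixel(const NumericMatrix img, const LogicalMatrix mask,
                     const int r, const int c, const int init_w,
                     const int max_w, const double spread,
                     const int min_clean, const double weight_floor) {
  return afm_pixel_impl(img, mask, r, c, init_w, max_w, spread, min_clean,
                        weight_floor);
}

// [[Rcpp::export]]
NumericMatrix cpp_afm_restore(const NumericMatrix img,
                              const LogicalMatrix mask, const int init_w,
                              const int max_w, const double spread,
                              const int min_clean, const double weight_floor) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c))
        out(r, c) = afm_pixel_impl(img, mask, r, c, init_w, max_w, spread,
                                   min_clean, weight_floor);
  return out;
}

namespace {

// mean squared difference over patch positions where both patches are clean;
// comparable only if the clean overlap covers at least min_clean_fraction of
// the patch
double patch_dist_impl(const NumericMatrix& ref, const LogicalMatrix& mask,
                       int pr, int pc, int qr, int qc, int patch_r,
                       double min_clean_fraction, bool& comparable) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int side = 2 * patch_r + 1;
  const int total = side * side;
  int nok = 0;
  double ss = 0.0;
  for (int dc = -patch_r; dc <= patch_r; ++dc) {
    for (int dr = -patch_r; dr <= patch_r; ++dr) {
      const int r1 = reflect_index(pr + dr, nr), c1 = reflect_index(pc + dc, nc);
      const int r2 = reflect_index(qr + dr, nr), c2 = reflect_index(qc + dc, nc);
      if (!mask(r1, c1) && !mask(r2, c2)) {
        const double d = ref(r1, c1) - ref(r2, c2);
        ss += d * d;
        ++nok;
      }
    }
  }
  if (nok == 0 || static_cast<double>(nok) < min_clean_fraction * total) {
    comparable = false;
    return NA_REAL;
  }
  comparable = true;
  return ss / nok;
}

}  // namespace

// [[Rcpp::export]]
double cpp_patch_distance(const NumericMatrix ref, const LogicalMatrix mask,
                          const int pr, const int pc, const int qr,
                          const int qc, const int patch_r,
                          const double min_clean_fraction) {
  bool comparable;
  return patch_dist_impl(ref, mask, pr, pc, qr, qc, patch_r,
                         min_clean_fraction, comparable);
}

// [[Rcpp::export]]
NumericMatrix cpp_nlm_restore(const NumericMatrix img,
                              const LogicalMatrix mask,
                              const NumericMatrix ref, const int patch_r,
                              const int search_r, const double h,
                              const double min_clean_fraction,
                              const int afm_init_w, const int afm_max_w,
                              const double afm_spread, const int afm_min_clean,
                              const double afm_weight_floor) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);
  const double h2 = h * h;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double sw = 0.0, swv = 0.0;
      const int r0 = std::max(0, r - search_r), r1 = std::min(nr - 1, r + search_r);
      const int c0 = std::max(0, c - search_r), c1 = std::min(nc - 1, c + search_r);
      for (int qc = c0; qc <= c1; ++qc) {
        for (int qr = r0; qr <= r1; ++qr) {
          if (mask(qr, qc)) continue;  // only clean pixels may contribute
          bool comparable;
          const double d = patch_dist_impl(ref, mask, r, c, qr, qc, patch_r,
                                           min_clean_fraction, comparable);
          if (!comparable) continue;
          const double w = std::exp(-d / h2);
          sw += w;
          swv += w * ref(qr, qc);
        }
      }
      out(r, c) = (sw > 0.0)
                      ? swv / sw
                      : afm_pixel_impl(ref, mask, r, c, afm_init_w, afm_max_w,
                                       afm_spread, afm_min_clean,
                                       afm_weight_floor);
    }
  }
  return out;
}
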