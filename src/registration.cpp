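#include <Rcpp.h>
using namespace Rcpp;

// Mean normalized cross-correlation of square patches around interest
// points, evaluated over every integer translation in [-max_shift,
// max_shift]^2. Patches are taken from the reference image; the candidate
// patch in the current image is displaced by the trial shift. Points whose
// displaced patch leaves the image, or whose patch has zero variance on
// either side, do not contribute at that shift. Ties in the mean score are
// broken toward the smaller displacement so that a featureless scene
// defaults to no motion.
// [[Rcpp::export(name = ".ncc_shift_search")]]
List ncc_shift_search(NumericMatrix ref, NumericMatrix cur,
                      IntegerMatrix pts, int patch_radius, int max_shift) {
  const int H = ref.nrow(), W = ref.ncol();
  const int r = patch_radius, m = max_shift;
  const int np = pts.nrow();
  const int side = 2 * m + 1;
  const int n = (2 * r + 1) * (2 * r + 1);
  NumericMatrix score(side, side);
  IntegerMatrix nused(side, side);

  // reference-patch statistics do not depend on the trial shift
  std::vector<double> ref_sum(np), ref_var(np);
  std::vector<bool> ref_ok(np);
  for (int p = 0; p < np; ++p) {
    const int y = pts(p, 0) - 1, x = pts(p, 1) - 1;  // 1-based in R
    ref_ok[p] = y - r >= 0 && y + r < H && x - r >= 0 && x + r < W;
    if (!ref_ok[p]) continue;
    double sa = 0, saa = 0;
    for (int i = -r; i <= r; ++i)
      for (int j = -r; j <= r; ++j) {
        const double a = ref(y + i, x + j);
        sa += a; saa += a * a;
      }
    ref_sum[p] = sa;
    ref_var[p] = saa - sa * sa / n;
    if (ref_var[p] <= 0.0) ref_ok[p] = false;
  }

  for (int dyi = 0; dyi < side; ++dyi) {
    for (int dxi = 0; dxi < side; ++dxi) {
      const int dy = dyi - m, dx = dxi - m;
      double acc = 0.0;
      int cnt = 0;
      for (int p = 0; p < np; ++p) {
        if (!ref_ok[p]) continue;
        const int y = pts(p, 0) - 1, x = pts(p, 1) - 1;
        const int cy = y + dy, cx = x + dx;
        if (cy - r < 0 || cy + r >= H || cx - r < 0 || cx + r >= W) continue;
        double sb = 0, sbb = 0, sab = 0;
        for (int i = -r; i <= r; ++i) {
          for (int j = -r; j <= r; ++j) {
            const double a = ref(y + i, x + j);
            const double b = cur(cy + i, cx + j);
            sb += b; sbb += b * b; sab += a * b;
          }
        }
        const double vb = sbb - sb * sb / n;
        if (vb <= 0.0) continue;
        acc += (sab - ref_sum[p] * sb / n) / std::sqrt(ref_var[p] * vb);
        ++cnt;
      }
      score(dyi, dxi) = cnt > 0 ? acc / cnt : R_NegInf;
      nused(dyi, dxi) = cnt;
    }
  }

  int best_dy = 0, best_dx = 0;
  double best = R_NegInf;
  for (int dyi = 0; dyi < side; ++dyi) {
    for (int dxi = 0; dxi < side; ++dxi) {
      const int dy = dyi - m, dx = dxi - m;
      const double s = score(dyi, dxi);
      const bool closer = dy * dy + dx * dx < best_dy * best_dy + best_dx * best_dx;
      if (s > best || (s == best && closer)) {
        best = s; best_dy = dy; best_dx = dx;
      }
    }
  }
  return List::create(_["dy"] = best_dy, _["dx"] = best_dx,
                      _["score"] = best,
                      _["n_points"] = nused(best_dy + m, best_dx + m),
                      _["surface"] = score);
}
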