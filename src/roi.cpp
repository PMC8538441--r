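#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// For each candidate voxel center, test whether the nearest tumor-surface
// voxel center lies within `radius` (mm). Brute force with early exit; the
// caller prefilters candidates to the tumor bounding box expanded by the
// shell radius, which keeps this small even on fine grids.

// [[Rcpp::export]]
LogicalVector roi_within_cpp(NumericVector cx, NumericVector cy,
                             NumericVector cz, NumericVector tx,
                             NumericVector ty, NumericVector tz,
                             double radius) {
    int n = cx.size(), m = tx.size();
    double r2 = radius * radius;
    LogicalVector out(n);
    for (int i = 0; i < n; ++i) {
        bool hit = false;
        for (int j = 0; j < m; ++j) {
            double ddx = cx[i] - tx[j];
            double ddy = cy[i] - ty[j];
            double ddz = cz[i] - tz[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) { hit = true; break; }
        }
        out[i] = hit;
    }
    return out;
}
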