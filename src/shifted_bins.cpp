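#include <Rcpp.h>
using namespace Rcpp;

// Per-bin activity sums and sample counts under circular position shifts.
//
// activity: activity samples at the masked frames (length M)
// bin_full: 1-based spatial bin index for every frame of the concatenated
//           trace (length T)
// mask_idx: 1-based frame indices of the masked samples (length M)
// shifts:   forward shifts (frames) applied to the position trace; shift 0
//           reproduces the true alignment
//
// Shifting position forward by s means the activity at frame f is paired
// with the position recorded at frame f - s (wrapped around the trace).
// [[Rcpp::export]]
List shifted_bin_stats(NumericVector activity, IntegerVector bin_full,
                       IntegerVector mask_idx, IntegerVector shifts,
                       int nbins) {
  const int T = bin_full.size();
  const int M = mask_idx.size();
  const int S = shifts.size();
  if (activity.size() != M) stop("activity and mask_idx lengths differ");
  NumericMatrix sums(nbins, S);
  IntegerMatrix counts(nbins, S);
  for (int s = 0; s < S; ++s) {
    const int sh = shifts[s] % T;
    for (int m = 0; m < M; ++m) {
      int j = (mask_idx[m] - 1 - sh) % T;
      if (j < 0) j += T;
      const int b = bin_full[j] - 1;
      if (b < 0 || b >= nbins) stop("bin index out of range");
      sums(b, s) += activity[m];
      counts(b, s) += 1;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
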