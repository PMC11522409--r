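#include <Rcpp.h>
using namespace Rcpp;

// Precise-timing spike detection scan.
//
// Finds local extrema of the filtered trace (3-point comparison; a plateau
// takes its first sample), then pairs each extremum with the
// largest-excursion opposite-sign extremum no more than max_sep samples
// later. A pair whose peak-to-peak amplitude reaches thr becomes a spike,
// timed on the extremum with the larger absolute amplitude; after an
// accepted spike no further spike is accepted for refr samples.
//
// Returns 1-based sample indices and peak-to-peak amplitudes.
// [[Rcpp::export]]
List ptsd_scan(NumericVector x, double thr, int max_sep, int refr) {
  int n = x.size();
  std::vector<int> eidx;
  std::vector<double> eval;
  eidx.reserve(n / 4);
  eval.reserve(n / 4);

  int i = 1;
  while (i < n - 1) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j; // plateau -> first sample
    if (j + 1 < n) {
      double prev = x[i - 1], next = x[j + 1], v = x[i];
      if ((v > prev && v > next) || (v < prev && v < next)) {
        eidx.push_back(i);
        eval.push_back(v);
      }
    }
    i = j + 1;
  }

  int m = (int)eidx.size();
  std::vector<int> sp_idx;
  std::vector<double> sp_amp;
  double last = -2.0 * refr - 10.0;

  int a = 0;
  while (a < m) {
    if (eidx[a] < last + refr) { ++a; continue; }
    // best opposite-sign partner within the peak lifetime
    int best = -1; double best_ptp = 0.0;
    for (int b = a + 1; b < m && eidx[b] - eidx[a] <= max_sep; ++b) {
      if ((eval[a] < 0) == (eval[b] < 0)) continue;
      double ptp = std::fabs(eval[a] - eval[b]);
      if (ptp > best_ptp) { best_ptp = ptp; best = b; }
    }
    if (best >= 0 && best_ptp >= thr) {
      int at = (std::fabs(eval[a]) >= std::fabs(eval[best])) ? a : best;
      if (eidx[at] >= last + refr) {
        sp_idx.push_back(eidx[at] + 1); // 1-based
        sp_amp.push_back(best_ptp);
        last = eidx[at];
        a = best + 1;
        continue;
      }
    }
    ++a;
  }

  return List::create(_["index"] = wrap(sp_idx), _["amplitude"] = wrap(sp_amp));
}
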