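#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Prominence-based local-maximum detection in the style of ImageJ's
// "find maxima". Candidates are 8-neighbourhood local maxima, processed in
// descending intensity order. From each candidate a flood fill grows over
// the connected region of pixels with value > v0 - tolerance. If the flood
// reaches a pixel brighter than the candidate, or a pixel already claimed
// by a stronger accepted maximum, the candidate lies within the tolerance
// band of higher ground and is merged (rejected). Otherwise it is accepted,
// its region is claimed, and the plateau (pixels equal to v0 inside the
// region) is reduced to its centroid. The reported prominence is the drop
// from the peak to the brightest pixel just outside the accepted region
// (>= tolerance by construction, capped at peak - image minimum).

// [[Rcpp::export]]
DataFrame cpp_find_maxima(NumericMatrix img, double tolerance) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // candidate local maxima (>= all 8 neighbours)
  std::vector<int> cand;
  cand.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      bool is_max = true;
      for (int k = 0; k < 8 && is_max; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (img(rr, cc) > v) is_max = false;
      }
      if (is_max) cand.push_back(r + c * nr);
    }
  }
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    double va = img(a % nr, a / nr), vb = img(b % nr, b / nr);
    if (va != vb) return va > vb;
    return a < b;
  });

  double img_min = img(0, 0);
  for (int i = 0; i < n; ++i) {
    double v = img(i % nr, i / nr);
    if (v < img_min) img_min = v;
  }

  std::vector<int> status(n, 0);     // 0 free, >0 claimed by accepted max id
  std::vector<int> visited(n, -1);   // last candidate index visiting pixel
  std::vector<int> queue_;
  queue_.reserve(1024);
  std::vector<double> out_row, out_col, out_peak, out_prom;

  int next_id = 0;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int p0 = cand[ci];
    if (status[p0] != 0) continue;       // inside an accepted region already
    double v0 = img(p0 % nr, p0 / nr);
    double lo = v0 - tolerance;

    queue_.clear();
    queue_.push_back(p0);
    visited[p0] = (int)ci;
    bool accepted = true;
    size_t head = 0;
    while (head < queue_.size()) {
      int p = queue_[head++];
      int r = p % nr, c = p / nr;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr + cc * nr;
        double vq = img(rr, cc);
        if (vq > v0) { accepted = false; break; }
        if (vq > lo && status[q] > 0) { accepted = false; break; }
        if (vq > lo && visited[q] != (int)ci) {
          visited[q] = (int)ci;
          queue_.push_back(q);
        }
      }
      if (!accepted) break;
    }
    if (!accepted) continue;

    ++next_id;
    double sum_r = 0, sum_c = 0;
    int n_plateau = 0;
    double boundary_max = img_min;
    for (size_t i = 0; i < queue_.size(); ++i) {
      int p = queue_[i];
      status[p] = next_id;
      int r = p % nr, c = p / nr;
      if (img(r, c) == v0) { sum_r += r; sum_c += c; ++n_plateau; }
    }
    for (size_t i = 0; i < queue_.size(); ++i) {
      int p = queue_[i];
      int r = p % nr, c = p / nr;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = rr + cc * nr;
        if (status[q] != next_id && img(rr, cc) > boundary_max)
          boundary_max = img(rr, cc);
      }
    }
    double prom = v0 - boundary_max;
    if (prom < tolerance) continue;   // e.g. the plateau of a flat image
    out_row.push_back(sum_r / n_plateau + 1.0);   // 1-based
    out_col.push_back(sum_c / n_plateau + 1.0);
    out_peak.push_back(v0);
    out_prom.push_back(prom);
  }

  return DataFrame::create(_["row"] = out_row, _["col"] = out_col,
                           _["peak"] = out_peak, _["prominence"] = out_prom);
}
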