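#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Topographic-prominence maxima detection by descending level-set flooding
// with union-find. Pixels are processed in groups of equal value from the
// top down; connected components of the superlevel set are merged as lower
// pixels join them. A plateau with no higher neighbour becomes a pending
// peak; when its component first touches a component whose peak is strictly
// higher, the merge level is its saddle and the peak is finalised with
// prominence = peak - saddle. Peaks are accepted when prominence exceeds
// the threshold strictly; the global maximum has no higher ground and is
// always accepted (prominence reported as +Inf). A plateau spanning the
// whole image has no lower neighbour and is not a maximum.

struct Peak {
  double row_c, col_c; // plateau centroid, 0-based
  double val;
};

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_find_maxima(NumericMatrix img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  const double *v = REAL(img);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return v[a] > v[b]; });

  std::vector<int> parent(n);
  std::vector<char> active(n, 0);
  std::vector<double> peak_val(n, 0.0);
  std::vector<std::vector<int> > pending(n); // peak indices per root
  std::vector<Peak> peaks;
  std::vector<double> acc_row, acc_col, acc_val, acc_prom;

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // finalise the pending peaks of the lower-peaked root when two components
  // merge at level `lev`; returns surviving root
  auto merge_at = [&](int ra, int rb, double lev) -> int {
    if (ra == rb) return ra;
    double pa = peak_val[ra], pb = peak_val[rb];
    if (pa < pb) { std::swap(ra, rb); std::swap(pa, pb); }
    // ra has the (weakly) higher peak
    if (pb < pa) {
      for (size_t k = 0; k < pending[rb].size(); ++k) {
        const Peak &p = peaks[pending[rb][k]];
        double prom = p.val - lev;
        if (prom > prominence) {
          acc_row.push_back(p.row_c);
          acc_col.push_back(p.col_c);
          acc_val.push_back(p.val);
          acc_prom.push_back(prom);
        }
      }
      pending[rb].clear();
    } else {
      // equal peak heights: neither is rejected yet, carry both
      pending[ra].insert(pending[ra].end(), pending[rb].begin(),
                         pending[rb].end());
      pending[rb].clear();
    }
    parent[rb] = ra;
    return ra;
  };

  int gi = 0;
  while (gi < n) {
    int gj = gi;
    double lev = v[order[gi]];
    while (gj < n && v[order[gj]] == lev) ++gj;
    // activate group pixels as singleton components
    for (int k = gi; k < gj; ++k) {
      int p = order[k];
      parent[p] = p;
      peak_val[p] = lev;
      active[p] = 1;
    }
    // union with higher (already active) neighbours, then within the level
    for (int pass = 0; pass < 2; ++pass) {
      for (int k = gi; k < gj; ++k) {
        int p = order[k];
        int pr = p % nr, pc = p / nr;
        for (int d = 0; d < 8; ++d) {
          int qr = pr + dr[d], qc = pc + dc[d];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qr + qc * nr;
          if (!active[q]) continue;
          bool higher = v[q] > lev;
          if ((pass == 0 && higher) || (pass == 1 && v[q] == lev)) {
            merge_at(find_root(parent, p), find_root(parent, q), lev);
          }
        }
      }
    }
    // components whose peak is still at this level are new peak plateaus
    std::unordered_map<int, std::vector<int> > plateau;
    for (int k = gi; k < gj; ++k) {
      int p = order[k];
      int r = find_root(parent, p);
      if (peak_val[r] == lev) plateau[r].push_back(p);
    }
    for (std::unordered_map<int, std::vector<int> >::iterator it =
             plateau.begin(); it != plateau.end(); ++it) {
      if ((int)it->second.size() == n) continue; // whole image: no lower nbr
      double sr = 0, sc = 0;
      for (size_t k = 0; k < it->second.size(); ++k) {
        sr += it->second[k] % nr;
        sc += it->second[k] / nr;
      }
      Peak pk;
      pk.row_c = sr / it->second.size();
      pk.col_c = sc / it->second.size();
      pk.val = lev;
      peaks.push_back(pk);
      pending[it->first].push_back((int)peaks.size() - 1);
    }
    gi = gj;
  }

  // survivors have no higher ground: global maxima, prominence infinite
  for (int i = 0; i < n; ++i) {
    if (parent[i] == i && active[i] && !pending[i].empty()) {
      for (size_t k = 0; k < pending[i].size(); ++k) {
        const Peak &p = peaks[pending[i][k]];
        acc_row.push_back(p.row_c);
        acc_col.push_back(p.col_c);
        acc_val.push_back(p.val);
        acc_prom.push_back(R_PosInf);
      }
      pending[i].clear();
    }
  }

  NumericMatrix out((int)acc_row.size(), 4);
  for (int i = 0; i < (int)acc_row.size(); ++i) {
    out(i, 0) = acc_row[i];
    out(i, 1) = acc_col[i];
    out(i, 2) = acc_val[i];
    out(i, 3) = acc_prom[i];
  }
  colnames(out) = CharacterVector::create("row", "col", "value", "prominence");
  return out;
}
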