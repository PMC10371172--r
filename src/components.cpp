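#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a binary 2D mask, 8-connectivity,
// non-periodic boundaries. Background = 0, labels 1..k in scan order.
// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerMatrix cc_label_2d(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Connected-component labeling of a binary 3D mask (flattened, dims =
// c(nx, ny, nz)), 26-connectivity, non-periodic.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    ++next;
    stack.clear();
    stack.push_back(i0);
    lab[i0] = next;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// ---- lattice self-assembly engine -----------------------------------------
//
// Square lattice, 4-connectivity, periodic boundaries. One step applies, in
// order: (1) nucleation: with prob pn occupy one uniformly random empty site;
// (2) growth: for each 4-connected cluster (identified after nucleation),
// with prob pg occupy one uniformly random empty perimeter site; (3) removal:
// each occupied site independently vacated with prob pr.
// Uses R's RNG so results are reproducible under set.seed().

static void label_periodic4(const std::vector<unsigned char>& occ, int nr, int nc,
                            std::vector<int>& lab,
                            std::vector<std::vector<int>>& members) {
  const int n = nr * nc;
  std::fill(lab.begin(), lab.end(), 0);
  members.clear();
  std::vector<int> stack;
  int next = 0;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!occ[i0] || lab[i0]) continue;
    ++next;
    members.push_back(std::vector<int>());
    stack.clear();
    stack.push_back(i0);
    lab[i0] = next;
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      members[next - 1].push_back(idx);
      int r = idx % nr, c = idx / nr;
      int nb[4] = {
        ((r + 1) % nr) + c * nr,
        ((r - 1 + nr) % nr) + c * nr,
        r + ((c + 1) % nc) * nr,
        r + ((c - 1 + nc) % nc) * nr
      };
      for (int k = 0; k < 4; ++k) {
        int j = nb[k];
        if (occ[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".assembly_run")]]
List assembly_run(IntegerMatrix lattice, double pn, double pg, double pr,
                  int n_steps) {
  const int nr = lattice.nrow(), nc = lattice.ncol(), n = nr * nc;
  std::vector<unsigned char> occ(n);
  int n_occ = 0;
  for (int i = 0; i < n; ++i) {
    occ[i] = lattice[i] != 0;
    if (occ[i]) ++n_occ;
  }
  std::vector<int> lab(n);
  std::vector<std::vector<int>> members;
  std::vector<int> perim;
  std::vector<int> stamp(n, -1);
  int token = 0;  // unique per cluster-growth attempt; dedupes perimeter sites
  IntegerVector occupancy(n_steps), inserted(n_steps), removed(n_steps);

  for (int step = 0; step < n_steps; ++step) {
    int ins = 0, rem = 0;
    // (1) nucleation
    if (n_occ < n && unif_rand() < pn) {
      int target = (int)(unif_rand() * (n - n_occ));
      if (target >= n - n_occ) target = n - n_occ - 1;
      int seen = 0;
      for (int i = 0; i < n; ++i) {
        if (!occ[i]) {
          if (seen == target) { occ[i] = 1; ++n_occ; ++ins; break; }
          ++seen;
        }
      }
    }
    // (2) growth: one empty perimeter site per existing cluster
    if (pg > 0 && n_occ > 0) {
      label_periodic4(occ, nr, nc, lab, members);
      for (size_t ci = 0; ci < members.size(); ++ci) {
        if (unif_rand() >= pg) continue;
        ++token;
        perim.clear();
        for (size_t mi = 0; mi < members[ci].size(); ++mi) {
          int idx = members[ci][mi];
          int r = idx % nr, c = idx / nr;
          int nb[4] = {
            ((r + 1) % nr) + c * nr,
            ((r - 1 + nr) % nr) + c * nr,
            r + ((c + 1) % nc) * nr,
            r + ((c - 1 + nc) % nc) * nr
          };
          for (int k = 0; k < 4; ++k) {
            int j = nb[k];
            if (!occ[j] && stamp[j] != token) {
              stamp[j] = token;
              perim.push_back(j);
            }
          }
        }
        if (!perim.empty()) {
          int pick = (int)(unif_rand() * perim.size());
          if (pick >= (int)perim.size()) pick = (int)perim.size() - 1;
          occ[perim[pick]] = 1;
          ++n_occ; ++ins;
        }
      }
    }
    // (3) removal
    if (pr > 0 && n_occ > 0) {
      for (int i = 0; i < n; ++i) {
        if (occ[i] && unif_rand() < pr) {
          occ[i] = 0; --n_occ; ++rem;
        }
      }
    }
    occupancy[step] = n_occ;
    inserted[step] = ins;
    removed[step] = rem;
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = occ[i];
  return List::create(_["lattice"] = out,
                      _["occupancy"] = occupancy,
                      _["inserted"] = inserted,
                      _["removed"] = removed);
}

// Cluster sizes of the current lattice under periodic 4-connectivity.
// [[Rcpp::export(name = ".assembly_sizes")]]
IntegerVector assembly_sizes(const IntegerMatrix& lattice) {
  const int nr = lattice.nrow(), nc = lattice.ncol(), n = nr * nc;
  std::vector<unsigned char> occ(n);
  for (int i = 0; i < n; ++i) occ[i] = lattice[i] != 0;
  std::vector<int> lab(n);
  std::vector<std::vector<int>> members;
  label_periodic4(occ, nr, nc, lab, members);
  IntegerVector sizes(members.size());
  for (size_t i = 0; i < members.size(); ++i)
    sizes[i] = (int)members[i].size();
  return sizes;
}
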