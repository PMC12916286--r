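#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flood-fill connected-component labeling.
// 2D: connectivity 4 or 8. 3D: connectivity 6 or 26.
// Labels are assigned in raster-scan order of the first foreground pixel,
// so the output is deterministic and labels form a contiguous set 1..K.

// [[Rcpp::export(name = ".cc_label2d")]]
IntegerMatrix cc_label2d(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(const LogicalVector& mask, const IntegerVector& dim,
                         int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((double)nx * ny * nz != (double)mask.size())
    stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + (long)ny * z);
        if (!mask[idx] || lab[idx]) continue;
        ++next;
        stack.clear();
        stack.push_back(idx);
        lab[idx] = next;
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int px = p % nx, rem = p / nx;
          int py = rem % ny, pz = rem / ny;
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dy = -1; dy <= 1; ++dy) {
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                if (connectivity == 6 &&
                    (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
                int qx = px + dx, qy = py + dy, qz = pz + dz;
                if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                    qz < 0 || qz >= nz) continue;
                int q = qx + nx * (qy + (long)ny * qz);
                if (mask[q] && !lab[q]) {
                  lab[q] = next;
                  stack.push_back(q);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
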