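#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
using namespace Rcpp;

// Texture-matrix kernels. All operate on a quantized VOI: an integer 3D
// array where 0 marks voxels outside the mask and in-mask voxels carry a
// grey level in 1..ng. Directions are voxel offsets; the canonical set is
// the 13 unique 3D directions (each direction and its negation count as
// one line orientation).

static inline bool inb(int x, int n) { return x >= 0 && x < n; }

// Symmetric, normalized grey-level co-occurrence matrix pooled over the
// supplied directions at voxel distance 1.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector lev, int ng, IntegerMatrix dirs) {
  IntegerVector dm = lev.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericMatrix C(ng, ng);
  double total = 0.0;
  int nd = dirs.nrow();
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int l1 = lev[x + nx * (y + ny * z)];
        if (l1 == 0) continue;
        for (int d = 0; d < nd; d++) {
          int x2 = x + dirs(d, 0), y2 = y + dirs(d, 1), z2 = z + dirs(d, 2);
          if (!inb(x2, nx) || !inb(y2, ny) || !inb(z2, nz)) continue;
          int l2 = lev[x2 + nx * (y2 + ny * z2)];
          if (l2 == 0) continue;
          // each unordered pair counted once per direction; symmetrize
          C(l1 - 1, l2 - 1) += 1.0;
          C(l2 - 1, l1 - 1) += 1.0;
          total += 2.0;
        }
      }
  if (total > 0)
    for (int i = 0; i < ng; i++)
      for (int j = 0; j < ng; j++) C(i, j) /= total;
  return C;
}

// Grey-level run-length counts pooled over directions. A run is a maximal
// sequence of consecutive in-mask voxels of equal level along a direction;
// out-of-mask voxels break runs. Returns an ng x max-run-length count
// matrix (trimmed to the longest observed run).
// [[Rcpp::export]]
IntegerMatrix cpp_glrlm(IntegerVector lev, int ng, IntegerMatrix dirs) {
  IntegerVector dm = lev.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int maxlen = nx + ny + nz;
  std::vector<int> counts((size_t)ng * maxlen, 0);
  int longest = 1;
  int nd = dirs.nrow();
  for (int d = 0; d < nd; d++) {
    int dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int l = lev[x + nx * (y + ny * z)];
          if (l == 0) continue;
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inb(xp, nx) && inb(yp, ny) && inb(zp, nz) &&
              lev[xp + nx * (yp + ny * zp)] == l)
            continue;  // not a run start
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inb(xn, nx) && inb(yn, ny) && inb(zn, nz) &&
                 lev[xn + nx * (yn + ny * zn)] == l) {
            len++; xn += dx; yn += dy; zn += dz;
          }
          counts[(size_t)(l - 1) + (size_t)ng * (len - 1)] += 1;
          if (len > longest) longest = len;
        }
  }
  IntegerMatrix out(ng, longest);
  for (int i = 0; i < ng; i++)
    for (int j = 0; j < longest; j++)
      out(i, j) = counts[(size_t)i + (size_t)ng * j];
  return out;
}

// Grey-level size-zone counts: zones are 26-connected components of equal
// level among in-mask voxels. Returns ng x max-zone-size counts.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lev, int ng) {
  IntegerVector dm = lev.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::map<std::pair<int, int>, int> zones;  // (level, size) -> count
  std::vector<int> stack;
  int maxsize = 1;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
        int l = lev[idx];
        if (l == 0 || seen[idx]) continue;
        int size = 0;
        stack.clear();
        stack.push_back((int)idx);
        seen[idx] = 1;
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          size++;
          int cz = cur / (nx * ny), rem = cur % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (int ddz = -1; ddz <= 1; ddz++)
            for (int ddy = -1; ddy <= 1; ddy++)
              for (int ddx = -1; ddx <= 1; ddx++) {
                if (ddx == 0 && ddy == 0 && ddz == 0) continue;
                int x2 = cx + ddx, y2 = cy + ddy, z2 = cz + ddz;
                if (!inb(x2, nx) || !inb(y2, ny) || !inb(z2, nz)) continue;
                size_t i2 = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
                if (!seen[i2] && lev[i2] == l) {
                  seen[i2] = 1;
                  stack.push_back((int)i2);
                }
              }
        }
        zones[std::make_pair(l, size)] += 1;
        if (size > maxsize) maxsize = size;
      }
  IntegerMatrix out(ng, maxsize);
  for (std::map<std::pair<int, int>, int>::iterator it = zones.begin();
       it != zones.end(); ++it)
    out(it->first.first - 1, it->first.second - 1) = it->second;
  return out;
}

// Neighbourhood grey-tone difference accumulators: for every in-mask voxel
// with at least one in-mask 26-neighbour, add |level - mean(neighbour
// levels)| to s[level] and bump n[level].
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lev, int ng) {
  IntegerVector dm = lev.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector s(ng);
  IntegerVector cnt(ng);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        int l = lev[x + nx * (y + ny * z)];
        if (l == 0) continue;
        double sum = 0.0;
        int k = 0;
        for (int ddz = -1; ddz <= 1; ddz++)
          for (int ddy = -1; ddy <= 1; ddy++)
            for (int ddx = -1; ddx <= 1; ddx++) {
              if (ddx == 0 && ddy == 0 && ddz == 0) continue;
              int x2 = x + ddx, y2 = y + ddy, z2 = z + ddz;
              if (!inb(x2, nx) || !inb(y2, ny) || !inb(z2, nz)) continue;
              int l2 = lev[x2 + nx * (y2 + ny * z2)];
              if (l2 == 0) continue;
              sum += l2; k++;
            }
        if (k > 0) {
          s[l - 1] += std::fabs((double)l - sum / k);
          cnt[l - 1] += 1;
        }
      }
  return List::create(Named("s") = s, Named("n") = cnt);
}
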