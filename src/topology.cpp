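#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Voxel lattice helpers. Volumes arrive as logical vectors in R's
// column-major layout with dims (nx, ny, nz); linear index
// l = x + nx*(y + ny*z) with 0-based x, y, z.

static inline bool in_bounds(int x, int y, int z, const int *d) {
  return x >= 0 && y >= 0 && z >= 0 && x < d[0] && y < d[1] && z < d[2];
}
static inline int lin(int x, int y, int z, const int *d) {
  return x + d[0] * (y + d[1] * z);
}

// j-adjacency predicate on an offset (dx,dy,dz) != (0,0,0):
//   6: |dx|+|dy|+|dz| == 1 (faces)
//  18: Chebyshev == 1 and L1 <= 2 (faces + edges)
//  26: Chebyshev == 1 (faces + edges + corners)
static inline bool offset_adjacent(int dx, int dy, int dz, int j) {
  int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
  int ch = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
  if (ch != 1) return false;
  if (j == 6) return l1 == 1;
  if (j == 18) return l1 <= 2;
  return true; // 26
}

// ---- connected-component labelling ------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vol, IntegerVector dims,
                                   int connectivity) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t n = vol.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int l0 = lin(x, y, z, d);
        if (!vol[l0] || lab[l0]) continue;
        lab[l0] = ++next;
        stack.clear();
        stack.push_back(l0);
        while (!stack.empty()) {
          int l = stack.back();
          stack.pop_back();
          int cx = l % d[0], cy = (l / d[0]) % d[1], cz = l / (d[0] * d[1]);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!offset_adjacent(dx, dy, dz, connectivity)) continue;
                int nx = cx + dx, ny = cy + dy, nz = cz + dz;
                if (!in_bounds(nx, ny, nz, d)) continue;
                int ln = lin(nx, ny, nz, d);
                if (vol[ln] && !lab[ln]) {
                  lab[ln] = next;
                  stack.push_back(ln);
                }
              }
        }
      }
  return lab;
}

// ---- simple-point test -------------------------------------------------

// nb: 27 occupancy flags of the 3x3x3 neighbourhood, offset (dx,dy,dz)
// stored at (dx+1) + 3*(dy+1) + 9*(dz+1); centre at 13.
//
// A black centre point is simple iff
//  (a) the black points of N26 form exactly one 26-connected component, and
//  (b) the white points of N18 form exactly one 6-connected component
//      (6-paths restricted to N18) that is 6-adjacent to the centre.
static bool simple_from_neighbourhood(const char *nb) {
  static int ox[27], oy[27], oz[27];
  static bool init = false;
  if (!init) {
    for (int o = 0; o < 27; ++o) {
      ox[o] = o % 3 - 1;
      oy[o] = (o / 3) % 3 - 1;
      oz[o] = o / 9 - 1;
    }
    init = true;
  }
  // (a) 26-components of black in N26
  char seen[27] = {0};
  int black_comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++black_comp;
    if (black_comp > 1) return false;
    std::vector<int> st(1, s);
    seen[s] = 1;
    while (!st.empty()) {
      int c = st.back();
      st.pop_back();
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || seen[t]) continue;
        if (offset_adjacent(ox[t] - ox[c], oy[t] - oy[c], oz[t] - oz[c], 26)) {
          seen[t] = 1;
          st.push_back(t);
        }
      }
    }
  }
  if (black_comp != 1) return false;
  // (b) 6-components of white in N18 that touch a face neighbour
  char seenw[27] = {0};
  int good_white = 0;
  for (int s = 0; s < 27; ++s) {
    int l1 = std::abs(ox[s]) + std::abs(oy[s]) + std::abs(oz[s]);
    if (s == 13 || l1 > 2 || nb[s] || seenw[s]) continue;
    bool touches = (l1 == 1);
    std::vector<int> st(1, s);
    seenw[s] = 1;
    while (!st.empty()) {
      int c = st.back();
      st.pop_back();
      for (int t = 0; t < 27; ++t) {
        int l1t = std::abs(ox[t]) + std::abs(oy[t]) + std::abs(oz[t]);
        if (t == 13 || l1t > 2 || nb[t] || seenw[t]) continue;
        if (offset_adjacent(ox[t] - ox[c], oy[t] - oy[c], oz[t] - oz[c], 6)) {
          if (l1t == 1) touches = true;
          seenw[t] = 1;
          st.push_back(t);
        }
      }
    }
    if (touches) ++good_white;
    if (good_white > 1) return false;
  }
  return good_white == 1;
}

static void extract_neighbourhood(const LogicalVector &vol, const int *d,
                                  int x, int y, int z, char *nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int nx = x + dx, ny = y + dy, nz = z + dz;
        nb[o] = in_bounds(nx, ny, nz, d) ? (char)(vol[lin(nx, ny, nz, d)] != 0)
                                         : (char)0;
      }
}

// [[Rcpp::export]]
bool cpp_is_simple(LogicalVector vol, IntegerVector dims, int x, int y, int z) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  char nb[27];
  extract_neighbourhood(vol, d, x, y, z, nb);
  return simple_from_neighbourhood(nb);
}

// [[Rcpp::export]]
bool cpp_is_simple_config(LogicalVector nb27) {
  char nb[27];
  for (int i = 0; i < 27; ++i) nb[i] = (char)(nb27[i] != 0);
  return simple_from_neighbourhood(nb);
}

static int count_black_26(const LogicalVector &vol, const int *d, int x, int y,
                          int z) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nx = x + dx, ny = y + dy, nz = z + dz;
        if (in_bounds(nx, ny, nz, d) && vol[lin(nx, ny, nz, d)]) ++c;
      }
  return c;
}

// ---- 6-subiteration sequential curve thinning --------------------------

// Direction order U, D, N, S, E, W (U = +z, N = +y, E = +x). In each
// subiteration the border points for that direction (direction neighbour
// white) that are simple and not curve endpoints (more than one black
// 26-neighbour) are deleted sequentially, re-checking simplicity at
// deletion time. The six subiterations are cycled until a full cycle
// deletes nothing.

// [[Rcpp::export]]
LogicalVector cpp_curve_thin(LogicalVector vol, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  LogicalVector out = clone(vol);
  const int DX[6] = {0, 0, 0, 0, 1, -1};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DZ[6] = {1, -1, 0, 0, 0, 0};
  char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<int> cand;
      for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
          for (int x = 0; x < d[0]; ++x) {
            int l = lin(x, y, z, d);
            if (!out[l]) continue;
            int bx = x + DX[dir], by = y + DY[dir], bz = z + DZ[dir];
            bool border =
                !in_bounds(bx, by, bz, d) || !out[lin(bx, by, bz, d)];
            if (!border) continue;
            if (count_black_26(out, d, x, y, z) <= 1) continue; // endpoint
            extract_neighbourhood(out, d, x, y, z, nb);
            if (simple_from_neighbourhood(nb)) cand.push_back(l);
          }
      for (size_t i = 0; i < cand.size(); ++i) {
        int l = cand[i];
        int x = l % d[0], y = (l / d[0]) % d[1], z = l / (d[0] * d[1]);
        if (!out[l]) continue;
        int bx = x + DX[dir], by = y + DY[dir], bz = z + DZ[dir];
        bool border = !in_bounds(bx, by, bz, d) || !out[lin(bx, by, bz, d)];
        if (!border) continue;
        if (count_black_26(out, d, x, y, z) <= 1) continue;
        extract_neighbourhood(out, d, x, y, z, nb);
        if (!simple_from_neighbourhood(nb)) continue;
        out[l] = FALSE;
        changed = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(LogicalVector vol, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  IntegerVector cnt(vol.size(), 0);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int l = lin(x, y, z, d);
        if (vol[l]) cnt[l] = count_black_26(vol, d, x, y, z);
      }
  return cnt;
}
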