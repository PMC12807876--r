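#include <Rcpp.h>
#include <array>
#include <queue>
#include <vector>
using namespace Rcpp;

// Voxel grids arrive as R arrays (column-major). Dim order within the package
// is (z, y, x) for volumes; 2-D images pass a trailing singleton.

static std::vector<std::array<int, 3> > neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3> > off;
  for (int d1 = -1; d1 <= 1; ++d1)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d3 = -1; d3 <= 1; ++d3) {
        if (d1 == 0 && d2 == 0 && d3 == 0) continue;
        int manhattan = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (connectivity == 6 && manhattan > 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        std::array<int, 3> a = {{d1, d2, d3}};
        off.push_back(a);
      }
  return off;
}

static void get_dims(SEXP x, int &n1, int &n2, int &n3) {
  RObject obj(x);
  if (obj.hasAttribute("dim")) {
    IntegerVector d = obj.attr("dim");
    n1 = d[0];
    n2 = d.size() > 1 ? d[1] : 1;
    n3 = d.size() > 2 ? d[2] : 1;
  } else {
    stop("input must be an array");
  }
}

// Connected-component labelling of a binary volume (6/18/26-connected).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  int n1, n2, n3;
  get_dims(mask, n1, n2, n3);
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(n, 0);
  labels.attr("dim") = mask.attr("dim");
  std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i3 = cur / ((R_xlen_t)n1 * n2);
      int rem = cur - (R_xlen_t)i3 * n1 * n2;
      int i2 = rem / n1;
      int i1 = rem - i2 * n1;
      for (size_t k = 0; k < off.size(); ++k) {
        int j1 = i1 + off[k][0], j2 = i2 + off[k][1], j3 = i3 + off[k][2];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t j = (R_xlen_t)j3 * n1 * n2 + (R_xlen_t)j2 * n1 + j1;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

struct WsNode {
  double value;   // flood altitude (negated intensity)
  long order;     // FIFO tie-break
  R_xlen_t index;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value > b.value;  // lowest altitude first
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding. The topographic surface
// is the negated intensity, so flooding proceeds from bright seed voxels
// outward/downhill, constrained to `mask`.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector intensity, IntegerVector markers,
                            LogicalVector mask, int connectivity) {
  int n1, n2, n3;
  get_dims(intensity, n1, n2, n3);
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(n, 0);
  labels.attr("dim") = intensity.attr("dim");
  std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (markers[s] > 0 && mask[s]) {
      labels[s] = markers[s];
      WsNode nd = {-intensity[s], counter++, s};
      pq.push(nd);
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t cur = nd.index;
    int lab = labels[cur];
    int i3 = cur / ((R_xlen_t)n1 * n2);
    int rem = cur - (R_xlen_t)i3 * n1 * n2;
    int i2 = rem / n1;
    int i1 = rem - i2 * n1;
    for (size_t k = 0; k < off.size(); ++k) {
      int j1 = i1 + off[k][0], j2 = i2 + off[k][1], j3 = i3 + off[k][2];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
        continue;
      R_xlen_t j = (R_xlen_t)j3 * n1 * n2 + (R_xlen_t)j2 * n1 + j1;
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = lab;
      WsNode nx = {-intensity[j], counter++, j};
      pq.push(nx);
    }
  }
  return labels;
}

static inline int nb8(const std::vector<int> &img, int nr, int nc, int r,
                      int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
  return img[(R_xlen_t)c * nr + r];
}

// Zhang–Suen morphological thinning of a 2-D binary image to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  int nr = input.nrow(), nc = input.ncol();
  std::vector<int> img((R_xlen_t)nr * nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) img[i] = input[i] ? 1 : 0;
  bool changed = true;
  std::vector<R_xlen_t> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img[(R_xlen_t)c * nr + r]) continue;
          // clockwise neighbours P2..P9 starting north
          int p2 = nb8(img, nr, nc, r - 1, c), p3 = nb8(img, nr, nc, r - 1, c + 1),
              p4 = nb8(img, nr, nc, r, c + 1), p5 = nb8(img, nr, nc, r + 1, c + 1),
              p6 = nb8(img, nr, nc, r + 1, c), p7 = nb8(img, nr, nc, r + 1, c - 1),
              p8 = nb8(img, nr, nc, r, c - 1), p9 = nb8(img, nr, nc, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((R_xlen_t)c * nr + r);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) out[i] = img[i] != 0;
  return out;
}

static void run_filter_cols(const std::vector<double> &in,
                            std::vector<double> &out, int nr, int nc, int radius,
                            bool maximum) {
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lo = std::max(0, r - radius), hi = std::min(nr - 1, r + radius);
      double v = in[(R_xlen_t)c * nr + lo];
      for (int k = lo + 1; k <= hi; ++k) {
        double x = in[(R_xlen_t)c * nr + k];
        if (maximum ? (x > v) : (x < v)) v = x;
      }
      out[(R_xlen_t)c * nr + r] = v;
    }
  }
}

// Separable rectangular min/max filter (window 2*radius+1, truncated at
// borders). Erosion/dilation building block for the rolling-ball background.
// [[Rcpp::export]]
NumericMatrix cpp_rect_filter(NumericMatrix x, int radius, bool maximum) {
  int nr = x.nrow(), nc = x.ncol();
  std::vector<double> a((R_xlen_t)nr * nc), b((R_xlen_t)nr * nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) a[i] = x[i];
  run_filter_cols(a, b, nr, nc, radius, maximum);
  // transpose, filter rows, transpose back
  std::vector<double> bt((R_xlen_t)nr * nc), ct((R_xlen_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) bt[(R_xlen_t)r * nc + c] = b[(R_xlen_t)c * nr + r];
  run_filter_cols(bt, ct, nc, nr, radius, maximum);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = ct[(R_xlen_t)r * nc + c];
  return out;
}

// A pixel is "simple" (removable without changing topology) iff its 8-
// neighbourhood foreground forms one 8-connected component touching it and
// its 4-adjacent background forms one 4-connected component within the
// neighbourhood. Sequentially removing simple pixels with >= 2 neighbours
// minimizes the skeleton: staircase corners left by thinning disappear, so
// junction pixels are exactly those whose arms are genuinely distinct.
static bool is_simple_px(const std::vector<int> &img, int nr, int nc, int r,
                         int c) {
  int fg[8], n_fg = 0;
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int k = 0; k < 8; ++k) {
    int rr = r + dy[k], cc = c + dx[k];
    fg[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc)
                ? img[(R_xlen_t)cc * nr + rr]
                : 0;
    if (fg[k]) ++n_fg;
  }
  if (n_fg < 2) return false;
  // count 8-connected components among fg neighbours
  bool seen[8] = {false};
  int comps = 0;
  for (int k = 0; k < 8; ++k) {
    if (!fg[k] || seen[k]) continue;
    ++comps;
    // BFS within the 8 neighbours using adjacency of their offsets
    int stack[8], sp = 0;
    stack[sp++] = k;
    seen[k] = true;
    while (sp) {
      int a = stack[--sp];
      for (int b = 0; b < 8; ++b) {
        if (!fg[b] || seen[b]) continue;
        if (std::abs(dy[a] - dy[b]) <= 1 && std::abs(dx[a] - dx[b]) <= 1) {
          seen[b] = true;
          stack[sp++] = b;
        }
      }
    }
  }
  if (comps != 1) return false;
  // 4-adjacent background components (4-connected within the neighbourhood)
  const int four[4] = {1, 3, 4, 6};  // N, W, E, S indices in the offset list
  int bg4 = 0;
  for (int k = 0; k < 4; ++k)
    if (!fg[four[k]]) ++bg4;
  if (bg4 == 0) return false;
  // among the 4-neighbours, check 4-connectivity through the diagonals
  // components of {N,W,E,S background} linked via bg diagonal between them
  int comp_id[4] = {-1, -1, -1, -1};
  int ncomp = 0;
  // diagonal k sits between two 4-neighbours:
  // NW(0): N(1) & W(3); NE(2): N(1) & E(4); SW(5): S(6) & W(3); SE(7): S(6) & E(4)
  const int diag[4][3] = {{0, 0, 1}, {2, 0, 2}, {5, 3, 1}, {7, 3, 2}};
  // map: four[] order is N=0 (idx1), W=1 (idx3), E=2 (idx4), S=3 (idx6)
  for (int k = 0; k < 4; ++k)
    if (!fg[four[k]]) comp_id[k] = ncomp++;
  for (int d = 0; d < 4; ++d) {
    int dk = diag[d][0], a = diag[d][1], b = diag[d][2];
    if (fg[dk]) continue;
    if (fg[four[a]] || fg[four[b]]) continue;
    int ca = comp_id[a], cb = comp_id[b];
    if (ca == cb) continue;
    for (int k = 0; k < 4; ++k)
      if (comp_id[k] == cb) comp_id[k] = ca;
  }
  bool used[4] = {false};
  int nbg = 0;
  for (int k = 0; k < 4; ++k) {
    if (fg[four[k]]) continue;
    int id = comp_id[k];
    bool dup = false;
    for (int j = 0; j < k; ++j)
      if (!fg[four[j]] && comp_id[j] == id) dup = true;
    if (!dup) ++nbg;
  }
  (void)used;
  return nbg == 1;
}

// [[Rcpp::export]]
LogicalMatrix cpp_skel_minimize(LogicalMatrix input) {
  int nr = input.nrow(), nc = input.ncol();
  std::vector<int> img((R_xlen_t)nr * nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) img[i] = input[i] ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (!img[(R_xlen_t)c * nr + r]) continue;
        if (is_simple_px(img, nr, nc, r, c)) {
          img[(R_xlen_t)c * nr + r] = 0;
          changed = true;
        }
      }
  }
  LogicalMatrix out(nr, nc);
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i) out[i] = img[i] != 0;
  return out;
}
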