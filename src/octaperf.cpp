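#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a logical matrix with 4- or
// 8-connectivity. Labels are assigned in column-major scan order starting at
// 1; background (FALSE) stays 0. Iterative flood fill with an explicit stack.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nnb = connectivity;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int rr = cr + dr[k], ccn = cc2 + dc[k];
          if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
          if (mask(rr, ccn) && lab(rr, ccn) == 0) {
            lab(rr, ccn) = next;
            stack.push_back(rr + ccn * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Bridson Poisson-disc sampling on the continuous domain [1, size] x
// [1, size] with minimum point distance r. Uses R's RNG so results are
// reproducible under set.seed(). Returns an n x 2 matrix (row, col).
// [[Rcpp::export(name = ".poisson_disc")]]
NumericMatrix poisson_disc(double size, double r, int k) {
  const double lo = 1.0, hi = size;
  const double cell = r / std::sqrt(2.0);
  const int g = std::max(1, (int)std::ceil((hi - lo) / cell));
  std::vector<int> grid((size_t)g * g, -1);
  std::vector<double> pr, pc;
  std::vector<int> active;
  pr.reserve(1024); pc.reserve(1024);
  auto gidx = [&](double x) {
    int i = (int)std::floor((x - lo) / cell);
    if (i < 0) i = 0;
    if (i >= g) i = g - 1;
    return i;
  };
  auto ok = [&](double x, double y) {
    const int gi = gidx(x), gj = gidx(y);
    for (int i = std::max(0, gi - 2); i <= std::min(g - 1, gi + 2); ++i)
      for (int j = std::max(0, gj - 2); j <= std::min(g - 1, gj + 2); ++j) {
        const int q = grid[(size_t)i * g + j];
        if (q >= 0) {
          const double dx = pr[q] - x, dy = pc[q] - y;
          if (dx * dx + dy * dy < r * r) return false;
        }
      }
    return true;
  };
  auto push = [&](double x, double y) {
    pr.push_back(x); pc.push_back(y);
    grid[(size_t)gidx(x) * g + gidx(y)] = (int)pr.size() - 1;
    active.push_back((int)pr.size() - 1);
  };
  push(lo + unif_rand() * (hi - lo), lo + unif_rand() * (hi - lo));
  while (!active.empty()) {
    const int ai = (int)std::floor(unif_rand() * active.size());
    const int p = active[std::min(ai, (int)active.size() - 1)];
    bool found = false;
    for (int t = 0; t < k; ++t) {
      const double rad = r * (1.0 + unif_rand());
      const double ang = 2.0 * M_PI * unif_rand();
      const double x = pr[p] + rad * std::cos(ang);
      const double y = pc[p] + rad * std::sin(ang);
      if (x < lo || x > hi || y < lo || y > hi) continue;
      if (ok(x, y)) { push(x, y); found = true; break; }
    }
    if (!found)
      active.erase(active.begin() + std::min(ai, (int)active.size() - 1));
  }
  const int n = (int)pr.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = pr[i]; out(i, 1) = pc[i]; }
  return out;
}

// Gabriel-graph edges among 2D points, restricted to pairs closer than
// max_len: (i, j) is an edge iff the open disc with diameter ij contains no
// other point. Returns an E x 2 matrix of 1-based node indices.
// [[Rcpp::export(name = ".gabriel_edges")]]
IntegerMatrix gabriel_edges(const NumericMatrix& pts, double max_len) {
  const int n = pts.nrow();
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 > max_len * max_len) continue;
      const double mx = 0.5 * (pts(i, 0) + pts(j, 0));
      const double my = 0.5 * (pts(i, 1) + pts(j, 1));
      const double rad2 = 0.25 * d2;
      bool empty = true;
      for (int q = 0; q < n && empty; ++q) {
        if (q == i || q == j) continue;
        const double qx = pts(q, 0) - mx, qy = pts(q, 1) - my;
        if (qx * qx + qy * qy < rad2) empty = false;
      }
      if (empty) { ei.push_back(i + 1); ej.push_back(j + 1); }
    }
  }
  IntegerMatrix out((int)ei.size(), 2);
  for (size_t e = 0; e < ei.size(); ++e) {
    out((int)e, 0) = ei[e];
    out((int)e, 1) = ej[e];
  }
  return out;
}

static inline double point_segment_dist2(double pr, double pc, double r0,
                                         double c0, double r1, double c1) {
  const double vr = r1 - r0, vc = c1 - c0;
  const double len2 = vr * vr + vc * vc;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((pr - r0) * vr + (pc - c0) * vc) / len2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  const double dr = pr - (r0 + t * vr), dc = pc - (c0 + t * vc);
  return dr * dr + dc * dc;
}

// Minimum distance from every pixel centre (1-based integer coordinates)
// to any of a set of line segments, evaluated only within `cap` of each
// segment's bounding box; pixels further than `cap` from all segments get
// R_PosInf. Used to rasterise vessel centrelines with a Gaussian profile.
// [[Rcpp::export(name = ".segment_distance_field")]]
NumericMatrix segment_distance_field(int nrow, int ncol, NumericVector r0,
                                     NumericVector c0, NumericVector r1,
                                     NumericVector c1, double cap) {
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), R_PosInf);
  const int ne = r0.size();
  for (int e = 0; e < ne; ++e) {
    const int rlo = std::max(1, (int)std::floor(std::min(r0[e], r1[e]) - cap));
    const int rhi = std::min(nrow, (int)std::ceil(std::max(r0[e], r1[e]) + cap));
    const int clo = std::max(1, (int)std::floor(std::min(c0[e], c1[e]) - cap));
    const int chi = std::min(ncol, (int)std::ceil(std::max(c0[e], c1[e]) + cap));
    for (int c = clo; c <= chi; ++c) {
      for (int r = rlo; r <= rhi; ++r) {
        const double d2 =
            point_segment_dist2((double)r, (double)c, r0[e], c0[e], r1[e], c1[e]);
        const double d = std::sqrt(d2);
        if (d < out(r - 1, c - 1)) out(r - 1, c - 1) = d;
      }
    }
  }
  return out;
}
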