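// Voronoi cells by per-seed half-space intersection.
//
// Each cell is built independently: start from a far axis-aligned bounding
// box, clip by bisector half-spaces towards other seeds in order of
// increasing distance, and stop once the security radius guarantees no
// further seed can cut the cell (a seed j with d(i,j) > 2 * max vertex
// distance cannot contribute). Clipping is incremental: a plane that does
// not cut the current cell is skipped in O(V), and a cutting plane only
// spawns vertices involving itself; planes that lose all vertex contact are
// pruned (the cell only shrinks, so they can never regain contact).
// Measures follow from the ordered polygon (2D, shoelace) or the facet
// decomposition about the seed (3D, pyramid volumes).
//
// A cell still touching the box is rebuilt with a larger box (margins 10x,
// 100x, 1000x, 100000x the seed extent); one that touches the largest box is
// reported unbounded (edge region). Interior seeds can own cells whose
// vertices lie far outside the data extent (circumcentres of sliver
// simplices), which is why a fixed margin will not do. Tolerances scale
// with each vertex's distance from the seed so that far boxes do not
// degrade near geometry.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

const double EPS_SUPP = 1e-8;   // plane-contact / feasibility slack
const double EPS_MERGE = 1e-8;  // duplicate-vertex merge radius
const double EPS_FACET = 1e-7;  // minimum facet extent for adjacency

struct Plane {
  double n[3];   // unit outward normal, constraint n . x <= c
  double c;
  int owner;     // >= 0: index of the opposing seed; -1: bounding-box side
};

inline double dotd(const double *a, const double *b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * b[k];
  return s;
}

bool solve_pair(const Plane &A, const Plane &B, double *out) {
  double det = A.n[0] * B.n[1] - A.n[1] * B.n[0];
  if (std::fabs(det) < 1e-12) return false;
  out[0] = (A.c * B.n[1] - B.c * A.n[1]) / det;
  out[1] = (A.n[0] * B.c - B.n[0] * A.c) / det;
  return true;
}

inline double det3(const double m[3][3]) {
  return m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1])
       - m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0])
       + m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
}

bool solve_triple(const Plane &A, const Plane &B, const Plane &C, double *out) {
  double m[3][3] = {{A.n[0], A.n[1], A.n[2]},
                    {B.n[0], B.n[1], B.n[2]},
                    {C.n[0], C.n[1], C.n[2]}};
  double det = det3(m);
  if (std::fabs(det) < 1e-10) return false;
  double rhs[3] = {A.c, B.c, C.c};
  for (int col = 0; col < 3; ++col) {
    double t[3][3];
    for (int r = 0; r < 3; ++r)
      for (int cc = 0; cc < 3; ++cc)
        t[r][cc] = (cc == col) ? rhs[r] : m[r][cc];
    out[col] = det3(t) / det;
  }
  return true;
}

struct CellResult {
  bool bounded;
  double measure;
  std::vector<int> neighbors;                // 0-based seed indices
  std::vector<std::array<double, 3>> verts;  // ordered polygon in 2D
};

// Order 2D points by angle around their centroid (in place), return area.
double order_and_area_2d(std::vector<std::array<double, 3>> &v) {
  size_t m = v.size();
  if (m < 3) return 0.0;
  double cx = 0, cy = 0;
  for (auto &p : v) { cx += p[0]; cy += p[1]; }
  cx /= m; cy /= m;
  std::sort(v.begin(), v.end(), [&](const std::array<double, 3> &a,
                                    const std::array<double, 3> &b) {
    return std::atan2(a[1] - cy, a[0] - cx) < std::atan2(b[1] - cy, b[0] - cx);
  });
  double area = 0.0;
  for (size_t k = 0; k < m; ++k) {
    size_t k2 = (k + 1) % m;
    area += v[k][0] * v[k2][1] - v[k2][0] * v[k][1];
  }
  return std::fabs(area) / 2.0;
}

// Area of the (convex) facet of plane p supported by verts[idx].
double facet_area_3d(const Plane &p,
                     const std::vector<std::array<double, 3>> &verts,
                     const std::vector<int> &idx) {
  size_t m = idx.size();
  if (m < 3) return 0.0;
  int kmin = 0;  // in-plane orthonormal basis
  for (int k = 1; k < 3; ++k)
    if (std::fabs(p.n[k]) < std::fabs(p.n[kmin])) kmin = k;
  double u[3] = {0, 0, 0};
  u[kmin] = 1.0;
  double nu = dotd(u, p.n, 3);
  for (int k = 0; k < 3; ++k) u[k] -= nu * p.n[k];
  double ul = std::sqrt(dotd(u, u, 3));
  for (int k = 0; k < 3; ++k) u[k] /= ul;
  double w[3] = {p.n[1] * u[2] - p.n[2] * u[1],
                 p.n[2] * u[0] - p.n[0] * u[2],
                 p.n[0] * u[1] - p.n[1] * u[0]};
  double c0 = 0, c1 = 0;
  std::vector<std::pair<double, std::pair<double, double>>> proj;
  proj.reserve(m);
  for (int id : idx) {
    const auto &v = verts[id];
    double a = dotd(v.data(), u, 3), b = dotd(v.data(), w, 3);
    proj.push_back({0.0, {a, b}});
    c0 += a; c1 += b;
  }
  c0 /= m; c1 /= m;
  for (auto &pr : proj)
    pr.first = std::atan2(pr.second.second - c1, pr.second.first - c0);
  std::sort(proj.begin(), proj.end(),
            [](const auto &a, const auto &b) { return a.first < b.first; });
  double area = 0.0;
  for (size_t k = 0; k < m; ++k) {
    size_t k2 = (k + 1) % m;
    area += proj[k].second.first * proj[k2].second.second
          - proj[k2].second.first * proj[k].second.second;
  }
  return std::fabs(area) / 2.0;
}

void build_cell(int i, const NumericMatrix &pts, int d, double span,
                const double *box_lo, const double *box_hi, CellResult &res) {
  const int n = pts.nrow();
  double pi_[3] = {0, 0, 0};
  for (int k = 0; k < d; ++k) pi_[k] = pts(i, k);

  // tolerance local to a vertex: relative to its distance from the seed,
  // floored at the data span
  auto tol_at = [&](const double *v, double eps) {
    double s = 0;
    for (int k = 0; k < d; ++k) s += (v[k] - pi_[k]) * (v[k] - pi_[k]);
    return eps * (span + std::sqrt(s));
  };

  std::vector<double> d2(n);
  std::vector<int> ord;
  ord.reserve(n - 1);
  for (int j = 0; j < n; ++j) {
    if (j == i) { d2[j] = 0; continue; }
    double s = 0;
    for (int k = 0; k < d; ++k) {
      double diff = pts(j, k) - pi_[k];
      s += diff * diff;
    }
    d2[j] = s;
    ord.push_back(j);
  }
  auto cmp = [&](int a, int b) { return d2[a] < d2[b]; };

  std::vector<Plane> planes;
  std::vector<std::array<double, 3>> verts;
  for (int k = 0; k < d; ++k) {
    Plane ph; ph.n[0] = ph.n[1] = ph.n[2] = 0;
    ph.n[k] = 1.0; ph.c = box_hi[k]; ph.owner = -1;
    planes.push_back(ph);
    Plane pl; pl.n[0] = pl.n[1] = pl.n[2] = 0;
    pl.n[k] = -1.0; pl.c = -box_lo[k]; pl.owner = -1;
    planes.push_back(pl);
  }
  for (int mask = 0; mask < (1 << d); ++mask) {
    std::array<double, 3> v = {0, 0, 0};
    for (int k = 0; k < d; ++k)
      v[k] = (mask & (1 << k)) ? box_hi[k] : box_lo[k];
    verts.push_back(v);
  }
  double rmax2 = 0;
  auto update_rmax = [&]() {
    rmax2 = 0;
    for (const auto &v : verts) {
      double s = 0;
      for (int k = 0; k < d; ++k) s += (v[k] - pi_[k]) * (v[k] - pi_[k]);
      if (s > rmax2) rmax2 = s;
    }
  };
  update_rmax();

  const int ncand = (int)ord.size();
  int sorted_upto = 0;
  std::vector<double> viol;
  for (int t = 0; t < ncand; ++t) {
    if (t >= sorted_upto) {  // sort candidates lazily, in doubling chunks
      int upto = std::min(ncand, std::max(2 * sorted_upto, 32));
      if (upto < ncand)
        std::nth_element(ord.begin() + sorted_upto, ord.begin() + upto,
                         ord.end(), cmp);
      std::sort(ord.begin() + sorted_upto, ord.begin() + upto, cmp);
      sorted_upto = upto;
    }
    int j = ord[t];
    if (d2[j] > 4.0 * rmax2) break;  // security radius

    Plane p;
    {
      double nv[3] = {0, 0, 0};
      for (int k = 0; k < d; ++k) nv[k] = pts(j, k) - pi_[k];
      double len = std::sqrt(dotd(nv, nv, d));
      for (int k = 0; k < 3; ++k) p.n[k] = (k < d) ? nv[k] / len : 0.0;
      double mid[3];
      for (int k = 0; k < d; ++k) mid[k] = (pts(j, k) + pi_[k]) / 2.0;
      p.c = dotd(p.n, mid, d);
      p.owner = j;
    }
    viol.assign(verts.size(), 0.0);
    bool cuts = false;
    for (size_t vi = 0; vi < verts.size(); ++vi) {
      viol[vi] = dotd(p.n, verts[vi].data(), d) - p.c;
      if (viol[vi] > tol_at(verts[vi].data(), EPS_SUPP)) cuts = true;
    }
    if (!cuts) continue;

    // keep feasible old vertices, add intersections involving the new plane
    std::vector<std::array<double, 3>> nv;
    for (size_t vi = 0; vi < verts.size(); ++vi)
      if (viol[vi] <= tol_at(verts[vi].data(), EPS_SUPP))
        nv.push_back(verts[vi]);
    const int np = (int)planes.size();
    double pt[3] = {0, 0, 0};
    auto feasible = [&](const double *x) {
      double tol = tol_at(x, EPS_SUPP);
      if (dotd(p.n, x, d) > p.c + tol) return false;
      for (int q = 0; q < np; ++q)
        if (dotd(planes[q].n, x, d) > planes[q].c + tol) return false;
      return true;
    };
    if (d == 2) {
      for (int a = 0; a < np; ++a) {
        if (!solve_pair(p, planes[a], pt)) continue;
        if (feasible(pt)) nv.push_back({pt[0], pt[1], 0.0});
      }
    } else {
      for (int a = 0; a < np; ++a)
        for (int b = a + 1; b < np; ++b) {
          if (!solve_triple(p, planes[a], planes[b], pt)) continue;
          if (feasible(pt)) nv.push_back({pt[0], pt[1], pt[2]});
        }
    }
    verts.clear();
    for (const auto &v : nv) {  // merge duplicates
      double mt = tol_at(v.data(), EPS_MERGE);
      bool dup = false;
      for (const auto &u : verts) {
        double s = 0;
        for (int k = 0; k < d; ++k) s += (v[k] - u[k]) * (v[k] - u[k]);
        if (s < mt * mt) { dup = true; break; }
      }
      if (!dup) verts.push_back(v);
    }
    planes.push_back(p);
    std::vector<Plane> kept;  // prune planes with no remaining contact
    for (const auto &q : planes) {
      bool touch = false;
      for (const auto &v : verts)
        if (std::fabs(dotd(q.n, v.data(), d) - q.c) <=
            tol_at(v.data(), EPS_SUPP)) {
          touch = true;
          break;
        }
      if (touch) kept.push_back(q);
    }
    planes.swap(kept);
    update_rmax();
  }

  // remaining planes all touch the cell; support sets for facet tests
  const int np = (int)planes.size();
  std::vector<std::vector<int>> support(np);
  bool touches_box = false;
  for (size_t vi = 0; vi < verts.size(); ++vi) {
    for (int q = 0; q < np; ++q) {
      double r = dotd(planes[q].n, verts[vi].data(), d) - planes[q].c;
      if (std::fabs(r) <= tol_at(verts[vi].data(), EPS_SUPP)) {
        support[q].push_back((int)vi);
        if (planes[q].owner < 0) touches_box = true;
      }
    }
  }
  res.bounded = !touches_box;
  res.neighbors.clear();

  if (d == 2) {
    for (int q = 0; q < np; ++q) {
      if (planes[q].owner < 0 || support[q].size() < 2) continue;
      double ext = 0, dmin2 = R_PosInf;
      for (size_t a = 0; a < support[q].size(); ++a) {
        const auto &va = verts[support[q][a]];
        double ds = 0;
        for (int k = 0; k < 2; ++k) ds += (va[k] - pi_[k]) * (va[k] - pi_[k]);
        dmin2 = std::min(dmin2, ds);
        for (size_t b = a + 1; b < support[q].size(); ++b) {
          const auto &vb = verts[support[q][b]];
          double s = (va[0] - vb[0]) * (va[0] - vb[0])
                   + (va[1] - vb[1]) * (va[1] - vb[1]);
          if (s > ext) ext = s;
        }
      }
      double fmin = EPS_FACET * (span + std::sqrt(dmin2));
      if (ext > fmin * fmin) res.neighbors.push_back(planes[q].owner);
    }
    res.measure = order_and_area_2d(verts);  // box-clipped if unbounded
    res.verts = verts;
  } else {
    double vol = 0;
    for (int q = 0; q < np; ++q) {
      if (support[q].size() < 3) continue;
      double area = facet_area_3d(planes[q], verts, support[q]);
      double dmin2 = R_PosInf;
      for (int id : support[q]) {
        double ds = 0;
        for (int k = 0; k < 3; ++k)
          ds += (verts[id][k] - pi_[k]) * (verts[id][k] - pi_[k]);
        dmin2 = std::min(dmin2, ds);
      }
      double fmin = EPS_FACET * (span + std::sqrt(dmin2));
      if (area <= fmin * fmin) continue;
      if (planes[q].owner >= 0) res.neighbors.push_back(planes[q].owner);
      double h = planes[q].c - dotd(planes[q].n, pi_, 3);
      vol += area * h / 3.0;
    }
    res.measure = vol;
    res.verts = verts;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_voronoi(NumericMatrix pts, double margin_factor = 10.0,
                 bool return_vertices = true) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  if (d != 2 && d != 3) stop("coordinates must be 2D or 3D");
  if (n < d + 2) stop("need at least d + 2 seeds");

  double lo[3], hi[3];
  for (int k = 0; k < d; ++k) {
    lo[k] = R_PosInf; hi[k] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo[k] = std::min(lo[k], pts(i, k));
      hi[k] = std::max(hi[k], pts(i, k));
    }
  }
  double span = 0;
  for (int k = 0; k < d; ++k) span = std::max(span, hi[k] - lo[k]);
  if (span <= 0) stop("degenerate seed set: zero spatial extent");

  NumericVector measure(n);
  LogicalVector bounded(n);
  List neighbors(n);
  List polys(return_vertices ? n : 0);

  std::vector<double> margins = {margin_factor, 100.0 * margin_factor,
                                 1000.0 * margin_factor,
                                 100000.0 * margin_factor};
  std::vector<int> todo(n);
  for (int i = 0; i < n; ++i) todo[i] = i;

  CellResult res;
  for (size_t stage = 0; stage < margins.size() && !todo.empty(); ++stage) {
    double box_lo[3], box_hi[3];
    for (int k = 0; k < d; ++k) {
      box_lo[k] = lo[k] - margins[stage] * span;
      box_hi[k] = hi[k] + margins[stage] * span;
    }
    std::vector<int> still;
    for (int i : todo) {
      build_cell(i, pts, d, span, box_lo, box_hi, res);
      bounded[i] = res.bounded;
      measure[i] = res.bounded ? res.measure : NA_REAL;
      IntegerVector nb(res.neighbors.size());
      for (size_t k = 0; k < res.neighbors.size(); ++k)
        nb[k] = res.neighbors[k] + 1;  // 1-based
      neighbors[i] = nb;
      if (return_vertices) {
        NumericMatrix vm(res.verts.size(), d);
        for (size_t r = 0; r < res.verts.size(); ++r)
          for (int k = 0; k < d; ++k) vm(r, k) = res.verts[r][k];
        polys[i] = vm;
      }
      if (!res.bounded && stage + 1 < margins.size()) still.push_back(i);
    }
    todo.swap(still);
  }

  return List::create(_["measure"] = measure, _["bounded"] = bounded,
                      _["neighbors"] = neighbors,
                      _["vertices"] = return_vertices ? (SEXP)polys : R_NilValue);
}
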