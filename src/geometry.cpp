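#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p.  Ericson, Real-Time Collision
// Detection, ch. 5.1.5 — region classification via barycentric signs.
static inline void closestPointTriangle(const double *p,
                                        const double *a, const double *b,
                                        const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Exact closest point on a triangle soup for each query point, accelerated by
// a uniform grid over triangle bounding boxes with expanding-shell search.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix queries, NumericMatrix V,
                         IntegerMatrix F) {
  const int nq = queries.nrow(), nf = F.nrow();
  if (nf < 1) stop("mesh has no faces");
  std::vector<double> tv(9 * nf);
  double lo[3] = {std::numeric_limits<double>::infinity(),
                  std::numeric_limits<double>::infinity(),
                  std::numeric_limits<double>::infinity()};
  double hi[3] = {-lo[0], -lo[1], -lo[2]};
  double area2_sum = 0.0;
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int j = 0; j < 3; ++j) {
        double c = V(vi, j);
        tv[9 * f + 3 * k + j] = c;
        if (c < lo[j]) lo[j] = c;
        if (c > hi[j]) hi[j] = c;
      }
    }
    const double *a = &tv[9 * f], *b = &tv[9 * f + 3], *c = &tv[9 * f + 6];
    double e1[3], e2[3];
    for (int j = 0; j < 3; ++j) { e1[j] = b[j] - a[j]; e2[j] = c[j] - a[j]; }
    double cr0 = e1[1] * e2[2] - e1[2] * e2[1];
    double cr1 = e1[2] * e2[0] - e1[0] * e2[2];
    double cr2 = e1[0] * e2[1] - e1[1] * e2[0];
    area2_sum += 0.5 * std::sqrt(cr0 * cr0 + cr1 * cr1 + cr2 * cr2);
  }
  // cell size ~ 2x the typical triangle edge scale, grid capped at 96^3
  double h = 2.0 * std::sqrt(std::max(area2_sum / nf, 1e-12));
  int dims[3];
  for (int j = 0; j < 3; ++j) {
    double ext = std::max(hi[j] - lo[j], 1e-9);
    int n = (int)std::ceil(ext / h);
    dims[j] = std::min(std::max(n, 1), 96);
  }
  double cell[3];
  for (int j = 0; j < 3; ++j) cell[j] = std::max(hi[j] - lo[j], 1e-9) / dims[j];
  double hmin = std::min(cell[0], std::min(cell[1], cell[2]));
  const int ncell = dims[0] * dims[1] * dims[2];
  std::vector<std::vector<int> > grid(ncell);
  for (int f = 0; f < nf; ++f) {
    int clo[3], chi[3];
    for (int j = 0; j < 3; ++j) {
      double mn = std::min(tv[9 * f + j], std::min(tv[9 * f + 3 + j],
                                                   tv[9 * f + 6 + j]));
      double mx = std::max(tv[9 * f + j], std::max(tv[9 * f + 3 + j],
                                                   tv[9 * f + 6 + j]));
      clo[j] = std::min(dims[j] - 1, std::max(0, (int)((mn - lo[j]) / cell[j])));
      chi[j] = std::min(dims[j] - 1, std::max(0, (int)((mx - lo[j]) / cell[j])));
    }
    for (int ix = clo[0]; ix <= chi[0]; ++ix)
      for (int iy = clo[1]; iy <= chi[1]; ++iy)
        for (int iz = clo[2]; iz <= chi[2]; ++iz)
          grid[(iz * dims[1] + iy) * dims[0] + ix].push_back(f);
  }
  std::vector<int> stamp(nf, -1);
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);
  const int rmax = dims[0] + dims[1] + dims[2] + 2;
  for (int q = 0; q < nq; ++q) {
    double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    int cq[3];
    for (int j = 0; j < 3; ++j) {
      cq[j] = std::min(dims[j] - 1,
                       std::max(0, (int)((p[j] - lo[j]) / cell[j])));
    }
    // distance from p to the grid box (0 if inside): shells start there
    double outside = 0.0;
    for (int j = 0; j < 3; ++j) {
      if (p[j] < lo[j]) outside = std::max(outside, lo[j] - p[j]);
      if (p[j] > hi[j]) outside = std::max(outside, p[j] - hi[j]);
    }
    double bd = std::numeric_limits<double>::infinity();
    int bf = -1;
    double bp[3] = {p[0], p[1], p[2]};
    double cp[3];
    for (int r = 0; r < rmax; ++r) {
      if (bf >= 0 && std::max(outside, (r - 1) * hmin) > bd) break;
      bool any_cell = false;
      int x0 = cq[0] - r, x1 = cq[0] + r;
      int y0 = cq[1] - r, y1 = cq[1] + r;
      int z0 = cq[2] - r, z1 = cq[2] + r;
      for (int ix = x0; ix <= x1; ++ix) {
        if (ix < 0 || ix >= dims[0]) continue;
        for (int iy = y0; iy <= y1; ++iy) {
          if (iy < 0 || iy >= dims[1]) continue;
          for (int iz = z0; iz <= z1; ++iz) {
            if (iz < 0 || iz >= dims[2]) continue;
            // shell only: skip interior cells already visited
            int cd = std::max(std::abs(ix - cq[0]),
                              std::max(std::abs(iy - cq[1]),
                                       std::abs(iz - cq[2])));
            if (cd != r) continue;
            any_cell = true;
            const std::vector<int> &bucket =
              grid[(iz * dims[1] + iy) * dims[0] + ix];
            for (size_t bi = 0; bi < bucket.size(); ++bi) {
              int f = bucket[bi];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              closestPointTriangle(p, &tv[9 * f], &tv[9 * f + 3],
                                   &tv[9 * f + 6], cp);
              double d = std::sqrt((cp[0] - p[0]) * (cp[0] - p[0]) +
                                   (cp[1] - p[1]) * (cp[1] - p[1]) +
                                   (cp[2] - p[2]) * (cp[2] - p[2]));
              if (d < bd) {
                bd = d; bf = f;
                bp[0] = cp[0]; bp[1] = cp[1]; bp[2] = cp[2];
              }
            }
          }
        }
      }
      if (!any_cell && r > 0 &&
          (x0 < 0 && x1 >= dims[0] && y0 < 0 && y1 >= dims[1] &&
           z0 < 0 && z1 >= dims[2])) {
        break; // whole grid exhausted
      }
    }
    pts(q, 0) = bp[0]; pts(q, 1) = bp[1]; pts(q, 2) = bp[2];
    dist[q] = bd;
    face[q] = bf + 1;
  }
  return List::create(_["point"] = pts, _["dist"] = dist, _["face"] = face);
}

// Line-mesh intersection along per-query directions.  Returns for each query
// the signed parameter t of the intersection with smallest |t| such that
// |t| <= tmax (NA when the line misses every face within the window).
// Intersections are tested in both directions (t may be negative).
// [[Rcpp::export]]
List cpp_line_mesh(NumericMatrix origins, NumericMatrix dirs, NumericMatrix V,
                   IntegerMatrix F, double tmax) {
  const int nq = origins.nrow(), nf = F.nrow();
  if (nf < 1) stop("mesh has no faces");
  std::vector<double> tv(9 * nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      tv[9 * f + 3 * k + 0] = V(vi, 0);
      tv[9 * f + 3 * k + 1] = V(vi, 1);
      tv[9 * f + 3 * k + 2] = V(vi, 2);
    }
  NumericVector tout(nq);
  IntegerVector face(nq);
  const double eps = 1e-12;
  for (int q = 0; q < nq; ++q) {
    double o[3] = {origins(q, 0), origins(q, 1), origins(q, 2)};
    double d[3] = {dirs(q, 0), dirs(q, 1), dirs(q, 2)};
    double bestt = NA_REAL;
    int bestf = NA_INTEGER;
    double besta = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      const double *a = &tv[9 * f], *b = &tv[9 * f + 3], *c = &tv[9 * f + 6];
      double e1[3], e2[3];
      for (int i = 0; i < 3; ++i) { e1[i] = b[i] - a[i]; e2[i] = c[i] - a[i]; }
      // Moller–Trumbore
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                      d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tvec[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
      double u = (tvec[0] * pv[0] + tvec[1] * pv[1] + tvec[2] * pv[2]) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qv[3] = {tvec[1] * e1[2] - tvec[2] * e1[1],
                      tvec[2] * e1[0] - tvec[0] * e1[2],
                      tvec[0] * e1[1] - tvec[1] * e1[0]};
      double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      double at = std::fabs(t);
      if (at <= tmax && at < besta) {
        besta = at; bestt = t; bestf = f + 1;
      }
    }
    tout[q] = bestt;
    face[q] = bestf;
  }
  return List::create(_["t"] = tout, _["face"] = face);
}
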