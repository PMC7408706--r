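#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Closest point on a triangle (a,b,c) to point p. Ericson's region test:
// classifies p against the vertex/edge/face Voronoi regions of the triangle
// and returns the exact closed-form foot point.
static inline void tri_closest(const double* p, const double* a,
                               const double* b, const double* c,
                               double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

struct MeshIndex {
  std::vector<double> V;   // 3*nv, row i at 3*i
  std::vector<int>    F;   // 3*nf, 0-based
  std::vector<double> FN;  // 3*nf unit normals
  double lo[3];
  double cell[3];
  int dim[3];
  std::vector< std::vector<int> > bins;
  std::vector<int> stamp;
  int stampval;
  int nf, nv;

  inline int bin_of(int ix, int iy, int iz) const {
    return (iz * dim[1] + iy) * dim[0] + ix;
  }
};

static inline int clampi(int x, int a, int b) {
  return x < a ? a : (x > b ? b : x);
}

// [[Rcpp::export]]
SEXP cp_build_index(NumericMatrix V, IntegerMatrix F) {
  MeshIndex* mi = new MeshIndex();
  int nv = V.nrow(), nf = F.nrow();
  mi->nv = nv; mi->nf = nf;
  mi->V.resize(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) mi->V[3*(size_t)i + j] = V(i, j);
  mi->F.resize(3 * (size_t)nf);
  mi->FN.resize(3 * (size_t)nf);
  double hi[3];
  for (int j = 0; j < 3; ++j) { mi->lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) {
      double x = V(i, j);
      if (x < mi->lo[j]) mi->lo[j] = x;
      if (x > hi[j]) hi[j] = x;
    }
  // cell edge targeting ~1 face per cell, clamped so tiny/flat meshes work
  double ext[3], vol = 1.0;
  for (int j = 0; j < 3; ++j) {
    ext[j] = std::max(hi[j] - mi->lo[j], 1e-9);
    vol *= ext[j];
  }
  double h = std::cbrt(vol / std::max(nf, 1));
  for (int j = 0; j < 3; ++j) {
    int d = (int)std::ceil(ext[j] / h);
    mi->dim[j] = clampi(d, 1, 128);
    mi->cell[j] = ext[j] / mi->dim[j];
  }
  mi->bins.resize((size_t)mi->dim[0] * mi->dim[1] * mi->dim[2]);

  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    mi->F[3*(size_t)f + 0] = ia;
    mi->F[3*(size_t)f + 1] = ib;
    mi->F[3*(size_t)f + 2] = ic;
    const double* a = &mi->V[3*(size_t)ia];
    const double* b = &mi->V[3*(size_t)ib];
    const double* c = &mi->V[3*(size_t)ic];
    double e1[3], e2[3], n[3];
    for (int j = 0; j < 3; ++j) { e1[j] = b[j] - a[j]; e2[j] = c[j] - a[j]; }
    n[0] = e1[1]*e2[2] - e1[2]*e2[1];
    n[1] = e1[2]*e2[0] - e1[0]*e2[2];
    n[2] = e1[0]*e2[1] - e1[1]*e2[0];
    double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (nn > 0) for (int j = 0; j < 3; ++j) n[j] /= nn;
    for (int j = 0; j < 3; ++j) mi->FN[3*(size_t)f + j] = n[j];
    // insert face into every cell overlapped by its AABB
    int c0[3], c1[3];
    for (int j = 0; j < 3; ++j) {
      double fmin = std::min(a[j], std::min(b[j], c[j]));
      double fmax = std::max(a[j], std::max(b[j], c[j]));
      c0[j] = clampi((int)std::floor((fmin - mi->lo[j]) / mi->cell[j]), 0, mi->dim[j] - 1);
      c1[j] = clampi((int)std::floor((fmax - mi->lo[j]) / mi->cell[j]), 0, mi->dim[j] - 1);
    }
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          mi->bins[mi->bin_of(ix, iy, iz)].push_back(f);
  }
  mi->stamp.assign(nf, 0);
  mi->stampval = 0;
  XPtr<MeshIndex> ptr(mi, true);
  return ptr;
}

static void query_one(MeshIndex* mi, const double* p,
                      double& best_d2, int& best_f, double* best_pt) {
  best_d2 = std::numeric_limits<double>::infinity();
  best_f = -1;
  mi->stampval++;
  int cc[3];
  for (int j = 0; j < 3; ++j)
    cc[j] = clampi((int)std::floor((p[j] - mi->lo[j]) / mi->cell[j]), 0, mi->dim[j] - 1);
  int maxr = 0;
  for (int j = 0; j < 3; ++j)
    maxr = std::max(maxr, std::max(cc[j], mi->dim[j] - 1 - cc[j]));

  double q[3];
  for (int r = 0; r <= maxr; ++r) {
    if (r > 0 && best_f >= 0) {
      // lower bound on the distance to any cell with Chebyshev index
      // distance >= r from the query's cell: exact query stops only when
      // the current best cannot be beaten by an unvisited shell
      double bound = std::numeric_limits<double>::infinity();
      for (int j = 0; j < 3; ++j) {
        double far_hi = mi->lo[j] + (double)(cc[j] + r) * mi->cell[j] - p[j];
        double far_lo = p[j] - (mi->lo[j] + (double)(cc[j] - r + 1) * mi->cell[j]);
        double bj = std::min(std::max(far_hi, 0.0), std::max(far_lo, 0.0));
        // a shell cell may exceed radius r on any single axis
        bound = std::min(bound, bj);
      }
      if (best_d2 <= bound * bound) break;
    }
    for (int iz = cc[2] - r; iz <= cc[2] + r; ++iz) {
      if (iz < 0 || iz >= mi->dim[2]) continue;
      for (int iy = cc[1] - r; iy <= cc[1] + r; ++iy) {
        if (iy < 0 || iy >= mi->dim[1]) continue;
        bool face_yz = (std::abs(iz - cc[2]) == r) || (std::abs(iy - cc[1]) == r);
        for (int ix = cc[0] - r; ix <= cc[0] + r; ++ix) {
          if (ix < 0 || ix >= mi->dim[0]) continue;
          if (!face_yz && std::abs(ix - cc[0]) != r) continue;  // interior already visited
          const std::vector<int>& lst = mi->bins[mi->bin_of(ix, iy, iz)];
          for (size_t k = 0; k < lst.size(); ++k) {
            int f = lst[k];
            if (mi->stamp[f] == mi->stampval) continue;
            mi->stamp[f] = mi->stampval;
            const double* a = &mi->V[3*(size_t)mi->F[3*(size_t)f + 0]];
            const double* b = &mi->V[3*(size_t)mi->F[3*(size_t)f + 1]];
            const double* c = &mi->V[3*(size_t)mi->F[3*(size_t)f + 2]];
            tri_closest(p, a, b, c, q);
            double d2 = 0;
            for (int j = 0; j < 3; ++j) {
              double dj = p[j] - q[j];
              d2 += dj * dj;
            }
            if (d2 < best_d2) {
              best_d2 = d2;
              best_f = f;
              for (int j = 0; j < 3; ++j) best_pt[j] = q[j];
            }
          }
        }
      }
    }
  }
}

// Exact nearest surface point for each row of P; distances in mesh units,
// sign positive when P lies on the outward-normal side of the nearest face.
// [[Rcpp::export]]
List cp_query(SEXP index, NumericMatrix P) {
  XPtr<MeshIndex> ptr(index);
  MeshIndex* mi = ptr.get();
  int n = P.nrow();
  NumericVector dist(n), sdist(n);
  IntegerVector face(n);
  NumericMatrix foot(n, 3);
  double p[3], best_pt[3];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) p[j] = P(i, j);
    double d2; int f;
    query_one(mi, p, d2, f, best_pt);
    double d = std::sqrt(d2);
    dist[i] = d;
    face[i] = f + 1;
    double dp = 0;
    for (int j = 0; j < 3; ++j) {
      foot(i, j) = best_pt[j];
      dp += (p[j] - best_pt[j]) * mi->FN[3*(size_t)f + j];
    }
    sdist[i] = (dp >= 0) ? d : -d;
  }
  return List::create(_["distance"] = dist, _["signed_distance"] = sdist,
                      _["face"] = face, _["point"] = foot);
}

// Closest point on a single triangle; exported for the low-level geometry API.
// [[Rcpp::export]]
NumericVector cp_point_triangle(NumericVector p, NumericMatrix tri) {
  double pp[3] = { p[0], p[1], p[2] };
  double a[3] = { tri(0,0), tri(0,1), tri(0,2) };
  double b[3] = { tri(1,0), tri(1,1), tri(1,2) };
  double c[3] = { tri(2,0), tri(2,1), tri(2,2) };
  double out[3];
  tri_closest(pp, a, b, c, out);
  return NumericVector::create(out[0], out[1], out[2]);
}
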