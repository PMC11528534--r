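// Clipped Voronoi tessellation of a simple polygonal domain, vertex-model
// elastic energy on the resulting cells, and finite-difference forces.
//
// Each Voronoi cell is the intersection of the domain polygon with the
// half-planes {p : (p - m_ij).(p_j - p_i) <= 0} over the other generators.
// Sutherland-Hodgman clipping is used with per-edge labels so that shared
// Voronoi edges (label = index of the opposing generator) and domain-boundary
// edges (label = -1 - domain edge index) can be recovered afterwards.
//
// Forces are central finite differences of the energy through the
// tessellation. For an infinitesimal move of generator i only cell i and its
// direct Voronoi neighbours change shape, so the perturbed energy is
// recomputed over that one-ring set, clipping only against generators within
// two rings. The step h is supplied by the caller (order 1e-6 of the domain
// diameter).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;
  std::vector<int> lab; // lab[k]: label of edge from vertex k to k+1 (cyclic)
  size_t size() const { return x.size(); }
};

// keep points with ax*px + ay*py <= b
Poly clip_halfplane(const Poly &p, double ax, double ay, double b, int newlab) {
  Poly out;
  const size_t n = p.size();
  if (n == 0) return out;
  out.x.reserve(n + 4); out.y.reserve(n + 4); out.lab.reserve(n + 4);
  static thread_local std::vector<double> d;
  d.resize(n);
  double scale = std::sqrt(ax * ax + ay * ay);
  if (scale <= 0.0) return p;
  for (size_t k = 0; k < n; ++k) d[k] = (ax * p.x[k] + ay * p.y[k] - b) / scale;
  const double eps = 1e-12;
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    bool in1 = d[k] <= eps, in2 = d[k2] <= eps;
    if (in1) {
      out.x.push_back(p.x[k]);
      out.y.push_back(p.y[k]);
      out.lab.push_back(p.lab[k]);
      if (!in2) {
        double t = d[k] / (d[k] - d[k2]);
        out.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
        out.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
        out.lab.push_back(newlab); // chord along the clipping line starts here
      }
    } else if (in2) {
      double t = d[k] / (d[k] - d[k2]);
      out.x.push_back(p.x[k] + t * (p.x[k2] - p.x[k]));
      out.y.push_back(p.y[k] + t * (p.y[k2] - p.y[k]));
      out.lab.push_back(p.lab[k]); // remainder of original edge k
    }
  }
  return out;
}

Poly domain_poly(const NumericVector &dx, const NumericVector &dy) {
  Poly p;
  int n = dx.size();
  p.x.assign(dx.begin(), dx.end());
  p.y.assign(dy.begin(), dy.end());
  p.lab.resize(n);
  for (int k = 0; k < n; ++k) p.lab[k] = -1 - k;
  return p;
}

Poly cell_poly(int i, const NumericVector &px, const NumericVector &py,
               const Poly &dom, const std::vector<int> &cand) {
  Poly cell = dom;
  for (int j : cand) {
    if (j == i) continue;
    double ax = px[j] - px[i], ay = py[j] - py[i];
    double b = 0.5 * (px[j] * px[j] + py[j] * py[j] -
                      px[i] * px[i] - py[i] * py[i]);
    cell = clip_halfplane(cell, ax, ay, b, j);
    if (cell.size() == 0) break;
  }
  return cell;
}

double poly_area(const Poly &p) {
  double a = 0.0;
  size_t n = p.size();
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    a += p.x[k] * p.y[k2] - p.x[k2] * p.y[k];
  }
  return 0.5 * a;
}

double poly_perim(const Poly &p) {
  double s = 0.0;
  size_t n = p.size();
  for (size_t k = 0; k < n; ++k) {
    size_t k2 = (k + 1) % n;
    s += std::hypot(p.x[k2] - p.x[k], p.y[k2] - p.y[k]);
  }
  return s;
}

std::vector<int> all_indices(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

double cell_energy(double A, double P, double A0, double P0,
                   double Kc, double Kv) {
  return 0.5 * Kv * (A - A0) * (A - A0) + 0.5 * Kc * (P - P0) * (P - P0);
}

} // namespace

// [[Rcpp::export]]
List cpp_voronoi(NumericVector px, NumericVector py,
                 NumericVector domx, NumericVector domy) {
  int n = px.size();
  Poly dom = domain_poly(domx, domy);
  std::vector<int> cand = all_indices(n);
  List polys(n);
  NumericVector area(n), perim(n);
  std::vector<int> ei, ej;
  std::vector<double> elen;
  std::vector<int> bcell, bedge;
  std::vector<double> blen, bmx, bmy;
  for (int i = 0; i < n; ++i) {
    Poly c = cell_poly(i, px, py, dom, cand);
    size_t m = c.size();
    NumericMatrix verts(m, 2);
    for (size_t k = 0; k < m; ++k) { verts(k, 0) = c.x[k]; verts(k, 1) = c.y[k]; }
    polys[i] = verts;
    area[i] = poly_area(c);
    perim[i] = poly_perim(c);
    for (size_t k = 0; k < m; ++k) {
      size_t k2 = (k + 1) % m;
      double L = std::hypot(c.x[k2] - c.x[k], c.y[k2] - c.y[k]);
      if (L < 1e-10) continue;
      int lab = c.lab[k];
      if (lab >= 0) {
        if (lab > i) { ei.push_back(i); ej.push_back(lab); elen.push_back(L); }
      } else {
        bcell.push_back(i);
        bedge.push_back(-1 - lab);
        blen.push_back(L);
        bmx.push_back(0.5 * (c.x[k] + c.x[k2]));
        bmy.push_back(0.5 * (c.y[k] + c.y[k2]));
      }
    }
  }
  int ne = ei.size(), nb = bcell.size();
  IntegerVector Ei(ne), Ej(ne);
  NumericVector El(ne);
  for (int k = 0; k < ne; ++k) { Ei[k] = ei[k] + 1; Ej[k] = ej[k] + 1; El[k] = elen[k]; }
  IntegerVector Bc(nb), Be(nb);
  NumericVector Bl(nb), Bx(nb), By(nb);
  for (int k = 0; k < nb; ++k) {
    Bc[k] = bcell[k] + 1; Be[k] = bedge[k] + 1;
    Bl[k] = blen[k]; Bx[k] = bmx[k]; By[k] = bmy[k];
  }
  return List::create(_["polygons"] = polys, _["area"] = area,
                      _["perimeter"] = perim,
                      _["edge_i"] = Ei, _["edge_j"] = Ej, _["edge_len"] = El,
                      _["bnd_cell"] = Bc, _["bnd_edge"] = Be,
                      _["bnd_len"] = Bl, _["bnd_mx"] = Bx, _["bnd_my"] = By);
}

// [[Rcpp::export]]
double cpp_energy(NumericVector px, NumericVector py,
                  NumericVector domx, NumericVector domy,
                  NumericVector A0, NumericVector P0,
                  double Kc, double Kv) {
  int n = px.size();
  Poly dom = domain_poly(domx, domy);
  std::vector<int> cand = all_indices(n);
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    Poly c = cell_poly(i, px, py, dom, cand);
    E += cell_energy(poly_area(c), poly_perim(c), A0[i], P0[i], Kc, Kv);
  }
  return E;
}

// [[Rcpp::export]]
List cpp_neighbors(NumericVector px, NumericVector py,
                   NumericVector domx, NumericVector domy) {
  int n = px.size();
  Poly dom = domain_poly(domx, domy);
  std::vector<int> all = all_indices(n);
  List out(n);
  for (int i = 0; i < n; ++i) {
    Poly c = cell_poly(i, px, py, dom, all);
    std::vector<int> nb;
    size_t m = c.size();
    for (size_t k = 0; k < m; ++k) {
      size_t k2 = (k + 1) % m;
      double L = std::hypot(c.x[k2] - c.x[k], c.y[k2] - c.y[k]);
      if (L < 1e-10) continue;
      if (c.lab[k] >= 0) nb.push_back(c.lab[k] + 1); // 1-based for R
    }
    out[i] = IntegerVector(nb.begin(), nb.end());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericVector px, NumericVector py,
                         NumericVector domx, NumericVector domy,
                         NumericVector A0, NumericVector P0,
                         double Kc, double Kv, double h,
                         Nullable<List> nb_in = R_NilValue) {
  int n = px.size();
  Poly dom = domain_poly(domx, domy);
  std::vector<int> all = all_indices(n);

  // adjacency from the unperturbed tessellation (or a caller-supplied
  // slightly stale one: it only selects the affected/candidate sets)
  std::vector<std::vector<int>> nb(n);
  if (nb_in.isNotNull()) {
    List lst(nb_in);
    if (lst.size() != n) stop("neighbour list has wrong length");
    for (int i = 0; i < n; ++i) {
      IntegerVector v = lst[i];
      for (int k = 0; k < v.size(); ++k) nb[i].push_back(v[k] - 1);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      Poly c = cell_poly(i, px, py, dom, all);
      size_t m = c.size();
      for (size_t k = 0; k < m; ++k) {
        size_t k2 = (k + 1) % m;
        double L = std::hypot(c.x[k2] - c.x[k], c.y[k2] - c.y[k]);
        if (L < 1e-10) continue;
        if (c.lab[k] >= 0) nb[i].push_back(c.lab[k]);
      }
    }
  }

  NumericMatrix F(n, 2);
  for (int i = 0; i < n; ++i) {
    // affected cells: i and its direct neighbours. Each affected cell c is
    // clipped against its own neighbour set plus i (for an infinitesimal
    // move of i no other plane of c's polygon changes or appears).
    std::vector<int> affect = {i};
    for (int j : nb[i]) affect.push_back(j);
    std::vector<std::vector<int>> cand(affect.size());
    for (size_t k = 0; k < affect.size(); ++k) {
      int c = affect[k];
      cand[k] = nb[c];
      if (c != i) cand[k].push_back(i);
    }

    NumericVector qpx(px.begin(), px.end()), qpy(py.begin(), py.end());
    for (int dim = 0; dim < 2; ++dim) {
      double Ep = 0.0, Em = 0.0;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double save = (dim == 0) ? qpx[i] : qpy[i];
        if (dim == 0) qpx[i] = save + sgn * h; else qpy[i] = save + sgn * h;
        double E = 0.0;
        for (size_t k = 0; k < affect.size(); ++k) {
          int c = affect[k];
          Poly pc = cell_poly(c, qpx, qpy, dom, cand[k]);
          E += cell_energy(poly_area(pc), poly_perim(pc), A0[c], P0[c], Kc, Kv);
        }
        if (sgn < 0) Em = E; else Ep = E;
        if (dim == 0) qpx[i] = save; else qpy[i] = save;
      }
      F(i, dim) = -(Ep - Em) / (2.0 * h);
    }
  }
  return F;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericVector x, NumericVector y,
                                NumericVector domx, NumericVector domy) {
  int n = x.size(), m = domx.size();
  LogicalVector inside(n);
  for (int q = 0; q < n; ++q) {
    bool in = false;
    for (int k = 0, k2 = m - 1; k < m; k2 = k++) {
      bool cross = ((domy[k] > y[q]) != (domy[k2] > y[q])) &&
        (x[q] < (domx[k2] - domx[k]) * (y[q] - domy[k]) /
                 (domy[k2] - domy[k]) + domx[k]);
      if (cross) in = !in;
    }
    inside[q] = in;
  }
  return inside;
}
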