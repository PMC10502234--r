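// Barnes-Hut quadtree for the Student-t repulsive sums of 2-D t-SNE.
//
// For each point i the traversal accumulates the moments
//   Zi      = sum_j E_ij              with E_ij = 1 / (1 + ||y_i - y_j||^2)
//   sumE2_i = sum_j E_ij^2
//   S_i     = sum_j E_ij^2 (y_i - y_j)                (2-vector)
//   T_i     = sum_j E_ij^3 (y_i - y_j)(y_i - y_j)^T   (xx, xy, yy)
// A cell is summarized as a point mass at its centre of mass when
// max_side / distance < theta; theta = 0 therefore opens every cell down
// to the leaves and reproduces the exact O(n^2) sums.

#include <Rcpp.h>
#include <vector>
#include <memory>
using namespace Rcpp;

struct Cell {
  double cx, cy, half;           // centre and half side length
  double comx = 0, comy = 0;     // centre of mass
  int count = 0;
  bool leaf = true;
  std::vector<int> idx;          // point indices (leaves only)
  std::unique_ptr<Cell> child[4];
  Cell(double cx_, double cy_, double half_) : cx(cx_), cy(cy_), half(half_) {}
};

static const int MAX_DEPTH = 64;
static const int LEAF_CAP = 1;

static int quadrant(const Cell& c, double x, double y) {
  return (x >= c.cx ? 1 : 0) + (y >= c.cy ? 2 : 0);
}

static void insert(Cell& c, int i, const double* xs, const double* ys, int depth) {
  c.comx = (c.comx * c.count + xs[i]) / (c.count + 1);
  c.comy = (c.comy * c.count + ys[i]) / (c.count + 1);
  c.count += 1;
  if (c.leaf) {
    c.idx.push_back(i);
    if ((int)c.idx.size() <= LEAF_CAP || depth >= MAX_DEPTH) return;
    // split: re-insert resident points into children
    c.leaf = false;
    std::vector<int> old;
    old.swap(c.idx);
    for (int j : old) {
      int q = quadrant(c, xs[j], ys[j]);
      if (!c.child[q]) {
        double h = c.half / 2;
        c.child[q] = std::make_unique<Cell>(
          c.cx + (q & 1 ? h : -h), c.cy + (q & 2 ? h : -h), h);
      }
      insert(*c.child[q], j, xs, ys, depth + 1);
    }
    return;
  }
  int q = quadrant(c, xs[i], ys[i]);
  if (!c.child[q]) {
    double h = c.half / 2;
    c.child[q] = std::make_unique<Cell>(
      c.cx + (q & 1 ? h : -h), c.cy + (q & 2 ? h : -h), h);
  }
  insert(*c.child[q], i, xs, ys, depth + 1);
}

struct Acc { double Z, E2, Sx, Sy, Txx, Txy, Tyy; };

static inline void add_mass(Acc& a, double dx, double dy, double m) {
  double e = 1.0 / (1.0 + dx * dx + dy * dy);
  double e2 = e * e, e3 = e2 * e;
  a.Z   += m * e;
  a.E2  += m * e2;
  a.Sx  += m * e2 * dx;
  a.Sy  += m * e2 * dy;
  a.Txx += m * e3 * dx * dx;
  a.Txy += m * e3 * dx * dy;
  a.Tyy += m * e3 * dy * dy;
}

static void traverse(const Cell& c, int i, double xi, double yi,
                     double theta, const double* xs, const double* ys, Acc& a) {
  if (c.count == 0) return;
  double dx = xi - c.comx, dy = yi - c.comy;
  double dist2 = dx * dx + dy * dy;
  double side = 2 * c.half;
  if (!c.leaf && dist2 > 0 && side * side < theta * theta * dist2) {
    add_mass(a, dx, dy, (double)c.count);   // far cell: point mass at centroid
    return;
  }
  if (c.leaf) {
    for (int j : c.idx) {
      if (j == i) continue;
      add_mass(a, xi - xs[j], yi - ys[j], 1.0);
    }
    return;
  }
  for (int q = 0; q < 4; ++q)
    if (c.child[q]) traverse(*c.child[q], i, xi, yi, theta, xs, ys, a);
}

// [[Rcpp::export(name = ".bh_moments")]]
List bh_moments(NumericMatrix Y, double theta) {
  if (Y.ncol() != 2) stop("Barnes-Hut mode requires a 2-D embedding");
  if (theta < 0 || theta >= 1) stop("theta must lie in [0, 1)");
  int n = Y.nrow();
  std::vector<double> xs(n), ys(n);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xs[i] = Y(i, 0); ys[i] = Y(i, 1);
    xmin = std::min(xmin, xs[i]); xmax = std::max(xmax, xs[i]);
    ymin = std::min(ymin, ys[i]); ymax = std::max(ymax, ys[i]);
  }
  double half = std::max(xmax - xmin, ymax - ymin) / 2 + 1e-9;
  Cell root((xmin + xmax) / 2, (ymin + ymax) / 2, half);
  for (int i = 0; i < n; ++i) insert(root, i, xs.data(), ys.data(), 0);

  NumericVector Zi(n), E2(n);
  NumericMatrix S(n, 2), T(n, 3);
  for (int i = 0; i < n; ++i) {
    Acc a = {0, 0, 0, 0, 0, 0, 0};
    traverse(root, i, xs[i], ys[i], theta, xs.data(), ys.data(), a);
    Zi[i] = a.Z; E2[i] = a.E2;
    S(i, 0) = a.Sx; S(i, 1) = a.Sy;
    T(i, 0) = a.Txx; T(i, 1) = a.Txy; T(i, 2) = a.Tyy;
  }
  return List::create(_["Zi"] = Zi, _["sumE2"] = E2, _["S"] = S, _["T"] = T);
}
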