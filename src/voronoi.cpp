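#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// k nearest neighbours (excluding self) by brute force with a partial
// sort; adequate for the 1e3-1e4 localizations of one nucleus.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix xy, int k) {
  const int n = xy.nrow();
  k = std::min(k, n - 1);
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int>> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = xy(j, 0) - xy(i, 0), dy = xy(j, 1) - xy(i, 1);
      d[j] = {dx * dx + dy * dy, j};
    }
    d[i].first = R_PosInf;
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = d[m].second + 1;
      dist(i, m) = std::sqrt(d[m].first);
    }
    std::sort(d.begin(), d.end(),
              [](const std::pair<double,int>&a, const std::pair<double,int>&b){
                return a.second < b.second; });
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Clip the polygon by the half-plane closer to the site than to
// neighbour `gen`; `eg` labels, for each vertex, the generator of the
// outgoing edge (-1 for a frame edge), so surviving edges keep their
// provenance and the new chord is labelled `gen`.
static void clip_halfplane(std::vector<double> &px, std::vector<double> &py,
                           std::vector<int> &eg,
                           double mx, double my, double ux, double uy,
                           int gen) {
  const int nv = px.size();
  if (nv == 0) return;
  std::vector<double> qx, qy;
  std::vector<int> qg;
  qx.reserve(nv + 4); qy.reserve(nv + 4); qg.reserve(nv + 4);
  std::vector<double> s(nv);
  for (int i = 0; i < nv; ++i)
    s[i] = (px[i] - mx) * ux + (py[i] - my) * uy;
  for (int i = 0; i < nv; ++i) {
    const int j = (i + 1) % nv;
    const bool ini = s[i] <= 1e-12, inj = s[j] <= 1e-12;
    if (ini) { qx.push_back(px[i]); qy.push_back(py[i]); qg.push_back(eg[i]); }
    if (ini != inj) {
      const double t = s[i] / (s[i] - s[j]);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
      // exit point starts the chord along the bisector; entry point
      // continues the original edge
      qg.push_back(ini ? gen : eg[i]);
    }
  }
  px.swap(qx); py.swap(qy); eg.swap(qg);
}

// Voronoi cell areas by iterative bisector clipping of a rectangular
// frame, using the k0 nearest neighbours as candidates and enlarging to
// every point within twice the farthest-vertex radius whenever the
// security criterion fails. Also returns, per cell, the indices
// (1-based) of the neighbours whose bisectors survive as polygon edges
// (the Voronoi adjacency).
// [[Rcpp::export]]
List cpp_voronoi_areas(NumericMatrix xy, NumericVector frame, int k0) {
  const int n = xy.nrow();
  List kn = cpp_knn(xy, std::min(k0, n - 1));
  IntegerMatrix idx = kn["idx"];
  NumericMatrix kd = kn["dist"];
  const int k = idx.ncol();
  NumericVector area(n);
  LogicalVector edge(n);
  IntegerVector nclip(n);
  const double fx0 = frame[0], fx1 = frame[1], fy0 = frame[2], fy1 = frame[3];
  const double ftol = 1e-7 * std::max(fx1 - fx0, fy1 - fy0);
  List adj(n);
  std::vector<double> px, py;
  std::vector<int> eg;
  for (int i = 0; i < n; ++i) {
    const double sx = xy(i, 0), sy = xy(i, 1);
    px = {fx0, fx1, fx1, fx0};
    py = {fy0, fy0, fy1, fy1};
    eg = {-1, -1, -1, -1};
    for (int m = 0; m < k && px.size() >= 3; ++m) {
      const int j = idx(i, m) - 1;
      clip_halfplane(px, py, eg,
                     0.5 * (sx + xy(j, 0)), 0.5 * (sy + xy(j, 1)),
                     xy(j, 0) - sx, xy(j, 1) - sy, j);
    }
    int used = k;
    if (px.size() >= 3) {
      double rv2 = 0.0;
      for (size_t v = 0; v < px.size(); ++v) {
        const double dx = px[v] - sx, dy = py[v] - sy;
        rv2 = std::max(rv2, dx * dx + dy * dy);
      }
      const double dk = kd(i, k - 1);
      if (4.0 * rv2 > dk * dk && k < n - 1) {
        // redo with every point within 2 * rv
        px = {fx0, fx1, fx1, fx0};
        py = {fy0, fy0, fy1, fy1};
        eg = {-1, -1, -1, -1};
        used = 0;
        for (int j = 0; j < n && px.size() >= 3; ++j) {
          if (j == i) continue;
          const double dx = xy(j, 0) - sx, dy = xy(j, 1) - sy;
          if (dx * dx + dy * dy <= 4.0 * rv2) {
            clip_halfplane(px, py, eg, sx + 0.5 * dx, sy + 0.5 * dy,
                           dx, dy, j);
            ++used;
          }
        }
      }
    }
    {
      std::vector<int> nb;
      for (size_t v = 0; v < eg.size(); ++v)
        if (eg[v] >= 0) nb.push_back(eg[v] + 1);
      std::sort(nb.begin(), nb.end());
      nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
      adj[i] = IntegerVector(nb.begin(), nb.end());
    }
    nclip[i] = used;
    double A = 0.0;
    const int nv = px.size();
    if (nv >= 3) {
      for (int v = 0; v < nv; ++v) {
        const int w = (v + 1) % nv;
        A += px[v] * py[w] - px[w] * py[v];
      }
      A = std::fabs(A) * 0.5;
    }
    area[i] = A;
    bool onf = false;
    for (int v = 0; v < nv && !onf; ++v) {
      onf = std::fabs(px[v] - fx0) < ftol || std::fabs(px[v] - fx1) < ftol ||
            std::fabs(py[v] - fy0) < ftol || std::fabs(py[v] - fy1) < ftol;
    }
    edge[i] = onf;
  }
  return List::create(_["area"] = area, _["edge"] = edge,
                      _["n_clip"] = nclip, _["adjacency"] = adj);
}
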