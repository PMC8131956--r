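#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Quasi-uniform unit sphere points (golden-spiral lattice); deterministic.
static std::vector<double> sphere_dots(int n) {
  std::vector<double> pts(3 * n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    pts[3 * k] = r * std::cos(th);
    pts[3 * k + 1] = r * std::sin(th);
    pts[3 * k + 2] = z;
  }
  return pts;
}

// Shrake-Rupley accessible surface area per atom.
// xyz: n x 3, radii: expanded radii (vdW + probe), n_dots per atom.
// [[Rcpp::export(name = ".cpp_sasa")]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii, int n_dots) {
  int n = xyz.nrow();
  std::vector<double> dots = sphere_dots(n_dots);
  NumericVector area(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), ri = radii[i];
    // neighbour prefilter
    std::vector<int> nb;
    double lim = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = ri + radii[j];
      if (d2 < rr * rr && d2 < lim * lim) nb.push_back(j);
    }
    int free_dots = 0;
    for (int k = 0; k < n_dots; ++k) {
      double px = xi + ri * dots[3 * k];
      double py = yi + ri * dots[3 * k + 1];
      double pz = zi + ri * dots[3 * k + 2];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < radii[j] * radii[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++free_dots;
    }
    area[i] = 4.0 * M_PI * ri * ri * free_dots / n_dots;
  }
  return area;
}

// Occluded-surface packing per atom: for each dot on the vdW sphere cast
// the outward normal ray; if it hits a neighbour's vdW sphere at ray
// length RL < rl_max the dot contributes (1 - RL/rl_max).  Atom OSP is the
// mean dot weight (in [0, 1]).
// [[Rcpp::export(name = ".cpp_osp")]]
NumericVector cpp_osp(NumericMatrix xyz, NumericVector radii, double rl_max,
                      int n_dots) {
  int n = xyz.nrow();
  std::vector<double> dots = sphere_dots(n_dots);
  NumericVector osp(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), ri = radii[i];
    std::vector<int> nb;
    double lim = ri + rl_max + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    double wsum = 0.0;
    for (int k = 0; k < n_dots; ++k) {
      double ux = dots[3 * k], uy = dots[3 * k + 1], uz = dots[3 * k + 2];
      double px = xi + ri * ux, py = yi + ri * uy, pz = zi + ri * uz;
      double best = rl_max;  // nearest intersection within rl_max
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j];
        double cx = xyz(j, 0) - px, cy = xyz(j, 1) - py, cz = xyz(j, 2) - pz;
        double c2 = cx * cx + cy * cy + cz * cz;
        if (c2 <= rj * rj) {   // dot already inside neighbour's sphere
          best = 0.0;
          break;
        }
        double b = cx * ux + cy * uy + cz * uz;  // projection on ray
        if (b <= 0.0) continue;                  // sphere behind the ray
        double disc = b * b - (c2 - rj * rj);
        if (disc <= 0.0) continue;               // ray misses the sphere
        double t = b - std::sqrt(disc);          // first intersection
        if (t >= 0.0 && t < best) best = t;
      }
      if (best < rl_max) wsum += 1.0 - best / rl_max;
    }
    osp[i] = wsum / n_dots;
  }
  return osp;
}
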