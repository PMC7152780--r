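#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial index over Voronoi seed points: square cells, each cell holds the
// indices of all seeds in its 3x3 neighbourhood so a single cell lookup
// yields every candidate within one cell size of the query point.
struct SeedGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector< std::vector<int> > cand;
  const double *sx, *sy;
  int n_seeds;

  SeedGrid(const NumericVector &sx_, const NumericVector &sy_, double cell_)
      : cell(cell_), sx(REAL(sx_)), sy(REAL(sy_)), n_seeds(sx_.size()) {
    double xmin = sx[0], xmax = sx[0], ymin = sy[0], ymax = sy[0];
    for (int i = 1; i < n_seeds; ++i) {
      xmin = std::min(xmin, sx[i]); xmax = std::max(xmax, sx[i]);
      ymin = std::min(ymin, sy[i]); ymax = std::max(ymax, sy[i]);
    }
    // pad so queries slightly outside the seed hull still land on the grid
    x0 = xmin - 2.0 * cell; y0 = ymin - 2.0 * cell;
    nx = (int)std::ceil((xmax - x0) / cell) + 3;
    ny = (int)std::ceil((ymax - y0) / cell) + 3;
    cand.assign((size_t)nx * ny, std::vector<int>());
    for (int i = 0; i < n_seeds; ++i) {
      int cx = (int)std::floor((sx[i] - x0) / cell);
      int cy = (int)std::floor((sy[i] - y0) / cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          int ax = cx + dx, ay = cy + dy;
          if (ax >= 0 && ax < nx && ay >= 0 && ay < ny)
            cand[(size_t)ax * ny + ay].push_back(i);
        }
    }
  }

  // nearest seed; exact (falls back to brute force when the candidate set
  // cannot be guaranteed to contain the true nearest neighbour)
  int nearest(double x, double y) const {
    int cx = (int)std::floor((x - x0) / cell);
    int cy = (int)std::floor((y - y0) / cell);
    int best = -1;
    double bd = R_PosInf;
    if (cx >= 0 && cx < nx && cy >= 0 && cy < ny) {
      const std::vector<int> &v = cand[(size_t)cx * ny + cy];
      for (size_t k = 0; k < v.size(); ++k) {
        double dx = sx[v[k]] - x, dy = sy[v[k]] - y;
        double d2 = dx * dx + dy * dy;
        if (d2 < bd || (d2 == bd && v[k] < best)) { bd = d2; best = v[k]; }
      }
      // distance to the border of the covered 3x3 block: if the best
      // candidate is closer than that, no seed outside can beat it
      double lx = x - (x0 + (cx - 1) * cell), rx = (x0 + (cx + 2) * cell) - x;
      double ly = y - (y0 + (cy - 1) * cell), ry = (y0 + (cy + 2) * cell) - y;
      double safe = std::min(std::min(lx, rx), std::min(ly, ry));
      if (best >= 0 && safe > 0 && bd <= safe * safe) return best;
    }
    best = -1; bd = R_PosInf;
    for (int i = 0; i < n_seeds; ++i) {
      double dx = sx[i] - x, dy = sy[i] - y;
      double d2 = dx * dx + dy * dy;
      if (d2 < bd) { bd = d2; best = i; }
    }
    return best;
  }
};

// Propagate molecules with trapping + corral hopping.
//
// Units: lengths nm, times ms, diffusion coefficients nm^2/ms.
// Per step: (1) trap/release with probability p_trap, (2) Gaussian
// displacement with per-axis variance 2*D*dt (D per current state),
// (3) antipodal wrap if the proposal leaves the circular arena,
// (4) if the (wrapped) proposal lies in a different Voronoi compartment
// the move is accepted with probability p_hop, otherwise rejected
// (molecule keeps its pre-step position).
// Unwrapped coordinates accumulate every accepted displacement without
// the wrap jumps, for mean-square-displacement analysis.
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector y0, LogicalVector trapped0,
                  NumericVector seed_x, NumericVector seed_y,
                  double arena_radius, int n_steps, double dt,
                  double d_free, double d_trap, double p_trap, double p_hop,
                  int record_stride, bool record_states, bool record_unwrapped,
                  double grid_cell) {
  const int n_mol = x0.size();
  const int n_rec = n_steps / record_stride + 1;
  SeedGrid grid(seed_x, seed_y, grid_cell);

  NumericMatrix rx(n_rec, n_mol), ry(n_rec, n_mol);
  NumericMatrix rux(record_unwrapped ? n_rec : 1,
                    record_unwrapped ? n_mol : 1);
  NumericMatrix ruy(record_unwrapped ? n_rec : 1,
                    record_unwrapped ? n_mol : 1);
  IntegerMatrix rtrap(record_states ? n_rec : 1, record_states ? n_mol : 1);
  IntegerMatrix rcomp(record_states ? n_rec : 1, record_states ? n_mol : 1);

  std::vector<double> x(n_mol), y(n_mol), ux(n_mol), uy(n_mol);
  std::vector<int> comp(n_mol), trapped(n_mol);
  for (int j = 0; j < n_mol; ++j) {
    x[j] = x0[j]; y[j] = y0[j]; ux[j] = x0[j]; uy[j] = y0[j];
    trapped[j] = trapped0[j] ? 1 : 0;
    comp[j] = grid.nearest(x[j], y[j]);
  }

  const double sd_free = std::sqrt(2.0 * d_free * dt);
  const double sd_trap = std::sqrt(2.0 * d_trap * dt);
  RNGScope scope;

  int rec = 0;
  for (int j = 0; j < n_mol; ++j) {
    rx(0, j) = x[j]; ry(0, j) = y[j];
    if (record_unwrapped) { rux(0, j) = ux[j]; ruy(0, j) = uy[j]; }
    if (record_states) { rtrap(0, j) = trapped[j]; rcomp(0, j) = comp[j] + 1; }
  }
  rec = 1;

  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < n_mol; ++j) {
      // trap/release before displacement; same probability both ways
      if (p_trap > 0.0 && unif_rand() < p_trap) trapped[j] = 1 - trapped[j];
      const double sd = trapped[j] ? sd_trap : sd_free;
      double ddx = sd * norm_rand(), ddy = sd * norm_rand();
      double px = x[j] + ddx, py = y[j] + ddy;
      // antipodal re-entry on the circular arena
      double r = std::sqrt(px * px + py * py);
      if (r > arena_radius) {
        double f = (2.0 * arena_radius - r) / r;
        px *= -f; py *= -f;
        r = std::sqrt(px * px + py * py);
        if (r > arena_radius) {  // pathological step >> arena: clamp
          px *= arena_radius / r; py *= arena_radius / r;
        }
      }
      // with p_hop = 1 every crossing is accepted, so the compartment
      // lookup is only needed when states are recorded
      if (p_hop >= 1.0 && !record_states) {
        x[j] = px; y[j] = py;
        ux[j] += ddx; uy[j] += ddy;
        continue;
      }
      int pc = grid.nearest(px, py);
      bool accept = true;
      if (pc != comp[j] && p_hop < 1.0)
        accept = (p_hop > 0.0) && (unif_rand() < p_hop);
      if (accept) {
        x[j] = px; y[j] = py; comp[j] = pc;
        ux[j] += ddx; uy[j] += ddy;
      }
    }
    if (s % record_stride == 0) {
      for (int j = 0; j < n_mol; ++j) {
        rx(rec, j) = x[j]; ry(rec, j) = y[j];
        if (record_unwrapped) { rux(rec, j) = ux[j]; ruy(rec, j) = uy[j]; }
        if (record_states) { rtrap(rec, j) = trapped[j]; rcomp(rec, j) = comp[j] + 1; }
      }
      ++rec;
    }
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["x"] = rx, _["y"] = ry);
  if (record_unwrapped) { out["ux"] = rux; out["uy"] = ruy; }
  if (record_states) { out["trapped"] = rtrap; out["compartment"] = rcomp; }
  return out;
}

// Intensity readout through Gaussian observation spots:
// I_k(t) = sum_j brightness * exp(-4*ln2 * r_jk(t)^2 / fwhm_k^2)
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_intensity(NumericMatrix x, NumericMatrix y,
                                     NumericVector cx, NumericVector cy,
                                     NumericVector fwhm, double brightness) {
  const int n_t = x.nrow(), n_mol = x.ncol(), n_spot = cx.size();
  NumericMatrix out(n_t, n_spot);
  const double ln2 = 0.6931471805599453;
  for (int k = 0; k < n_spot; ++k) {
    const double a = 4.0 * ln2 / (fwhm[k] * fwhm[k]);
    for (int t = 0; t < n_t; ++t) {
      double acc = 0.0;
      for (int j = 0; j < n_mol; ++j) {
        double dx = x(t, j) - cx[k], dy = y(t, j) - cy[k];
        acc += std::exp(-a * (dx * dx + dy * dy));
      }
      out(t, k) = brightness * acc;
    }
  }
  return out;
}

// Nearest-seed compartment lookup for arbitrary query points (R-side use).
// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(NumericVector qx, NumericVector qy,
                               NumericVector seed_x, NumericVector seed_y,
                               double grid_cell) {
  SeedGrid grid(seed_x, seed_y, grid_cell);
  const int n = qx.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = grid.nearest(qx[i], qy[i]) + 1;
  return out;
}
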