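// Deterministic streamline integration core.
//
// Fixed-step bidirectional Euler tracking over a voxel direction field:
// nearest-neighbour direction lookup, trilinear stopping-metric
// interpolation, sign alignment of the local direction with the incoming
// one, termination on the metric rule (floor or ceiling), on a turning
// angle >= the configured maximum, on an invalid/missing voxel or on
// leaving the grid.  Pure function of its inputs (seed positions are drawn
// by the caller), so tracking is reproducible bit-for-bit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Field {
  const double *dir;      // nx*ny*nz*3
  const double *metric;   // nx*ny*nz
  const int *valid;       // nx*ny*nz
  int nx, ny, nz;
  bool ceiling;           // true: stop when metric >= thr; false: <= thr
  double thr;

  inline bool in_grid(const double v[3]) const {
    return v[0] >= 0.0 && v[0] <= nx - 1.0 &&
           v[1] >= 0.0 && v[1] <= ny - 1.0 &&
           v[2] >= 0.0 && v[2] <= nz - 1.0;
  }
  inline int nn_index(const double v[3]) const {
    int i = (int)std::lround(v[0]);
    int j = (int)std::lround(v[1]);
    int k = (int)std::lround(v[2]);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return -1;
    return i + nx * (j + ny * k);
  }
  inline double interp_metric(const double v[3]) const {
    int i0 = (int)std::floor(v[0]), j0 = (int)std::floor(v[1]),
        k0 = (int)std::floor(v[2]);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = v[0] - i0, fy = v[1] - j0, fz = v[2] - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1.0 - fx) * (dj ? fy : 1.0 - fy) *
                     (dk ? fz : 1.0 - fz);
          if (w == 0.0) continue;
          double m = metric[(i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk))];
          if (!R_finite(m)) m = ceiling ? R_PosInf : 0.0;  // unfitted: terminal
          acc += w * m;
        }
    return acc;
  }
  inline bool metric_pass(const double v[3]) const {
    double m = interp_metric(v);
    return ceiling ? (m < thr) : (m > thr);
  }
  inline bool direction_at(const double v[3], double d[3]) const {
    int ix = nn_index(v);
    if (ix < 0 || !valid[ix]) return false;
    long n3 = (long)nx * ny * nz;
    d[0] = dir[ix]; d[1] = dir[ix + n3]; d[2] = dir[ix + 2 * n3];
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (!R_finite(nrm) || nrm < 0.5) return false;
    d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
    return true;
  }
};

inline void world_to_voxel(const double *inv, const double p[3], double v[3]) {
  for (int r = 0; r < 3; ++r)
    v[r] = inv[r] * p[0] + inv[r + 4] * p[1] + inv[r + 8] * p[2] + inv[r + 12];
}

// integrate one direction; returns number of points appended to buf (voxel
// coords are recomputed per step from world coords)
int integrate(const Field &f, const double *inv, double seed[3], double d0[3],
              double step, double cos_min, int max_pts,
              std::vector<double> &buf) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  int n = 0;
  while (n < max_pts) {
    double pn[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
    double v[3];
    world_to_voxel(inv, pn, v);
    if (!f.in_grid(v)) break;
    double dn[3];
    if (!f.direction_at(v, dn)) break;
    if (!f.metric_pass(v)) break;
    double dot = d[0] * dn[0] + d[1] * dn[1] + d[2] * dn[2];
    if (dot < 0) { dn[0] = -dn[0]; dn[1] = -dn[1]; dn[2] = -dn[2]; dot = -dot; }
    // turning angle between incoming segment and the direction we would
    // follow next; >= max angle terminates
    if (dot < cos_min) break;
    buf.push_back(pn[0]); buf.push_back(pn[1]); buf.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    d[0] = dn[0]; d[1] = dn[1]; d[2] = dn[2];
    ++n;
  }
  return n;
}

}  // namespace

// [[Rcpp::export(name = ".track_batch")]]
List track_batch(NumericVector dirfield, NumericVector metric,
                 IntegerVector valid, IntegerVector grid_dim,
                 NumericMatrix seeds_world, NumericMatrix inv_affine,
                 double step, double max_angle_deg, double threshold,
                 bool ceiling, double min_len, double max_len) {
  Field f;
  f.dir = REAL(dirfield); f.metric = REAL(metric); f.valid = INTEGER(valid);
  f.nx = grid_dim[0]; f.ny = grid_dim[1]; f.nz = grid_dim[2];
  f.ceiling = ceiling; f.thr = threshold;
  const double *inv = REAL(inv_affine);
  double cos_min = std::cos(max_angle_deg * M_PI / 180.0);
  int max_pts = (int)std::floor(max_len / step) + 2;

  int nseed = seeds_world.nrow();
  std::vector<NumericMatrix> kept;
  std::vector<double> fwd, bwd;
  for (int s = 0; s < nseed; ++s) {
    double seed[3] = {seeds_world(s, 0), seeds_world(s, 1), seeds_world(s, 2)};
    double v[3];
    world_to_voxel(inv, seed, v);
    double d0[3];
    if (!f.in_grid(v) || !f.direction_at(v, d0) || !f.metric_pass(v)) continue;
    fwd.clear(); bwd.clear();
    int nf = integrate(f, inv, seed, d0, step, cos_min, max_pts, fwd);
    double d0m[3] = {-d0[0], -d0[1], -d0[2]};
    int nb = integrate(f, inv, seed, d0m, step, cos_min, max_pts, bwd);
    int npts = nf + nb + 1;
    double len = (npts - 1) * step;
    if (len < min_len || len > max_len) continue;
    NumericMatrix sl(npts, 3);
    // backward points reversed, then seed, then forward
    for (int i = 0; i < nb; ++i)
      for (int c = 0; c < 3; ++c) sl(i, c) = bwd[3 * (nb - 1 - i) + c];
    for (int c = 0; c < 3; ++c) sl(nb, c) = seed[c];
    for (int i = 0; i < nf; ++i)
      for (int c = 0; c < 3; ++c) sl(nb + 1 + i, c) = fwd[3 * i + c];
    kept.push_back(sl);
  }
  List out((int)kept.size());
  for (size_t i = 0; i < kept.size(); ++i) out[i] = kept[i];
  return out;
}
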