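// Compiled inner loops of the Watson-NODDI voxel fit.
//
// The forward model is evaluated thousands of times per voxel inside the
// derivative-free refinement, so the sum-of-squares objective and the coarse
// grid search run compiled.  The algebra mirrors the R reference
// implementation (noddi_signal_fast); a test asserts the two agree to
// machine precision.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int LMAX = 24;           // even Legendre orders 0..24 -> 13 terms
const int NL = LMAX / 2 + 1;
const double D_PAR_C = 1.7e-3;

// P_0..P_24 at a single point, even orders written to out[0..NL-1]
inline void legendre_even(double t, double *out) {
  double pm2 = 1.0, pm1 = t;
  out[0] = 1.0;
  for (int l = 1; l < LMAX; ++l) {
    double p = ((2 * l + 1) * t * pm1 - l * pm2) / (l + 1);
    pm2 = pm1; pm1 = p;
    if ((l + 1) % 2 == 0) out[(l + 1) / 2] = p;
  }
}

// Watson moments p_l(kappa) (even orders) + tau = <(mu.n)^2>
// quad: nodes t_i (nq), weights w_i, Pl matrix (nq x NL, column-major)
inline void watson_moments_c(double kappa, int nq, const double *qt,
                             const double *qw, const double *qP,
                             double *pl, double *tau) {
  double den = 0.0;
  for (int j = 0; j < NL; ++j) pl[j] = 0.0;
  for (int i = 0; i < nq; ++i) {
    double w = qw[i] * std::exp(kappa * (qt[i] * qt[i] - 1.0));
    den += w;
    for (int j = 0; j < NL; ++j) pl[j] += w * qP[i + j * nq];
  }
  for (int j = 0; j < NL; ++j) pl[j] /= den;
  *tau = (2.0 * pl[1] + 1.0) / 3.0;
}

struct Scheme {
  int nframe, nq;
  const double *b, *gx, *gy, *gz, *iso, *cl;  // cl: NL x nframe
  const int *b0;
  const double *qt, *qw, *qP;
};

double sse_eval(const Scheme &s, const double *y, double viso, double vic,
                double kappa, const double mu[3]) {
  std::vector<double> pl(NL);
  double tau;
  watson_moments_c(kappa, s.nq, s.qt, s.qw, s.qP, pl.data(), &tau);
  double d_perp = D_PAR_C * (1.0 - vic);
  double dd = D_PAR_C - d_perp;
  double Pl[NL];
  double sse = 0.0;
  for (int f = 0; f < s.nframe; ++f) {
    double model;
    if (s.b0[f]) {
      model = 1.0;
    } else {
      double c = s.gx[f] * mu[0] + s.gy[f] * mu[1] + s.gz[f] * mu[2];
      legendre_even(c, Pl);
      double a_ic = 0.0;
      for (int j = 0; j < NL; ++j) a_ic += s.cl[j + f * NL] * pl[j] * Pl[j];
      double d_eff = d_perp + dd * (tau * c * c + (1.0 - tau) * (1.0 - c * c) / 2.0);
      double a_ec = std::exp(-s.b[f] * d_eff);
      model = (1.0 - viso) * (vic * a_ic + (1.0 - vic) * a_ec) + viso * s.iso[f];
    }
    double r = y[f] - model;
    sse += r * r;
  }
  return sse;
}

Scheme make_scheme(List pre) {
  Scheme s;
  NumericVector b = pre["b"], iso = pre["iso"], qt = pre["qt"], qw = pre["qw"];
  NumericMatrix g = pre["g"], cl = pre["clmat"], qP = pre["qP"];
  IntegerVector b0 = pre["b0int"];
  s.nframe = b.size(); s.nq = qt.size();
  s.b = REAL(b); s.iso = REAL(iso); s.qt = REAL(qt); s.qw = REAL(qw);
  s.gx = REAL(g); s.gy = s.gx + s.nframe; s.gz = s.gy + s.nframe;
  s.cl = REAL(cl); s.qP = REAL(qP); s.b0 = INTEGER(b0);
  return s;
}

}  // namespace

// Objective for the Nelder-Mead refinement: par = (logit viso, logit vic,
// log kappa [clamped to 0.01..64], theta, phi)
// [[Rcpp::export(name = ".noddi_sse")]]
double noddi_sse(NumericVector par, NumericVector y, List pre) {
  Scheme s = make_scheme(pre);
  double viso = 1.0 / (1.0 + std::exp(-par[0]));
  double vic = 1.0 / (1.0 + std::exp(-par[1]));
  double kappa = std::exp(par[2]);
  if (kappa < 0.01) kappa = 0.01;
  if (kappa > 64.0) kappa = 64.0;
  double mu[3] = {std::sin(par[3]) * std::cos(par[4]),
                  std::sin(par[3]) * std::sin(par[4]), std::cos(par[3])};
  return sse_eval(s, REAL(y), viso, vic, kappa, mu);
}

// Coarse grid search with the orientation fixed at mu0; kappa moments are
// recomputed per candidate (cheap relative to the frame loop)
// [[Rcpp::export(name = ".noddi_grid")]]
NumericVector noddi_grid(NumericVector y, NumericVector mu0, List pre,
                         NumericVector viso_grid, NumericVector vic_grid,
                         NumericVector kappa_grid) {
  Scheme s = make_scheme(pre);
  const double *yp = REAL(y);
  double mu[3] = {mu0[0], mu0[1], mu0[2]};

  // precompute per-frame a_ic per kappa and the angular factor
  int nf = s.nframe;
  std::vector<double> Pl_c(nf * NL), c2(nf);
  double Pl[NL];
  for (int f = 0; f < nf; ++f) {
    double c = s.gx[f] * mu[0] + s.gy[f] * mu[1] + s.gz[f] * mu[2];
    c2[f] = c * c;
    legendre_even(c, Pl);
    for (int j = 0; j < NL; ++j) Pl_c[f * NL + j] = Pl[j];
  }
  double best_sse = R_PosInf, best[3] = {0, 0, 1};
  std::vector<double> a_ic(nf), a_ec(nf), pl(NL);
  for (int ik = 0; ik < kappa_grid.size(); ++ik) {
    double kappa = kappa_grid[ik], tau;
    watson_moments_c(kappa, s.nq, s.qt, s.qw, s.qP, pl.data(), &tau);
    for (int f = 0; f < nf; ++f) {
      if (s.b0[f]) { a_ic[f] = 1.0; continue; }
      double acc = 0.0;
      for (int j = 0; j < NL; ++j) acc += s.cl[j + f * NL] * pl[j] * Pl_c[f * NL + j];
      a_ic[f] = acc;
    }
    for (int iv = 0; iv < vic_grid.size(); ++iv) {
      double vic = vic_grid[iv];
      double d_perp = D_PAR_C * (1.0 - vic), dd = D_PAR_C - d_perp;
      for (int f = 0; f < nf; ++f) {
        if (s.b0[f]) { a_ec[f] = 1.0; continue; }
        double d_eff = d_perp + dd * (tau * c2[f] + (1.0 - tau) * (1.0 - c2[f]) / 2.0);
        a_ec[f] = std::exp(-s.b[f] * d_eff);
      }
      for (int is = 0; is < viso_grid.size(); ++is) {
        double viso = viso_grid[is];
        double sse = 0.0;
        for (int f = 0; f < nf; ++f) {
          double a_tis = vic * a_ic[f] + (1.0 - vic) * a_ec[f];
          double model = s.b0[f] ? 1.0
            : (1.0 - viso) * a_tis + viso * s.iso[f];
          double r = yp[f] - model;
          sse += r * r;
        }
        if (sse < best_sse) {
          best_sse = sse;
          best[0] = viso; best[1] = vic; best[2] = kappa;
        }
      }
    }
  }
  return NumericVector::create(best[0], best[1], best[2], best_sse);
}
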