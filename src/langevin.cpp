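// Langevin engines built on the exact Ornstein-Uhlenbeck propagator over one
// time step with the force frozen at the step's start:
//   v' = e^{-g h} v + (f/(M g)) (1 - e^{-g h}) + dv
//   x' = x + v (1 - e^{-g h})/g + (f/M) (h - (1 - e^{-g h})/g)/g + dx
// (dv, dx) are jointly Gaussian with the exact OU covariance
//   var(dv)    = (kT/M) (1 - e^{-2 g h})
//   var(dx)    = (kT/(M g^2)) (2 g h - 3 + 4 e^{-g h} - e^{-2 g h})
//   cov(dx,dv) = (kT/(M g)) (1 - e^{-g h})^2
// With the noise off and a constant force this reduces to the deterministic
// position recurrence with kernels (1 - e^{-g h})/g, which composes exactly
// across step subdivisions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "xrng.h"
using namespace Rcpp;

struct OUCoef {
  double ev;        // e^{-g h}
  double cxv;       // position coefficient of v
  double cxf;       // position coefficient of f/M... actually of f (includes 1/M)
  double cvf;       // velocity coefficient of f (includes 1/M)
  double sdv;       // sqrt var(dv)
  double c_xv;      // cov(dx,dv)/var(dv)
  double sdx_cond;  // sqrt(var(dx) - cov^2/var(dv))
  bool noise;
};

static OUCoef ou_coeffs(double gamma, double kT, double M, double h,
                        bool noise_on) {
  OUCoef c;
  if (gamma <= 0.0) { // ballistic limit; fluctuation-dissipation gives zero noise
    c.ev = 1.0; c.cxv = h; c.cxf = 0.5 * h * h / M; c.cvf = h / M;
    c.sdv = c.c_xv = c.sdx_cond = 0.0; c.noise = false;
    return c;
  }
  double w = gamma * h;
  double em = std::exp(-w);
  double one_em = -std::expm1(-w);      // 1 - e^{-w}, stable
  c.ev = em;
  c.cxv = one_em / gamma;
  c.cvf = one_em / (gamma * M);
  c.cxf = (h - one_em / gamma) / (gamma * M);
  if (noise_on && kT > 0.0) {
    double svv2 = (kT / M) * (-std::expm1(-2.0 * w));
    double S; // 2w - 3 + 4 e^{-w} - e^{-2w}, series for small w (cancellation)
    if (w < 1e-3) {
      S = (2.0 / 3.0) * w * w * w *
          (1.0 - 0.75 * w + 0.35 * w * w - 17.0 / 120.0 * w * w * w);
    } else {
      S = 2.0 * w - 3.0 + 4.0 * em - em * em;
    }
    double sxx2 = (kT / (M * gamma * gamma)) * S;
    double sxv = (kT / (M * gamma)) * one_em * one_em;
    c.sdv = std::sqrt(svv2);
    c.c_xv = sxv / svv2;
    double cond = sxx2 - sxv * sxv / svv2;
    c.sdx_cond = cond > 0.0 ? std::sqrt(cond) : 0.0;
    c.noise = true;
  } else {
    c.sdv = c.c_xv = c.sdx_cond = 0.0;
    c.noise = false;
  }
  return c;
}

static inline void ou_advance(double &x, double &v, double f, const OUCoef &c,
                              XRng &rng) {
  double xn = x + c.cxv * v + c.cxf * f;
  double vn = c.ev * v + c.cvf * f;
  if (c.noise) {
    double n1 = rng.gauss(), n2 = rng.gauss();
    double dv = c.sdv * n1;
    double dx = c.c_xv * dv + c.sdx_cond * n2;
    xn += dx; vn += dv;
  }
  x = xn; v = vn;
}

// Single 1-D particle, optional harmonic tether (stiffness k about 0) and
// constant force.  Samples (x, v) every `stride` steps.
// [[Rcpp::export(name = ".cpp_lv_single")]]
List cpp_lv_single(int n_samples, int stride, double gamma, double kT,
                   double M, double dt, double f_const, double k_spring,
                   double x0, double v0, bool noise_on, double seed) {
  XRng rng((uint64_t)seed);
  OUCoef c = ou_coeffs(gamma, kT, M, dt, noise_on);
  NumericVector xs(n_samples), vs(n_samples);
  double x = x0, v = v0;
  for (int i = 0; i < n_samples; ++i) {
    for (int s = 0; s < stride; ++s) {
      double f = f_const - k_spring * x;
      ou_advance(x, v, f, c, rng);
    }
    xs[i] = x; vs[i] = v;
  }
  return List::create(_["x"] = xs, _["v"] = vs);
}

// First-passage times of a single 1-D particle over the concave potential
// U(x) = -b1 x^2 + b2 x (force 2 b1 x - b2), reflecting at 0, absorbed at L.
// [[Rcpp::export(name = ".cpp_lv_barrier_fpt")]]
NumericVector cpp_lv_barrier_fpt(int n_events, double b1, double b2, double L,
                                 double gamma, double kT, double M, double dt,
                                 double x0, double max_steps_d, bool noise_on,
                                 double seed) {
  XRng rng((uint64_t)seed);
  OUCoef c = ou_coeffs(gamma, kT, M, dt, noise_on);
  long long max_steps = (long long)max_steps_d;
  NumericVector out(n_events);
  for (int e = 0; e < n_events; ++e) {
    double x = x0, v = 0.0;
    long long step = 0;
    bool hit = false;
    while (step < max_steps) {
      double f = 2.0 * b1 * x - b2;
      ou_advance(x, v, f, c, rng);
      ++step;
      if (x < 0.0) { x = -x; v = -v; }
      if (x >= L) { hit = true; break; }
    }
    out[e] = hit ? step * dt : NA_REAL;
  }
  return out;
}

// ---- bead-spring chain in a slit/pore geometry -----------------------------

struct ChainParams {
  int N, dim;
  double dt, gamma, kT, M, bond_k, bond_a;
  bool ev_on; double ev_k, ev_r;
  bool wall_on; double wall_x0, wall_th, pore_r, wall_k;
  int drive_mode; // 0 none, 1 uniform, 2 in-pore, 3 end force (bead 0)
  double drive_f;
  bool frozen0;   // hold bead 0 fixed (equilibration)
  bool noise_on;
};

static void chain_forces(const std::vector<double> &x, std::vector<double> &F,
                         const ChainParams &p) {
  const int N = p.N, dim = p.dim;
  std::fill(F.begin(), F.end(), 0.0);
  // harmonic bonds between consecutive beads
  for (int i = 0; i < N - 1; ++i) {
    double d[3] = {0, 0, 0}, r2 = 0.0;
    for (int k = 0; k < dim; ++k) {
      d[k] = x[(i + 1) * dim + k] - x[i * dim + k];
      r2 += d[k] * d[k];
    }
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    double fmag = p.bond_k * (r - p.bond_a) / r;
    for (int k = 0; k < dim; ++k) {
      F[i * dim + k] += fmag * d[k];
      F[(i + 1) * dim + k] -= fmag * d[k];
    }
  }
  // soft purely repulsive excluded volume (optional)
  if (p.ev_on) {
    double rc = p.ev_r;
    for (int i = 0; i < N; ++i)
      for (int j = i + 2; j < N; ++j) {
        double d[3] = {0, 0, 0}, r2 = 0.0;
        for (int k = 0; k < dim; ++k) {
          d[k] = x[j * dim + k] - x[i * dim + k];
          r2 += d[k] * d[k];
        }
        if (r2 >= rc * rc || r2 < 1e-24) continue;
        double r = std::sqrt(r2);
        double fmag = p.ev_k * (rc - r) / r;
        for (int k = 0; k < dim; ++k) {
          F[i * dim + k] -= fmag * d[k];
          F[j * dim + k] += fmag * d[k];
        }
      }
  }
  // impenetrable membrane with a slit/cylindrical opening: half-harmonic
  // repulsion along x from the nearest face for beads inside the slab whose
  // transverse position lies outside the opening
  if (p.wall_on) {
    double x1 = p.wall_x0 + p.wall_th;
    for (int i = 0; i < N; ++i) {
      double xi = x[i * dim + 0];
      if (xi <= p.wall_x0 || xi >= x1) continue;
      double t2 = 0.0;
      for (int k = 1; k < dim; ++k) t2 += x[i * dim + k] * x[i * dim + k];
      if (t2 < p.pore_r * p.pore_r) continue; // threading the opening
      double dl = xi - p.wall_x0, dr = x1 - xi;
      if (dl <= dr) F[i * dim + 0] -= p.wall_k * dl;
      else F[i * dim + 0] += p.wall_k * dr;
    }
  }
  // driving force along +x
  if (p.drive_mode == 1) {
    for (int i = 0; i < N; ++i) F[i * dim + 0] += p.drive_f;
  } else if (p.drive_mode == 2) {
    double x1 = p.wall_x0 + p.wall_th;
    for (int i = 0; i < N; ++i) {
      double xi = x[i * dim + 0];
      if (xi > p.wall_x0 && xi < x1) F[i * dim + 0] += p.drive_f;
    }
  } else if (p.drive_mode == 3) {
    F[0] += p.drive_f;
  }
}

// [[Rcpp::export(name = ".cpp_lv_chain")]]
List cpp_lv_chain(NumericMatrix pos, NumericMatrix vel, double n_steps_d,
                  double dt, double gamma, double kT, double M, double bond_k,
                  double bond_a, bool ev_on, double ev_k, double ev_r,
                  bool wall_on, double wall_x0, double wall_th, double pore_r,
                  double wall_k, int drive_mode, double drive_f, bool frozen0,
                  bool noise_on, bool stop_when_crossed, double seed) {
  ChainParams p;
  p.dim = pos.nrow(); p.N = pos.ncol();
  if (p.dim != 2 && p.dim != 3) stop("positions must be dim x N with dim 2 or 3");
  if (vel.nrow() != p.dim || vel.ncol() != p.N)
    stop("velocity array must match positions");
  p.dt = dt; p.gamma = gamma; p.kT = kT; p.M = M;
  p.bond_k = bond_k; p.bond_a = bond_a;
  p.ev_on = ev_on; p.ev_k = ev_k; p.ev_r = ev_r;
  p.wall_on = wall_on; p.wall_x0 = wall_x0; p.wall_th = wall_th;
  p.pore_r = pore_r; p.wall_k = wall_k;
  p.drive_mode = drive_mode; p.drive_f = drive_f;
  p.frozen0 = frozen0; p.noise_on = noise_on;

  XRng rng((uint64_t)seed);
  OUCoef c = ou_coeffs(gamma, kT, M, dt, noise_on);
  const int n = p.N * p.dim;
  std::vector<double> x(n), v(n), F(n);
  for (int i = 0; i < p.N; ++i)
    for (int k = 0; k < p.dim; ++k) {
      x[i * p.dim + k] = pos(k, i);
      v[i * p.dim + k] = vel(k, i);
    }
  double midx = wall_x0 + 0.5 * wall_th;
  long long n_steps = (long long)n_steps_d, step = 0;
  bool crossed = false;
  int m_count = 0;
  for (; step < n_steps; ++step) {
    chain_forces(x, F, p);
    int start = p.frozen0 ? 1 : 0;
    for (int i = start; i < p.N; ++i)
      for (int k = 0; k < p.dim; ++k)
        ou_advance(x[i * p.dim + k], v[i * p.dim + k], F[i * p.dim + k], c, rng);
    if (stop_when_crossed) {
      m_count = 0;
      for (int i = 0; i < p.N; ++i)
        if (x[i * p.dim + 0] > midx) ++m_count;
      if (m_count == p.N) { crossed = true; ++step; break; }
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (!stop_when_crossed) {
    m_count = 0;
    for (int i = 0; i < p.N; ++i)
      if (x[i * p.dim + 0] > midx) ++m_count;
  }
  NumericMatrix pos_out(p.dim, p.N), vel_out(p.dim, p.N);
  for (int i = 0; i < p.N; ++i)
    for (int k = 0; k < p.dim; ++k) {
      pos_out(k, i) = x[i * p.dim + k];
      vel_out(k, i) = v[i * p.dim + k];
    }
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["steps_done"] = (double)step,
                      _["m_count"] = m_count, _["crossed"] = crossed);
}
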