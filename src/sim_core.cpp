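// Compiled core: minimum-image pair search (cell list), WCA forces,
// alignment + cohesion torques, and the Euler-Maruyama integration loop.
// All distances in sigma, energies in kBT, times in tau_R (D_R = 1).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// Accumulates WCA forces and alignment/cohesion torques for one pair (i, j).
// dx, dy is the minimum-image separation r_i - r_j.
struct PairAccum {
  double eps, sigma2, rc2, T0, invratio, tcut2, min_sep2;
  std::vector<double>* fx;
  std::vector<double>* fy;
  std::vector<double>* tq;
  const std::vector<double>* cphi;
  const std::vector<double>* sphi;
  const double* phi;
  bool overlap;

  inline void operator()(int i, int j, double dx, double dy) {
    const double r2 = dx * dx + dy * dy;
    if (r2 < min_sep2) { overlap = true; return; }
    if (r2 < rc2) {
      const double s2 = sigma2 / r2;
      const double s6 = s2 * s2 * s2;
      const double s12 = s6 * s6;
      const double f_over_r2 = 24.0 * eps * (2.0 * s12 - s6) / r2;
      (*fx)[i] += f_over_r2 * dx;
      (*fy)[i] += f_over_r2 * dy;
      (*fx)[j] -= f_over_r2 * dx;
      (*fy)[j] -= f_over_r2 * dy;
    }
    if (tcut2 > 0.0 && r2 < tcut2) {
      const double r = std::sqrt(r2);
      const double rx = dx / r, ry = dy / r;
      const double sin_ji = std::sin(phi[j] - phi[i]);
      // torque on i: T_A sin(phi_j - phi_i) - T_C sin(theta_{u_i, rhat_ij})
      // with sin(theta) = u_i x rhat = cos(phi_i) ry - sin(phi_i) rx
      (*tq)[i] += T0 * (sin_ji - invratio * ((*cphi)[i] * ry - (*sphi)[i] * rx));
      // torque on j uses rhat_ji = -rhat_ij
      (*tq)[j] += T0 * (-sin_ji - invratio * (-(*cphi)[j] * ry + (*sphi)[j] * rx));
    }
  }
};

// Visit every unordered pair within `cutoff` (minimum image) exactly once.
template <typename F>
static void for_each_pair(const std::vector<double>& x,
                          const std::vector<double>& y,
                          double L, double cutoff, F& visit) {
  const int N = (int)x.size();
  const double cut2 = cutoff * cutoff;
  int nc = (int)std::floor(L / cutoff);
  const int cap = std::max(4, 2 * ((int)std::sqrt((double)N) + 1));
  if (nc > cap) nc = cap;

  if (nc < 4 || N < 32) {  // brute force for small systems / boxes
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        const double dx = min_image(x[i] - x[j], L);
        const double dy = min_image(y[i] - y[j], L);
        if (dx * dx + dy * dy < cut2) visit(i, j, dx, dy);
      }
    }
    return;
  }

  std::vector<int> head(nc * nc, -1), nxt(N);
  for (int i = 0; i < N; ++i) {
    int cx = (int)(x[i] / L * nc);
    int cy = (int)(y[i] / L * nc);
    if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
    if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
    const int c = cy * nc + cx;
    nxt[i] = head[c];
    head[c] = i;
  }
  // half stencil so each cell pair is visited once
  const int offs[4][2] = {{1, 0}, {1, 1}, {0, 1}, {-1, 1}};
  for (int cy = 0; cy < nc; ++cy) {
    for (int cx = 0; cx < nc; ++cx) {
      const int c = cy * nc + cx;
      for (int i = head[c]; i >= 0; i = nxt[i]) {
        for (int j = nxt[i]; j >= 0; j = nxt[j]) {
          const double dx = min_image(x[i] - x[j], L);
          const double dy = min_image(y[i] - y[j], L);
          if (dx * dx + dy * dy < cut2) visit(i, j, dx, dy);
        }
      }
      for (int k = 0; k < 4; ++k) {
        const int ncx = (cx + offs[k][0] + nc) % nc;
        const int ncy = (cy + offs[k][1] + nc) % nc;
        const int c2 = ncy * nc + ncx;
        for (int i = head[c]; i >= 0; i = nxt[i]) {
          for (int j = head[c2]; j >= 0; j = nxt[j]) {
            const double dx = min_image(x[i] - x[j], L);
            const double dy = min_image(y[i] - y[j], L);
            if (dx * dx + dy * dy < cut2) visit(i, j, dx, dy);
          }
        }
      }
    }
  }
}

static void compute_forces_torques(const std::vector<double>& x,
                                   const std::vector<double>& y,
                                   const std::vector<double>& phi,
                                   double L, double eps, double sigma,
                                   double T0, double ratio, double Rcut,
                                   double min_sep,
                                   std::vector<double>& fx,
                                   std::vector<double>& fy,
                                   std::vector<double>& tq) {
  const int N = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(tq.begin(), tq.end(), 0.0);
  const double rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  const double tcut = (T0 > 0.0) ? Rcut : 0.0;
  const double cutoff = std::max(rc, tcut);

  std::vector<double> cphi(N), sphi(N);
  for (int i = 0; i < N; ++i) { cphi[i] = std::cos(phi[i]); sphi[i] = std::sin(phi[i]); }

  PairAccum acc;
  acc.eps = eps; acc.sigma2 = sigma * sigma; acc.rc2 = rc * rc;
  acc.T0 = T0; acc.invratio = 1.0 / ratio;
  acc.tcut2 = tcut * tcut; acc.min_sep2 = min_sep * min_sep;
  acc.fx = &fx; acc.fy = &fy; acc.tq = &tq;
  acc.cphi = &cphi; acc.sphi = &sphi; acc.phi = phi.data();
  acc.overlap = false;

  for_each_pair(x, y, L, cutoff, acc);
  if (acc.overlap)
    stop("pair separation below the minimum allowed distance; reduce dt");
}

// [[Rcpp::export]]
List cpp_forces_torques(NumericMatrix pos, NumericVector phi, double L,
                        double eps, double sigma, double T0, double ratio,
                        double Rcut, double min_sep) {
  const int N = pos.nrow();
  std::vector<double> x(N), y(N), ph(N), fx(N), fy(N), tq(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); ph[i] = phi[i]; }
  compute_forces_torques(x, y, ph, L, eps, sigma, T0, ratio, Rcut, min_sep,
                         fx, fy, tq);
  NumericMatrix F(N, 2);
  NumericVector T(N);
  for (int i = 0; i < N; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; T[i] = tq[i]; }
  return List::create(_["force"] = F, _["torque"] = T);
}

struct PairCollect {
  std::vector<double> rows;  // i, j (0-based), dx, dy, r
  inline void operator()(int i, int j, double dx, double dy) {
    const double r = std::sqrt(dx * dx + dy * dy);
    rows.push_back(i); rows.push_back(j);
    rows.push_back(dx); rows.push_back(dy); rows.push_back(r);
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_build_pairs(NumericMatrix pos, double L, double cutoff) {
  const int N = pos.nrow();
  std::vector<double> x(N), y(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  PairCollect pc;
  for_each_pair(x, y, L, cutoff, pc);
  const int np = (int)pc.rows.size() / 5;
  NumericMatrix out(2 * np, 5);  // both ordered directions
  for (int p = 0; p < np; ++p) {
    const double i = pc.rows[5 * p], j = pc.rows[5 * p + 1];
    const double dx = pc.rows[5 * p + 2], dy = pc.rows[5 * p + 3];
    const double r = pc.rows[5 * p + 4];
    out(2 * p, 0) = i + 1; out(2 * p, 1) = j + 1;
    out(2 * p, 2) = dx;    out(2 * p, 3) = dy;    out(2 * p, 4) = r;
    out(2 * p + 1, 0) = j + 1; out(2 * p + 1, 1) = i + 1;
    out(2 * p + 1, 2) = -dx;   out(2 * p + 1, 3) = -dy;   out(2 * p + 1, 4) = r;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericVector phi0, IntegerMatrix image0,
                  double L, double v0, double mu, double D, double muR,
                  double DR, double eps, double sigma, double T0, double ratio,
                  double Rcut, double dt, int n_equil, int n_collect,
                  int sample_every, double min_sep,
                  double noise_trans, double noise_rot) {
  const int N = pos0.nrow();
  std::vector<double> x(N), y(N), ph(N), fx(N), fy(N), tq(N);
  std::vector<int> imx(N), imy(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); ph[i] = phi0[i];
    imx[i] = image0(i, 0); imy[i] = image0(i, 1);
  }

  const int n_samp = 1 + n_collect / sample_every;
  NumericVector times(n_samp);
  NumericVector pos_out(Dimension(n_samp, N, 2));
  IntegerVector img_out(Dimension(n_samp, N, 2));
  NumericMatrix phi_out(n_samp, N);

  const double sq_t = noise_trans * std::sqrt(2.0 * D * dt);
  const double sq_r = noise_rot * std::sqrt(2.0 * DR * dt);
  const double twopi = 2.0 * M_PI;

  int samp = 0;
  auto record = [&](int step_collect) {
    times[samp] = step_collect * dt;
    for (int i = 0; i < N; ++i) {
      pos_out[samp + n_samp * i] = x[i];
      pos_out[samp + n_samp * (i + N)] = y[i];
      img_out[samp + n_samp * i] = imx[i];
      img_out[samp + n_samp * (i + N)] = imy[i];
      phi_out(samp, i) = ph[i];
    }
    ++samp;
  };

  const long total = (long)n_equil + n_collect;
  for (long s = 0; s <= total; ++s) {
    if (s >= n_equil) {
      const long c = s - n_equil;
      if (c % sample_every == 0 && samp < n_samp) record((int)c);
      if (c >= n_collect) break;
    }
    compute_forces_torques(x, y, ph, L, eps, sigma, T0, ratio, Rcut, min_sep,
                           fx, fy, tq);
    for (int i = 0; i < N; ++i) {
      const double nx = (noise_trans > 0.0) ? norm_rand() : 0.0;
      const double ny = (noise_trans > 0.0) ? norm_rand() : 0.0;
      const double na = (noise_rot > 0.0) ? norm_rand() : 0.0;
      double xi = x[i] + (v0 * std::cos(ph[i]) + mu * fx[i]) * dt + sq_t * nx;
      double yi = y[i] + (v0 * std::sin(ph[i]) + mu * fy[i]) * dt + sq_t * ny;
      double pi_new = ph[i] + muR * tq[i] * dt + sq_r * na;
      if (!std::isfinite(xi) || !std::isfinite(yi) || !std::isfinite(pi_new))
        stop("non-finite update at step %ld: integration unstable, reduce dt", s);
      // rewrap into [0, L), book-keeping periodic images
      const double wx = std::floor(xi / L);
      const double wy = std::floor(yi / L);
      imx[i] += (int)wx; imy[i] += (int)wy;
      x[i] = xi - wx * L; y[i] = yi - wy * L;
      // wrap phi to (-pi, pi]
      pi_new = pi_new - twopi * std::floor((pi_new + M_PI) / twopi);
      if (pi_new <= -M_PI) pi_new += twopi;
      ph[i] = pi_new;
    }
    if (s % 20000 == 0) checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["pos"] = pos_out,
                      _["image"] = img_out, _["phi"] = phi_out);
}
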