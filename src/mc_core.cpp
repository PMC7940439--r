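#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brownian-dynamics simulation of calcium ions in a hemispherical shell
// with a partially absorbing sensor at the centre.
//
// Geometry: reflecting hemisphere of radius R over the plane z = 0,
// sensor = hemisphere of radius rho at the origin.  Free ions take
// Gaussian steps with diffusion coefficient D0; buffer-bound ions use the
// buffer's coefficient (0 = immobile).  Buffer exchange is a per-step
// Markov transition with exact exponential probabilities.  A step that
// crosses the sensor sphere binds with the Robin-consistent surface
// probability kappa*sqrt(pi*dt/D0) (or always, for a perfectly absorbing
// sensor), otherwise reflects.  Bound ions unbind after an exponential
// waiting time 1/koff and restart just outside the sensor surface.
//
// event codes: 1 = bind, 2 = unbind

struct Ion {
  double x, y, z;
  int buf;        // 0 free, i >= 1 bound to buffer i
  bool bound;     // on sensor
  bool active;    // has entered
  double t_unbind;
  double entry;
};

// [[Rcpp::export(name = ".mc_core")]]
List mc_core(double R, double rho, double D0, double kappa, bool absorb,
             double koff,
             NumericVector bufD, NumericVector buf_k0i, NumericVector buf_ki0,
             IntegerVector ion_trial, NumericVector ion_entry,
             NumericVector ion_r,
             double dt, double horizon, int capacity, double burnin) {
  const int n_ions = ion_trial.size();
  int n_trials = 0;
  for (int i = 0; i < n_ions; ++i)
    if (ion_trial[i] + 1 > n_trials) n_trials = ion_trial[i] + 1;
  const int M = bufD.size();

  const double p_bind = absorb ? 1.0 : kappa * std::sqrt(M_PI * dt / D0);
  const double sig0 = std::sqrt(2.0 * D0 * dt);
  std::vector<double> sigb(M), p_rel(M);
  double ktot = 0.0;
  for (int m = 0; m < M; ++m) {
    sigb[m] = std::sqrt(2.0 * bufD[m] * dt);
    p_rel[m] = 1.0 - std::exp(-buf_ki0[m] * dt);
    ktot += buf_k0i[m];
  }
  const double p_cap = (M > 0) ? 1.0 - std::exp(-ktot * dt) : 0.0;

  std::vector<int> ev_trial; std::vector<double> ev_time;
  std::vector<int> ev_code;
  // time spent per (trial, buffer state incl. free) for equilibrium checks
  NumericMatrix state_time(n_trials, M + 1);

  RNGScope scope;

  // group ions by trial (input is expected sorted by trial, but be safe)
  std::vector< std::vector<int> > by_trial(n_trials);
  for (int i = 0; i < n_ions; ++i) by_trial[ion_trial[i]].push_back(i);

  const long n_steps = (long)std::ceil(horizon / dt);

  for (int tr = 0; tr < n_trials; ++tr) {
    const std::vector<int>& idx = by_trial[tr];
    const int ni = idx.size();
    std::vector<Ion> ions(ni);
    for (int k = 0; k < ni; ++k) {
      int i = idx[k];
      ions[k].x = ion_r[i]; ions[k].y = 0.0; ions[k].z = 0.0;
      ions[k].buf = 0; ions[k].bound = false; ions[k].active = false;
      ions[k].entry = ion_entry[i];
      ions[k].t_unbind = R_PosInf;
    }
    int bound_count = 0;

    for (long s = 0; s < n_steps; ++s) {
      const double t0 = s * dt, t1 = t0 + dt;
      for (int k = 0; k < ni; ++k) {
        Ion& io = ions[k];
        if (!io.active) {
          if (io.entry <= t1) io.active = true;
          else continue;
        }
        if (io.bound) {
          if (io.t_unbind <= t1) {
            // unbind: restart at sensor surface, random upper direction
            double u = unif_rand(), v = unif_rand();
            double cth = u;                 // z >= 0 hemisphere
            double sth = std::sqrt(1.0 - cth * cth);
            double ph = 2.0 * M_PI * v;
            double rr = rho * (1.0 + 1e-9);
            io.x = rr * sth * std::cos(ph);
            io.y = rr * sth * std::sin(ph);
            io.z = rr * cth;
            io.bound = false; io.buf = 0;
            --bound_count;
            ev_trial.push_back(tr + 1); ev_time.push_back(io.t_unbind);
            ev_code.push_back(2);
            io.t_unbind = R_PosInf;
          } else continue;
        }
        if (t1 > burnin) state_time(tr, io.buf) += dt;
        // buffer exchange
        if (io.buf == 0) {
          if (M > 0 && unif_rand() < p_cap) {
            double pick = unif_rand() * ktot, acc = 0.0;
            for (int m = 0; m < M; ++m) {
              acc += buf_k0i[m];
              if (pick <= acc) { io.buf = m + 1; break; }
            }
          }
        } else {
          if (unif_rand() < p_rel[io.buf - 1]) io.buf = 0;
        }
        // diffusive displacement
        const double sig = (io.buf == 0) ? sig0 : sigb[io.buf - 1];
        if (sig > 0.0) {
          double nx = io.x + sig * norm_rand();
          double ny = io.y + sig * norm_rand();
          double nz = io.z + sig * norm_rand();
          // perfectly absorbing sensor: a Brownian bridge may touch the
          // surface even when the endpoint stays outside; the radial
          // excursion probability exp(-d1 d2 / (D dt)) captures it
          if (absorb && io.buf == 0 &&
              (capacity == 0 || bound_count < capacity)) {
            double r_old = std::sqrt(io.x * io.x + io.y * io.y + io.z * io.z);
            double r_new = std::sqrt(nx * nx + ny * ny + nz * nz);
            if (r_new > rho) {
              double d1 = r_old - rho, d2 = r_new - rho;
              if (d1 > 0.0 && d2 > 0.0 &&
                  unif_rand() < std::exp(-d1 * d2 / (D0 * dt))) {
                io.bound = true;
                ++bound_count;
                ev_trial.push_back(tr + 1); ev_time.push_back(t1);
                ev_code.push_back(1);
                if (koff > 0.0) io.t_unbind = t1 + exp_rand() / koff;
                else io.t_unbind = R_PosInf;
                continue;
              }
            }
          }
          // resolve boundaries (few iterations suffice for small steps)
          for (int it = 0; it < 12; ++it) {
            if (nz < 0.0) { nz = -nz; continue; }
            double r2 = nx * nx + ny * ny + nz * nz;
            double rr = std::sqrt(r2);
            if (rr > R) {
              double f = (2.0 * R - rr) / rr;
              nx *= f; ny *= f; nz *= f;
              continue;
            }
            if (rr < rho) {
              bool can_bind = (io.buf == 0) &&
                (capacity == 0 || bound_count < capacity);
              if (can_bind && unif_rand() < p_bind) {
                io.bound = true;
                ++bound_count;
                double tb = t1;
                ev_trial.push_back(tr + 1); ev_time.push_back(tb);
                ev_code.push_back(1);
                if (koff > 0.0)
                  io.t_unbind = tb + exp_rand() / koff;
                else io.t_unbind = R_PosInf;
              } else {
                double f = (2.0 * rho - rr) / rr;
                if (rr < 1e-12) { f = 1.0; nx = rho; ny = 0; nz = 0; }
                else { nx *= f; ny *= f; nz *= f; }
                continue;
              }
            }
            break;
          }
          if (!io.bound) {
            // safety: confine in case iterative reflection failed
            double rr = std::sqrt(nx * nx + ny * ny + nz * nz);
            if (rr > R || rr < rho || nz < 0.0)
              stop("mc_core: ion escaped the domain after reflection");
            io.x = nx; io.y = ny; io.z = nz;
          }
        }
      }
    }
  }
  return List::create(
    _["trial"] = wrap(ev_trial),
    _["time"] = wrap(ev_time),
    _["code"] = wrap(ev_code),
    _["state_time"] = state_time,
    _["n_trials"] = n_trials);
}
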