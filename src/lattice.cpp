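#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mass-spring voxel lattice integrator (semi-implicit Euler).
//
// One particle per voxel; spring-like beams connect axis-adjacent
// particles, with per-beam resting length refreshed every step as the
// average of the two incident voxels' current lengths (ballistic resting
// length + damped sinusoidal actuation).  Rotational stiffness of the
// beams is approximated by straightness springs spanning each collinear
// beam pair.  Ground contact is a one-sided penalty spring with viscous
// normal damping and impulse-capped Coulomb friction.
//
// Forces are accumulated per particle over its neighbor slots in a fixed
// direction order (x-, x+, y-, y+, z-, z+), every pairwise term is
// computed from the particle's own side, and each direction pair is
// summed on its own before pair sums are combined.  A reflection along
// any axis then only swaps the two terms of one two-term sum, which IEEE
// addition performs commutatively, so a mirror-symmetric robot follows an
// exactly mirror-symmetric trajectory even though the frictional contact
// dynamics is chaotic.
//
// Units: cm, g, s (gravity in cm/s^2, stiffness in g/s^2 = dyn/cm).

static inline double xi_damp(double x) {
  double v = (4.0 * x - 1.0) / 3.0;
  return v < 1.0 ? v : 1.0;
}

// [[Rcpp::export]]
List run_lattice_cpp(NumericMatrix pos0, NumericMatrix vel0,
                     IntegerMatrix nbr,        // n x 6 neighbor ids, -1 none
                     IntegerMatrix span_other, // n x 6 far endpoint, -1 none
                     IntegerMatrix span_mid,   // n x 6 middle particle
                     NumericVector ell0, NumericVector ell1,
                     NumericVector phi0, NumericVector phi1,
                     double A, double freq, double tau,
                     double t_start, int n_steps, double dt,
                     double mass, double spring_k, double bend_k,
                     double damping_c, double gravity,
                     double ground_k, double ground_c, double mu,
                     double slip_eps,
                     IntegerVector top_particles,  // 0-based
                     int record_every) {
  const int n = pos0.nrow();
  const int ntop = top_particles.size();

  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  // row-major flat copies of the topology for cache-friendly access
  std::vector<int> NB(n * 6), SO(n * 6), SM(n * 6);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < 6; ++s) {
      NB[i * 6 + s] = nbr(i, s);
      SO[i * 6 + s] = span_other(i, s);
      SM[i * 6 + s] = span_mid(i, s);
    }
  std::vector<double> L(n), fx(n), fy(n), fz(n);

  const int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericVector r_time(n_rec), r_comx(n_rec), r_comy(n_rec), r_comz(n_rec),
      r_topmin(n_rec), r_minz(n_rec), r_speed(n_rec), r_energy(n_rec);
  int i_rec = 0;

  const double twopif = 2.0 * M_PI * freq;
  const double inv_tau = 1.0 / tau;

  for (int step = 0; step <= n_steps; ++step) {
    const double t_raw = t_start + step * dt;
    const double t = t_raw > tau ? tau : t_raw;
    const double s = t * inv_tau;

    // per-voxel current lengths
    for (int i = 0; i < n; ++i) {
      const double rest = ell0[i] + s * (ell1[i] - ell0[i]);
      const double phi = phi0[i] + s * (phi1[i] - phi0[i]);
      L[i] = rest + A * std::sin(twopif * t + phi) * xi_damp(rest);
    }

    // force accumulation (positions fixed at the current time level)
    for (int i = 0; i < n; ++i) {
      double prx[3] = {0, 0, 0}, pry[3] = {0, 0, 0}, prz[3] = {0, 0, 0};
      double srx[3] = {0, 0, 0}, sry[3] = {0, 0, 0}, srz[3] = {0, 0, 0};
      const int *nb = &NB[i * 6], *so = &SO[i * 6], *sm = &SM[i * 6];

      for (int axis = 0; axis < 3; ++axis) {
        for (int side = 0; side < 2; ++side) {
          const int slot = 2 * axis + side;
          const int j = nb[slot];
          if (j >= 0) {
            const double dx = px[j] - px[i], dy = py[j] - py[i],
                         dz = pz[j] - pz[i];
            double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (dist < 1e-12) dist = 1e-12;
            const double rest = 0.5 * (L[i] + L[j]);
            const double fmag = spring_k * (dist - rest) / dist;
            prx[axis] += fmag * dx;
            pry[axis] += fmag * dy;
            prz[axis] += fmag * dz;
          }
          const int q = so[slot];
          if (q >= 0) {
            const int m = sm[slot];
            const double dx = px[q] - px[i], dy = py[q] - py[i],
                         dz = pz[q] - pz[i];
            double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (dist < 1e-12) dist = 1e-12;
            const double rest = 0.5 * (L[i] + L[q]) + L[m];
            const double fmag = bend_k * (dist - rest) / dist;
            srx[axis] += fmag * dx;
            sry[axis] += fmag * dy;
            srz[axis] += fmag * dz;
          }
        }
      }

      double fxi = ((prx[0] + prx[1]) + prx[2]) +
                   ((srx[0] + srx[1]) + srx[2]);
      double fyi = ((pry[0] + pry[1]) + pry[2]) +
                   ((sry[0] + sry[1]) + sry[2]);
      double fzi = ((prz[0] + prz[1]) + prz[2]) +
                   ((srz[0] + srz[1]) + srz[2]);

      fzi -= mass * gravity;
      if (pz[i] < 0.0) {
        double N = -ground_k * pz[i] - ground_c * vz[i];
        if (N < 0.0) N = 0.0;
        fzi += N;
        // Coulomb friction, capped at the force that would bring the
        // tangential velocity to rest within one step (slow contacts
        // stick rather than chatter).
        const double vmag = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
        if (vmag > slip_eps) {
          const double fric = std::min(mu * N, mass * vmag / dt);
          fxi -= fric * vx[i] / vmag;
          fyi -= fric * vy[i] / vmag;
        }
      }
      fxi -= damping_c * vx[i];
      fyi -= damping_c * vy[i];
      fzi -= damping_c * vz[i];
      fx[i] = fxi; fy[i] = fyi; fz[i] = fzi;
    }

    // record the pre-step state on sample steps
    if (record_every > 0 && (step % record_every == 0) && i_rec < n_rec) {
      double cx = 0, cy = 0, cz = 0, sx = 0, sy = 0;
      double e_kin = 0, e_pot = 0, e_elastic = 0, e_ground = 0;
      double minz = R_PosInf, topmin = R_PosInf;
      for (int i = 0; i < n; ++i) {
        cx += px[i]; cy += py[i]; cz += pz[i];
        sx += vx[i]; sy += vy[i];
        e_kin += 0.5 * mass *
            (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        e_pot += mass * gravity * pz[i];
        if (pz[i] < 0.0) e_ground += 0.5 * ground_k * pz[i] * pz[i];
        if (pz[i] < minz) minz = pz[i];
        const int *nb = &NB[i * 6], *so = &SO[i * 6], *sm = &SM[i * 6];
        for (int slot = 0; slot < 6; ++slot) {
          const int j = nb[slot];
          if (j >= 0) {
            const double dx = px[j] - px[i], dy = py[j] - py[i],
                         dz = pz[j] - pz[i];
            const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double rest = 0.5 * (L[i] + L[j]);
            e_elastic += 0.25 * spring_k * (dist - rest) * (dist - rest);
          }
          const int q = so[slot];
          if (q >= 0) {
            const double dx = px[q] - px[i], dy = py[q] - py[i],
                         dz = pz[q] - pz[i];
            const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double rest = 0.5 * (L[i] + L[q]) + L[sm[slot]];
            e_elastic += 0.25 * bend_k * (dist - rest) * (dist - rest);
          }
        }
      }
      for (int j = 0; j < ntop; ++j) {
        const double z = pz[top_particles[j]];
        if (z < topmin) topmin = z;
      }
      r_time[i_rec] = t_raw;
      r_comx[i_rec] = cx / n; r_comy[i_rec] = cy / n; r_comz[i_rec] = cz / n;
      r_topmin[i_rec] = (ntop > 0) ? topmin : NA_REAL;
      r_minz[i_rec] = minz;
      r_speed[i_rec] = std::sqrt(sx * sx + sy * sy) / n;
      r_energy[i_rec] = e_kin + e_elastic + e_pot + e_ground;
      ++i_rec;
    }

    if (step < n_steps) {  // semi-implicit Euler
      const double r = dt / mass;
      for (int i = 0; i < n; ++i) {
        vx[i] += fx[i] * r; vy[i] += fy[i] * r; vz[i] += fz[i] * r;
        px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
      }
    }

    if ((step & 127) == 0 || step == n_steps) {
      for (int i = 0; i < n; ++i) {
        const bool bad = !std::isfinite(px[i]) || !std::isfinite(py[i]) ||
                         !std::isfinite(pz[i]) ||
                         std::fabs(px[i]) > 1e3 || std::fabs(py[i]) > 1e3 ||
                         std::fabs(pz[i]) > 1e3;
        if (bad)
          stop("lattice integration diverged at t=%.4f s (dt=%g, spring_k=%g);"
               " reduce dt or stiffness", t_raw, dt, spring_k);
      }
    }
  }

  NumericMatrix pos_f(n, 3), vel_f(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_f(i, 0) = px[i]; pos_f(i, 1) = py[i]; pos_f(i, 2) = pz[i];
    vel_f(i, 0) = vx[i]; vel_f(i, 1) = vy[i]; vel_f(i, 2) = vz[i];
  }

  return List::create(
      _["time"] = r_time, _["com_x"] = r_comx, _["com_y"] = r_comy,
      _["com_z"] = r_comz, _["top_min_z"] = r_topmin, _["min_z"] = r_minz,
      _["speed"] = r_speed, _["energy"] = r_energy,
      _["pos"] = pos_f, _["vel"] = vel_f,
      _["t_end"] = t_start + n_steps * dt);
}
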