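// Force field and Langevin integrator for the bead-spring brush model.
//
// Conventions:
//  - positions are stored unwrapped; for pair/bond/angle vectors the
//    coordinates are first wrapped into the periodic box (x, y only) and the
//    minimum-image convention applied; z is never periodic.
//  - pair interactions: truncated (optionally energy-shifted) 12-6
//    Lennard-Jones between all beads, Debye-Hueckel screened Coulomb between
//    charged beads; per-pair LJ size is the Lorentz mean of the bead sigmas.
//  - bonded terms: harmonic stretch K_bond (r - r0)^2 on bond pairs, harmonic
//    bend K_bend (theta - theta0)^2 on angle triples.
//  - during time stepping, nonbonded pairs come from a Verlet neighbor list
//    with a 0.3 sigma skin, rebuilt when any mobile bead has moved more than
//    half the skin since the last build; this is exact (verified against the
//    brute-force pair sum). Immobile-immobile pairs are skipped while
//    stepping (their forces are never used); full-system energies are
//    evaluated with every pair included.
//  - random numbers come from R's RNG stream (seeded from R), so results are
//    reproducible with set.seed().
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct FFParams {
  double eps_lj;
  double rc_factor;   // LJ cutoff as a multiple of the pair sigma (2^(1/6) in good solvent)
  bool   shift_lj;    // add +u(rc) so the potential is continuous at the cutoff (WCA)
  double k_bond, r0;
  double k_bend, theta0;
  double coulomb;     // C/eps combined prefactor, energy*length/charge^2
  double kappa;
  double rc_debye;
};

static FFParams read_params(const List& p) {
  FFParams f;
  f.eps_lj    = as<double>(p["eps_lj"]);
  f.rc_factor = as<double>(p["rc_factor"]);
  f.shift_lj  = as<bool>(p["shift_lj"]);
  f.k_bond    = as<double>(p["k_bond"]);
  f.r0        = as<double>(p["r0"]);
  f.k_bend    = as<double>(p["k_bend"]);
  f.theta0    = as<double>(p["theta0"]);
  f.coulomb   = as<double>(p["coulomb"]);
  f.kappa     = as<double>(p["kappa"]);
  f.rc_debye  = as<double>(p["rc_debye"]);
  return f;
}

static inline double wrap0(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w = 0.0;
  return w;
}

struct System {
  int n;
  std::vector<double> x, y, z;          // unwrapped
  std::vector<double> wx, wy;           // wrapped copies for pair geometry
  std::vector<double> fx, fy, fz;
  std::vector<double> charge, sigma, mass, gamma_;
  std::vector<int> mobile;              // 0/1
  std::vector<int> species;             // 0 wall, 1 tether, 2 chain, 3 tracer
  IntegerMatrix bonds, angles;          // 1-based from R
  std::unordered_set<long long> excl;   // nonbonded exclusions, key i*n+j (i<j)
  double Lx, Ly;
  FFParams ff;
  double max_sigma;

  // neighbor list
  double skin;
  std::vector<int> nlist;               // flat (i, j) pairs
  std::vector<double> x0, y0, z0;       // positions at list build

  // per-evaluation energy bookkeeping
  double u_lj, u_bond, u_bend, u_debye;
  std::vector<double> per_bead;         // half-split pair + bond, angle on centre
  bool want_per_bead;

  bool excluded(int i, int j) const {
    if (excl.empty()) return false;
    long long a = i < j ? i : j, b = i < j ? j : i;
    return excl.count(a * (long long)n + b) > 0;
  }

  void update_wrapped() {
    for (int i = 0; i < n; ++i) {
      wx[i] = wrap0(x[i], Lx);
      wy[i] = wrap0(y[i], Ly);
    }
  }

  // minimum-image separation from wrapped coordinates (|dx| < L before fix)
  inline void pair_delta(int i, int j, double& dx, double& dy, double& dz) const {
    dx = wx[i] - wx[j];
    if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
    dy = wy[i] - wy[j];
    if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
    dz = z[i] - z[j];
  }

  inline double pair_cutoff(int i, int j) const {
    double rc = ff.rc_factor * 0.5 * (sigma[i] + sigma[j]);
    if (charge[i] != 0.0 && charge[j] != 0.0 && ff.rc_debye > rc)
      rc = ff.rc_debye;
    return rc;
  }

  // accumulate LJ + Debye for pair (i, j); exclusions already filtered out
  inline void pair_interact(int i, int j) {
    double dx, dy, dz;
    pair_delta(i, j, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    double sij = 0.5 * (sigma[i] + sigma[j]);
    double rc_lj = ff.rc_factor * sij;
    bool qq = charge[i] != 0.0 && charge[j] != 0.0;
    double rc_max = qq ? std::max(rc_lj, ff.rc_debye) : rc_lj;
    if (r2 >= rc_max * rc_max) return;
    double fscal = 0.0, u = 0.0;
    if (r2 < rc_lj * rc_lj && ff.eps_lj != 0.0) {
      double sr2 = sij * sij / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      double ulj = 4.0 * ff.eps_lj * (sr12 - sr6);
      if (ff.shift_lj) {
        double src2 = 1.0 / (ff.rc_factor * ff.rc_factor);
        double src6 = src2 * src2 * src2;
        ulj -= 4.0 * ff.eps_lj * (src6 * src6 - src6);
      }
      u_lj += ulj;
      u += ulj;
      fscal += 24.0 * ff.eps_lj * (2.0 * sr12 - sr6) / r2;
    }
    if (qq) {
      double r = std::sqrt(r2);
      if (r < ff.rc_debye) {
        double ud = ff.coulomb * charge[i] * charge[j] * std::exp(-ff.kappa * r) / r;
        u_debye += ud;
        u += ud;
        fscal += ud * (ff.kappa + 1.0 / r) / r;
      }
    }
    fx[i] += fscal * dx; fy[i] += fscal * dy; fz[i] += fscal * dz;
    fx[j] -= fscal * dx; fy[j] -= fscal * dy; fz[j] -= fscal * dz;
    if (want_per_bead) {
      per_bead[i] += 0.5 * u;
      per_bead[j] += 0.5 * u;
    }
  }

  void bonded_terms() {
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double dx, dy, dz;
      pair_delta(i, j, dx, dy, dz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - ff.r0;
      double u = ff.k_bond * dr * dr;
      u_bond += u;
      double fscal = -2.0 * ff.k_bond * dr / r;
      fx[i] += fscal * dx; fy[i] += fscal * dy; fz[i] += fscal * dz;
      fx[j] -= fscal * dx; fy[j] -= fscal * dy; fz[j] -= fscal * dz;
      if (want_per_bead) { per_bead[i] += 0.5 * u; per_bead[j] += 0.5 * u; }
    }
    if (ff.k_bend != 0.0) {
      for (int a = 0; a < angles.nrow(); ++a) {
        int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
        double d1x, d1y, d1z, d2x, d2y, d2z;
        pair_delta(i, j, d1x, d1y, d1z);
        pair_delta(k, j, d2x, d2y, d2z);
        double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
        double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
        double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
        double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        double s = std::sqrt(1.0 - c * c);
        if (s < 1e-8) s = 1e-8;
        double theta = std::acos(c);
        double dth = theta - ff.theta0;
        double u = ff.k_bend * dth * dth;
        u_bend += u;
        double aa = -2.0 * ff.k_bend * dth / s;
        double a11 = aa * c / rsq1;
        double a12 = -aa / (r1 * r2);
        double a22 = aa * c / rsq2;
        double f1x = a11 * d1x + a12 * d2x, f1y = a11 * d1y + a12 * d2y, f1z = a11 * d1z + a12 * d2z;
        double f3x = a22 * d2x + a12 * d1x, f3y = a22 * d2y + a12 * d1y, f3z = a22 * d2z + a12 * d1z;
        fx[i] += f1x; fy[i] += f1y; fz[i] += f1z;
        fx[k] += f3x; fy[k] += f3y; fz[k] += f3z;
        fx[j] -= f1x + f3x; fy[j] -= f1y + f3y; fz[j] -= f1z + f3z;
        if (want_per_bead) per_bead[j] += u;
      }
    }
  }

  // enumerate candidate pairs through a cell grid and hand them to `emit`.
  // rc is the enumeration radius (list cutoff); falls back to all pairs for
  // boxes narrower than three cells.
  template <class F>
  void for_candidate_pairs(double rc, F emit) {
    update_wrapped();
    int ncx = (int)std::floor(Lx / rc);
    int ncy = (int)std::floor(Ly / rc);
    bool grid_too_large = (double)ncx * (double)ncy > 4.0 * n + 1024.0;
    if (ncx < 3 || ncy < 3 || grid_too_large) {
      // narrow box: no x,y pruning possible; sweep beads in z order and
      // stop once the z gap alone exceeds the enumeration radius
      std::vector<int> ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return z[a] < z[b]; });
      for (int a = 0; a < n; ++a) {
        int i = ord[a];
        for (int b = a + 1; b < n && z[ord[b]] - z[i] < rc; ++b)
          emit(i, ord[b]);
      }
      return;
    }
    double zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      if (z[i] < zmin) zmin = z[i];
      if (z[i] > zmax) zmax = z[i];
    }
    int ncz = (int)std::floor((zmax - zmin) / rc) + 1;
    double csx = Lx / ncx, csy = Ly / ncy, csz = rc;
    int ncells = ncx * ncy * ncz;
    std::vector<int> head(ncells, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(wx[i] / csx); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(wy[i] / csy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)((z[i] - zmin) / csz); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
    static const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          if (head[c] < 0) continue;
          for (int s = 0; s < 14; ++s) {
            int axj = (cx + off[s][0] + ncx) % ncx;
            int ayj = (cy + off[s][1] + ncy) % ncy;
            int azj = cz + off[s][2];
            if (azj < 0 || azj >= ncz) continue;
            int c2 = (azj * ncy + ayj) * ncx + axj;
            if (s == 0) {
              for (int i = head[c]; i >= 0; i = nxt[i])
                for (int j = nxt[i]; j >= 0; j = nxt[j]) emit(i, j);
            } else {
              if (c2 == c) continue;
              for (int i = head[c]; i >= 0; i = nxt[i])
                for (int j = head[c2]; j >= 0; j = nxt[j]) emit(i, j);
            }
          }
        }
  }

  void build_neighbor_list(bool skip_immobile) {
    nlist.clear();
    double rc_list = std::max(ff.rc_factor * max_sigma, ff.rc_debye) + skin;
    for_candidate_pairs(rc_list, [&](int i, int j) {
      if (skip_immobile && !mobile[i] && !mobile[j]) return;
      if (excluded(i, j)) return;
      double dx, dy, dz;
      pair_delta(i, j, dx, dy, dz);
      double rc = pair_cutoff(i, j) + skin;
      if (dx * dx + dy * dy + dz * dz < rc * rc) {
        nlist.push_back(i);
        nlist.push_back(j);
      }
    });
    x0 = x; y0 = y; z0 = z;
  }

  bool list_stale() const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  void zero_accumulators(bool per_bead_energy) {
    u_lj = u_bond = u_bend = u_debye = 0.0;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    want_per_bead = per_bead_energy;
    if (per_bead_energy) per_bead.assign(n, 0.0);
  }

  // fast path for stepping: neighbor list (rebuilt on demand)
  void evaluate_list() {
    if (nlist.empty() || list_stale()) build_neighbor_list(true);
    zero_accumulators(false);
    update_wrapped();
    for (size_t p = 0; p < nlist.size(); p += 2)
      pair_interact(nlist[p], nlist[p + 1]);
    bonded_terms();
  }

  // exact full evaluation, every pair included
  void evaluate_full(bool per_bead_energy) {
    zero_accumulators(per_bead_energy);
    double rc = std::max(ff.rc_factor * max_sigma, ff.rc_debye);
    for_candidate_pairs(rc, [&](int i, int j) {
      if (!excluded(i, j)) pair_interact(i, j);
    });
    bonded_terms();
  }

  // interaction energy of one bead: full (unsplit) LJ + Debye pair energies.
  double bead_interaction_energy(int t) {
    update_wrapped();
    double rc = std::max(ff.rc_factor * max_sigma, ff.rc_debye);
    double u = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == t || excluded(t, j)) continue;
      double dx, dy, dz;
      pair_delta(t, j, dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) continue;
      double sij = 0.5 * (sigma[t] + sigma[j]);
      double rc_lj = ff.rc_factor * sij;
      if (r2 < rc_lj * rc_lj && ff.eps_lj != 0.0) {
        double sr2 = sij * sij / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        double ulj = 4.0 * ff.eps_lj * (sr12 - sr6);
        if (ff.shift_lj) {
          double src2 = 1.0 / (ff.rc_factor * ff.rc_factor);
          double src6 = src2 * src2 * src2;
          ulj -= 4.0 * ff.eps_lj * (src6 * src6 - src6);
        }
        u += ulj;
      }
      if (charge[t] != 0.0 && charge[j] != 0.0) {
        double r = std::sqrt(r2);
        if (r < ff.rc_debye)
          u += ff.coulomb * charge[t] * charge[j] * std::exp(-ff.kappa * r) / r;
      }
    }
    return u;
  }
};

static System make_system(const NumericMatrix& pos, const LogicalVector& mobile,
                          const NumericVector& mass, const NumericVector& gamma_,
                          const NumericVector& charge, const NumericVector& sigma,
                          const IntegerVector& species, const IntegerMatrix& bonds,
                          const IntegerMatrix& angles, const IntegerMatrix& excl,
                          const List& params, const NumericVector& box) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.wx.resize(s.n); s.wy.resize(s.n);
  s.fx.resize(s.n); s.fy.resize(s.n); s.fz.resize(s.n);
  s.charge.resize(s.n); s.sigma.resize(s.n); s.mass.resize(s.n); s.gamma_.resize(s.n);
  s.mobile.resize(s.n); s.species.resize(s.n);
  s.max_sigma = 0.0;
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.charge[i] = charge[i]; s.sigma[i] = sigma[i];
    s.mass[i] = mass[i]; s.gamma_[i] = gamma_[i];
    s.mobile[i] = mobile[i] ? 1 : 0; s.species[i] = species[i];
    if (sigma[i] > s.max_sigma) s.max_sigma = sigma[i];
  }
  s.bonds = bonds; s.angles = angles;
  for (int e = 0; e < excl.nrow(); ++e) {
    int i = excl(e, 0) - 1, j = excl(e, 1) - 1;
    long long a = i < j ? i : j, b = i < j ? j : i;
    s.excl.insert(a * (long long)s.n + b);
  }
  s.ff = read_params(params);
  s.Lx = box[0]; s.Ly = box[1];
  s.skin = 0.3;
  return s;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, LogicalVector mobile, NumericVector mass,
                       NumericVector gamma_, NumericVector charge, NumericVector sigma,
                       IntegerVector species, IntegerMatrix bonds, IntegerMatrix angles,
                       IntegerMatrix excl, List params, NumericVector box,
                       bool per_bead = true) {
  System s = make_system(pos, mobile, mass, gamma_, charge, sigma, species,
                         bonds, angles, excl, params, box);
  s.evaluate_full(per_bead);
  NumericMatrix forces(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    forces(i, 0) = s.fx[i]; forces(i, 1) = s.fy[i]; forces(i, 2) = s.fz[i];
  }
  List out = List::create(
    _["u_lj"] = s.u_lj, _["u_bond"] = s.u_bond, _["u_bend"] = s.u_bend,
    _["u_debye"] = s.u_debye,
    _["u_total"] = s.u_lj + s.u_bond + s.u_bend + s.u_debye,
    _["forces"] = forces);
  if (per_bead) out["per_bead"] = NumericVector(s.per_bead.begin(), s.per_bead.end());
  return out;
}

// BAOAB Langevin stepping (velocity Verlet in the gamma -> 0 limit).
// Integrates mobile beads only; positions stay unwrapped.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, LogicalVector mobile,
                      NumericVector mass, NumericVector gamma_, NumericVector charge,
                      NumericVector sigma, IntegerVector species,
                      IntegerMatrix bonds, IntegerMatrix angles, IntegerMatrix excl,
                      List params, NumericVector box, double dt, double kT,
                      int n_steps, int dump_every, int tracer = 0,
                      bool record_energy = true, bool record_chain = false) {
  System s = make_system(pos, mobile, mass, gamma_, charge, sigma, species,
                         bonds, angles, excl, params, box);
  int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n), c1(n), c3(n);
  std::vector<int> mob;
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    if (s.mobile[i]) {
      mob.push_back(i);
      double g = s.gamma_[i];
      c1[i] = (g > 0.0) ? std::exp(-g * dt / s.mass[i]) : 1.0;
      c3[i] = std::sqrt(kT * (1.0 - c1[i] * c1[i]) / s.mass[i]);
    }
  }
  int tr = tracer - 1;  // -1 when absent
  int nframes = n_steps / dump_every + 1;
  NumericVector times(nframes);
  NumericMatrix tracer_pos(nframes, 3);
  NumericVector tracer_u(nframes), chain_epb(nframes), max_chain_z(nframes);
  List chain_frames(record_chain ? nframes : 0);
  int nchain = 0;
  for (int i = 0; i < n; ++i)
    if (s.species[i] == 1 || s.species[i] == 2) ++nchain;

  RNGScope rng;
  s.evaluate_list();

  int frame = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % dump_every == 0) {
      times[frame] = step * dt;
      if (tr >= 0) {
        tracer_pos(frame, 0) = s.x[tr];
        tracer_pos(frame, 1) = s.y[tr];
        tracer_pos(frame, 2) = s.z[tr];
        if (!std::isfinite(s.x[tr]) || !std::isfinite(s.y[tr]) || !std::isfinite(s.z[tr]))
          stop("non-finite tracer coordinate at step %d", step);
      }
      double mz = R_NegInf;
      for (int i = 0; i < n; ++i)
        if ((s.species[i] == 1 || s.species[i] == 2) && s.z[i] > mz) mz = s.z[i];
      max_chain_z[frame] = mz;
      if (record_energy) {
        if (tr >= 0) tracer_u[frame] = s.bead_interaction_energy(tr);
        if (nchain > 0) {
          s.evaluate_full(true);
          double uc = 0.0;
          for (int i = 0; i < n; ++i)
            if (s.species[i] == 1 || s.species[i] == 2) uc += s.per_bead[i];
          chain_epb[frame] = uc / nchain;
          s.evaluate_list();  // restore stepping forces
        }
      }
      if (record_chain) {
        NumericMatrix fr(n, 3);
        for (int i = 0; i < n; ++i) {
          fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i];
        }
        chain_frames[frame] = fr;
      }
      ++frame;
    }
    if (step == n_steps) break;

    for (size_t m = 0; m < mob.size(); ++m) {   // B
      int i = mob[m];
      double h = 0.5 * dt / s.mass[i];
      vx[i] += h * s.fx[i]; vy[i] += h * s.fy[i]; vz[i] += h * s.fz[i];
    }
    for (size_t m = 0; m < mob.size(); ++m) {   // A
      int i = mob[m];
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
    }
    for (size_t m = 0; m < mob.size(); ++m) {   // O
      int i = mob[m];
      if (s.gamma_[i] > 0.0) {
        vx[i] = c1[i] * vx[i] + c3[i] * norm_rand();
        vy[i] = c1[i] * vy[i] + c3[i] * norm_rand();
        vz[i] = c1[i] * vz[i] + c3[i] * norm_rand();
      }
    }
    for (size_t m = 0; m < mob.size(); ++m) {   // A
      int i = mob[m];
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
    }
    s.evaluate_list();
    for (size_t m = 0; m < mob.size(); ++m) {   // B
      int i = mob[m];
      double h = 0.5 * dt / s.mass[i];
      vx[i] += h * s.fx[i]; vy[i] += h * s.fy[i]; vz[i] += h * s.fz[i];
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = s.x[i]; pos_out(i, 1) = s.y[i]; pos_out(i, 2) = s.z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  List out = List::create(
    _["times"] = times, _["tracer_pos"] = tracer_pos,
    _["tracer_energy"] = tracer_u, _["chain_energy_per_bead"] = chain_epb,
    _["max_chain_z"] = max_chain_z, _["positions"] = pos_out, _["velocities"] = vel_out);
  if (record_chain) out["frames"] = chain_frames;
  return out;
}

// Ensemble of non-interacting free particles under the same BAOAB scheme with
// F = 0 (the bulk limit of the model). Returns frames x n x 3 displacements
// from the origin; initial velocities are Maxwell-Boltzmann.
// [[Rcpp::export]]
List cpp_run_free(int n, NumericVector mass, NumericVector gamma_, double dt,
                  double kT, int n_steps, int dump_every) {
  std::vector<double> x(n, 0.0), y(n, 0.0), z(n, 0.0), vx(n), vy(n), vz(n), c1(n), c3(n);
  RNGScope rng;
  for (int i = 0; i < n; ++i) {
    double sv = std::sqrt(kT / mass[i]);
    vx[i] = sv * norm_rand(); vy[i] = sv * norm_rand(); vz[i] = sv * norm_rand();
    c1[i] = (gamma_[i] > 0.0) ? std::exp(-gamma_[i] * dt / mass[i]) : 1.0;
    c3[i] = std::sqrt(kT * (1.0 - c1[i] * c1[i]) / mass[i]);
  }
  int nframes = n_steps / dump_every + 1;
  NumericVector times(nframes);
  NumericVector posv(Dimension(nframes, n, 3));
  int frame = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % dump_every == 0) {
      times[frame] = step * dt;
      for (int i = 0; i < n; ++i) {
        posv[frame + nframes * i] = x[i];
        posv[frame + nframes * (n + i)] = y[i];
        posv[frame + nframes * (2 * n + i)] = z[i];
      }
      ++frame;
    }
    if (step == n_steps) break;
    for (int i = 0; i < n; ++i) {
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
      if (gamma_[i] > 0.0) {
        vx[i] = c1[i] * vx[i] + c3[i] * norm_rand();
        vy[i] = c1[i] * vy[i] + c3[i] * norm_rand();
        vz[i] = c1[i] * vz[i] + c3[i] * norm_rand();
      }
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
  }
  return List::create(_["times"] = times, _["positions"] = posv);
}
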