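// Velocity-Verlet tensile-test engine for bead-chain fibrils with breakable
// trilinear bonds, 12-6 pair interactions (cell list + Verlet pair list),
// harmonic angles and an optional Langevin thermostat. Units: Å, fs,
// kcal/mol, g/mol ("real" units); ftm2v converts force/mass to Å/fs^2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double FTM2V = 4.184e-4;          // (kcal/mol/A)/(g/mol) -> A/fs^2
static const double KB = 0.0019872041;         // kcal/mol/K

// xorshift-based deterministic RNG + Box-Muller (platform independent)
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (s >> 11) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct BondType {
  double r0, r1, rbreak, k0, k1, a, fmax, w, winf;
  bool breakable;
};

// signed bond tension (+ = tensile restoring pull) as function of r
static inline double bond_tension(const BondType& bt, double r) {
  if (r < bt.r1) return bt.k0 * (r - bt.r0);  // includes compressive side
  if (!bt.breakable || r < bt.rbreak)
    return bt.k0 * (bt.r1 - bt.r0) + bt.k1 * (r - bt.r1);
  if (r < bt.rbreak + bt.a) return bt.fmax * (1.0 - (r - bt.rbreak) / bt.a);
  return 0.0;
}

static inline double bond_epot(const BondType& bt, double r) {
  double d1 = bt.r1 - bt.r0;
  if (r < bt.r0) { double d = r - bt.r0; return 0.5 * bt.k0 * d * d; }
  if (r < bt.r1) { double d = r - bt.r0; return 0.5 * bt.k0 * d * d; }
  if (!bt.breakable || r < bt.rbreak) {
    double d = r - bt.r1;
    return 0.5 * bt.k0 * d1 * d1 + bt.k0 * d1 * d + 0.5 * bt.k1 * d * d;
  }
  if (r < bt.rbreak + bt.a) {
    double sft = r - bt.rbreak;
    return bt.w + bt.fmax * sft - bt.fmax * sft * sft / (2.0 * bt.a);
  }
  return bt.winf;
}

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix coords, IntegerVector grip, double mass,
                IntegerMatrix bonds_ij, IntegerVector bond_type,
                IntegerVector bond_obs, NumericMatrix bond_par,
                IntegerMatrix angles,
                double k_theta, double theta0,
                double lj_sigma, double lj_eps, double lj_cutoff,
                List protocol, int seed,
                Nullable<NumericMatrix> v0_ = R_NilValue) {
  const int n = coords.nrow();
  const int nb = bonds_ij.nrow();
  const int na = angles.nrow();

  std::vector<double> x(n), y(n), z(n), vx(n, 0), vy(n, 0), vz(n, 0);
  std::vector<double> fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }

  // bond types (1-based type index into bond_par rows)
  std::vector<BondType> btypes(bond_par.nrow());
  for (int t = 0; t < bond_par.nrow(); ++t) {
    BondType bt;
    bt.r0 = bond_par(t, 0); bt.r1 = bond_par(t, 1); bt.rbreak = bond_par(t, 2);
    bt.k0 = bond_par(t, 3); bt.k1 = bond_par(t, 4); bt.a = bond_par(t, 5);
    bt.breakable = R_finite(bt.rbreak);
    if (bt.breakable) {
      double d1 = bt.r1 - bt.r0, d2 = bt.rbreak - bt.r1;
      bt.fmax = bt.k0 * d1 + bt.k1 * d2;
      bt.w = 0.5 * bt.k0 * d1 * d1 + bt.k0 * d1 * d2 + 0.5 * bt.k1 * d2 * d2;
      bt.winf = bt.w + 0.5 * bt.fmax * bt.a;
    } else {
      bt.fmax = bt.w = bt.winf = R_PosInf;
      bt.a = R_PosInf;
    }
    btypes[t] = bt;
  }
  std::vector<int> bi(nb), bj(nb), bt_idx(nb);
  std::vector<char> alive(nb, 1);
  for (int b = 0; b < nb; ++b) {
    bi[b] = bonds_ij(b, 0) - 1; bj[b] = bonds_ij(b, 1) - 1;
    bt_idx[b] = bond_type[b] - 1;
    if (bi[b] < 0 || bj[b] < 0 || bi[b] >= n || bj[b] >= n)
      stop("bond index out of range");
    if (bt_idx[b] < 0 || bt_idx[b] >= (int)btypes.size())
      stop("unparameterized bond type");
  }

  // pair exclusions: bonded (1-2) and angle ends (1-3)
  std::unordered_set<uint64_t> excl;
  auto key = [n](int a, int b) {
    int lo = a < b ? a : b, hi = a < b ? b : a;
    return (uint64_t)lo * (uint64_t)n + (uint64_t)hi;
  };
  for (int b = 0; b < nb; ++b) excl.insert(key(bi[b], bj[b]));
  std::vector<int> ai(na), aj(na), ak(na);
  for (int q = 0; q < na; ++q) {
    ai[q] = angles(q, 0) - 1; aj[q] = angles(q, 1) - 1; ak[q] = angles(q, 2) - 1;
    excl.insert(key(ai[q], ak[q]));
  }

  // protocol
  const double dt = as<double>(protocol["dt"]);
  const double pull_speed = as<double>(protocol["pull_speed"]);
  const int equil_steps = as<int>(protocol["equil_steps"]);
  const int record_interval = as<int>(protocol["record_interval"]);
  const double temperature = as<double>(protocol["temperature"]);
  const double damping = as<double>(protocol["damping"]);
  const double strain_limit = as<double>(protocol["strain_limit"]);
  const double collapse_frac = as<double>(protocol["collapse_frac"]);
  const double collapse_min_strain = as<double>(protocol["collapse_min_strain"]);
  const double l0 = as<double>(protocol["l0"]);
  int n_steps = as<int>(protocol["n_steps"]);  // pulling steps; <0 -> derive
  if (n_steps < 0) {
    n_steps = (pull_speed > 0)
      ? (int)std::floor(strain_limit * l0 / (pull_speed * dt))
      : 0;
  }
  const bool langevin = damping > 0.0;

  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // initial velocities
  if (v0_.isNotNull()) {
    NumericMatrix v0(v0_);
    for (int i = 0; i < n; ++i) {
      vx[i] = v0(i, 0); vy[i] = v0(i, 1); vz[i] = v0(i, 2);
    }
  } else if (temperature > 0) {
    double sv = std::sqrt(KB * temperature * FTM2V / mass);
    double sx = 0, sy = 0, sz = 0; int nfree = 0;
    for (int i = 0; i < n; ++i) {
      if (grip[i] != 0) continue;
      vx[i] = sv * rng.gauss(); vy[i] = sv * rng.gauss(); vz[i] = sv * rng.gauss();
      sx += vx[i]; sy += vy[i]; sz += vz[i]; ++nfree;
    }
    if (nfree > 0) {
      for (int i = 0; i < n; ++i) if (grip[i] == 0) {
        vx[i] -= sx / nfree; vy[i] -= sy / nfree; vz[i] -= sz / nfree;
      }
    }
  }

  // cell/pair list
  const double skin = 2.0;
  const double rlist = lj_cutoff + skin;
  const double rlist2 = rlist * rlist, rcut2 = lj_cutoff * lj_cutoff;
  std::vector<int> plist;  // flattened (i,j)
  std::vector<double> xref(n), yref(n), zref(n);
  const bool use_lj = lj_eps > 0.0;
  // shift so pair energy is zero at the cutoff
  double sr6c = std::pow(lj_sigma / lj_cutoff, 6.0);
  const double e_shift = 4.0 * lj_eps * (sr6c * sr6c - sr6c);

  auto build_pairs = [&]() {
    plist.clear();
    if (!use_lj) return;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    double cs = rlist;
    int ncx = std::max(1, (int)((xmax - xmin) / cs) + 1);
    int ncy = std::max(1, (int)((ymax - ymin) / cs) + 1);
    int ncz = std::max(1, (int)((zmax - zmin) / cs) + 1);
    std::vector<int> head((size_t)ncx * ncy * ncz, -1), nxt(n, -1);
    auto cidx = [&](int cx, int cy, int cz) {
      return ((size_t)cz * ncy + cy) * ncx + cx;
    };
    std::vector<int> pcx(n), pcy(n), pcz(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)((x[i] - xmin) / cs)));
      int cy = std::min(ncy - 1, std::max(0, (int)((y[i] - ymin) / cs)));
      int cz = std::min(ncz - 1, std::max(0, (int)((z[i] - zmin) / cs)));
      pcx[i] = cx; pcy[i] = cy; pcz[i] = cz;
      size_t c = cidx(cx, cy, cz);
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int dcx = -1; dcx <= 1; ++dcx)
        for (int dcy = -1; dcy <= 1; ++dcy)
          for (int dcz = -1; dcz <= 1; ++dcz) {
            int cx = pcx[i] + dcx, cy = pcy[i] + dcy, cz = pcz[i] + dcz;
            if (cx < 0 || cy < 0 || cz < 0 || cx >= ncx || cy >= ncy || cz >= ncz)
              continue;
            for (int j = head[cidx(cx, cy, cz)]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rlist2 && excl.find(key(i, j)) == excl.end()) {
                plist.push_back(i); plist.push_back(j);
              }
            }
          }
    }
    for (int i = 0; i < n; ++i) { xref[i] = x[i]; yref[i] = y[i]; zref[i] = z[i]; }
  };

  auto need_rebuild = [&]() {
    double lim2 = (skin / 2) * (skin / 2);
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - xref[i], dy = y[i] - yref[i], dz = z[i] - zref[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  };

  // break log
  std::vector<int> brk_step, brk_bond, brk_type;
  double e_diss = 0.0;

  // force computation; returns potential energy if want_energy
  double fz_left = 0, fz_right = 0;
  int cur_step = 0;
  auto forces = [&](bool want_energy) -> double {
    double pe = 0.0;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // bonds
    for (int b = 0; b < nb; ++b) {
      if (!alive[b]) continue;
      const BondType& bt = btypes[bt_idx[b]];
      int i = bi[b], j = bj[b];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (bt.breakable && r >= bt.rbreak + bt.a) {
        alive[b] = 0;
        e_diss += bt.winf;
        brk_step.push_back(cur_step);
        brk_bond.push_back(b + 1);
        brk_type.push_back(bt_idx[b] + 1);
        continue;
      }
      double t = bond_tension(bt, r);
      double fac = -t / r;  // force on i along (i - j)
      fx[i] += fac * dx; fy[i] += fac * dy; fz[i] += fac * dz;
      fx[j] -= fac * dx; fy[j] -= fac * dy; fz[j] -= fac * dz;
      if (want_energy) pe += bond_epot(bt, r);
    }
    // pairs
    if (use_lj) {
      for (size_t p = 0; p < plist.size(); p += 2) {
        int i = plist[p], j = plist[p + 1];
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rcut2) continue;
        double inv2 = 1.0 / r2;
        double s2 = lj_sigma * lj_sigma * inv2;
        double s6 = s2 * s2 * s2;
        double fac = 24.0 * lj_eps * (2.0 * s6 * s6 - s6) * inv2;
        fx[i] += fac * dx; fy[i] += fac * dy; fz[i] += fac * dz;
        fx[j] -= fac * dx; fy[j] -= fac * dy; fz[j] -= fac * dz;
        if (want_energy) pe += 4.0 * lj_eps * (s6 * s6 - s6) - e_shift;
      }
    }
    // angles (harmonic, E = K (theta - theta0)^2)
    for (int q = 0; q < na; ++q) {
      int i = ai[q], j = aj[q], k = ak[q];
      double d1x = x[i] - x[j], d1y = y[i] - y[j], d1z = z[i] - z[j];
      double d2x = x[k] - x[j], d2y = y[k] - y[j], d2z = z[k] - z[j];
      double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
      double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
      double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
      double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
      c = std::max(-1.0, std::min(1.0, c));
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double dtheta = std::acos(c) - theta0;
      double tk = k_theta * dtheta;
      double aa = -2.0 * tk / s;
      double a11 = aa * c / rsq1, a12 = -aa / (r1 * r2), a22 = aa * c / rsq2;
      double f1x = a11 * d1x + a12 * d2x;
      double f1y = a11 * d1y + a12 * d2y;
      double f1z = a11 * d1z + a12 * d2z;
      double f3x = a22 * d2x + a12 * d1x;
      double f3y = a22 * d2y + a12 * d1y;
      double f3z = a22 * d2z + a12 * d1z;
      fx[i] += f1x; fy[i] += f1y; fz[i] += f1z;
      fx[k] += f3x; fy[k] += f3y; fz[k] += f3z;
      fx[j] -= f1x + f3x; fy[j] -= f1y + f3y; fz[j] -= f1z + f3z;
      if (want_energy) pe += k_theta * dtheta * dtheta;
    }
    fz_left = fz_right = 0.0;
    for (int i = 0; i < n; ++i) {
      if (grip[i] == 1) fz_left += fz[i];
      else if (grip[i] == 2) fz_right += fz[i];
    }
    return pe;
  };

  // records
  std::vector<double> rec_step, rec_time, rec_disp, rec_strain, rec_fgrip,
      rec_bbf, rec_bbx, rec_agef, rec_agex, rec_ke, rec_pe, rec_ediss,
      rec_wext, rec_wthermo;
  std::vector<int> rec_nage, rec_ncol;
  int n_broken_age = 0, n_broken_col = 0;

  double w_ext = 0.0, w_thermo = 0.0;
  const double lang_pref = langevin
      ? std::sqrt(2.0 * mass * KB * std::max(0.0, temperature) * FTM2V /
                  (damping * dt)) / FTM2V
      : 0.0;
  // note: noise force in kcal/mol/A; friction = -(m/(damp*FTM2V)) v

  auto record = [&](int step, double t_pull, double disp) {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      if (grip[i] != 0) continue;
      ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    ke *= 0.5 * mass / FTM2V;
    double pe = forces(true);
    // mean bond observables
    double sbf = 0, sbx = 0, saf = 0, sax = 0;
    int nbb = 0, nage = 0;
    for (int b = 0; b < nb; ++b) {
      if (!alive[b]) continue;
      int t = bt_idx[b];
      if (t != 0 && t != 2) continue;
      if (t == 0 && bond_obs[b] == 0) continue;  // outside observation window
      int i = bi[b], j = bj[b];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const BondType& bt = btypes[t];
      if (t == 0) { sbf += bond_tension(bt, r); sbx += r - bt.r0; ++nbb; }
      else { saf += bond_tension(bt, r); sax += r - bt.r0; ++nage; }
    }
    n_broken_age = 0; n_broken_col = 0;
    for (size_t q = 0; q < brk_type.size(); ++q) {
      if (brk_type[q] == 3) ++n_broken_age;
      else if (brk_type[q] == 1) ++n_broken_col;
    }
    rec_step.push_back(step);
    rec_time.push_back(t_pull);
    rec_disp.push_back(disp);
    rec_strain.push_back(l0 > 0 ? disp / l0 : 0.0);
    rec_fgrip.push_back(0.5 * (fz_left - fz_right));
    rec_bbf.push_back(nbb ? sbf / nbb : 0.0);
    rec_bbx.push_back(nbb ? sbx / nbb : 0.0);
    rec_agef.push_back(nage ? saf / nage : 0.0);
    rec_agex.push_back(nage ? sax / nage : 0.0);
    rec_nage.push_back(n_broken_age);
    rec_ncol.push_back(n_broken_col);
    rec_ke.push_back(ke);
    rec_pe.push_back(pe);
    rec_ediss.push_back(e_diss);
    rec_wext.push_back(w_ext);
    rec_wthermo.push_back(w_thermo);
    return pe;
  };

  build_pairs();
  forces(false);
  if (equil_steps == 0) record(0, 0.0, 0.0);

  const int total_steps = equil_steps + n_steps;
  double peak_f = 0.0;
  bool stopped = false;

  for (int step = 1; step <= total_steps && !stopped; ++step) {
    cur_step = step;
    bool pulling = step > equil_steps;
    double vgrip = pulling ? 0.5 * pull_speed : 0.0;

    // half kick + drift
    for (int i = 0; i < n; ++i) {
      if (grip[i] == 0) {
        double c = 0.5 * dt * FTM2V / mass;
        vx[i] += c * fx[i]; vy[i] += c * fy[i]; vz[i] += c * fz[i];
        x[i] += vx[i] * dt; y[i] += vy[i] * dt; z[i] += vz[i] * dt;
      } else {
        double vg = (grip[i] == 1) ? -vgrip : vgrip;
        vx[i] = 0; vy[i] = 0; vz[i] = vg;
        z[i] += vg * dt;
      }
    }
    if (need_rebuild()) build_pairs();
    forces(false);
    // external work by the moving grips (interaction reaction force x grip velocity)
    if (pulling) {
      w_ext += (-fz_left * (-vgrip) + -fz_right * vgrip) * dt;
    }
    // Langevin thermostat on free particles
    if (langevin) {
      double fric = mass / (damping * FTM2V);
      for (int i = 0; i < n; ++i) {
        if (grip[i] != 0) continue;
        double flx = -fric * vx[i] + lang_pref * rng.gauss();
        double fly = -fric * vy[i] + lang_pref * rng.gauss();
        double flz = -fric * vz[i] + lang_pref * rng.gauss();
        fx[i] += flx; fy[i] += fly; fz[i] += flz;
        w_thermo += (flx * vx[i] + fly * vy[i] + flz * vz[i]) * dt;
      }
    }
    // second half kick
    for (int i = 0; i < n; ++i) {
      if (grip[i] != 0) continue;
      double c = 0.5 * dt * FTM2V / mass;
      vx[i] += c * fx[i]; vy[i] += c * fy[i]; vz[i] += c * fz[i];
    }

    if (step == equil_steps || (pulling && (step - equil_steps) % record_interval == 0)
        || step == total_steps) {
      double t_pull = pulling ? (step - equil_steps) * dt : 0.0;
      double disp = pull_speed * t_pull;
      for (int i = 0; i < n; ++i) {
        if (!R_finite(x[i]) || !R_finite(z[i]))
          stop("integration blow-up: non-finite coordinate at step %d", step);
      }
      record(step, t_pull, disp);
      double fg = rec_fgrip.back();
      if (fg > peak_f) peak_f = fg;
      double strain = rec_strain.back();
      if (collapse_frac > 0 && strain > collapse_min_strain &&
          peak_f > 0 && fg < collapse_frac * peak_f) {
        stopped = true;
      }
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  if (rec_step.empty()) record(0, 0.0, 0.0);

  NumericMatrix coords_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    coords_out(i, 0) = x[i]; coords_out(i, 1) = y[i]; coords_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  LogicalVector alive_out(nb);
  for (int b = 0; b < nb; ++b) alive_out[b] = alive[b] != 0;

  return List::create(
    _["series"] = List::create(
      _["step"] = rec_step, _["time"] = rec_time, _["displacement"] = rec_disp,
      _["strain"] = rec_strain, _["fgrip"] = rec_fgrip,
      _["f_backbone"] = rec_bbf, _["ext_backbone"] = rec_bbx,
      _["f_age"] = rec_agef, _["ext_age"] = rec_agex,
      _["broken_age"] = rec_nage, _["broken_collagen"] = rec_ncol,
      _["e_kin"] = rec_ke, _["e_pot"] = rec_pe, _["e_diss"] = rec_ediss,
      _["w_ext"] = rec_wext, _["w_thermo"] = rec_wthermo),
    _["breaks"] = List::create(
      _["step"] = brk_step, _["bond"] = brk_bond, _["type"] = brk_type),
    _["coords"] = coords_out, _["velocities"] = vel_out,
    _["alive"] = alive_out);
}
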