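// Simulation kernels for coarse-grained structure-based models.
//
// A "compiled system" is an R list assembled by compile_system() in R:
//   n        number of beads
//   bonds    m x 2 integer matrix (0-based bead indices)
//   bond_r0  native bond lengths (nm)
//   kb       per-bond stiffness (eps/nm^2, temperature rescale folded in)
//   angles   a x 3, theta0, ka
//   dih      d x 4, phi0, kd
//   cpair    k x 2 contact pairs, csig native distances, ceps per-contact
//            well depths (class epsilon, rho and rescale folded in),
//            ccls class codes 0 intra, 1 inter, 2 linker, 3 binary, 4 binding
//   nbpair   p x 2 excluded-volume pairs, excl_sigma, escale per-pair scale
//   epair    e x 2 electrostatic pairs, eqq = A*qi*qj per pair, debye length
//   frozen   logical mask; frozen beads get zero force and never move
//
// All RNG goes through R's generator (RNGScope), so set.seed() in R makes
// every trajectory reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NCOMP = 8; // bonded intra inter linker binary binding elec excl

struct Sys {
  int n;
  IntegerMatrix bonds; NumericVector bond_r0, kb;
  IntegerMatrix angles; NumericVector theta0, ka;
  IntegerMatrix dih; NumericVector phi0, kd;
  IntegerMatrix cpair; NumericVector csig, ceps; IntegerVector ccls;
  IntegerMatrix nbpair; double excl_sigma; NumericVector escale;
  IntegerMatrix epair; NumericVector eqq; double debye;
  LogicalVector frozen;
  Sys(const List& s)
    : n(as<int>(s["n"])),
      bonds(as<IntegerMatrix>(s["bonds"])), bond_r0(as<NumericVector>(s["bond_r0"])),
      kb(as<NumericVector>(s["kb"])),
      angles(as<IntegerMatrix>(s["angles"])), theta0(as<NumericVector>(s["theta0"])),
      ka(as<NumericVector>(s["ka"])),
      dih(as<IntegerMatrix>(s["dih"])), phi0(as<NumericVector>(s["phi0"])),
      kd(as<NumericVector>(s["kd"])),
      cpair(as<IntegerMatrix>(s["cpair"])), csig(as<NumericVector>(s["csig"])),
      ceps(as<NumericVector>(s["ceps"])), ccls(as<IntegerVector>(s["ccls"])),
      nbpair(as<IntegerMatrix>(s["nbpair"])), excl_sigma(as<double>(s["excl_sigma"])),
      escale(as<NumericVector>(s["escale"])),
      epair(as<IntegerMatrix>(s["epair"])), eqq(as<NumericVector>(s["eqq"])),
      debye(as<double>(s["debye"])),
      frozen(as<LogicalVector>(s["frozen"])) {}
};

static inline void addv(std::vector<double>& F, int i, double fx, double fy, double fz) {
  F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
}

// Potential energy components and forces (-dV/dx).  pos is length 3n
// (x0,y0,z0,x1,...).  comps must have length NCOMP; F length 3n (zeroed here).
static void eval_system(const Sys& S, const std::vector<double>& pos,
                        double* comps, std::vector<double>& F) {
  std::fill(F.begin(), F.end(), 0.0);
  for (int c = 0; c < NCOMP; ++c) comps[c] = 0.0;

  // bonds: kb (r - r0)^2
  for (int b = 0; b < S.bonds.nrow(); ++b) {
    int i = S.bonds(b, 0), j = S.bonds(b, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - S.bond_r0[b];
    comps[0] += S.kb[b] * dr * dr;
    double fmag = -2.0 * S.kb[b] * dr / r; // along j-i on j
    addv(F, j, fmag * dx, fmag * dy, fmag * dz);
    addv(F, i, -fmag * dx, -fmag * dy, -fmag * dz);
  }

  // angles: ka (theta - theta0)^2, vertex at middle index
  for (int a = 0; a < S.angles.nrow(); ++a) {
    int i = S.angles(a, 0), j = S.angles(a, 1), k = S.angles(a, 2);
    double ax = pos[3*i] - pos[3*j], ay = pos[3*i+1] - pos[3*j+1], az = pos[3*i+2] - pos[3*j+2];
    double bx = pos[3*k] - pos[3*j], by = pos[3*k+1] - pos[3*j+1], bz = pos[3*k+2] - pos[3*j+2];
    double la = std::sqrt(ax*ax + ay*ay + az*az), lb = std::sqrt(bx*bx + by*by + bz*bz);
    double ct = (ax*bx + ay*by + az*bz) / (la * lb);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct*ct);
    if (st < 1e-8) st = 1e-8;
    double dth = th - S.theta0[a];
    comps[0] += S.ka[a] * dth * dth;
    double dVdth = 2.0 * S.ka[a] * dth;
    // dtheta/dri = (ct*ahat - bhat) / (la*st)
    double fix = -dVdth * (ct * ax / la - bx / lb) / (la * st);
    double fiy = -dVdth * (ct * ay / la - by / lb) / (la * st);
    double fiz = -dVdth * (ct * az / la - bz / lb) / (la * st);
    double fkx = -dVdth * (ct * bx / lb - ax / la) / (lb * st);
    double fky = -dVdth * (ct * by / lb - ay / la) / (lb * st);
    double fkz = -dVdth * (ct * bz / lb - az / la) / (lb * st);
    addv(F, i, fix, fiy, fiz);
    addv(F, k, fkx, fky, fkz);
    addv(F, j, -fix - fkx, -fiy - fky, -fiz - fkz);
  }

  // dihedrals: kd [ (1 - cos(phi-phi0)) + 0.5 (1 - cos 3(phi-phi0)) ]
  for (int d = 0; d < S.dih.nrow(); ++d) {
    int i = S.dih(d, 0), j = S.dih(d, 1), k = S.dih(d, 2), l = S.dih(d, 3);
    double b1x = pos[3*j] - pos[3*i], b1y = pos[3*j+1] - pos[3*i+1], b1z = pos[3*j+2] - pos[3*i+2];
    double b2x = pos[3*k] - pos[3*j], b2y = pos[3*k+1] - pos[3*j+1], b2z = pos[3*k+2] - pos[3*j+2];
    double b3x = pos[3*l] - pos[3*k], b3y = pos[3*l+1] - pos[3*k+1], b3z = pos[3*l+2] - pos[3*k+2];
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z, n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z, n2z = b2x*b3y - b2y*b3x;
    double lb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    double mx = n1y*n2z - n1z*n2y, my = n1z*n2x - n1x*n2z, mz = n1x*n2y - n1y*n2x;
    double y = (mx*b2x + my*b2y + mz*b2z) / lb2;
    double x = n1x*n2x + n1y*n2y + n1z*n2z;
    double phi = std::atan2(y, x);
    double dphi = phi - S.phi0[d];
    comps[0] += S.kd[d] * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    double dVdphi = S.kd[d] * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;
    // dphi/dr1 = -(|b2|/|n1|^2) n1, dphi/dr4 = +(|b2|/|n2|^2) n2,
    // dphi/dr2 = -(1+t) dphi/dr1 + s dphi/dr4,
    // dphi/dr3 =     t dphi/dr1 - (1+s) dphi/dr4,
    // with t = (b1.b2)/|b2|^2, s = (b3.b2)/|b2|^2; F_i = -dV/dphi dphi/dr_i
    double g1 = -lb2 / n1sq, g4 = lb2 / n2sq;
    double d1x = g1 * n1x, d1y = g1 * n1y, d1z = g1 * n1z;
    double d4x = g4 * n2x, d4y = g4 * n2y, d4z = g4 * n2z;
    double tt = (b1x*b2x + b1y*b2y + b1z*b2z) / (lb2 * lb2);
    double ss = (b3x*b2x + b3y*b2y + b3z*b2z) / (lb2 * lb2);
    double f1x = -dVdphi * d1x, f1y = -dVdphi * d1y, f1z = -dVdphi * d1z;
    double f4x = -dVdphi * d4x, f4y = -dVdphi * d4y, f4z = -dVdphi * d4z;
    double f2x = -dVdphi * (-(1 + tt) * d1x + ss * d4x);
    double f2y = -dVdphi * (-(1 + tt) * d1y + ss * d4y);
    double f2z = -dVdphi * (-(1 + tt) * d1z + ss * d4z);
    double f3x = -dVdphi * (tt * d1x - (1 + ss) * d4x);
    double f3y = -dVdphi * (tt * d1y - (1 + ss) * d4y);
    double f3z = -dVdphi * (tt * d1z - (1 + ss) * d4z);
    addv(F, i, f1x, f1y, f1z);
    addv(F, j, f2x, f2y, f2z);
    addv(F, k, f3x, f3y, f3z);
    addv(F, l, f4x, f4y, f4z);
  }

  // native contacts: 12-10 well, eps [5 (s/r)^12 - 6 (s/r)^10]
  for (int c = 0; c < S.cpair.nrow(); ++c) {
    int i = S.cpair(c, 0), j = S.cpair(c, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    double s2 = S.csig[c] * S.csig[c];
    double q2 = s2 / r2;
    double q10 = q2 * q2 * q2 * q2 * q2;
    double q12 = q10 * q2;
    double eps = S.ceps[c];
    comps[1 + S.ccls[c]] += eps * (5.0 * q12 - 6.0 * q10);
    // dV/dr = eps (-60 s^12/r^13 + 60 s^10/r^11); force on j = -dV/dr * rhat
    double dVdr_over_r = eps * 60.0 * (q10 - q12) / r2;
    double fmag = -dVdr_over_r; // force on j along +d when dVdr negative
    addv(F, j, fmag * dx, fmag * dy, fmag * dz);
    addv(F, i, -fmag * dx, -fmag * dy, -fmag * dz);
  }

  // excluded volume: (sigma/r)^12 on listed non-contact pairs
  double es2 = S.excl_sigma * S.excl_sigma;
  for (int p = 0; p < S.nbpair.nrow(); ++p) {
    int i = S.nbpair(p, 0), j = S.nbpair(p, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 > 9.0 * es2) continue; // negligible beyond 3 sigma
    double q2 = es2 / r2;
    double q12 = q2 * q2 * q2; q12 = q12 * q12;
    double sc = S.escale[p];
    comps[7] += sc * q12;
    double fmag = sc * 12.0 * q12 / r2; // repulsive: push j outward
    addv(F, j, fmag * dx, fmag * dy, fmag * dz);
    addv(F, i, -fmag * dx, -fmag * dy, -fmag * dz);
  }

  // Debye-Hueckel: eqq * exp(-r/lambda) / r
  for (int p = 0; p < S.epair.nrow(); ++p) {
    int i = S.epair(p, 0), j = S.epair(p, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double ex = std::exp(-r / S.debye);
    double v = S.eqq[p] * ex / r;
    comps[6] += v;
    // dV/dr = -v (1/r + 1/lambda); force on j = -dV/dr * rhat
    double fmag = v * (1.0 / r + 1.0 / S.debye) / r;
    addv(F, j, fmag * dx, fmag * dy, fmag * dz);
    addv(F, i, -fmag * dx, -fmag * dy, -fmag * dz);
  }

  // frozen beads feel nothing
  for (int i = 0; i < S.n; ++i)
    if (S.frozen[i]) { F[3*i] = 0.0; F[3*i+1] = 0.0; F[3*i+2] = 0.0; }
}

// [[Rcpp::export]]
NumericVector cg_energy_cpp(List sys, NumericMatrix pos) {
  Sys S(sys);
  std::vector<double> p(3 * S.n), F(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = pos(i, d);
  double comps[NCOMP];
  eval_system(S, p, comps, F);
  NumericVector out(NCOMP + 1);
  double tot = 0.0;
  for (int c = 0; c < NCOMP; ++c) { out[c] = comps[c]; tot += comps[c]; }
  out[NCOMP] = tot;
  out.attr("names") = CharacterVector::create("bonded", "intra", "inter",
    "linker", "binary_basin", "binding", "electrostatic", "excluded", "total");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cg_forces_cpp(List sys, NumericMatrix pos) {
  Sys S(sys);
  std::vector<double> p(3 * S.n), F(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = pos(i, d);
  double comps[NCOMP];
  eval_system(S, p, comps, F);
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = F[3*i+d];
  return out;
}

// ---- collective variable used for biasing: dRMS over binding contacts ----
static double cv_drms(const std::vector<double>& pos, const IntegerMatrix& bp,
                      const NumericVector& bs) {
  double acc = 0.0;
  int nb = bp.nrow();
  for (int c = 0; c < nb; ++c) {
    int i = bp(c, 0), j = bp(c, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - bs[c];
    acc += d * d;
  }
  return std::sqrt(acc / nb);
}

// gradient of dRMS wrt coordinates, added as force -k*(cv-c)*dcv/dx etc.
static void cv_drms_add_force(const std::vector<double>& pos, const IntegerMatrix& bp,
                              const NumericVector& bs, double cv, double prefac,
                              std::vector<double>& F, const LogicalVector& frozen) {
  // d(dRMS)/d rj = (r_ij - sigma_ij) / (N * dRMS) * rhat on j
  int nb = bp.nrow();
  if (cv < 1e-10) return;
  for (int c = 0; c < nb; ++c) {
    int i = bp(c, 0), j = bp(c, 1);
    double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1], dz = pos[3*j+2] - pos[3*i+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double g = (r - bs[c]) / (nb * cv * r); // times vector d gives dcv/drj
    double f = prefac * g;
    if (!frozen[j]) { F[3*j] += f * dx; F[3*j+1] += f * dy; F[3*j+2] += f * dz; }
    if (!frozen[i]) { F[3*i] -= f * dx; F[3*i+1] -= f * dy; F[3*i+2] -= f * dz; }
  }
}

static double metad_bias(double s, const std::vector<double>& hx,
                         const std::vector<double>& hh, double w) {
  double v = 0.0;
  for (size_t i = 0; i < hx.size(); ++i) {
    double d = (s - hx[i]) / w;
    v += hh[i] * std::exp(-0.5 * d * d);
  }
  return v;
}

// Langevin BAOAB integrator with optional umbrella / well-tempered
// metadynamics bias on dRMS.  bias list fields:
//   type: 0 none, 1 umbrella, 2 metadynamics
//   bpair, bsig: contact pairs defining the CV
//   umbrella: center, k
//   metad: h0, width, pace, biasfactor, stop_lo, stop_hi, freq_adaptive,
//          hills_x, hills_h (resume)
// [[Rcpp::export]]
List cg_langevin_cpp(List sys, NumericMatrix pos0, double dt, double friction,
                     double temperature, int nsteps, int record_interval,
                     List bias, double t0) {
  RNGScope scope;
  Sys S(sys);
  int n = S.n;
  std::vector<double> p(3 * n), v(3 * n, 0.0), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = pos0(i, d);

  // Maxwell-Boltzmann start (mass 1), frozen beads at rest
  for (int i = 0; i < n; ++i) {
    if (S.frozen[i]) continue;
    for (int d = 0; d < 3; ++d) v[3*i+d] = std::sqrt(temperature) * norm_rand();
  }

  int btype = as<int>(bias["type"]);
  IntegerMatrix bp; NumericVector bs;
  double ucenter = 0.0, uk = 0.0;
  double h0 = 0.0, hw = 0.1, bf = 5.0, stop_lo = NA_REAL, stop_hi = NA_REAL;
  int pace = 0; bool freq_adaptive = false;
  std::vector<double> hx, hh;
  if (btype > 0) {
    bp = as<IntegerMatrix>(bias["bpair"]);
    bs = as<NumericVector>(bias["bsig"]);
  }
  if (btype == 1) { ucenter = as<double>(bias["center"]); uk = as<double>(bias["k"]); }
  double wall_x = NA_REAL, wall_k = 0.0;
  if (btype == 2) {
    h0 = as<double>(bias["h0"]); hw = as<double>(bias["width"]);
    pace = as<int>(bias["pace"]); bf = as<double>(bias["biasfactor"]);
    stop_lo = as<double>(bias["stop_lo"]); stop_hi = as<double>(bias["stop_hi"]);
    freq_adaptive = as<bool>(bias["freq_adaptive"]);
    wall_x = as<double>(bias["wall_x"]); wall_k = as<double>(bias["wall_k"]);
    NumericVector rx = bias["hills_x"], rh = bias["hills_h"];
    hx.assign(rx.begin(), rx.end());
    hh.assign(rh.begin(), rh.end());
  }

  int nrec = nsteps / record_interval;
  NumericVector times(nrec);
  NumericMatrix energies(nrec, NCOMP + 1);
  NumericVector cvs(nrec), bias_e(nrec);
  NumericVector frames(nrec * n * 3);
  std::vector<double> hill_t;

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));
  double comps[NCOMP];
  eval_system(S, p, comps, F);

  double rescaled_time = 0.0, acc_sum = 0.0; // metadynamics bookkeeping
  double arrival = NA_REAL, arrival_rescaled = NA_REAL;
  int next_power = 1; // freq-adaptive: pace doubles when <exp(bV)> crosses 10^next_power
  int rec = 0;
  double cur_cv = (btype > 0) ? cv_drms(p, bp, bs) : 0.0;

  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * F[3*i+d];
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) p[3*i+d] += 0.5 * dt * v[3*i+d];
    }
    // O
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) v[3*i+d] = c1 * v[3*i+d] + c2 * norm_rand();
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) p[3*i+d] += 0.5 * dt * v[3*i+d];
    }
    // force at new positions (+ bias forces)
    eval_system(S, p, comps, F);
    double vbias = 0.0;
    if (btype > 0) {
      cur_cv = cv_drms(p, bp, bs);
      if (btype == 1) {
        vbias = 0.5 * uk * (cur_cv - ucenter) * (cur_cv - ucenter);
        cv_drms_add_force(p, bp, bs, cur_cv, -uk * (cur_cv - ucenter), F, S.frozen);
      } else {
        vbias = metad_bias(cur_cv, hx, hh, hw);
        // force from hills: -dVb/ds * ds/dx
        double dVds = 0.0;
        for (size_t hgi = 0; hgi < hx.size(); ++hgi) {
          double dd = (cur_cv - hx[hgi]) / hw;
          dVds += -hh[hgi] * dd / hw * std::exp(-0.5 * dd * dd);
        }
        // static confining wall (kept out of the acceleration factor)
        if (!ISNA(wall_x) && cur_cv > wall_x)
          dVds += wall_k * (cur_cv - wall_x);
        cv_drms_add_force(p, bp, bs, cur_cv, -dVds, F, S.frozen);
        rescaled_time += dt * std::exp(vbias / temperature);
        acc_sum += std::exp(vbias / temperature);
        if (!ISNA(stop_lo) && cur_cv >= stop_lo && cur_cv <= stop_hi && ISNA(arrival)) {
          arrival = t0 + step * dt;
          arrival_rescaled = rescaled_time;
          break;
        }
        if (pace > 0 && step % pace == 0) {
          double hnew = h0 * std::exp(-vbias / ((bf - 1.0) * temperature));
          hx.push_back(cur_cv); hh.push_back(hnew);
          hill_t.push_back(t0 + step * dt);
          if (freq_adaptive) {
            double acc = acc_sum / step;
            if (acc > std::pow(10.0, next_power)) { pace *= 2; ++next_power; }
          }
        }
      }
    }
    // B
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * F[3*i+d];
    }

    if (step % record_interval == 0 && rec < nrec) {
      double tot = 0.0;
      for (int c = 0; c < NCOMP; ++c) { energies(rec, c) = comps[c]; tot += comps[c]; }
      energies(rec, NCOMP) = tot;
      if (!std::isfinite(tot) || std::fabs(tot) > 1e8)
        stop("energy divergence at t = %f (|E| = %f)", t0 + step * dt, tot);
      times[rec] = t0 + step * dt;
      cvs[rec] = cur_cv;
      bias_e[rec] = (btype == 1) ? 0.5 * uk * (cur_cv - ucenter) * (cur_cv - ucenter)
                                 : vbias;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) frames[rec * 3 * n + 3 * i + d] = p[3*i+d];
      ++rec;
    }
  }

  NumericMatrix posN(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) posN(i, d) = p[3*i+d];
  if (rec < nrec) { // early stop: trim records
    times = NumericVector(times.begin(), times.begin() + rec);
    cvs = NumericVector(cvs.begin(), cvs.begin() + rec);
    bias_e = NumericVector(bias_e.begin(), bias_e.begin() + rec);
    NumericMatrix e2(rec, NCOMP + 1);
    for (int r = 0; r < rec; ++r)
      for (int c = 0; c <= NCOMP; ++c) e2(r, c) = energies(r, c);
    energies = e2;
    frames = NumericVector(frames.begin(), frames.begin() + rec * 3 * n);
  }
  frames.attr("dim") = IntegerVector::create(3, n, rec > 0 ? rec : 0);

  return List::create(
    _["times"] = times, _["frames"] = frames, _["energies"] = energies,
    _["cv"] = cvs, _["bias_energy"] = bias_e, _["final_pos"] = posN,
    _["hills_x"] = NumericVector(hx.begin(), hx.end()),
    _["hills_h"] = NumericVector(hh.begin(), hh.end()),
    _["hill_times"] = NumericVector(hill_t.begin(), hill_t.end()),
    _["rescaled_time"] = rescaled_time,
    _["arrival_time"] = arrival, _["arrival_rescaled"] = arrival_rescaled,
    _["pace_final"] = pace);
}

// ---- 1D double well: V(x) = barrier (x^2 - 1)^2 + tilt * x ----

// [[Rcpp::export]]
List dw_langevin_cpp(double barrier, double tilt, double x0, double dt,
                     double friction, double temperature, int nsteps,
                     int record_interval, List bias) {
  RNGScope scope;
  int btype = as<int>(bias["type"]);
  double ucenter = 0.0, uk = 0.0;
  double h0 = 0.0, hw = 0.1, bf = 5.0, stop_lo = NA_REAL, stop_hi = NA_REAL;
  int pace = 0; bool freq_adaptive = false;
  double wall_x = NA_REAL, wall_k = 0.0;
  std::vector<double> hx, hh, hill_t;
  if (btype == 1) { ucenter = as<double>(bias["center"]); uk = as<double>(bias["k"]); }
  if (btype == 2) {
    h0 = as<double>(bias["h0"]); hw = as<double>(bias["width"]);
    pace = as<int>(bias["pace"]); bf = as<double>(bias["biasfactor"]);
    stop_lo = as<double>(bias["stop_lo"]); stop_hi = as<double>(bias["stop_hi"]);
    freq_adaptive = as<bool>(bias["freq_adaptive"]);
    wall_x = as<double>(bias["wall_x"]); wall_k = as<double>(bias["wall_k"]);
    NumericVector rx = bias["hills_x"], rh = bias["hills_h"];
    hx.assign(rx.begin(), rx.end());
    hh.assign(rh.begin(), rh.end());
  }

  int nrec = nsteps / record_interval;
  NumericVector times(nrec), xs(nrec), es(nrec), bias_e(nrec);
  double x = x0, v = std::sqrt(temperature) * norm_rand();
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));
  double rescaled_time = 0.0, acc_sum = 0.0;
  double arrival = NA_REAL, arrival_rescaled = NA_REAL;
  int next_power = 1, rec = 0;

  double f = -4.0 * barrier * x * (x * x - 1.0) - tilt;
  if (btype == 1) f += -uk * (x - ucenter);

  for (int step = 1; step <= nsteps; ++step) {
    v += 0.5 * dt * f;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * norm_rand();
    x += 0.5 * dt * v;
    f = -4.0 * barrier * x * (x * x - 1.0) - tilt;
    double vbias = 0.0;
    if (btype == 1) {
      vbias = 0.5 * uk * (x - ucenter) * (x - ucenter);
      f += -uk * (x - ucenter);
    } else if (btype == 2) {
      vbias = metad_bias(x, hx, hh, hw);
      double dVds = 0.0;
      for (size_t hgi = 0; hgi < hx.size(); ++hgi) {
        double dd = (x - hx[hgi]) / hw;
        dVds += -hh[hgi] * dd / hw * std::exp(-0.5 * dd * dd);
      }
      if (!ISNA(wall_x) && x > wall_x) dVds += wall_k * (x - wall_x);
      f += -dVds;
      rescaled_time += dt * std::exp(vbias / temperature);
      acc_sum += std::exp(vbias / temperature);
      if (!ISNA(stop_lo) && x >= stop_lo && x <= stop_hi && ISNA(arrival)) {
        arrival = step * dt;
        arrival_rescaled = rescaled_time;
        break;
      }
      if (pace > 0 && step % pace == 0) {
        double hnew = h0 * std::exp(-vbias / ((bf - 1.0) * temperature));
        hx.push_back(x); hh.push_back(hnew);
        hill_t.push_back(step * dt);
        if (freq_adaptive) {
          double acc = acc_sum / step;
          if (acc > std::pow(10.0, next_power)) { pace *= 2; ++next_power; }
        }
      }
    }
    v += 0.5 * dt * f;
    if (step % record_interval == 0 && rec < nrec) {
      times[rec] = step * dt;
      xs[rec] = x;
      double e0 = barrier * (x * x - 1.0) * (x * x - 1.0) + tilt * x;
      es[rec] = e0;
      bias_e[rec] = vbias;
      ++rec;
    }
  }
  if (rec < nrec) {
    times = NumericVector(times.begin(), times.begin() + rec);
    xs = NumericVector(xs.begin(), xs.begin() + rec);
    es = NumericVector(es.begin(), es.begin() + rec);
    bias_e = NumericVector(bias_e.begin(), bias_e.begin() + rec);
  }
  return List::create(
    _["times"] = times, _["x"] = xs, _["energies"] = es, _["bias_energy"] = bias_e,
    _["final_x"] = x,
    _["hills_x"] = NumericVector(hx.begin(), hx.end()),
    _["hills_h"] = NumericVector(hh.begin(), hh.end()),
    _["hill_times"] = NumericVector(hill_t.begin(), hill_t.end()),
    _["rescaled_time"] = rescaled_time,
    _["arrival_time"] = arrival, _["arrival_rescaled"] = arrival_rescaled,
    _["pace_final"] = pace);
}

// first passage of a 1D double well to x >= target, unbiased (oracle helper)
// [[Rcpp::export]]
double dw_first_passage_cpp(double barrier, double tilt, double x0, double dt,
                            double friction, double temperature, double target,
                            int max_steps) {
  RNGScope scope;
  double x = x0, v = std::sqrt(temperature) * norm_rand();
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));
  double f = -4.0 * barrier * x * (x * x - 1.0) - tilt;
  for (int step = 1; step <= max_steps; ++step) {
    v += 0.5 * dt * f;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * norm_rand();
    x += 0.5 * dt * v;
    f = -4.0 * barrier * x * (x * x - 1.0) - tilt;
    v += 0.5 * dt * f;
    if (x >= target) return step * dt;
  }
  return NA_REAL;
}
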