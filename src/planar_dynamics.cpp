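// Planar kinematic-tree rigid-body dynamics and the coupled
// neuromusculoskeletal integration loop.
//
// Bodies form a tree; each body carries exactly one generalized
// coordinate (prismatic-x, prismatic-z, or revolute).  A floating base
// is modelled as two massless prismatic pseudo-bodies followed by a
// revolute body (the trunk).  Revolute coordinates may carry a sense
// (+1/-1) and an offset so that the user-facing coordinate can follow
// an anatomical joint-angle convention (angles increase with
// extension) while the kinematics use counter-clockwise rotations.
//
// Equations of motion: M(q) qdd = Q - b(q,qd) - G(q), assembled from
// CoM Jacobians (mass matrix) and velocity-product accelerations with
// qdd = 0 (bias), which is the standard Lagrangian formulation for a
// tree of rigid links.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Body {
  int parent;       // -1 for root (world)
  int jtype;        // 0 prismatic-x, 1 prismatic-z, 2 revolute
  double sense;     // revolute only: rel angle = offset + sense * q
  double offset;
  double ax, az;    // joint anchor in parent frame
  double mass;
  double comx;      // CoM offset along link x-axis
  double inertia;   // about CoM
  double length;    // distal end at (length, 0) in link frame
};

struct PModel {
  int n;
  std::vector<Body> body;
  std::vector<int> tips;                    // body indices with a tip
  std::vector<std::vector<int> > anc;       // ancestors-or-self per body
  double gravity;
};

struct FKOut {
  // per body
  std::vector<double> th, om;
  std::vector<double> ox, oz, vox, voz;     // joint origin pos/vel
  std::vector<double> cx, cz, vcx, vcz;     // CoM pos/vel
  std::vector<double> bacx, bacz;           // CoM bias acceleration (qdd=0)
};

static PModel model_from_list(const List& ml) {
  PModel m;
  IntegerVector parent = ml["parent"];
  IntegerVector jtype  = ml["jtype"];
  NumericVector sense  = ml["sense"];
  NumericVector offset = ml["offset"];
  NumericVector ax = ml["anchor_x"], az = ml["anchor_z"];
  NumericVector mass = ml["mass"], comx = ml["comx"];
  NumericVector inert = ml["inertia"], len = ml["length"];
  IntegerVector tips = ml["tips"];
  m.n = parent.size();
  m.gravity = as<double>(ml["gravity"]);
  m.body.resize(m.n);
  for (int i = 0; i < m.n; i++) {
    Body& b = m.body[i];
    b.parent = parent[i]; b.jtype = jtype[i];
    b.sense = sense[i]; b.offset = offset[i];
    b.ax = ax[i]; b.az = az[i];
    b.mass = mass[i]; b.comx = comx[i];
    b.inertia = inert[i]; b.length = len[i];
  }
  for (int i = 0; i < tips.size(); i++) m.tips.push_back(tips[i]);
  m.anc.resize(m.n);
  for (int i = 0; i < m.n; i++) {
    int k = i;
    while (k >= 0) { m.anc[i].push_back(k); k = m.body[k].parent; }
  }
  return m;
}

static void fk(const PModel& m, const double* q, const double* qd, FKOut& o) {
  int n = m.n;
  o.th.assign(n, 0.0); o.om.assign(n, 0.0);
  o.ox.assign(n, 0.0); o.oz.assign(n, 0.0);
  o.vox.assign(n, 0.0); o.voz.assign(n, 0.0);
  o.cx.assign(n, 0.0); o.cz.assign(n, 0.0);
  o.vcx.assign(n, 0.0); o.vcz.assign(n, 0.0);
  o.bacx.assign(n, 0.0); o.bacz.assign(n, 0.0);
  // per-body joint-origin bias acceleration
  std::vector<double> aox(n, 0.0), aoz(n, 0.0);
  for (int i = 0; i < n; i++) {
    const Body& b = m.body[i];
    double thp = 0, omp = 0, oxp = 0, ozp = 0, vxp = 0, vzp = 0, axp = 0, azp = 0;
    if (b.parent >= 0) {
      int p = b.parent;
      thp = o.th[p]; omp = o.om[p];
      oxp = o.ox[p]; ozp = o.oz[p];
      vxp = o.vox[p]; vzp = o.voz[p];
      axp = aox[p]; azp = aoz[p];
    }
    double cthp = std::cos(thp), sthp = std::sin(thp);
    // anchor in world
    double wx = cthp * b.ax - sthp * b.az;
    double wz = sthp * b.ax + cthp * b.az;
    if (b.jtype == 2) {
      double rel = b.offset + b.sense * q[i];
      o.th[i] = thp + rel;
      o.om[i] = omp + b.sense * qd[i];
      o.ox[i] = oxp + wx;
      o.oz[i] = ozp + wz;
      // v = v_p + om_p x w  (2D: om x (x,z) = (-om*z, om*x))
      o.vox[i] = vxp - omp * wz;
      o.voz[i] = vzp + omp * wx;
      // bias acc: a_p + alpha_p x w (=0) - om_p^2 w
      aox[i] = axp - omp * omp * wx;
      aoz[i] = azp - omp * omp * wz;
    } else {
      double ex = (b.jtype == 0) ? 1.0 : 0.0;
      double ez = (b.jtype == 0) ? 0.0 : 1.0;
      double dx = cthp * ex - sthp * ez;   // axis in world
      double dz = sthp * ex + cthp * ez;
      o.th[i] = thp; o.om[i] = omp;
      double rx = wx + q[i] * dx, rz = wz + q[i] * dz;
      o.ox[i] = oxp + rx;
      o.oz[i] = ozp + rz;
      o.vox[i] = vxp - omp * rz + qd[i] * dx;
      o.voz[i] = vzp + omp * rx + qd[i] * dz;
      // bias: a_p - om^2 r + 2 om x (qd * d)
      aox[i] = axp - omp * omp * rx - 2.0 * omp * qd[i] * dz;
      aoz[i] = azp - omp * omp * rz + 2.0 * omp * qd[i] * dx;
    }
    double cth = std::cos(o.th[i]), sth = std::sin(o.th[i]);
    double dxc = cth * b.comx, dzc = sth * b.comx;
    o.cx[i] = o.ox[i] + dxc;
    o.cz[i] = o.oz[i] + dzc;
    o.vcx[i] = o.vox[i] - o.om[i] * dzc;
    o.vcz[i] = o.voz[i] + o.om[i] * dxc;
    o.bacx[i] = aox[i] - o.om[i] * o.om[i] * dxc;
    o.bacz[i] = aoz[i] - o.om[i] * o.om[i] * dzc;
  }
}

// Jacobian column of a point attached to body i w.r.t. coordinate k
// (k must be an ancestor-or-self of i).  Returns (Jx, Jz, Jth).
static inline void jac_col(const PModel& m, const FKOut& o, int k,
                           double px, double pz,
                           double& jx, double& jz, double& jth) {
  const Body& b = m.body[k];
  if (b.jtype == 2) {
    jx = -b.sense * (pz - o.oz[k]);
    jz =  b.sense * (px - o.ox[k]);
    jth = b.sense;
  } else {
    double thp = 0;
    if (b.parent >= 0) thp = o.th[b.parent];
    double ex = (b.jtype == 0) ? 1.0 : 0.0;
    double ez = (b.jtype == 0) ? 0.0 : 1.0;
    jx = std::cos(thp) * ex - std::sin(thp) * ez;
    jz = std::sin(thp) * ex + std::cos(thp) * ez;
    jth = 0.0;
  }
}

static void mass_matrix(const PModel& m, const FKOut& o, arma::mat& M) {
  int n = m.n;
  M.zeros(n, n);
  for (int i = 0; i < n; i++) {
    const Body& b = m.body[i];
    if (b.mass == 0.0 && b.inertia == 0.0) continue;
    const std::vector<int>& A = m.anc[i];
    size_t na = A.size();
    std::vector<double> jx(na), jz(na), jth(na);
    for (size_t a = 0; a < na; a++)
      jac_col(m, o, A[a], o.cx[i], o.cz[i], jx[a], jz[a], jth[a]);
    for (size_t a = 0; a < na; a++)
      for (size_t c = a; c < na; c++) {
        double v = b.mass * (jx[a] * jx[c] + jz[a] * jz[c]) +
                   b.inertia * jth[a] * jth[c];
        M(A[a], A[c]) += v;
        if (a != c) M(A[c], A[a]) += v;
      }
  }
}

// bias(q,qd) + gravity, as generalized forces on the LHS:
// M qdd + bias = Q
static void bias_vector(const PModel& m, const FKOut& o, arma::vec& bias) {
  int n = m.n;
  bias.zeros(n);
  for (int i = 0; i < n; i++) {
    const Body& b = m.body[i];
    if (b.mass == 0.0 && b.inertia == 0.0) continue;
    const std::vector<int>& A = m.anc[i];
    for (size_t a = 0; a < A.size(); a++) {
      double jx, jz, jth;
      jac_col(m, o, A[a], o.cx[i], o.cz[i], jx, jz, jth);
      bias[A[a]] += b.mass * (jx * o.bacx[i] + jz * o.bacz[i]) +
                    b.mass * m.gravity * jz;
      // revolute bias alpha terms vanish for qdd = 0 in a tree
    }
  }
}

static void tip_state(const PModel& m, const FKOut& o, int t,
                      double& px, double& pz, double& vx, double& vz) {
  int i = m.tips[t];
  const Body& b = m.body[i];
  double cth = std::cos(o.th[i]), sth = std::sin(o.th[i]);
  double dx = cth * b.length, dz = sth * b.length;
  px = o.ox[i] + dx; pz = o.oz[i] + dz;
  vx = o.vox[i] - o.om[i] * dz;
  vz = o.voz[i] + o.om[i] * dx;
}

// Generalized forces from planar forces applied at the limb tips.
static void tip_force_Q(const PModel& m, const FKOut& o,
                        const arma::mat& F, arma::vec& Q) {
  for (size_t t = 0; t < m.tips.size(); t++) {
    if (F(t, 0) == 0.0 && F(t, 1) == 0.0) continue;
    int i = m.tips[t];
    double px, pz, vx, vz;
    tip_state(m, o, t, px, pz, vx, vz);
    const std::vector<int>& A = m.anc[i];
    for (size_t a = 0; a < A.size(); a++) {
      double jx, jz, jth;
      jac_col(m, o, A[a], px, pz, jx, jz, jth);
      Q[A[a]] += jx * F(t, 0) + jz * F(t, 1);
    }
  }
}

static arma::vec fwd_dyn(const PModel& m, const double* q, const double* qd,
                         const arma::vec& Qapp, const arma::mat& tipF) {
  FKOut o;
  fk(m, q, qd, o);
  arma::mat M;
  arma::vec b, Q = Qapp;
  mass_matrix(m, o, M);
  bias_vector(m, o, b);
  tip_force_Q(m, o, tipF, Q);
  return arma::solve(M, Q - b, arma::solve_opts::likely_sympd);
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export(name = ".pd_fk")]]
List pd_fk(List ml, NumericVector q, NumericVector qd) {
  PModel m = model_from_list(ml);
  FKOut o;
  fk(m, q.begin(), qd.begin(), o);
  int nt = m.tips.size();
  NumericMatrix tp(nt, 2), tv(nt, 2);
  for (int t = 0; t < nt; t++) {
    double px, pz, vx, vz;
    tip_state(m, o, t, px, pz, vx, vz);
    tp(t, 0) = px; tp(t, 1) = pz; tv(t, 0) = vx; tv(t, 1) = vz;
  }
  NumericMatrix orig(m.n, 2), ov(m.n, 2), com(m.n, 2), vcom(m.n, 2);
  for (int i = 0; i < m.n; i++) {
    orig(i, 0) = o.ox[i]; orig(i, 1) = o.oz[i];
    ov(i, 0) = o.vox[i]; ov(i, 1) = o.voz[i];
    com(i, 0) = o.cx[i]; com(i, 1) = o.cz[i];
    vcom(i, 0) = o.vcx[i]; vcom(i, 1) = o.vcz[i];
  }
  return List::create(_["theta"] = wrap(o.th), _["omega"] = wrap(o.om),
                      _["origin"] = orig, _["origin_vel"] = ov,
                      _["com"] = com, _["com_vel"] = vcom,
                      _["tip_pos"] = tp, _["tip_vel"] = tv);
}

// [[Rcpp::export(name = ".pd_mass_matrix")]]
NumericMatrix pd_mass_matrix(List ml, NumericVector q) {
  PModel m = model_from_list(ml);
  std::vector<double> qd(m.n, 0.0);
  FKOut o;
  fk(m, q.begin(), qd.data(), o);
  arma::mat M;
  mass_matrix(m, o, M);
  return wrap(M);
}

// [[Rcpp::export(name = ".pd_bias")]]
NumericVector pd_bias(List ml, NumericVector q, NumericVector qd) {
  PModel m = model_from_list(ml);
  FKOut o;
  fk(m, q.begin(), qd.begin(), o);
  arma::vec b;
  bias_vector(m, o, b);
  return wrap(b);
}

// [[Rcpp::export(name = ".pd_fwd_dyn")]]
NumericVector pd_fwd_dyn(List ml, NumericVector q, NumericVector qd,
                         NumericVector Qapp, NumericMatrix tipF) {
  PModel m = model_from_list(ml);
  arma::vec Q(Qapp.begin(), m.n);
  arma::mat F(tipF.begin(), tipF.nrow(), 2);
  arma::vec qdd = fwd_dyn(m, q.begin(), qd.begin(), Q, F);
  return wrap(qdd);
}

// [[Rcpp::export(name = ".pd_energy")]]
double pd_energy(List ml, NumericVector q, NumericVector qd) {
  PModel m = model_from_list(ml);
  FKOut o;
  fk(m, q.begin(), qd.begin(), o);
  double E = 0.0;
  for (int i = 0; i < m.n; i++) {
    const Body& b = m.body[i];
    E += 0.5 * b.mass * (o.vcx[i] * o.vcx[i] + o.vcz[i] * o.vcz[i]) +
         0.5 * b.inertia * o.om[i] * o.om[i] +
         b.mass * m.gravity * o.cz[i];
  }
  return E;
}

// ================================================================== sim

struct Muscle {
  double fmax, tact, tdeact, lmax, base;
  int nj;
  int j[2];          // coordinate index in q
  double lsign[2];   // +1: lengthens as angle increases
  double coef[2];    // deg per 1% length change
  double neut[2];    // neutral angle, deg
  double ma[2];      // moment arm, m
  int osc;           // oscillator index 0..3 (LF RF LH RH)
  int limb;          // tip index 0..3
  double Kh, Dh, Ksp;
  double w[4];       // nominal synergy weights
};

struct Curves {
  double fl_w;                   // force-length width
  double fv_vmax;                // concentric cutoff (normalized velocity)
  double fv_c;                   // concentric shape factor
  double fv_ecc_a, fv_ecc_b;     // eccentric branch parameters
  double fv_ecc_cap;
  double fp_c, fp_k;             // passive exponential
  double fp_damp;                // passive parallel damping (per vbar)
};

static inline double f_l(const Curves& c, double l) {
  double u = (l - 1.0) / c.fl_w;
  return std::exp(-u * u);
}
static inline double f_v(const Curves& c, double v) {
  if (v >= c.fv_vmax) return 0.0;
  if (v >= 0.0)
    return (1.0 - v / c.fv_vmax) / (1.0 + v / (c.fv_vmax * c.fv_c));
  double f = c.fv_ecc_cap - (c.fv_ecc_cap - 1.0) * (1.0 + v) /
             (1.0 - c.fv_ecc_a * v / c.fv_ecc_b);
  if (f > c.fv_ecc_cap) f = c.fv_ecc_cap;
  if (f < 1.0) f = 1.0;
  return f;
}
static inline double f_p(const Curves& c, double l) {
  if (l <= 1.0) return 0.0;
  return c.fp_c * (std::exp(c.fp_k * (l - 1.0)) - 1.0);
}
// passive viscosity: resists lengthening only (vbar < 0), so it never
// saps active force during shortening
static inline double f_damp(const Curves& c, double v) {
  return (v < 0.0) ? -c.fp_damp * v : 0.0;
}

static std::vector<Muscle> muscles_from_list(const List& msl) {
  NumericVector fmax = msl["fmax"], tact = msl["tact"], tdeact = msl["tdeact"];
  NumericVector lmax = msl["lmax"], base = msl["base_len"];
  IntegerVector nj = msl["njoints"], j1 = msl["j1"], j2 = msl["j2"];
  NumericVector ls1 = msl["lsign1"], ls2 = msl["lsign2"];
  NumericVector c1 = msl["coef1"], c2 = msl["coef2"];
  NumericVector n1 = msl["neut1"], n2 = msl["neut2"];
  NumericVector ma1 = msl["ma1"], ma2 = msl["ma2"];
  IntegerVector osc = msl["osc"], limb = msl["limb"];
  NumericVector Kh = msl["Kh"], Dh = msl["Dh"], Ksp = msl["Ksp"];
  NumericMatrix w = msl["w_hat"];
  int nm = fmax.size();
  std::vector<Muscle> mus(nm);
  for (int i = 0; i < nm; i++) {
    Muscle& u = mus[i];
    u.fmax = fmax[i]; u.tact = tact[i]; u.tdeact = tdeact[i];
    u.lmax = lmax[i]; u.base = base[i];
    u.nj = nj[i]; u.j[0] = j1[i]; u.j[1] = j2[i];
    u.lsign[0] = ls1[i]; u.lsign[1] = ls2[i];
    u.coef[0] = c1[i]; u.coef[1] = c2[i];
    u.neut[0] = n1[i]; u.neut[1] = n2[i];
    u.ma[0] = ma1[i]; u.ma[1] = ma2[i];
    u.osc = osc[i]; u.limb = limb[i];
    u.Kh = Kh[i]; u.Dh = Dh[i]; u.Ksp = Ksp[i];
    for (int k = 0; k < 4; k++) u.w[k] = w(i, k);
  }
  return mus;
}

static const double RAD2DEG = 57.29577951308232;

static inline void muscle_kin(const Muscle& u, const double* q,
                              const double* qd, double vnorm,
                              double& lbar, double& vbar) {
  lbar = u.base;
  double dldt = 0.0;
  for (int k = 0; k < u.nj; k++) {
    double ang = q[u.j[k]] * RAD2DEG;
    double rate = qd[u.j[k]] * RAD2DEG;
    lbar += u.lsign[k] * (ang - u.neut[k]) / u.coef[k] * 0.01;
    dldt += u.lsign[k] * rate / u.coef[k] * 0.01;
  }
  vbar = -dldt / vnorm;
}

// activation ODE rhs (Eq form: tact * adot + {tact/tdeact + (1 - tact/tdeact) u} a = u)
static inline double act_rhs(double a, double u, double tact, double tdeact) {
  double r = tact / tdeact;
  return (u - (r + (1.0 - r) * u) * a) / tact;
}

struct Ctrl {
  double K1, K2, Delta;
  double Tfl, beta_hat;
  double Phi_hat[4], Psi_hat[4];
  double h0sh_hat, h0hip_hat, v0_hat;
  double aSh, aHip, aSpd;
  double tauDelay;
  double vnorm;                  // velocity normalization (1/s units of lmax)
  double ramp_rate;              // d beta per gait cycle
};

static Ctrl ctrl_from_list(const List& cl) {
  Ctrl c;
  c.K1 = as<double>(cl["K1"]); c.K2 = as<double>(cl["K2"]);
  c.Delta = as<double>(cl["Delta"]);
  c.Tfl = as<double>(cl["Tfl"]); c.beta_hat = as<double>(cl["beta_hat"]);
  NumericVector ph = cl["Phi_hat"], ps = cl["Psi_hat"];
  for (int i = 0; i < 4; i++) { c.Phi_hat[i] = ph[i]; c.Psi_hat[i] = ps[i]; }
  c.h0sh_hat = as<double>(cl["h0_shoulder"]);
  c.h0hip_hat = as<double>(cl["h0_hip"]);
  c.v0_hat = as<double>(cl["v0"]);
  c.aSh = as<double>(cl["alpha_shoulder"]);
  c.aHip = as<double>(cl["alpha_hip"]);
  c.aSpd = as<double>(cl["alpha_speed"]);
  c.tauDelay = as<double>(cl["tau_delay"]);
  c.vnorm = as<double>(cl["vnorm"]);
  c.ramp_rate = as<double>(cl["ramp_rate"]);
  return c;
}

static const double TWOPI = 6.283185307179586;

static inline double wrap2pi(double x) {
  x -= TWOPI * std::floor(x / TWOPI);
  if (x >= TWOPI) x = 0.0;
  return x;
}

// Pulse phases at extension fraction beta (Eq-12-style rescaling).
static void scaled_schedule(const Ctrl& c, double beta,
                            double* Phi, double* Psi) {
  double bh = c.beta_hat;
  for (int i = 0; i < 4; i++) {
    if (i < 2) {
      Phi[i] = beta / bh * c.Phi_hat[i];
      Psi[i] = beta / bh * c.Psi_hat[i];
    } else {
      double s = (1.0 - beta) / (1.0 - bh);
      double t = TWOPI * (beta - bh) / (1.0 - bh);
      Phi[i] = s * c.Phi_hat[i] + t;
      Psi[i] = s * c.Psi_hat[i] + t;
    }
  }
}

// Oscillator coupling: contralateral antiphase, ipsilateral offset Delta
// (+Delta in the forelimb equations, -Delta in the hindlimb ones).
static void osc_rhs(const Ctrl& c, double T, const double* phi, double* dphi) {
  double w = TWOPI / T;
  // order: 0 LF, 1 RF, 2 LH, 3 RH
  dphi[0] = w - c.K1 * std::sin(phi[0] - phi[1] - M_PI)
              - c.K2 * std::sin(phi[0] - phi[2] + c.Delta);
  dphi[1] = w - c.K1 * std::sin(phi[1] - phi[0] - M_PI)
              - c.K2 * std::sin(phi[1] - phi[3] + c.Delta);
  dphi[2] = w - c.K1 * std::sin(phi[2] - phi[3] - M_PI)
              - c.K2 * std::sin(phi[2] - phi[0] - c.Delta);
  dphi[3] = w - c.K1 * std::sin(phi[3] - phi[2] - M_PI)
              - c.K2 * std::sin(phi[3] - phi[1] - c.Delta);
}

struct SimPar {
  double dt, duration;
  int log_every;
  double kv, cv, kh, ch;         // contact
  double mu;                     // friction-cone bound |Fx| <= mu Fz
  double pitch_max;              // |pitch| failure bound (rad)
  double height_fail_frac;
  double qd_max;
  double jl_min, jl_max;         // joint-range hard stops (rad)
  double jl_k, jl_c;             // stop stiffness / damping
  // start-up assist: trunk height/pitch PD faded out by assist_end
  double assist_until, assist_end, assist_floor;
  double assist_kz, assist_cz, assist_kp, assist_cp;
  double assist_zref, assist_pref;
};

// Continuous state layout helper
struct StateIdx {
  int nq, nm;
  int q0, qd0, a0, aS0, aH0, aV0, ph0, len;
  StateIdx(int nq_, int nm_) : nq(nq_), nm(nm_) {
    q0 = 0; qd0 = nq; a0 = 2 * nq;
    aS0 = a0 + nm; aH0 = aS0 + nm; aV0 = aH0 + nm;
    ph0 = aV0 + nm; len = ph0 + 4;
  }
};

struct DerivCtx {
  double assist_w;
  const PModel* m;
  const std::vector<Muscle>* mus;
  const Curves* cv;
  const Ctrl* ct;
  const SimPar* sp;
  double beta;
  double T;
  // zero-order-hold controls for this step
  std::vector<double> u, uS, uH, uV;
  // contact anchors
  double anchor_x[4];
  bool anchored[4];
};

// contact force at a tip given its position/velocity
static inline void contact_force(const SimPar& sp, const DerivCtx& cx, int t,
                                 double px, double pz, double vx, double vz,
                                 double& Fx, double& Fz) {
  Fx = 0.0; Fz = 0.0;
  if (pz >= 0.0) return;
  Fz = -sp.kv * pz - sp.cv * vz;
  if (Fz < 0.0) Fz = 0.0;
  if (cx.anchored[t]) {
    Fx = -sp.kh * (px - cx.anchor_x[t]) - sp.ch * vx;
    double lim = sp.mu * Fz;           // Coulomb friction cone
    if (Fx > lim) Fx = lim;
    if (Fx < -lim) Fx = -lim;
  }
}

static void deriv(const DerivCtx& cx, const StateIdx& S,
                  const double* x, double* dx) {
  const PModel& m = *cx.m;
  const std::vector<Muscle>& mus = *cx.mus;
  int nq = S.nq, nm = S.nm;
  const double* q = x + S.q0;
  const double* qd = x + S.qd0;

  FKOut o;
  fk(m, q, qd, o);

  // muscle tensions and joint torques
  arma::vec Q(nq, arma::fill::zeros);
  for (int i = 0; i < nm; i++) {
    const Muscle& u = mus[i];
    double lbar, vbar;
    muscle_kin(u, q, qd, cx.ct->vnorm, lbar, vbar);
    double a = x[S.a0 + i];
    double F = u.fmax * (a * f_l(*cx.cv, lbar) * f_v(*cx.cv, vbar) +
                         f_p(*cx.cv, lbar) + f_damp(*cx.cv, vbar));
    if (F < 0.0) F = 0.0;
    for (int k = 0; k < u.nj; k++)
      Q[u.j[k]] += -u.lsign[k] * u.ma[k] * F;   // extensor-positive torque
  }

  // start-up assist (faded out): steadies trunk height and pitch while
  // the gait entrains, zero afterwards
  if (cx.assist_w > 0.0) {
    const SimPar& sp = *cx.sp;
    Q[1] += cx.assist_w * (-sp.assist_kz * (q[1] - sp.assist_zref) -
                           sp.assist_cz * qd[1]);
    Q[2] += cx.assist_w * (-sp.assist_kp * (q[2] - sp.assist_pref) -
                           sp.assist_cp * qd[2]);
  }

  // anatomical joint-range stops (one-sided spring, damped into the stop)
  {
    const SimPar& sp = *cx.sp;
    for (int j = 3; j < nq; j++) {
      if (q[j] > sp.jl_max) {
        Q[j] += -sp.jl_k * (q[j] - sp.jl_max);
        if (qd[j] > 0) Q[j] += -sp.jl_c * qd[j];
      } else if (q[j] < sp.jl_min) {
        Q[j] += -sp.jl_k * (q[j] - sp.jl_min);
        if (qd[j] < 0) Q[j] += -sp.jl_c * qd[j];
      }
    }
  }

  // contact forces
  arma::mat tf(4, 2, arma::fill::zeros);
  for (int t = 0; t < 4; t++) {
    double px, pz, vx, vz, Fx, Fz;
    tip_state(m, o, t, px, pz, vx, vz);
    contact_force(*cx.sp, cx, t, px, pz, vx, vz, Fx, Fz);
    tf(t, 0) = Fx; tf(t, 1) = Fz;
  }

  arma::mat M;
  arma::vec b;
  mass_matrix(m, o, M);
  bias_vector(m, o, b);
  tip_force_Q(m, o, tf, Q);
  arma::vec qdd = arma::solve(M, Q - b, arma::solve_opts::likely_sympd);

  for (int k = 0; k < nq; k++) {
    dx[S.q0 + k] = qd[k];
    dx[S.qd0 + k] = qdd[k];
  }
  for (int i = 0; i < nm; i++) {
    const Muscle& u = mus[i];
    dx[S.a0 + i]  = act_rhs(x[S.a0 + i],  cx.u[i],  u.tact, u.tdeact);
    dx[S.aS0 + i] = act_rhs(x[S.aS0 + i], cx.uS[i], u.tact, u.tdeact);
    dx[S.aH0 + i] = act_rhs(x[S.aH0 + i], cx.uH[i], u.tact, u.tdeact);
    dx[S.aV0 + i] = act_rhs(x[S.aV0 + i], cx.uV[i], u.tact, u.tdeact);
  }
  osc_rhs(*cx.ct, cx.T, x + S.ph0, dx + S.ph0);
}

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List ml, List msl, List cl, List spl, List init) {
  PModel m = model_from_list(ml);
  std::vector<Muscle> mus = muscles_from_list(msl);
  Ctrl ct = ctrl_from_list(cl);
  List cvl = msl["curves"];
  Curves cv;
  cv.fl_w = as<double>(cvl["fl_width"]);
  cv.fv_vmax = as<double>(cvl["fv_vmax"]);
  cv.fv_c = as<double>(cvl["fv_shape"]);
  cv.fv_ecc_a = as<double>(cvl["fv_ecc_a"]);
  cv.fv_ecc_b = as<double>(cvl["fv_ecc_b"]);
  cv.fv_ecc_cap = as<double>(cvl["fv_ecc_cap"]);
  cv.fp_c = as<double>(cvl["fp_scale"]);
  cv.fp_k = as<double>(cvl["fp_rate"]);
  cv.fp_damp = as<double>(cvl["fp_damp"]);

  SimPar sp;
  sp.dt = as<double>(spl["dt"]);
  sp.duration = as<double>(spl["duration"]);
  sp.log_every = as<int>(spl["log_every"]);
  sp.kv = as<double>(spl["k_vert"]); sp.cv = as<double>(spl["c_vert"]);
  sp.kh = as<double>(spl["k_horiz"]); sp.ch = as<double>(spl["c_horiz"]);
  sp.mu = as<double>(spl["mu"]);
  sp.pitch_max = as<double>(spl["pitch_max"]);
  sp.height_fail_frac = as<double>(spl["height_fail_frac"]);
  sp.qd_max = as<double>(spl["qd_max"]);
  sp.jl_min = as<double>(spl["jl_min"]); sp.jl_max = as<double>(spl["jl_max"]);
  sp.jl_k = as<double>(spl["jl_k"]); sp.jl_c = as<double>(spl["jl_c"]);
  sp.assist_until = as<double>(spl["assist_until"]);
  sp.assist_end = as<double>(spl["assist_end"]);
  sp.assist_floor = as<double>(spl["assist_floor"]);
  sp.assist_kz = as<double>(spl["assist_kz"]);
  sp.assist_cz = as<double>(spl["assist_cz"]);
  sp.assist_kp = as<double>(spl["assist_kp"]);
  sp.assist_cp = as<double>(spl["assist_cp"]);
  sp.assist_zref = as<double>(spl["assist_zref"]);
  sp.assist_pref = as<double>(spl["assist_pref"]);

  int nq = m.n, nm = mus.size();
  StateIdx S(nq, nm);
  std::vector<double> x(S.len, 0.0);

  double beta = as<double>(spl["beta_start"]);
  double beta_target = as<double>(spl["beta_target"]);
  long step0 = 0;
  int delay_steps = (int)std::lround(ct.tauDelay / sp.dt);
  if (delay_steps < 1) delay_steps = 1;
  std::vector<double> bufH(delay_steps * nm, 0.0), bufV(delay_steps * nm, 0.0);
  DerivCtx cx;
  cx.m = &m; cx.mus = &mus; cx.cv = &cv; cx.ct = &ct; cx.sp = &sp;
  cx.u.assign(nm, 0.0); cx.uS.assign(nm, 0.0);
  cx.uH.assign(nm, 0.0); cx.uV.assign(nm, 0.0);
  bool stance_prev[4] = {false, false, false, false};
  for (int t = 0; t < 4; t++) { cx.anchored[t] = false; cx.anchor_x[t] = 0.0; }
  double t0 = 0.0;

  if (init.containsElementNamed("resume") && as<bool>(init["resume"])) {
    NumericVector xv = init["state"];
    std::copy(xv.begin(), xv.end(), x.begin());
    NumericVector av = init["anchor_x"];
    LogicalVector an = init["anchored"], stp = init["stance"];
    for (int t = 0; t < 4; t++) {
      cx.anchor_x[t] = av[t]; cx.anchored[t] = an[t];
      stance_prev[t] = stp[t];
    }
    NumericVector bh = init["bufH"], bv = init["bufV"];
    std::copy(bh.begin(), bh.end(), bufH.begin());
    std::copy(bv.begin(), bv.end(), bufV.begin());
    step0 = (long)as<double>(init["step"]);
    t0 = as<double>(init["time"]);
    beta = as<double>(init["beta"]);
  } else {
    NumericVector q0v = init["q"], qd0v = init["qd"], a0v = init["a"],
                  ph0v = init["phi"];
    for (int k = 0; k < nq; k++) { x[S.q0 + k] = q0v[k]; x[S.qd0 + k] = qd0v[k]; }
    for (int i = 0; i < nm; i++) {
      x[S.a0 + i] = a0v[i];
      x[S.aS0 + i] = a0v[i];
    }
    for (int k = 0; k < 4; k++) x[S.ph0 + k] = ph0v[k];
  }

  long nsteps = (long)std::llround(sp.duration / sp.dt);
  long nlog = nsteps / sp.log_every + 1;

  NumericVector Lt(nlog), Lbeta(nlog);
  NumericMatrix Lq(nlog, nq), Lqd(nlog, nq), Lphi(nlog, 4);
  NumericMatrix Ltf(nlog, 8);
  IntegerMatrix Lst(nlog, 4);
  NumericMatrix La(nlog, nm), Lu(nlog, nm), LuS(nlog, nm), LuH(nlog, nm),
      LuV(nlog, nm), LF(nlog, nm), Llb(nlog, nm), Lvb(nlog, nm);
  NumericMatrix Lacc(nlog, 10);   // cum: +,-,S+,S-,H+,H-,V+,V-,P+,P-
  std::vector<std::vector<double> > td(4), lo(4);

  double acc[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  double prevP[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  bool havePrevP = false;

  std::string status = "ok";
  double fail_time = NA_REAL;
  int li = 0;

  std::vector<double> k1(S.len), k2(S.len), k3(S.len), k4(S.len), xt(S.len);
  std::vector<double> Fm(nm), lbars(nm), vbars(nm);

  for (long n = 0; n <= nsteps; n++) {
    double tnow = t0 + n * sp.dt;
    long gstep = step0 + n;

    // --- sense / contact bookkeeping at step boundary
    FKOut o;
    fk(m, &x[S.q0], &x[S.qd0], o);
    double tpx[4], tpz[4], tvx[4], tvz[4], cFx[4], cFz[4];
    bool stance[4];
    for (int t = 0; t < 4; t++) {
      tip_state(m, o, t, tpx[t], tpz[t], tvx[t], tvz[t]);
      if (tpz[t] < 0.0 && !cx.anchored[t]) {
        cx.anchored[t] = true;
        cx.anchor_x[t] = tpx[t];
      } else if (tpz[t] >= 0.0 && cx.anchored[t]) {
        cx.anchored[t] = false;
      }
      contact_force(sp, cx, t, tpx[t], tpz[t], tvx[t], tvz[t], cFx[t], cFz[t]);
      if (cx.anchored[t]) {
        // if the friction cone saturated, let the anchor slip so the
        // spring tracks the sliding foot
        double Fs = -sp.kh * (tpx[t] - cx.anchor_x[t]) - sp.ch * tvx[t];
        double lim = sp.mu * cFz[t];
        if (Fs > lim || Fs < -lim)
          cx.anchor_x[t] = tpx[t] + (cFx[t] + sp.ch * tvx[t]) / sp.kh;
      }
      stance[t] = (cFz[t] > 0.0);
      if (stance[t] && !stance_prev[t]) td[t].push_back(tnow);
      if (!stance[t] && stance_prev[t]) lo[t].push_back(tnow);
      stance_prev[t] = stance[t];
    }

    // --- control (zero-order hold over the step)
    if (tnow <= sp.assist_until) cx.assist_w = 1.0;
    else if (tnow < sp.assist_end)
      cx.assist_w = sp.assist_floor + (1.0 - sp.assist_floor) *
        (sp.assist_end - tnow) / (sp.assist_end - sp.assist_until);
    else cx.assist_w = sp.assist_floor;
    cx.beta = beta;
    cx.T = ct.Tfl / (1.0 - beta);
    double Phi[4], Psi[4];
    scaled_schedule(ct, beta, Phi, Psi);
    double wsc = (1.0 - beta) / (1.0 - ct.beta_hat);
    double h0sh = ct.h0sh_hat + ct.aSh * (beta - ct.beta_hat);
    double h0hip = ct.h0hip_hat + ct.aHip * (beta - ct.beta_hat);
    double v0 = ct.v0_hat + ct.aSpd * (beta - ct.beta_hat);
    // sensed quantities: shoulder origins bodies 3 (L) / 5 (R),
    // hip origins bodies 7 (L) / 10 (R), trunk CoM velocity body 2
    double hsh[2] = {o.oz[3], o.oz[5]};
    double hshd[2] = {o.voz[3], o.voz[5]};
    double hhip[2] = {o.oz[7], o.oz[10]};
    double hhipd[2] = {o.voz[7], o.voz[10]};
    double vfwd = o.vcx[2];

    int slot = (int)(gstep % delay_steps);
    for (int i = 0; i < nm; i++) {
      const Muscle& u = mus[i];
      double phi_i = wrap2pi(x[S.ph0 + u.osc]);
      double usyn = 0.0;
      for (int p = 0; p < 4; p++) {
        if (phi_i >= Phi[p] && phi_i < Psi[p]) {
          double w = u.w[p];
          if (p < 2) w *= wsc;
          usyn += w;
        }
      }
      // regulator command at sensing time (stance-gated), then delayed
      double pH = 0.0, pV = 0.0;
      if (stance[u.limb]) {
        int side = (u.limb == 0 || u.limb == 2) ? 0 : 1; // L tips 0,2
        bool fore = (u.limb < 2);
        if (u.Kh != 0.0 || u.Dh != 0.0) {
          if (fore)
            pH = -u.Kh * (hsh[side] - h0sh) - u.Dh * hshd[side];
          else
            pH = -u.Kh * (hhip[side] - h0hip) - u.Dh * hhipd[side];
        }
        if (u.Ksp != 0.0) pV = -u.Ksp * (vfwd - v0);
      }
      double dH = 0.0, dV = 0.0;
      if (gstep >= delay_steps) {
        dH = bufH[slot * nm + i];
        dV = bufV[slot * nm + i];
      }
      bufH[slot * nm + i] = pH;
      bufV[slot * nm + i] = pV;

      double ut = usyn + dH + dV;
      cx.u[i] = std::min(1.0, std::max(0.0, ut));
      cx.uS[i] = std::min(1.0, std::max(0.0, usyn));
      cx.uH[i] = std::min(1.0, std::max(0.0, dH));
      cx.uV[i] = std::min(1.0, std::max(0.0, dV));
    }

    // --- instantaneous muscle mechanics (for logging + work accumulators)
    double P[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int i = 0; i < nm; i++) {
      const Muscle& u = mus[i];
      double lbar, vbar;
      muscle_kin(u, &x[S.q0], &x[S.qd0], ct.vnorm, lbar, vbar);
      lbars[i] = lbar; vbars[i] = vbar;
      double fl = f_l(cv, lbar), fv = f_v(cv, vbar);
      double fp = f_p(cv, lbar) + f_damp(cv, vbar);
      double F = u.fmax * (x[S.a0 + i] * fl * fv + fp);
      if (F < 0.0) F = 0.0;
      Fm[i] = F;
      double vm = vbar * ct.vnorm * u.lmax;   // m/s, contraction-positive
      double vp = vm > 0 ? vm : 0.0, vn = vm < 0 ? -vm : 0.0;
      P[0] += F * vp; P[1] += F * vn;
      double FS = u.fmax * x[S.aS0 + i] * fl * fv;
      double FH = u.fmax * x[S.aH0 + i] * fl * fv;
      double FV = u.fmax * x[S.aV0 + i] * fl * fv;
      double FP = u.fmax * fp;
      P[2] += FS * vp; P[3] += FS * vn;
      P[4] += FH * vp; P[5] += FH * vn;
      P[6] += FV * vp; P[7] += FV * vn;
      P[8] += FP * vp; P[9] += FP * vn;
    }
    if (havePrevP)
      for (int k = 0; k < 10; k++) acc[k] += 0.5 * (prevP[k] + P[k]) * sp.dt;
    for (int k = 0; k < 10; k++) prevP[k] = P[k];
    havePrevP = true;

    // --- logging
    if (n % sp.log_every == 0 && li < nlog) {
      Lt[li] = tnow; Lbeta[li] = beta;
      for (int k = 0; k < nq; k++) { Lq(li, k) = x[S.q0 + k]; Lqd(li, k) = x[S.qd0 + k]; }
      for (int k = 0; k < 4; k++) {
        Lphi(li, k) = wrap2pi(x[S.ph0 + k]);
        Lst(li, k) = stance[k] ? 1 : 0;
        Ltf(li, 2 * k) = cFx[k]; Ltf(li, 2 * k + 1) = cFz[k];
      }
      for (int i = 0; i < nm; i++) {
        La(li, i) = x[S.a0 + i]; Lu(li, i) = cx.u[i];
        LuS(li, i) = cx.uS[i]; LuH(li, i) = cx.uH[i]; LuV(li, i) = cx.uV[i];
        LF(li, i) = Fm[i]; Llb(li, i) = lbars[i]; Lvb(li, i) = vbars[i];
      }
      for (int k = 0; k < 10; k++) Lacc(li, k) = acc[k];
      li++;
    }

    // --- failure checks
    double pitch = x[S.q0 + 2];
    double hfail = sp.height_fail_frac;
    bool bad = false;
    for (int k = 0; k < S.len; k++)
      if (!std::isfinite(x[k])) { bad = true; break; }
    if (bad || std::fabs(x[S.qd0]) > sp.qd_max ||
        std::fabs(x[S.qd0 + 1]) > sp.qd_max) {
      status = "blowup"; fail_time = tnow; break;
    }
    if (std::fabs(pitch) > sp.pitch_max ||
        o.oz[3] < hfail * h0sh || o.oz[5] < hfail * h0sh ||
        o.oz[7] < hfail * h0hip || o.oz[10] < hfail * h0hip) {
      status = "fall"; fail_time = tnow; break;
    }

    if (n == nsteps) break;

    // --- RK4 step
    double h = sp.dt;
    deriv(cx, S, x.data(), k1.data());
    for (int k = 0; k < S.len; k++) xt[k] = x[k] + 0.5 * h * k1[k];
    deriv(cx, S, xt.data(), k2.data());
    for (int k = 0; k < S.len; k++) xt[k] = x[k] + 0.5 * h * k2[k];
    deriv(cx, S, xt.data(), k3.data());
    for (int k = 0; k < S.len; k++) xt[k] = x[k] + h * k3[k];
    deriv(cx, S, xt.data(), k4.data());
    for (int k = 0; k < S.len; k++)
      x[k] += h / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    for (int k = 0; k < 4; k++) x[S.ph0 + k] = wrap2pi(x[S.ph0 + k]);
    // clamp activations against integration round-off
    for (int k = S.a0; k < S.ph0; k++) {
      if (x[k] < 0.0) x[k] = 0.0;
      if (x[k] > 1.0) x[k] = 1.0;
    }

    // --- quasi-static beta ramp (per-cycle rate)
    if (beta != beta_target && ct.ramp_rate > 0.0) {
      double db = ct.ramp_rate * sp.dt / cx.T;
      if (beta < beta_target) beta = std::min(beta_target, beta + db);
      else beta = std::max(beta_target, beta - db);
    }

    if ((n & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // trim logs to li rows
  auto trimM = [&](NumericMatrix& M0) {
    NumericMatrix out(li, M0.ncol());
    for (int r = 0; r < li; r++)
      for (int c2 = 0; c2 < M0.ncol(); c2++) out(r, c2) = M0(r, c2);
    return out;
  };
  NumericVector Tt(li), Tb(li);
  for (int r = 0; r < li; r++) { Tt[r] = Lt[r]; Tb[r] = Lbeta[r]; }
  IntegerMatrix Lst2(li, 4);
  for (int r = 0; r < li; r++)
    for (int c2 = 0; c2 < 4; c2++) Lst2(r, c2) = Lst(r, c2);

  List events = List::create(
      _["touchdown"] = List::create(td[0], td[1], td[2], td[3]),
      _["liftoff"] = List::create(lo[0], lo[1], lo[2], lo[3]));

  NumericVector xs(x.begin(), x.end());
  List resume = List::create(
      _["resume"] = true, _["state"] = xs,
      _["anchor_x"] = NumericVector::create(cx.anchor_x[0], cx.anchor_x[1],
                                            cx.anchor_x[2], cx.anchor_x[3]),
      _["anchored"] = LogicalVector::create(cx.anchored[0], cx.anchored[1],
                                            cx.anchored[2], cx.anchored[3]),
      _["stance"] = LogicalVector::create(stance_prev[0], stance_prev[1],
                                          stance_prev[2], stance_prev[3]),
      _["bufH"] = NumericVector(bufH.begin(), bufH.end()),
      _["bufV"] = NumericVector(bufV.begin(), bufV.end()),
      _["step"] = (double)(step0 + nsteps), _["time"] = t0 + nsteps * sp.dt,
      _["beta"] = beta);

  return List::create(
      _["time"] = Tt, _["beta"] = Tb, _["q"] = trimM(Lq), _["qd"] = trimM(Lqd),
      _["phi"] = trimM(Lphi), _["stance"] = Lst2, _["tip_force"] = trimM(Ltf),
      _["a"] = trimM(La), _["u"] = trimM(Lu), _["u_syn"] = trimM(LuS),
      _["u_height"] = trimM(LuH), _["u_speed"] = trimM(LuV),
      _["tension"] = trimM(LF), _["lbar"] = trimM(Llb), _["vbar"] = trimM(Lvb),
      _["work"] = trimM(Lacc), _["events"] = events, _["status"] = status,
      _["fail_time"] = fail_time, _["resume"] = resume);
}
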