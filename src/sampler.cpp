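// Coarse-grained lid-peptide model: chain geometry, energy, Metropolis sampler.
//
// The chain is a CA trace with fixed pseudo-bond length and pseudo-bond angle;
// one pseudo-dihedral per sliding 4-particle window is the only internal degree
// of freedom. The chain is anchored at its C-terminal stub (the attachment to
// the structured core), so the lab frame is the core frame. Two "core anchor"
// pseudo-particles rigidly extend the stub and serve the lid-core dihedral CV.
// An optional rigid 3-particle ligand (centroid, contact site, orientation
// marker) lives in a flat-bottom binding box and rewards proximity between its
// contact site and one designated lid residue.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double D2R = M_PI / 180.0;
static const double R_KCAL = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------- vector ops
static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
static inline void vunit(double* a) {
  double n = vnorm(a);
  a[0] /= n; a[1] /= n; a[2] /= n;
}
static inline double vdist(const double* a, const double* b) {
  double d[3]; vsub(a, b, d); return vnorm(d);
}

// Signed dihedral (degrees, in (-180, 180]) of points p1-p2-p3-p4.
static double dihedral4(const double* p1, const double* p2,
                        const double* p3, const double* p4) {
  double b1[3], b2[3], b3[3];
  vsub(p2, p1, b1); vsub(p3, p2, b2); vsub(p4, p3, b3);
  double n1[3], n2[3];
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double b2n = vnorm(b2);
  double u2[3] = {b2[0] / b2n, b2[1] / b2n, b2[2] / b2n};
  double cr[3]; vcross(n1, n2, cr);
  double ang = std::atan2(vdot(cr, u2), vdot(n1, n2)) / D2R;
  if (ang <= -180.0) ang += 360.0;
  return ang;
}

// NeRF placement: put D so that |D-A| = r, angle(D,A,B) = theta_deg and
// dihedral(D,A,B,C) = phi_deg, given attached atom A, previous B, prev-prev C.
static void nerf_place(const double* A, const double* B, const double* C,
                       double r, double theta_deg, double phi_deg, double* D) {
  double theta = theta_deg * D2R, phi = phi_deg * D2R;
  double ab[3], bc[3];
  vsub(B, C, ab);        // C -> B
  vsub(A, B, bc);        // B -> A
  double bcu[3] = {bc[0], bc[1], bc[2]};
  vunit(bcu);
  double n[3]; vcross(ab, bcu, n); vunit(n);
  double m[3]; vcross(n, bcu, m);
  double d2[3];
  d2[0] = -r * std::cos(theta);
  d2[1] = r * std::sin(theta) * std::cos(phi);
  d2[2] = r * std::sin(theta) * std::sin(phi);
  D[0] = A[0] + bcu[0] * d2[0] + m[0] * d2[1] + n[0] * d2[2];
  D[1] = A[1] + bcu[1] * d2[0] + m[1] * d2[1] + n[1] * d2[2];
  D[2] = A[2] + bcu[2] * d2[0] + m[2] * d2[1] + n[2] * d2[2];
}

static inline double wrap_deg(double x) {
  x -= 360.0 * std::floor(x / 360.0); // [0, 360)
  if (x > 180.0) x -= 360.0;          // (-180, 180]
  return x;
}

// ------------------------------------------------------------ chain building
// Particle layout (0-based): 0..n_res-1 chain CAs (0 = lid tip / N-terminus,
// n_res-1 = core attachment), then 2 core anchors. The stub (last three CAs)
// is fixed; torsion i places particle i from particles i+1, i+2, i+3.
struct Chain {
  int n_res;
  double bond, alpha;
  std::vector<double> pos;   // (n_res + 2) x 3
  double* at(int i) { return &pos[3 * i]; }
  const double* at(int i) const { return &pos[3 * i]; }

  void init_stub() {
    int n = n_res;
    pos.assign(3 * (n + 2), 0.0);
    double a = alpha * D2R;
    // fixed stub
    at(n - 1)[0] = 0.0; at(n - 1)[1] = 0.0; at(n - 1)[2] = 0.0;
    at(n - 2)[0] = bond; at(n - 2)[1] = 0.0; at(n - 2)[2] = 0.0;
    at(n - 3)[0] = bond - bond * std::cos(a);
    at(n - 3)[1] = -bond * std::sin(a);
    at(n - 3)[2] = 0.0;
    // core anchors extend past the C-terminal CA with trans geometry
    nerf_place(at(n - 1), at(n - 2), at(n - 3), bond, alpha, 180.0, at(n));
    nerf_place(at(n), at(n - 1), at(n - 2), bond, alpha, 180.0, at(n + 1));
  }
  // rebuild particles from index `from` down to 0 given torsions (degrees)
  void rebuild(const std::vector<double>& tor, int from) {
    for (int i = from; i >= 0; --i)
      nerf_place(at(i + 1), at(i + 2), at(i + 3), bond, alpha, tor[i], at(i));
  }
};

// ------------------------------------------------------------------- system
struct LidSys {
  int n_res;
  double bond, alpha;
  double theta_h, sigma_h, theta_c, sigma_c, du_hc;
  double J;
  double kT;
  bool ligand;
  int contact_idx;              // 0-based particle index
  double eps, r_contact, sw_width;
  double box_half, box_k;
  double anchor[3];
  double site_off;              // contact-site / marker offset from centroid
};

static LidSys sys_from_list(const List& s) {
  LidSys y;
  y.n_res = as<int>(s["n_residues"]);
  y.bond = as<double>(s["bond_length"]);
  y.alpha = as<double>(s["pseudo_angle"]);
  y.theta_h = as<double>(s["theta_h"]);
  y.sigma_h = as<double>(s["sigma_h"]);
  y.theta_c = as<double>(s["theta_c"]);
  y.sigma_c = as<double>(s["sigma_c"]);
  y.du_hc = as<double>(s["delta_u_hc"]);
  y.J = as<double>(s["coupling_j"]);
  y.kT = R_KCAL * as<double>(s["temperature"]);
  y.ligand = as<bool>(s["ligand_present"]);
  y.contact_idx = as<int>(s["contact_residue_index"]) - 1;
  y.eps = as<double>(s["contact_epsilon"]);
  y.r_contact = as<double>(s["contact_range"]);
  y.sw_width = as<double>(s["switch_width"]);
  y.box_half = as<double>(s["box_halfwidth"]);
  y.box_k = as<double>(s["box_k"]);
  NumericVector an = s["anchor"];
  y.anchor[0] = an[0]; y.anchor[1] = an[1]; y.anchor[2] = an[2];
  y.site_off = as<double>(s["ligand_site_offset"]);
  return y;
}

// Two-basin torsion potential: -kT log of a two-Gaussian mixture in angle.
static inline double v_torsion(const LidSys& s, double t) {
  double dh = wrap_deg(t - s.theta_h), dc = wrap_deg(t - s.theta_c);
  double ah = std::exp(-s.du_hc / s.kT);
  double z = ah * std::exp(-dh * dh / (2.0 * s.sigma_h * s.sigma_h)) +
             std::exp(-dc * dc / (2.0 * s.sigma_c * s.sigma_c));
  return -s.kT * std::log(z);
}

static inline double v_couple(const LidSys& s, double t1, double t2) {
  return -s.J * std::cos((t1 - t2) * D2R);
}

// Ligand pose: centroid c, unit quaternion q = (w,x,y,z). Body axes e1
// (to contact site) and e2 (to orientation marker), scaled by site_off.
static void quat_rotate(const double* q, const double* v, double* out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double R[9] = {
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)};
  for (int i = 0; i < 3; ++i)
    out[i] = R[3 * i] * v[0] + R[3 * i + 1] * v[1] + R[3 * i + 2] * v[2];
}

static void ligand_particles(const LidSys& s, const double* c, const double* q,
                             double* site, double* marker) {
  double e1[3] = {s.site_off, 0, 0}, e2[3] = {0, s.site_off, 0}, r[3];
  quat_rotate(q, e1, r);
  site[0] = c[0] + r[0]; site[1] = c[1] + r[1]; site[2] = c[2] + r[2];
  quat_rotate(q, e2, r);
  marker[0] = c[0] + r[0]; marker[1] = c[1] + r[1]; marker[2] = c[2] + r[2];
}

static inline double switch_fn(const LidSys& s, double d) {
  return 1.0 / (1.0 + std::exp((d - s.r_contact) / s.sw_width));
}

static double e_ligand(const LidSys& s, const Chain& ch, const double* c,
                       const double* q) {
  if (!s.ligand) return 0.0;
  double site[3], marker[3];
  ligand_particles(s, c, q, site, marker);
  double e = -s.eps * switch_fn(s, vdist(site, ch.at(s.contact_idx)));
  for (int a = 0; a < 3; ++a) {
    double ex = std::fabs(c[a] - s.anchor[a]) - s.box_half;
    if (ex > 0) e += s.box_k * ex * ex;
  }
  return e;
}

static double e_torsions(const LidSys& s, const std::vector<double>& t) {
  double e = 0.0;
  int nt = (int)t.size();
  for (int i = 0; i < nt; ++i) e += v_torsion(s, t[i]);
  for (int i = 0; i + 1 < nt; ++i) e += v_couple(s, t[i], t[i + 1]);
  return e;
}

// CVs: extension = |centroid(tip) - centroid(base)|; lid-core dihedral =
// signed dihedral of centroid(tip), centroid(base), anchorA, anchorB.
static void centroid(const Chain& ch, const IntegerVector& idx, double* out) {
  out[0] = out[1] = out[2] = 0.0;
  for (int j = 0; j < idx.size(); ++j) {
    const double* p = ch.at(idx[j] - 1);
    out[0] += p[0]; out[1] += p[1]; out[2] += p[2];
  }
  out[0] /= idx.size(); out[1] /= idx.size(); out[2] /= idx.size();
}

static void chain_cvs(const Chain& ch, const IntegerVector& tip,
                      const IntegerVector& base, double* ext, double* dih) {
  double ct[3], cb[3];
  centroid(ch, tip, ct);
  centroid(ch, base, cb);
  *ext = vdist(ct, cb);
  *dih = dihedral4(ct, cb, ch.at(ch.n_res), ch.at(ch.n_res + 1));
}

static inline double e_bias(double ext, double dih, const double* c,
                            const double* k) {
  double de = ext - c[0];
  double dd = wrap_deg(dih - c[1]) * D2R;
  return 0.5 * k[0] * de * de + 0.5 * k[1] * dd * dd;
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export]]
NumericMatrix build_chain_cpp(NumericVector torsions, int n_res, double bond,
                              double alpha_deg) {
  Chain ch; ch.n_res = n_res; ch.bond = bond; ch.alpha = alpha_deg;
  ch.init_stub();
  std::vector<double> t(torsions.begin(), torsions.end());
  ch.rebuild(t, n_res - 4);
  NumericMatrix out(n_res + 2, 3);
  for (int i = 0; i < n_res + 2; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = ch.pos[3 * i + j];
  return out;
}

// [[Rcpp::export]]
double dihedral_cpp(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  return dihedral4(&p1[0], &p2[0], &p3[0], &p4[0]);
}

// [[Rcpp::export]]
double chain_energy_cpp(List sys, NumericVector torsions,
                        Nullable<NumericVector> lig_pose) {
  LidSys s = sys_from_list(sys);
  std::vector<double> t(torsions.begin(), torsions.end());
  double e = e_torsions(s, t);
  if (s.ligand) {
    if (lig_pose.isNull()) stop("ligand_present but no ligand pose supplied");
    NumericVector lp(lig_pose);
    Chain ch; ch.n_res = s.n_res; ch.bond = s.bond; ch.alpha = s.alpha;
    ch.init_stub();
    ch.rebuild(t, s.n_res - 4);
    double q[4] = {lp[3], lp[4], lp[5], lp[6]};
    e += e_ligand(s, ch, &lp[0], q);
  }
  if (!std::isfinite(e)) stop("non-finite energy");
  return e;
}

// [[Rcpp::export]]
NumericVector torsion_potential_cpp(List sys, NumericVector theta) {
  LidSys s = sys_from_list(sys);
  NumericVector out(theta.size());
  for (int i = 0; i < theta.size(); ++i) out[i] = v_torsion(s, theta[i]);
  return out;
}

// Metropolis sampler. Returns stored frames: torsions, coordinates (chain +
// anchors [+ ligand particles]), CVs, ligand poses, acceptance statistics.
// [[Rcpp::export]]
List mc_sample_chain(List sys, int n_sweeps, int stride, int burnin,
                     bool has_bias, NumericVector bias_center,
                     NumericVector bias_k, IntegerVector tip_idx,
                     IntegerVector base_idx, NumericVector init_torsions,
                     double step_deg, double lig_step, double lig_rot_deg) {
  LidSys s = sys_from_list(sys);
  int nt = s.n_res - 3;
  if ((int)init_torsions.size() != nt) stop("init_torsions length mismatch");

  Chain ch; ch.n_res = s.n_res; ch.bond = s.bond; ch.alpha = s.alpha;
  ch.init_stub();
  std::vector<double> tor(init_torsions.begin(), init_torsions.end());
  for (int i = 0; i < nt; ++i) tor[i] = wrap_deg(tor[i]);
  ch.rebuild(tor, s.n_res - 4);

  double lc[3] = {s.anchor[0], s.anchor[1], s.anchor[2]};
  double lq[4] = {1, 0, 0, 0};

  double ext, dih;
  chain_cvs(ch, tip_idx, base_idx, &ext, &dih);
  double eb = has_bias ? e_bias(ext, dih, &bias_center[0], &bias_k[0]) : 0.0;
  double el = e_ligand(s, ch, lc, lq);

  int n_frames = n_sweeps / stride; // frames recorded after burn-in

  int np = s.n_res + 2 + (s.ligand ? 3 : 0);
  NumericMatrix out_tor(n_frames, nt);
  NumericMatrix out_cv(n_frames, 2);
  NumericMatrix out_pose(n_frames, 7);
  NumericVector out_coords(n_frames * np * 3);
  long acc_t = 0, try_t = 0, acc_l = 0, try_l = 0;

  Chain trial = ch;
  std::vector<double> ttor = tor;
  int fr = 0;
  // Lazy geometry: without a bias, torsion moves only need the contact
  // residue's position (and only when a ligand is present and the moved
  // torsion is at or above the contact index). Positions at indices >=
  // contact are kept current; everything below is rebuilt at recording.
  bool lazy = !has_bias;

  for (int sw = 1; sw <= burnin + n_sweeps; ++sw) {
    // torsion sweep
    for (int i = 0; i < nt; ++i) {
      ++try_t;
      double told = tor[i];
      double tnew = (unif_rand() < 0.8)
                        ? wrap_deg(told + norm_rand() * step_deg)
                        : wrap_deg(unif_rand() * 360.0 - 180.0);
      double dE = v_torsion(s, tnew) - v_torsion(s, told);
      if (i > 0) dE += v_couple(s, tor[i - 1], tnew) - v_couple(s, tor[i - 1], told);
      if (i < nt - 1) dE += v_couple(s, tnew, tor[i + 1]) - v_couple(s, told, tor[i + 1]);
      ttor[i] = tnew;
      if (!lazy) {
        // full trial geometry: CVs for the bias plus any contact term
        std::copy(ch.pos.begin(), ch.pos.end(), trial.pos.begin());
        trial.rebuild(ttor, i);
        double text, tdih;
        chain_cvs(trial, tip_idx, base_idx, &text, &tdih);
        double teb = e_bias(text, tdih, &bias_center[0], &bias_k[0]);
        double tel = e_ligand(s, trial, lc, lq);
        dE += (teb - eb) + (tel - el);
        if (!std::isfinite(dE)) stop("non-finite energy change in sampler");
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / s.kT)) {
          tor[i] = tnew;
          std::copy(trial.pos.begin(), trial.pos.end(), ch.pos.begin());
          ext = text; dih = tdih; eb = teb; el = tel;
          ++acc_t;
        } else {
          ttor[i] = told;
        }
      } else {
        bool geom = s.ligand && i >= s.contact_idx;
        double tel = el;
        if (geom) {
          // rebuild only the segment from i down to the contact residue
          for (int j = i; j >= s.contact_idx; --j) {
            nerf_place(j + 1 > i ? ch.at(j + 1) : trial.at(j + 1),
                       j + 2 > i ? ch.at(j + 2) : trial.at(j + 2),
                       j + 3 > i ? ch.at(j + 3) : trial.at(j + 3),
                       s.bond, s.alpha, ttor[j], trial.at(j));
          }
          tel = e_ligand(s, trial, lc, lq);
          dE += tel - el;
        }
        if (!std::isfinite(dE)) stop("non-finite energy change in sampler");
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / s.kT)) {
          tor[i] = tnew;
          if (geom) {
            for (int j = i; j >= s.contact_idx; --j) {
              ch.at(j)[0] = trial.at(j)[0];
              ch.at(j)[1] = trial.at(j)[1];
              ch.at(j)[2] = trial.at(j)[2];
            }
            el = tel;
          }
          ++acc_t;
        } else {
          ttor[i] = told;
        }
      }
    }
    // ligand rigid-body moves
    if (s.ligand) {
      for (int m = 0; m < 5; ++m) {
        ++try_l;
        double nc[3] = {lc[0], lc[1], lc[2]};
        double nq[4] = {lq[0], lq[1], lq[2], lq[3]};
        if (unif_rand() < 0.5) {
          nc[0] += norm_rand() * lig_step;
          nc[1] += norm_rand() * lig_step;
          nc[2] += norm_rand() * lig_step;
        } else {
          double ax[3] = {norm_rand(), norm_rand(), norm_rand()};
          double n = vnorm(ax);
          if (n < 1e-12) continue;
          double angle = norm_rand() * lig_rot_deg * D2R;
          double hw = std::cos(angle / 2), hs = std::sin(angle / 2) / n;
          double dq[4] = {hw, ax[0] * hs, ax[1] * hs, ax[2] * hs};
          // quaternion product dq * lq
          nq[0] = dq[0] * lq[0] - dq[1] * lq[1] - dq[2] * lq[2] - dq[3] * lq[3];
          nq[1] = dq[0] * lq[1] + dq[1] * lq[0] + dq[2] * lq[3] - dq[3] * lq[2];
          nq[2] = dq[0] * lq[2] - dq[1] * lq[3] + dq[2] * lq[0] + dq[3] * lq[1];
          nq[3] = dq[0] * lq[3] + dq[1] * lq[2] - dq[2] * lq[1] + dq[3] * lq[0];
          double qq = std::sqrt(nq[0] * nq[0] + nq[1] * nq[1] + nq[2] * nq[2] + nq[3] * nq[3]);
          for (int z = 0; z < 4; ++z) nq[z] /= qq;
        }
        double tel = e_ligand(s, ch, nc, nq);
        double dE = tel - el;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / s.kT)) {
          lc[0] = nc[0]; lc[1] = nc[1]; lc[2] = nc[2];
          lq[0] = nq[0]; lq[1] = nq[1]; lq[2] = nq[2]; lq[3] = nq[3];
          el = tel;
          ++acc_l;
        }
      }
    }
    // record
    if (sw > burnin && (sw - burnin) % stride == 0) {
      if (lazy) {
        // positions below the contact (or the whole chain, apo) are stale
        ch.rebuild(tor, nt - 1);
        chain_cvs(ch, tip_idx, base_idx, &ext, &dih);
      }
      for (int i = 0; i < nt; ++i) out_tor(fr, i) = tor[i];
      out_cv(fr, 0) = ext; out_cv(fr, 1) = dih;
      for (int p = 0; p < s.n_res + 2; ++p)
        for (int j = 0; j < 3; ++j)
          out_coords[fr * np * 3 + p * 3 + j] = ch.pos[3 * p + j];
      if (s.ligand) {
        double site[3], marker[3];
        ligand_particles(s, lc, lq, site, marker);
        const double* lig3[3] = {lc, site, marker};
        for (int p = 0; p < 3; ++p)
          for (int j = 0; j < 3; ++j)
            out_coords[fr * np * 3 + (s.n_res + 2 + p) * 3 + j] = lig3[p][j];
        out_pose(fr, 0) = lc[0]; out_pose(fr, 1) = lc[1]; out_pose(fr, 2) = lc[2];
        out_pose(fr, 3) = lq[0]; out_pose(fr, 4) = lq[1];
        out_pose(fr, 5) = lq[2]; out_pose(fr, 6) = lq[3];
      }
      ++fr;
    }
  }
  out_coords.attr("dim") = IntegerVector::create(3, np, n_frames);
  return List::create(
      _["torsions"] = out_tor, _["cv"] = out_cv, _["coords"] = out_coords,
      _["lig_pose"] = out_pose, _["n_particles"] = np,
      _["acc_torsion"] = try_t ? (double)acc_t / try_t : NA_REAL,
      _["acc_ligand"] = try_l ? (double)acc_l / try_l : NA_REAL);
}

// k-th nearest-neighbour distances, optionally periodic per dimension.
// period[j] <= 0 means Euclidean in that dimension; otherwise minimum image.
// [[Rcpp::export]]
NumericVector kth_nn_dist_cpp(NumericMatrix X, int k, NumericVector period) {
  int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be < number of samples");
  NumericVector out(n);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < k; ++m) best[m] = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double df = std::fabs(X(i, c) - X(j, c));
        if (period[c] > 0) {
          df -= period[c] * std::floor(df / period[c]);
          if (df > period[c] / 2) df = period[c] - df;
        }
        s += df * df;
      }
      if (s < best[k - 1]) {
        int m = k - 1;
        while (m > 0 && best[m - 1] > s) { best[m] = best[m - 1]; --m; }
        best[m] = s;
      }
    }
    out[i] = std::sqrt(best[k - 1]);
  }
  return out;
}

// k-th NN geodesic distance on SO(3) from unit quaternions (n x 4) with
// antipodal identification: d = 2*acos(|q_i . q_j|).
// [[Rcpp::export]]
NumericVector kth_nn_quat_cpp(NumericMatrix Q, int k) {
  int n = Q.nrow();
  if (Q.ncol() != 4) stop("quaternion matrix must have 4 columns");
  if (k >= n) stop("k must be < number of samples");
  NumericVector out(n);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < k; ++m) best[m] = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dot = 0.0;
      for (int c = 0; c < 4; ++c) dot += Q(i, c) * Q(j, c);
      dot = std::fabs(dot);
      if (dot > 1.0) dot = 1.0;
      double dist = 2.0 * std::acos(dot);
      if (dist < best[k - 1]) {
        int m = k - 1;
        while (m > 0 && best[m - 1] > dist) { best[m] = best[m - 1]; --m; }
        best[m] = dist;
      }
    }
    out[i] = best[k - 1];
  }
  return out;
}
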