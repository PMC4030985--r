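// Coarse-grained C-alpha force field and samplers.
//
// Energy terms (reduced units, eps_native = 1 sets the scale; lengths in
// Angstrom):
//   bonds      k_bond   * (r - r0)^2
//   angles     k_angle  * (theta - theta0)^2
//   dihedrals  k_dih1 * (1 - cos(phi - phi0)) + k_dih3 * (1 - cos(3(phi - phi0)))
//   native     eps * (5 (r0/r)^12 - 6 (r0/r)^10)        (minimum -eps at r0)
//   repulsive  eps_rep * (sigma_rep / r)^12              (non-native pairs)
//   non-native lambda_nn * B[i,j] * s(r),  s = 1/(1+exp((r - rc)/w))
//
// All randomness is drawn from R's RNG so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Model {
  int n;
  double k_bond, k_angle, k_dih1, k_dih3;
  std::vector<double> bond_r0, angle_t0, dih_phi0;
  // native contacts
  std::vector<int> nat_i, nat_j;          // 0-based
  std::vector<double> nat_r0;
  double eps_nat;
  // excluded volume + quasi-chemical non-native term
  double sigma_rep, eps_rep;
  int min_seq_sep;
  double lambda_nn, nn_cutoff, nn_width;
  bool has_nn;
  std::vector<double> B;                  // n*n pair energies (row-major)
  std::vector<int> nat_id;                // n*n: 0 none, else 1+index
  std::vector<std::vector<int>> nat_of_bead;
};

static Model parse_model(const List& m) {
  Model M;
  M.n = as<int>(m["n"]);
  M.k_bond = as<double>(m["k_bond"]);
  M.k_angle = as<double>(m["k_angle"]);
  M.k_dih1 = as<double>(m["k_dih1"]);
  M.k_dih3 = as<double>(m["k_dih3"]);
  M.bond_r0 = as<std::vector<double>>(m["bond_r0"]);
  M.angle_t0 = as<std::vector<double>>(m["angle_t0"]);
  M.dih_phi0 = as<std::vector<double>>(m["dih_phi0"]);
  IntegerVector ni = m["nat_i"], nj = m["nat_j"];
  NumericVector nr = m["nat_r0"];
  M.eps_nat = as<double>(m["eps_native"]);
  M.sigma_rep = as<double>(m["sigma_rep"]);
  M.eps_rep = as<double>(m["eps_rep"]);
  M.min_seq_sep = as<int>(m["min_seq_sep"]);
  M.lambda_nn = as<double>(m["lambda_nn"]);
  M.nn_cutoff = as<double>(m["nn_cutoff"]);
  M.nn_width = as<double>(m["nn_width"]);
  M.has_nn = M.lambda_nn > 0.0;
  int K = ni.size();
  M.nat_i.resize(K); M.nat_j.resize(K); M.nat_r0.resize(K);
  M.nat_id.assign((size_t)M.n * M.n, 0);
  M.nat_of_bead.assign(M.n, {});
  for (int k = 0; k < K; ++k) {
    M.nat_i[k] = ni[k] - 1;
    M.nat_j[k] = nj[k] - 1;
    M.nat_r0[k] = nr[k];
    M.nat_id[(size_t)M.nat_i[k] * M.n + M.nat_j[k]] = k + 1;
    M.nat_id[(size_t)M.nat_j[k] * M.n + M.nat_i[k]] = k + 1;
    M.nat_of_bead[M.nat_i[k]].push_back(k);
    M.nat_of_bead[M.nat_j[k]].push_back(k);
  }
  if (M.has_nn) {
    NumericMatrix B = m["B"];
    M.B.assign(B.begin(), B.end());     // column-major, symmetric anyway
  }
  return M;
}

static inline double dist3(const double* x, int i, int j) {
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// pair energy between beads i<j (non-bonded part only); r precomputed
static inline double pair_e(const Model& M, int i, int j, double r) {
  int id = M.nat_id[(size_t)i * M.n + j];
  if (id > 0) {
    double q = M.nat_r0[id - 1] / r;
    double q2 = q * q;
    double q10 = q2 * q2 * q2 * q2 * q2;
    return M.eps_nat * (5.0 * q10 * q2 - 6.0 * q10);
  }
  double q = M.sigma_rep / r;
  double q2 = q * q;
  double e = M.eps_rep * q2 * q2 * q2 * q2 * q2 * q2;
  if (M.has_nn) {
    double z = (r - M.nn_cutoff) / M.nn_width;
    if (z < 30.0) {
      double s = 1.0 / (1.0 + std::exp(z));
      e += M.lambda_nn * M.B[(size_t)j * M.n + i] * s;
    }
  }
  return e;
}

// d(pair energy)/dr
static inline double pair_de(const Model& M, int i, int j, double r) {
  int id = M.nat_id[(size_t)i * M.n + j];
  if (id > 0) {
    double r0 = M.nat_r0[id - 1];
    double q = r0 / r;
    double q2 = q * q;
    double q10 = q2 * q2 * q2 * q2 * q2;
    return M.eps_nat * (-60.0 * q10 * q2 + 60.0 * q10) / r;
  }
  double q = M.sigma_rep / r;
  double q2 = q * q;
  double q12 = q2 * q2 * q2 * q2 * q2 * q2;
  double de = -12.0 * M.eps_rep * q12 / r;
  if (M.has_nn) {
    double z = (r - M.nn_cutoff) / M.nn_width;
    if (z < 30.0) {
      double s = 1.0 / (1.0 + std::exp(z));
      de += M.lambda_nn * M.B[(size_t)j * M.n + i] *
        (-s * (1.0 - s) / M.nn_width);
    }
  }
  return de;
}

struct Terms {
  double bond = 0, angle = 0, dih = 0, native = 0, rep = 0, nn = 0;
  double total() const { return bond + angle + dih + native + rep + nn; }
};

static double bead_angle_c(const double* x, int a, int b, int c) {
  double u[3], v[3], nu = 0, nv = 0, d = 0;
  for (int k = 0; k < 3; ++k) {
    u[k] = x[3 * a + k] - x[3 * b + k];
    v[k] = x[3 * c + k] - x[3 * b + k];
    nu += u[k] * u[k]; nv += v[k] * v[k]; d += u[k] * v[k];
  }
  double ca = d / std::sqrt(nu * nv);
  if (ca > 1) ca = 1; if (ca < -1) ca = -1;
  return std::acos(ca);
}

static void cross_c(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static double dihedral_c(const double* x, int i) {
  double b1[3], b2[3], b3[3], m[3], nn2[3], mm[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = x[3 * (i + 1) + k] - x[3 * i + k];
    b2[k] = x[3 * (i + 2) + k] - x[3 * (i + 1) + k];
    b3[k] = x[3 * (i + 3) + k] - x[3 * (i + 2) + k];
  }
  cross_c(b1, b2, m);
  cross_c(b2, b3, nn2);
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double u2[3] = { b2[0] / nb2, b2[1] / nb2, b2[2] / nb2 };
  cross_c(m, u2, mm);
  double xx = m[0] * nn2[0] + m[1] * nn2[1] + m[2] * nn2[2];
  double yy = mm[0] * nn2[0] + mm[1] * nn2[1] + mm[2] * nn2[2];
  return std::atan2(yy, xx);
}

// bonded energy of all terms whose bead window intersects [lo, hi]
static double bonded_window(const Model& M, const double* x, int lo, int hi) {
  int n = M.n;
  double e = 0;
  int b0 = std::max(0, lo - 1), b1 = std::min(n - 2, hi);
  for (int b = b0; b <= b1; ++b) {
    double dr = dist3(x, b, b + 1) - M.bond_r0[b];
    e += M.k_bond * dr * dr;
  }
  int a0 = std::max(0, lo - 2), a1 = std::min(n - 3, hi);
  for (int a = a0; a <= a1; ++a) {
    double dt = bead_angle_c(x, a, a + 1, a + 2) - M.angle_t0[a];
    e += M.k_angle * dt * dt;
  }
  int d0 = std::max(0, lo - 3), d1 = std::min(n - 4, hi);
  for (int d = d0; d <= d1; ++d) {
    double dphi = dihedral_c(x, d) - M.dih_phi0[d];
    e += M.k_dih1 * (1 - std::cos(dphi)) + M.k_dih3 * (1 - std::cos(3 * dphi));
  }
  return e;
}

static Terms full_energy(const Model& M, const double* x) {
  Terms T;
  int n = M.n;
  for (int b = 0; b < n - 1; ++b) {
    double dr = dist3(x, b, b + 1) - M.bond_r0[b];
    T.bond += M.k_bond * dr * dr;
  }
  for (int a = 0; a < n - 2; ++a) {
    double dt = bead_angle_c(x, a, a + 1, a + 2) - M.angle_t0[a];
    T.angle += M.k_angle * dt * dt;
  }
  for (int d = 0; d < n - 3; ++d) {
    double dphi = dihedral_c(x, d) - M.dih_phi0[d];
    T.dih += M.k_dih1 * (1 - std::cos(dphi)) +
             M.k_dih3 * (1 - std::cos(3 * dphi));
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + M.min_seq_sep; j < n; ++j) {
      double r = dist3(x, i, j);
      int id = M.nat_id[(size_t)i * n + j];
      if (id > 0) {
        double q = M.nat_r0[id - 1] / r;
        double q2 = q * q;
        double q10 = q2 * q2 * q2 * q2 * q2;
        T.native += M.eps_nat * (5.0 * q10 * q2 - 6.0 * q10);
      } else {
        double q = M.sigma_rep / r;
        double q2 = q * q;
        T.rep += M.eps_rep * q2 * q2 * q2 * q2 * q2 * q2;
        if (M.has_nn) {
          double z = (r - M.nn_cutoff) / M.nn_width;
          if (z < 30.0) {
            T.nn += M.lambda_nn * M.B[(size_t)j * n + i] /
              (1.0 + std::exp(z));
          }
        }
      }
    }
  }
  return T;
}

// analytic forces (negative gradient); fills f (3n)
static void full_force(const Model& M, const double* x, double* f) {
  int n = M.n;
  std::fill(f, f + 3 * n, 0.0);
  // bonds
  for (int b = 0; b < n - 1; ++b) {
    double d[3], r = 0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3 * (b + 1) + k] - x[3 * b + k]; r += d[k] * d[k]; }
    r = std::sqrt(r);
    double coef = 2.0 * M.k_bond * (r - M.bond_r0[b]) / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * b + k] += coef * d[k];
      f[3 * (b + 1) + k] -= coef * d[k];
    }
  }
  // angles: V = k (theta - t0)^2
  for (int a = 0; a < n - 2; ++a) {
    const double* pa = x + 3 * a;
    const double* pb = x + 3 * (a + 1);
    const double* pc = x + 3 * (a + 2);
    double u[3], v[3], nu = 0, nv = 0, duv = 0;
    for (int k = 0; k < 3; ++k) {
      u[k] = pa[k] - pb[k]; v[k] = pc[k] - pb[k];
      nu += u[k] * u[k]; nv += v[k] * v[k]; duv += u[k] * v[k];
    }
    nu = std::sqrt(nu); nv = std::sqrt(nv);
    double ct = duv / (nu * nv);
    if (ct > 1) ct = 1; if (ct < -1) ct = -1;
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    double theta = std::acos(ct);
    double dVdt = 2.0 * M.k_angle * (theta - M.angle_t0[a]);
    // dtheta/du_k etc.
    for (int k = 0; k < 3; ++k) {
      double dthu = -(v[k] / (nu * nv) - ct * u[k] / (nu * nu)) / st;
      double dthv = -(u[k] / (nu * nv) - ct * v[k] / (nv * nv)) / st;
      f[3 * a + k]       -= dVdt * dthu;
      f[3 * (a + 2) + k] -= dVdt * dthv;
      f[3 * (a + 1) + k] += dVdt * (dthu + dthv);
    }
  }
  // dihedrals
  for (int d = 0; d < n - 3; ++d) {
    double b1[3], b2[3], b3[3], m[3], nn2[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = x[3 * (d + 1) + k] - x[3 * d + k];
      b2[k] = x[3 * (d + 2) + k] - x[3 * (d + 1) + k];
      b3[k] = x[3 * (d + 3) + k] - x[3 * (d + 2) + k];
    }
    cross_c(b1, b2, m);
    cross_c(b2, b3, nn2);
    double m2 = m[0] * m[0] + m[1] * m[1] + m[2] * m[2];
    double n2 = nn2[0] * nn2[0] + nn2[1] * nn2[1] + nn2[2] * nn2[2];
    double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    if (m2 < 1e-14 || n2 < 1e-14) continue;
    double phi = dihedral_c(x, d);
    double dphi = phi - M.dih_phi0[d];
    double dVdphi = M.k_dih1 * std::sin(dphi) +
                    3.0 * M.k_dih3 * std::sin(3 * dphi);
    // Blondel-Karplus gradients, sign-matched to dihedral_c
    double c1 = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (m2 * nb2);
    double c2 = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (n2 * nb2);
    for (int k = 0; k < 3; ++k) {
      double g0 = nb2 / m2 * m[k];                 // dphi/dp0
      double g3 = -nb2 / n2 * nn2[k];              // dphi/dp3
      double g1 = -g0 - c1 * m[k] - c2 * nn2[k];
      double g2 = -g3 + c1 * m[k] + c2 * nn2[k];
      f[3 * d + k]       -= dVdphi * g0;
      f[3 * (d + 1) + k] -= dVdphi * g1;
      f[3 * (d + 2) + k] -= dVdphi * g2;
      f[3 * (d + 3) + k] -= dVdphi * g3;
    }
  }
  // pairs
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + M.min_seq_sep; j < n; ++j) {
      double dvec[3], r = 0;
      for (int k = 0; k < 3; ++k) {
        dvec[k] = x[3 * j + k] - x[3 * i + k];
        r += dvec[k] * dvec[k];
      }
      r = std::sqrt(r);
      double de = pair_de(M, i, j, r);
      double coef = de / r;
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += coef * dvec[k];
        f[3 * j + k] -= coef * dvec[k];
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_energy_force(NumericMatrix x, List model, bool want_force = true) {
  Model M = parse_model(model);
  if (x.nrow() != M.n) stop("conformation has %d beads, model expects %d",
                            x.nrow(), M.n);
  std::vector<double> xx(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int k = 0; k < 3; ++k) xx[3 * i + k] = x(i, k);
  for (double v : xx) if (!std::isfinite(v)) stop("non-finite coordinates");
  Terms T = full_energy(M, xx.data());
  List out = List::create(
    _["energy"] = T.total(),
    _["terms"] = NumericVector::create(
      _["bond"] = T.bond, _["angle"] = T.angle, _["dihedral"] = T.dih,
      _["native"] = T.native, _["repulsive"] = T.rep,
      _["nonnative"] = T.nn));
  if (want_force) {
    std::vector<double> f(3 * M.n);
    full_force(M, xx.data(), f.data());
    NumericMatrix fm(M.n, 3);
    for (int i = 0; i < M.n; ++i)
      for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
    out["force"] = fm;
  }
  return out;
}

// fraction of native contacts formed (sharp count)
static double q_sharp(const Model& M, const double* x, double tol) {
  int K = M.nat_i.size();
  if (K == 0) return NA_REAL;
  int formed = 0;
  for (int k = 0; k < K; ++k) {
    if (dist3(x, M.nat_i[k], M.nat_j[k]) <= tol * M.nat_r0[k]) ++formed;
  }
  return (double)formed / K;
}

// [[Rcpp::export]]
double cpp_q_native(NumericMatrix x, List model, double tol) {
  Model M = parse_model(model);
  std::vector<double> xx(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int k = 0; k < 3; ++k) xx[3 * i + k] = x(i, k);
  return q_sharp(M, xx.data(), tol);
}

// smoothed Q and its gradient (for the Langevin ratchet force)
static double q_smooth(const Model& M, const double* x, double tol,
                       double w, double* grad /* may be null */) {
  int K = M.nat_i.size();
  if (grad) std::fill(grad, grad + 3 * M.n, 0.0);
  double q = 0;
  for (int k = 0; k < K; ++k) {
    int i = M.nat_i[k], j = M.nat_j[k];
    double dvec[3], r = 0;
    for (int c = 0; c < 3; ++c) {
      dvec[c] = x[3 * j + c] - x[3 * i + c];
      r += dvec[c] * dvec[c];
    }
    r = std::sqrt(r);
    double z = (r - tol * M.nat_r0[k]) / w;
    double s = (z > 30) ? 0.0 : ((z < -30) ? 1.0 : 1.0 / (1.0 + std::exp(z)));
    q += s;
    if (grad && s > 1e-12 && s < 1.0 - 1e-12) {
      double ds_dr = -s * (1.0 - s) / w;       // d sigma/d r
      double coef = ds_dr / ((double)K * r);
      for (int c = 0; c < 3; ++c) {
        grad[3 * j + c] += coef * dvec[c];
        grad[3 * i + c] -= coef * dvec[c];
      }
    }
  }
  return q / K;
}

// pair energy between one moved bead set [m1,m2] and the static rest,
// plus Q contribution bookkeeping
static double pairs_vs_rest(const Model& M, const double* x, int m1, int m2) {
  double e = 0;
  int n = M.n;
  for (int a = m1; a <= m2; ++a) {
    for (int b = 0; b < n; ++b) {
      if (b >= m1 && b <= m2) continue;
      int i = std::min(a, b), j = std::max(a, b);
      if (j - i < M.min_seq_sep) continue;
      e += pair_e(M, i, j, dist3(x, i, j));
    }
  }
  return e;
}

// number of formed native contacts with exactly one end in [m1,m2]
static int q_count_boundary(const Model& M, const double* x, int m1, int m2,
                            double tol) {
  int cnt = 0;
  for (int a = m1; a <= m2; ++a) {
    for (int idx : M.nat_of_bead[a]) {
      int i = M.nat_i[idx], j = M.nat_j[idx];
      int other = (i == a) ? j : i;
      // both ends moved: count the pair only from its smaller end
      if (other >= m1 && other <= m2 && a != std::min(i, j)) continue;
      if (dist3(x, i, j) <= tol * M.nat_r0[idx]) ++cnt;
    }
  }
  return cnt;
}

static inline double bias_e(double k_ratchet, double qrec, double q) {
  if (k_ratchet <= 0 || q >= qrec) return 0.0;
  double d = qrec - q;
  return 0.5 * k_ratchet * d * d;
}

// Metropolis MC with crankshaft + single-bead moves and optional
// ratchet-and-pawl bias on the sharp native-contact fraction.
// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix x0, List model, int n_sweeps, double kBT,
                List moveset, int stride, double k_ratchet, double q_stop,
                double q_tol, double q_record0) {
  Model M = parse_model(model);
  int n = M.n;
  if (x0.nrow() != n) stop("bead-count mismatch");
  double crank_max = as<double>(moveset["crankshaft_max_angle"]);
  double disp_max = as<double>(moveset["displacement_max"]);
  double mix = as<double>(moveset["mix"]);
  int seg_min = as<int>(moveset["seg_min"]);
  int seg_max = as<int>(moveset["seg_max"]);

  std::vector<double> x(3 * n), xn(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = x0(i, k);

  Terms T0 = full_energy(M, x.data());
  double E = T0.total();
  int K = M.nat_i.size();
  int formed = 0;
  for (int k = 0; k < K; ++k)
    if (dist3(x.data(), M.nat_i[k], M.nat_j[k]) <= q_tol * M.nat_r0[k])
      ++formed;
  double Q = K > 0 ? (double)formed / K : NA_REAL;
  double qrec = std::max(q_record0, Q);
  bool use_ratchet = k_ratchet > 0 && K > 0;

  std::vector<double> frames, e_log, q_log, qrec_log, bias_log;
  std::vector<int> t_log;
  long accepted = 0, proposed = 0;
  auto save = [&](int sweep) {
    frames.insert(frames.end(), x.begin(), x.end());
    e_log.push_back(E);
    q_log.push_back(Q);
    qrec_log.push_back(qrec);
    bias_log.push_back(use_ratchet ? bias_e(k_ratchet, qrec, Q) : 0.0);
    t_log.push_back(sweep);
  };
  save(0);

  bool diverged = false, reached = false;
  int cur_sweep = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    cur_sweep = sweep;
    for (int p = 0; p < n; ++p) {
      ++proposed;
      int m1, m2;
      xn = x;
      if (n >= 4 && R::unif_rand() < mix) {
        // crankshaft: rotate interior of [i, j] about the i--j axis
        int seg = seg_min +
          (int)std::floor(R::unif_rand() * (seg_max - seg_min + 1));
        if (seg > n - 2) seg = n - 2;
        int i = (int)std::floor(R::unif_rand() * (n - seg - 1));
        int j = i + seg + 1;
        if (j > n - 1) { j = n - 1; i = j - seg - 1; }
        double ang = crank_max * (2.0 * R::unif_rand() - 1.0);
        double ax[3], na = 0;
        for (int k = 0; k < 3; ++k) {
          ax[k] = x[3 * j + k] - x[3 * i + k];
          na += ax[k] * ax[k];
        }
        na = std::sqrt(na);
        if (na < 1e-9) continue;
        for (int k = 0; k < 3; ++k) ax[k] /= na;
        double ct = std::cos(ang), st = std::sin(ang);
        for (int b = i + 1; b < j; ++b) {
          double v[3];
          for (int k = 0; k < 3; ++k) v[k] = x[3 * b + k] - x[3 * i + k];
          double axv[3];
          cross_c(ax, v, axv);
          double adv = ax[0] * v[0] + ax[1] * v[1] + ax[2] * v[2];
          for (int k = 0; k < 3; ++k) {
            xn[3 * b + k] = x[3 * i + k] +
              v[k] * ct + axv[k] * st + ax[k] * adv * (1 - ct);
          }
        }
        m1 = i + 1; m2 = j - 1;
      } else {
        int b = (int)std::floor(R::unif_rand() * n);
        for (int k = 0; k < 3; ++k)
          xn[3 * b + k] = x[3 * b + k] + disp_max * (2.0 * R::unif_rand() - 1.0);
        m1 = m2 = b;
      }
      double dE = bonded_window(M, xn.data(), m1, m2) -
                  bonded_window(M, x.data(), m1, m2) +
                  pairs_vs_rest(M, xn.data(), m1, m2) -
                  pairs_vs_rest(M, x.data(), m1, m2);
      double Qn = Q;
      int dformed = 0;
      if (K > 0) {
        int c_old = q_count_boundary(M, x.data(), m1, m2, q_tol);
        int c_new = q_count_boundary(M, xn.data(), m1, m2, q_tol);
        dformed = c_new - c_old;
        Qn = (double)(formed + dformed) / K;
      }
      double dB = use_ratchet
        ? bias_e(k_ratchet, qrec, Qn) - bias_e(k_ratchet, qrec, Q) : 0.0;
      double dTot = dE + dB;
      bool acc = dTot <= 0.0 ||
        (kBT > 0 && R::unif_rand() < std::exp(-dTot / kBT));
      if (acc) {
        // swap in proposal (only moved beads differ)
        for (int b = m1; b <= m2; ++b)
          for (int k = 0; k < 3; ++k) x[3 * b + k] = xn[3 * b + k];
        E += dE;
        if (K > 0) {
          formed += dformed;
          Q = Qn;
          if (use_ratchet && Q > qrec) qrec = Q;
        }
        ++accepted;
      }
    }
    // periodic refresh kills numerical drift of the incremental sums
    if (sweep % 50 == 0) {
      E = full_energy(M, x.data()).total();
      if (K > 0) {
        formed = 0;
        for (int k = 0; k < K; ++k)
          if (dist3(x.data(), M.nat_i[k], M.nat_j[k]) <= q_tol * M.nat_r0[k])
            ++formed;
        Q = (double)formed / K;
      }
    }
    if (sweep % stride == 0) save(sweep);
    if (E > 1e8) { diverged = true; break; }
    if (K > 0 && q_stop > 0 && Q >= q_stop) { reached = true; break; }
  }
  // make sure the final state is stored
  {
    bool same = true;
    size_t F = frames.size() / (3 * (size_t)n);
    const double* lastf = frames.data() + 3 * (size_t)n * (F - 1);
    for (int i = 0; i < 3 * n && same; ++i)
      if (lastf[i] != x[i]) same = false;
    if (!same) save(cur_sweep);
  }
  size_t F = frames.size() / (3 * (size_t)n);
  NumericVector fr(frames.begin(), frames.end());
  fr.attr("dim") = IntegerVector::create(3, n, (int)F);
  return List::create(
    _["frames"] = fr,
    _["sweep"] = IntegerVector(t_log.begin(), t_log.end()),
    _["energy"] = NumericVector(e_log.begin(), e_log.end()),
    _["q"] = NumericVector(q_log.begin(), q_log.end()),
    _["q_record"] = NumericVector(qrec_log.begin(), qrec_log.end()),
    _["bias_energy"] = NumericVector(bias_log.begin(), bias_log.end()),
    _["acceptance"] = (double)accepted / (double)proposed,
    _["diverged"] = diverged,
    _["reached_qstop"] = reached);
}

// Overdamped Langevin: x' = x + dt/Gamma * F + sqrt(2 kBT dt / Gamma) eta,
// with optional ratchet bias force on the smoothed contact fraction.
// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix x0, List model, int n_steps, double dt,
                      double Gamma, double kBT, int stride, double k_ratchet,
                      double q_stop, double q_tol, double q_width,
                      double q_record0) {
  Model M = parse_model(model);
  int n = M.n;
  if (x0.nrow() != n) stop("bead-count mismatch");
  std::vector<double> x(3 * n), f(3 * n), qg(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = x0(i, k);
  double noise_sd = std::sqrt(2.0 * kBT * dt / Gamma);
  int K = M.nat_i.size();
  bool use_ratchet = k_ratchet > 0 && K > 0;
  double Q = K > 0 ? q_sharp(M, x.data(), q_tol) : NA_REAL;
  double qs = use_ratchet ? q_smooth(M, x.data(), q_tol, q_width, nullptr)
                          : 0.0;
  double qrec = std::max(q_record0, use_ratchet ? qs : 0.0);
  std::vector<double> frames, e_log, q_log, qrec_log, bias_log;
  std::vector<int> t_log;
  auto save = [&](int step) {
    frames.insert(frames.end(), x.begin(), x.end());
    e_log.push_back(full_energy(M, x.data()).total());
    q_log.push_back(K > 0 ? q_sharp(M, x.data(), q_tol) : NA_REAL);
    qrec_log.push_back(use_ratchet ? qrec : NA_REAL);
    bias_log.push_back(use_ratchet ? bias_e(k_ratchet, qrec, qs) : 0.0);
    t_log.push_back(step);
  };
  save(0);
  bool diverged = false, reached = false;
  for (int step = 1; step <= n_steps; ++step) {
    full_force(M, x.data(), f.data());
    if (use_ratchet) {
      qs = q_smooth(M, x.data(), q_tol, q_width, qg.data());
      if (qs > qrec) qrec = qs;
      else {
        double coef = k_ratchet * (qrec - qs);
        for (int i = 0; i < 3 * n; ++i) f[i] += coef * qg[i];
      }
    }
    for (int i = 0; i < 3 * n; ++i) {
      if (!std::isfinite(f[i]))
        stop("non-finite force during propagation at step %d", step);
      x[i] += dt / Gamma * f[i] + noise_sd * R::norm_rand();
    }
    if (step % stride == 0) save(step);
    if (K > 0 && q_stop > 0) {
      double qnow = q_sharp(M, x.data(), q_tol);
      if (qnow >= q_stop) { reached = true; if (step % stride != 0) save(step); break; }
    }
    if (step % 200 == 0 && full_energy(M, x.data()).total() > 1e8) {
      diverged = true;
      break;
    }
  }
  if (t_log.back() < n_steps && !reached && !diverged) save(n_steps);
  size_t F = frames.size() / (3 * (size_t)n);
  NumericVector fr(frames.begin(), frames.end());
  fr.attr("dim") = IntegerVector::create(3, n, (int)F);
  return List::create(
    _["frames"] = fr,
    _["sweep"] = IntegerVector(t_log.begin(), t_log.end()),
    _["energy"] = NumericVector(e_log.begin(), e_log.end()),
    _["q"] = NumericVector(q_log.begin(), q_log.end()),
    _["q_record"] = NumericVector(qrec_log.begin(), qrec_log.end()),
    _["bias_energy"] = NumericVector(bias_log.begin(), bias_log.end()),
    _["acceptance"] = 1.0,
    _["diverged"] = diverged,
    _["reached_qstop"] = reached);
}

// Onsager-Machlup action of a stride-1 trajectory under the UNBIASED
// force: S = Gamma/(4 kBT dt) * sum_i |x_{i+1} - x_i - F(x_i) dt/Gamma|^2
// [[Rcpp::export]]
double cpp_om_action(NumericVector frames, List model, double dt,
                     double Gamma, double kBT) {
  Model M = parse_model(model);
  IntegerVector dims = frames.attr("dim");
  int n = dims[1];
  int F = dims[2];
  if (n != M.n) stop("bead-count mismatch");
  if (F < 2) stop("need at least two frames");
  std::vector<double> f(3 * n);
  const double* fx = frames.begin();
  double S = 0;
  double pref = Gamma / (4.0 * kBT * dt);
  for (int t = 0; t < F - 1; ++t) {
    const double* xt = fx + (size_t)3 * n * t;
    const double* xt1 = fx + (size_t)3 * n * (t + 1);
    full_force(M, xt, f.data());
    for (int i = 0; i < 3 * n; ++i) {
      double d = xt1[i] - xt[i] - f[i] * dt / Gamma;
      S += pref * d * d;
    }
  }
  return S;
}
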