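// Compiled core: pair potentials (LJ / WCA / soft-core WCA), bonded terms,
// radius-of-gyration and position restraints, BAOAB Langevin propagation with
// an optional Monte Carlo volume barostat, steepest-descent minimisation,
// Widom insertion energies, and Shrake-Rupley SASA.
//
// Units: nm, ps, K, amu, kJ/mol.  1 amu nm^2 ps^-2 == 1 kJ/mol, so kinetic
// energy in these units needs no conversion factor.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

static const double GAS_R = 0.0083145; // kJ mol^-1 K^-1

// ---------------------------------------------------------------------------
// deterministic Gaussian stream (mt19937_64 + Box-Muller), portable
struct GaussRNG {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit GaussRNG(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit uniform in (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// pair kernels.  fr = -(dU/dr)/r so that the force on i is fr * (xi - xj).
// Work where possible in r^2 and r^6 to avoid square roots.

static inline void lj_kernel(double r2, double sig, double eps, double r2cut,
                             double &u, double &fr) {
  u = 0.0; fr = 0.0;
  if (r2 >= r2cut || eps == 0.0) return;
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  u = 4.0 * eps * s6 * (s6 - 1.0);
  fr = 24.0 * eps * s6 * (2.0 * s6 - 1.0) / r2;
}

static inline void wca_kernel(double r2, double sig, double eps,
                              double &u, double &fr) {
  u = 0.0; fr = 0.0;
  double rmin2 = std::cbrt(2.0) * sig * sig; // (2^{1/6} sigma)^2
  if (r2 >= rmin2 || eps == 0.0) return;
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  u = 4.0 * eps * s6 * (s6 - 1.0) + eps;
  fr = 24.0 * eps * s6 * (2.0 * s6 - 1.0) / r2;
}

// soft-core WCA, Beutler r^6 mixing: rsc^6 = alpha sig_sc^6 (1-lam)^p + r^6,
// V = lam * V_WCA(rsc).  Returns energy, fr and dU/dlam.
static inline void sc_kernel(double r2, double sig, double eps, double lam,
                             double alpha, int p, double sigsc,
                             double &u, double &fr, double &dudl) {
  u = 0.0; fr = 0.0; dudl = 0.0;
  if (eps == 0.0) return;
  double r6 = r2 * r2 * r2;
  double oml = 1.0 - lam;
  double omlp = (p == 1) ? oml : std::pow(oml, p);
  double omlp1 = (p == 1) ? 1.0 : p * std::pow(oml, p - 1);
  double s6c = alpha * std::pow(sigsc, 6) * omlp;
  double rsc6 = s6c + r6;
  double sig6 = std::pow(sig, 6);
  double rmin6 = 2.0 * sig6; // (2^{1/6} sigma)^6
  if (rsc6 >= rmin6) return;
  double A = 4.0 * eps * sig6 * sig6, B = 4.0 * eps * sig6;
  double inv = 1.0 / rsc6;
  double uw = A * inv * inv - B * inv + eps;        // V_WCA as fn of rsc^6
  double duw = -2.0 * A * inv * inv * inv + B * inv * inv; // dV/d(rsc^6)
  double drsc6_dl = -alpha * std::pow(sigsc, 6) * omlp1;
  u = lam * uw;
  dudl = uw + lam * duw * drsc6_dl;
  // dU/dr = lam * duw * 6 r^5 ; fr = -(dU/dr)/r
  fr = -lam * duw * 6.0 * r2 * r2;
}

// dispatch on mode: 0 = LJ, 1 = WCA, 2 = softcore-WCA, 3 = excluded
static inline void pair_kernel(int mode, double r2, double sig, double eps,
                               double r2cut, double lam, double alpha, int p,
                               double sigsc, double &u, double &fr, double &dudl) {
  u = 0.0; fr = 0.0; dudl = 0.0;
  switch (mode) {
  case 0: lj_kernel(r2, sig, eps, r2cut, u, fr); break;
  case 1: wca_kernel(r2, sig, eps, u, fr); break;
  case 2: sc_kernel(r2, sig, eps, lam, alpha, p, sigsc, u, fr, dudl); break;
  default: break;
  }
}

// [[Rcpp::export]]
List cpp_pair_potential(NumericVector r, double sigma, double eps, int mode,
                        double cutoff, double lam, double alpha, int p,
                        double sigsc) {
  int n = r.size();
  NumericVector u(n), f(n), dudl(n);
  double r2cut = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("pair potential requires r > 0");
    double ui, fri, dl;
    pair_kernel(mode, r[i] * r[i], sigma, eps, r2cut, lam, alpha, p, sigsc,
                ui, fri, dl);
    u[i] = ui; f[i] = fri * r[i]; dudl[i] = dl; // f = -dU/dr (magnitude)
  }
  return List::create(_["energy"] = u, _["force"] = f, _["dudl"] = dudl);
}

// ---------------------------------------------------------------------------
// helpers

static inline double min_image(double d, double L) {
  if (L <= 0) return d;
  return d - L * std::floor(d / L + 0.5);
}

struct FFView {
  const double *sigma, *eps;
  const int *mode;
  int nsp;
  double cutoff, r2cut, lam, sc_alpha, sc_sigma;
  int sc_p;
};

// exclusion lookup via sorted per-particle lists
struct Exclusions {
  std::vector<std::vector<int>> ex;
  void build(int N, const IntegerMatrix &pairs) {
    ex.assign(N, {});
    for (int k = 0; k < pairs.nrow(); ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      ex[i].push_back(j); ex[j].push_back(i);
    }
    for (auto &v : ex) std::sort(v.begin(), v.end());
  }
  bool excluded(int i, int j) const {
    const auto &v = ex[i];
    if (v.empty()) return false;
    return std::binary_search(v.begin(), v.end(), j);
  }
};

// all-pairs / cell-list nonbonded evaluation.  Positions may be unwrapped;
// minimum image is applied per pair.  neighbor_mode: 0 brute force, 1 cell
// list, -1 auto (cell list when >= 3 cells per dimension and N > 100).
static void nonbonded(const std::vector<double> &x, int N,
                      const int *sp, const double *box, const FFView &ff,
                      const Exclusions &excl, int neighbor_mode,
                      std::vector<double> &f, double &epair, double &dudl,
                      double &virial) {
  epair = 0.0; dudl = 0.0; virial = 0.0;
  int nc[3];
  bool cells_ok = true;
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)std::floor(box[d] / ff.cutoff);
    if (nc[d] < 3) cells_ok = false;
  }
  bool use_cells = (neighbor_mode == 1) || (neighbor_mode < 0 && cells_ok && N > 100);
  if (use_cells && !cells_ok) stop("cell list requested but box < 3 cells per dimension");

  auto do_pair = [&](int i, int j) {
    if (excl.excluded(i, j)) return;
    int m = ff.mode[sp[i] * ff.nsp + sp[j]];
    if (m == 3) return;
    double dx = min_image(x[3 * i] - x[3 * j], box[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= ff.r2cut && m != 2) return; // softcore evaluated regardless (short ranged anyway)
    double sig = ff.sigma[sp[i] * ff.nsp + sp[j]];
    double eps = ff.eps[sp[i] * ff.nsp + sp[j]];
    double u, fr, dl;
    pair_kernel(m, r2, sig, eps, ff.r2cut, ff.lam, ff.sc_alpha, ff.sc_p,
                ff.sc_sigma, u, fr, dl);
    epair += u; dudl += dl;
    virial += fr * r2;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
  };

  if (!use_cells) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) do_pair(i, j);
    return;
  }
  // cell list
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(N, -1), cellof(N);
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double w = x[3 * i + d] / box[d];
      w -= std::floor(w); // wrapped fraction in [0,1)
      int ci = (int)(w * nc[d]);
      if (ci >= nc[d]) ci = nc[d] - 1;
      c[d] = ci;
    }
    int cid = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cellof[i] = cid; nxt[i] = head[cid]; head[cid] = i;
  }
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cid = (cz * nc[1] + cy) * nc[0] + cx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int nxc = (cx + dx + nc[0]) % nc[0];
              int nyc = (cy + dy + nc[1]) % nc[1];
              int nzc = (cz + dz + nc[2]) % nc[2];
              int nid = (nzc * nc[1] + nyc) * nc[0] + nxc;
              if (nid < cid) continue; // visit each cell pair once
              for (int i = head[cid]; i != -1; i = nxt[i])
                for (int j = head[nid]; j != -1; j = nxt[j]) {
                  if (nid == cid && j >= i) continue;
                  do_pair(std::max(i, j), std::min(i, j));
                }
            }
  }
}

// bonded terms.  bonds: (i, j, r0, k); angles: (i, j, k, theta0, ktheta)
static void bonded(const std::vector<double> &x, const double *box,
                   const NumericMatrix &bonds, const NumericMatrix &angles,
                   std::vector<double> &f, double &ebond, double &eangle) {
  ebond = 0.0; eangle = 0.0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double r0 = bonds(b, 2), k = bonds(b, 3);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) stop("zero-length bond");
    double dr = r - r0;
    ebond += 0.5 * k * dr * dr;
    double fr = -k * dr / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1,
        k = (int)angles(a, 2) - 1;
    double th0 = angles(a, 3), kt = angles(a, 4);
    double rij[3], rkj[3];
    for (int d = 0; d < 3; ++d) {
      rij[d] = x[3 * i + d] - x[3 * j + d];
      rkj[d] = x[3 * k + d] - x[3 * j + d];
    }
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    double cth = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij * nkj);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - th0;
    eangle += 0.5 * kt * dth * dth;
    double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
    double coef = kt * dth / sth; // -dU/dcos(theta) prefactor sign folded below
    for (int d = 0; d < 3; ++d) {
      double dcos_di = (rkj[d] / (nij * nkj)) - cth * rij[d] / (nij * nij);
      double dcos_dk = (rij[d] / (nij * nkj)) - cth * rkj[d] / (nkj * nkj);
      double fi = coef * dcos_di;
      double fk = coef * dcos_dk;
      f[3 * i + d] += fi;
      f[3 * k + d] += fk;
      f[3 * j + d] -= (fi + fk);
    }
  }
}

// radius of gyration (equal masses) over a selection; positions unwrapped
static double rg_of(const std::vector<double> &x, const IntegerVector &sel,
                    double cm[3]) {
  int n = sel.size();
  cm[0] = cm[1] = cm[2] = 0.0;
  for (int s = 0; s < n; ++s) {
    int i = sel[s] - 1;
    cm[0] += x[3 * i]; cm[1] += x[3 * i + 1]; cm[2] += x[3 * i + 2];
  }
  cm[0] /= n; cm[1] /= n; cm[2] /= n;
  double s2 = 0.0;
  for (int s = 0; s < n; ++s) {
    int i = sel[s] - 1;
    double dx = x[3 * i] - cm[0], dy = x[3 * i + 1] - cm[1],
           dz = x[3 * i + 2] - cm[2];
    s2 += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s2 / n);
}

// harmonic restraint on Rg: V = kb/2 (Rg - rg0)^2
static double rg_restraint(const std::vector<double> &x, const IntegerVector &sel,
                           double kb, double rg0, std::vector<double> &f,
                           double &rg_out) {
  double cm[3];
  double rg = rg_of(x, sel, cm);
  rg_out = rg;
  if (kb == 0.0) return 0.0;
  if (rg < 1e-10 && rg0 != 0.0)
    stop("degenerate Rg restraint gradient: Rg = 0 with rg0 != 0");
  double dr = rg - rg0;
  int n = sel.size();
  if (rg > 1e-10) {
    double pref = -kb * dr / (n * rg);
    for (int s = 0; s < n; ++s) {
      int i = sel[s] - 1;
      f[3 * i] += pref * (x[3 * i] - cm[0]);
      f[3 * i + 1] += pref * (x[3 * i + 1] - cm[1]);
      f[3 * i + 2] += pref * (x[3 * i + 2] - cm[2]);
    }
  }
  return 0.5 * kb * dr * dr;
}

static double posres(const std::vector<double> &x, const IntegerVector &sel,
                     const NumericMatrix &ref, double kpr,
                     std::vector<double> &f) {
  if (kpr == 0.0 || sel.size() == 0) return 0.0;
  double e = 0.0;
  for (int s = 0; s < sel.size(); ++s) {
    int i = sel[s] - 1;
    for (int d = 0; d < 3; ++d) {
      double dx = x[3 * i + d] - ref(s, d);
      e += 0.5 * kpr * dx * dx;
      f[3 * i + d] += -kpr * dx;
    }
  }
  return e;
}

struct EnergyOut {
  double epair, ebond, eangle, ergres, eposres, dudl, virial, rg;
  double total() const { return epair + ebond + eangle + ergres + eposres; }
};

static void eval_all(const std::vector<double> &x, int N, const int *sp,
                     const double *box, const FFView &ff, const Exclusions &excl,
                     int neighbor_mode, const NumericMatrix &bonds,
                     const NumericMatrix &angles, const IntegerVector &rg_sel,
                     double rg_kb, double rg0, const IntegerVector &pr_sel,
                     const NumericMatrix &pr_ref, double kpr,
                     std::vector<double> &f, EnergyOut &e) {
  std::fill(f.begin(), f.end(), 0.0);
  nonbonded(x, N, sp, box, ff, excl, neighbor_mode, f, e.epair, e.dudl, e.virial);
  bonded(x, box, bonds, angles, f, e.ebond, e.eangle);
  e.rg = NA_REAL;
  e.ergres = 0.0;
  if (rg_sel.size() >= 2) {
    double rg;
    e.ergres = rg_restraint(x, rg_sel, rg_kb, rg0, f, rg);
    e.rg = rg;
  }
  e.eposres = posres(x, pr_sel, pr_ref, kpr, f);
}

static FFView make_ffview(const NumericMatrix &sigma_ij, const NumericMatrix &eps_ij,
                          const IntegerMatrix &mode_ij, double cutoff, double lam,
                          double sc_alpha, int sc_p, double sc_sigma) {
  FFView ff;
  ff.sigma = sigma_ij.begin(); ff.eps = eps_ij.begin(); ff.mode = mode_ij.begin();
  ff.nsp = sigma_ij.nrow();
  ff.cutoff = cutoff; ff.r2cut = cutoff * cutoff; ff.lam = lam;
  ff.sc_alpha = sc_alpha; ff.sc_p = sc_p; ff.sc_sigma = sc_sigma;
  return ff;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix x, NumericVector box, IntegerVector sp0,
                       NumericMatrix sigma_ij, NumericMatrix eps_ij,
                       IntegerMatrix mode_ij, double cutoff, double lam,
                       double sc_alpha, int sc_p, double sc_sigma,
                       NumericMatrix bonds, NumericMatrix angles,
                       IntegerMatrix excl_pairs, IntegerVector rg_sel,
                       double rg_kb, double rg0, IntegerVector pr_sel,
                       NumericMatrix pr_ref, double kpr, int neighbor_mode) {
  int N = x.nrow();
  std::vector<double> xs(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) xs[3 * i + d] = x(i, d);
  FFView ff = make_ffview(sigma_ij, eps_ij, mode_ij, cutoff, lam, sc_alpha,
                          sc_p, sc_sigma);
  Exclusions excl; excl.build(N, excl_pairs);
  std::vector<double> f(3 * N);
  EnergyOut e;
  eval_all(xs, N, sp0.begin(), box.begin(), ff, excl, neighbor_mode, bonds,
           angles, rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = f[3 * i + d];
  return List::create(
      _["energy"] = NumericVector::create(
          _["pair"] = e.epair, _["bond"] = e.ebond, _["angle"] = e.eangle,
          _["rg_restraint"] = e.ergres, _["pos_restraint"] = e.eposres,
          _["total"] = e.total()),
      _["forces"] = F, _["dudl"] = e.dudl, _["virial"] = e.virial,
      _["rg"] = e.rg);
}

// [[Rcpp::export]]
double cpp_rg(NumericMatrix x, IntegerVector sel) {
  int N = x.nrow();
  std::vector<double> xs(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) xs[3 * i + d] = x(i, d);
  double cm[3];
  return rg_of(xs, sel, cm);
}

// molecule-in-shell counts.  mol_id: per particle (1-based); mol_role: per
// molecule 0 polymer / 1 water / 2 alcohol.  A molecule is in the first shell
// if any of its sites lies within `cutoff` (minimum image) of any polymer
// site.  Returns (nw_shell, na_shell, nw_bulk, na_bulk).
static void shell_counts(const std::vector<double> &x, int N, const double *box,
                         const IntegerVector &poly_sel, const IntegerVector &mol_id,
                         const IntegerVector &mol_role, double cutoff,
                         int out[4]) {
  int nmol = mol_role.size();
  std::vector<char> inshell(nmol, 0);
  double c2 = cutoff * cutoff;
  if (cutoff > 0) {
    for (int i = 0; i < N; ++i) {
      int m = mol_id[i] - 1;
      if (mol_role[m] == 0 || inshell[m]) continue;
      for (int s = 0; s < poly_sel.size(); ++s) {
        int j = poly_sel[s] - 1;
        double dx = min_image(x[3*i] - x[3*j], box[0]);
        double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
        double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
        if (dx*dx + dy*dy + dz*dz <= c2) { inshell[m] = 1; break; }
      }
    }
  }
  out[0] = out[1] = out[2] = out[3] = 0;
  for (int m = 0; m < nmol; ++m) {
    if (mol_role[m] == 1) { if (inshell[m]) out[0]++; else out[2]++; }
    else if (mol_role[m] == 2) { if (inshell[m]) out[1]++; else out[3]++; }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_shell_counts(NumericMatrix x, NumericVector box,
                               IntegerVector poly_sel, IntegerVector mol_id,
                               IntegerVector mol_role, double cutoff) {
  int N = x.nrow();
  std::vector<double> xs(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) xs[3 * i + d] = x(i, d);
  int out[4];
  shell_counts(xs, N, box.begin(), poly_sel, mol_id, mol_role, cutoff, out);
  return IntegerVector::create(_["nw_shell"] = out[0], _["na_shell"] = out[1],
                               _["nw_bulk"] = out[2], _["na_bulk"] = out[3]);
}

// Verlet neighbor list for the propagation loop: pairs within
// cutoff + skin, rebuilt (brute force) when accumulated displacement could
// break validity or after an accepted volume move.
struct NeighborList {
  std::vector<int> pi, pj;
  double skin = 0.25;
  double travel = 0.0; // conservative accumulated max displacement
  void build(const std::vector<double> &x, int N, const double *box,
             double cutoff, const Exclusions &excl) {
    pi.clear(); pj.clear();
    double r2max = (cutoff + skin) * (cutoff + skin);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (excl.excluded(i, j)) continue;
        double dx = min_image(x[3*i] - x[3*j], box[0]);
        double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
        double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
        if (dx*dx + dy*dy + dz*dz < r2max) { pi.push_back(i); pj.push_back(j); }
      }
    travel = 0.0;
  }
};

// nonbonded evaluation over a prebuilt pair list
static void nonbonded_list(const std::vector<double> &x, const int *sp,
                           const double *box, const FFView &ff,
                           const NeighborList &nl, std::vector<double> &f,
                           double &epair, double &dudl, double &virial) {
  epair = 0.0; dudl = 0.0; virial = 0.0;
  size_t M = nl.pi.size();
  for (size_t k = 0; k < M; ++k) {
    int i = nl.pi[k], j = nl.pj[k];
    int m = ff.mode[sp[i] * ff.nsp + sp[j]];
    if (m == 3) continue;
    double dx = min_image(x[3*i] - x[3*j], box[0]);
    double dy = min_image(x[3*i+1] - x[3*j+1], box[1]);
    double dz = min_image(x[3*i+2] - x[3*j+2], box[2]);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= ff.r2cut && m != 2) continue;
    double u, fr, dl;
    pair_kernel(m, r2, ff.sigma[sp[i] * ff.nsp + sp[j]],
                ff.eps[sp[i] * ff.nsp + sp[j]], ff.r2cut, ff.lam,
                ff.sc_alpha, ff.sc_p, ff.sc_sigma, u, fr, dl);
    epair += u; dudl += dl; virial += fr * r2;
    f[3*i] += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j] -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
  }
}

// eval_all variant using the neighbor list for the pair term
static void eval_all_nl(const std::vector<double> &x, int N, const int *sp,
                        const double *box, const FFView &ff,
                        const NeighborList &nl, const NumericMatrix &bonds,
                        const NumericMatrix &angles, const IntegerVector &rg_sel,
                        double rg_kb, double rg0, const IntegerVector &pr_sel,
                        const NumericMatrix &pr_ref, double kpr,
                        std::vector<double> &f, EnergyOut &e) {
  std::fill(f.begin(), f.end(), 0.0);
  nonbonded_list(x, sp, box, ff, nl, f, e.epair, e.dudl, e.virial);
  bonded(x, box, bonds, angles, f, e.ebond, e.eangle);
  e.rg = NA_REAL;
  e.ergres = 0.0;
  if (rg_sel.size() >= 2) {
    double rg;
    e.ergres = rg_restraint(x, rg_sel, rg_kb, rg0, f, rg);
    e.rg = rg;
  }
  e.eposres = posres(x, pr_sel, pr_ref, kpr, f);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin propagation with sampling observers and optional MC volume
// barostat.  Returns final state plus records sampled every `stride` steps.
// [[Rcpp::export]]
List cpp_run_segment(NumericMatrix x, NumericMatrix v, NumericVector box,
                     IntegerVector sp0, NumericVector mass,
                     NumericMatrix sigma_ij, NumericMatrix eps_ij,
                     IntegerMatrix mode_ij, double cutoff, double lam,
                     double sc_alpha, int sc_p, double sc_sigma,
                     NumericMatrix bonds, NumericMatrix angles,
                     IntegerMatrix excl_pairs, IntegerVector rg_sel,
                     double rg_kb, double rg0, IntegerVector pr_sel,
                     NumericMatrix pr_ref, double kpr, int neighbor_mode,
                     int n_steps, double dt, double temperature,
                     double friction_time, int seed, int stride,
                     int baro_interval, double baro_pressure, double baro_dlnV,
                     IntegerVector mol_id, IntegerVector mol_role,
                     double shell_cutoff, int step0) {
  int N = x.nrow();
  std::vector<double> xs(3 * N), vs(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { xs[3*i+d] = x(i, d); vs[3*i+d] = v(i, d); }
  double bx[3] = {box[0], box[1], box[2]};
  // molecules holding position-restrained particles are excluded from
  // barostat scaling (fixed reference conformation); only free molecules
  // carry the ideal-gas volume entropy
  int nmol_all = mol_role.size();
  std::vector<char> mol_scales(nmol_all, 1);
  for (int q = 0; q < pr_sel.size(); ++q)
    mol_scales[mol_id[pr_sel[q] - 1] - 1] = 0;
  int nmol_free = 0;
  for (int m = 0; m < nmol_all; ++m) nmol_free += mol_scales[m];
  FFView ff = make_ffview(sigma_ij, eps_ij, mode_ij, cutoff, lam, sc_alpha,
                          sc_p, sc_sigma);
  Exclusions excl; excl.build(N, excl_pairs);
  GaussRNG rng(static_cast<uint64_t>(seed));
  double kT = GAS_R * temperature;
  double gamma = (friction_time > 0) ? 1.0 / friction_time : 0.0;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  bool use_nl = (neighbor_mode != 0) && (N > 400);
  NeighborList nl;
  if (use_nl) nl.build(xs, N, bx, ff.cutoff, excl);
  EnergyOut e;
  if (use_nl)
    eval_all_nl(xs, N, sp0.begin(), bx, ff, nl, bonds, angles, rg_sel,
                rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);
  else
    eval_all(xs, N, sp0.begin(), bx, ff, excl, neighbor_mode, bonds, angles,
             rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);

  int nrec = (stride > 0) ? n_steps / stride : 0;
  NumericVector rec_step(nrec), rec_rg(nrec), rec_epair(nrec), rec_ebond(nrec),
      rec_eangle(nrec), rec_ergres(nrec), rec_eposres(nrec), rec_ekin(nrec),
      rec_dudl(nrec), rec_virial(nrec), rec_vol(nrec);
  IntegerVector rec_nw(nrec), rec_na(nrec), rec_nwb(nrec), rec_nab(nrec);
  int irec = 0;
  int n_baro_try = 0, n_baro_acc = 0;
  int nmol = mol_role.size();

  for (int step = 1; step <= n_steps; ++step) {
    // B half kick
    for (int i = 0; i < N; ++i) {
      double im = 0.5 * dt / mass[i];
      for (int d = 0; d < 3; ++d) vs[3*i+d] += im * f[3*i+d];
    }
    // A half drift
    double vmax2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double v2 = vs[3*i]*vs[3*i] + vs[3*i+1]*vs[3*i+1] + vs[3*i+2]*vs[3*i+2];
      if (v2 > vmax2) vmax2 = v2;
    }
    for (int k = 0; k < 3 * N; ++k) xs[k] += 0.5 * dt * vs[k];
    // O (Ornstein-Uhlenbeck)
    if (gamma > 0) {
      for (int i = 0; i < N; ++i) {
        double sd = std::sqrt(kT / mass[i]);
        for (int d = 0; d < 3; ++d)
          vs[3*i+d] = c1 * vs[3*i+d] + c2 * sd * rng.norm();
      }
    }
    // A half drift
    for (int i = 0; i < N; ++i) {
      double v2 = vs[3*i]*vs[3*i] + vs[3*i+1]*vs[3*i+1] + vs[3*i+2]*vs[3*i+2];
      if (v2 > vmax2) vmax2 = v2;
    }
    for (int k = 0; k < 3 * N; ++k) xs[k] += 0.5 * dt * vs[k];
    // force (refresh the pair list when accumulated drift could invalidate it)
    if (use_nl) {
      nl.travel += std::sqrt(vmax2) * dt;
      if (2.0 * nl.travel > nl.skin) nl.build(xs, N, bx, ff.cutoff, excl);
      eval_all_nl(xs, N, sp0.begin(), bx, ff, nl, bonds, angles, rg_sel,
                  rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);
    } else
      eval_all(xs, N, sp0.begin(), bx, ff, excl, neighbor_mode, bonds, angles,
               rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);
    // B half kick
    for (int i = 0; i < N; ++i) {
      double im = 0.5 * dt / mass[i];
      for (int d = 0; d < 3; ++d) vs[3*i+d] += im * f[3*i+d];
    }

    if (!std::isfinite(e.total()))
      stop("dynamics blew up at step %d (non-finite potential energy)",
           step0 + step);

    // MC volume move (molecular centre-of-mass scaling)
    if (baro_interval > 0 && step % baro_interval == 0) {
      ++n_baro_try;
      double V = bx[0] * bx[1] * bx[2];
      double lnV = std::log(V) + (2.0 * rng.unif() - 1.0) * baro_dlnV;
      double Vn = std::exp(lnV);
      double s = std::cbrt(Vn / V);
      // molecule centres of mass
      std::vector<double> cmx(3 * nmol, 0.0), cmm(nmol, 0.0);
      for (int i = 0; i < N; ++i) {
        int m = mol_id[i] - 1;
        for (int d = 0; d < 3; ++d) cmx[3*m+d] += mass[i] * xs[3*i+d];
        cmm[m] += mass[i];
      }
      for (int m = 0; m < nmol; ++m)
        for (int d = 0; d < 3; ++d) cmx[3*m+d] /= cmm[m];
      std::vector<double> xn(3 * N);
      for (int i = 0; i < N; ++i) {
        int m = mol_id[i] - 1;
        for (int d = 0; d < 3; ++d)
          xn[3*i+d] = xs[3*i+d] +
            (mol_scales[m] ? (s - 1.0) * cmx[3*m+d] : 0.0);
      }
      double bn[3] = {bx[0] * s, bx[1] * s, bx[2] * s};
      double U0 = e.total();
      std::vector<double> ftmp(3 * N);
      EnergyOut en;
      eval_all(xn, N, sp0.begin(), bn, ff, excl, 0, bonds, angles,
               rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, ftmp, en);
      double dU = en.total() - U0;
      double arg = -(dU + baro_pressure * (Vn - V)) / kT +
                   (nmol_free + 1.0) * std::log(Vn / V);
      if (std::log(rng.unif()) < arg) {
        ++n_baro_acc;
        xs.swap(xn); f.swap(ftmp); e = en;
        bx[0] = bn[0]; bx[1] = bn[1]; bx[2] = bn[2];
        if (use_nl) nl.build(xs, N, bx, ff.cutoff, excl);
      }
    }

    if (stride > 0 && step % stride == 0 && irec < nrec) {
      double ekin = 0.0;
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          ekin += 0.5 * mass[i] * vs[3*i+d] * vs[3*i+d];
      rec_step[irec] = step0 + step;
      rec_rg[irec] = e.rg;
      rec_epair[irec] = e.epair; rec_ebond[irec] = e.ebond;
      rec_eangle[irec] = e.eangle; rec_ergres[irec] = e.ergres;
      rec_eposres[irec] = e.eposres; rec_ekin[irec] = ekin;
      rec_dudl[irec] = e.dudl; rec_virial[irec] = e.virial;
      rec_vol[irec] = bx[0] * bx[1] * bx[2];
      if (shell_cutoff > 0 && rg_sel.size() > 0) {
        int out[4];
        shell_counts(xs, N, bx, rg_sel, mol_id, mol_role, shell_cutoff, out);
        rec_nw[irec] = out[0]; rec_na[irec] = out[1];
        rec_nwb[irec] = out[2]; rec_nab[irec] = out[3];
      } else {
        rec_nw[irec] = NA_INTEGER; rec_na[irec] = NA_INTEGER;
        rec_nwb[irec] = NA_INTEGER; rec_nab[irec] = NA_INTEGER;
      }
      ++irec;
    }
  }

  NumericMatrix X(N, 3), V(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { X(i, d) = xs[3*i+d]; V(i, d) = vs[3*i+d]; }
  DataFrame rec = DataFrame::create(
      _["step"] = rec_step, _["rg"] = rec_rg, _["e_pair"] = rec_epair,
      _["e_bond"] = rec_ebond, _["e_angle"] = rec_eangle,
      _["e_rg_restraint"] = rec_ergres, _["e_pos_restraint"] = rec_eposres,
      _["e_kin"] = rec_ekin, _["dudl"] = rec_dudl, _["virial"] = rec_virial,
      _["volume"] = rec_vol, _["nw_shell"] = rec_nw, _["na_shell"] = rec_na,
      _["nw_bulk"] = rec_nwb, _["na_bulk"] = rec_nab);
  return List::create(_["x"] = X, _["v"] = V,
                      _["box"] = NumericVector::create(bx[0], bx[1], bx[2]),
                      _["records"] = rec,
                      _["baro_tried"] = n_baro_try, _["baro_accepted"] = n_baro_acc,
                      _["step"] = step0 + n_steps);
}

// steepest descent with adaptive step size
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix x, NumericVector box, IntegerVector sp0,
                  NumericMatrix sigma_ij, NumericMatrix eps_ij,
                  IntegerMatrix mode_ij, double cutoff, double lam,
                  double sc_alpha, int sc_p, double sc_sigma,
                  NumericMatrix bonds, NumericMatrix angles,
                  IntegerMatrix excl_pairs, IntegerVector rg_sel, double rg_kb,
                  double rg0, IntegerVector pr_sel, NumericMatrix pr_ref,
                  double kpr, int neighbor_mode, int max_steps, double ftol,
                  double step0) {
  int N = x.nrow();
  std::vector<double> xs(3 * N), f(3 * N), xtrial(3 * N), ftrial(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) xs[3*i+d] = x(i, d);
  double bx[3] = {box[0], box[1], box[2]};
  FFView ff = make_ffview(sigma_ij, eps_ij, mode_ij, cutoff, lam, sc_alpha,
                          sc_p, sc_sigma);
  Exclusions excl; excl.build(N, excl_pairs);
  EnergyOut e, et;
  eval_all(xs, N, sp0.begin(), bx, ff, excl, neighbor_mode, bonds, angles,
           rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, f, e);
  double h = step0;
  int it = 0;
  double fmax = 0.0;
  for (; it < max_steps; ++it) {
    fmax = 0.0;
    for (int k = 0; k < 3 * N; ++k) fmax = std::max(fmax, std::fabs(f[k]));
    if (fmax < ftol) break;
    for (int k = 0; k < 3 * N; ++k) xtrial[k] = xs[k] + h * f[k] / fmax;
    eval_all(xtrial, N, sp0.begin(), bx, ff, excl, neighbor_mode, bonds, angles,
             rg_sel, rg_kb, rg0, pr_sel, pr_ref, kpr, ftrial, et);
    if (std::isfinite(et.total()) && et.total() < e.total()) {
      xs.swap(xtrial); f.swap(ftrial); e = et;
      h = std::min(h * 1.2, 0.2);
    } else {
      h *= 0.5;
      if (h < 1e-10) break;
    }
  }
  NumericMatrix X(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) X(i, d) = xs[3*i+d];
  return List::create(_["x"] = X, _["energy"] = e.total(), _["fmax"] = fmax,
                      _["iterations"] = it);
}

// interaction energy of a ghost particle of species `gsp` (0-based) at each
// trial position with every existing particle (minimum image), used for Widom
// insertion.  Evaluated with the mode table row of the ghost species.
// [[Rcpp::export]]
NumericVector cpp_insertion_energy(NumericMatrix x, NumericVector box,
                                   IntegerVector sp0, NumericMatrix sigma_ij,
                                   NumericMatrix eps_ij, IntegerMatrix mode_ij,
                                   double cutoff, double lam, double sc_alpha,
                                   int sc_p, double sc_sigma, int gsp,
                                   NumericMatrix ins_pos) {
  int N = x.nrow(), M = ins_pos.nrow(), nsp = sigma_ij.nrow();
  double r2cut = cutoff * cutoff;
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double u = 0.0;
    for (int i = 0; i < N; ++i) {
      int s = sp0[i];
      int md = mode_ij(gsp, s);
      if (md == 3) continue;
      double dx = min_image(ins_pos(m, 0) - x(i, 0), box[0]);
      double dy = min_image(ins_pos(m, 1) - x(i, 1), box[1]);
      double dz = min_image(ins_pos(m, 2) - x(i, 2), box[2]);
      double r2 = dx*dx + dy*dy + dz*dz;
      double ui, fri, dl;
      pair_kernel(md, r2, sigma_ij(gsp, s), eps_ij(gsp, s), r2cut, lam,
                  sc_alpha, sc_p, sc_sigma, ui, fri, dl);
      u += ui;
      if (u > 1e8) { u = 1e8; break; } // deep overlap: cap, exp(-bU) ~ 0 anyway
    }
    out[m] = u;
    (void)nsp;
  }
  return out;
}

// Shrake-Rupley SASA with a golden-spiral quadrature (no PBC; conformers are
// analysed in vacuum).  radii are the bare sphere radii; probe is added.
// [[Rcpp::export]]
List cpp_sasa(NumericMatrix x, NumericVector radii, double probe, int n_points) {
  int N = x.nrow();
  // golden spiral directions
  std::vector<double> dir(3 * n_points);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    dir[3*k] = r * std::cos(th); dir[3*k+1] = r * std::sin(th); dir[3*k+2] = z;
  }
  NumericVector area(N);
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    double Ri = radii[i] + probe;
    int nfree = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = x(i,0) + Ri * dir[3*k], py = x(i,1) + Ri * dir[3*k+1],
             pz = x(i,2) + Ri * dir[3*k+2];
      bool buried = false;
      for (int j = 0; j < N && !buried; ++j) {
        if (j == i) continue;
        double Rj = radii[j] + probe;
        double dx = px - x(j,0), dy = py - x(j,1), dz = pz - x(j,2);
        if (dx*dx + dy*dy + dz*dz < Rj * Rj) buried = true;
      }
      if (!buried) ++nfree;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * nfree / n_points;
    total += area[i];
  }
  return List::create(_["total"] = total, _["per_particle"] = area);
}
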