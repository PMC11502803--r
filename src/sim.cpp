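// Core numerics for the sticker-and-spacer CTD model: shifted 12-6 +
// Debye-Hueckel pair interactions, BAOAB Langevin dynamics with linked-cell
// neighbour search, inter-chain contact counting, and a lattice pivot
// generator for self-avoiding walks. Units: nm, kJ/mol, ps, K, e.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct PairParams {
  const double *eps;   // ntype x ntype effective well depths (column-major)
  int ntype;
  double sigma, cutoff, cutoff2;
  double ecut, ecut2;  // electrostatic cutoff (>= LJ cutoff)
  double rmax2;        // max(cutoff2, ecut2): interaction range
  double lj_c0;        // 4*((s/c)^12 - (s/c)^6): shift factor, times eps
  double wca_eps;      // pairs at/below this well depth are purely repulsive
  double rmin2;        // squared 12-6 minimum distance (WCA cut)
  double kq;           // coulomb_k / dielectric
  double lambda;       // Debye length, nm
  double elec_shift;   // exp(-ecut/lambda)/ecut
};

static PairParams make_pair_params(const NumericMatrix &eps, double sigma,
                                   double cutoff, double kq, double lambda,
                                   double ecut, double wca_eps) {
  PairParams p;
  p.eps = REAL(eps);
  p.ntype = eps.nrow();
  p.sigma = sigma;
  p.cutoff = cutoff;
  p.cutoff2 = cutoff * cutoff;
  p.ecut = ecut;
  p.ecut2 = ecut * ecut;
  p.rmax2 = p.ecut2 > p.cutoff2 ? p.ecut2 : p.cutoff2;
  double sc = sigma / cutoff;
  double sc6 = sc * sc * sc; sc6 *= sc6;
  p.lj_c0 = 4.0 * (sc6 * sc6 - sc6);
  p.wca_eps = wca_eps;
  p.rmin2 = sigma * sigma * std::cbrt(2.0);
  p.kq = kq;
  p.lambda = lambda;
  p.elec_shift = std::exp(-ecut / lambda) / ecut;
  return p;
}

// without charges the interaction range is just the LJ cutoff
static void shrink_range_if_neutral(PairParams &p, const NumericVector &q) {
  for (R_xlen_t i = 0; i < q.size(); ++i) if (q[i] != 0.0) return;
  p.ecut2 = p.cutoff2;
  p.rmax2 = p.cutoff2;
}

// energy and |F|/r for one pair at squared distance r2 (< rmax2);
// the 12-6 term is shifted to zero at cutoff, the screened Coulomb term
// at its own (longer) cutoff
static inline void pair_eval(const PairParams &p, int ti, int tj,
                             double qi, double qj, double r2,
                             double &e_lj, double &e_el, double &fr) {
  e_lj = 0.0; e_el = 0.0; fr = 0.0;
  if (r2 < p.cutoff2) {
    double eps = p.eps[ti + p.ntype * tj];
    bool wca = eps <= p.wca_eps * (1.0 + 1e-9);
    if (!wca || r2 < p.rmin2) {
      double s2 = p.sigma * p.sigma / r2;
      double s6 = s2 * s2 * s2;
      double s12 = s6 * s6;
      // non-sticky (floor) pairs: WCA, i.e. the 12-6 core shifted to zero
      // at its minimum; others: 12-6 shifted to zero at the cutoff
      e_lj = 4.0 * eps * (s12 - s6) + (wca ? eps : -eps * p.lj_c0);
      fr = 4.0 * eps * (12.0 * s12 - 6.0 * s6) / r2; // -dU/dr * (1/r)
    }
  }
  double qq = qi * qj;
  if (qq != 0.0 && r2 < p.ecut2) {
    double r = std::sqrt(r2);
    double ex = std::exp(-r / p.lambda);
    e_el = p.kq * qq * (ex / r - p.elec_shift);
    fr += p.kq * qq * ex * (1.0 / (p.lambda * r) + 1.0 / r2) / r;
  }
}

typedef std::unordered_set<int64_t> ExclSet;

static ExclSet make_exclusions(const IntegerMatrix &bonds, int n) {
  ExclSet s;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    if (i > j) std::swap(i, j);
    s.insert((int64_t)i * n + j);
  }
  return s;
}

static inline bool excluded(const ExclSet &s, int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return s.count((int64_t)i * n + j) > 0;
}

// ---- linked-cell nonbonded evaluation -------------------------------------

struct NBResult { double e_lj, e_el; };

// coords: n x 3 (row-major triplets in x[]); forces accumulated in f[] if
// not null. use_pbc: orthorhombic box; otherwise open boundaries.
static NBResult nonbonded_eval(const double *x, int n, const int *type,
                               const double *charge, const PairParams &p,
                               const ExclSet &excl, bool use_pbc,
                               const double *box, double *f) {
  NBResult res = {0.0, 0.0};
  double lo[3] = {0, 0, 0}, L[3];
  if (use_pbc) {
    for (int d = 0; d < 3; ++d) L[d] = box[d];
  } else {
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = hi[d] = x[d]; }
    for (int i = 1; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = x[3 * i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 3; ++d) L[d] = hi[d] - lo[d] + 1e-9;
  }
  int nc[3];
  bool cells_ok = true;
  for (int d = 0; d < 3; ++d) {
    double rmax = std::sqrt(p.rmax2);
    nc[d] = (int)std::floor(L[d] / rmax);
    if (nc[d] < 1) nc[d] = 1;
    if (nc[d] > 64) nc[d] = 64; // cap memory; cells stay >= cutoff
    if (use_pbc && nc[d] < 3) cells_ok = false;
  }
  if (n < 400) cells_ok = false; // small systems: fused O(n^2) is faster

  auto do_pair = [&](int i, int j) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    if (use_pbc) {
      dx = min_image(dx, L[0]); dy = min_image(dy, L[1]); dz = min_image(dz, L[2]);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= p.rmax2 || r2 <= 0.0) return;
    if (!excl.empty() && excluded(excl, i, j, n)) return;
    double elj, eel, fr;
    pair_eval(p, type[i], type[j], charge[i], charge[j], r2, elj, eel, fr);
    res.e_lj += elj; res.e_el += eel;
    if (f) {
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  };
  if (!cells_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) do_pair(i, j);
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1), cidx(n);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double v = x[3 * i + d] - lo[d];
        if (use_pbc) { v -= L[d] * std::floor(v / L[d]); }
        int k = (int)(v / L[d] * nc[d]);
        if (k >= nc[d]) k = nc[d] - 1;
        if (k < 0) k = 0;
        c[d] = k;
      }
      int cc = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
      cidx[i] = cc; nxt[i] = head[cc]; head[cc] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c0 = cx + nc[0] * (cy + nc[1] * cz);
          // half stencil: same cell (i<j) + 13 forward neighbours
          static const int off[13][3] = {
            {1,0,0},{0,1,0},{1,1,0},{-1,1,0},{0,0,1},{1,0,1},{-1,0,1},
            {0,1,1},{1,1,1},{-1,1,1},{0,-1,1},{1,-1,1},{-1,-1,1}};
          if (head[c0] < 0) continue;
          for (int i = head[c0]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j]) do_pair(i, j);
          for (int k = 0; k < 13; ++k) {
            int ex = cx + off[k][0], ey = cy + off[k][1], ez = cz + off[k][2];
            if (use_pbc) {
              ex = (ex + nc[0]) % nc[0];
              ey = (ey + nc[1]) % nc[1];
              ez = (ez + nc[2]) % nc[2];
            } else if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                       ez < 0 || ez >= nc[2]) continue;
            int c1 = ex + nc[0] * (ey + nc[1] * ez);
            if (c1 == c0 || head[c1] < 0) continue;
            for (int i = head[c0]; i >= 0; i = nxt[i])
              for (int j = head[c1]; j >= 0; j = nxt[j]) do_pair(i, j);
          }
        }
  }
  return res;
}

static double bonded_eval(const double *x, const IntegerMatrix &bonds,
                          const double *r0, double kbond, bool use_pbc,
                          const double *box, double *f) {
  double e = 0.0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    if (use_pbc) {
      dx = min_image(dx, box[0]); dy = min_image(dy, box[1]); dz = min_image(dz, box[2]);
    }
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0[b];
    e += 0.5 * kbond * dr * dr;
    if (f && r > 0) {
      double fr = -kbond * dr / r;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  }
  return e;
}

// harmonic turn-bias restraints: rows (i, j, r0, k)
static double bias_eval(const double *x, const NumericMatrix &bias,
                        bool use_pbc, const double *box, double *f) {
  double e = 0.0;
  for (int b = 0; b < bias.nrow(); ++b) {
    int i = (int)bias(b, 0) - 1, j = (int)bias(b, 1) - 1;
    double r0 = bias(b, 2), k = bias(b, 3);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    if (use_pbc) {
      dx = min_image(dx, box[0]); dy = min_image(dy, box[1]); dz = min_image(dz, box[2]);
    }
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0;
    e += 0.5 * k * dr * dr;
    if (f && r > 0) {
      double fr = -k * dr / r;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix coords, IntegerVector type,
                               NumericVector charge, NumericMatrix eps,
                               double sigma, double cutoff, double ecut,
                               double wca_eps,
                               double kq, double lambda, IntegerMatrix bonds,
                               NumericVector bond_r0, double kbond,
                               NumericMatrix bias, LogicalVector use_pbc,
                               NumericVector box) {
  int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  PairParams p = make_pair_params(eps, sigma, cutoff, kq, lambda, ecut, wca_eps);
  shrink_range_if_neutral(p, charge);
  ExclSet excl = make_exclusions(bonds, n);
  bool pbc = use_pbc[0];
  NBResult nb = nonbonded_eval(x.data(), n, INTEGER(type), REAL(charge), p,
                               excl, pbc, REAL(box), nullptr);
  double eb = bonded_eval(x.data(), bonds, REAL(bond_r0), kbond, pbc,
                          REAL(box), nullptr);
  eb += bias_eval(x.data(), bias, pbc, REAL(box), nullptr);
  return NumericVector::create(_["bonded"] = eb, _["nonbonded"] = nb.e_lj,
                               _["electrostatic"] = nb.e_el);
}

// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix coords0, IntegerVector type,
                      NumericVector charge, NumericMatrix eps, double sigma,
                      double cutoff, double ecut, double wca_eps,
                      double kq, double lambda,
                      IntegerMatrix bonds, NumericVector bond_r0,
                      double kbond, NumericMatrix bias, LogicalVector use_pbc,
                      NumericVector box, int n_steps, double dt,
                      double friction, double temperature, double mass,
                      int sample_every, double fmax) {
  int n = coords0.nrow();
  bool pbc = use_pbc[0];
  std::vector<double> x(3 * n), v(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);
  PairParams p = make_pair_params(eps, sigma, cutoff, kq, lambda, ecut, wca_eps);
  shrink_range_if_neutral(p, charge);
  ExclSet excl = make_exclusions(bonds, n);

  double kT = KB * temperature;
  double vsd = std::sqrt(kT / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = vsd * R::norm_rand();

  // Verlet neighbour lists with displacement-triggered rebuild: a short
  // list at the LJ range for all pairs except charged-charged, and a long
  // list at the electrostatic range for the (few) charged-charged pairs
  const double skin = 0.3;
  const double rs2 = (p.cutoff + skin) * (p.cutoff + skin);
  const double rl2 = (p.ecut + skin) * (p.ecut + skin);
  std::vector<int> nb_i, nb_j;   // short-range list
  std::vector<int> el_i, el_j;   // charged-charged list
  std::vector<int> charged;
  for (int i = 0; i < n; ++i) if (charge[i] != 0.0) charged.push_back(i);
  std::vector<double> x_ref(3 * n);
  const double *bx = REAL(box);
  auto mi_d2 = [&](int i, int j) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    if (pbc) {
      dx = min_image(dx, bx[0]); dy = min_image(dy, bx[1]);
      dz = min_image(dz, bx[2]);
    }
    return dx * dx + dy * dy + dz * dz;
  };
  auto build_list = [&]() {
    nb_i.clear(); nb_j.clear(); el_i.clear(); el_j.clear();
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        bool qq = charge[i] != 0.0 && charge[j] != 0.0;
        if (qq) continue;
        if (mi_d2(i, j) < rs2 && !(!excl.empty() && excluded(excl, i, j, n))) {
          nb_i.push_back(i); nb_j.push_back(j);
        }
      }
    for (size_t a = 0; a + 1 < charged.size(); ++a)
      for (size_t b = a + 1; b < charged.size(); ++b) {
        int i = charged[a], j = charged[b];
        if (mi_d2(i, j) < rl2 && !(!excl.empty() && excluded(excl, i, j, n))) {
          el_i.push_back(i); el_j.push_back(j);
        }
      }
    x_ref = x;
  };
  auto need_rebuild = [&]() {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - x_ref[3 * i];
      double dy = x[3 * i + 1] - x_ref[3 * i + 1];
      double dz = x[3 * i + 2] - x_ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  };
  auto eval_list = [&](const std::vector<int> &li, const std::vector<int> &lj) {
    for (size_t k = 0; k < li.size(); ++k) {
      int i = li[k], j = lj[k];
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      if (pbc) {
        dx = min_image(dx, bx[0]); dy = min_image(dy, bx[1]);
        dz = min_image(dz, bx[2]);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= p.rmax2 || r2 <= 0.0) continue;
      double elj, eel, fr;
      pair_eval(p, type[i], type[j], charge[i], charge[j], r2, elj, eel, fr);
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  };
  auto nb_forces = [&]() { eval_list(nb_i, nb_j); eval_list(el_i, el_j); };
  auto all_forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    if (need_rebuild()) build_list();
    nb_forces();
    bonded_eval(x.data(), bonds, REAL(bond_r0), kbond, pbc, bx, f.data());
    bias_eval(x.data(), bias, pbc, bx, f.data());
    if (fmax > 0) { // per-bead force clamp (relaxation of strained starts)
      for (int i = 0; i < n; ++i) {
        double fm = std::sqrt(f[3 * i] * f[3 * i] + f[3 * i + 1] * f[3 * i + 1] +
                              f[3 * i + 2] * f[3 * i + 2]);
        if (fm > fmax) {
          double sc = fmax / fm;
          f[3 * i] *= sc; f[3 * i + 1] *= sc; f[3 * i + 2] *= sc;
        }
      }
    }
  };

  int nf = n_steps / sample_every + 1;
  NumericVector frames((R_xlen_t)nf * n * 3);
  NumericVector ktemp(nf);
  int fi = 0;
  auto store = [&](int slot) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[(R_xlen_t)slot + (R_xlen_t)nf * (i + (R_xlen_t)n * d)] = x[3 * i + d];
    double ke = 0.0;
    for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
    ktemp[slot] = mass * ke / (3.0 * n * KB);
  };
  store(fi++);
  if (n_steps > 0) {
    build_list();
    all_forces();
    double c1 = std::exp(-friction * dt);
    double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));
    for (int step = 1; step <= n_steps; ++step) {
      for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] / mass;
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * R::norm_rand();
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      all_forces();
      for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] / mass;
      if (step % sample_every == 0) store(fi++);
      if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    }
  }
  frames.attr("dim") = IntegerVector::create(nf, n, 3);
  return List::create(_["frames"] = frames, _["kinetic_temperature"] = ktemp);
}

// residue-by-residue nonbonded energy matrix (LJ + electrostatic) for one
// frame; side beads are aggregated onto their parent residue via `residue`.
// [[Rcpp::export]]
NumericMatrix cpp_residue_energy_matrix(NumericMatrix coords,
                                        IntegerVector type,
                                        NumericVector charge,
                                        IntegerVector residue,
                                        NumericMatrix eps, double sigma,
                                        double cutoff, double ecut,
                                        double wca_eps, double kq,
                                        double lambda, IntegerMatrix bonds,
                                        LogicalVector use_pbc,
                                        NumericVector box, int n_residues) {
  int n = coords.nrow();
  bool pbc = use_pbc[0];
  PairParams p = make_pair_params(eps, sigma, cutoff, kq, lambda, ecut, wca_eps);
  shrink_range_if_neutral(p, charge);
  ExclSet excl = make_exclusions(bonds, n);
  NumericMatrix em(n_residues, n_residues);
  const double *bx = REAL(box);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (excluded(excl, i, j, n)) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      if (pbc) {
        dx = min_image(dx, bx[0]); dy = min_image(dy, bx[1]); dz = min_image(dz, bx[2]);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= p.rmax2 || r2 <= 0.0) continue;
      double elj, eel, fr;
      pair_eval(p, type[i], type[j], charge[i], charge[j], r2, elj, eel, fr);
      int ri = residue[i] - 1, rj = residue[j] - 1;
      if (ri == rj) continue; // side bead vs own backbone already excluded
      em(ri, rj) += elj + eel;
      em(rj, ri) += elj + eel;
    }
  return em;
}

// inter-chain bead-pair contact counts (minimum image, strict r < cutoff)
// [[Rcpp::export]]
IntegerMatrix cpp_chain_pair_contacts(NumericMatrix coords,
                                      IntegerVector chain_id,
                                      NumericVector box, double cutoff) {
  int n = coords.nrow();
  int nch = 0;
  for (int i = 0; i < n; ++i) if (chain_id[i] > nch) nch = chain_id[i];
  IntegerMatrix cc(nch, nch);
  double c2 = cutoff * cutoff;
  const double *bx = REAL(box);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (chain_id[i] == chain_id[j]) continue;
      double dx = min_image(coords(i, 0) - coords(j, 0), bx[0]);
      if (std::fabs(dx) >= cutoff) continue;
      double dy = min_image(coords(i, 1) - coords(j, 1), bx[1]);
      if (std::fabs(dy) >= cutoff) continue;
      double dz = min_image(coords(i, 2) - coords(j, 2), bx[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < c2) {
        int a = chain_id[i] - 1, b = chain_id[j] - 1;
        cc(a, b) += 1; cc(b, a) += 1;
      }
    }
  return cc;
}

// ---- lattice self-avoiding walks by the pivot algorithm --------------------

static void octahedral_group(std::vector<std::array<int, 9>> &mats) {
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int pp = 0; pp < 6; ++pp)
    for (int sgn = 0; sgn < 8; ++sgn) {
      std::array<int, 9> m{};
      for (int r = 0; r < 3; ++r) {
        int s = (sgn >> r) & 1 ? -1 : 1;
        m[3 * r + perms[pp][r]] = s;
      }
      mats.push_back(m);
    }
}

static inline int64_t pack3(int x, int y, int z) {
  return ((int64_t)(x + 2048)) | ((int64_t)(y + 2048) << 13) |
         ((int64_t)(z + 2048) << 26);
}

// n beads; returns n_conf x n x 3 lattice coordinates (unit spacing).
// Decorrelation: `stride` accepted pivots between samples after `warmup`
// accepted pivots from a rod start. Errors out if the acceptance budget
// is exhausted.
// [[Rcpp::export]]
NumericVector cpp_saw_pivot(int n, int n_conf, int warmup, int stride,
                            double max_attempt_factor) {
  std::vector<std::array<int, 9>> G;
  octahedral_group(G);
  std::vector<std::array<int, 3>> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = {i, 0, 0};

  NumericVector out((R_xlen_t)n_conf * n * 3);
  int64_t needed = (int64_t)warmup + (int64_t)stride * n_conf;
  int64_t max_attempts = (int64_t)(max_attempt_factor * (double)needed);
  int64_t accepted = 0, attempts = 0;
  int stored = 0;
  std::vector<std::array<int, 3>> trial(n);
  while (stored < n_conf) {
    if (++attempts > max_attempts)
      stop("pivot algorithm failed to decorrelate within the attempt budget "
           "(%d of %d samples after %lld attempts); increase the budget or "
           "shorten the chain", stored, n_conf, (long long)attempts);
    int p = 1 + (int)(unif_rand() * (n - 2));
    if (p >= n - 1) p = n - 2;
    int gi = 1 + (int)(unif_rand() * 47); // skip identity
    if (gi > 47) gi = 47;
    const std::array<int, 9> &m = G[gi];
    std::unordered_set<int64_t> occ;
    occ.reserve(2 * p);
    for (int i = 0; i <= p; ++i) occ.insert(pack3(xs[i][0], xs[i][1], xs[i][2]));
    bool ok = true;
    for (int i = p + 1; i < n; ++i) {
      int rx = xs[i][0] - xs[p][0], ry = xs[i][1] - xs[p][1], rz = xs[i][2] - xs[p][2];
      int nx = xs[p][0] + m[0] * rx + m[1] * ry + m[2] * rz;
      int ny = xs[p][1] + m[3] * rx + m[4] * ry + m[5] * rz;
      int nz = xs[p][2] + m[6] * rx + m[7] * ry + m[8] * rz;
      if (occ.count(pack3(nx, ny, nz))) { ok = false; break; }
      trial[i] = {nx, ny, nz};
    }
    if (!ok) continue;
    for (int i = p + 1; i < n; ++i) xs[i] = trial[i];
    ++accepted;
    if (accepted >= warmup &&
        (accepted - warmup) % stride == 0 && accepted > warmup) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          out[(R_xlen_t)stored + (R_xlen_t)n_conf * (i + (R_xlen_t)n * d)] =
            (double)xs[i][d];
      ++stored;
    }
  }
  out.attr("dim") = IntegerVector::create(n_conf, n, 3);
  return out;
}

// mean-square distances per separation s, averaged over frames:
// returns vector of length n-1 with sum of squared distances and a count
// matrix is unnecessary since every (frame, pair) contributes once.
// [[Rcpp::export]]
NumericMatrix cpp_internal_distance_moments(NumericVector frames) {
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], n = dim[1];
  NumericMatrix out(n - 1, 3); // sum r, sum r^2, count
  const double *p = REAL(frames);
  for (int f = 0; f < nf; ++f)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = p[f + (R_xlen_t)nf * (i + (R_xlen_t)n * 0)] -
                    p[f + (R_xlen_t)nf * (j + (R_xlen_t)n * 0)];
        double dy = p[f + (R_xlen_t)nf * (i + (R_xlen_t)n * 1)] -
                    p[f + (R_xlen_t)nf * (j + (R_xlen_t)n * 1)];
        double dz = p[f + (R_xlen_t)nf * (i + (R_xlen_t)n * 2)] -
                    p[f + (R_xlen_t)nf * (j + (R_xlen_t)n * 2)];
        double r2 = dx * dx + dy * dy + dz * dz;
        int s = j - i - 1;
        out(s, 0) += std::sqrt(r2);
        out(s, 1) += r2;
        out(s, 2) += 1.0;
      }
  return out;
}
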