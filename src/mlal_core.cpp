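// Core numerics: SOAP-style power-spectrum descriptors (pair expansion with
// analytic gradients), analytic toy force fields, kernel-ridge potential
// evaluation and the velocity-Verlet/Langevin MD integrator.
//
// Units: eV, Angstrom, fs, amu.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double EVA_AMU_ACC = 9.64853322e-3;   // (eV/A)/amu -> A/fs^2
static const double AMU_A2_FS2_TO_EV = 1.0 / EVA_AMU_ACC;
static const double KB_EV = 8.617333262e-5;        // eV/K
static const double COUL_K = 14.399645;            // eV*A*e^-2

// ---------------------------------------------------------------- geometry

struct Cell {
  bool periodic = false;
  double h[9];    // row vectors
  double hinv[9];
  void set(const NumericMatrix& m) {
    periodic = true;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) h[3 * i + j] = m(i, j);
    // invert 3x3
    double a = h[0], b = h[1], c = h[2], d = h[3], e = h[4], f = h[5],
           g = h[6], hh = h[7], k = h[8];
    double det = a * (e * k - f * hh) - b * (d * k - f * g) + c * (d * hh - e * g);
    double inv[9] = {
      (e * k - f * hh), -(b * k - c * hh), (b * f - c * e),
      -(d * k - f * g), (a * k - c * g), -(a * f - c * d),
      (d * hh - e * g), -(a * hh - b * g), (a * e - b * d)
    };
    for (int i = 0; i < 9; ++i) hinv[i] = inv[i] / det;
    // transpose to get proper inverse
    std::swap(hinv[1], hinv[3]); std::swap(hinv[2], hinv[6]); std::swap(hinv[5], hinv[7]);
  }
  // minimum-image displacement dx = r_b - r_a
  inline void mic(double& dx, double& dy, double& dz) const {
    if (!periodic) return;
    double fx = dx * hinv[0] + dy * hinv[3] + dz * hinv[6];
    double fy = dx * hinv[1] + dy * hinv[4] + dz * hinv[7];
    double fz = dx * hinv[2] + dy * hinv[5] + dz * hinv[8];
    fx -= std::round(fx); fy -= std::round(fy); fz -= std::round(fz);
    dx = fx * h[0] + fy * h[3] + fz * h[6];
    dy = fx * h[1] + fy * h[4] + fz * h[7];
    dz = fx * h[2] + fy * h[5] + fz * h[8];
  }
};

static Cell make_cell(Nullable<NumericMatrix> cellN, bool periodic) {
  Cell c;
  if (periodic && cellN.isNotNull()) c.set(NumericMatrix(cellN));
  return c;
}

// ------------------------------------------------------------------- SOAP

struct SoapSpec {
  double rcut, sigma;
  int nmax, lmax, S;
  std::vector<double> mu;
  int D;
  std::vector<int> idx0; // [((s1*S+s2)*nmax+n1)*nmax+n2] -> canonical offset (l=0)
  void init(double rcut_, int nmax_, int lmax_, double sigma_, int S_) {
    rcut = rcut_; nmax = nmax_; lmax = lmax_; sigma = sigma_; S = S_;
    mu.resize(nmax);
    for (int n = 0; n < nmax; ++n) mu[n] = rcut * n / nmax;
    idx0.assign(S * S * nmax * nmax, -1);
    int off = 0;
    for (int s1 = 0; s1 < S; ++s1)
      for (int s2 = s1; s2 < S; ++s2)
        for (int n1 = 0; n1 < nmax; ++n1)
          for (int n2 = (s1 == s2 ? n1 : 0); n2 < nmax; ++n2) {
            idx0[((s1 * S + s2) * nmax + n1) * nmax + n2] = off;
            idx0[((s2 * S + s1) * nmax + n2) * nmax + n1] = off;
            off += lmax + 1;
          }
    D = off;
  }
  inline int slot(int s1, int s2, int n1, int n2) const {
    return idx0[((s1 * S + s2) * nmax + n1) * nmax + n2];
  }
};

static SoapSpec parse_soap(const List& sp) {
  SoapSpec s;
  s.init(as<double>(sp["r_cut"]), as<int>(sp["n_max"]), as<int>(sp["l_max"]),
         as<double>(sp["sigma_atom"]), as<int>(sp["n_species"]));
  return s;
}

struct Neigh { int j; double dx, dy, dz, r; };

static void neighbour_lists(const double* pos, int N, const Cell& cell,
                            double rcut, std::vector<std::vector<Neigh> >& nb) {
  nb.assign(N, std::vector<Neigh>());
  double rc2 = rcut * rcut;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      double dx = pos[3 * j] - pos[3 * i];
      double dy = pos[3 * j + 1] - pos[3 * i + 1];
      double dz = pos[3 * j + 2] - pos[3 * i + 2];
      cell.mic(dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2 && r2 > 1e-16) {
        Neigh nn; nn.j = j; nn.dx = dx; nn.dy = dy; nn.dz = dz; nn.r = std::sqrt(r2);
        nb[i].push_back(nn);
      }
    }
}

static inline void radial_basis(const SoapSpec& sp, double r,
                                double* g, double* gp) {
  double fc = 0.5 * (std::cos(M_PI * r / sp.rcut) + 1.0);
  double fcp = -0.5 * M_PI / sp.rcut * std::sin(M_PI * r / sp.rcut);
  double is2 = 1.0 / (sp.sigma * sp.sigma);
  for (int n = 0; n < sp.nmax; ++n) {
    double dr = r - sp.mu[n];
    double e = std::exp(-0.5 * dr * dr * is2);
    g[n] = e * fc;
    if (gp) gp[n] = e * (-dr * is2) * fc + e * fcp;
  }
}

static inline void legendre(int lmax, double u, double* P, double* Pp) {
  P[0] = 1.0; if (Pp) Pp[0] = 0.0;
  if (lmax >= 1) { P[1] = u; if (Pp) Pp[1] = 1.0; }
  for (int l = 1; l < lmax; ++l) {
    P[l + 1] = ((2 * l + 1) * u * P[l] - l * P[l - 1]) / (l + 1);
    if (Pp) Pp[l + 1] = ((2 * l + 1) * (P[l] + u * Pp[l]) - l * Pp[l - 1]) / (l + 1);
  }
}

// Accumulate the (unnormalised) power spectrum of atom i into out[D].
static void atom_power_spectrum(const SoapSpec& sp, const std::vector<Neigh>& nb,
                                const int* spec, double* out,
                                std::vector<double>& Gbuf) {
  int M = (int)nb.size();
  if (M == 0) return;
  Gbuf.resize((size_t)M * sp.nmax);
  std::vector<double> P(sp.lmax + 1);
  for (int a = 0; a < M; ++a)
    radial_basis(sp, nb[a].r, &Gbuf[(size_t)a * sp.nmax], nullptr);
  for (int a = 0; a < M; ++a) {
    int sa = spec[nb[a].j];
    const double* Ga = &Gbuf[(size_t)a * sp.nmax];
    for (int b = 0; b < M; ++b) {
      int sb = spec[nb[b].j];
      const double* Gb = &Gbuf[(size_t)b * sp.nmax];
      double u;
      if (a == b) u = 1.0;
      else u = (nb[a].dx * nb[b].dx + nb[a].dy * nb[b].dy + nb[a].dz * nb[b].dz) /
               (nb[a].r * nb[b].r);
      if (u > 1.0) u = 1.0; if (u < -1.0) u = -1.0;
      legendre(sp.lmax, u, P.data(), nullptr);
      for (int n1 = 0; n1 < sp.nmax; ++n1) {
        double ga = Ga[n1];
        for (int n2 = 0; n2 < sp.nmax; ++n2) {
          int s0 = sp.slot(sa, sb, n1, n2);
          double gg = ga * Gb[n2];
          for (int l = 0; l <= sp.lmax; ++l) out[s0 + l] += gg * P[l];
        }
      }
    }
  }
}

// Accumulate grad_x (v . q) over the pair terms of atom i; grad is 3N.
static void atom_ps_grad(const SoapSpec& sp, int i, const std::vector<Neigh>& nb,
                         const int* spec, const double* v, double* grad) {
  int M = (int)nb.size();
  if (M == 0) return;
  std::vector<double> G((size_t)M * sp.nmax), Gp((size_t)M * sp.nmax);
  std::vector<double> P(sp.lmax + 1), Pp(sp.lmax + 1);
  for (int a = 0; a < M; ++a)
    radial_basis(sp, nb[a].r, &G[(size_t)a * sp.nmax], &Gp[(size_t)a * sp.nmax]);
  for (int a = 0; a < M; ++a) {
    int sa = spec[nb[a].j];
    const double* Ga = &G[(size_t)a * sp.nmax];
    const double* Gpa = &Gp[(size_t)a * sp.nmax];
    double uxa = nb[a].dx / nb[a].r, uya = nb[a].dy / nb[a].r, uza = nb[a].dz / nb[a].r;
    for (int b = 0; b < M; ++b) {
      int sb = spec[nb[b].j];
      const double* Gb = &G[(size_t)b * sp.nmax];
      const double* Gpb = &Gp[(size_t)b * sp.nmax];
      double uxb = nb[b].dx / nb[b].r, uyb = nb[b].dy / nb[b].r, uzb = nb[b].dz / nb[b].r;
      double u, duax = 0, duay = 0, duaz = 0, dubx = 0, duby = 0, dubz = 0;
      bool diag = (a == b);
      if (diag) u = 1.0;
      else {
        u = uxa * uxb + uya * uyb + uza * uzb;
        if (u > 1.0) u = 1.0; if (u < -1.0) u = -1.0;
        duax = (uxb - u * uxa) / nb[a].r;
        duay = (uyb - u * uya) / nb[a].r;
        duaz = (uzb - u * uza) / nb[a].r;
        dubx = (uxa - u * uxb) / nb[b].r;
        duby = (uya - u * uyb) / nb[b].r;
        dubz = (uza - u * uzb) / nb[b].r;
      }
      legendre(sp.lmax, u, P.data(), Pp.data());
      // contract v over (n1,n2,l) for this pair
      double cr_a = 0.0, cr_b = 0.0, cu = 0.0;
      for (int n1 = 0; n1 < sp.nmax; ++n1) {
        for (int n2 = 0; n2 < sp.nmax; ++n2) {
          int s0 = sp.slot(sa, sb, n1, n2);
          double vP = 0.0, vPp = 0.0;
          for (int l = 0; l <= sp.lmax; ++l) {
            vP += v[s0 + l] * P[l];
            vPp += v[s0 + l] * Pp[l];
          }
          cr_a += Gpa[n1] * Gb[n2] * vP;
          cr_b += Ga[n1] * Gpb[n2] * vP;
          if (!diag) cu += Ga[n1] * Gb[n2] * vPp;
        }
      }
      double gax = cr_a * uxa + cu * duax;
      double gay = cr_a * uya + cu * duay;
      double gaz = cr_a * uza + cu * duaz;
      double gbx = cr_b * uxb + cu * dubx;
      double gby = cr_b * uyb + cu * duby;
      double gbz = cr_b * uzb + cu * dubz;
      int ja = nb[a].j, jb = nb[b].j;
      grad[3 * ja] += gax; grad[3 * ja + 1] += gay; grad[3 * ja + 2] += gaz;
      grad[3 * jb] += gbx; grad[3 * jb + 1] += gby; grad[3 * jb + 2] += gbz;
      grad[3 * i] -= gax + gbx; grad[3 * i + 1] -= gay + gby; grad[3 * i + 2] -= gaz + gbz;
    }
  }
}

// Full Jacobian of the (unnormalised, centre-species-resolved, averaged)
// global vector q with respect to all coordinates: J is (S*D) x 3N.
static void atom_ps_jac(const SoapSpec& sp, int i, const std::vector<Neigh>& nb,
                        const int* spec, int block, double* J, int Dtot,
                        int N) {
  int M = (int)nb.size();
  if (M == 0) return;
  std::vector<double> G((size_t)M * sp.nmax), Gp((size_t)M * sp.nmax);
  std::vector<double> P(sp.lmax + 1), Pp(sp.lmax + 1);
  for (int a = 0; a < M; ++a)
    radial_basis(sp, nb[a].r, &G[(size_t)a * sp.nmax], &Gp[(size_t)a * sp.nmax]);
  auto Jat = [&](int d, int atom, int comp) -> double& {
    return J[(size_t)(3 * atom + comp) * Dtot + block + d];
  };
  for (int a = 0; a < M; ++a) {
    int sa = spec[nb[a].j];
    const double* Ga = &G[(size_t)a * sp.nmax];
    const double* Gpa = &Gp[(size_t)a * sp.nmax];
    double ua[3] = {nb[a].dx / nb[a].r, nb[a].dy / nb[a].r, nb[a].dz / nb[a].r};
    for (int b = 0; b < M; ++b) {
      int sb = spec[nb[b].j];
      const double* Gb = &G[(size_t)b * sp.nmax];
      const double* Gpb = &Gp[(size_t)b * sp.nmax];
      double ub[3] = {nb[b].dx / nb[b].r, nb[b].dy / nb[b].r, nb[b].dz / nb[b].r};
      double u, dua[3] = {0, 0, 0}, dub[3] = {0, 0, 0};
      bool diag = (a == b);
      if (diag) u = 1.0;
      else {
        u = ua[0] * ub[0] + ua[1] * ub[1] + ua[2] * ub[2];
        if (u > 1.0) u = 1.0;
        if (u < -1.0) u = -1.0;
        for (int c = 0; c < 3; ++c) {
          dua[c] = (ub[c] - u * ua[c]) / nb[a].r;
          dub[c] = (ua[c] - u * ub[c]) / nb[b].r;
        }
      }
      legendre(sp.lmax, u, P.data(), Pp.data());
      int ja = nb[a].j, jb = nb[b].j;
      for (int n1 = 0; n1 < sp.nmax; ++n1)
        for (int n2 = 0; n2 < sp.nmax; ++n2) {
          int s0 = sp.slot(sa, sb, n1, n2);
          double rga = Gpa[n1] * Gb[n2], rgb = Ga[n1] * Gpb[n2];
          double gg = Ga[n1] * Gb[n2];
          for (int l = 0; l <= sp.lmax; ++l) {
            int d = s0 + l;
            for (int c = 0; c < 3; ++c) {
              double ta = rga * P[l] * ua[c] + (diag ? 0.0 : gg * Pp[l] * dua[c]);
              double tb = rgb * P[l] * ub[c] + (diag ? 0.0 : gg * Pp[l] * dub[c]);
              Jat(d, ja, c) += ta;
              Jat(d, jb, c) += tb;
              Jat(d, i, c) -= ta + tb;
            }
          }
        }
    }
  }
}

// [[Rcpp::export]]
List soap_global_cpp(NumericMatrix pos, IntegerVector species0, List soapspec,
                     Nullable<NumericMatrix> cellN, bool periodic,
                     bool jacobian) {
  SoapSpec sp = parse_soap(soapspec);
  int N = pos.nrow();
  int Dtot = sp.D * sp.S;
  std::vector<double> p(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  Cell cell = make_cell(cellN, periodic);
  std::vector<std::vector<Neigh> > nb;
  neighbour_lists(p.data(), N, cell, sp.rcut, nb);
  std::vector<int> spec(species0.begin(), species0.end());
  NumericVector q(Dtot);
  std::vector<double> Gbuf;
  for (int i = 0; i < N; ++i)
    atom_power_spectrum(sp, nb[i], spec.data(),
                        REAL(q) + (size_t)spec[i] * sp.D, Gbuf);
  for (int d = 0; d < Dtot; ++d) q[d] /= N;
  if (!jacobian) return List::create(_["q"] = q);
  NumericMatrix J(Dtot, 3 * N);
  for (int i = 0; i < N; ++i)
    atom_ps_jac(sp, i, nb[i], spec.data(), spec[i] * sp.D, REAL(J), Dtot, N);
  for (R_xlen_t d = 0; d < (R_xlen_t)Dtot * 3 * N; ++d) J[d] /= N;
  return List::create(_["q"] = q, _["jacobian"] = J);
}

// [[Rcpp::export]]
NumericMatrix soap_atoms_cpp(NumericMatrix pos, IntegerVector species0,
                             List soapspec, Nullable<NumericMatrix> cellN,
                             bool periodic) {
  SoapSpec sp = parse_soap(soapspec);
  int N = pos.nrow();
  std::vector<double> p(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  Cell cell = make_cell(cellN, periodic);
  std::vector<std::vector<Neigh> > nb;
  neighbour_lists(p.data(), N, cell, sp.rcut, nb);
  NumericMatrix out(N, sp.D);
  std::vector<double> row(sp.D), Gbuf;
  std::vector<int> spec(species0.begin(), species0.end());
  for (int i = 0; i < N; ++i) {
    std::fill(row.begin(), row.end(), 0.0);
    atom_power_spectrum(sp, nb[i], spec.data(), row.data(), Gbuf);
    for (int d = 0; d < sp.D; ++d) out(i, d) = row[d];
  }
  return out;
}

// ------------------------------------------------------------ force fields

struct Bond { int i, j; double k, r0; };
struct Angle { int i, j, k; double ka, th0; };  // j is the vertex
struct LJPair { int i, j; double eps, sigma; };
struct DWell { int i, j; double h, c, w, s; };
struct Coupl { int i1, j1, i2, j2; double g; };

struct FF {
  std::vector<Bond> bonds;
  std::vector<Angle> angles;
  std::vector<LJPair> ljs;
  std::vector<DWell> dwells;
  std::vector<Coupl> coups;
  std::vector<double> charge;
  std::vector<int> mol;
  double coul_rcut = 0.0;
  bool has_coul = false;
};

static FF parse_ff(const List& spec) {
  FF ff;
  if (spec.containsElementNamed("bonds") && !Rf_isNull(spec["bonds"])) {
    NumericMatrix b = spec["bonds"];
    for (int r = 0; r < b.nrow(); ++r)
      ff.bonds.push_back({(int)b(r, 0) - 1, (int)b(r, 1) - 1, b(r, 2), b(r, 3)});
  }
  if (spec.containsElementNamed("angles") && !Rf_isNull(spec["angles"])) {
    NumericMatrix a = spec["angles"];
    for (int r = 0; r < a.nrow(); ++r)
      ff.angles.push_back({(int)a(r, 0) - 1, (int)a(r, 1) - 1, (int)a(r, 2) - 1,
                           a(r, 3), a(r, 4)});
  }
  if (spec.containsElementNamed("lj") && !Rf_isNull(spec["lj"])) {
    NumericMatrix l = spec["lj"];
    for (int r = 0; r < l.nrow(); ++r)
      ff.ljs.push_back({(int)l(r, 0) - 1, (int)l(r, 1) - 1, l(r, 2), l(r, 3)});
  }
  if (spec.containsElementNamed("double_wells") && !Rf_isNull(spec["double_wells"])) {
    NumericMatrix d = spec["double_wells"];
    for (int r = 0; r < d.nrow(); ++r)
      ff.dwells.push_back({(int)d(r, 0) - 1, (int)d(r, 1) - 1, d(r, 2), d(r, 3),
                           d(r, 4), d(r, 5)});
  }
  if (spec.containsElementNamed("couplings") && !Rf_isNull(spec["couplings"])) {
    NumericMatrix c = spec["couplings"];
    for (int r = 0; r < c.nrow(); ++r)
      ff.coups.push_back({(int)c(r, 0) - 1, (int)c(r, 1) - 1, (int)c(r, 2) - 1,
                          (int)c(r, 3) - 1, c(r, 4)});
  }
  if (spec.containsElementNamed("charges") && !Rf_isNull(spec["charges"])) {
    NumericVector q = spec["charges"];
    ff.charge.assign(q.begin(), q.end());
    IntegerVector m = spec["mol"];
    ff.mol.assign(m.begin(), m.end());
    ff.coul_rcut = as<double>(spec["coul_rcut"]);
    ff.has_coul = true;
  }
  return ff;
}

static double ff_energy_forces(const FF& ff, const double* pos, int N,
                               const Cell& cell, double* F) {
  double E = 0.0;
  if (F) std::fill(F, F + 3 * N, 0.0);
  auto disp = [&](int i, int j, double& dx, double& dy, double& dz) {
    dx = pos[3 * j] - pos[3 * i];
    dy = pos[3 * j + 1] - pos[3 * i + 1];
    dz = pos[3 * j + 2] - pos[3 * i + 2];
    cell.mic(dx, dy, dz);
  };
  auto add_pair_force = [&](int i, int j, double fr, double dx, double dy,
                            double dz, double r) {
    // fr = dE/dr; force on j is -fr * unit(j-i)
    if (!F) return;
    double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
    F[3 * j] -= fx; F[3 * j + 1] -= fy; F[3 * j + 2] -= fz;
    F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
  };
  double dx, dy, dz;
  for (const Bond& b : ff.bonds) {
    disp(b.i, b.j, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    E += 0.5 * b.k * (r - b.r0) * (r - b.r0);
    add_pair_force(b.i, b.j, b.k * (r - b.r0), dx, dy, dz, r);
  }
  for (const Angle& an : ff.angles) {
    double ux, uy, uz, vx, vy, vz;
    disp(an.j, an.i, ux, uy, uz);
    disp(an.j, an.k, vx, vy, vz);
    double ru = std::sqrt(ux * ux + uy * uy + uz * uz);
    double rv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (ru * rv);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    E += 0.5 * an.ka * (th - an.th0) * (th - an.th0);
    if (F) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double dEdth = an.ka * (th - an.th0);
      double uhx = ux / ru, uhy = uy / ru, uhz = uz / ru;
      double vhx = vx / rv, vhy = vy / rv, vhz = vz / rv;
      // grad_i theta = -(vh - c*uh)/(ru*s); grad_k theta = -(uh - c*vh)/(rv*s)
      double gix = -(vhx - c * uhx) / (ru * s);
      double giy = -(vhy - c * uhy) / (ru * s);
      double giz = -(vhz - c * uhz) / (ru * s);
      double gkx = -(uhx - c * vhx) / (rv * s);
      double gky = -(uhy - c * vhy) / (rv * s);
      double gkz = -(uhz - c * vhz) / (rv * s);
      F[3 * an.i] -= dEdth * gix; F[3 * an.i + 1] -= dEdth * giy; F[3 * an.i + 2] -= dEdth * giz;
      F[3 * an.k] -= dEdth * gkx; F[3 * an.k + 1] -= dEdth * gky; F[3 * an.k + 2] -= dEdth * gkz;
      F[3 * an.j] += dEdth * (gix + gkx);
      F[3 * an.j + 1] += dEdth * (giy + gky);
      F[3 * an.j + 2] += dEdth * (giz + gkz);
    }
  }
  for (const LJPair& lj : ff.ljs) {
    disp(lj.i, lj.j, dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double sr6 = std::pow(lj.sigma * lj.sigma / r2, 3.0);
    E += 4.0 * lj.eps * (sr6 * sr6 - sr6);
    double dEdr = 4.0 * lj.eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
    add_pair_force(lj.i, lj.j, dEdr, dx, dy, dz, r);
  }
  for (const DWell& dw : ff.dwells) {
    disp(dw.i, dw.j, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double t = r - dw.c;
    double q = t * t - dw.w * dw.w;
    double w4 = dw.w * dw.w * dw.w * dw.w;
    E += dw.h * q * q / w4 + dw.s * t;
    double dEdr = dw.h * 4.0 * q * t / w4 + dw.s;
    add_pair_force(dw.i, dw.j, dEdr, dx, dy, dz, r);
  }
  for (const Coupl& cp : ff.coups) {
    double d1x, d1y, d1z, d2x, d2y, d2z;
    disp(cp.i1, cp.j1, d1x, d1y, d1z);
    disp(cp.i2, cp.j2, d2x, d2y, d2z);
    double r1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
    double r2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
    double dr = r1 - r2;
    E += cp.g * dr * dr;
    add_pair_force(cp.i1, cp.j1, 2.0 * cp.g * dr, d1x, d1y, d1z, r1);
    add_pair_force(cp.i2, cp.j2, -2.0 * cp.g * dr, d2x, d2y, d2z, r2);
  }
  if (ff.has_coul) {
    double rc = ff.coul_rcut;
    for (int i = 0; i < N; ++i) {
      if (ff.charge[i] == 0.0) continue;
      for (int j = i + 1; j < N; ++j) {
        if (ff.charge[j] == 0.0 || ff.mol[i] == ff.mol[j]) continue;
        disp(i, j, dx, dy, dz);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r >= rc) continue;
        double qq = COUL_K * ff.charge[i] * ff.charge[j];
        // shifted-force Coulomb: V(rc)=0, V'(rc)=0 (C1 smooth truncation)
        E += qq * (1.0 / r - 1.0 / rc + (r - rc) / (rc * rc));
        double dEdr = qq * (-1.0 / (r * r) + 1.0 / (rc * rc));
        add_pair_force(i, j, dEdr, dx, dy, dz, r);
      }
    }
  }
  return E;
}

// --------------------------------------------------------------- KRR model

struct KRR {
  SoapSpec soap;
  std::vector<double> P;    // T x D row-major, unit rows
  std::vector<double> alpha;
  int T = 0;
  double zeta = 4.0, shift = 0.0;
  // two-body core-repulsion baseline: V = A ((r_on/r)^6 - 1)^2 for r < r_on
  bool has_core = false;
  double coreA = 1.0;
  std::vector<double> r_on; // S x S
};

// shared core-repulsion evaluation over a neighbour list (pairs i<j)
static double core_eval(const std::vector<std::vector<Neigh> >& nb,
                        const int* spec, int S, const std::vector<double>& r_on,
                        double A, double* F) {
  double E = 0.0;
  for (size_t i = 0; i < nb.size(); ++i)
    for (const Neigh& nn : nb[i]) {
      if (nn.j <= (int)i) continue;
      double ron = r_on[spec[i] * S + spec[nn.j]];
      if (nn.r >= ron || ron <= 0) continue;
      double x = std::pow(ron / nn.r, 6.0);
      E += A * (x - 1.0) * (x - 1.0);
      if (F) {
        double dEdr = 2.0 * A * (x - 1.0) * (-6.0 * x / nn.r);
        double fx = dEdr * nn.dx / nn.r, fy = dEdr * nn.dy / nn.r,
               fz = dEdr * nn.dz / nn.r;
        F[3 * nn.j] -= fx; F[3 * nn.j + 1] -= fy; F[3 * nn.j + 2] -= fz;
        F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz;
      }
    }
  return E;
}

static KRR parse_krr(const List& spec) {
  KRR k;
  k.soap = parse_soap(spec["soap"]);
  NumericMatrix P = spec["train_descriptors"];
  k.T = P.nrow();
  int D = k.soap.D * k.soap.S;
  if (P.ncol() != D)
    stop("training descriptor length (%d) does not match the descriptor "
         "spec (%d)", (int)P.ncol(), D);
  k.P.resize((size_t)k.T * D);
  for (int t = 0; t < k.T; ++t)
    for (int d = 0; d < D; ++d) k.P[(size_t)t * D + d] = P(t, d);
  NumericVector a = spec["alpha"];
  k.alpha.assign(a.begin(), a.end());
  k.zeta = as<double>(spec["zeta"]);
  k.shift = as<double>(spec["shift"]);
  if (spec.containsElementNamed("core_r_on") && !Rf_isNull(spec["core_r_on"])) {
    NumericMatrix ron = spec["core_r_on"];
    k.has_core = true;
    k.coreA = as<double>(spec["core_A"]);
    k.r_on.assign(ron.begin(), ron.end());
  }
  return k;
}

static double krr_energy_forces(const KRR& kr, const double* pos, int N,
                                const int* spec, const Cell& cell, double* F) {
  const SoapSpec& sp = kr.soap;
  // global vector = per-centre-species averaged blocks, concatenated
  int D = sp.D * sp.S;
  std::vector<std::vector<Neigh> > nb;
  neighbour_lists(pos, N, cell, sp.rcut, nb);
  std::vector<double> q(D, 0.0), Gbuf;
  for (int i = 0; i < N; ++i)
    atom_power_spectrum(sp, nb[i], spec, q.data() + (size_t)spec[i] * sp.D,
                        Gbuf);
  for (int d = 0; d < D; ++d) q[d] /= N;
  double nrm = 0.0;
  for (int d = 0; d < D; ++d) nrm += q[d] * q[d];
  nrm = std::sqrt(nrm);
  if (F) std::fill(F, F + 3 * N, 0.0);
  double Ecore = 0.0;
  if (kr.has_core) Ecore = core_eval(nb, spec, sp.S, kr.r_on, kr.coreA, F);
  if (nrm < 1e-300) return kr.shift + Ecore;
  std::vector<double> pbar(D);
  for (int d = 0; d < D; ++d) pbar[d] = q[d] / nrm;
  double E = kr.shift + Ecore;
  std::vector<double> w(D, 0.0);
  for (int t = 0; t < kr.T; ++t) {
    const double* Pt = &kr.P[(size_t)t * D];
    double s = 0.0;
    for (int d = 0; d < D; ++d) s += pbar[d] * Pt[d];
    double as = std::fabs(s);
    E += kr.alpha[t] * std::pow(as, kr.zeta);
    if (F) {
      double coef = kr.alpha[t] * kr.zeta *
                    std::pow(as, kr.zeta - 1.0) * (s >= 0 ? 1.0 : -1.0);
      for (int d = 0; d < D; ++d) w[d] += coef * Pt[d];
    }
  }
  if (F) {
    double wp = 0.0;
    for (int d = 0; d < D; ++d) wp += w[d] * pbar[d];
    std::vector<double> v(D);
    for (int d = 0; d < D; ++d) v[d] = (w[d] - wp * pbar[d]) / (nrm * N);
    std::vector<double> grad(3 * N, 0.0);
    for (int i = 0; i < N; ++i)
      atom_ps_grad(sp, i, nb[i], spec, v.data() + (size_t)spec[i] * sp.D,
                   grad.data());
    for (int d = 0; d < 3 * N; ++d) F[d] -= grad[d];
  }
  return E;
}

// [[Rcpp::export]]
List core_eval_cpp(NumericMatrix pos, IntegerVector species0, int n_species,
                   NumericMatrix r_on, double A,
                   Nullable<NumericMatrix> cellN, bool periodic) {
  int N = pos.nrow();
  std::vector<double> p(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) p[3 * i + d] = pos(i, d);
  Cell cell = make_cell(cellN, periodic);
  double rmax = 0.0;
  for (int i = 0; i < r_on.size(); ++i) rmax = std::max(rmax, r_on[i]);
  std::vector<std::vector<Neigh> > nb;
  neighbour_lists(p.data(), N, cell, std::max(rmax, 1e-3), nb);
  std::vector<int> spec(species0.begin(), species0.end());
  std::vector<double> ron(r_on.begin(), r_on.end());
  std::vector<double> F(3 * N, 0.0);
  double E = core_eval(nb, spec.data(), n_species, ron, A, F.data());
  NumericMatrix Fm(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(_["energy"] = E, _["forces"] = Fm);
}

// ------------------------------------------------------------------ biases

struct Bias {
  int type;            // 0 distance, 1 rcoord
  int a[4];
  double k, center;
};

static std::vector<Bias> parse_biases(const List& bl) {
  std::vector<Bias> out;
  for (int i = 0; i < bl.size(); ++i) {
    List b = bl[i];
    Bias bb;
    std::string ty = as<std::string>(b["type"]);
    bb.type = (ty == "rcoord") ? 1 : 0;
    IntegerVector at = b["atoms"];
    for (int j = 0; j < at.size() && j < 4; ++j) bb.a[j] = at[j] - 1;
    bb.k = as<double>(b["k"]);
    bb.center = as<double>(b["center"]);
    out.push_back(bb);
  }
  return out;
}

// returns bias energy, adds forces, writes coordinate value into *val
static double bias_energy_forces(const Bias& b, const double* pos,
                                 const Cell& cell, double* F, double* val) {
  auto dist_grad = [&](int i, int j, double& r, double g[6]) {
    double dx = pos[3 * j] - pos[3 * i];
    double dy = pos[3 * j + 1] - pos[3 * i + 1];
    double dz = pos[3 * j + 2] - pos[3 * i + 2];
    cell.mic(dx, dy, dz);
    r = std::sqrt(dx * dx + dy * dy + dz * dz);
    g[0] = -dx / r; g[1] = -dy / r; g[2] = -dz / r;   // d r / d pos_i
    g[3] = dx / r;  g[4] = dy / r;  g[5] = dz / r;    // d r / d pos_j
  };
  double g1[6], g2[6], r1, r2;
  if (b.type == 0) {
    dist_grad(b.a[0], b.a[1], r1, g1);
    double xi = r1;
    if (val) *val = xi;
    double dEdxi = b.k * (xi - b.center);
    if (F) {
      for (int d = 0; d < 3; ++d) {
        F[3 * b.a[0] + d] -= dEdxi * g1[d];
        F[3 * b.a[1] + d] -= dEdxi * g1[3 + d];
      }
    }
    return 0.5 * b.k * (xi - b.center) * (xi - b.center);
  }
  dist_grad(b.a[0], b.a[1], r1, g1);
  dist_grad(b.a[2], b.a[3], r2, g2);
  double xi = 0.5 * (r1 + r2);
  if (val) *val = xi;
  double dEdxi = b.k * (xi - b.center);
  if (F) {
    for (int d = 0; d < 3; ++d) {
      F[3 * b.a[0] + d] -= 0.5 * dEdxi * g1[d];
      F[3 * b.a[1] + d] -= 0.5 * dEdxi * g1[3 + d];
      F[3 * b.a[2] + d] -= 0.5 * dEdxi * g2[d];
      F[3 * b.a[3] + d] -= 0.5 * dEdxi * g2[3 + d];
    }
  }
  return 0.5 * b.k * (xi - b.center) * (xi - b.center);
}

// --------------------------------------------------------- potential facade

struct PotHandle {
  int type;  // 0 ff, 1 krr
  FF ff;
  KRR krr;
};

static PotHandle parse_pot(const List& potspec) {
  PotHandle p;
  std::string ty = as<std::string>(potspec["type"]);
  if (ty == "ff") { p.type = 0; p.ff = parse_ff(potspec); }
  else if (ty == "krr") { p.type = 1; p.krr = parse_krr(potspec); }
  else stop("unknown potential type: %s", ty.c_str());
  return p;
}

static double pot_eval(const PotHandle& p, const double* pos, int N,
                       const int* spec, const Cell& cell, double* F) {
  if (p.type == 0) return ff_energy_forces(p.ff, pos, N, cell, F);
  return krr_energy_forces(p.krr, pos, N, spec, cell, F);
}

// [[Rcpp::export]]
List pot_eval_cpp(List potspec, NumericMatrix pos, IntegerVector species0,
                  Nullable<NumericMatrix> cellN, bool periodic,
                  bool want_forces) {
  PotHandle p = parse_pot(potspec);
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  Cell cell = make_cell(cellN, periodic);
  std::vector<int> spec(species0.begin(), species0.end());
  std::vector<double> F;
  double E;
  if (want_forces) {
    F.assign(3 * N, 0.0);
    E = pot_eval(p, x.data(), N, spec.data(), cell, F.data());
    NumericMatrix Fm(N, 3);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
    return List::create(_["energy"] = E, _["forces"] = Fm);
  }
  E = pot_eval(p, x.data(), N, spec.data(), cell, nullptr);
  return List::create(_["energy"] = E);
}

// ------------------------------------------------------------------ MD run

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                IntegerVector species0, List potspec, List biaslist,
                LogicalVector frozen, double dt, int nsteps, double friction,
                double temperature, int stride,
                Nullable<NumericMatrix> cellN, bool periodic,
                double fmax_abort) {
  PotHandle pot = parse_pot(potspec);
  std::vector<Bias> biases = parse_biases(biaslist);
  int N = pos0.nrow();
  int NB = (int)biases.size();
  std::vector<double> x(3 * N), vv(3 * N), F(3 * N), m(N);
  std::vector<int> spec(species0.begin(), species0.end());
  std::vector<bool> frz(N, false);
  for (int i = 0; i < N; ++i) {
    m[i] = mass[i];
    frz[i] = frozen[i];
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos0(i, d);
      vv[3 * i + d] = frozen[i] ? 0.0 : vel0(i, d);
    }
  }
  Cell cell = make_cell(cellN, periodic);

  bool langevin = friction > 0.0;
  double c1 = langevin ? std::exp(-friction * dt) : 1.0;

  int nframes = nsteps / stride + 1;
  NumericVector times(nframes), epot_v(nframes), ekin_v(nframes);
  NumericMatrix biasvals(nframes, std::max(NB, 1));
  NumericVector posrec((R_xlen_t)nframes * N * 3);
  posrec.attr("dim") = IntegerVector::create(N, 3, nframes);

  auto eval_all = [&](double* bv) -> double {
    double E = pot_eval(pot, x.data(), N, spec.data(), cell, F.data());
    for (int b = 0; b < NB; ++b) {
      double val;
      E += bias_energy_forces(biases[b], x.data(), cell, F.data(), &val);
      if (bv) bv[b] = val;
    }
    return E;
  };
  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < N; ++i)
      if (!frz[i])
        ke += 0.5 * m[i] * (vv[3 * i] * vv[3 * i] + vv[3 * i + 1] * vv[3 * i + 1] +
                            vv[3 * i + 2] * vv[3 * i + 2]);
    return ke * AMU_A2_FS2_TO_EV;
  };
  auto forces_bad = [&]() {
    for (int d = 0; d < 3 * N; ++d)
      if (!std::isfinite(F[d]) || std::fabs(F[d]) > fmax_abort) return true;
    return false;
  };

  std::vector<double> bv(std::max(NB, 1), 0.0);
  std::vector<double> x_prev(x);      // last stable coordinates
  double epot = eval_all(bv.data());
  bool unstable = forces_bad();
  int rec = 0, steps_done = 0;
  auto record = [&](double t) {
    times[rec] = t; epot_v[rec] = epot; ekin_v[rec] = kinetic();
    for (int b = 0; b < NB; ++b) biasvals(rec, b) = bv[b];
    double* pr = REAL(posrec) + (R_xlen_t)rec * N * 3;
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) pr[d * N + i] = x[3 * i + d];
    ++rec;
  };
  record(0.0);

  if (!unstable) {
    for (int step = 1; step <= nsteps; ++step) {
      // BAOAB: half kick, half drift, OU, half drift, force, half kick
      for (int i = 0; i < N; ++i) {
        if (frz[i]) continue;
        double f2 = 0.5 * dt * EVA_AMU_ACC / m[i];
        for (int d = 0; d < 3; ++d) vv[3 * i + d] += f2 * F[3 * i + d];
      }
      for (int i = 0; i < N; ++i)
        if (!frz[i])
          for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * vv[3 * i + d];
      if (langevin) {
        for (int i = 0; i < N; ++i) {
          if (frz[i]) continue;
          double c2 = std::sqrt((1.0 - c1 * c1) * KB_EV * temperature /
                                (m[i] * AMU_A2_FS2_TO_EV));
          for (int d = 0; d < 3; ++d)
            vv[3 * i + d] = c1 * vv[3 * i + d] + c2 * norm_rand();
        }
      }
      for (int i = 0; i < N; ++i)
        if (!frz[i])
          for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * vv[3 * i + d];
      epot = eval_all(bv.data());
      if (forces_bad()) {
        unstable = true; steps_done = step; record(step * dt);
        x = x_prev;     // report the last stable frame as final
        break;
      }
      x_prev = x;
      for (int i = 0; i < N; ++i) {
        if (frz[i]) continue;
        double f2 = 0.5 * dt * EVA_AMU_ACC / m[i];
        for (int d = 0; d < 3; ++d) vv[3 * i + d] += f2 * F[3 * i + d];
      }
      steps_done = step;
      if (step % stride == 0) record(step * dt);
    }
  }

  if (rec < nframes) {
    times = NumericVector(times.begin(), times.begin() + rec);
    epot_v = NumericVector(epot_v.begin(), epot_v.begin() + rec);
    ekin_v = NumericVector(ekin_v.begin(), ekin_v.begin() + rec);
    NumericMatrix bv2(rec, std::max(NB, 1));
    for (int r = 0; r < rec; ++r)
      for (int b = 0; b < std::max(NB, 1); ++b) bv2(r, b) = biasvals(r, b);
    biasvals = bv2;
    NumericVector pr2((R_xlen_t)rec * N * 3);
    std::copy(REAL(posrec), REAL(posrec) + (R_xlen_t)rec * N * 3, REAL(pr2));
    pr2.attr("dim") = IntegerVector::create(N, 3, rec);
    posrec = pr2;
  }

  NumericMatrix xf(N, 3), vf(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { xf(i, d) = x[3 * i + d]; vf(i, d) = vv[3 * i + d]; }

  return List::create(
    _["positions"] = posrec, _["times"] = times, _["epot"] = epot_v,
    _["ekin"] = ekin_v, _["bias_values"] = biasvals,
    _["final_positions"] = xf, _["final_velocities"] = vf,
    _["unstable"] = unstable, _["steps_done"] = steps_done
  );
}
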