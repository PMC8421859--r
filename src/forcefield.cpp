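// Energy and analytic-force kernels for the three-bead coarse-grained model.
// All energies in kcal/mol, lengths in Angstrom, charges in e.
// Every kernel accumulates F = -grad V into a shared force array; the R layer
// assembles the per-term topology ("spec") once per chain + force field.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> dvec;

struct Frame {
  const double* x;
  int n;
  double box;
  bool periodic;
  Frame(const NumericMatrix& coords, double box_, bool periodic_)
    : x(coords.begin()), n(coords.nrow()), box(box_), periodic(periodic_) {}
  // displacement r_j - r_i, optionally wrapped to the minimum image
  inline void disp(int i, int j, double* d, bool wrap) const {
    d[0] = x[j] - x[i];
    d[1] = x[j + n] - x[i + n];
    d[2] = x[j + 2 * n] - x[i + 2 * n];
    if (wrap && periodic && box > 0) {
      for (int k = 0; k < 3; ++k) d[k] -= box * std::round(d[k] / box);
    }
  }
  inline void get(int i, double* p) const {
    p[0] = x[i]; p[1] = x[i + n]; p[2] = x[i + 2 * n];
  }
};

// add pair force for scalar potential E(r): F_i += (dE/dr) * d/r, F_j -= same
inline void pair_force(double* F, int n, int i, int j, const double* d,
                       double r, double dEdr) {
  if (r <= 0) return;
  double s = dEdr / r;
  for (int k = 0; k < 3; ++k) {
    F[i + k * n] += s * d[k];
    F[j + k * n] -= s * d[k];
  }
}

inline double norm3(const double* v) {
  return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// ---- V_con: harmonic bead-bead linkage, E = k (r - r0)^2 -------------------
static double e_bonds(const Frame& fr, const List& p, double* F) {
  IntegerVector bi = p["i"], bj = p["j"];
  NumericVector r0 = p["r0"], kk = p["k"];
  double E = 0, d[3];
  for (int b = 0; b < bi.size(); ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    fr.disp(i, j, d, false);
    double r = norm3(d), dr = r - r0[b];
    E += kk[b] * dr * dr;
    pair_force(F, fr.n, i, j, d, r, 2.0 * kk[b] * dr);
  }
  return E;
}

// ---- V_chain: harmonic in cos(theta) about each Calpha ---------------------
static double e_angles(const Frame& fr, const List& p, double* F) {
  IntegerVector ia = p["a"], ib = p["b"], ic = p["c"];
  double k = as<double>(p["k"]), c0 = as<double>(p["cos0"]);
  double E = 0, u[3], v[3];
  for (int t = 0; t < ia.size(); ++t) {
    int a = ia[t] - 1, b = ib[t] - 1, c = ic[t] - 1;
    fr.disp(b, a, u, false);
    fr.disp(b, c, v, false);
    double lu = norm3(u), lv = norm3(v);
    if (lu <= 0 || lv <= 0) continue;
    double cs = dot3(u, v) / (lu * lv);
    double dE = 2.0 * k * (cs - c0);
    E += k * (cs - c0) * (cs - c0);
    for (int m = 0; m < 3; ++m) {
      double dca = v[m] / (lu * lv) - cs * u[m] / (lu * lu);
      double dcc = u[m] / (lu * lv) - cs * v[m] / (lv * lv);
      F[a + m * fr.n] -= dE * dca;
      F[c + m * fr.n] -= dE * dcc;
      F[b + m * fr.n] += dE * (dca + dcc);
    }
  }
  return E;
}

// ---- V_chi: chirality, E = k (C - C0)^2, C = (v1 x v2) . v3 ----------------
static double e_chirality(const Frame& fr, const List& p, double* F) {
  IntegerVector ia = p["a"], ib = p["b"], ic = p["c"], id = p["d"];
  double k = as<double>(p["k"]), c0 = as<double>(p["chi0"]);
  double E = 0, v1[3], v2[3], v3[3], g1[3], g2[3], g3[3];
  for (int t = 0; t < ia.size(); ++t) {
    int a = ia[t] - 1, b = ib[t] - 1, c = ic[t] - 1, d = id[t] - 1;
    fr.disp(b, a, v1, false);
    fr.disp(b, c, v2, false);
    fr.disp(b, d, v3, false);
    double cr[3];
    cross3(v1, v2, cr);
    double C = dot3(cr, v3);
    double dE = 2.0 * k * (C - c0);
    E += k * (C - c0) * (C - c0);
    cross3(v2, v3, g1);  // dC/dv1
    cross3(v3, v1, g2);  // dC/dv2
    // dC/dv3 = v1 x v2 = cr
    for (int m = 0; m < 3; ++m) g3[m] = cr[m];
    for (int m = 0; m < 3; ++m) {
      F[a + m * fr.n] -= dE * g1[m];
      F[c + m * fr.n] -= dE * g2[m];
      F[d + m * fr.n] -= dE * g3[m];
      F[b + m * fr.n] += dE * (g1[m] + g2[m] + g3[m]);
    }
  }
  return E;
}

// ---- V_rama: pseudo-dihedral basins over four consecutive Calpha -----------
static double e_rama(const Frame& fr, const List& p, double* F) {
  IntegerVector ia = p["a"], ib = p["b"], ic = p["c"], id = p["d"];
  NumericVector A = p["A"], phi0 = p["phi0"], kap = p["kappa"];
  double E = 0, b1[3], b2[3], b3[3], m[3], nn[3];
  for (int t = 0; t < ia.size(); ++t) {
    int a = ia[t] - 1, b = ib[t] - 1, c = ic[t] - 1, d = id[t] - 1;
    fr.disp(a, b, b1, false);
    fr.disp(b, c, b2, false);
    fr.disp(c, d, b3, false);
    cross3(b1, b2, m);
    cross3(b2, b3, nn);
    double lm2 = dot3(m, m), ln2 = dot3(nn, nn), lb2 = norm3(b2);
    if (lm2 <= 1e-12 || ln2 <= 1e-12 || lb2 <= 0) continue;  // degenerate
    double cx[3];
    cross3(m, nn, cx);
    double phi = std::atan2(dot3(cx, b2) / lb2, dot3(m, nn));
    double dEdphi = 0;
    for (int s = 0; s < A.size(); ++s) {
      double dp = phi - phi0[s];
      double g = std::exp(kap[s] * (std::cos(dp) - 1.0));
      E += -A[s] * g;
      dEdphi += A[s] * kap[s] * std::sin(dp) * g;
    }
    double da[3], dd[3], db[3], dc[3];
    double ca = -dot3(b1, b2) / (lb2 * lb2), cb = -dot3(b3, b2) / (lb2 * lb2);
    for (int q = 0; q < 3; ++q) {
      da[q] = -(lb2 / lm2) * m[q];
      dd[q] = (lb2 / ln2) * nn[q];
      db[q] = (ca - 1.0) * da[q] - cb * dd[q];
      dc[q] = (cb - 1.0) * dd[q] - ca * da[q];
      F[a + q * fr.n] -= dEdphi * da[q];
      F[b + q * fr.n] -= dEdphi * db[q];
      F[c + q * fr.n] -= dEdphi * dc[q];
      F[d + q * fr.n] -= dEdphi * dd[q];
    }
  }
  return E;
}

// ---- V_excl: short-range repulsion, E = k (r - cut)^2 for r < cut ----------
static double e_excl(const Frame& fr, const List& p, double* F) {
  IntegerVector beads = p["beads"], res = p["res"];
  NumericVector sig = p["sig"];
  double k = as<double>(p["k"]);
  int min_sep = as<int>(p["min_sep"]);
  double E = 0, d[3];
  int nb = beads.size();
  for (int a = 0; a < nb; ++a) {
    for (int b = a + 1; b < nb; ++b) {
      if (std::abs(res[a] - res[b]) < min_sep) continue;
      int i = beads[a] - 1, j = beads[b] - 1;
      fr.disp(i, j, d, true);
      double cut = 0.5 * (sig[a] + sig[b]);
      double r = norm3(d);
      if (r >= cut) continue;
      double dr = r - cut;
      E += k * dr * dr;
      pair_force(F, fr.n, i, j, d, r, 2.0 * k * dr);
    }
  }
  return E;
}

// two-sided switching well 0.25 (1 + tanh(eta (r-a))) (1 + tanh(eta (b-r)))
inline double well(double r, double a, double b, double eta, double* dwdr) {
  double t1 = std::tanh(eta * (r - a));
  double t2 = std::tanh(eta * (b - r));
  double w = 0.25 * (1.0 + t1) * (1.0 + t2);
  *dwdr = 0.25 * eta * ((1.0 - t1 * t1) * (1.0 + t2) -
                        (1.0 + t1) * (1.0 - t2 * t2));
  return w;
}

// ---- V_contact: direct + water-mediated residue-pair wells -----------------
static double e_contact(const Frame& fr, const List& p, double* F) {
  IntegerVector site = p["site"], rtype = p["rtype"];
  NumericMatrix gamma = p["gamma"];
  double eta = as<double>(p["eta"]);
  double rd1 = as<double>(p["rd1"]), rd2 = as<double>(p["rd2"]);
  double rw1 = as<double>(p["rw1"]), rw2 = as<double>(p["rw2"]);
  double wfrac = as<double>(p["wfrac"]);
  int min_sep = as<int>(p["min_sep"]);
  double skip = rw2 + 14.0 / eta;
  double E = 0, d[3];
  int nres = site.size();
  for (int i = 0; i < nres; ++i) {
    for (int j = i + min_sep; j < nres; ++j) {
      int bi = site[i] - 1, bj = site[j] - 1;
      fr.disp(bi, bj, d, true);
      double r = norm3(d);
      if (r > skip) continue;
      double g = gamma(rtype[i], rtype[j]);
      double dw1, dw2;
      double w1 = well(r, rd1, rd2, eta, &dw1);
      double w2 = well(r, rw1, rw2, eta, &dw2);
      E += -g * (w1 + wfrac * w2);
      pair_force(F, fr.n, bi, bj, d, r, -g * (dw1 + wfrac * dw2));
    }
  }
  return E;
}

// ---- V_burial: residue-type propensity by smooth local density -------------
static double e_burial(const Frame& fr, const List& p, double* F) {
  IntegerVector site = p["site"], rtype = p["rtype"];
  NumericMatrix beta = p["beta"];  // 20 x nwell
  NumericVector lo = p["lo"], hi = p["hi"];
  double eta_d = as<double>(p["eta_d"]), r_d = as<double>(p["r_d"]);
  double eta_b = as<double>(p["eta_b"]);
  int min_sep = as<int>(p["min_sep"]);
  int nres = site.size(), nw = lo.size();
  double skip = r_d + 14.0 / eta_d;
  dvec rho(nres, 0.0), dVdrho(nres, 0.0);
  double d[3];
  for (int i = 0; i < nres; ++i) {
    for (int j = i + min_sep; j < nres; ++j) {
      fr.disp(site[i] - 1, site[j] - 1, d, true);
      double r = norm3(d);
      if (r > skip) continue;
      double th = 0.5 * (1.0 + std::tanh(eta_d * (r_d - r)));
      rho[i] += th;
      rho[j] += th;
    }
  }
  double E = 0;
  for (int i = 0; i < nres; ++i) {
    for (int w = 0; w < nw; ++w) {
      double dw;
      double th = well(rho[i], lo[w], hi[w], eta_b, &dw);
      E += -beta(rtype[i], w) * th;
      dVdrho[i] += -beta(rtype[i], w) * dw;
    }
  }
  for (int i = 0; i < nres; ++i) {
    for (int j = i + min_sep; j < nres; ++j) {
      int bi = site[i] - 1, bj = site[j] - 1;
      fr.disp(bi, bj, d, true);
      double r = norm3(d);
      if (r > skip) continue;
      double t = std::tanh(eta_d * (r_d - r));
      double dthdr = -0.5 * eta_d * (1.0 - t * t);
      pair_force(F, fr.n, bi, bj, d, r, (dVdrho[i] + dVdrho[j]) * dthdr);
    }
  }
  return E;
}

// ---- V_helical: Gaussian well on the i, i+4 Calpha distance ----------------
static double e_helical(const Frame& fr, const List& p, double* F) {
  IntegerVector ii = p["i"], jj = p["j"];
  double g0 = as<double>(p["gamma"]), r0 = as<double>(p["r0"]),
         sg = as<double>(p["sigma"]);
  double E = 0, d[3];
  for (int t = 0; t < ii.size(); ++t) {
    int i = ii[t] - 1, j = jj[t] - 1;
    fr.disp(i, j, d, false);
    double r = norm3(d), dr = r - r0;
    double g = std::exp(-dr * dr / (2.0 * sg * sg));
    E += -g0 * g;
    pair_force(F, fr.n, i, j, d, r, g0 * g * dr / (sg * sg));
  }
  return E;
}

// ---- V_beta: cooperative Gaussian pairing of strand-like contacts ----------
static double e_beta(const Frame& fr, const List& p, double* F) {
  IntegerVector ca = p["ca"];  // Calpha bead per residue
  double g0 = as<double>(p["gamma"]), r0 = as<double>(p["r0"]),
         sg = as<double>(p["sigma"]);
  int min_sep = as<int>(p["min_sep"]);
  int nres = ca.size();
  double E = 0, d1[3], d2[3];
  double span = 8.0 * sg;
  for (int i = 0; i < nres - 1; ++i) {
    for (int j = i + min_sep; j < nres; ++j) {
      int a = ca[i] - 1, b = ca[j] - 1;
      fr.disp(a, b, d1, false);
      double r1 = norm3(d1), dr1 = r1 - r0;
      if (std::fabs(dr1) > span) continue;
      double g1 = std::exp(-dr1 * dr1 / (2.0 * sg * sg));
      // antiparallel partner (i+1, j-1); parallel partner (i+1, j+1)
      int part[2] = {j - 1, j + 1};
      for (int s = 0; s < 2; ++s) {
        int jp = part[s];
        if (jp <= i + 1 || jp >= nres) continue;
        if (std::abs(jp - (i + 1)) < min_sep) continue;
        int c = ca[i + 1] - 1, e = ca[jp] - 1;
        fr.disp(c, e, d2, false);
        double r2 = norm3(d2), dr2 = r2 - r0;
        if (std::fabs(dr2) > span) continue;
        double g2 = std::exp(-dr2 * dr2 / (2.0 * sg * sg));
        E += -g0 * g1 * g2;
        pair_force(F, fr.n, a, b, d1, r1, g0 * g2 * g1 * dr1 / (sg * sg));
        pair_force(F, fr.n, c, e, d2, r2, g0 * g1 * g2 * dr2 / (sg * sg));
      }
    }
  }
  return E;
}

// ---- V_P-AP: pre-stabilization well on distant Calpha pairs ----------------
static double e_pap(const Frame& fr, const List& p, double* F) {
  IntegerVector ca = p["ca"];
  double g0 = as<double>(p["gamma"]), r1 = as<double>(p["r1"]),
         r2 = as<double>(p["r2"]), eta = as<double>(p["eta"]);
  int min_sep = as<int>(p["min_sep"]);
  int nres = ca.size();
  double skip = r2 + 14.0 / eta;
  double E = 0, d[3];
  for (int i = 0; i < nres; ++i) {
    for (int j = i + min_sep; j < nres; ++j) {
      int a = ca[i] - 1, b = ca[j] - 1;
      fr.disp(a, b, d, true);
      double r = norm3(d);
      if (r > skip) continue;
      double dw;
      double w = well(r, r1, r2, eta, &dw);
      E += -g0 * w;
      pair_force(F, fr.n, a, b, d, r, -g0 * dw);
    }
  }
  return E;
}

// ---- V_DH: screened Coulomb over charged bead pairs ------------------------
static double e_dh(const Frame& fr, const List& p, double* F) {
  IntegerVector beads = p["beads"];
  NumericVector q = p["q"];
  double kelec = as<double>(p["kelec"]), epsr = as<double>(p["epsr"]);
  double kappa = as<double>(p["kappa"]), cutoff = as<double>(p["cutoff"]);
  bool shift = as<bool>(p["shift"]);
  int nq = beads.size();
  double E = 0, d[3];
  for (int a = 0; a < nq; ++a) {
    for (int b = a + 1; b < nq; ++b) {
      int i = beads[a] - 1, j = beads[b] - 1;
      fr.disp(i, j, d, true);
      double r = norm3(d);
      if (r > cutoff || r <= 0) continue;
      double pref = kelec * q[a] * q[b] / epsr;
      double v = pref * std::exp(-kappa * r) / r;
      E += v;
      if (shift && std::isfinite(cutoff))
        E -= pref * std::exp(-kappa * cutoff) / cutoff;
      pair_force(F, fr.n, i, j, d, r, -v * (1.0 / r + kappa));
    }
  }
  return E;
}

// ---- V_FM: fragment-memory Gaussians on stored pair distances --------------
static double e_fm(const Frame& fr, const List& p, double* F) {
  IntegerVector ii = p["i"], jj = p["j"];
  NumericVector r0 = p["r0"], sig = p["sigma"], w = p["w"];
  double lambda = as<double>(p["lambda"]);
  if (lambda == 0) return 0.0;
  double E = 0, d[3];
  for (int t = 0; t < ii.size(); ++t) {
    int i = ii[t] - 1, j = jj[t] - 1;
    fr.disp(i, j, d, false);
    double r = norm3(d), dr = r - r0[t];
    double g = std::exp(-dr * dr / (2.0 * sig[t] * sig[t]));
    E += -lambda * w[t] * g;
    pair_force(F, fr.n, i, j, d, r,
               lambda * w[t] * g * dr / (sig[t] * sig[t]));
  }
  return E;
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix coords, List spec) {
  double box = as<double>(spec["box"]);
  bool periodic = as<bool>(spec["periodic"]);
  Frame fr(coords, box, periodic);
  NumericMatrix forces(coords.nrow(), 3);
  double* F = forces.begin();

  const char* names[] = {"v_con", "v_chain", "v_chi", "v_rama", "v_excl",
                         "v_contact", "v_burial", "v_beta", "v_pap",
                         "v_helical", "v_dh", "v_fm"};
  const char* keys[] = {"bonds", "angles", "chis", "ramas", "excl",
                        "contact", "burial", "beta", "pap",
                        "helical", "dh", "fm"};
  NumericVector terms(12);
  terms.names() = CharacterVector(names, names + 12);
  for (int t = 0; t < 12; ++t) {
    if (!spec.containsElementNamed(keys[t])) continue;
    RObject o = spec[keys[t]];
    if (o.isNULL()) continue;
    List p(o);
    double e = 0;
    switch (t) {
      case 0: e = e_bonds(fr, p, F); break;
      case 1: e = e_angles(fr, p, F); break;
      case 2: e = e_chirality(fr, p, F); break;
      case 3: e = e_rama(fr, p, F); break;
      case 4: e = e_excl(fr, p, F); break;
      case 5: e = e_contact(fr, p, F); break;
      case 6: e = e_burial(fr, p, F); break;
      case 7: e = e_beta(fr, p, F); break;
      case 8: e = e_pap(fr, p, F); break;
      case 9: e = e_helical(fr, p, F); break;
      case 10: e = e_dh(fr, p, F); break;
      case 11: e = e_fm(fr, p, F); break;
    }
    terms[t] = e;
  }
  double total = 0;
  for (int t = 0; t < 12; ++t) total += terms[t];
  return List::create(_["terms"] = terms, _["energy"] = total,
                      _["forces"] = forces);
}

// Harmonic bias on the mass-weighted radius of gyration of a bead subset.
// dRg/dr_i = m_i (r_i - com) / (M Rg); com-motion terms cancel exactly.
// [[Rcpp::export]]
List rg_bias_cpp(NumericMatrix coords, IntegerVector idx, NumericVector mass,
                 double k, double rg0) {
  int n = coords.nrow(), ns = idx.size();
  double M = 0, com[3] = {0, 0, 0};
  for (int a = 0; a < ns; ++a) {
    int i = idx[a] - 1;
    M += mass[a];
    com[0] += mass[a] * coords(i, 0);
    com[1] += mass[a] * coords(i, 1);
    com[2] += mass[a] * coords(i, 2);
  }
  for (int q = 0; q < 3; ++q) com[q] /= M;
  double s2 = 0;
  for (int a = 0; a < ns; ++a) {
    int i = idx[a] - 1;
    for (int q = 0; q < 3; ++q) {
      double d = coords(i, q) - com[q];
      s2 += mass[a] * d * d;
    }
  }
  double rg = std::sqrt(s2 / M);
  double E = 0.5 * k * (rg - rg0) * (rg - rg0);
  NumericMatrix forces(n, 3);
  if (rg > 1e-10) {
    double pref = -k * (rg - rg0) / (M * rg);
    for (int a = 0; a < ns; ++a) {
      int i = idx[a] - 1;
      for (int q = 0; q < 3; ++q)
        forces(i, q) = pref * mass[a] * (coords(i, q) - com[q]);
    }
  }
  return List::create(_["energy"] = E, _["rg"] = rg, _["forces"] = forces);
}
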