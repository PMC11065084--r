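// Total-Lagrangian kernels for trilinear hexahedra with a compressible
// neo-Hookean energy evaluated on the elastic part of F = Fe Fg, where
// Fg = diag(s, s, 1), s = sqrt(theta_g), is in-plane areal growth about the
// fixed reference skin normal e3 (flat reference block).
//
// Selective reduced integration: the shear (mu) term is integrated at the
// 2x2x2 Gauss points, the volumetric lambda ln(Je)^2 term at the element
// centroid only, to avoid locking at lambda = 40 mu (nu ~ 0.488).
//
// Units: mm, N, MPa, tonne/mm^3, seconds.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Mat3 {
  double a[9]; // row-major
  double &operator()(int i, int j) { return a[3 * i + j]; }
  double operator()(int i, int j) const { return a[3 * i + j]; }
};

inline double det3(const Mat3 &m) {
  return m(0,0) * (m(1,1) * m(2,2) - m(1,2) * m(2,1))
       - m(0,1) * (m(1,0) * m(2,2) - m(1,2) * m(2,0))
       + m(0,2) * (m(1,0) * m(2,1) - m(1,1) * m(2,0));
}

inline void invT3(const Mat3 &m, double d, Mat3 &out) {
  // out = m^{-T} = cof(m) / d, d = det(m)
  out(0,0) =  (m(1,1)*m(2,2) - m(1,2)*m(2,1)) / d;
  out(0,1) = -(m(1,0)*m(2,2) - m(1,2)*m(2,0)) / d;
  out(0,2) =  (m(1,0)*m(2,1) - m(1,1)*m(2,0)) / d;
  out(1,0) = -(m(0,1)*m(2,2) - m(0,2)*m(2,1)) / d;
  out(1,1) =  (m(0,0)*m(2,2) - m(0,2)*m(2,0)) / d;
  out(1,2) = -(m(0,0)*m(2,1) - m(0,1)*m(2,0)) / d;
  out(2,0) =  (m(0,1)*m(1,2) - m(0,2)*m(1,1)) / d;
  out(2,1) = -(m(0,0)*m(1,2) - m(0,2)*m(1,0)) / d;
  out(2,2) =  (m(0,0)*m(1,1) - m(0,1)*m(1,0)) / d;
}

// Node ordering of the 8-node hex in natural coordinates.
const double sgn[8][3] = {
  {-1,-1,-1}, {1,-1,-1}, {1,1,-1}, {-1,1,-1},
  {-1,-1, 1}, {1,-1, 1}, {1,1, 1}, {-1,1, 1}
};

inline void dshape(double xi, double eta, double ze, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    double sx = sgn[a][0], sy = sgn[a][1], sz = sgn[a][2];
    dN[a][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
    dN[a][1] = 0.125 * sy * (1 + sx * xi) * (1 + sz * ze);
    dN[a][2] = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

// Per-gauss-point reference shape gradients dN_a/dX and weight detJ * w_q.
struct GPData {
  double G[8][3];
  double w;
};

// 9 points per element: 8 full Gauss points (mu term) + centroid (lambda).
struct ElemData {
  GPData gp[9];
  int nodes[8];
};

void precompute(const NumericMatrix &nodes, const IntegerMatrix &hexes,
                std::vector<ElemData> &elems) {
  const double g = 1.0 / std::sqrt(3.0);
  const double pts[9][4] = {
    {-g,-g,-g,1},{g,-g,-g,1},{g,g,-g,1},{-g,g,-g,1},
    {-g,-g,g,1},{g,-g,g,1},{g,g,g,1},{-g,g,g,1},
    {0,0,0,8}
  };
  int ne = hexes.nrow();
  elems.resize(ne);
  double dN[8][3];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) elems[e].nodes[a] = hexes(e, a) - 1;
    for (int q = 0; q < 9; ++q) {
      dshape(pts[q][0], pts[q][1], pts[q][2], dN);
      Mat3 J; // J(k,l) = dX_l/dxi_k
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double s = 0;
          for (int a = 0; a < 8; ++a)
            s += dN[a][k] * nodes(elems[e].nodes[a], l);
          J(k, l) = s;
        }
      double dJ = det3(J);
      if (dJ <= 0) stop("non-positive element Jacobian in reference mesh");
      Mat3 JinvT;
      invT3(J, dJ, JinvT); // (J^{-1})(l,k) = JinvT(k,l)
      for (int a = 0; a < 8; ++a)
        for (int l = 0; l < 3; ++l) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += JinvT(k, l) * dN[a][k];
          elems[e].gp[q].G[a][l] = s;
        }
      elems[e].gp[q].w = dJ * pts[q][3];
    }
  }
}

inline void defgrad(const GPData &gp, const double ue[8][3], Mat3 &F) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = (i == j) ? 1.0 : 0.0;
      for (int a = 0; a < 8; ++a) s += ue[a][i] * gp.G[a][j];
      F(i, j) = s;
    }
}

// First Piola-Kirchhoff stress per unit reference volume for the energy
// Psi_ref = theta_g * Psi_NH(Fe): P = theta_g * Pe * Fg^{-T} with
// Pe = mu (Fe - Fe^{-T}) + lam ln(Je) Fe^{-T}. Returns false if Je <= 0.
inline bool piola(const Mat3 &F, double theta_g, double mu, double lam,
                  bool mu_term, bool lam_term, Mat3 &P, double *psi) {
  double s = std::sqrt(theta_g);
  Mat3 Fe;
  for (int i = 0; i < 3; ++i) {
    Fe(i, 0) = F(i, 0) / s;
    Fe(i, 1) = F(i, 1) / s;
    Fe(i, 2) = F(i, 2);
  }
  double Je = det3(Fe);
  if (Je <= 1e-12) return false;
  Mat3 FeiT;
  invT3(Fe, Je, FeiT);
  double lnJ = std::log(Je);
  Mat3 Pe;
  for (int i = 0; i < 9; ++i) Pe.a[i] = 0.0;
  if (mu_term)
    for (int i = 0; i < 9; ++i) Pe.a[i] += mu * (Fe.a[i] - FeiT.a[i]);
  if (lam_term)
    for (int i = 0; i < 9; ++i) Pe.a[i] += lam * lnJ * FeiT.a[i];
  for (int i = 0; i < 3; ++i) {
    P(i, 0) = theta_g * Pe(i, 0) / s;
    P(i, 1) = theta_g * Pe(i, 1) / s;
    P(i, 2) = theta_g * Pe(i, 2);
  }
  if (psi) {
    double I1e = 0;
    for (int i = 0; i < 9; ++i) I1e += Fe.a[i] * Fe.a[i];
    double e = 0;
    if (mu_term) e += mu / 2 * (I1e - 3) - mu * lnJ;
    if (lam_term) e += lam / 2 * lnJ * lnJ;
    *psi = theta_g * e;
  }
  return true;
}

// Internal force (and optionally energy) of one element. theta_g is carried
// per full Gauss point; the centroid (lambda) point uses their mean.
inline bool elem_fint(const ElemData &ed, const double ue[8][3],
                      const double tg[8], double mu, double lam,
                      double fe[8][3], double *energy) {
  Mat3 F, P;
  double psi = 0;
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i) fe[a][i] = 0.0;
  if (energy) *energy = 0.0;
  double tgc = 0;
  for (int q = 0; q < 8; ++q) tgc += tg[q];
  tgc /= 8.0;
  for (int q = 0; q < 9; ++q) {
    const GPData &gp = ed.gp[q];
    defgrad(gp, ue, F);
    bool mu_term = (q < 8), lam_term = (q == 8);
    double t = (q < 8) ? tg[q] : tgc;
    if (!piola(F, t, mu, lam, mu_term, lam_term, P, energy ? &psi : nullptr))
      return false;
    if (energy) *energy += gp.w * psi;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        fe[a][i] += gp.w * (P(i, 0) * gp.G[a][0] + P(i, 1) * gp.G[a][1] +
                            P(i, 2) * gp.G[a][2]);
  }
  return true;
}

inline void gather_ue(const std::vector<double> &u, const int *nd,
                      double ue[8][3]) {
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i) ue[a][i] = u[3 * nd[a] + i];
}

bool assemble_fint(const std::vector<ElemData> &elems,
                   const NumericMatrix &theta_g, double mu, double lam,
                   const std::vector<double> &u, std::vector<double> &fint,
                   double *energy) {
  double ue[8][3], fe[8][3], tg[8], psi;
  std::fill(fint.begin(), fint.end(), 0.0);
  if (energy) *energy = 0.0;
  for (size_t e = 0; e < elems.size(); ++e) {
    const int *nd = elems[e].nodes;
    gather_ue(u, nd, ue);
    for (int q = 0; q < 8; ++q) tg[q] = theta_g(e, q);
    if (!elem_fint(elems[e], ue, tg, mu, lam, fe, energy ? &psi : nullptr))
      return false;
    if (energy) *energy += psi;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * nd[a] + i] += fe[a][i];
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
List cpp_fint(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u,
              NumericMatrix theta_g, double mu, double lam) {
  std::vector<ElemData> elems;
  precompute(nodes, hexes, elems);
  std::vector<double> uv(u.begin(), u.end()), fint(u.size());
  double energy = 0;
  bool ok = assemble_fint(elems, theta_g, mu, lam, uv, fint, &energy);
  return List::create(_["fint"] = NumericVector(fint.begin(), fint.end()),
                      _["energy"] = energy, _["ok"] = ok);
}

// Analytic consistent tangent stiffness (triplets) plus internal force.
// For P(F) = theta_g Pe(Fe) Fg^{-T}, Fe = F Fg^{-1}, Fg = diag(s, s, 1),
// the material tangent contracts, per Gauss point, to
//   K_(ai)(bk) += w theta_g [ c1 M_ab d_ik + c2 Q_ak Q_bi + c3 Q_ai Q_bk ]
// with Gt_aj = G_aj g_j (g = diag of Fg^{-1}), M = Gt Gt^T,
// Q_ak = sum_j FeiT_kj Gt_aj, and (SRI split)
//   mu term (8 gps):      c1 = mu, c2 = mu,           c3 = 0
//   lambda term (centroid): c1 = 0, c2 = -lam ln(Je), c3 = lam.
// Only the upper triangle (i <= j) is emitted, with rows/columns of fixed
// dofs dropped and a unit diagonal put in their place, so the caller can
// factorise the constrained symmetric system directly.
// [[Rcpp::export]]
List cpp_tangent(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u,
                 NumericMatrix theta_g, double mu, double lam,
                 LogicalVector fixed) {
  std::vector<ElemData> elems;
  precompute(nodes, hexes, elems);
  int ne = hexes.nrow();
  R_xlen_t nt = (R_xlen_t)ne * (24 * 25) / 2 + u.size();
  IntegerVector ti(nt), tj(nt);
  NumericVector tx(nt);
  NumericVector fint(u.size());
  std::vector<double> uv(u.begin(), u.end());
  double ue[8][3], fe[8][3], tg[8];
  double Ke[24][24];
  Mat3 F, P;
  bool ok = true;
  R_xlen_t idx = 0;
  for (int e = 0; e < ne && ok; ++e) {
    const int *nd = elems[e].nodes;
    gather_ue(uv, nd, ue);
    for (int q = 0; q < 8; ++q) tg[q] = theta_g(e, q);
    double tgc = 0;
    for (int q = 0; q < 8; ++q) tgc += tg[q];
    tgc /= 8.0;
    ok = elem_fint(elems[e], ue, tg, mu, lam, fe, nullptr);
    if (!ok) break;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * nd[a] + i] += fe[a][i];
    for (int a = 0; a < 24; ++a)
      for (int b = 0; b < 24; ++b) Ke[a][b] = 0.0;
    for (int q = 0; q < 9 && ok; ++q) {
      const GPData &gp = elems[e].gp[q];
      double t = (q < 8) ? tg[q] : tgc;
      double s = std::sqrt(t);
      double g[3] = {1.0 / s, 1.0 / s, 1.0};
      defgrad(gp, ue, F);
      Mat3 Fe;
      for (int i = 0; i < 3; ++i) {
        Fe(i, 0) = F(i, 0) * g[0];
        Fe(i, 1) = F(i, 1) * g[1];
        Fe(i, 2) = F(i, 2);
      }
      double Je = det3(Fe);
      if (Je <= 1e-12) { ok = false; break; }
      Mat3 FeiT;
      invT3(Fe, Je, FeiT);
      double Gt[8][3], Q[8][3];
      for (int a = 0; a < 8; ++a)
        for (int j = 0; j < 3; ++j) Gt[a][j] = gp.G[a][j] * g[j];
      for (int a = 0; a < 8; ++a)
        for (int k = 0; k < 3; ++k)
          Q[a][k] = FeiT(k, 0) * Gt[a][0] + FeiT(k, 1) * Gt[a][1] +
                    FeiT(k, 2) * Gt[a][2];
      double c1, c2, c3;
      if (q < 8) { c1 = mu; c2 = mu; c3 = 0.0; }
      else { c1 = 0.0; c2 = -lam * std::log(Je); c3 = lam; }
      double wt = gp.w * t;
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b) {
          double Mab = Gt[a][0] * Gt[b][0] + Gt[a][1] * Gt[b][1] +
                       Gt[a][2] * Gt[b][2];
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              double v = c2 * Q[a][k] * Q[b][i];
              if (c3 != 0.0) v += c3 * Q[a][i] * Q[b][k];
              if (i == k) v += c1 * Mab;
              Ke[3 * a + i][3 * b + k] += wt * v;
            }
        }
    }
    if (!ok) break;
    for (int b = 0; b < 8; ++b)
      for (int j = 0; j < 3; ++j) {
        int col = 3 * nd[b] + j;
        if (fixed[col]) continue;
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            int row = 3 * nd[a] + i;
            if (row > col || fixed[row]) continue;
            ti[idx] = row + 1;
            tj[idx] = col + 1;
            tx[idx] = Ke[3 * a + i][3 * b + j];
            ++idx;
          }
      }
  }
  for (int d = 0; d < u.size(); ++d)
    if (fixed[d]) {
      ti[idx] = d + 1;
      tj[idx] = d + 1;
      tx[idx] = 1.0;
      ++idx;
    }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["n"] = (double)idx,
                      _["fint"] = fint, _["ok"] = ok);
}

// Element-wise forward-difference tangent stiffness, assembled as triplets,
// plus the internal force at the base state. Retained as an independent
// cross-check of the analytic tangent.
// [[Rcpp::export]]
List cpp_tangent_fd(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u,
                    NumericMatrix theta_g, double mu, double lam,
                    double h = 1e-7) {
  std::vector<ElemData> elems;
  precompute(nodes, hexes, elems);
  int ne = hexes.nrow();
  R_xlen_t nt = (R_xlen_t)ne * 24 * 24;
  IntegerVector ti(nt), tj(nt);
  NumericVector tx(nt);
  NumericVector fint(u.size());
  std::vector<double> uv(u.begin(), u.end());
  double ue[8][3], f0[8][3], f1[8][3], tg[8];
  bool ok = true;
  R_xlen_t idx = 0;
  for (int e = 0; e < ne && ok; ++e) {
    const int *nd = elems[e].nodes;
    gather_ue(uv, nd, ue);
    for (int q = 0; q < 8; ++q) tg[q] = theta_g(e, q);
    ok = elem_fint(elems[e], ue, tg, mu, lam, f0, nullptr);
    if (!ok) break;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * nd[a] + i] += f0[a][i];
    for (int b = 0; b < 8 && ok; ++b)
      for (int j = 0; j < 3 && ok; ++j) {
        double save = ue[b][j];
        ue[b][j] = save + h;
        ok = elem_fint(elems[e], ue, tg, mu, lam, f1, nullptr);
        ue[b][j] = save;
        if (!ok) break;
        int col = 3 * nd[b] + j + 1;
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            ti[idx] = 3 * nd[a] + i + 1;
            tj[idx] = col;
            tx[idx] = (f1[a][i] - f0[a][i]) / h;
            ++idx;
          }
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["fint"] = fint, _["ok"] = ok);
}

// Per-element field quantities: total and elastic areal stretch about e3 at
// every full Gauss point, Von Mises stress at the element centroid.
// [[Rcpp::export]]
List cpp_fields(NumericMatrix nodes, IntegerMatrix hexes,
                NumericVector u, NumericMatrix theta_g, double mu,
                double lam) {
  std::vector<ElemData> elems;
  precompute(nodes, hexes, elems);
  int ne = hexes.nrow();
  NumericMatrix theta_e(ne, 8), theta_F(ne, 8);
  NumericVector vm(ne);
  std::vector<double> uv(u.begin(), u.end());
  double ue[8][3];
  Mat3 F, FinvT;
  for (int e = 0; e < ne; ++e) {
    gather_ue(uv, elems[e].nodes, ue);
    for (int q = 0; q < 8; ++q) {
      defgrad(elems[e].gp[q], ue, F);
      double dF = det3(F);
      invT3(F, dF, FinvT);
      double c0 = dF * FinvT(0, 2), c1 = dF * FinvT(1, 2),
             c2 = dF * FinvT(2, 2);
      theta_F(e, q) = std::sqrt(c0 * c0 + c1 * c1 + c2 * c2);
      theta_e(e, q) = theta_F(e, q) / theta_g(e, q);
    }
    // centroid Von Mises from the elastic part at mean growth
    defgrad(elems[e].gp[8], ue, F);
    double tgc = 0;
    for (int q = 0; q < 8; ++q) tgc += theta_g(e, q);
    tgc /= 8.0;
    double sc = std::sqrt(tgc);
    Mat3 Fe;
    for (int i = 0; i < 3; ++i) {
      Fe(i, 0) = F(i, 0) / sc;
      Fe(i, 1) = F(i, 1) / sc;
      Fe(i, 2) = F(i, 2);
    }
    double Je = det3(Fe);
    if (Je <= 0) {
      vm[e] = NA_REAL;
      continue;
    }
    double lnJ = std::log(Je);
    double sig[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double b = 0;
        for (int k = 0; k < 3; ++k) b += Fe(i, k) * Fe(j, k);
        sig[3 * i + j] = (mu * (b - (i == j ? 1.0 : 0.0)) +
                          (i == j ? lam * lnJ : 0.0)) / Je;
      }
    double tr = (sig[0] + sig[4] + sig[8]) / 3.0;
    double devsq = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double d = sig[3 * i + j] - (i == j ? tr : 0.0);
        devsq += d * d;
      }
    vm[e] = std::sqrt(1.5 * devsq);
  }
  return List::create(_["theta_e"] = theta_e, _["theta_F"] = theta_F,
                      _["von_mises"] = vm);
}

// Explicit central-difference dynamics about a statically equilibrated
// state. Fixed dofs are held at their static values (zero velocity). The
// impact is a constant nodal force on `load_dofs` while t < t_pulse. The
// static internal force is subtracted so the integrator sees only the
// perturbation about equilibrium. Records the probe node every step.
// Stiffness-proportional damping (coefficient beta, seconds) is applied by
// evaluating the internal force at u + beta v, i.e. f_int + beta K(u) v to
// first order: high-frequency (grid-scale) ringing is damped while the
// signal band is left essentially untouched.
// [[Rcpp::export]]
List cpp_wave(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u0,
              NumericMatrix theta_g, double mu, double lam, double rho_t,
              LogicalVector fixed, IntegerVector load_dofs,
              NumericVector load_vals, double t_pulse, double dt, int nsteps,
              int probe_node, double beta = 0.0) {
  std::vector<ElemData> elems;
  precompute(nodes, hexes, elems);
  int ne = hexes.nrow(), ndof = u0.size();

  std::vector<double> mass(ndof, 0.0);
  for (int e = 0; e < ne; ++e) {
    double vol = 0;
    for (int q = 0; q < 8; ++q) vol += elems[e].gp[q].w;
    double m = rho_t * vol / 8.0;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) mass[3 * elems[e].nodes[a] + i] += m;
  }

  std::vector<double> u(u0.begin(), u0.end()), v(ndof, 0.0),
      fint(ndof, 0.0), fint0(ndof, 0.0), fext(ndof, 0.0);
  for (int k = 0; k < load_dofs.size(); ++k) fext[load_dofs[k] - 1] = load_vals[k];
  NumericMatrix uprobe(nsteps + 1, 3);
  NumericVector tout(nsteps + 1), ke_trace(nsteps + 1), se_trace(nsteps + 1);
  double work = 0.0, ke_max = 0.0, energy0 = 0.0, energy = 0.0;
  bool ok = assemble_fint(elems, theta_g, mu, lam, u, fint0, &energy0);
  std::string reason = ok ? "" : "inverted";

  int pbase = 3 * (probe_node - 1);
  for (int i = 0; i < 3; ++i) uprobe(0, i) = u[pbase + i];
  tout[0] = 0.0;

  std::vector<double> u_eval(ndof);
  for (int step = 1; step <= nsteps && ok; ++step) {
    if (beta > 0.0) {
      for (int d = 0; d < ndof; ++d) u_eval[d] = u[d] + beta * v[d];
      ok = assemble_fint(elems, theta_g, mu, lam, u_eval, fint, &energy);
    } else {
      ok = assemble_fint(elems, theta_g, mu, lam, u, fint, &energy);
    }
    if (!ok) { reason = "inverted"; break; }
    bool pulse_on = ((step - 1) * dt) < t_pulse;
    double ke = 0.0; // kinetic energy at t_{n}, centred half-step velocity
    for (int d = 0; d < ndof; ++d) {
      if (fixed[d]) { v[d] = 0.0; continue; }
      double f = -(fint[d] - fint0[d]) + (pulse_on ? fext[d] : 0.0);
      double a = f / mass[d];
      double vc = v[d] + 0.5 * dt * a;
      ke += 0.5 * mass[d] * vc * vc;
      v[d] += dt * a;
      if (pulse_on && fext[d] != 0.0) work += fext[d] * dt * v[d];
      u[d] += dt * v[d];
    }
    if (ke > ke_max) ke_max = ke;
    ke_trace[step] = ke;
    se_trace[step] = energy - energy0;
    for (int i = 0; i < 3; ++i) uprobe(step, i) = u[pbase + i];
    tout[step] = step * dt;
    if (work > 0 && ke > 10.0 * work) {
      ok = false;
      reason = "instability";
      break;
    }
  }
  return List::create(_["ok"] = ok, _["reason"] = reason, _["t"] = tout,
                      _["u_probe"] = uprobe, _["work"] = work,
                      _["ke_max"] = ke_max, _["ke"] = ke_trace,
                      _["se"] = se_trace);
}
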