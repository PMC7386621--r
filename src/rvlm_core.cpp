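#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector layout (0-based). Order matches rvlm_parameter_table().
//  0 C | 1 E_Na | 2 E_K | 3 E_H | 4 E_L | 5 A | 6 g_NaT |
//  7-11  m  (V_t, dV, dV_tau, t0, eps)
// 12-16  h | 17 g_K | 18-22 n | 23 p_T | 24-28 q | 29-33 r |
// 34 g_H | 35-39 z | 40 g_L
// State vector: [V, m, h, n, q, r, z]

static const int IP_C = 0, IP_ENA = 1, IP_EK = 2, IP_EH = 3, IP_EL = 4,
                 IP_A = 5, IP_GNAT = 6, IP_GK = 17, IP_PT = 23, IP_GH = 34,
                 IP_GL = 40;
static const int GATE_STATE[6] = {1, 2, 3, 4, 5, 6};   // m h n q r z
static const int GATE_POFF[6]  = {7, 12, 18, 24, 29, 35};

// y/(1 - exp(-y)), stable near 0
static inline double gfun(double y) {
  if (std::fabs(y) < 1e-4) return 1.0 + y / 2.0 + y * y / 12.0;
  return y / (1.0 - std::exp(-y));
}
static inline double gfun_d(double y) {
  if (std::fabs(y) < 1e-4) return 0.5 + y / 6.0 - y * y * y / 180.0;
  double e = std::exp(-y), d = 1.0 - e;
  return (d - y * e) / (d * d);
}

// GHK voltage factor Phi(V) = z F g(y) (Ca_i - Ca_o e^{-y}),  y = zFV/(RT)
// V in mV, concentrations mol cm^-3; current density (A cm^-2) is
// P[cm/s] * act^2 * inact * Phi.  consts = (F, Rgas, T, zCa, Ca_i, Ca_o)
static inline double ghk_phi(double V_mV, const double* k, double* dPhi) {
  double F = k[0], R = k[1], T = k[2], z = k[3], Ci = k[4], Co = k[5];
  double a = z * F / (R * T) * 1e-3;  // per mV
  double y = a * V_mV;
  double e = std::exp(-y);
  double conc = Ci - Co * e;
  double phi = z * F * gfun(y) * conc;
  if (dPhi) *dPhi = z * F * a * (gfun_d(y) * conc + gfun(y) * Co * e);
  return phi;
}

// [[Rcpp::export]]
double ghk_phi_cpp(double V_mV, NumericVector consts) {
  return ghk_phi(V_mV, REAL(consts), nullptr);
}

struct PointDeriv {
  double F[7];
  double dFVdx[7];     // dF_V/d(V,m,h,n,q,r,z)
  double dFVdu;
  double dFVdp[11];    // wrt C,E_Na,E_K,E_H,E_L,A,g_NaT,g_K,p_T,g_H,g_L
  double dGdV[6];      // gate eq: dF_g/dV
  double dGdx[6];      //          dF_g/dx_g
  double dGdp[6][5];   //          dF_g/d(V_t,dV,dV_tau,t0,eps)
};
static const int FV_PIDX[11] = {IP_C, IP_ENA, IP_EK, IP_EH, IP_EL, IP_A,
                                IP_GNAT, IP_GK, IP_PT, IP_GH, IP_GL};

// Evaluate RHS and (optionally) all first derivatives at one mesh point.
static void eval_point(const double* x, const double* p, double Iinj,
                       double u, double Vexp, bool nudge, const double* k,
                       PointDeriv& out, bool want_jac) {
  double V = x[0];
  double Cm = p[IP_C];

  // gate kinetics
  double xinf[6], tau[6];
  for (int gi = 0; gi < 6; ++gi) {
    const double* gp = p + GATE_POFF[gi];
    double Vt = gp[0], dV = gp[1], dVt = gp[2], t0 = gp[3], eps = gp[4];
    double s = (V - Vt) / dV, w = (V - Vt) / dVt;
    double ths = std::tanh(s), thw = std::tanh(w);
    double sech2s = 1.0 - ths * ths, sech2w = 1.0 - thw * thw;
    xinf[gi] = 0.5 * (1.0 + ths);
    tau[gi] = t0 + eps * sech2w;
    double xg = x[GATE_STATE[gi]];
    double Fg = (xinf[gi] - xg) / tau[gi];
    out.F[GATE_STATE[gi]] = Fg;
    if (want_jac) {
      double dxinf_dV = 0.5 * sech2s / dV;
      double dtau_dV = -2.0 * eps * thw * sech2w / dVt;
      double it = 1.0 / tau[gi], it2 = it * it;
      out.dGdx[gi] = -it;
      out.dGdV[gi] = dxinf_dV * it - (xinf[gi] - xg) * dtau_dV * it2;
      // params: V_t, dV, dV_tau, t0, eps
      double dxinf_dVt = -dxinf_dV;
      double dxinf_ddV = -0.5 * sech2s * s / dV;
      double dtau_dVt = 2.0 * eps * thw * sech2w / dVt;
      double dtau_ddVt = 2.0 * eps * thw * sech2w * w / dVt;
      double num = xinf[gi] - xg;
      out.dGdp[gi][0] = dxinf_dVt * it - num * dtau_dVt * it2;
      out.dGdp[gi][1] = dxinf_ddV * it;
      out.dGdp[gi][2] = -num * dtau_ddVt * it2;
      out.dGdp[gi][3] = -num * it2;
      out.dGdp[gi][4] = -num * sech2w * it2;
    }
  }

  double m = x[1], h = x[2], n = x[3], q = x[4], r = x[5], zg = x[6];
  double m3 = m * m * m, n3 = n * n * n, n4 = n3 * n;
  double dvna = p[IP_ENA] - V, dvk = p[IP_EK] - V, dvh = p[IP_EH] - V,
         dvl = p[IP_EL] - V;
  double dPhi;
  double phi = ghk_phi(V, k, want_jac ? &dPhi : nullptr);
  // p_T in 1e-4 cm/s; A cm^-2 -> uA cm^-2 gives factor 1e-4*1e6 = 100
  double Jghk = p[IP_PT] * 100.0 * q * q * r * phi;
  double Jna = p[IP_GNAT] * m3 * h * dvna;
  double Jk = p[IP_GK] * n4 * dvk;
  double Jh = p[IP_GH] * zg * dvh;
  double Jl = p[IP_GL] * dvl;
  // I_inj pA over A (1e4 um^2 = 1e-4 cm^2): pA->uA 1e-6, /1e-4 cm^2 => 1e-2
  double Jinj = Iinj * 1e-2 / p[IP_A];
  double Fsum = Jna + Jk + Jh + Jl - Jghk + Jinj;
  out.F[0] = Fsum / Cm + (nudge ? u * (Vexp - V) : 0.0);

  if (want_jac) {
    double iC = 1.0 / Cm;
    out.dFVdx[0] = (-p[IP_GNAT] * m3 * h - p[IP_GK] * n4 - p[IP_GH] * zg -
                    p[IP_GL] - p[IP_PT] * 100.0 * q * q * r * dPhi) * iC -
                   (nudge ? u : 0.0);
    out.dFVdx[1] = 3.0 * p[IP_GNAT] * m * m * h * dvna * iC;
    out.dFVdx[2] = p[IP_GNAT] * m3 * dvna * iC;
    out.dFVdx[3] = 4.0 * p[IP_GK] * n3 * dvk * iC;
    out.dFVdx[4] = -p[IP_PT] * 100.0 * 2.0 * q * r * phi * iC;
    out.dFVdx[5] = -p[IP_PT] * 100.0 * q * q * phi * iC;
    out.dFVdx[6] = p[IP_GH] * dvh * iC;
    out.dFVdu = nudge ? (Vexp - V) : 0.0;
    out.dFVdp[0] = -Fsum * iC * iC;              // C
    out.dFVdp[1] = p[IP_GNAT] * m3 * h * iC;     // E_Na
    out.dFVdp[2] = p[IP_GK] * n4 * iC;           // E_K
    out.dFVdp[3] = p[IP_GH] * zg * iC;           // E_H
    out.dFVdp[4] = p[IP_GL] * iC;                // E_L
    out.dFVdp[5] = -Iinj * 1e-2 / (p[IP_A] * p[IP_A]) * iC;  // A
    out.dFVdp[6] = m3 * h * dvna * iC;           // g_NaT
    out.dFVdp[7] = n4 * dvk * iC;                // g_K
    out.dFVdp[8] = -100.0 * q * q * r * phi * iC;  // p_T
    out.dFVdp[9] = zg * dvh * iC;                // g_H
    out.dFVdp[10] = dvl * iC;                    // g_L
  }
}

// [[Rcpp::export]]
NumericVector rvlm_rhs_cpp(NumericVector x, NumericVector p, double Iinj,
                           double u, double Vexp, bool nudge,
                           NumericVector consts) {
  PointDeriv pd;
  eval_point(REAL(x), REAL(p), Iinj, u, Vexp, nudge, REAL(consts), pd, false);
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = pd.F[i];
  return out;
}

// [[Rcpp::export]]
List rvlm_jac_cpp(NumericVector x, NumericVector p, double Iinj, double u,
                  double Vexp, bool nudge, NumericVector consts) {
  PointDeriv pd;
  eval_point(REAL(x), REAL(p), Iinj, u, Vexp, nudge, REAL(consts), pd, true);
  NumericVector F(7);
  NumericMatrix Jx(7, 7), Jp(7, 41);
  for (int i = 0; i < 7; ++i) F[i] = pd.F[i];
  for (int j = 0; j < 7; ++j) Jx(0, j) = pd.dFVdx[j];
  for (int j = 0; j < 11; ++j) Jp(0, FV_PIDX[j]) = pd.dFVdp[j];
  for (int gi = 0; gi < 6; ++gi) {
    int l = GATE_STATE[gi];
    Jx(l, 0) = pd.dGdV[gi];
    Jx(l, l) = pd.dGdx[gi];
    for (int j = 0; j < 5; ++j) Jp(l, GATE_POFF[gi] + j) = pd.dGdp[gi][j];
  }
  return List::create(_["F"] = F, _["Jx"] = Jx, _["Ju"] = pd.dFVdu,
                      _["Jp"] = Jp);
}

// Collocation residuals and sparse constraint Jacobian (triplets, 0-based).
// Decision vector z: per retained point j: x_j (7) then u_j; params last.
// Constraint rows per group (23): 7 Boole, 7 Hermite@i+1, 7 Hermite@i+3,
// 2 control-smoothness rows.  Residuals are step-scaled: Boole /(4 dt),
// Hermite /(2 dt), so feasibility tolerances are in rate units (per ms).
// [[Rcpp::export]]
List colloc_eval_cpp(NumericVector z, int npts, IntegerVector grp_start,
                     NumericVector grp_dt, NumericVector Vexp,
                     NumericVector Iinj, NumericVector IinjEnd,
                     NumericVector consts, bool nudge, bool want_jac) {
  const double* zp = REAL(z);
  const double* k = REAL(consts);
  int G = grp_start.size();
  const double* par = zp + 8 * npts;
  static const double wB[5] = {7.0, 32.0, 12.0, 32.0, 7.0};

  NumericVector rcon(23 * G);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (want_jac) { ti.reserve(700 * G); tj.reserve(700 * G); tv.reserve(700 * G); }
  std::vector<PointDeriv> pd(5);

  for (int g = 0; g < G; ++g) {
    int gs = grp_start[g];
    double dt = grp_dt[g];
    int rbase = 23 * g;
    int pcb = 8 * npts;
    for (int kk = 0; kk < 5; ++kk) {
      int j = gs + kk;
      // the closing node of a group uses the left-limit current so a
      // protocol step at a shared group boundary stays consistent
      double Ival = (kk == 4) ? IinjEnd[j] : Iinj[j];
      eval_point(zp + 8 * j, par, Ival, zp[8 * j + 7], Vexp[j], nudge, k,
                 pd[kk], want_jac);
    }
    double s4 = 1.0 / (4.0 * dt), s2 = 1.0 / (2.0 * dt);

    // Boole rows
    for (int l = 0; l < 7; ++l) {
      double acc = (zp[8 * (gs + 4) + l] - zp[8 * gs + l]) * s4;
      for (int kk = 0; kk < 5; ++kk) acc -= wB[kk] / 90.0 * pd[kk].F[l];
      rcon[rbase + l] = acc;
      if (!want_jac) continue;
      int row = rbase + l;
      ti.push_back(row); tj.push_back(8 * (gs + 4) + l); tv.push_back(s4);
      ti.push_back(row); tj.push_back(8 * gs + l); tv.push_back(-s4);
      for (int kk = 0; kk < 5; ++kk) {
        double cf = -wB[kk] / 90.0;
        int cb = 8 * (gs + kk);
        if (l == 0) {
          for (int c = 0; c < 7; ++c) {
            ti.push_back(row); tj.push_back(cb + c);
            tv.push_back(cf * pd[kk].dFVdx[c]);
          }
          ti.push_back(row); tj.push_back(cb + 7);
          tv.push_back(cf * pd[kk].dFVdu);
          for (int c = 0; c < 11; ++c) {
            ti.push_back(row); tj.push_back(pcb + FV_PIDX[c]);
            tv.push_back(cf * pd[kk].dFVdp[c]);
          }
        } else {
          int gi = l - 1;
          ti.push_back(row); tj.push_back(cb + 0);
          tv.push_back(cf * pd[kk].dGdV[gi]);
          ti.push_back(row); tj.push_back(cb + l);
          tv.push_back(cf * pd[kk].dGdx[gi]);
          for (int c = 0; c < 5; ++c) {
            ti.push_back(row); tj.push_back(pcb + GATE_POFF[gi] + c);
            tv.push_back(cf * pd[kk].dGdp[gi][c]);
          }
        }
      }
    }

    // Hermite rows at interior points gs+1 and gs+3
    for (int which = 0; which < 2; ++which) {
      int c0 = (which == 0) ? 1 : 3;  // centre offset within group
      for (int l = 0; l < 7; ++l) {
        int row = rbase + 7 + 7 * which + l;
        double res = (zp[8 * (gs + c0) + l] -
                      0.5 * (zp[8 * (gs + c0 - 1) + l] +
                             zp[8 * (gs + c0 + 1) + l])) * s2 -
                     0.125 * (pd[c0 - 1].F[l] - pd[c0 + 1].F[l]);
        rcon[row] = res;
        if (!want_jac) continue;
        ti.push_back(row); tj.push_back(8 * (gs + c0) + l); tv.push_back(s2);
        ti.push_back(row); tj.push_back(8 * (gs + c0 - 1) + l);
        tv.push_back(-0.5 * s2);
        ti.push_back(row); tj.push_back(8 * (gs + c0 + 1) + l);
        tv.push_back(-0.5 * s2);
        for (int side = 0; side < 2; ++side) {
          int kk = (side == 0) ? c0 - 1 : c0 + 1;
          double cf = (side == 0) ? -0.125 : 0.125;
          int cb = 8 * (gs + kk);
          if (l == 0) {
            for (int c = 0; c < 7; ++c) {
              ti.push_back(row); tj.push_back(cb + c);
              tv.push_back(cf * pd[kk].dFVdx[c]);
            }
            ti.push_back(row); tj.push_back(cb + 7);
            tv.push_back(cf * pd[kk].dFVdu);
            for (int c = 0; c < 11; ++c) {
              ti.push_back(row); tj.push_back(pcb + FV_PIDX[c]);
              tv.push_back(cf * pd[kk].dFVdp[c]);
            }
          } else {
            int gi = l - 1;
            ti.push_back(row); tj.push_back(cb + 0);
            tv.push_back(cf * pd[kk].dGdV[gi]);
            ti.push_back(row); tj.push_back(cb + l);
            tv.push_back(cf * pd[kk].dGdx[gi]);
            for (int c = 0; c < 5; ++c) {
              ti.push_back(row); tj.push_back(pcb + GATE_POFF[gi] + c);
              tv.push_back(cf * pd[kk].dGdp[gi][c]);
            }
          }
        }
      }
    }

    // control smoothness: Hermite conditions on u with finite-difference
    // slopes as its dynamics (linear in u)
    {
      double cu1[5] = {-0.25, 0.625, -0.5, 0.125, 0.0};
      double cu2[5] = {0.0, 0.125, -0.5, 0.625, -0.25};
      for (int which = 0; which < 2; ++which) {
        const double* cu = (which == 0) ? cu1 : cu2;
        int row = rbase + 21 + which;
        double res = 0.0;
        for (int kk = 0; kk < 5; ++kk) res += cu[kk] * zp[8 * (gs + kk) + 7];
        rcon[row] = res * s2;
        if (want_jac) {
          for (int kk = 0; kk < 5; ++kk) {
            if (cu[kk] != 0.0) {
              ti.push_back(row); tj.push_back(8 * (gs + kk) + 7);
              tv.push_back(cu[kk] * s2);
            }
          }
        }
      }
    }
  }

  // cost residuals: (Vexp - V) then u  (cost = 0.5*sum(r^2))
  NumericVector rcost(2 * npts);
  for (int j = 0; j < npts; ++j) {
    rcost[j] = Vexp[j] - zp[8 * j];
    rcost[npts + j] = zp[8 * j + 7];
  }
  if (!want_jac)
    return List::create(_["rcost"] = rcost, _["rcon"] = rcon);
  return List::create(_["rcost"] = rcost, _["rcon"] = rcon,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["v"] = NumericVector(tv.begin(), tv.end()));
}

// Synchronized (nudged) forward integration with first-order parameter
// sensitivities.  The state advances by RK4 substeps on the data grid
// with the control term gs*(Vexp(t) - V) (Vexp linearly interpolated
// within each sample); the sensitivity system dS/dt = Jx S + Jp, linear
// in S, advances by the A-stable trapezoidal rule over each full sample
// step.  Used by the synchronization-based initialization stage.
// [[Rcpp::export]]
List sync_forward_cpp(NumericVector x0, NumericVector p,
                      IntegerVector fidx, NumericVector Vexp,
                      NumericVector Iinj, double dt, double gs,
                      int substeps, NumericVector consts,
                      bool want_sens) {
  int npts = Vexp.size();
  int K = fidx.size();
  const double* par = REAL(p);
  const double* k = REAL(consts);
  NumericMatrix X(npts, 7);
  NumericMatrix SV(npts, want_sens ? K : 0);
  std::vector<double> S(7 * K, 0.0);
  double x[7], xt[7], k1[7], k2[7], k3[7], k4[7];
  for (int i = 0; i < 7; ++i) { x[i] = x0[i]; X(0, i) = x[i]; }
  PointDeriv pd0, pd1;
  double h = dt / substeps;

  for (int j = 0; j + 1 < npts; ++j) {
    // Jacobian at the left endpoint (for sensitivity trapezoid)
    if (want_sens)
      eval_point(x, par, Iinj[j], gs, Vexp[j], true, k, pd0, true);
    for (int s = 0; s < substeps; ++s) {
      double f0 = (double)s / substeps, f1 = (double)(s + 1) / substeps;
      double fm = (f0 + f1) / 2;
      double ve0 = Vexp[j] * (1 - f0) + Vexp[j + 1] * f0;
      double vem = Vexp[j] * (1 - fm) + Vexp[j + 1] * fm;
      double ve1 = Vexp[j] * (1 - f1) + Vexp[j + 1] * f1;
      PointDeriv q;
      eval_point(x, par, Iinj[j], gs, ve0, true, k, q, false);
      for (int i = 0; i < 7; ++i) { k1[i] = q.F[i]; xt[i] = x[i] + 0.5 * h * k1[i]; }
      eval_point(xt, par, Iinj[j], gs, vem, true, k, q, false);
      for (int i = 0; i < 7; ++i) { k2[i] = q.F[i]; xt[i] = x[i] + 0.5 * h * k2[i]; }
      eval_point(xt, par, Iinj[j], gs, vem, true, k, q, false);
      for (int i = 0; i < 7; ++i) { k3[i] = q.F[i]; xt[i] = x[i] + h * k3[i]; }
      eval_point(xt, par, Iinj[j], gs, ve1, true, k, q, false);
      for (int i = 0; i < 7; ++i) {
        k4[i] = q.F[i];
        x[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      }
      for (int i = 1; i < 7; ++i) {  // gates stay in [0,1]
        if (x[i] < 0) x[i] = 0;
        if (x[i] > 1) x[i] = 1;
      }
    }
    for (int i = 0; i < 7; ++i) X(j + 1, i) = x[i];

    if (want_sens) {
      eval_point(x, par, Iinj[j + 1], gs, Vexp[j + 1], true, k, pd1, true);
      // assemble dense 7x7 Jacobians
      double J0[49], J1[49];
      auto fill = [](const PointDeriv& pd, double* J) {
        for (int c = 0; c < 49; ++c) J[c] = 0.0;
        for (int c = 0; c < 7; ++c) J[0 + 7 * c] = pd.dFVdx[c];
        for (int gi = 0; gi < 6; ++gi) {
          int l = GATE_STATE[gi];
          J[l + 7 * 0] = pd.dGdV[gi];
          J[l + 7 * l] = pd.dGdx[gi];
        }
      };
      fill(pd0, J0); fill(pd1, J1);
      // Jp columns for free parameters at both endpoints
      auto jpcol = [&](const PointDeriv& pd, int pi, double* col) {
        for (int i = 0; i < 7; ++i) col[i] = 0.0;
        for (int c = 0; c < 11; ++c)
          if (FV_PIDX[c] == pi) col[0] = pd.dFVdp[c];
        for (int gi = 0; gi < 6; ++gi)
          for (int c = 0; c < 5; ++c)
            if (GATE_POFF[gi] + c == pi) col[GATE_STATE[gi]] = pd.dGdp[gi][c];
      };
      // M = I - dt/2 J1 ; RHS = (I + dt/2 J0) S + dt/2 (Jp0 + Jp1)
      double M[49];
      for (int i = 0; i < 49; ++i) M[i] = -0.5 * dt * J1[i];
      for (int i = 0; i < 7; ++i) M[i + 7 * i] += 1.0;
      // LU factor M (partial pivot)
      int piv[7];
      for (int i = 0; i < 7; ++i) piv[i] = i;
      for (int c = 0; c < 7; ++c) {
        int best = c;
        for (int r2 = c + 1; r2 < 7; ++r2)
          if (std::fabs(M[r2 + 7 * c]) > std::fabs(M[best + 7 * c])) best = r2;
        if (best != c)
          for (int cc = 0; cc < 7; ++cc)
            std::swap(M[c + 7 * cc], M[best + 7 * cc]);
        int tmp = piv[c]; piv[c] = piv[best]; piv[best] = tmp;
        for (int r2 = c + 1; r2 < 7; ++r2) {
          M[r2 + 7 * c] /= M[c + 7 * c];
          for (int cc = c + 1; cc < 7; ++cc)
            M[r2 + 7 * cc] -= M[r2 + 7 * c] * M[c + 7 * cc];
        }
      }
      double cp0[7], cp1[7], rhs[7], y[7];
      for (int kk = 0; kk < K; ++kk) {
        int pi = fidx[kk];
        jpcol(pd0, pi, cp0); jpcol(pd1, pi, cp1);
        double* Sc = S.data() + 7 * kk;
        for (int i = 0; i < 7; ++i) {
          double acc = Sc[i] + 0.5 * dt * cp0[i] + 0.5 * dt * cp1[i];
          for (int c = 0; c < 7; ++c) acc += 0.5 * dt * J0[i + 7 * c] * Sc[c];
          rhs[i] = acc;
        }
        // permute and solve LU y = rhs
        double pr[7];
        for (int i = 0; i < 7; ++i) pr[i] = rhs[piv[i]];
        for (int i = 0; i < 7; ++i) {
          double acc = pr[i];
          for (int c = 0; c < i; ++c) acc -= M[i + 7 * c] * y[c];
          y[i] = acc;
        }
        for (int i = 6; i >= 0; --i) {
          double acc = y[i];
          for (int c = i + 1; c < 7; ++c) acc -= M[i + 7 * c] * y[c];
          y[i] = acc / M[i + 7 * i];
        }
        for (int i = 0; i < 7; ++i) Sc[i] = y[i];
        SV(j + 1, kk) = y[0];
      }
      pd0 = pd1;
    }
  }
  if (want_sens)
    return List::create(_["states"] = X, _["SV"] = SV);
  return List::create(_["states"] = X);
}

// ---- exact second derivatives of the RHS ------------------------------
// Hessian of the weighted constraint sum  sum_i omega_i c_i(z)  for the
// step-scaled Boole/Hermite rows.  Each constraint row is a linear
// combination of F_l evaluations at the group's points, so the Hessian
// aggregates, per (point, state-row), a scalar weight times the small
// dense Hessian block of F_l with respect to its active variables.

static inline double gfun_dd(double y) {
  if (std::fabs(y) < 1e-4) return 1.0 / 6.0 - y * y / 60.0;
  double e = std::exp(-y), D = 1.0 - e;
  return e * (y - 2.0) / (D * D) + 2.0 * y * e * e / (D * D * D);
}

// Phi(V), Phi', Phi'' (per mV)
static inline void ghk_phi2(double V_mV, const double* k, double& phi,
                            double& d1, double& d2) {
  double F = k[0], R = k[1], T = k[2], z = k[3], Ci = k[4], Co = k[5];
  double a = z * F / (R * T) * 1e-3;
  double y = a * V_mV;
  double e = std::exp(-y);
  double conc = Ci - Co * e;
  phi = z * F * gfun(y) * conc;
  d1 = z * F * a * (gfun_d(y) * conc + gfun(y) * Co * e);
  d2 = z * F * a * a * (gfun_dd(y) * conc + 2.0 * gfun_d(y) * Co * e -
                        gfun(y) * Co * e);
}

struct Trip {
  std::vector<int> i, j;
  std::vector<double> v;
  void add(int a, int b, double x) {
    if (x == 0.0) return;
    i.push_back(a); j.push_back(b); v.push_back(x);
    if (a != b) { i.push_back(b); j.push_back(a); v.push_back(x); }
  }
};

// [[Rcpp::export]]
List colloc_hess_cpp(NumericVector z, int npts, IntegerVector grp_start,
                     NumericVector grp_dt, NumericVector Vexp,
                     NumericVector Iinj, NumericVector consts, bool nudge,
                     NumericVector omega) {
  const double* zp = REAL(z);
  const double* k = REAL(consts);
  const double* par = zp + 8 * npts;
  int G = grp_start.size();
  int pcb = 8 * npts;
  static const double wB[5] = {7.0, 32.0, 12.0, 32.0, 7.0};

  // aggregate per-(retained point, state l) weights
  std::vector<double> W((size_t)npts * 7, 0.0);
  for (int g = 0; g < G; ++g) {
    int gs = grp_start[g], rbase = 23 * g;
    for (int l = 0; l < 7; ++l) {
      for (int kk = 0; kk < 5; ++kk)
        W[(size_t)(gs + kk) * 7 + l] += omega[rbase + l] * (-wB[kk] / 90.0);
      // Hermite at gs+1: F at gs, gs+2 with coef -1/8, +1/8
      W[(size_t)gs * 7 + l] += omega[rbase + 7 + l] * (-0.125);
      W[(size_t)(gs + 2) * 7 + l] += omega[rbase + 7 + l] * (0.125);
      // Hermite at gs+3: F at gs+2, gs+4
      W[(size_t)(gs + 2) * 7 + l] += omega[rbase + 14 + l] * (-0.125);
      W[(size_t)(gs + 4) * 7 + l] += omega[rbase + 14 + l] * (0.125);
    }
  }

  Trip H;
  H.i.reserve((size_t)npts * 700);
  for (int jpt = 0; jpt < npts; ++jpt) {
    const double* x = zp + 8 * jpt;
    int cb = 8 * jpt;
    const double* w7 = W.data() + (size_t)jpt * 7;
    bool any = false;
    for (int l = 0; l < 7; ++l) if (w7[l] != 0.0) { any = true; break; }
    if (!any) continue;

    // ---- V row ----
    double wV = w7[0];
    if (wV != 0.0) {
      double V = x[0], mm = x[1], hh = x[2], nn = x[3], qq = x[4],
             rr = x[5], zg = x[6], u = x[7];
      double C = par[IP_C];
      double g1 = par[IP_GNAT], E1 = par[IP_ENA];
      double g2 = par[IP_GK], E2 = par[IP_EK];
      double g3 = par[IP_GH], E3 = par[IP_EH];
      double g4 = par[IP_GL], E4 = par[IP_EL];
      double pT = par[IP_PT], A = par[IP_A];
      double d1 = E1 - V, d2 = E2 - V, d3 = E3 - V, d4 = E4 - V;
      double phi, ph1, ph2;
      ghk_phi2(V, k, phi, ph1, ph2);
      double m2 = mm * mm, m3 = m2 * mm, n2 = nn * nn, n3 = n2 * nn,
             n4 = n3 * nn;
      double iC = 1.0 / C;
      int cV = cb + 0, cm = cb + 1, chh = cb + 2, cn = cb + 3,
          cq = cb + 4, cr = cb + 5, cz = cb + 6, cu = cb + 7;
      int pC = pcb + IP_C, pg1 = pcb + IP_GNAT, pE1 = pcb + IP_ENA,
          pg2 = pcb + IP_GK, pE2 = pcb + IP_EK, pg3 = pcb + IP_GH,
          pE3 = pcb + IP_EH, pg4 = pcb + IP_GL, pE4 = pcb + IP_EL,
          ppT = pcb + IP_PT, pA = pcb + IP_A;
      double s = wV * iC;
      // NaT
      H.add(cm, cm, s * 6.0 * g1 * mm * hh * d1);
      H.add(cm, chh, s * 3.0 * g1 * m2 * d1);
      H.add(cm, cV, s * -3.0 * g1 * m2 * hh);
      H.add(cm, pg1, s * 3.0 * m2 * hh * d1);
      H.add(cm, pE1, s * 3.0 * g1 * m2 * hh);
      H.add(chh, cV, s * -g1 * m3);
      H.add(chh, pg1, s * m3 * d1);
      H.add(chh, pE1, s * g1 * m3);
      H.add(cV, pg1, s * -m3 * hh);
      H.add(pg1, pE1, s * m3 * hh);
      // K
      H.add(cn, cn, s * 12.0 * g2 * n2 * d2);
      H.add(cn, cV, s * -4.0 * g2 * n3);
      H.add(cn, pg2, s * 4.0 * n3 * d2);
      H.add(cn, pE2, s * 4.0 * g2 * n3);
      H.add(cV, pg2, s * -n4);
      H.add(pg2, pE2, s * n4);
      // HCN
      H.add(cz, cV, s * -g3);
      H.add(cz, pg3, s * d3);
      H.add(cz, pE3, s * g3);
      H.add(cV, pg3, s * -zg);
      H.add(pg3, pE3, s * 1.0);
      // Leak
      H.add(cV, pg4, s * -1.0);
      H.add(pg4, pE4, s * 1.0);
      // CaT (enters T with minus sign)
      H.add(cq, cq, s * -200.0 * pT * rr * phi);
      H.add(cq, cr, s * -200.0 * pT * qq * phi);
      H.add(cq, cV, s * -200.0 * pT * qq * rr * ph1);
      H.add(cr, cV, s * -100.0 * pT * qq * qq * ph1);
      H.add(cV, cV, s * -100.0 * pT * qq * qq * rr * ph2);
      H.add(cq, ppT, s * -200.0 * qq * rr * phi);
      H.add(cr, ppT, s * -100.0 * qq * qq * phi);
      H.add(cV, ppT, s * -100.0 * qq * qq * rr * ph1);
      // injection
      H.add(pA, pA, s * 0.02 * Iinj[jpt] / (A * A * A));
      // capacitance cross terms: F = T/C (+ u term); dF/dC = -T/C^2
      double Tval = g1 * m3 * hh * d1 + g2 * n4 * d2 + g3 * zg * d3 +
                    g4 * d4 - pT * 100.0 * qq * qq * rr * phi +
                    Iinj[jpt] * 1e-2 / A;
      double sC = -wV * iC * iC;
      H.add(pC, pC, wV * 2.0 * Tval * iC * iC * iC);
      // T_xi for xi in vars/params of T
      H.add(pC, cV, sC * (-g1 * m3 * hh - g2 * n4 - g3 * zg - g4 -
                          pT * 100.0 * qq * qq * rr * ph1));
      H.add(pC, cm, sC * 3.0 * g1 * m2 * hh * d1);
      H.add(pC, chh, sC * g1 * m3 * d1);
      H.add(pC, cn, sC * 4.0 * g2 * n3 * d2);
      H.add(pC, cq, sC * -200.0 * pT * qq * rr * phi);
      H.add(pC, cr, sC * -100.0 * pT * qq * qq * phi);
      H.add(pC, cz, sC * g3 * d3);
      H.add(pC, pg1, sC * m3 * hh * d1);
      H.add(pC, pE1, sC * g1 * m3 * hh);
      H.add(pC, pg2, sC * n4 * d2);
      H.add(pC, pE2, sC * g2 * n4);
      H.add(pC, pg3, sC * zg * d3);
      H.add(pC, pE3, sC * g3 * zg);
      H.add(pC, pg4, sC * d4);
      H.add(pC, pE4, sC * g4);
      H.add(pC, ppT, sC * -100.0 * qq * qq * rr * phi);
      H.add(pC, pA, sC * -Iinj[jpt] * 1e-2 / (A * A));
      // nudging term u (Vexp - V)
      if (nudge) H.add(cu, cV, wV * -1.0);
    }

    // ---- gate rows ----
    for (int gi = 0; gi < 6; ++gi) {
      int l = GATE_STATE[gi];
      double wg = w7[l];
      if (wg == 0.0) continue;
      const double* gp = par + GATE_POFF[gi];
      double Vt = gp[0], dV = gp[1], dVt = gp[2], t0 = gp[3], eps = gp[4];
      double V = x[0], xg = x[l];
      double sarg = (V - Vt) / dV, warg = (V - Vt) / dVt;
      double ths = std::tanh(sarg), thw = std::tanh(warg);
      double ss = 1.0 - ths * ths, sw = 1.0 - thw * thw;  // sech^2
      double xinf = 0.5 * (1.0 + ths);
      double tau = t0 + eps * sw;
      double N = xinf - xg;
      double swp = -2.0 * sw * thw;                 // d sech2 / dw
      double swpp = 4.0 * sw * thw * thw - 2.0 * sw * sw;
      // local coords: 0 V, 1 x, 2 Vt, 3 dV, 4 dVt, 5 t0, 6 eps
      double Na[7] = {0}, Ta[7] = {0};
      double Nab[7][7] = {{0}}, Tab[7][7] = {{0}};
      double s_a[7] = {0}, w_a[7] = {0};
      s_a[0] = 1.0 / dV; s_a[2] = -1.0 / dV; s_a[3] = -sarg / dV;
      w_a[0] = 1.0 / dVt; w_a[2] = -1.0 / dVt; w_a[4] = -warg / dVt;
      // x_inf derivatives
      for (int a = 0; a < 7; ++a) Na[a] = 0.5 * ss * s_a[a];
      Na[1] = -1.0;
      double s_ab[7][7] = {{0}};
      s_ab[0][3] = s_ab[3][0] = -1.0 / (dV * dV);
      s_ab[2][3] = s_ab[3][2] = 1.0 / (dV * dV);
      s_ab[3][3] = 2.0 * sarg / (dV * dV);
      double w_ab[7][7] = {{0}};
      w_ab[0][4] = w_ab[4][0] = -1.0 / (dVt * dVt);
      w_ab[2][4] = w_ab[4][2] = 1.0 / (dVt * dVt);
      w_ab[4][4] = 2.0 * warg / (dVt * dVt);
      for (int a = 0; a < 7; ++a)
        for (int b = a; b < 7; ++b) {
          if (a == 1 || b == 1) continue;
          Nab[a][b] = Nab[b][a] =
            -ths * ss * s_a[a] * s_a[b] + 0.5 * ss * s_ab[a][b];
        }
      // tau derivatives
      for (int a = 0; a < 7; ++a) Ta[a] = eps * swp * w_a[a];
      Ta[1] = 0.0; Ta[5] = 1.0; Ta[6] = sw;
      for (int a = 0; a < 7; ++a)
        for (int b = a; b < 7; ++b) {
          double v = 0.0;
          bool aVw = (a == 0 || a == 2 || a == 4);
          bool bVw = (b == 0 || b == 2 || b == 4);
          if (aVw && bVw)
            v = eps * (swpp * w_a[a] * w_a[b] + swp * w_ab[a][b]);
          else if (a == 6 && bVw) v = swp * w_a[b];
          else if (b == 6 && aVw) v = swp * w_a[a];
          Tab[a][b] = Tab[b][a] = v;
        }
      int cols[7] = {cb + 0, cb + l, pcb + GATE_POFF[gi] + 0,
                     pcb + GATE_POFF[gi] + 1, pcb + GATE_POFF[gi] + 2,
                     pcb + GATE_POFF[gi] + 3, pcb + GATE_POFF[gi] + 4};
      double it = 1.0 / tau, it2 = it * it, it3 = it2 * it;
      for (int a = 0; a < 7; ++a)
        for (int b = a; b < 7; ++b) {
          double Fab = Nab[a][b] * it -
            (Na[a] * Ta[b] + Na[b] * Ta[a]) * it2 -
            N * Tab[a][b] * it2 + 2.0 * N * Ta[a] * Ta[b] * it3;
          if (Fab != 0.0) H.add(cols[a], cols[b], wg * Fab);
        }
    }
  }
  return List::create(_["i"] = IntegerVector(H.i.begin(), H.i.end()),
                      _["j"] = IntegerVector(H.j.begin(), H.j.end()),
                      _["v"] = NumericVector(H.v.begin(), H.v.end()));
}
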