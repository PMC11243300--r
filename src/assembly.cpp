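// Element assembly kernels for the 2D solvers.
// Units: SI (m, s, Pa, kg). Meshes arrive already converted from mm.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// P1 gradients and area for triangle (x1..y3): g[2][3], returns area
static double p1_grads(const double *px, const double *py, double g[2][3]) {
  double x21 = px[1] - px[0], x31 = px[2] - px[0];
  double y21 = py[1] - py[0], y31 = py[2] - py[0];
  double det = x21 * y31 - x31 * y21;   // 2*area (CCW positive)
  double A = 0.5 * det;
  g[0][0] = (py[1] - py[2]) / det; g[1][0] = (px[2] - px[1]) / det;
  g[0][1] = (py[2] - py[0]) / det; g[1][1] = (px[0] - px[2]) / det;
  g[0][2] = (py[0] - py[1]) / det; g[1][2] = (px[1] - px[0]) / det;
  return A;
}

// Stabilized equal-order (P1-P1) incompressible Navier-Stokes, ALE form,
// kinematic scaling (momentum divided by rho; pressure unknown is p/rho).
// Linear system in z = [vx; vy; pt] with frozen advection field a = v* - v_m.
// Terms: backward-Euler time derivative, Galerkin convection/viscous/pressure,
// SUPG + PSPG on the P1 residual, grad-div. tau_m per element:
//   tau_m = ((2/dt)^2 + (2|a|/h)^2 + (4 nu/h^2)^2)^(-1/2),  tau_c = h^2/tau_m
// [[Rcpp::export]]
List fluid_assemble_cpp(NumericMatrix nodes, IntegerMatrix tri,
                        NumericVector vnx, NumericVector vny,
                        NumericVector ax, NumericVector ay,
                        NumericVector vx, NumericVector vy,
                        double inv_dt, double nu,
                        double fx, double fy, int stab,
                        double supg_s = 1.0, double pspg_s = 1.0,
                        double gdiv_s = 1.0, double a_ref = -1.0) {
  int N = nodes.nrow(), M = tri.nrow();
  // recovered per-element Laplacian of the current velocity iterate:
  // patch-averaged (area-weighted) nodal gradients, then element divergence;
  // restores the viscous part of the P1 residual for the stabilization terms
  NumericMatrix lap(M, 2);
  bool has_lap = true;
  {
    std::vector<double> gxe(3*M), gye(3*M), Ae(M);
    std::vector<double> gnum(4*N, 0.0), aden(N, 0.0);
    std::vector<double> Gel(4*M);
    for (int e = 0; e < M; ++e) {
      int n0 = tri(e,0)-1, n1 = tri(e,1)-1, n2 = tri(e,2)-1;
      double px[3] = {nodes(n0,0), nodes(n1,0), nodes(n2,0)};
      double py[3] = {nodes(n0,1), nodes(n1,1), nodes(n2,1)};
      double g[2][3];
      double A = p1_grads(px, py, g);
      Ae[e] = A;
      int nd[3] = {n0, n1, n2};
      double Gxu=0, Gyu=0, Gxv=0, Gyv=0;
      for (int j = 0; j < 3; ++j) {
        gxe[3*e+j] = g[0][j]; gye[3*e+j] = g[1][j];
        Gxu += g[0][j]*vx[nd[j]]; Gyu += g[1][j]*vx[nd[j]];
        Gxv += g[0][j]*vy[nd[j]]; Gyv += g[1][j]*vy[nd[j]];
      }
      Gel[4*e]=Gxu; Gel[4*e+1]=Gyu; Gel[4*e+2]=Gxv; Gel[4*e+3]=Gyv;
      for (int j = 0; j < 3; ++j) {
        aden[nd[j]] += A;
        for (int c = 0; c < 4; ++c) gnum[4*nd[j]+c] += A * Gel[4*e+c];
      }
    }
    for (int e = 0; e < M; ++e) {
      int nd[3] = {tri(e,0)-1, tri(e,1)-1, tri(e,2)-1};
      double lu=0, lv=0;
      for (int j = 0; j < 3; ++j) {
        double w = 1.0 / (aden[nd[j]] > 0 ? aden[nd[j]] : 1.0);
        lu += gxe[3*e+j]*gnum[4*nd[j]+0]*w + gye[3*e+j]*gnum[4*nd[j]+1]*w;
        lv += gxe[3*e+j]*gnum[4*nd[j]+2]*w + gye[3*e+j]*gnum[4*nd[j]+3]*w;
      }
      lap(e,0) = lu; lap(e,1) = lv;
    }
  }
  int nent = M * 81 + 1;
  IntegerVector II(nent), JJ(nent);
  NumericVector XX(nent);
  NumericVector rhs(3 * N);
  int k = 0;
  double mloc[3][3] = {{2,1,1},{1,2,1},{1,1,2}}; // * A/12

  for (int e = 0; e < M; ++e) {
    int n0 = tri(e,0)-1, n1 = tri(e,1)-1, n2 = tri(e,2)-1;
    int nd[3] = {n0, n1, n2};
    double px[3] = {nodes(n0,0), nodes(n1,0), nodes(n2,0)};
    double py[3] = {nodes(n0,1), nodes(n1,1), nodes(n2,1)};
    double g[2][3];
    double A = p1_grads(px, py, g);
    double h = std::sqrt(4.0 * A / std::sqrt(3.0));
    double acx = (ax[n0]+ax[n1]+ax[n2])/3.0, acy = (ay[n0]+ay[n1]+ay[n2])/3.0;
    double amag = std::sqrt(acx*acx + acy*acy);
    if (a_ref > 0) amag = a_ref;   // global advection scale keeps tau smooth
    double tm = 0.0, tc = 0.0;
    if (stab) {
      double t1 = 2.0*inv_dt, t2 = 2.0*amag/h, t3 = 4.0*nu/(h*h);
      tm = 1.0/std::sqrt(t1*t1 + t2*t2 + t3*t3);
      tc = gdiv_s * h*h/tm;
    }
    double vncx = (vnx[n0]+vnx[n1]+vnx[n2])/3.0;
    double vncy = (vny[n0]+vny[n1]+vny[n2])/3.0;
    // a . grad(phi_j)
    double adg[3];
    for (int j = 0; j < 3; ++j) adg[j] = acx*g[0][j] + acy*g[1][j];

    for (int i = 0; i < 3; ++i) {
      int gi = nd[i];
      int rx = gi, ry = N + gi, rp = 2*N + gi;
      for (int j = 0; j < 3; ++j) {
        int gj = nd[j];
        int cx = gj, cy = N + gj, cp = 2*N + gj;
        double mij = A/12.0 * mloc[i][j];
        double gg = g[0][i]*g[0][j] + g[1][i]*g[1][j];
        // momentum: mass + convection + viscous (Laplacian form nu grad v :
        // grad w, whose do-nothing outlet traction nu dv/dn - p n is exact
        // for developed channel flow; on no-slip walls it coincides with the
        // true Cauchy traction)
        double diag_core = mij*inv_dt + (A/3.0)*adg[j] + nu*A*gg;
        double kxx = diag_core;
        double kyy = diag_core;
        double kxy = 0.0;
        double kyx = 0.0;
        // SUPG: tau (a.grad wi) * [ (1/3) inv_dt vj + adg_j vj + grad p ]
        double supg_i = supg_s * tm * A * adg[i];
        kxx += supg_i * (inv_dt/3.0 + adg[j]);
        kyy += supg_i * (inv_dt/3.0 + adg[j]);
        // grad-div
        double gdxx = tc * A * g[0][i]*g[0][j];
        double gdyy = tc * A * g[1][i]*g[1][j];
        double gdxy = tc * A * g[0][i]*g[1][j];
        double gdyx = tc * A * g[1][i]*g[0][j];
        II[k]=rx; JJ[k]=cx; XX[k]=kxx+gdxx; ++k;
        II[k]=ry; JJ[k]=cy; XX[k]=kyy+gdyy; ++k;
        II[k]=rx; JJ[k]=cy; XX[k]=kxy+gdxy; ++k;
        II[k]=ry; JJ[k]=cx; XX[k]=kyx+gdyx; ++k;
        // pressure gradient (momentum rows): -(div w, p) + SUPG grad p
        II[k]=rx; JJ[k]=cp; XX[k]=-(A/3.0)*g[0][i] + supg_i*g[0][j]; ++k;
        II[k]=ry; JJ[k]=cp; XX[k]=-(A/3.0)*g[1][i] + supg_i*g[1][j]; ++k;
        // continuity rows: (q, div v) + PSPG
        double pspg_x = pspg_s * tm * A * g[0][i];
        double pspg_y = pspg_s * tm * A * g[1][i];
        II[k]=rp; JJ[k]=cx; XX[k]=(A/3.0)*g[0][j] + pspg_x*(inv_dt/3.0 + adg[j]); ++k;
        II[k]=rp; JJ[k]=cy; XX[k]=(A/3.0)*g[1][j] + pspg_y*(inv_dt/3.0 + adg[j]); ++k;
        II[k]=rp; JJ[k]=cp; XX[k]=pspg_s*tm*A*gg; ++k;
        // rhs from old-time velocity in consistent mass
        rhs[rx] += mij*inv_dt*vnx[gj];
        rhs[ry] += mij*inv_dt*vny[gj];
      }
      // rhs: body force + SUPG/PSPG of (f + vn/dt + nu*recovered Laplacian)
      double rmx = fx + inv_dt*vncx, rmy = fy + inv_dt*vncy;
      if (has_lap) { rmx += nu*lap(e,0); rmy += nu*lap(e,1); }
      rhs[rx] += (A/3.0)*fx + supg_s*tm*A*adg[i]*rmx;
      rhs[ry] += (A/3.0)*fy + supg_s*tm*A*adg[i]*rmy;
      rhs[rp] += pspg_s*tm*A*(g[0][i]*rmx + g[1][i]*rmy);
    }
  }
  return List::create(_["i"] = II[Range(0, k-1)], _["j"] = JJ[Range(0, k-1)],
                      _["x"] = XX[Range(0, k-1)], _["rhs"] = rhs);
}

// ---------------- solid: Neo-Hookean + Simo-Taylor, mixed u-p, P1-P1 -------
// Total-Lagrangian element residual, plane strain. One-point quadrature.
// dof layout per element: [ux1 uy1 ux2 uy2 ux3 uy3 p1 p2 p3]
static void solid_elem_residual(const double *X, const double *Y,
                                const double *ue, const double *pe,
                                double mu, double kappa, double stab_alpha,
                                int finite_vol, double res[9]) {
  double g[2][3];
  double A = p1_grads(X, Y, g);
  double h2 = 4.0 * A / std::sqrt(3.0);
  // F = I + du/dX
  double F11=1, F12=0, F21=0, F22=1;
  for (int j = 0; j < 3; ++j) {
    F11 += ue[2*j]   * g[0][j];  F12 += ue[2*j]   * g[1][j];
    F21 += ue[2*j+1] * g[0][j];  F22 += ue[2*j+1] * g[1][j];
  }
  double J = F11*F22 - F12*F21;
  if (J <= 0) { for (int i=0;i<9;++i) res[i] = NA_REAL; return; }
  double pc = (pe[0]+pe[1]+pe[2])/3.0;
  // B = F F^T (2x2); plane strain B33 = 1
  double B11 = F11*F11 + F12*F12, B12 = F11*F21 + F12*F22;
  double B22 = F21*F21 + F22*F22;
  double trB = B11 + B22 + 1.0;   // plane strain: B33 = 1
  double c = mu * std::pow(J, -5.0/3.0);
  double s11 = pc + c*(B11 - trB/3.0);
  double s22 = pc + c*(B22 - trB/3.0);
  double s12 = c*B12;
  // P = J sigma F^{-T}; F^{-1} = (1/J)[F22 -F12; -F21 F11]
  // F^{-T} = (1/J)[F22 -F21; -F12 F11]
  double P11 = s11*F22 - s12*F12;   // J sigma * F^{-T} -> J cancels
  double P12 = -s11*F21 + s12*F11;
  double P21 = s12*F22 - s22*F12;
  double P22 = -s12*F21 + s22*F11;
  double divu = (F11 - 1.0) + (F22 - 1.0);
  double vol_res;
  if (finite_vol) vol_res = 0.5*(J - 1.0/J) - pc/kappa;
  else            vol_res = divu - pc/kappa;
  double gpx = 0, gpy = 0;
  for (int j = 0; j < 3; ++j) { gpx += pe[j]*g[0][j]; gpy += pe[j]*g[1][j]; }
  for (int i = 0; i < 3; ++i) {
    res[2*i]   = A * (P11*g[0][i] + P12*g[1][i]);
    res[2*i+1] = A * (P21*g[0][i] + P22*g[1][i]);
    res[6+i]   = A * ( vol_res/3.0
                 - stab_alpha*(h2/mu) * (g[0][i]*gpx + g[1][i]*gpy) );
  }
}

// residual + FD tangent assembly over all elements
// [[Rcpp::export]]
List solid_assemble_cpp(NumericMatrix nodes0, IntegerMatrix tri,
                        NumericVector u, NumericVector p,
                        NumericVector mu_e, NumericVector kappa_e,
                        double stab_alpha, int finite_vol, int want_tangent) {
  int N = nodes0.nrow(), M = tri.nrow();
  NumericVector R(3 * N);
  int nent = want_tangent ? M * 81 : 1;
  IntegerVector II(nent), JJ(nent);
  NumericVector XX(nent);
  int k = 0;
  for (int e = 0; e < M; ++e) {
    int nd[3] = {tri(e,0)-1, tri(e,1)-1, tri(e,2)-1};
    double X[3], Y[3], ue[6], pe[3];
    for (int j = 0; j < 3; ++j) {
      X[j] = nodes0(nd[j],0); Y[j] = nodes0(nd[j],1);
      ue[2*j] = u[nd[j]]; ue[2*j+1] = u[N + nd[j]]; pe[j] = p[nd[j]];
    }
    double res[9];
    solid_elem_residual(X, Y, ue, pe, mu_e[e], kappa_e[e],
                        stab_alpha, finite_vol, res);
    if (ISNA(res[0])) stop("inverted element in solid assembly (element %d)", e+1);
    int dof[9];
    for (int j = 0; j < 3; ++j) {
      dof[2*j] = nd[j]; dof[2*j+1] = N + nd[j]; dof[6+j] = 2*N + nd[j];
    }
    for (int i = 0; i < 9; ++i) R[dof[i]] += res[i];
    if (want_tangent) {
      double hchar = std::sqrt(std::fabs((X[1]-X[0])*(Y[2]-Y[0]) -
                                         (X[2]-X[0])*(Y[1]-Y[0])));
      double eps_u = 1e-6 * (hchar > 1e-12 ? hchar : 1e-12);
      double eps_p = 1e-6 * kappa_e[e];
      double rp[9], rm[9], ue2[6], pe2[3];
      for (int jd = 0; jd < 9; ++jd) {
        for (int t = 0; t < 6; ++t) ue2[t] = ue[t];
        for (int t = 0; t < 3; ++t) pe2[t] = pe[t];
        double eps = (jd < 6) ? eps_u : eps_p;
        if (jd < 6) ue2[jd] += eps; else pe2[jd-6] += eps;
        solid_elem_residual(X, Y, ue2, pe2, mu_e[e], kappa_e[e],
                            stab_alpha, finite_vol, rp);
        if (jd < 6) ue2[jd] -= 2*eps; else pe2[jd-6] -= 2*eps;
        solid_elem_residual(X, Y, ue2, pe2, mu_e[e], kappa_e[e],
                            stab_alpha, finite_vol, rm);
        bool bad = ISNA(rp[0]) || ISNA(rm[0]);
        for (int i = 0; i < 9; ++i) {
          double v = bad ? 0.0 : (rp[i] - rm[i]) / (2*eps);
          II[k] = dof[i]; JJ[k] = dof[jd]; XX[k] = v; ++k;
        }
      }
    }
  }
  if (want_tangent)
    return List::create(_["R"] = R, _["i"] = II[Range(0,k-1)],
                        _["j"] = JJ[Range(0,k-1)], _["x"] = XX[Range(0,k-1)]);
  return List::create(_["R"] = R);
}
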