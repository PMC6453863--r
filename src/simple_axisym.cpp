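// Steady incompressible axisymmetric Navier-Stokes on a staggered uniform
// (z, r) finite-volume grid, SIMPLE pressure-velocity coupling, first-order
// upwind convection, central diffusion. Scaffold struts enter as solid
// (masked) cells: stair-step immersed rectangular obstacles with no-slip on
// their faces. All quantities SI; fluxes/areas are per radian of azimuth.
//
// Grid: nz x nr cells. u (axial) on axial faces, (nz+1) x nr, node at
// z = i*dz, r = (j+0.5)*dr. v (radial) on radial faces, nz x (nr+1), node at
// z = (i+0.5)*dz, r = j*dr. p at cell centres. Axis r=0: symmetry; r=R and
// solid faces: no-slip; inlet: prescribed u profile; outlet: zero-gradient u
// rescaled for global mass balance, reference pressure 0.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double upos(double x) { return x > 0 ? x : 0; }

// [[Rcpp::export]]
List simple_axisym_cpp(int nz, int nr, double dz, double dr,
                       LogicalMatrix solid, NumericVector u_in,
                       double mu, double rho,
                       double relax_u, double relax_p,
                       double tol, int max_iter,
                       int sweeps_uv, int sweeps_p, double omega_p) {
  NumericMatrix u(nz + 1, nr), v(nz, nr + 1), p(nz, nr);
  NumericMatrix aPu(nz + 1, nr), aPv(nz, nr + 1);
  NumericMatrix aEu(nz + 1, nr), aWu(nz + 1, nr), aNu(nz + 1, nr), aSu(nz + 1, nr), bu(nz + 1, nr);
  NumericMatrix aEv(nz, nr + 1), aWv(nz, nr + 1), aNv(nz, nr + 1), aSv(nz, nr + 1), bv(nz, nr + 1);
  NumericMatrix pc(nz, nr);
  std::vector<char> uSolid((nz + 1) * nr, 0), vSolid(nz * (nr + 1), 0);

  auto US = [&](int i, int j) -> char& { return uSolid[(size_t)i * nr + j]; };
  auto VS = [&](int i, int j) -> char& { return vSolid[(size_t)i * (nr + 1) + j]; };

  // face solidity: a u face is blocked if either adjacent cell is solid
  for (int i = 0; i <= nz; ++i)
    for (int j = 0; j < nr; ++j) {
      bool sL = (i > 0) ? solid(i - 1, j) : false;
      bool sR = (i < nz) ? solid(i, j) : false;
      US(i, j) = (sL || sR) ? 1 : 0;
    }
  for (int i = 0; i < nz; ++i)
    for (int j = 0; j <= nr; ++j) {
      bool sS = (j > 0) ? solid(i, j - 1) : true;   // below axis face: none
      bool sN = (j < nr) ? solid(i, j) : true;      // above wall face: solid
      if (j == 0) { VS(i, j) = 1; continue; }       // axis: v = 0
      if (j == nr) { VS(i, j) = 1; continue; }      // outer wall: v = 0
      VS(i, j) = (sS || sN) ? 1 : 0;
    }

  // inlet profile; inlet flux per radian
  double Qin = 0;
  for (int j = 0; j < nr; ++j) {
    double rj = (j + 0.5) * dr;
    if (!solid(0, j)) { u(0, j) = u_in[j]; Qin += u_in[j] * rj * dr; }
  }
  if (Qin <= 0) stop("inlet entirely blocked or zero inflow");
  // initial guess: inlet profile advected downstream
  for (int i = 1; i <= nz; ++i)
    for (int j = 0; j < nr; ++j) u(i, j) = US(i, j) ? 0.0 : u(0, j);

  NumericVector res_hist(max_iter);
  double res = 1e30;
  int iter = 0;
  bool converged = false;

  double mom_scale = rho * Qin * (Qin / (0.5 * nr * dr * nr * dr)); // ~rho*Q*ubar
  for (iter = 0; iter < max_iter; ++iter) {
    double resu = 0, resv = 0;
    // ---- u momentum coefficients ----
    for (int i = 1; i < nz; ++i) {
      for (int j = 0; j < nr; ++j) {
        if (US(i, j)) { u(i, j) = 0; aPu(i, j) = 1; continue; }
        double rj = (j + 0.5) * dr;
        double Aew = rj * dr;
        double An = (j + 1) * dr * dz, As = j * dr * dz;
        double De = mu * Aew / dz, Dw = De;
        double Dn = mu * An / dr, Ds = mu * As / dr;
        double Fe = rho * 0.5 * (u(i, j) + u(i + 1, j)) * Aew;
        double Fw = rho * 0.5 * (u(i - 1, j) + u(i, j)) * Aew;
        double Fn = rho * 0.5 * (v(i - 1, j + 1) + v(i, j + 1)) * An;
        double Fs = rho * 0.5 * (v(i - 1, j) + v(i, j)) * As;
        double aE = De + upos(-Fe), aW = Dw + upos(Fw);
        double aN, aS;
        bool wallN = (j == nr - 1) || US(i, j + 1);
        bool wallS = (j > 0) && US(i, j - 1);
        double extra = 0;
        if (wallN) { aN = 0; extra += 2 * Dn; }  // no-slip at face, dist dr/2
        else aN = Dn + upos(-Fn);
        if (j == 0) aS = 0;                       // axis: As = 0 anyway
        else if (wallS) { aS = 0; extra += 2 * Ds; }
        else aS = Ds + upos(Fs);
        double aP = aE + aW + aN + aS + extra + (Fe - Fw + Fn - Fs);
        double b = (p(i - 1, j) - p(i, j)) * Aew;
        double uN = (j < nr - 1) ? u(i, j + 1) : 0.0;
        double uS = (j > 0) ? u(i, j - 1) : 0.0;
        resu += std::fabs(aP * u(i, j) - aE * u(i + 1, j) - aW * u(i - 1, j) -
                          aN * uN - aS * uS - b);
        aP /= relax_u;
        b += (1 - relax_u) * aP * u(i, j);
        aEu(i, j) = aE; aWu(i, j) = aW; aNu(i, j) = aN; aSu(i, j) = aS;
        aPu(i, j) = aP; bu(i, j) = b;
      }
    }
    // ---- v momentum coefficients ----
    for (int i = 0; i < nz; ++i) {
      for (int j = 1; j < nr; ++j) {
        if (VS(i, j)) { v(i, j) = 0; aPv(i, j) = 1; continue; }
        double rf = j * dr;
        double Aew = rf * dr;
        double An = (j + 0.5) * dr * dz, As = (j - 0.5) * dr * dz;
        double De = mu * Aew / dz, Dw = De;
        double Dn = mu * An / dr, Ds = mu * As / dr;
        double Fe = rho * 0.5 * (u(i + 1, j - 1) + u(i + 1, j)) * Aew;
        double Fw = rho * 0.5 * (u(i, j - 1) + u(i, j)) * Aew;
        double Fn = rho * 0.5 * (v(i, j) + v(i, j + 1)) * An;
        double Fs = rho * 0.5 * (v(i, j - 1) + v(i, j)) * As;
        double aE = De + upos(-Fe), aW = Dw + upos(Fw);
        double aN = Dn + upos(-Fn), aS = Ds + upos(Fs);
        double aP = aE + aW + aN + aS + (Fe - Fw + Fn - Fs);
        aP += mu * rf * dr * dz / (rf * rf);     // cylindrical -mu*v/r^2 term
        double b = (p(i, j - 1) - p(i, j)) * rf * dz;
        double vE = (i < nz - 1) ? v(i + 1, j) : v(i, j);
        double vW = (i > 0) ? v(i - 1, j) : 0.0;
        resv += std::fabs(aP * v(i, j) - aE * vE - aW * vW -
                          aN * v(i, j + 1) - aS * v(i, j - 1) - b);
        aP /= relax_u;
        b += (1 - relax_u) * aP * v(i, j);
        aEv(i, j) = aE; aWv(i, j) = aW; aNv(i, j) = aN; aSv(i, j) = aS;
        aPv(i, j) = aP; bv(i, j) = b;
      }
    }
    // ---- Gauss-Seidel sweeps on momentum ----
    for (int s = 0; s < sweeps_uv; ++s) {
      for (int i = 1; i < nz; ++i)
        for (int j = 0; j < nr; ++j) {
          if (US(i, j)) continue;
          double uN = (j < nr - 1) ? u(i, j + 1) : 0.0;
          double uS = (j > 0) ? u(i, j - 1) : u(i, j); // axis handled by aS=0
          double num = aEu(i, j) * u(i + 1, j) + aWu(i, j) * u(i - 1, j) +
            aNu(i, j) * uN + aSu(i, j) * uS + bu(i, j);
          u(i, j) = num / aPu(i, j);
        }
      for (int i = 0; i < nz; ++i)
        for (int j = 1; j < nr; ++j) {
          if (VS(i, j)) continue;
          double vE = (i < nz - 1) ? v(i + 1, j) : v(i, j);   // outlet dv/dz=0
          double vW = (i > 0) ? v(i - 1, j) : 0.0;            // inlet v=0
          double num = aEv(i, j) * vE + aWv(i, j) * vW +
            aNv(i, j) * v(i, j + 1) + aSv(i, j) * v(i, j - 1) + bv(i, j);
          v(i, j) = num / aPv(i, j);
        }
    }
    // ---- outlet: zero-gradient u, rescaled for global mass balance ----
    double Qout = 0;
    for (int j = 0; j < nr; ++j) {
      u(nz, j) = US(nz, j) ? 0.0 : u(nz - 1, j);
      Qout += u(nz, j) * (j + 0.5) * dr * dr;
    }
    if (Qout > 1e-300) {
      double f = Qin / Qout;
      for (int j = 0; j < nr; ++j) u(nz, j) *= f;
    }
    // ---- pressure correction ----
    double resc = 0;
    std::fill(pc.begin(), pc.end(), 0.0);
    // d coefficients via lambdas
    auto dU = [&](int i, int j) -> double {
      if (i <= 0 || i >= nz || US(i, j)) return 0.0;
      return ((j + 0.5) * dr * dr) / aPu(i, j);
    };
    auto dV = [&](int i, int j) -> double {
      if (j <= 0 || j >= nr || VS(i, j)) return 0.0;
      return (j * dr * dz) / aPv(i, j);
    };
    NumericMatrix aEp(nz, nr), aWp(nz, nr), aNp(nz, nr), aSp(nz, nr),
      aPp(nz, nr), bp(nz, nr);
    for (int i = 0; i < nz; ++i)
      for (int j = 0; j < nr; ++j) {
        if (solid(i, j)) { aPp(i, j) = 1; continue; }
        double rj = (j + 0.5) * dr;
        double Ae = rj * dr, An = (j + 1) * dr * dz, As = j * dr * dz;
        double b = rho * (u(i, j) * Ae - u(i + 1, j) * Ae +
                          v(i, j) * As - v(i, j + 1) * An);
        double aE = rho * Ae * dU(i + 1, j);
        double aW = rho * Ae * dU(i, j);
        double aN = rho * An * dV(i, j + 1);
        double aS = rho * As * dV(i, j);
        // links into solid cells carry d = 0 already
        aEp(i, j) = aE; aWp(i, j) = aW; aNp(i, j) = aN; aSp(i, j) = aS;
        aPp(i, j) = aE + aW + aN + aS;
        bp(i, j) = b;
        resc += std::fabs(b);
      }
    resc /= (rho * Qin);
    for (int s = 0; s < sweeps_p; ++s) {
      for (int i = 0; i < nz; ++i)
        for (int j = 0; j < nr; ++j) {
          if (solid(i, j) || aPp(i, j) <= 0) continue;
          double pE = (i < nz - 1) ? pc(i + 1, j) : 0.0;
          double pW = (i > 0) ? pc(i - 1, j) : 0.0;
          double pN = (j < nr - 1) ? pc(i, j + 1) : 0.0;
          double pS = (j > 0) ? pc(i, j - 1) : 0.0;
          double num = aEp(i, j) * pE + aWp(i, j) * pW +
            aNp(i, j) * pN + aSp(i, j) * pS + bp(i, j);
          pc(i, j) = (1 - omega_p) * pc(i, j) + omega_p * num / aPp(i, j);
        }
    }
    // anchor correction at the outlet row mean so p stays referenced there
    double pref = 0; int nref = 0;
    for (int j = 0; j < nr; ++j)
      if (!solid(nz - 1, j)) { pref += pc(nz - 1, j); ++nref; }
    pref /= std::max(nref, 1);
    // ---- apply corrections ----
    for (int i = 0; i < nz; ++i)
      for (int j = 0; j < nr; ++j)
        if (!solid(i, j)) p(i, j) += relax_p * (pc(i, j) - pref);
    for (int i = 1; i < nz; ++i)
      for (int j = 0; j < nr; ++j)
        if (!US(i, j)) u(i, j) += dU(i, j) * (pc(i - 1, j) - pc(i, j));
    for (int i = 0; i < nz; ++i)
      for (int j = 1; j < nr; ++j)
        if (!VS(i, j)) v(i, j) += dV(i, j) * (pc(i, j - 1) - pc(i, j));

    res = std::max(resc, (resu + resv) / mom_scale);
    res_hist[iter] = res;
    if (res < tol && iter > 10) { converged = true; ++iter; break; }
  }

  return List::create(_["u"] = u, _["v"] = v, _["p"] = p,
                      _["converged"] = converged, _["iterations"] = iter,
                      _["residual"] = res,
                      _["residual_history"] = res_hist[Range(0, std::max(iter - 1, 0))],
                      _["Qin_per_rad"] = Qin);
}
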