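#include <Rcpp.h>
using namespace Rcpp;

// Explicit conservative update of the coupled nucleoplasm / order-parameter
// equations on a masked lattice. Fields are stored as compact vectors over
// the mask cells; `nbr` holds, for each cell, the indices of its four
// lattice neighbours (the cell's own index where a neighbour falls outside
// the mask, which makes the mirror/no-flux closure automatic and keeps the
// update exactly conservative).
//
// Each step:
//   mu_n = -(f_h + f_e)/2 - lam/2 - kappa * lap(phi_n)
//   mu_d =  (f_h - f_e)/2 + lam/2 - kappa * lap(phi_d)
//   phi_n += dt * M_n * lap(mu_n)
//   phi_d += dt * (M_d * lap(mu_d) + 2*(Gamma_me*phi_e - Gamma_ac*phi_h))
// with f_h, f_e the bulk partial derivatives and
// lam = -V'(phi_h) * exp(-d/d0)/d0 (per-cell decay precomputed).
//
// Excursions of phi_d beyond the simplex by more than clip_tol are
// projected back at fixed phi_n (counted); smaller interfacial overshoot
// is left to the double-well restoring force.
// [[Rcpp::export]]
List cpp_evolve(NumericVector phi_n, NumericVector phi_d,
                IntegerMatrix nbr,
                NumericVector gme, double gac,
                NumericVector vhc, double vec, NumericVector decay,
                double phi_h0, double cc, double kappa,
                double Mn, double Md, double h, double dt,
                int nsteps, double clip_tol) {
  const int n = phi_n.size();
  const double ih2 = 1.0 / (h * h);
  const double vslope0 = 1.0 / phi_h0;
  std::vector<double> pn(phi_n.begin(), phi_n.end());
  std::vector<double> pd(phi_d.begin(), phi_d.end());
  std::vector<double> mun(n), mud(n), ln(n), ld(n);
  std::vector<int> n0(n), n1(n), n2(n), n3(n);
  for (int i = 0; i < n; ++i) {
    n0[i] = nbr(i, 0); n1[i] = nbr(i, 1);
    n2[i] = nbr(i, 2); n3[i] = nbr(i, 3);
  }
  const double *g = REAL(gme);
  const double *vh = REAL(vhc);
  const double *dc = REAL(decay);
  long clips = 0;
  int done = 0;
  bool bad = false;

  for (int s = 0; s < nsteps && !bad; ++s) {
    double *Pn = pn.data(), *Pd = pd.data();
    for (int i = 0; i < n; ++i) {
      const double lapn = (Pn[n0[i]] + Pn[n1[i]] + Pn[n2[i]] + Pn[n3[i]]
                           - 4.0 * Pn[i]) * ih2;
      const double lapd = (Pd[n0[i]] + Pd[n1[i]] + Pd[n2[i]] + Pd[n3[i]]
                           - 4.0 * Pd[i]) * ih2;
      const double ph = 0.5 * (1.0 - Pn[i] + Pd[i]);
      const double pe = 0.5 * (1.0 - Pn[i] - Pd[i]);
      const double fh = cc * ph * (phi_h0 - ph) * (phi_h0 - 2.0 * ph);
      const double fe = cc * pe;
      double lam = 0.0;
      if (ph > 0.0 && ph < phi_h0) lam = -(vh[i] - vec) * vslope0 * dc[i];
      mun[i] = -0.5 * (fh + fe) - 0.5 * lam - kappa * lapn;
      mud[i] =  0.5 * (fh - fe) + 0.5 * lam - kappa * lapd;
    }
    const double *Mu = mun.data(), *Mv = mud.data();
    for (int i = 0; i < n; ++i) {
      ln[i] = (Mu[n0[i]] + Mu[n1[i]] + Mu[n2[i]] + Mu[n3[i]]
               - 4.0 * Mu[i]) * ih2;
      ld[i] = (Mv[n0[i]] + Mv[n1[i]] + Mv[n2[i]] + Mv[n3[i]]
               - 4.0 * Mv[i]) * ih2;
    }
    for (int i = 0; i < n; ++i) {
      const double ph = 0.5 * (1.0 - Pn[i] + Pd[i]);
      const double pe = 0.5 * (1.0 - Pn[i] - Pd[i]);
      Pn[i] += dt * Mn * ln[i];
      Pd[i] += dt * (Md * ld[i] + 2.0 * (g[i] * pe - gac * ph));
      const double chrom = 1.0 - Pn[i];
      if (Pd[i] > chrom + clip_tol) { Pd[i] = chrom; ++clips; }
      else if (Pd[i] < -chrom - clip_tol) { Pd[i] = -chrom; ++clips; }
    }
    done = s + 1;
    if ((s + 1) % 50 == 0) {
      for (int i = 0; i < n && !bad; i += 97) {
        if (!std::isfinite(pn[i]) || !std::isfinite(pd[i])) bad = true;
      }
    }
  }
  return List::create(_["phi_n"] = NumericVector(pn.begin(), pn.end()),
                      _["phi_d"] = NumericVector(pd.begin(), pd.end()),
                      _["clips"] = (double)clips,
                      _["steps"] = done,
                      _["diverged"] = bad);
}
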