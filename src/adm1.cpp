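// ADM1 biochemical engine, pH speciation, gas-liquid transfer, and the
// coupled multi-tank (tanks-in-series) mass balance, plus a stiff
// backward-Euler step-doubling integrator with modified Newton iterations.
//
// Units: concentrations kgCOD/m3 (== g/L) except S_IC, S_IN, S_cat, S_an and
// gas CO2 in kmol/m3 (== mol/L); volumes in L; flows in L/d; time in days.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- state layout -----------------------------------------------------------
enum LiqIdx { iSsu = 0, iSaa, iSfa, iSva, iSbu, iSpro, iSac, iSh2, iSch4,
              iSic, iSin, iSi, iXc, iXch, iXpr, iXli, iXsu, iXaa, iXfa,
              iXc4, iXpro, iXac, iXh2, iXi, iScat, iSan };
static const int NLIQ = 26;        // liquid components per tank
static const int NGAS = 3;         // gas h2 (kgCOD/m3), ch4 (kgCOD/m3), co2 (kmol/m3)
static const int NAUX = 2;         // cumulative gas COD out (g), cumulative gas volume (L)
static const int NTS  = NLIQ + NGAS + NAUX; // 31 states per tank
static const int NPROC = 19;

static const double RGAS = 0.083145;   // bar L / (mol K)
// COD equivalents, kgCOD per kmol
static const double COD_VA = 208.0, COD_BU = 160.0, COD_PRO = 112.0,
                    COD_AC = 64.0, COD_H2 = 16.0, COD_CH4 = 64.0;

// ---- parameters -------------------------------------------------------------
struct ADM1P {
  double k_dis, k_hyd_ch, k_hyd_pr, k_hyd_li, K_S_IN;
  double k_m_su, K_S_su, k_m_aa, K_S_aa, k_m_fa, K_S_fa, K_I_h2_fa;
  double k_m_c4, K_S_c4, K_I_h2_c4, k_m_pro, K_S_pro, K_I_h2_pro;
  double k_m_ac, K_S_ac, K_I_nh3, k_m_h2, K_S_h2;
  double k_dec[7];
  double Y_su, Y_aa, Y_fa, Y_c4, Y_pro, Y_ac, Y_h2;
  double f_sI_xc, f_ch_xc, f_pr_xc, f_li_xc, f_xI_xc, f_fa_li;
  double f_h2_su, f_bu_su, f_pro_su, f_ac_su;
  double f_h2_aa, f_va_aa, f_bu_aa, f_pro_aa, f_ac_aa;
  double f_ac_fa, f_h2_fa, f_pro_va, f_ac_va, f_h2_va;
  double f_ac_bu, f_h2_bu, f_ac_pro, f_h2_pro;
  double N_xc, N_I, N_aa, N_bac;
  double C_su, C_aa, C_fa, C_va, C_bu, C_pro, C_ac, C_ch4, C_sI,
         C_xc, C_ch, C_pr, C_li, C_xI, C_bac;
  double pH_UL_aa, pH_LL_aa, pH_UL_ac, pH_LL_ac, pH_UL_h2, pH_LL_h2;
  double T_base, T_op;
  double K_w, K_a_va, K_a_bu, K_a_pro, K_a_ac, K_a_co2, K_a_IN;
  double K_H_h2, K_H_ch4, K_H_co2;   // M/bar at T_op
  double k_L_a, k_p, P_atm, p_h2o;
  arma::mat nu;                      // NLIQ x NPROC stoichiometric matrix

  void build(const NumericVector& pv);
};

static double pget(const NumericVector& pv, const char* nm) {
  if (!pv.containsElementNamed(nm))
    stop(std::string("missing ADM1 parameter: ") + nm);
  return as<double>(pv[nm]);
}

void ADM1P::build(const NumericVector& pv) {
  k_dis = pget(pv, "k_dis"); k_hyd_ch = pget(pv, "k_hyd_ch");
  k_hyd_pr = pget(pv, "k_hyd_pr"); k_hyd_li = pget(pv, "k_hyd_li");
  K_S_IN = pget(pv, "K_S_IN");
  k_m_su = pget(pv, "k_m_su"); K_S_su = pget(pv, "K_S_su");
  k_m_aa = pget(pv, "k_m_aa"); K_S_aa = pget(pv, "K_S_aa");
  k_m_fa = pget(pv, "k_m_fa"); K_S_fa = pget(pv, "K_S_fa");
  K_I_h2_fa = pget(pv, "K_I_h2_fa");
  k_m_c4 = pget(pv, "k_m_c4"); K_S_c4 = pget(pv, "K_S_c4");
  K_I_h2_c4 = pget(pv, "K_I_h2_c4");
  k_m_pro = pget(pv, "k_m_pro"); K_S_pro = pget(pv, "K_S_pro");
  K_I_h2_pro = pget(pv, "K_I_h2_pro");
  k_m_ac = pget(pv, "k_m_ac"); K_S_ac = pget(pv, "K_S_ac");
  K_I_nh3 = pget(pv, "K_I_nh3");
  k_m_h2 = pget(pv, "k_m_h2"); K_S_h2 = pget(pv, "K_S_h2");
  const char* decs[7] = {"k_dec_Xsu", "k_dec_Xaa", "k_dec_Xfa", "k_dec_Xc4",
                         "k_dec_Xpro", "k_dec_Xac", "k_dec_Xh2"};
  for (int i = 0; i < 7; ++i) k_dec[i] = pget(pv, decs[i]);
  Y_su = pget(pv, "Y_su"); Y_aa = pget(pv, "Y_aa"); Y_fa = pget(pv, "Y_fa");
  Y_c4 = pget(pv, "Y_c4"); Y_pro = pget(pv, "Y_pro"); Y_ac = pget(pv, "Y_ac");
  Y_h2 = pget(pv, "Y_h2");
  f_sI_xc = pget(pv, "f_sI_xc"); f_ch_xc = pget(pv, "f_ch_xc");
  f_pr_xc = pget(pv, "f_pr_xc"); f_li_xc = pget(pv, "f_li_xc");
  f_xI_xc = pget(pv, "f_xI_xc"); f_fa_li = pget(pv, "f_fa_li");
  f_h2_su = pget(pv, "f_h2_su"); f_bu_su = pget(pv, "f_bu_su");
  f_pro_su = pget(pv, "f_pro_su"); f_ac_su = pget(pv, "f_ac_su");
  f_h2_aa = pget(pv, "f_h2_aa"); f_va_aa = pget(pv, "f_va_aa");
  f_bu_aa = pget(pv, "f_bu_aa"); f_pro_aa = pget(pv, "f_pro_aa");
  f_ac_aa = pget(pv, "f_ac_aa");
  f_ac_fa = pget(pv, "f_ac_fa"); f_h2_fa = pget(pv, "f_h2_fa");
  f_pro_va = pget(pv, "f_pro_va"); f_ac_va = pget(pv, "f_ac_va");
  f_h2_va = pget(pv, "f_h2_va");
  f_ac_bu = pget(pv, "f_ac_bu"); f_h2_bu = pget(pv, "f_h2_bu");
  f_ac_pro = pget(pv, "f_ac_pro"); f_h2_pro = pget(pv, "f_h2_pro");
  N_xc = pget(pv, "N_xc"); N_I = pget(pv, "N_I"); N_aa = pget(pv, "N_aa");
  N_bac = pget(pv, "N_bac");
  C_su = pget(pv, "C_su"); C_aa = pget(pv, "C_aa"); C_fa = pget(pv, "C_fa");
  C_va = pget(pv, "C_va"); C_bu = pget(pv, "C_bu"); C_pro = pget(pv, "C_pro");
  C_ac = pget(pv, "C_ac"); C_ch4 = pget(pv, "C_ch4"); C_sI = pget(pv, "C_sI");
  C_xc = pget(pv, "C_xc"); C_ch = pget(pv, "C_ch"); C_pr = pget(pv, "C_pr");
  C_li = pget(pv, "C_li"); C_xI = pget(pv, "C_xI"); C_bac = pget(pv, "C_bac");
  pH_UL_aa = pget(pv, "pH_UL_aa"); pH_LL_aa = pget(pv, "pH_LL_aa");
  pH_UL_ac = pget(pv, "pH_UL_ac"); pH_LL_ac = pget(pv, "pH_LL_ac");
  pH_UL_h2 = pget(pv, "pH_UL_h2"); pH_LL_h2 = pget(pv, "pH_LL_h2");
  T_base = pget(pv, "T_base"); T_op = pget(pv, "T_op");
  k_L_a = pget(pv, "k_L_a"); k_p = pget(pv, "k_p"); P_atm = pget(pv, "P_atm");

  // van 't Hoff temperature correction from T_base; R expressed in J/(mol K)
  const double RJ = 8.3145;
  double fac = (1.0 / T_base - 1.0 / T_op) / RJ;
  K_w    = 1e-14 * std::exp(55900.0 * fac);
  K_a_va  = std::pow(10.0, -4.86);
  K_a_bu  = std::pow(10.0, -4.82);
  K_a_pro = std::pow(10.0, -4.88);
  K_a_ac  = std::pow(10.0, -4.76);
  K_a_co2 = std::pow(10.0, -6.35) * std::exp(7646.0 * fac);
  K_a_IN  = std::pow(10.0, -9.25) * std::exp(51965.0 * fac);
  K_H_h2  = 7.8e-4 * std::exp(-4180.0 * fac);
  K_H_ch4 = 1.4e-3 * std::exp(-14240.0 * fac);
  K_H_co2 = 3.5e-2 * std::exp(-19410.0 * fac);
  p_h2o = 0.0313 * std::exp(5290.0 * (1.0 / 298.15 - 1.0 / T_op));

  // stoichiometric matrix; IC and IN rows closed by C and N balance
  nu.zeros(NLIQ, NPROC);
  arma::mat& v = nu;
  // p0 disintegration
  v(iXc, 0) = -1; v(iSi, 0) = f_sI_xc; v(iXch, 0) = f_ch_xc;
  v(iXpr, 0) = f_pr_xc; v(iXli, 0) = f_li_xc; v(iXi, 0) = f_xI_xc;
  // p1-p3 hydrolysis
  v(iXch, 1) = -1; v(iSsu, 1) = 1;
  v(iXpr, 2) = -1; v(iSaa, 2) = 1;
  v(iXli, 3) = -1; v(iSsu, 3) = 1 - f_fa_li; v(iSfa, 3) = f_fa_li;
  // p4 uptake sugars
  v(iSsu, 4) = -1; v(iSbu, 4) = (1 - Y_su) * f_bu_su;
  v(iSpro, 4) = (1 - Y_su) * f_pro_su; v(iSac, 4) = (1 - Y_su) * f_ac_su;
  v(iSh2, 4) = (1 - Y_su) * f_h2_su; v(iXsu, 4) = Y_su;
  // p5 uptake amino acids
  v(iSaa, 5) = -1; v(iSva, 5) = (1 - Y_aa) * f_va_aa;
  v(iSbu, 5) = (1 - Y_aa) * f_bu_aa; v(iSpro, 5) = (1 - Y_aa) * f_pro_aa;
  v(iSac, 5) = (1 - Y_aa) * f_ac_aa; v(iSh2, 5) = (1 - Y_aa) * f_h2_aa;
  v(iXaa, 5) = Y_aa;
  // p6 uptake LCFA
  v(iSfa, 6) = -1; v(iSac, 6) = (1 - Y_fa) * f_ac_fa;
  v(iSh2, 6) = (1 - Y_fa) * f_h2_fa; v(iXfa, 6) = Y_fa;
  // p7 uptake valerate
  v(iSva, 7) = -1; v(iSpro, 7) = (1 - Y_c4) * f_pro_va;
  v(iSac, 7) = (1 - Y_c4) * f_ac_va; v(iSh2, 7) = (1 - Y_c4) * f_h2_va;
  v(iXc4, 7) = Y_c4;
  // p8 uptake butyrate
  v(iSbu, 8) = -1; v(iSac, 8) = (1 - Y_c4) * f_ac_bu;
  v(iSh2, 8) = (1 - Y_c4) * f_h2_bu; v(iXc4, 8) = Y_c4;
  // p9 uptake propionate
  v(iSpro, 9) = -1; v(iSac, 9) = (1 - Y_pro) * f_ac_pro;
  v(iSh2, 9) = (1 - Y_pro) * f_h2_pro; v(iXpro, 9) = Y_pro;
  // p10 uptake acetate, p11 uptake hydrogen
  v(iSac, 10) = -1; v(iSch4, 10) = 1 - Y_ac; v(iXac, 10) = Y_ac;
  v(iSh2, 11) = -1; v(iSch4, 11) = 1 - Y_h2; v(iXh2, 11) = Y_h2;
  // p12-p18 decay to composites
  int xbio[7] = {iXsu, iXaa, iXfa, iXc4, iXpro, iXac, iXh2};
  for (int k = 0; k < 7; ++k) { v(xbio[k], 12 + k) = -1; v(iXc, 12 + k) = 1; }

  // close carbon and nitrogen balances via S_IC / S_IN
  arma::vec Cc(NLIQ, arma::fill::zeros), Nn(NLIQ, arma::fill::zeros);
  Cc(iSsu) = C_su; Cc(iSaa) = C_aa; Cc(iSfa) = C_fa; Cc(iSva) = C_va;
  Cc(iSbu) = C_bu; Cc(iSpro) = C_pro; Cc(iSac) = C_ac; Cc(iSch4) = C_ch4;
  Cc(iSi) = C_sI; Cc(iXc) = C_xc; Cc(iXch) = C_ch; Cc(iXpr) = C_pr;
  Cc(iXli) = C_li; Cc(iXi) = C_xI;
  for (int k = 0; k < 7; ++k) Cc(xbio[k]) = C_bac;
  Nn(iSaa) = N_aa; Nn(iSi) = N_I; Nn(iXc) = N_xc; Nn(iXpr) = N_aa;
  Nn(iXi) = N_I;
  for (int k = 0; k < 7; ++k) Nn(xbio[k]) = N_bac;
  for (int j = 0; j < NPROC; ++j) {
    double cbal = 0, nbal = 0;
    for (int i = 0; i < NLIQ; ++i) { cbal += Cc(i) * v(i, j); nbal += Nn(i) * v(i, j); }
    v(iSic, j) = -cbal;
    v(iSin, j) = -nbal;
  }
}

// ---- speciation -------------------------------------------------------------
// Charge balance: S_cat + S_nh4 + h - S_hco3 - sum(organic anions) - S_an - OH = 0
// Monotone increasing in h; safeguarded Newton on [1e-14, 1].
struct Speciation {
  double h, pH, S_hco3, S_co2, S_nh3, S_nh4;
  double S_va_ion, S_bu_ion, S_pro_ion, S_ac_ion;
  double residual;
  bool ok;
};

static Speciation solve_speciation_c(const double* y, const ADM1P& P) {
  double Sva = std::max(y[iSva], 0.0) / COD_VA;
  double Sbu = std::max(y[iSbu], 0.0) / COD_BU;
  double Spro = std::max(y[iSpro], 0.0) / COD_PRO;
  double Sac = std::max(y[iSac], 0.0) / COD_AC;
  double Sic = std::max(y[iSic], 0.0), Sin = std::max(y[iSin], 0.0);
  double Scat = std::max(y[iScat], 0.0), San = std::max(y[iSan], 0.0);

  auto bal = [&](double h) {
    return Scat + Sin * h / (h + P.K_a_IN) + h
      - Sic * P.K_a_co2 / (h + P.K_a_co2)
      - Sac * P.K_a_ac / (h + P.K_a_ac)
      - Spro * P.K_a_pro / (h + P.K_a_pro)
      - Sbu * P.K_a_bu / (h + P.K_a_bu)
      - Sva * P.K_a_va / (h + P.K_a_va)
      - P.K_w / h - San;
  };
  auto dbal = [&](double h) {
    return 1.0 + Sin * P.K_a_IN / std::pow(h + P.K_a_IN, 2)
      + Sic * P.K_a_co2 / std::pow(h + P.K_a_co2, 2)
      + Sac * P.K_a_ac / std::pow(h + P.K_a_ac, 2)
      + Spro * P.K_a_pro / std::pow(h + P.K_a_pro, 2)
      + Sbu * P.K_a_bu / std::pow(h + P.K_a_bu, 2)
      + Sva * P.K_a_va / std::pow(h + P.K_a_va, 2)
      + P.K_w / (h * h);
  };

  Speciation fail;
  fail.ok = false; fail.h = NA_REAL; fail.pH = NA_REAL;
  for (int i = 0; i < NLIQ; ++i)
    if (!std::isfinite(y[i])) return fail;
  double lo = 1e-14, hi = 1.0;
  // an absurdly concentrated (diverged-Newton) state can break the bracket;
  // report failure and let the caller shrink its step
  if (bal(lo) > 0 || bal(hi) < 0) return fail;
  double h = 1e-7;
  for (int it = 0; it < 200; ++it) {
    double f = bal(h);
    if (std::fabs(f) < 1e-14) break;
    if (f > 0) hi = h; else lo = h;
    double step = f / dbal(h);
    double hn = h - step;
    if (!(hn > lo && hn < hi)) hn = 0.5 * (lo + hi);  // bisection safeguard
    if (std::fabs(hn - h) < 1e-18 * h) { h = hn; break; }
    h = hn;
  }
  Speciation s;
  s.ok = true;
  s.h = h; s.pH = -std::log10(h);
  s.S_hco3 = Sic * P.K_a_co2 / (h + P.K_a_co2);
  s.S_co2 = Sic - s.S_hco3;
  s.S_nh4 = Sin * h / (h + P.K_a_IN);
  s.S_nh3 = Sin - s.S_nh4;
  s.S_va_ion = Sva * P.K_a_va / (h + P.K_a_va) * COD_VA;
  s.S_bu_ion = Sbu * P.K_a_bu / (h + P.K_a_bu) * COD_BU;
  s.S_pro_ion = Spro * P.K_a_pro / (h + P.K_a_pro) * COD_PRO;
  s.S_ac_ion = Sac * P.K_a_ac / (h + P.K_a_ac) * COD_AC;
  s.residual = bal(h);
  return s;
}

// ---- inhibition and process rates ------------------------------------------
struct Inhib {
  double pH_aa, pH_ac, pH_h2, IN_lim, h2_fa, h2_c4, h2_pro, nh3;
};

static double ph_inhib_lower(double pH, double UL, double LL) {
  if (pH >= UL) return 1.0;
  double x = (pH - UL) / (UL - LL);
  return std::exp(-3.0 * x * x);
}

static Inhib inhibition_c(const double* y, const Speciation& sp, const ADM1P& P) {
  Inhib I;
  I.pH_aa = ph_inhib_lower(sp.pH, P.pH_UL_aa, P.pH_LL_aa);
  I.pH_ac = ph_inhib_lower(sp.pH, P.pH_UL_ac, P.pH_LL_ac);
  I.pH_h2 = ph_inhib_lower(sp.pH, P.pH_UL_h2, P.pH_LL_h2);
  double Sin = std::max(y[iSin], 0.0);
  I.IN_lim = Sin / (Sin + P.K_S_IN);
  double Sh2 = std::max(y[iSh2], 0.0);
  I.h2_fa = 1.0 / (1.0 + Sh2 / P.K_I_h2_fa);
  I.h2_c4 = 1.0 / (1.0 + Sh2 / P.K_I_h2_c4);
  I.h2_pro = 1.0 / (1.0 + Sh2 / P.K_I_h2_pro);
  I.nh3 = 1.0 / (1.0 + sp.S_nh3 / P.K_I_nh3);
  return I;
}

static void process_rates_c(const double* y, const ADM1P& P,
                            const Speciation& sp, double* rho) {
  Inhib I = inhibition_c(y, sp, P);
  auto pos = [&](int i) { return std::max(y[i], 0.0); };
  auto monod = [](double s, double K) { return s / (K + s); };
  rho[0] = P.k_dis * pos(iXc);
  rho[1] = P.k_hyd_ch * pos(iXch);
  rho[2] = P.k_hyd_pr * pos(iXpr);
  rho[3] = P.k_hyd_li * pos(iXli);
  double I56 = I.pH_aa * I.IN_lim;
  rho[4] = P.k_m_su * monod(pos(iSsu), P.K_S_su) * pos(iXsu) * I56;
  rho[5] = P.k_m_aa * monod(pos(iSaa), P.K_S_aa) * pos(iXaa) * I56;
  rho[6] = P.k_m_fa * monod(pos(iSfa), P.K_S_fa) * pos(iXfa) * I56 * I.h2_fa;
  double Sva = pos(iSva), Sbu = pos(iSbu);
  double comp_va = Sva / (Sva + Sbu + 1e-6), comp_bu = Sbu / (Sva + Sbu + 1e-6);
  rho[7] = P.k_m_c4 * monod(Sva, P.K_S_c4) * pos(iXc4) * comp_va * I56 * I.h2_c4;
  rho[8] = P.k_m_c4 * monod(Sbu, P.K_S_c4) * pos(iXc4) * comp_bu * I56 * I.h2_c4;
  rho[9] = P.k_m_pro * monod(pos(iSpro), P.K_S_pro) * pos(iXpro) * I56 * I.h2_pro;
  rho[10] = P.k_m_ac * monod(pos(iSac), P.K_S_ac) * pos(iXac)
            * I.pH_ac * I.IN_lim * I.nh3;
  rho[11] = P.k_m_h2 * monod(pos(iSh2), P.K_S_h2) * pos(iXh2)
            * I.pH_h2 * I.IN_lim;
  int xbio[7] = {iXsu, iXaa, iXfa, iXc4, iXpro, iXac, iXh2};
  for (int k = 0; k < 7; ++k) rho[12 + k] = P.k_dec[k] * pos(xbio[k]);
}

// gas transfer rates (per unit liquid volume, 1/d); h2/ch4 in kgCOD/m3/d,
// co2 in kmol/m3/d
static void gas_transfer_c(const double* y, const ADM1P& P,
                           const Speciation& sp, double* rhoT, double* pgas,
                           double* Ptot) {
  double p_h2 = std::max(y[NLIQ + 0], 0.0) / COD_H2 * RGAS * P.T_op;
  double p_ch4 = std::max(y[NLIQ + 1], 0.0) / COD_CH4 * RGAS * P.T_op;
  double p_co2 = std::max(y[NLIQ + 2], 0.0) * RGAS * P.T_op;
  rhoT[0] = P.k_L_a * (std::max(y[iSh2], 0.0) - COD_H2 * P.K_H_h2 * p_h2);
  rhoT[1] = P.k_L_a * (std::max(y[iSch4], 0.0) - COD_CH4 * P.K_H_ch4 * p_ch4);
  rhoT[2] = P.k_L_a * (sp.S_co2 - P.K_H_co2 * p_co2);
  pgas[0] = p_h2; pgas[1] = p_ch4; pgas[2] = p_co2;
  *Ptot = p_h2 + p_ch4 + p_co2 + P.p_h2o;
}

// ---- network derivative -----------------------------------------------------
struct Network {
  int n_tanks;
  arma::vec V_liq, V_gas, srf;   // L, L, dimensionless >= 1
};

// segments: rows (t_start, t_end, q_L_d, Sin[0..25])
static int find_segment(double t, const arma::mat& seg) {
  int n = seg.n_rows;
  for (int i = 0; i < n; ++i)
    if (t < seg(i, 1) - 1e-12) return i;
  return n - 1;
}

static void network_deriv_c(double t, const double* y, double* dy,
                            const ADM1P& P, const Network& net,
                            const arma::mat& seg) {
  int is = find_segment(t, seg);
  double q = seg(is, 2);
  double rho[NPROC], rhoT[NGAS], pgas[NGAS], Ptot;

  // influent fluxes into tank 1 (g/d or kmol/d)
  std::vector<double> influx(NLIQ);
  for (int i = 0; i < NLIQ; ++i) influx[i] = q * seg(is, 3 + i);

  for (int k = 0; k < net.n_tanks; ++k) {
    const double* yk = y + k * NTS;
    double* dyk = dy + k * NTS;
    double V = net.V_liq(k), Vg = net.V_gas(k), srf = net.srf(k);

    Speciation sp = solve_speciation_c(yk, P);
    if (!sp.ok) {  // poison the derivative so the integrator rejects the step
      for (int i = 0; i < net.n_tanks * NTS; ++i) dy[i] = NA_REAL;
      return;
    }
    process_rates_c(yk, P, sp, rho);
    gas_transfer_c(yk, P, sp, rhoT, pgas, &Ptot);

    // biochemistry
    for (int i = 0; i < NLIQ; ++i) {
      double b = 0;
      for (int j = 0; j < NPROC; ++j) b += P.nu(i, j) * rho[j];
      dyk[i] = b;
    }
    // gas-liquid transfer
    dyk[iSh2]  -= rhoT[0];
    dyk[iSch4] -= rhoT[1];
    dyk[iSic]  -= rhoT[2];

    // advection: soluble components flow with the liquid; particulates are
    // retained by the granular bed (outflow divided by srf)
    for (int i = 0; i < NLIQ; ++i) {
      bool part = (i >= iXc && i <= iXi);
      double out = part ? q * std::max(yk[i], 0.0) / srf
                        : q * std::max(yk[i], 0.0);
      dyk[i] += (influx[i] - out) / V;
      influx[i] = out;  // becomes the next tank's influent flux
    }

    // headspace: transfer in, pressure-driven outflow
    double qgas = P.k_p * V * std::max(Ptot - P.P_atm, 0.0); // L/d
    double Sgh2 = std::max(yk[NLIQ + 0], 0.0);
    double Sgch4 = std::max(yk[NLIQ + 1], 0.0);
    double Sgco2 = std::max(yk[NLIQ + 2], 0.0);
    dyk[NLIQ + 0] = -Sgh2 * qgas / Vg + rhoT[0] * V / Vg;
    dyk[NLIQ + 1] = -Sgch4 * qgas / Vg + rhoT[1] * V / Vg;
    dyk[NLIQ + 2] = -Sgco2 * qgas / Vg + rhoT[2] * V / Vg;
    // bookkeeping: cumulative gas COD (g) and gas volume (L) leaving tank k
    dyk[NLIQ + 3] = qgas * (Sgh2 + Sgch4);
    dyk[NLIQ + 4] = qgas;
  }
}

// ---- stiff integrator -------------------------------------------------------
// Backward Euler with step doubling: one full step and two half steps per
// attempted step; the difference gives the error estimate and Richardson
// extrapolation a second-order accepted value. Modified Newton with lazily
// refreshed finite-difference Jacobian and reused LU factorizations.
struct Stepper {
  const ADM1P& P;
  const Network& net;
  const arma::mat& seg;
  int n;
  double rtol, atol;
  arma::mat J;            // cached Jacobian of f
  bool have_J = false;
  arma::mat Lf, Uf; arma::umat Pf; // LU of (I - h J)
  double h_fac = -1.0;
  long nfev = 0, njac = 0, nlu = 0, nstep = 0, nreject = 0;

  Stepper(const ADM1P& P_, const Network& net_, const arma::mat& seg_,
          int n_, double rtol_, double atol_)
    : P(P_), net(net_), seg(seg_), n(n_), rtol(rtol_), atol(atol_) {}

  void f(double t, const arma::vec& y, arma::vec& dy) {
    network_deriv_c(t, y.memptr(), dy.memptr(), P, net, seg);
    ++nfev;
  }

  double wrms(const arma::vec& e, const arma::vec& y) {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double w = atol + rtol * std::fabs(y(i));
      s += std::pow(e(i) / w, 2);
    }
    return std::sqrt(s / n);
  }

  void numjac(double t, const arma::vec& y, const arma::vec& f0) {
    J.set_size(n, n);
    arma::vec yp = y, fp(n);
    for (int j = 0; j < n; ++j) {
      double d = std::max(1.5e-8 * std::fabs(y(j)), 1e-10);
      yp(j) = y(j) + d;
      f(t, yp, fp);
      J.col(j) = (fp - f0) / d;
      yp(j) = y(j);
    }
    ++njac;
  }

  bool factor(double h) {
    arma::mat M = arma::eye(n, n) - h * J;
    arma::mat Lm, Um, Pm;
    if (!arma::lu(Lm, Um, Pm, M)) return false;
    if (arma::any(arma::abs(Um.diag()) < 1e-300)) return false;
    Lf = Lm; Uf = Um;
    Pmat = Pm;
    h_fac = h;
    ++nlu;
    return true;
  }
  arma::mat Pmat;

  arma::vec lusolve(const arma::vec& b) {
    arma::vec z = arma::solve(arma::trimatl(Lf), Pmat * b);
    return arma::solve(arma::trimatu(Uf), z);
  }

  // one backward-Euler solve: y_out solves y_out = y0 + h f(t1, y_out)
  bool be_solve(double t1, const arma::vec& y0, double h,
                const arma::vec& ypred, arma::vec& yout) {
    if (std::fabs(h - h_fac) > 1e-12 * h_fac)
      if (!factor(h)) return false;
    arma::vec yk = ypred, fk(n);
    if (!yk.is_finite()) return false;
    for (int it = 0; it < 10; ++it) {
      f(t1, yk, fk);
      if (!fk.is_finite()) return false;
      arma::vec res = y0 + h * fk - yk;
      arma::vec d = lusolve(res);
      yk += d;
      if (!yk.is_finite()) return false;
      if (wrms(d, yk) < 0.02) { yout = yk; return true; }
    }
    return false;
  }
};

// integrate from t0 to t1 writing cubic-Hermite interpolated output
// [[Rcpp::export]]
List cpp_simulate(NumericVector y0_, NumericVector params,
                  NumericVector V_liq_, NumericVector V_gas_,
                  NumericVector srf_, NumericMatrix segments_,
                  NumericVector t_eval_, double rtol, double atol,
                  double h_init, double max_steps) {
  ADM1P P; P.build(params);
  Network net;
  net.n_tanks = V_liq_.size();
  net.V_liq = as<arma::vec>(V_liq_);
  net.V_gas = as<arma::vec>(V_gas_);
  net.srf = as<arma::vec>(srf_);
  arma::mat seg = as<arma::mat>(segments_);
  arma::vec t_eval = as<arma::vec>(t_eval_);
  int n = y0_.size();
  if (n != net.n_tanks * NTS) stop("state vector length mismatch");

  Stepper S(P, net, seg, n, rtol, atol);
  arma::vec y = as<arma::vec>(y0_), f0(n), f1(n);
  double t = t_eval.min();
  double t_end = t_eval.max();
  arma::mat out(t_eval.n_elem, n);
  arma::uword iout = 0;
  // emit initial point(s)
  while (iout < t_eval.n_elem && t_eval(iout) <= t + 1e-14) {
    out.row(iout) = y.t(); ++iout;
  }

  double h = h_init;
  long n_clip = 0;
  S.f(t, y, f0);
  S.numjac(t, y, f0);
  int steps_since_jac = 0;

  while (t < t_end - 1e-12 && S.nstep < (long)max_steps) {
    // do not step across a segment boundary
    int is = find_segment(t, seg);
    double t_lim = std::min(seg(is, 1), t_end);
    if (t + h > t_lim) h = t_lim - t;
    if (h < 1e-14) { t = t_lim; S.f(t, y, f0); S.numjac(t, y, f0); continue; }

    arma::vec yfull(n), yh1(n), yh2(n);
    bool ok = S.be_solve(t + h, y, h, y + h * f0, yfull);
    if (ok) ok = S.be_solve(t + h / 2, y, h / 2, y + 0.5 * h * f0, yh1);
    if (ok) ok = S.be_solve(t + h, yh1, h / 2, yfull, yh2);
    if (!ok) {
      // refresh Jacobian once, else shrink the step
      if (steps_since_jac > 0) {
        S.f(t, y, f0); S.numjac(t, y, f0); steps_since_jac = 0;
        S.h_fac = -1;
      } else {
        h *= 0.25;
        if (h < 1e-13) stop("integrator step size underflow");
      }
      ++S.nreject;
      continue;
    }

    arma::vec est = yh2 - yfull;
    double err = S.wrms(est, yh2) / 0.5;  // error of the half-step solution
    if (err <= 1.0) {
      arma::vec ynew = 2.0 * yh2 - yfull; // Richardson, 2nd order
      for (int i = 0; i < n; ++i)
        if (ynew(i) < 0) { if (ynew(i) < -1e-6) ++n_clip; ynew(i) = 0; }
      double tnew = t + h;
      S.f(tnew, ynew, f1);
      // cubic Hermite output on (t, tnew)
      while (iout < t_eval.n_elem && t_eval(iout) <= tnew + 1e-12) {
        double s = (t_eval(iout) - t) / h;
        double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
        double h10 = s * (1 - s) * (1 - s);
        double h01 = s * s * (3 - 2 * s);
        double h11 = s * s * (s - 1);
        arma::vec yi = h00 * y + h10 * h * f0 + h01 * ynew + h11 * h * f1;
        out.row(iout) = yi.t();
        ++iout;
      }
      t = tnew; y = ynew; f0 = f1;
      ++S.nstep; ++steps_since_jac;
      if (steps_since_jac > 25) {
        S.numjac(t, y, f0); steps_since_jac = 0; S.h_fac = -1;
      }
      double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(err + 1e-12, -0.5)));
      if (fac > 1.2 || fac < 1.0) h *= fac;   // avoid refactoring for tiny gains
    } else {
      ++S.nreject;
      h *= std::max(0.1, 0.9 * std::pow(err, -0.5));
      if (steps_since_jac > 5) { S.numjac(t, y, f0); steps_since_jac = 0; S.h_fac = -1; }
    }
  }
  if (t < t_end - 1e-10)
    stop("integration failed: max_steps reached at t = %f d", t);

  // diagnostics at output points: pH and gas flow per tank
  arma::mat pH_out(t_eval.n_elem, net.n_tanks);
  arma::mat qgas_out(t_eval.n_elem, net.n_tanks);
  double rhoT[NGAS], pgas[NGAS], Ptot;
  for (arma::uword r = 0; r < t_eval.n_elem; ++r) {
    for (int k = 0; k < net.n_tanks; ++k) {
      arma::rowvec yk = out.row(r).cols(k * NTS, k * NTS + NTS - 1);
      std::vector<double> ykv(yk.begin(), yk.end());
      Speciation sp = solve_speciation_c(ykv.data(), P);
      gas_transfer_c(ykv.data(), P, sp, rhoT, pgas, &Ptot);
      pH_out(r, k) = sp.pH;
      qgas_out(r, k) = P.k_p * net.V_liq(k) * std::max(Ptot - P.P_atm, 0.0);
    }
  }

  return List::create(
    _["y"] = wrap(out), _["t"] = wrap(t_eval),
    _["pH"] = wrap(pH_out), _["q_gas"] = wrap(qgas_out),
    _["n_steps"] = (double)S.nstep, _["n_reject"] = (double)S.nreject,
    _["n_fev"] = (double)S.nfev, _["n_jac"] = (double)S.njac,
    _["n_clip"] = (double)n_clip);
}

// ---- thin wrappers for the module surface ----------------------------------

// [[Rcpp::export]]
List cpp_speciation(NumericVector y_liq, NumericVector params) {
  ADM1P P; P.build(params);
  if (y_liq.size() < NLIQ) stop("need %d liquid components", NLIQ);
  Speciation s = solve_speciation_c(REAL(y_liq), P);
  if (!s.ok) stop("speciation failure: no charge-balance root in (1e-14, 1)");
  return List::create(
    _["pH"] = s.pH, _["h_ion"] = s.h, _["residual"] = s.residual,
    _["S_hco3_ion"] = s.S_hco3, _["S_co2"] = s.S_co2,
    _["S_nh3"] = s.S_nh3, _["S_nh4_ion"] = s.S_nh4,
    _["S_va_ion"] = s.S_va_ion, _["S_bu_ion"] = s.S_bu_ion,
    _["S_pro_ion"] = s.S_pro_ion, _["S_ac_ion"] = s.S_ac_ion);
}

// [[Rcpp::export]]
List cpp_inhibition(NumericVector y_liq, NumericVector params) {
  ADM1P P; P.build(params);
  Speciation s = solve_speciation_c(REAL(y_liq), P);
  if (!s.ok) stop("speciation failure: no charge-balance root in (1e-14, 1)");
  Inhib I = inhibition_c(REAL(y_liq), s, P);
  return List::create(
    _["pH_aa"] = I.pH_aa, _["pH_ac"] = I.pH_ac, _["pH_h2"] = I.pH_h2,
    _["IN_lim"] = I.IN_lim, _["h2_fa"] = I.h2_fa, _["h2_c4"] = I.h2_c4,
    _["h2_pro"] = I.h2_pro, _["nh3"] = I.nh3, _["pH"] = s.pH);
}

// [[Rcpp::export]]
NumericVector cpp_process_rates(NumericVector y_liq, NumericVector params) {
  ADM1P P; P.build(params);
  Speciation s = solve_speciation_c(REAL(y_liq), P);
  if (!s.ok) stop("speciation failure: no charge-balance root in (1e-14, 1)");
  double rho[NPROC];
  process_rates_c(REAL(y_liq), P, s, rho);
  return NumericVector(rho, rho + NPROC);
}

// [[Rcpp::export]]
NumericVector cpp_biochem_deriv(NumericVector y_liq, NumericVector params) {
  ADM1P P; P.build(params);
  Speciation s = solve_speciation_c(REAL(y_liq), P);
  if (!s.ok) stop("speciation failure: no charge-balance root in (1e-14, 1)");
  double rho[NPROC];
  process_rates_c(REAL(y_liq), P, s, rho);
  NumericVector dy(NLIQ);
  for (int i = 0; i < NLIQ; ++i) {
    double b = 0;
    for (int j = 0; j < NPROC; ++j) b += P.nu(i, j) * rho[j];
    dy[i] = b;
  }
  return dy;
}

// [[Rcpp::export]]
List cpp_gas_transfer(NumericVector y_tank, NumericVector params) {
  ADM1P P; P.build(params);
  if (y_tank.size() < NLIQ + NGAS) stop("need %d tank states", NLIQ + NGAS);
  Speciation s = solve_speciation_c(REAL(y_tank), P);
  if (!s.ok) stop("speciation failure: no charge-balance root in (1e-14, 1)");
  double rhoT[NGAS], pgas[NGAS], Ptot;
  gas_transfer_c(REAL(y_tank), P, s, rhoT, pgas, &Ptot);
  return List::create(
    _["rho_T_h2"] = rhoT[0], _["rho_T_ch4"] = rhoT[1], _["rho_T_co2"] = rhoT[2],
    _["p_h2"] = pgas[0], _["p_ch4"] = pgas[1], _["p_co2"] = pgas[2],
    _["P_total"] = Ptot);
}

// [[Rcpp::export]]
NumericVector cpp_network_deriv(double t, NumericVector y, NumericVector params,
                                NumericVector V_liq_, NumericVector V_gas_,
                                NumericVector srf_, NumericMatrix segments_) {
  ADM1P P; P.build(params);
  Network net;
  net.n_tanks = V_liq_.size();
  net.V_liq = as<arma::vec>(V_liq_);
  net.V_gas = as<arma::vec>(V_gas_);
  net.srf = as<arma::vec>(srf_);
  arma::mat seg = as<arma::mat>(segments_);
  if (y.size() != net.n_tanks * NTS) stop("state vector length mismatch");
  NumericVector dy(y.size());
  network_deriv_c(t, REAL(y), REAL(dy), P, net, seg);
  return dy;
}

// [[Rcpp::export]]
NumericMatrix cpp_stoichiometry(NumericVector params) {
  ADM1P P; P.build(params);
  return wrap(P.nu);
}
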