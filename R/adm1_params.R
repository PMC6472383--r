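#' ADM1 parameter set
#'
#' Returns the full kinetic / stoichiometric / physico-chemical constant set
#' for Anaerobic Digestion Model No. 1 at mesophilic conditions (operating
#' temperature 310.15 K), in the standard realisation used by the benchmark
#' simulation community. Units: first-order and maximum-uptake constants 1/d,
#' half-saturation constants kgCOD/m3 (inorganic nitrogen kmol/m3), inhibition
#' constants kmol/m3, carbon/nitrogen contents kmol per kgCOD, gas transfer
#' coefficient 1/d.
#'
#' `preset = "calibrated"` overlays the four Monod constants calibrated for a
#' lab-scale glucose-fed internal-circulation reactor:
#' `k_m_ac = 13.13`, `k_m_pro = 9.90`, `K_S_ac = 0.14`, `K_S_pro = 0.30`.
#'
#' @param preset `"mesophilic"` (defaults) or `"calibrated"`.
#' @param ... named overrides applied on top of the preset.
#' @return a named list of class `adm1_params`.
#' @export
adm1_params <- function(preset = c("mesophilic", "calibrated"), ...) {
  preset <- match.arg(preset)
  p <- list(
    # first-order constants (1/d)
    k_dis = 0.5, k_hyd_ch = 10, k_hyd_pr = 10, k_hyd_li = 10,
    k_dec_Xsu = 0.02, k_dec_Xaa = 0.02, k_dec_Xfa = 0.02, k_dec_Xc4 = 0.02,
    k_dec_Xpro = 0.02, k_dec_Xac = 0.02, k_dec_Xh2 = 0.02,
    # Monod uptake kinetics
    k_m_su = 30, K_S_su = 0.5,
    k_m_aa = 50, K_S_aa = 0.3,
    k_m_fa = 6, K_S_fa = 0.4, K_I_h2_fa = 5e-6,
    k_m_c4 = 20, K_S_c4 = 0.2, K_I_h2_c4 = 1e-5,
    k_m_pro = 13, K_S_pro = 0.1, K_I_h2_pro = 3.5e-6,
    k_m_ac = 8, K_S_ac = 0.15, K_I_nh3 = 0.0018,
    k_m_h2 = 35, K_S_h2 = 7e-6,
    K_S_IN = 1e-4,
    # yields (kgCOD biomass / kgCOD substrate)
    Y_su = 0.10, Y_aa = 0.08, Y_fa = 0.06, Y_c4 = 0.06, Y_pro = 0.04,
    Y_ac = 0.05, Y_h2 = 0.06,
    # product fractions
    f_sI_xc = 0.1, f_ch_xc = 0.2, f_pr_xc = 0.2, f_li_xc = 0.3, f_xI_xc = 0.2,
    f_fa_li = 0.95,
    f_h2_su = 0.19, f_bu_su = 0.13, f_pro_su = 0.27, f_ac_su = 0.41,
    f_h2_aa = 0.06, f_va_aa = 0.23, f_bu_aa = 0.26, f_pro_aa = 0.05,
    f_ac_aa = 0.40,
    f_ac_fa = 0.7, f_h2_fa = 0.3,
    f_pro_va = 0.54, f_ac_va = 0.31, f_h2_va = 0.15,
    f_ac_bu = 0.8, f_h2_bu = 0.2,
    f_ac_pro = 0.57, f_h2_pro = 0.43,
    # nitrogen and carbon contents (kmol per kgCOD)
    N_xc = 0.0376 / 14, N_I = 0.06 / 14, N_aa = 0.007, N_bac = 0.08 / 14,
    C_su = 0.0313, C_aa = 0.03, C_fa = 0.0217, C_va = 0.024, C_bu = 0.025,
    C_pro = 0.0268, C_ac = 0.0313, C_ch4 = 0.0156, C_sI = 0.03,
    C_xc = 0.02786, C_ch = 0.0313, C_pr = 0.03, C_li = 0.022, C_xI = 0.03,
    C_bac = 0.0313,
    # pH inhibition limits (lower-inhibition-only form)
    pH_UL_aa = 5.5, pH_LL_aa = 4, pH_UL_ac = 7, pH_LL_ac = 6,
    pH_UL_h2 = 6, pH_LL_h2 = 5,
    # physico-chemical
    T_base = 298.15, T_op = 310.15,
    k_L_a = 200,
    # headspace outflow resistance, L gas per d per bar overpressure per L liquid
    k_p = 3125,
    P_atm = 1.013)
  if (preset == "calibrated")
    p[c("k_m_ac", "k_m_pro", "K_S_ac", "K_S_pro")] <-
      list(13.13, 9.90, 0.14, 0.30)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown ADM1 parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "adm1_params")
}

#' @export
print.adm1_params <- function(x, ...) {
  cat(sprintf("<adm1_params> %d constants, T_op = %.2f K, k_m_ac = %.4g, K_S_ac = %.4g\n",
              length(unclass(x)), x$T_op, x$k_m_ac, x$K_S_ac))
  invisible(x)
}

# flatten to the named numeric vector the C++ core consumes
params_vector <- function(params) {
  stopifnot(inherits(params, "adm1_params"))
  unlist(unclass(params))
}

#' Read / write an ADM1 parameter set as flat key-value YAML
#'
#' @param path file path.
#' @export
read_adm1_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(adm1_params, c(list(preset = vals$preset %||% "mesophilic"),
                         vals[setdiff(names(vals), "preset")]))
}

#' @rdname read_adm1_params
#' @param params an [adm1_params()] object.
#' @export
write_adm1_params <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), function(v) v), path,
                   precision = 15)
  invisible(path)
}

# canonical component ordering shared with the C++ core
.adm1_liq_names <- c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac",
                     "S_h2", "S_ch4", "S_IC", "S_IN", "S_I",
                     "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa",
                     "X_c4", "X_pro", "X_ac", "X_h2", "X_I", "S_cat", "S_an")
.adm1_gas_names <- c("S_gas_h2", "S_gas_ch4", "S_gas_co2")
.adm1_aux_names <- c("cum_gas_cod", "cum_gas_vol")
.adm1_state_names <- c(.adm1_liq_names, .adm1_gas_names, .adm1_aux_names)

#' ADM1 state vector for one tank
#'
#' Builds a named state vector (26 liquid components, 3 headspace
#' concentrations, 2 bookkeeping accumulators) with all components defaulting
#' to zero. Concentrations are kgCOD/m3 except `S_IC`, `S_IN`, `S_cat`,
#' `S_an` and `S_gas_co2` (kmol/m3).
#'
#' @param ... named component values, e.g. `S_su = 3, S_IC = 0.1`.
#' @return named numeric vector of class `adm1_state`.
#' @export
adm1_state <- function(...) {
  y <- setNames(numeric(length(.adm1_state_names)), .adm1_state_names)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), .adm1_state_names)
    if (length(unknown))
      stop("unknown ADM1 state component(s): ", paste(unknown, collapse = ", "))
    if (any(unlist(dots) < 0)) stop("concentrations must be non-negative")
    y[names(dots)] <- unlist(dots)
  }
  structure(y, class = "adm1_state")
}

#' Benchmark-like seed state for reactor start-up
#'
#' A generic post-inoculation state for a granular-sludge anaerobic reactor:
#' moderate concentrations of the seven biomass groups, inorganic carbon and
#' nitrogen pools, and near-neutral pH. Used to initialise start-up
#' simulations; biomass is later distributed across tanks proportional to
#' volume.
#'
#' @param biomass_total total biomass concentration (kgCOD/m3) split across
#'   the seven groups in fixed benchmark-like proportions.
#' @export
adm1_seed_state <- function(biomass_total = 10) {
  share <- c(X_su = 0.25, X_aa = 0.08, X_fa = 0.05, X_c4 = 0.10,
             X_pro = 0.07, X_ac = 0.30, X_h2 = 0.15)
  args <- as.list(biomass_total * share)
  args <- c(args, list(S_IC = 0.10, S_IN = 0.01, S_cat = 0.045, S_an = 0.02,
                       S_ac = 0.1, S_pro = 0.02, X_I = 1.0,
                       S_gas_ch4 = 1.0, S_gas_co2 = 0.01))
  do.call(adm1_state, args)
}
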