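#' Monod uptake rate
#'
#' `rate = k_m * s / (k_s + s) * x * inhibition` — the substrate-uptake form
#' used by all eight ADM1 uptake processes.
#'
#' @param s substrate concentration (kgCOD/m3).
#' @param x biomass concentration (kgCOD/m3).
#' @param k_m maximum specific uptake rate (1/d).
#' @param k_s half-saturation constant (kgCOD/m3).
#' @param inhibition multiplicative inhibition factor in \[0, 1\].
#' @export
monod_rate <- function(s, x, k_m, k_s, inhibition = 1) {
  stopifnot(all(s >= 0), all(x >= 0), all(k_m >= 0), all(k_s >= 0))
  k_m * s / (k_s + s) * x * inhibition
}

#' First-order rate
#'
#' Used for disintegration, hydrolysis and biomass decay: `rate = k * x`.
#'
#' @param x concentration (kgCOD/m3).
#' @param k rate constant (1/d).
#' @export
first_order_rate <- function(x, k) {
  stopifnot(all(x >= 0), all(k >= 0))
  k * x
}

# coerce a user state to the full named per-tank vector
as_state_vector <- function(state) {
  if (inherits(state, "adm1_state")) return(unclass(state))
  if (is.numeric(state) && !is.null(names(state)))
    return(unclass(do.call(adm1_state, as.list(state))))
  stop("state must be an adm1_state or a named numeric vector")
}

#' Solve acid-base speciation and pH
#'
#' Solves the ion charge balance for the hydrogen-ion concentration with
#' instantaneous-equilibrium dissociation of the VFA acid/base pairs,
#' bicarbonate, ammonium and water, by safeguarded Newton iteration bracketed
#' on `(1e-14, 1)`. The returned residual charge is below 1e-12 kmol/m3.
#'
#' @param state an [adm1_state()] (or named vector of totals).
#' @param params an [adm1_params()].
#' @return list with `pH`, `h_ion`, ionised species concentrations, free CO2
#'   and ammonia, and the charge-balance `residual`.
#' @export
solve_speciation <- function(state, params = adm1_params()) {
  y <- as_state_vector(state)
  cpp_speciation(y, params_vector(params))
}

#' Per-process inhibition factors
#'
#' Lower-limit pH inhibition per trophic group, non-competitive hydrogen
#' inhibition, free-ammonia inhibition of the acetate step, and the inorganic
#' nitrogen growth limitation. All factors lie in \[0, 1\] and equal 1 when
#' the inhibitor is absent.
#'
#' @inheritParams solve_speciation
#' @export
inhibition_terms <- function(state, params = adm1_params()) {
  y <- as_state_vector(state)
  cpp_inhibition(y, params_vector(params))
}

#' The 19 ADM1 process rates
#'
#' Disintegration, three hydrolyses, eight Monod uptakes (with their
#' inhibition terms) and seven first-order biomass decays, in the canonical
#' process order.
#'
#' @inheritParams solve_speciation
#' @return named numeric vector of length 19 (1/d basis, kgCOD/m3/d).
#' @export
process_rates <- function(state, params = adm1_params()) {
  y <- as_state_vector(state)
  r <- cpp_process_rates(y, params_vector(params))
  names(r) <- c("disintegration", "hydrolysis_ch", "hydrolysis_pr",
                "hydrolysis_li", "uptake_su", "uptake_aa", "uptake_fa",
                "uptake_va", "uptake_bu", "uptake_pro", "uptake_ac",
                "uptake_h2", paste0("decay_", c("Xsu", "Xaa", "Xfa", "Xc4",
                                                "Xpro", "Xac", "Xh2")))
  r
}

#' Biochemical derivative contribution
#'
#' `sum_j rho_j nu_ij` over the 19 processes for the 26 liquid components.
#' The stoichiometric matrix closes elemental carbon and nitrogen balances
#' through the inorganic carbon and nitrogen pools, so COD, C and N are
#' conserved by this term alone (COD leaves only via gas transfer).
#'
#' @inheritParams solve_speciation
#' @return named derivative vector for the 26 liquid components (per day).
#' @export
biochemical_derivatives <- function(state, params = adm1_params()) {
  y <- as_state_vector(state)
  setNames(cpp_biochem_deriv(y, params_vector(params)), .adm1_liq_names)
}

#' Stoichiometric matrix of the biochemical network
#'
#' @param params an [adm1_params()].
#' @return 26 x 19 matrix (components x processes).
#' @export
adm1_stoichiometry <- function(params = adm1_params()) {
  m <- cpp_stoichiometry(params_vector(params))
  dimnames(m) <- list(.adm1_liq_names,
                      names(process_rates(adm1_state(S_IN = 1e-3), params)))
  m
}

#' Gas-liquid transfer rates
#'
#' `rho_T = k_L_a (S_liq - K_H p_gas)` per gas (hydrogen, methane, carbon
#' dioxide), with partial pressures from the headspace state via the ideal
#' gas law. Positive rates move mass from liquid to gas.
#'
#' @param state an [adm1_state()] including the `S_gas_*` components.
#' @param params an [adm1_params()].
#' @return list with the three transfer rates, partial pressures and total
#'   headspace pressure.
#' @export
gas_transfer <- function(state, params = adm1_params()) {
  y <- as_state_vector(state)
  cpp_gas_transfer(y, params_vector(params))
}

#' Soluble effluent COD of a state
#'
#' Sum of the soluble COD-carrying components
#' `S_su + S_aa + S_fa + S_va + S_bu + S_pro + S_ac + S_I` (g/L). Dissolved
#' gases are excluded; particulates are excluded by default because the
#' three-phase separator retains granules, but can be included.
#'
#' @inheritParams solve_speciation
#' @param include_particulates also count `X_*` components (default FALSE).
#' @export
effluent_cod <- function(state, include_particulates = FALSE) {
  y <- as_state_vector(state)
  val <- sum(y[c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac", "S_I")])
  if (include_particulates)
    val <- val + sum(y[c("X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa",
                         "X_c4", "X_pro", "X_ac", "X_h2", "X_I")])
  unname(val)
}

# COD equivalence weights over liquid components (1 for organics, 0 for
# inorganic pools); used by conservation checks
cod_weights <- function() {
  w <- setNames(rep(1, length(.adm1_liq_names)), .adm1_liq_names)
  w[c("S_IC", "S_IN", "S_cat", "S_an")] <- 0
  w
}
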