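# Shared fixtures and independent oracles, built in code.

# local composite trapezoid (tests must not reach into package internals)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# ADM1 parameter set with every reaction and gas-transfer constant zeroed:
# reduces the network to a linear advection chain (inert transport).
zero_kinetics_params <- function(...) {
  adm1_params(k_dis = 0, k_hyd_ch = 0, k_hyd_pr = 0, k_hyd_li = 0,
              k_m_su = 0, k_m_aa = 0, k_m_fa = 0, k_m_c4 = 0, k_m_pro = 0,
              k_m_ac = 0, k_m_h2 = 0,
              k_dec_Xsu = 0, k_dec_Xaa = 0, k_dec_Xfa = 0, k_dec_Xc4 = 0,
              k_dec_Xpro = 0, k_dec_Xac = 0, k_dec_Xh2 = 0,
              k_L_a = 0, ...)
}

# Numerical convolution oracle for the hypoexponential density: convolves the
# N exponential stage densities on a uniform grid with trapezoid end
# correction (second-order accurate), independent of the partial-fraction
# evaluation under test.
hypoexp_convolution_oracle <- function(fractions, theta, h = 2e-4) {
  grid <- seq(0, max(theta) + h, by = h)
  dens <- function(r) exp(-grid / r) / r
  f <- dens(fractions[1])
  for (k in seq_along(fractions)[-1]) {
    g <- dens(fractions[k])
    m <- length(grid)
    full <- convolve(f, rev(g), type = "open")[seq_len(m)] * h
    # trapezoid end correction: the open convolution uses rectangle weights
    full <- full - h * (f[1] * g + f * g[1]) / 2
    f <- pmax(full, 0)
  }
  approx(grid, f, theta)$y
}

# Independent charge-balance oracle: plain bisection in R on the same
# physical balance, written without reference to the package's solver.
speciation_bisection_oracle <- function(state, params) {
  Ka <- function(pK, dH = 0) {
    10^(-pK) * exp(dH * (1 / params$T_base - 1 / params$T_op) / 8.3145)
  }
  Kw <- 1e-14 * exp(55900 * (1 / params$T_base - 1 / params$T_op) / 8.3145)
  bal <- function(h) {
    state[["S_cat"]] + state[["S_IN"]] * h / (h + Ka(9.25, 51965)) + h -
      state[["S_IC"]] * Ka(6.35, 7646) / (h + Ka(6.35, 7646)) -
      (state[["S_ac"]] / 64) * Ka(4.76) / (h + Ka(4.76)) -
      (state[["S_pro"]] / 112) * Ka(4.88) / (h + Ka(4.88)) -
      (state[["S_bu"]] / 160) * Ka(4.82) / (h + Ka(4.82)) -
      (state[["S_va"]] / 208) * Ka(4.86) / (h + Ka(4.86)) -
      Kw / h - state[["S_an"]]
  }
  lo <- 1e-14; hi <- 1
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (bal(mid) > 0) hi <- mid else lo <- mid
  }
  -log10(sqrt(lo * hi))
}

# random valid ADM1 state with all pools populated (for conservation checks)
random_adm1_state <- function() {
  vals <- list(S_su = runif(1, 0, 2), S_aa = runif(1, 0, 1),
               S_fa = runif(1, 0, 1), S_va = runif(1, 0, 0.5),
               S_bu = runif(1, 0, 0.5), S_pro = runif(1, 0, 0.5),
               S_ac = runif(1, 0, 1), S_h2 = runif(1, 0, 1e-6),
               S_ch4 = runif(1, 0, 0.05), S_IC = runif(1, 0.02, 0.15),
               S_IN = runif(1, 0.002, 0.05), S_I = runif(1, 0, 1),
               X_c = runif(1, 0, 2), X_ch = runif(1, 0, 1),
               X_pr = runif(1, 0, 1), X_li = runif(1, 0, 1),
               X_su = runif(1, 0, 3), X_aa = runif(1, 0, 1),
               X_fa = runif(1, 0, 1), X_c4 = runif(1, 0, 1),
               X_pro = runif(1, 0, 1), X_ac = runif(1, 0, 3),
               X_h2 = runif(1, 0, 1), X_I = runif(1, 0, 2),
               S_cat = runif(1, 0.01, 0.06), S_an = runif(1, 0, 0.02))
  do.call(adm1_state, vals)
}

# exact theta-domain curve sampled from a TIS density
sampled_tis_curve <- function(spec, theta_max = 6, dt = 0.02) {
  th <- seq(0, theta_max, by = dt)
  exit_age_curve(th, tis_density(spec, th), domain = "theta")
}

# the printed RTD analysis table for the eight tracer runs
# (HRT h, D/uL, Pe, N, biomass)
table2_runs <- data.frame(
  run = paste0("R", 1:8),
  hrt_h = c(24, 16, 8, 4, 24, 16, 8, 4),
  dispersion = c(0.32, 0.29, 0.25, 0.21, 0.31, 0.31, 0.35, 0.42),
  peclet = c(3.12, 3.47, 4.02, 4.74, 3.19, 3.27, 2.89, 2.40),
  n_tanks = c(2.25, 2.41, 2.66, 2.99, 2.28, 2.32, 2.15, 1.93),
  biomass = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
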