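p_meso <- adm1_params()
p_cal <- adm1_params("calibrated")

test_that("kinetic rate primitives follow Monod and first-order forms", {
  # half saturation: s = K_s halves the maximum rate
  expect_equal(monod_rate(0.5, 2, 10, 0.5), 10 * 2 / 2)
  expect_equal(monod_rate(0.14, 1, p_cal$k_m_ac, p_cal$K_S_ac), 6.565)
  # saturation and zero limits
  expect_equal(monod_rate(1e9, 1, 8, 0.15), 8, tolerance = 1e-8)
  expect_equal(monod_rate(0, 1, 8, 0.15), 0)
  expect_equal(monod_rate(1, 0, 8, 0.15), 0)
  # inhibition scales multiplicatively
  expect_equal(monod_rate(0.3, 1, 8, 0.15, inhibition = 0.25),
               monod_rate(0.3, 1, 8, 0.15) * 0.25)

  expect_equal(first_order_rate(5, 0.02), 0.1)
  expect_equal(first_order_rate(0, 0.02), 0)
  expect_equal(first_order_rate(10, 0.02), 2 * first_order_rate(5, 0.02))
  expect_error(first_order_rate(-1, 0.02))
})

test_that("inhibition factors are bounded, monotone, and vanish correctly", {
  base <- adm1_state(S_IN = 0.01, S_IC = 0.05, S_cat = 0.05)
  I <- inhibition_terms(base, p_meso)
  # absent inhibitors give factor 1
  expect_equal(I$h2_fa, 1)
  expect_equal(I$h2_pro, 1)
  # free ammonia absent (no inorganic nitrogen): no ammonia inhibition
  expect_equal(inhibition_terms(adm1_state(S_IC = 0.05, S_cat = 0.05),
                                p_meso)$nh3, 1)
  # pH at/above the upper limit leaves the group uninhibited
  expect_gte(I$pH, p_meso$pH_UL_ac)
  expect_equal(I$pH_ac, 1)
  # hydrogen at its inhibition constant halves the factor
  I2 <- inhibition_terms(adm1_state(S_IN = 0.01, S_IC = 0.05, S_cat = 0.05,
                                    S_h2 = p_meso$K_I_h2_pro), p_meso)
  expect_equal(I2$h2_pro, 0.5)
  # monotone non-increasing in the inhibitor, all factors within [0, 1]
  prev <- rep(1, 3)
  for (sh2 in c(0, 1e-6, 1e-5, 1e-4)) {
    Ih <- inhibition_terms(adm1_state(S_IN = 0.01, S_IC = 0.05, S_cat = 0.05,
                                      S_h2 = sh2), p_meso)
    cur <- c(Ih$h2_fa, Ih$h2_c4, Ih$h2_pro)
    expect_true(all(cur <= prev + 1e-12))
    vals <- unlist(Ih[c("pH_aa", "pH_ac", "pH_h2", "IN_lim", "h2_fa",
                        "h2_c4", "h2_pro", "nh3")])
    expect_true(all(vals >= 0 & vals <= 1))
    prev <- cur
  }
})

test_that("the 19 process rates activate sparsely and match hand values", {
  r0 <- process_rates(adm1_state(), p_meso)
  expect_length(r0, 19)
  expect_true(all(r0 == 0))

  # sugar-only state: one active uptake, one active decay, nothing else
  s <- adm1_state(S_su = 1, X_su = 0.5, S_IN = 0.01, S_IC = 0.05, S_cat = 0.05)
  r <- process_rates(s, p_meso)
  expect_gt(r[["uptake_su"]], 0)
  up <- r[grepl("^uptake", names(r))]
  expect_true(all(up[names(up) != "uptake_su"] == 0))
  dec <- r[grepl("^decay", names(r))]
  expect_true(all(dec[names(dec) != "decay_Xsu"] == 0))

  # hand-computed rates (pH above every upper limit, so pH factors are 1)
  sp <- solve_speciation(s, p_meso)
  expect_gte(sp$pH, p_meso$pH_UL_aa)
  I_IN <- 0.01 / (0.01 + p_meso$K_S_IN)
  expect_equal(r[["uptake_su"]],
               p_meso$k_m_su * 1 / (p_meso$K_S_su + 1) * 0.5 * I_IN,
               tolerance = 1e-10)
  expect_equal(r[["decay_Xsu"]], p_meso$k_dec_Xsu * 0.5, tolerance = 1e-12)
  s2 <- adm1_state(X_c = 2, X_ch = 1.5)
  r2 <- process_rates(s2, p_meso)
  expect_equal(r2[["disintegration"]], p_meso$k_dis * 2, tolerance = 1e-12)
  expect_equal(r2[["hydrolysis_ch"]], p_meso$k_hyd_ch * 1.5, tolerance = 1e-12)
})

test_that("biochemical stoichiometry conserves COD, carbon and nitrogen", {
  nu <- adm1_stoichiometry(p_meso)
  w_cod <- rep(1, nrow(nu)); names(w_cod) <- rownames(nu)
  w_cod[c("S_IC", "S_IN", "S_cat", "S_an")] <- 0
  expect_lt(max(abs(colSums(nu * w_cod))), 1e-12)

  # carbon: content-weighted columns must vanish, counting S_IC at 1 kmol C
  cc <- c(S_su = p_meso$C_su, S_aa = p_meso$C_aa, S_fa = p_meso$C_fa,
          S_va = p_meso$C_va, S_bu = p_meso$C_bu, S_pro = p_meso$C_pro,
          S_ac = p_meso$C_ac, S_h2 = 0, S_ch4 = p_meso$C_ch4, S_IC = 1,
          S_IN = 0, S_I = p_meso$C_sI, X_c = p_meso$C_xc, X_ch = p_meso$C_ch,
          X_pr = p_meso$C_pr, X_li = p_meso$C_li, X_su = p_meso$C_bac,
          X_aa = p_meso$C_bac, X_fa = p_meso$C_bac, X_c4 = p_meso$C_bac,
          X_pro = p_meso$C_bac, X_ac = p_meso$C_bac, X_h2 = p_meso$C_bac,
          X_I = p_meso$C_xI, S_cat = 0, S_an = 0)
  expect_lt(max(abs(colSums(nu * cc[rownames(nu)]))), 1e-14)
  # nitrogen likewise, counting S_IN at 1 kmol N
  nn <- setNames(rep(0, nrow(nu)), rownames(nu))
  nn[c("S_aa", "X_pr")] <- p_meso$N_aa
  nn[c("S_I", "X_I")] <- p_meso$N_I
  nn["X_c"] <- p_meso$N_xc
  nn[c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")] <- p_meso$N_bac
  nn["S_IN"] <- 1
  expect_lt(max(abs(colSums(nu * nn))), 1e-14)

  # random states: COD-weighted biochemical derivative is zero
  set.seed(21)
  for (i in 1:10) {
    d <- biochemical_derivatives(random_adm1_state(), p_meso)
    expect_lt(abs(sum(d * w_cod[names(d)])), 1e-8)
  }
})

test_that("single-process stoichiometry flows substrate to biomass and methane", {
  # isolate acetate uptake: no decay, acetate and its degrader only
  p_iso <- adm1_params(k_dec_Xac = 0)
  s <- adm1_state(S_ac = 0.5, X_ac = 1, S_IN = 0.01, S_IC = 0.05, S_cat = 0.06)
  rho <- process_rates(s, p_iso)[["uptake_ac"]]
  expect_gt(rho, 0)
  d <- biochemical_derivatives(s, p_iso)
  expect_equal(d[["S_ac"]], -rho, tolerance = 1e-12)
  expect_equal(d[["X_ac"]], p_iso$Y_ac * rho, tolerance = 1e-12)
  expect_equal(d[["S_ch4"]], (1 - p_iso$Y_ac) * rho, tolerance = 1e-12)
  # zero state gives zero derivatives
  expect_true(all(biochemical_derivatives(adm1_state(), p_iso) == 0))
})

test_that("charge-balance speciation matches an independent bisection oracle", {
  # pure water at the reference temperature: pH 7 by K_w symmetry
  p25 <- adm1_params(T_op = 298.15)
  expect_equal(solve_speciation(adm1_state(), p25)$pH, 7, tolerance = 1e-6)
  # excess strong base raises pH above 7
  expect_gt(solve_speciation(adm1_state(S_cat = 0.01), p25)$pH, 7)

  # benchmark-like state against the oracle
  s <- adm1_state(S_IC = 0.15, S_IN = 0.13, S_ac = 0.2, S_pro = 0.03,
                  S_bu = 0.02, S_va = 0.01, S_cat = 0.04, S_an = 0.02)
  sp <- solve_speciation(s, p_meso)
  expect_equal(sp$pH, speciation_bisection_oracle(s, p_meso), tolerance = 1e-6)
  expect_lt(abs(sp$residual), 1e-12)

  # speciated fractions are consistent with their totals
  expect_equal(sp$S_hco3_ion + sp$S_co2, 0.15, tolerance = 1e-12)
  expect_equal(sp$S_nh3 + sp$S_nh4_ion, 0.13, tolerance = 1e-12)

  # pH is monotone increasing in the cation content
  phs <- vapply(c(0.01, 0.02, 0.04, 0.06),
                function(cat) solve_speciation(
                  adm1_state(S_IC = 0.1, S_IN = 0.01, S_ac = 0.2,
                             S_cat = cat), p_meso)$pH, 0)
  expect_true(all(diff(phs) > 0))

  # random states always satisfy the residual contract
  set.seed(8)
  for (i in 1:10)
    expect_lt(abs(solve_speciation(random_adm1_state(), p_meso)$residual),
              1e-12)
})

test_that("gas-liquid transfer is zero at equilibrium and linear around it", {
  # construct a headspace exactly in equilibrium with the liquid
  s_ch4 <- 0.05
  p_ch4 <- s_ch4  # placeholder, computed below
  # choose S_gas so K_H * p = S_liq
  RT <- 0.083145 * p_meso$T_op
  fac <- (1 / p_meso$T_base - 1 / p_meso$T_op) / 8.3145
  K_H_ch4 <- 1.4e-3 * exp(-14240 * fac)
  S_gas_ch4_eq <- s_ch4 / (64 * K_H_ch4) / (RT / 64)
  s <- adm1_state(S_ch4 = s_ch4, S_gas_ch4 = S_gas_ch4_eq)
  g <- gas_transfer(s, p_meso)
  expect_equal(g$rho_T_ch4, 0, tolerance = 1e-10)
  # supersaturated liquid transfers to the gas phase
  g2 <- gas_transfer(adm1_state(S_ch4 = 2 * s_ch4, S_gas_ch4 = S_gas_ch4_eq),
                     p_meso)
  expect_gt(g2$rho_T_ch4, 0)
  # direct formula check for hydrogen
  s3 <- adm1_state(S_h2 = 1e-6, S_gas_h2 = 0.8)
  g3 <- gas_transfer(s3, p_meso)
  K_H_h2 <- 7.8e-4 * exp(-4180 * fac)
  p_h2 <- 0.8 / 16 * RT
  expect_equal(g3$rho_T_h2, p_meso$k_L_a * (1e-6 - 16 * K_H_h2 * p_h2),
               tolerance = 1e-12)
  expect_equal(g3$p_h2, p_h2, tolerance = 1e-12)
})

test_that("soluble effluent COD sums the organic solutes only", {
  expect_equal(effluent_cod(adm1_state()), 0)
  expect_equal(effluent_cod(adm1_state(S_ac = 0.5, S_pro = 0.3)), 0.8)
  # inorganic pools and (by default) particulates are excluded
  expect_equal(effluent_cod(adm1_state(S_ac = 1, S_IC = 0.5, S_cat = 0.2,
                                       X_su = 3)), 1)
  expect_equal(effluent_cod(adm1_state(S_ac = 1, X_su = 3),
                            include_particulates = TRUE), 4)
})

test_that("parameter presets and overrides are validated", {
  expect_equal(p_cal$k_m_ac, 13.13)
  expect_equal(p_cal$k_m_pro, 9.90)
  expect_equal(p_cal$K_S_ac, 0.14)
  expect_equal(p_cal$K_S_pro, 0.30)
  # the preset only touches the four calibrated constants
  expect_equal(p_cal$k_m_su, p_meso$k_m_su)
  expect_error(adm1_params(not_a_param = 1), "unknown ADM1 parameter")
  over <- adm1_params(k_m_ac = 9)
  expect_equal(over$k_m_ac, 9)
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yml")
  write_adm1_params(p_cal, path)
  back <- read_adm1_params(path)
  expect_equal(unclass(back), unclass(p_cal), tolerance = 1e-12)
  # product fractions sum to 1 for each fermented substrate
  expect_equal(p_meso$f_h2_su + p_meso$f_bu_su + p_meso$f_pro_su +
                 p_meso$f_ac_su, 1)
  expect_equal(p_meso$f_h2_aa + p_meso$f_va_aa + p_meso$f_bu_aa +
                 p_meso$f_pro_aa + p_meso$f_ac_aa, 1)
  expect_equal(p_meso$f_sI_xc + p_meso$f_ch_xc + p_meso$f_pr_xc +
                 p_meso$f_li_xc + p_meso$f_xI_xc, 1)
})
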