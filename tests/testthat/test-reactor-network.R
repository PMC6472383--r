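test_that("ISC network construction splits volume by the given ratio", {
  net <- build_isc_network(16, c(1, 2, 5))
  expect_equal(net$tank_volumes_L, c(2, 4, 10))
  expect_equal(sum(net$headspace_L), 10)
  expect_equal(net$headspace_L, 10 * c(2, 4, 10) / 16)
  expect_equal(build_isc_network(8, c(1, 3))$tank_volumes_L, c(2, 6))
  expect_error(build_isc_network(16, c(1, 1, 1)), "strictly increasing")
  expect_error(build_isc_network(-16, c(1, 2, 5)), "positive")
  expect_error(reactor_network(c(2, 4), solids_retention_factor = 0.5), ">= 1")
})

test_that("influent scenarios validate their segment structure", {
  f <- map_feed(feed_recipe(3))
  expect_error(influent_scenario(c(0, 5), c(5, 4), c(1, 1), list(f, f)),
               "positive duration")
  expect_error(influent_scenario(c(0, 6), c(5, 10), c(1, 1), list(f, f)),
               "contiguous")
  expect_error(influent_scenario(0, 10, -1, list(f)), "non-negative")
  sc <- influent_scenario(c(0, 5), c(5, 10), c(1, 2), list(f, f))
  expect_s3_class(sc, "influent_scenario")
})

test_that("pure advection has the feed composition as its fixed point", {
  p0 <- zero_kinetics_params()
  net <- build_isc_network(16, c(1, 2, 5), solids_retention_factor = 1)
  feed <- map_feed(feed_recipe(3))
  sc <- influent_scenario(0, 1000, 0.75, list(feed))
  y <- rep(as.numeric(unclass(feed)), 3)
  dy <- network_derivatives(10, y, net, sc, p0)
  # liquid components of every tank are stationary (aux accumulators are not)
  liq_idx <- as.vector(outer(1:26, (0:2) * 31, "+"))
  expect_lt(max(abs(dy[liq_idx])), 1e-12)
})

test_that("an inert solute washes out exponentially from a single tank", {
  p0 <- zero_kinetics_params()
  net1 <- reactor_network(10, solids_retention_factor = 1)
  sc0 <- influent_scenario(0, 100, 0.5, list(adm1_state()))
  sim <- simulate_reactor(net1, sc0, p0, initial_state = adm1_state(S_I = 2),
                          t_end_h = 100, dt_out_h = 1, rtol = 1e-8,
                          atol = 1e-12)
  analytic <- 2 * exp(-0.5 * sim$time_h / 10)
  expect_lt(max(abs(sim$states[, "S_I", 1] - analytic)), 1e-6)
})

test_that("the zero-kinetics chain reproduces the hypoexponential RTD", {
  # an impulse of inert solute in tank 1 leaves through the chain with the
  # increasing-size tanks-in-series density: outlet C(t) = (M/q) E_t(t)
  p0 <- zero_kinetics_params()
  net <- build_isc_network(16, c(1, 2, 5), solids_retention_factor = 1)
  q <- 0.75
  sc0 <- influent_scenario(0, 200, q, list(adm1_state()))
  mass <- 260  # mg
  y0 <- rep(as.numeric(unclass(adm1_state())), 3)
  y0[12] <- mass / 2 / 1000  # S_I in tank 1 (2 L), g/L
  sim <- simulate_reactor(net, sc0, p0, initial_state = y0, t_end_h = 170,
                          dt_out_h = 0.5, rtol = 1e-8, atol = 1e-12)
  outlet_mg_L <- sim$states[, "S_I", 3] * 1000
  t_mean <- 16 / q
  analytic <- mass / (q * t_mean) * isc_density(sim$time_h / t_mean,
                                                c(1, 2, 5) / 8)
  expect_lt(max(abs(outlet_mg_L - analytic)), 1e-5 * max(analytic))
})

test_that("inert feed passes through unchanged at steady state", {
  p0 <- zero_kinetics_params()
  net <- build_isc_network(16, c(1, 2, 5), solids_retention_factor = 1)
  feed <- adm1_state(S_I = 2.5)
  sc <- influent_scenario(0, 24 * 15, 16 / 24, list(feed))
  sim <- simulate_reactor(net, sc, p0, initial_state = adm1_state(),
                          t_end_h = 24 * 15)
  expect_equal(tail(sim$effluent$cod_g_L, 1), 2.5, tolerance = 1e-4)
})

test_that("numerical tracer transport matches the analytic curve", {
  net <- build_isc_network(16, c(1, 2, 5))
  tr <- simulate_tracer(net, 260, flow_L_h = 0.75, t_end_h = 120,
                        dt_out_h = 0.25)
  expect_equal(attr(tr, "t_mean_h"), 16 / 0.75, tolerance = 1e-12)
  expect_equal(attr(tr, "mean_conc_mg_L"), 260 / 16, tolerance = 1e-12)
  t_mean <- 16 / 0.75
  analytic <- 260 / (0.75 * t_mean) * isc_density(tr$time_h / t_mean,
                                                  c(1, 2, 5) / 8)
  expect_lt(max(abs(tr$conc_mg_L - analytic)) / max(analytic), 1e-4)
  # injected mass is recovered at the outlet within 0.5%
  recovered <- 0.75 * trapz(tr$time_h, tr$conc_mg_L)
  expect_equal(recovered, 260, tolerance = 5e-3)
  # linearity: doubling the pulse doubles the outlet curve pointwise
  tr2 <- simulate_tracer(net, 520, flow_L_h = 0.75, t_end_h = 120,
                         dt_out_h = 0.25)
  expect_equal(tr2$conc_mg_L, 2 * tr$conc_mg_L, tolerance = 1e-12)
})

test_that("solver tolerance is converged for effluent trajectories", {
  net <- build_isc_network(16, c(1, 2, 5))
  sc <- steady_scenario(feed_recipe(3), hrt_h = 24, volume_L = 16,
                        t_end_h = 24 * 5)
  p <- adm1_params("calibrated")
  s1 <- simulate_reactor(net, sc, p, t_end_h = 24 * 5, rtol = 1e-6)
  s2 <- simulate_reactor(net, sc, p, t_end_h = 24 * 5, rtol = 5e-7)
  rel <- max(abs(s1$effluent$cod_g_L - s2$effluent$cod_g_L) /
               pmax(s2$effluent$cod_g_L, 1e-6))
  expect_lt(rel, 1e-3)
  # states stay non-negative at every output point
  expect_gte(min(s1$states[, 1:29, ]), 0)
})

test_that("batch digestion conserves total COD across liquid and gas", {
  # closed bottle: no liquid flow; COD can only move to the headspace, and
  # the cumulative gas bookkeeping must account for what leaves
  net1 <- reactor_network(10, headspace_total_L = 5,
                          solids_retention_factor = 1)
  sc0 <- influent_scenario(0, 24 * 30, 0, list(adm1_state()))
  y0 <- adm1_state(S_su = 3, X_su = 0.5, X_ac = 1, X_h2 = 0.5, X_pro = 0.3,
                   S_IC = 0.08, S_IN = 0.02, S_cat = 0.06)
  sim <- simulate_reactor(net1, sc0, adm1_params(), initial_state = y0,
                          t_end_h = 24 * 30)
  w <- rep(1, 26)
  w[c(10, 11, 25, 26)] <- 0  # S_IC, S_IN, S_cat, S_an carry no COD
  total <- function(i) {
    yk <- sim$states[i, , 1]
    10 * sum(w * yk[1:26]) + 5 * (yk[["S_gas_h2"]] + yk[["S_gas_ch4"]]) +
      yk[["cum_gas_cod"]]
  }
  start <- total(1)
  drift <- vapply(seq(1, length(sim$time_h), by = 40), total, 0) / start - 1
  expect_lt(max(abs(drift)), 0.005)
})

test_that("tidy CSV export round-trips the effluent series", {
  net <- build_isc_network(16, c(1, 2, 5))
  sc <- steady_scenario(feed_recipe(3), hrt_h = 24, volume_L = 16,
                        t_end_h = 12)
  sim <- simulate_reactor(net, sc, adm1_params("calibrated"), t_end_h = 12)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(sim, p1, p2, header_comment = "hash=x seed=1")
  tidy <- read.csv(p1, comment.char = "#")
  expect_named(tidy, c("time", "tank", "variable", "value"))
  expect_setequal(unique(tidy$tank), 1:3)
  eff <- read.csv(p2, comment.char = "#")
  expect_equal(eff$cod_g_L, sim$effluent$cod_g_L, tolerance = 1e-12)
})
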