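test_that("Erlang and gamma tank-chain densities match hand evaluation", {
  expect_equal(esc_density(0.5, 1), exp(-0.5), tolerance = 1e-12)
  expect_equal(esc_density(1, 2), 4 * exp(-2), tolerance = 1e-12)
  expect_equal(esc_density(1, 3), 13.5 * exp(-3), tolerance = 1e-12)
  expect_error(esc_density(1, 2.5), "integer")

  # gamma form generalizes the Erlang at integer N ...
  th <- seq(0, 6, by = 0.1)
  for (n in 1:4)
    expect_equal(eesc_density(th, n), esc_density(th, n), tolerance = 1e-12)
  # ... and matches the direct formula at real N
  n <- 2.25
  expect_equal(eesc_density(1, n), n^n / gamma(n) * exp(-n), tolerance = 1e-12)
  expect_equal(eesc_density(1, 2.25), 0.5768, tolerance = 1e-4)
  expect_error(eesc_density(1, 0), "> 0")
})

test_that("all TIS densities are proper with the stated mean and variance", {
  th <- seq(0, 50, by = 0.005)
  set.seed(11)
  specs <- list(tis_spec("ESC", 1), tis_spec("ESC", 4), tis_spec("EESC", 2.41),
                tis_spec("ISC", fractions = c(1, 2, 5) / 8),
                tis_spec("ISC", fractions = c(0.05, 0.25, 0.7)))
  for (i in 1:5) {
    r <- sort(runif(sample(2:5, 1), 0.05, 1)); r <- r / sum(r)
    if (any(diff(r) <= 1e-3)) next
    specs[[length(specs) + 1]] <- tis_spec("ISC", fractions = r)
  }
  for (spec in specs) {
    dens <- tis_density(spec, th)
    mom <- tis_moments(spec)
    area <- integrate(function(x) tis_density(spec, x), 0, 50,
                      rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(area, 1, tolerance = 1e-6)
    expect_equal(trapz(th, th * dens), mom$mean, tolerance = 1e-4)
    expect_equal(trapz(th, th^2 * dens) - mom$mean^2, mom$variance,
                 tolerance = 1e-4)
  }
  # analytic moments themselves
  expect_equal(tis_moments(tis_spec("ESC", 4)), list(mean = 1, variance = 0.25))
  expect_equal(tis_moments(tis_spec("ISC", fractions = c(1, 2, 5) / 8)),
               list(mean = 1, variance = 30 / 64))
})

test_that("hypoexponential density agrees with the convolution oracle", {
  # frozen spot value for the 1:2:5 chain
  expect_equal(isc_density(0, c(1, 2, 5) / 8), 0)
  expect_equal(isc_density(1, c(1, 2, 5) / 8), 0.5760, tolerance = 1e-4)

  th <- seq(0.1, 5, by = 0.1)
  set.seed(3)
  cases <- list(c(1, 2, 5) / 8, c(0.1, 0.3, 0.6), c(0.3, 0.7),
                c(0.05, 0.1, 0.25, 0.6), c(0.04, 0.08, 0.16, 0.28, 0.44))
  for (i in 1:5) {
    r <- sort(runif(sample(2:5, 1), 0.05, 1)); r <- r / sum(r)
    if (any(diff(r) <= 5e-3)) next
    cases[[length(cases) + 1]] <- r
  }
  for (r in cases) {
    expect_lt(max(abs(isc_density(th, r) -
                        hypoexp_convolution_oracle(r, th))), 1e-6)
  }
})

test_that("near-equal tank sizes fall back continuously to the Erlang form", {
  th <- c(0.2, 0.5, 1, 2, 4)
  # exactly equal sizes: Erlang-2 via the stable path
  expect_equal(isc_density(th, c(0.5, 0.5)), esc_density(th, 2),
               tolerance = 1e-10)
  # just either side of the degeneracy threshold
  for (eps in c(1e-9, 1e-7, 1e-5, 1e-3)) {
    r <- c(0.5 - eps, 0.5 + eps)
    expect_lt(max(abs(isc_density(th, r) - esc_density(th, 2))), 1e-4)
  }
  three <- c(1, 1, 1) / 3
  expect_equal(isc_density(th, three), esc_density(th, 3), tolerance = 1e-10)
})

test_that("chi-square fitting recovers generating tank fractions", {
  truth <- c(0.1, 0.3, 0.6)
  curve <- sampled_tis_curve(tis_spec("ISC", fractions = truth))
  fit <- fit_tis(curve, tis_spec("ISC", fractions = c(1, 2, 5) / 8))
  expect_lt(max(abs(fit$spec$fractions - truth)), 1e-3)
  expect_lt(fit$chi2, 1e-8)
  expect_true(fit$converged)

  # noiseless recovery to 3 decimals from a different truth
  truth2 <- c(0.05, 0.25, 0.7)
  fit2 <- fit_tis(sampled_tis_curve(tis_spec("ISC", fractions = truth2)),
                  tis_spec("ISC", fractions = c(1, 2, 5) / 8))
  expect_lt(max(abs(fit2$spec$fractions - truth2)), 1e-3)

  # EESC fit recovers a real tank count
  fit3 <- fit_tis(sampled_tis_curve(tis_spec("EESC", 2.41)),
                  tis_spec("EESC", 2))
  expect_equal(fit3$spec$n_tanks, 2.41, tolerance = 1e-4)

  # Erlang data under an ISC template: nesting means the ISC fit can do at
  # least as well as the (true) equal-size model, approaching equal sizes
  erl <- sampled_tis_curve(tis_spec("ESC", 3))
  fit4 <- fit_tis(erl, tis_spec("ISC", fractions = c(1, 2, 5) / 8))
  chi2_esc <- fit_tis(erl, tis_spec("ESC", 3))$chi2
  expect_lte(fit4$chi2, chi2_esc + 1e-10)
  expect_lt(max(fit4$spec$fractions) - min(fit4$spec$fractions), 0.05)
})

test_that("fitting tolerates measurement noise at the tested level", {
  truth <- c(0.1, 0.3, 0.6)
  curve0 <- sampled_tis_curve(tis_spec("ISC", fractions = truth))
  set.seed(123)
  noisy <- pmax(curve0$density + rnorm(length(curve0$density), 0, 0.02), 0)
  curve <- exit_age_curve(curve0$times, noisy, "theta")
  fit <- fit_tis(curve, tis_spec("ISC", fractions = c(1, 2, 5) / 8),
                 sigma_obs = 0.02)
  expect_lt(max(abs(fit$spec$fractions - truth)), 0.05)
})

test_that("model selection ranks the generating model first, reproducibly", {
  candidates <- list(tis_spec("ESC", 2), tis_spec("EESC", 2),
                     tis_spec("ISC", fractions = c(1, 2, 5) / 8))
  # ISC data: ISC wins
  isc_curve <- sampled_tis_curve(tis_spec("ISC", fractions = c(0.05, 0.25, 0.7)))
  tab <- select_model(isc_curve, candidates)
  expect_equal(tab$model[1], "ISC")
  # Erlang-2 data: the ESC candidate fits exactly
  erl_curve <- sampled_tis_curve(tis_spec("ESC", 2))
  tab2 <- select_model(erl_curve, candidates)
  expect_lt(tab2$chi2[tab2$model == "ESC"], 1e-12)
  # deterministic reruns on noisy data
  set.seed(5)
  noisy <- exit_age_curve(isc_curve$times,
                          pmax(isc_curve$density +
                                 rnorm(length(isc_curve$density), 0, 0.02), 0),
                          "theta")
  r1 <- select_model(noisy, candidates)
  r2 <- select_model(noisy, candidates)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$chi2, r2$chi2)
  expect_error(select_model(isc_curve, candidates[1]), "at least 2")
})

test_that("TIS spec validation enforces the increasing-size constraints", {
  expect_error(tis_spec("ISC", fractions = c(0.5, 0.3, 0.2)), "increasing")
  expect_error(tis_spec("ISC", fractions = c(0.2, 0.3)), "sum to 1")
  expect_error(tis_spec("ESC", 2.5), "integer")
  expect_silent(tis_spec("EESC", 2.5))
  # fit report CSV mirrors the run-table layout
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- select_model(sampled_tis_curve(tis_spec("ESC", 2)),
                      list(tis_spec("ESC", 2), tis_spec("EESC", 2)))
  write_tis_report(tab, path)
  re <- read.csv(path, comment.char = "#")
  expect_named(re, c("model", "n_tanks", "fractions", "chi2"))
})
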