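#' Feed recipe for glucose-based synthetic wastewater
#'
#' The influent emulated here is synthetic wastewater made from glucose, urea
#' and KH2PO4 at a COD : NH4-N : PO4-P ratio of 200:5:1, buffered with
#' sodium bicarbonate.
#'
#' @param cod_g_L influent COD (g/L); default 3.
#' @param cod_n_p_ratio `c(COD, N, P)` mass ratio; default `c(200, 5, 1)`.
#' @param fraction_as_sugar fraction of COD fed as monosaccharide (default 1).
#' @param cation_kmol_m3 strong-cation concentration (kmol/m3) representing
#'   the bicarbonate dose that holds the reactor near pH 7; the same amount of
#'   inorganic carbon is fed.
#' @return object of class `feed_recipe`.
#' @export
feed_recipe <- function(cod_g_L = 3, cod_n_p_ratio = c(200, 5, 1),
                        fraction_as_sugar = 1, cation_kmol_m3 = 0.04) {
  if (cod_g_L < 0) stop("COD must be non-negative")
  if (any(cod_n_p_ratio <= 0)) stop("ratio entries must be positive")
  if (fraction_as_sugar < 0 || fraction_as_sugar > 1)
    stop("fraction_as_sugar must lie in [0, 1]")
  structure(list(cod_g_L = cod_g_L, cod_n_p_ratio = cod_n_p_ratio,
                 fraction_as_sugar = fraction_as_sugar,
                 cation_kmol_m3 = cation_kmol_m3),
            class = "feed_recipe")
}

#' Map a feed recipe to an influent ADM1 state
#'
#' COD enters as monosaccharide (`S_su = cod * fraction_as_sugar`; any
#' remainder as soluble inerts), ammonium nitrogen follows the COD:N ratio
#' (`S_IN = cod * N/COD / 14` kmol/m3), and the bicarbonate dose contributes
#' equal strong cations and inorganic carbon.
#'
#' @param recipe a [feed_recipe()].
#' @return influent [adm1_state()].
#' @export
map_feed <- function(recipe) {
  stopifnot(inherits(recipe, "feed_recipe"))
  n_over_cod <- recipe$cod_n_p_ratio[2] / recipe$cod_n_p_ratio[1]
  adm1_state(
    S_su = recipe$cod_g_L * recipe$fraction_as_sugar,
    S_I = recipe$cod_g_L * (1 - recipe$fraction_as_sugar),
    S_IN = recipe$cod_g_L * n_over_cod / 14,
    S_IC = recipe$cation_kmol_m3,
    S_cat = recipe$cation_kmol_m3)
}

#' Steady influent scenario
#'
#' Constant feed at the recipe COD; flow either given directly or derived
#' from the network volume and a hydraulic residence time.
#'
#' @param recipe a [feed_recipe()].
#' @param flow_L_h feed flow (L/h); give either this or `hrt_h` + `volume_L`.
#' @param t_end_h horizon (h).
#' @param hrt_h,volume_L alternative flow specification `flow = volume / hrt`.
#' @export
steady_scenario <- function(recipe, flow_L_h = NULL, t_end_h = 24 * 60,
                            hrt_h = NULL, volume_L = NULL) {
  if (is.null(flow_L_h)) {
    if (is.null(hrt_h) || is.null(volume_L))
      stop("give flow_L_h, or hrt_h together with volume_L")
    flow_L_h <- volume_L / hrt_h
  }
  influent_scenario(0, t_end_h, flow_L_h, list(map_feed(recipe)))
}

#' Organic overloading shock scenario
#'
#' Steady feed interrupted by a window at `factor` times the base COD
#' concentration (default six-fold, 18 g/L from a 3 g/L base, lasting 8 h)
#' at constant flow set by the hydraulic residence time.
#'
#' @param recipe base [feed_recipe()].
#' @param factor COD multiplier during the shock (> 1).
#' @param duration_h shock window length (h).
#' @param hrt_h hydraulic residence time fixing the flow (h).
#' @param volume_L network liquid volume (L).
#' @param shock_start_h window start (h).
#' @param t_end_h horizon (h).
#' @export
organic_shock_scenario <- function(recipe, factor = 6, duration_h = 8,
                                   hrt_h = 24, volume_L = 16,
                                   shock_start_h = 24 * 10,
                                   t_end_h = 24 * 20) {
  if (factor < 1) stop("shock factor must be >= 1")
  q <- volume_L / hrt_h
  base <- map_feed(recipe)
  shock_recipe <- recipe
  shock_recipe$cod_g_L <- recipe$cod_g_L * factor
  shock <- map_feed(shock_recipe)
  if (factor == 1)
    return(influent_scenario(0, t_end_h, q, list(base)))
  t1 <- shock_start_h; t2 <- shock_start_h + duration_h
  stopifnot(t1 > 0, t2 < t_end_h)
  influent_scenario(c(0, t1, t2), c(t1, t2, t_end_h), rep(q, 3),
                    list(base, shock, base))
}

#' Hydraulic overloading shock scenario
#'
#' Flow multiplied by `factor` (default six-fold for 12 h) while the feed
#' composition stays at the base recipe.
#'
#' @inheritParams organic_shock_scenario
#' @param duration_h shock window length (h); default 12.
#' @export
hydraulic_shock_scenario <- function(recipe, factor = 6, duration_h = 12,
                                     hrt_h = 24, volume_L = 16,
                                     shock_start_h = 24 * 10,
                                     t_end_h = 24 * 20) {
  if (factor < 1) stop("shock factor must be >= 1")
  q <- volume_L / hrt_h
  base <- map_feed(recipe)
  if (factor == 1)
    return(influent_scenario(0, t_end_h, q, list(base)))
  t1 <- shock_start_h; t2 <- shock_start_h + duration_h
  stopifnot(t1 > 0, t2 < t_end_h)
  influent_scenario(c(0, t1, t2), c(t1, t2, t_end_h), c(q, factor * q, q),
                    list(base, base, base))
}

#' Lithium mass in a lithium sulfate monohydrate tracer dose
#'
#' The pulse tracer is dosed as Li2SO4.H2O; lithium does not adsorb onto
#' granular sludge and is harmless to the biomass, which is what makes it a
#' suitable inert tracer. Returns the Li+ mass in milligrams for a given salt
#' dose in grams.
#'
#' @param salt_g mass of Li2SO4.H2O dosed (g).
#' @export
lithium_dose_mg <- function(salt_g = 2.397) {
  m_li <- 6.941; m_s <- 32.06; m_o <- 15.999; m_h <- 1.008
  m_salt <- 2 * m_li + m_s + 4 * m_o + 2 * m_h + m_o  # monohydrate
  1000 * salt_g * 2 * m_li / m_salt
}

#' Synthetic pulse-tracer experiment
#'
#' Samples the simulated outlet tracer curve on the experimental schedule
#' (every 0.5 h at 4 h and 8 h HRT, every 1 h at 16 h and 24 h HRT; other
#' HRTs use `hrt / 8`) over three residence times, and adds zero-mean
#' Gaussian noise clipped at zero. Deterministic under a fixed seed.
#'
#' @param network a [reactor_network()].
#' @param hrt_h hydraulic residence time (h) fixing the flow.
#' @param pulse_mass_mg injected tracer mass (mg).
#' @param noise_sd_mg_L additive noise standard deviation (mg/L).
#' @param seed RNG seed.
#' @return a [tracer_series()].
#' @export
synthetic_tracer_experiment <- function(network, hrt_h, pulse_mass_mg = 260,
                                        noise_sd_mg_L = 0.2, seed = 1) {
  V <- sum(network$tank_volumes_L)
  q <- V / hrt_h
  dt <- if (hrt_h %in% c(4, 8)) 0.5 else if (hrt_h %in% c(16, 24)) 1 else hrt_h / 8
  sim <- simulate_tracer(network, pulse_mass_mg, flow_L_h = q,
                         t_end_h = 3 * hrt_h, dt_out_h = dt)
  conc <- sim$conc_mg_L
  if (noise_sd_mg_L > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    conc <- pmax(conc + rnorm(length(conc), 0, noise_sd_mg_L), 0)
  }
  # the t = 0 outlet sample is tracer-free; keep it that way after noise
  conc[1] <- 0
  suppressWarnings(tracer_series(sim$time_h, conc,
                run_id = sprintf("synthetic_hrt%g", hrt_h),
                hrt_nominal = hrt_h, flow = q, with_biomass = FALSE))
}

#' Synthetic noisy effluent-COD observations
#'
#' Samples the effluent COD of a simulation on a regular schedule and applies
#' multiplicative Gaussian noise; the per-point measurement standard
#' deviation `sigma = noise_fraction * model value` is recorded for
#' chi-square weighting. Deterministic under a fixed seed.
#'
#' @param result a `simulation_result`.
#' @param sampling_interval_h spacing of observation times (h).
#' @param noise_fraction relative noise level (>= 0).
#' @param seed RNG seed.
#' @param sigma_floor lower bound on the recorded sigma (g/L) so that
#'   weights stay finite when the model output approaches zero.
#' @return data.frame `time_h, cod_g_L, sigma_g_L`.
#' @export
synthetic_effluent_observations <- function(result, sampling_interval_h = 24,
                                            noise_fraction = 0.05, seed = 1,
                                            sigma_floor = 1e-6) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  tt <- seq(min(result$time_h), max(result$time_h), by = sampling_interval_h)
  model <- approx(result$effluent$time_h, result$effluent$cod_g_L, tt)$y
  sigma <- pmax(noise_fraction * model, sigma_floor)
  obs <- model
  if (noise_fraction > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    obs <- model * (1 + rnorm(length(model), 0, noise_fraction))
  }
  data.frame(time_h = tt, cod_g_L = obs, sigma_g_L = sigma)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
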