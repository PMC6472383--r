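# iscadm1

Modelling internal-circulation (IC) anaerobic reactors as a chain of
unequal-volume stirred tanks, with Anaerobic Digestion Model No. 1 (ADM1)
running in every tank.

Anaerobic reactors are usually simulated as a single ideally mixed vessel,
but tracer experiments on IC reactors show a mixing pattern between plug flow
and complete mixing (equivalent tank counts around 2–3). `iscadm1` is for
environmental process engineers and modellers who want to (a) quantify that
mixing pattern from pulse-tracer data and (b) run a hydraulically resolved
ADM1 simulation on top of it, including calibration of the kinetic constants
that dominate effluent quality.

## What is inside

* **RTD analysis** (`exit_age_from_tracer`, `rtd_moments`, `normalize_rtd`,
  `peclet_from_variance`, `tanks_equivalent`, `rtd_summary`): exit-age
  function E(t) = C(t)/∫C dt, mean residence time t̄, variance σt²,
  dimensionless variance σθ² = σt²/t̄², closed-vessel axial-dispersion
  inversion σθ² = 2/Pe − (2/Pe²)(1 − e^(−Pe)), dispersion number 1/Pe, and
  equivalent tank count N = 1/σθ².
* **Tanks-in-series models** (`esc_density`, `eesc_density`, `isc_density`,
  `fit_tis`, `select_model`): Erlang and gamma chains, and the
  increasing-size chain with hypoexponential RTD
  E(θ) = Σᵢ rᵢ^(N−2)/Πⱼ≠ᵢ(rᵢ − rⱼ) · e^(−θ/rᵢ) over volume fractions
  r₁ < … < r_N; χ²-fitting of the fractions with ordering constraints.
* **ADM1 core** (`adm1_params`, `process_rates`, `biochemical_derivatives`,
  `solve_speciation`, `gas_transfer`, `effluent_cod`): the 19-process
  mesophilic constant set, charge-balance pH, inhibition terms, gas–liquid
  transfer. A `"calibrated"` preset carries k_m_ac = 13.13, k_m_pro = 9.90,
  K_S_ac = 0.14, K_S_pro = 0.30 (1/d and kgCOD/m³).
* **Reactor network** (`build_isc_network`, `simulate_reactor`,
  `simulate_tracer`, `cod_balance`): the 2 L + 4 L + 10 L (1:2:5) default
  chain, a built-in stiff integrator (no external ODE solver needed),
  configurable granule retention, and exact COD-budget bookkeeping.
* **Scenarios & synthetic data** (`feed_recipe`, `map_feed`,
  `steady_scenario`, `organic_shock_scenario`, `hydraulic_shock_scenario`,
  `synthetic_tracer_experiment`, `synthetic_effluent_observations`):
  3 g/L glucose feed at COD:N:P = 200:5:1, 6× organic shock for 8 h,
  6× hydraulic shock for 12 h, seeded noise generators.
* **Sensitivity & calibration** (`absolute_relative_sensitivity`,
  `rank_parameters`, `chi_square`, `calibrate`): p·∂y/∂p central-difference
  sensitivities and Levenberg–Marquardt estimation of the four Monod
  constants against effluent-COD observations, weighted by
  χ² = Σ((y_meas − y)/σ_meas)².
* **Command line** (`icr_cli`, wrapper in `inst/exec/iscadm1`): subcommands
  `rtd-analyze`, `rtd-fit`, `simulate`, `tracer`, `sensitivity`,
  `calibrate`, `synth` over YAML run configs; artifacts carry a config hash
  and seed for byte-exact reproduction.

## Worked example

```r
library(iscadm1)

# hydraulics: analyse a synthetic pulse-tracer run at 24 h HRT
net <- build_isc_network(total_volume_L = 16, ratio = c(1, 2, 5))
tr  <- synthetic_tracer_experiment(net, hrt_h = 24, noise_sd_mg_L = 0, seed = 1)
rtd_summary(tr)
#>            run_id t_mean_h var_t_h2 theta_var   peclet dispersion_number  n_tanks
#> 1 synthetic_hrt24 22.90133 200.3579 0.3820193 3.929076         0.2545127 2.617669

# biochemistry: steady start-up at 3 g/L glucose, 24 h HRT, 60 days
sc  <- steady_scenario(feed_recipe(3), hrt_h = 24, volume_L = 16, t_end_h = 24 * 60)
sim <- simulate_reactor(net, sc, adm1_params("calibrated"), t_end_h = 24 * 60)
tail(sim$effluent, 1)
#>      time_h    cod_g_L     vfa_g_L       pH
#> 1441   1440 0.07188513 0.006298109 7.001818
100 * (3 - tail(sim$effluent$cod_g_L, 1)) / 3   # COD removal, %
#> [1] 97.60383
```

The tracer summary says the 16 L chain at 24 h nominal HRT behaves like
≈2.6 equivalent tanks (moderate back-mixing between plug flow and complete
mixing; the finite 3-HRT sampling window biases t̄ slightly). The
simulation reaches a steady effluent
of ≈0.07 g/L COD at pH 7.0 — a 97.6% removal, comfortably above the 80%
stable-running criterion for this reactor class.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the headline computation from scratch against the installed package:
it builds the 1:2:5 network, feeds 3 g/L glucose-based synthetic wastewater
at 24 h HRT with the calibrated kinetics, integrates 60 days, and writes the
steady-state COD removal percentage as JSON.

## Layout

```
R/            module surface (RTD, TIS, ADM1, network, scenarios, calibration, CLI)
src/          ADM1 derivative core + stiff integrator (Rcpp/RcppArmadillo)
tests/        testthat suite incl. acceptance criteria
scripts/      acceptance.R
vignettes/    methods vignette (model, assumptions, numerics, design choices)
```
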