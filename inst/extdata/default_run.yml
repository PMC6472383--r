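# Default run configuration: 1:2:5 three-tank chain (16 L), 3 g/L glucose
# feed at 24 h HRT, calibrated Monod constants, 60-day steady run.
reactor:
  total_volume_L: 16
  ratio: [1, 2, 5]
  headspace_total_L: 10
  solids_retention_factor: 50
  temperature_K: 310.15
feed:
  cod_g_L: 3
  cod_n_p_ratio: [200, 5, 1]
  fraction_as_sugar: 1
  cation_kmol_m3: 0.04
scenario:
  kind: steady
  hrt_h: 24
  t_end_h: 1440
kinetics:
  preset: calibrated
solver:
  rtol: 1.0e-6
  atol: 1.0e-10
  dt_out_h: 1
seed: 1
output_dir: "."
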