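# Example run configuration: water-regime two-Kubo fixture.
# Keys carry their units; see params_to_config() / read_run_config().
seed: 1
snr: 600
complex: false
grid:
  tau1_n: 16
  tau1_dt_ps: 0.25
  omega3_start_cm1: 2110
  omega3_step_cm1: 1.5
  omega3_n: 64
  omega_rf_cm1: 2110
truth:
  a01_au: 1.0
  a12_au: 1.1
  omega01_cm1: 2163.0
  d_omega1_cm1: 0.15
  anh_cm1: 25.5
  beta: 1.1
  inv_t_lt_ps1: 0.12
  inv_t_hom_ps1: 0.42
  phi0_rad: 0.0
  lt12_ratio: 0.5
  kubo1_delta_sq_cm2: 12.0
  kubo1_tau_ps: 0.4
  kubo2_delta_sq_cm2: 10.0
  kubo2_tau_ps: 3.6
model:
  n_kubo: 2
cls:
  n_exp: 2
  upper_fraction: 0.8
  inv_t_lt_ps1: 0.12
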