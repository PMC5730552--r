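seed: 1
out_dir: fgstdp-out
device:
  mode: tunneling
  tau_s: ~
  t_tun_nm: 1.3
  c_fg_fF: 2.0
  barrier_eV: 3.1
  m_star: 0.4
  area_nm2: 7200.0
synapse:
  dv_pre_mV: 180.0
  dv_post_mV: 135.0
  tau_pre_ms: 55.3991
  tau_post_ms: 274.244
  gain_pre: 3.6
  gain_post: 4.8
  theta_post_mV: 350.0
  theta_pre_mV: 330.0
  c_plus: 0.1
  c_minus: 0.054003
  lambda_plus_mV: 250.0
  lambda_minus_mV: 700.0
  vtc_vmax_mV: 500.0
  vtc_slope_mV: 200.0
  w_rest_mV: 151.0
  pairing_mode: nearest
neuron:
  tau_m_ms: 10.0
  threshold_mV: 90.0
  alpha: 0.3
  reset_mV: 0.0
protocol:
  kind: compete
  duration_s: 150.0
  rates_hz:
  - 5.0
  - 5.0
  rate_hz: 20.0
  bin_ms: 200.0
  dt_pair_ms: 1.0
  period_ms: 50.0
  sup_rate_hz: 50.0
  sup_weight_mV: 50.0
  synced_source: 1.0
  sample_dt_s: 0.5
variability:
  a_rdf: 1.27e-09
  a_ler: 1.04e-12
  vth_frac_per_mV: 0.01
  n_circuits: 200.0
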