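# The typical small excitatory synapse: default run configuration.
geometry:
  cleft_radius: {value: 200, unit: nm}
  psd_radius: {value: 110, unit: nm}
  cleft_height: {value: 19, unit: nm}
  outer_radius: {value: 2, unit: um}
receptors:
  - {kind: AMPAR, count: 50}
release:
  q: 2700
  mode: centre
engine:
  dt: {value: 0.1, unit: us}
  v_m: {value: -80, unit: mV}
  d_in: {value: 0.33, unit: um2_per_ms}
  d_out: {value: 0.4, unit: um2_per_ms}
  dr: {value: 10, unit: nm}
  rho_local: {value: 20, unit: nm}
  record_dt: {value: 1, unit: us}
seeds:
  base_seed: 1
  n_trials: 20
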