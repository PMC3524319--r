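# Example run configuration: priming thresholds, screening thresholds,
# generic protocol timing and search settings.
seed: 1
thresholds:
  tau_ld: 0.1
  tau_hd: 0.1
  rho: 0.5
  delta: 0.1
screening:
  fc: 2
  alpha: 0.05
  relaxed_fc: 1.5
protocol:
  ld_dose: 0.1
  hd_dose: 1
  ld_duration: 50
  hd_duration: 50
  wash: 0
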