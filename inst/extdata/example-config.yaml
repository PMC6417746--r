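# Example run configuration: MSO passive properties, default grid, frozen
# KLT, coincidence protocol settings.  Omitted keys take package defaults.
cell:
  Rin: 8.5        # MOhm
  tau_exp: 0.34   # ms
  Vrest: -58.0    # mV
  alpha: 0.01     # A2/A1
  Cm: 0.9         # uF/cm^2
grid:
  step: 0.05
  bounds: [0.1, 0.9]
channels:
  gna: 1.0
  gna_mode: x_gna_ref
  klt_placement: none
  klt_mode: frozen
  klt_fraction: 0.1
stimulus:
  freq: 500       # Hz
  mean_rate: 200  # spikes/s per fiber
  n_fibers: 5
  refractory: 0.75  # ms
protocol:
  n_trials: 100
  duration: 250   # ms
  noncoincident_mode: antiphase
seed: 1
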