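# Face-validation study configuration: 9 pre- and 9 post-onset windows at
# 1-s steps, cross-spectra modelled over 8-48 Hz, signal-to-noise ratio 4.
# Intrinsic (superficial-pyramidal self-inhibition) excursions of +2 log
# units decay with an 8-s time constant in both sources; the forward
# extrinsic excursion of +1 log unit decays with a 2-s time constant.
tau_intrinsic: 8        # s
tau_extrinsic: 2        # s
amplitudes:
  intrinsic1: 2.0       # log units at onset
  intrinsic2: 2.0
  forward: 1.0
n_pre: 9
n_post: 9
step: 1                 # s between window starts
snr: 4                  # RMS amplitude ratio, per channel and window
seed: 1
grid:
  from: 8               # Hz
  to: 48
  by: 1
architecture: fw_primary
invert_changes: [intrinsic1, intrinsic2, forward, backward]
basis_order: 3
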