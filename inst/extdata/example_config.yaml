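# Run configuration schema for the incmusic pipeline.
# Every field is optional; omitted fields fall back to the defaults shown
# by incmusic::default_config().
scenario:
  name: hemorrhage_growth      # hemorrhage_growth | negative_contrast | none
  position: [0.025, 0.025, 0.044]   # target center, meters
  v1_ml: 10                    # inclusion volume at first snapshot, mL
  v2_ml: 26                    # inclusion volume at second snapshot, mL
array:
  n_antennas: 16
  cap_radius: 0.10             # helmet cap sphere radius, m
  cap_extent: 120              # full opening angle, degrees
grid:
  x: [-0.07, 0.07]             # region under test, meters
  y: [-0.07, 0.07]
  z: [0.0, 0.088]
  spacing: 0.01                # in-plane voxel spacing, m
  n_slices: 11
frequencies:
  fmin: 1.0e9                  # Hz
  fmax: 2.0e9
  n: 50
noise:
  attenuation_db: 0            # channel attenuation (<= 0 dB)
  floor: 0                     # receiver noise RMS amplitude (linear)
  snr_db: 30                   # if set, overrides `floor` from the stack RMS
  seed: 1
method: both                   # music | migration | both
thresholds:
  tau: 0.1                     # relative singular-value threshold
  eps_floor: 1.0e-12           # pseudospectrum floor
  detection: 0.75              # detection threshold, fraction in (0, 1)
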