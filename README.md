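# incmusic

Differential Incoherent MUSIC imaging for helmet-style multistatic
microwave monitoring of evolving brain lesions.

## The problem

Hemorrhagic stroke monitoring needs a bedside-capable imager that can tell
whether a lesion is growing. Microwave systems exploit the strong
dielectric contrast between blood and brain matter: a wearable helmet of
`No = 16` antennas measures the multistatic scattering matrix of the head
at two time instants and images the *change*. Differencing the snapshots
cancels all static structure (skull, skin, helmet), so the approach needs
no matching medium and tolerates an uncalibrated background — the keys to
a wearable device.

`incmusic` implements the full computational chain on synthetic data, with
Touchstone import for measured data:

* **dielectrics** — tissue permittivity/conductivity tables at 1 GHz
  (numerical-phantom and measured-mixture sources), complex permittivity,
  the 75/25 white/gray brain blend, uncertainty sampling;
* **phantom** — helmet array, voxel grid, two-snapshot differential
  scenarios (10 → 26 mL hemorrhage growth, air-filled negative-contrast
  mirror), rasterization of the changed region;
* **forward** — linear (Born) synthesis of the differential multistatic
  stack `ΔS(ωᵢ) = Hr A(ωᵢ) δC(ωᵢ) Aᵀ(ωᵢ) Ht` over 50 frequencies in
  [1, 2] GHz, channel attenuation, receiver noise, and a Monte Carlo
  channel-stability harness;
* **imaging** — differential Incoherent MUSIC
  (`ϕ(ωᵢ, rₙ) = 1 / ‖P_N SVₙ(ωᵢ)‖²`, incoherent product
  `Φ = ∏ᵢ ϕ(ωᵢ, ·)`, slice-stacked 3D volume), the Incoherent Migration
  baseline, and binary target detection;
* **metrics** — signal-to-clutter ratio (SCR), signal-to-mean ratio
  (SMR), spatial displacement (SD), support displacement;
* **io / cli** — JSON stack/volume containers, 16-port Touchstone v1
  snapshot pairs, YAML run configs, and an `incmusic` command-line
  pipeline (`simulate`, `image`, `score`, `study-attenuation`,
  `end2end`).

## Worked example

Simulate a hemorrhage growing from 10 to 26 mL (a 16 mL differential
target) under the standard helmet, add receiver noise at 30 dB SNR, image
with MUSIC, and score against the known truth:

```r
library(incmusic)

arr   <- make_helmet()                    # 16 antennas, rings of 6/6/4
grid  <- make_grid()                      # 14 x 14 x 11 voxels, 11 slices
freqs <- frequency_grid()                 # 50 points, [1, 2] GHz

scene <- hemorrhage_growth_scenario(c(0.025, 0.025, 0.044))
stack <- simulate_stack(scene, arr, grid, freqs)
noisy <- add_noise_snr(stack, snr_db = 30, rng_seed = 1)

vol  <- music_image(noisy, background = scene$background)
mask <- truth_mask(scene, grid)
rep  <- score_reconstruction(vol, mask, report = detect(vol))

print(stack)
print(vol)
print(rep)
```

```
<diff_stack> 50 frequencies (1.00-2.00 GHz), 16 x 16 matrices
<pseudospectrum_volume> MUSIC, 14 x 14 x 11; peak at (25, 25, 60) mm
<reconstruction_report> MUSIC: TARGET DETECTED (statistic 83.1), peak at (25, 25, 60) mm, slice 8
  SCR 300.00 dB, SMR 802.88 dB, SD 16.00 mm
```

Reading the numbers: the target is declared detected (the log-domain
peak-to-median statistic 83.1 far exceeds the clutter-only level, which
sits near 10). The peak lands at (25, 25, 60) mm — exactly on the spherical
shell of voxels that changed between the snapshots, i.e. zero displacement
from the true changed region (`sd_support_voxels()` returns 0). The
center-referenced SD of 16 mm is the shell radius: for a growing inclusion
the center itself contains no scatterer, so SD is bounded below by the
inner shell radius even for a perfect reconstruction. SCR is reported at
its 300 dB cap and SMR at ≈ 800 dB — incoherent products over 50
frequencies produce astronomically deep clutter floors on synthetic
noise-limited data; these figures compare methods within a run (MUSIC's
dynamic range is consistently far above Migration's ≈ 116 dB) and are not
comparable to bench measurements.

The same chain runs from the shell:

```sh
exec/incmusic end2end --out-dir runs/demo --seed 1
exec/incmusic study-attenuation --out att.csv --trials 200
```

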