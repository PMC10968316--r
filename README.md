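# mrmotionsim

Simulation of rigid-body motion artifacts in brain MR images, paired-dataset
construction for artifact-reduction networks, and the matching quantitative
evaluation suite — in R, with no scanner raw data required.

## The problem

Head motion during an MR scan corrupts the acquisition in a very specific
way: k-space is filled one phase-encode line per repetition time, so a
movement leaves every line acquired *before* it consistent with the original
anatomy and every line *after* it consistent with the moved anatomy. The
reconstructed magnitude image mixes the two and shows ghosting and streaks
along the phase-encode direction. Deep artifact-reduction models (U-Net
style encoder–decoders) need large sets of perfectly paired clean/corrupted
images, which real scanners cannot provide — but this acquisition physics
can be simulated on top of ordinary magnitude images.

`mrmotionsim` is for researchers building or evaluating such models. It
implements:

- **Motion simulation** — per-slice random rigid motion schedules
  (rotations uniform in ±5°, translations uniform in ±10 px on each axis,
  2–4 cumulative unrestored movements, first onset after more than half the
  acquisition), full-3D volume transforms, and k-space line replacement:
  each phase-encode line of the composite k-space is taken from the motion
  state active at its acquisition time,

  `artifact = |IFFT( compose(FFT(clean slice), FFT(moved slices), schedule) )|`,

  with the signed residual map `artifact − clean` as a second learning
  target.
- **Dataset construction** — one paired sample (clean, artifact, residual,
  schedule) per slice; 200 volumes × a 50-slice extraction window give
  10,000 pairs, split 7000/1000/2000 under the default 0.7/0.1/0.2
  fractions; persisted as NIfTI stacks plus a JSON manifest.
- **Metrics** — RMSE, PSNR `= 10·log10(S²peak/RMSE²)`, Pearson CC, and the
  universal image quality index
  `UQI = 4·μf·μg·σfg / ((μf²+μg²)(σf²+σg²))`; reference-free background COV
  `σb/μb` and CNR `(μt−μb)/√(σt²+σb²)` with k-means (k = 4) intensity
  segmentation; paired t-tests between methods.
- **A network harness** — the encoder–decoder architecture (two 3×3
  conv + ReLU + BN per level, stride-2 max pooling, channel doubling from a
  64-map first level, transposed-conv upsampling with concatenation skips,
  1×1 output head; L2 loss, Adam, defaults lr 5e-4 / 300 epochs),
  hand-implemented with exact backpropagation, trainable at desk scale in
  both direct-image and residual-map modes.
- **A synthetic phantom** — nested-ellipsoid volumes (background, white-,
  gray-, and bright CSF-like classes) with known labels, so the entire
  pipeline is testable without external data.

## Worked example

```r
library(mrmotionsim)

# a 64x64x60 phantom, normalized, with the standard 50-slice window
ph  <- generate_phantom(phantom_spec(matrix_size = 64, n_slices = 60,
                                     noise_sd = 0.01, seed = 7))
v   <- extract_center_slices(normalize_volume(ph$volume), 50)

# per-slice random motion + k-space line replacement
sim <- simulate_artifact_volume(v, simulation_params(), seed = 7)
print(sim$schedules[[25]])
#> <motion_schedule> 4 event(s) over 64 phase-encode lines
#>   line  39: rot (-0.31, -1.45, +0.13) deg, shift (-1.85, +9.02, +7.30) px
#>   line  53: rot (+2.94, -1.45, -2.40) deg, shift (-9.06, +6.76, +1.29) px
#>   line  55: rot (+4.04, -1.43, +4.14) deg, shift (-5.56, +3.15, +3.39) px
#>   line  57: rot (+4.11, -2.96, +0.11) deg, shift (-2.70, +4.18, -0.52) px

# how corrupted are the artifact slices, against their motion-free originals?
refs <- lapply(1:50, function(z) v$data[, , z])
arts <- lapply(1:50, function(z) sim$artifact$data[, , z])
evaluate_pairs(refs, arts)
#> <metrics_report> 50 pair(s)
#>   rmse    0.0382 +/- 0.0263
#>   psnr   27.3538 +/- 5.4928
#>   uqi     0.9744 +/- 0.0307
#>   cc      0.9808 +/- 0.0232
```

Slice 25's acquisition was interrupted by four movements, the first after
line 39 of 64 — so the first 39 lines (including the contrast-carrying
center of k-space) are motion-free and the later, high-frequency lines come
from progressively displaced anatomy. Across the 50 slices the corruption
averages RMSE 0.038 (intensities in [0, 1]) and PSNR 27.4 dB; UQI and CC
stay near 1 because the onset constraint preserves gross contrast. The
per-slice spread (± values are SDs) is the point: schedules differ per
slice, so a dataset built this way spans mild to severe artifacts.

Training the artifact-reduction network on such pairs:

```r
samples <- build_pairs(list(v), simulation_params(), seed = 7)
split   <- split_dataset(samples, c(0.7, 0.1, 0.2), seed = 7)
cfg     <- unet_config(depth = 2, base_channels = 8, epochs = 150,
                       batch_size = 4, learning_rate = 1e-3,
                       mode = "residual", seed = 7)
model   <- train_unet(build_unet(cfg), samples, split = split)
fixed   <- correct_image(model, samples[[split$test[1]]]$artifact)
```

A command-line front end (`inst/cli/mrmotionsim.R`) exposes `phantom`,
`extract`, `simulate`, `evaluate` and `run` (full YAML-configured pipeline
via `run_pipeline()`).

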