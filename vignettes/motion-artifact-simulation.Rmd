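---
title: "Simulating rigid-body motion artifacts in brain MR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rigid-body motion artifacts in brain MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmotionsim)
```

## The physical model

An MR image is acquired line by line in the spatial-frequency domain
(k-space): one phase-encode line per repetition time (TR). If the head moves
during the scan, the lines acquired after the movement are the Fourier data
of a *different* (rigidly moved) anatomy. The reconstructed image mixes the
two inconsistent data sets, which appears as ghosting and streaking along
the phase-encode direction.

`mrmotionsim` reproduces this process directly:

1. A motion schedule is sampled for each slice: the number of movements, the
   TR (phase-encode line) at which each occurs, and each movement's rigid
   transform (three rotations, three translations).
2. The whole 3D volume is moved through the schedule's states. Movements
   accumulate — the anatomy is never restored to its pre-movement position —
   so state $k$ is obtained by transforming state $k-1$. Because the moves
   are volumetric, through-plane (z-axis, nodding/swallowing-like) motion is
   represented, not just in-plane displacement.
3. For one slice, the motion-free image and every state's matching slice are
   transformed to centered 2D k-space. Walking the phase-encode lines in
   acquisition order, each line of the composite k-space is taken from the
   state active at its acquisition time.
4. The inverse transform's complex magnitude is the motion-artifact image,
   and the signed difference `artifact - clean` is the residual map.

The per-slice records (clean, artifact, residual, schedule) feed a paired
dataset for training artifact-reduction networks in two modes: *direct*
(artifact in, clean image out) and *residual* (artifact in, residual map
out; the correction subtracts the prediction from the input).

## Default simulation parameters

| parameter | default | meaning |
|---|---|---|
| `max_rotation_deg` | 5 | per-axis rotation bound, degrees |
| `max_translation_px` | 10 | per-axis translation bound, pixels |
| `n_movements_range` | 2–4 | movements per slice acquisition |
| `min_onset_fraction` | 0.5 | fraction of lines acquired before the first movement |
| `per_slice_independent` | TRUE | fresh random schedule per slice |
| `cumulative_resampling` | TRUE | transform the previous state, not the original |
| `interpolation` | trilinear | resampling kernel |
| `ordering` | linear | phase-encode acquisition order |

These defaults are the study conditions of the simulation protocol this
package implements: uniform random rotations within ±5°, translations
within ±10 pixels, two to four unrestored movements, and a first onset
constrained past half of the acquisition. Under linear ordering that
constraint keeps every line up to and including the zero-frequency (DC) line
motion-free, which is what keeps the gross contrast of the corrupted image
anchored to the true anatomy. Note that the constraint protects the *first
half* of the centered layout: lines immediately *after* DC may legitimately
be corrupted, so a symmetric band around DC is not guaranteed clean.

Choices the protocol leaves open, fixed here and exposed as options:

* **Rotation convention.** Intrinsic rotations about the volume center in
  the fixed order x, then y, then z, in degrees. Any fixed order is
  acceptable for bounded random angles; fixing one makes runs reproducible.
* **Acquisition ordering.** `"linear"` (sequential, one line per TR,
  echo-train length 1) is the default; with it, the half-acquisition onset
  constraint protects the k-space center, which is the stated reason for the
  constraint. `"centric"` (center-out) is available for sensitivity
  analyses; under it, late movements corrupt only the k-space periphery.
* **Cumulative vs composed resampling.** Transforming the previous state
  (`cumulative_resampling = TRUE`) matches the physical accumulation of
  motion but compounds interpolation smoothing; composing the rigid
  transforms and resampling the original once avoids the compounding. The
  two agree exactly for integer translations and within interpolation
  tolerance otherwise; cumulative is the default as the more faithful
  reading of unrestored motion.
* **Magnitude reconstruction.** A composed k-space is not conjugate
  symmetric, so its inverse transform is complex; the complex magnitude is
  taken, as MR images are magnitude images (option: real part).
* **Signed residuals.** Residual maps are stored signed so that
  `clean + residual == artifact` holds exactly and residual-mode correction
  is algebraically invertible. Absolute values are a display choice only.
* **Onset constraint scope.** The half-acquisition constraint is applied to
  all onsets, not only the first; since onsets are sorted and motion is
  never restored, later onsets necessarily exceed the first, so this is
  equivalent for the first movement and simply keeps the candidate set one
  uniform pool.

Numerical details: resampling outside the field of view yields zero
(an object moving out of frame leaves signal-free space); interpolated
intensities are clipped at zero because magnitudes are nonnegative; the FFT
convention is unnormalized forward / $1/N$ inverse with centered layout, so
Parseval's identity reads $\sum |f|^2 = \sum |F|^2 / N$.

## The synthetic phantom

Real T2-weighted brain volumes cannot ship with a package, so every stage is
exercised on a synthetic phantom: nested ellipsoids of distinct mean
intensity — background 0, a white-matter-like body (0.4), a gray-matter-like
interior (0.6), and a small bright CSF-like ventricle pair (0.95) — plus
additive Gaussian voxel noise (default sd 0.01) and a known voxel-wise label
mask. The bright CSF-like class matters: high-intensity structures dominate
ghosting behavior on T2-weighted images, so tests exercise that regime.

What the phantom does *not* emulate: anatomical texture and gyral
structure, Rician noise statistics of magnitude images (Gaussian is used so
metric oracles stay closed-form), intensity inhomogeneity, and partial
volume effects. Passing tests therefore demonstrate the correctness of the
simulation/bookkeeping machinery and the trainability of the networks on
well-posed data — not clinical performance on scanner images.

```{r phantom, eval = FALSE}
ph <- generate_phantom(phantom_spec(matrix_size = 64, n_slices = 60,
                                    noise_sd = 0.01, seed = 7))
v <- extract_center_slices(normalize_volume(ph$volume), 50)
sim <- simulate_artifact_volume(v, simulation_params(), seed = 7)
```

## Dataset bookkeeping

`build_pairs()` emits one paired sample per slice, so 200 volumes with the
standard 50-slice extraction window yield exactly 10,000 pairs, and the
default 0.7/0.1/0.2 split partitions them 7000/1000/2000
(floor-sized partitions, remainder to train). Splitting is slice-level by
default, which reproduces those counts; `by_subject = TRUE` keeps all slices
of a subject in one partition — methodologically safer against subject
leakage, at the cost of only-approximate partition sizes. The 50-slice
window is centered on the geometric middle slice by default; an anatomical
landmark (widest lateral-ventricle view) is what the window is meant to
approximate on real data, so a `center_index` override and a bright-area
heuristic (`center = "auto"`, area above the 95th intensity percentile as a
CSF proxy) are provided.

The dataset container is a directory of three NIfTI-1 stacks
(clean/artifact/residual) plus a JSON manifest carrying subjects, slice
indices, every motion schedule, and the split — any artifact image is
exactly reproducible from its schedule sidecar.

## Quality metrics

Similarity metrics between a reference $f$ and comparison $g$:
RMSE $=\sqrt{\sum_i (f_i-g_i)^2 / N}$; PSNR
$=10\log_{10}(S_\text{peak}^2/\text{RMSE}^2)$ with $S_\text{peak}$ the
reference maximum (whole frame by default, a region of interest if given);
Pearson CC; and the universal image quality index
$\text{UQI} = 4\mu_f\mu_g\sigma_{fg} /
((\mu_f^2+\mu_g^2)(\sigma_f^2+\sigma_g^2))$, computed globally (no sliding
window, since no window size is part of the printed definition). Population
(divide-by-$N$) moments are used throughout, matching the plain sums of the
definitions. PSNR of identical images is reported as an `Inf` sentinel and
excluded from aggregates rather than raised as an error, so batch
evaluation never aborts.

Reference-free metrics for images without a ground truth: background
coefficient of variation $\text{COV} = \sigma_b/\mu_b$ (artifacts spray
signal into air, raising it) and contrast-to-noise ratio
$\text{CNR} = (\mu_t-\mu_b)/\sqrt{\sigma_t^2+\sigma_b^2}$. Their masks come
from k-means clustering of pixel intensities with $k = 4$ (background,
white-, gray-, CSF-like; $k$ is a free choice — four matches the phantom's
class count and typical brain tissue models). Clusters are relabeled by
ascending mean so label 0 is always background; gray matter is taken as the
second-brightest cluster by default. Initial centers are spread evenly over
the intensity range — with heavily imbalanced classes (air dominates, CSF is
tiny) random-subset initialization regularly loses the small bright
cluster, while range-spaced centers start near every mode; a seeded
random-restart fallback covers degenerate cases. Method comparisons use
two-sided paired t-tests on per-pair metric values.

## The artifact-reduction network

The network is the classic encoder–decoder with skip connections: per
contraction level two 3×3 convolutions, each followed by ReLU and batch
normalization, then stride-2 max pooling; 64 feature maps at the first
level, doubling per level (the default depth of 4 gives 64-128-256-512 and
a 1024-channel bottleneck); an expansion path that upsamples with stride-2
transposed convolutions, halves the channels back down to 64 and
concatenates the matching encoder features; and a final 1×1 convolution to
one channel. Training minimizes mean squared error with Adam at learning
rate 5e-4 for 300 epochs in the full-scale configuration.

Implementation choices where the architecture family leaves room:

* **Upsampling** is a 2×2 stride-2 transposed convolution (learned), the
  common reading of "upsampling with stride 2"; skip connections are channel
  concatenation.
* **Zero-initialized head.** The final 1×1 convolution starts at zero, so
  the untrained network predicts a zero image (residual mode therefore
  starts exactly at the identity correction). The head's own gradient is
  nonzero from the first step, so training is not impeded, and early
  optimization is much better conditioned.
* **Normalization statistics at inference** default to the running averages
  accumulated during training (`bn_inference = "running"`). The
  instance-style alternative (each input normalized by its own statistics)
  is available but degrades direct-mode reconstruction, which depends on
  absolute intensity calibration that single-image statistics disturb.
* **Learning-rate schedule.** A step decay (×0.1 after 60% and 85% of
  epochs) stabilizes the late phase of small-batch training; set
  `lr_decay = 1` for a constant rate.
* Weights elsewhere are He-scaled Gaussians, seeded; batch shuffling derives
  from the same seed, so training is reproducible up to floating-point
  summation order.

Direct and residual modes share everything except the target tensor fed to
the loss, which makes their comparison a controlled experiment; residual
mode's corrected image is `artifact - predicted_residual`, clipped at zero.

## Desk-scale training and what it shows

The full-scale regime (256×256, 7000 training pairs, 300 epochs) is far
beyond a package check, so the shipped tests and the acceptance script run
a desk-scale configuration chosen once: 20 pairs (two 10-slice phantoms at
64×64), depth 2, 8 base channels, batch 4, learning rate 1e-3, 150 epochs
— a few minutes per mode on one CPU. Under this budget both modes reduce
held-out RMSE below the uncorrected artifacts, and residual-map training
typically matches or beats direct-image training, the directional
counterpart of the full-scale finding that residual learning is the easier
estimation problem (the residual carries only artifact structure, while a
direct image entangles anatomy, contrast and noise with the artifact). At
this scale the margin between the modes is within sampling noise for some
seeds, so the mode comparison is reported, not hard-asserted; the
*reduction versus uncorrected input* is asserted.

Problem sizes used by the test suite and acceptance script: the bookkeeping
check builds the full 10,000-pair set at 64×64 (about 3 minutes); the
k-space composition oracle runs 100 randomized small instances exactly; the
schedule-constraint check draws 1,000 seeded schedules; the learning check
trains both modes at the desk scale above.

## Known limitations

* Motion occurs between lines (one line per TR, echo-train length 1);
  intra-line motion, echo trains (the `ordering`/onset machinery supports
  adding them), spin-history and B0 effects are not modeled.
* 2D (slice-wise) k-space corruption only; no volumetric encoding,
  multi-coil acquisition or k-space noise injection.
* The phantom is geometric; conclusions about clinical images require real
  data through the same interfaces (`read_volume`, `build_pairs`).
* The hand-written network harness is CPU-bound and deliberately small; it
  is an architecture contract and desk-scale testbed, not a replacement for
  a GPU training stack at the full study scale.
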