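---
title: "Phase-space ECG biometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-space ECG biometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

`ecgpsr` identifies individuals from single heartbeats of single-lead ECG.
The core idea is a temporal-to-spatial transform: instead of classifying the
beat waveform directly, each beat is embedded into a two-dimensional phase
space by plotting the signal against a delayed copy of itself,

$$X(t) = [\,x_n(t)\;\; x_n(t+\tau)\,],$$

where $x_n$ is the beat normalized to $[0,1]$ and $\tau$ is the time delay.
The P wave, QRS complex and T wave of a cardiac cycle map to distinct loops
in this plane — a minor loop, a dominant outer loop, and an inner loop —
whose geometry is characteristic of the individual's cardiac conduction and
torso projection, while being far less sensitive to R-peak alignment and
interval variability than the raw waveform. The trajectory is discretized
over an $r \times r$ grid of the unit square, recording only the absence or
presence of the trajectory in each cell. The resulting binary phase
portrait is the input image of a convolutional network with one output unit
per enrolled individual.

The processing chain for one recording is:

1. **Band-limiting.** Zero-phase (forward–backward) Butterworth filters:
   high-pass at 1 Hz against baseline wander, low-pass at 40 Hz against
   high-frequency noise. Each pass is order 2, so the effective magnitude
   response is order 4. Zero-phase filtering is essential here because the
   fiducial timing must not shift.
2. **QRS detection.** A Pan–Tompkins-style detector: 5–15 Hz band-pass,
   differentiation, squaring, 150 ms moving-window integration, adaptive
   dual thresholds with running signal/noise estimates, search-back over
   long gaps at half threshold, a 200 ms refractory period, and the
   standard T-wave discrimination rule (a candidate within 360 ms of the
   previous beat whose maximal slope is below half the previous beat's is
   rejected). Detections are snapped to the local absolute maximum of the
   1–40 Hz signal within ±50 ms, so the fiducial is the R peak itself.
3. **Verification.** A fiducial is kept only if both adjacent RR intervals
   are within ±20% of the record's median RR and its ±100 ms QRS window
   correlates at least 0.8 with the record's median QRS template. This
   removes false detections and ectopic beats. These three thresholds are
   not principled constants; they are exposed as arguments of
   `verify_beats()`.
4. **Segmentation.** One cardiac cycle per beat, with 35% of the cycle
   before the fiducial and 65% after. The cycle length is fixed at the
   record's median RR rather than each beat's own RR, so that all of a
   record's segments (and hence portraits) have identical length; beats
   whose window would overrun the record are dropped.
5. **Portrait construction.** Upsample ×10 by Gaussian interpolation,
   normalize to $[0,1]$, delay-embed, rasterize over $r \times r$, and
   resize to the network's input size by block replication
   (`beat_to_portrait()`).
6. **Identification.** A CNN trained with Adam on cross-entropy for 75
   epochs (dropout 0.5 on the two hidden classifier layers), scored each
   epoch as the percentage of correctly identified validation beats.

Two reference architectures are built in: `build_original_spec()`, an
AlexNet-derived five-convolution network for 256 × 256 portraits
(72,362,963 parameters at 115 classes), and `build_scaled_spec()`, a
two-convolution reduction for 32 × 32 portraits (6,711,251 parameters) —
roughly a tenfold size reduction at comparable accuracy on well-chosen
$(\tau, r)$.

The factorial experiment (`run_sweep()`) crosses ten delays
$\tau \in \{2, 4, 8, 12, 16, 20, 24, 28, 32, 36\}$ ms with five grid
densities $r \in \{16, 32, 64, 128, 256\}$ — 50 combinations — and reports
per-epoch validation accuracy plus stage averages over epochs 16–30,
31–45, 46–60 and 61–75. Small delays contract the trajectory toward the
diagonal (under-expanded loops) and coarse grids blur the loop detail;
both depress early-epoch accuracy, which is the qualitative signature the
synthetic experiments reproduce.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau_ms` | 2–36 (sweep), 20–28 best | ms | expansion of P/QRS/T loops |
| `partitions` (r) | 16–256 (sweep) | cells/axis | portrait detail |
| `out_pixels` | 256 (original net), 32 (scaled) | px | network input size |
| `upsample_factor` | 10 | — | trajectory continuity; makes all printed delays exactly representable at the upsampled rate |
| `train_beats` / `val_beats` | 100 / 25 | beats | chronological split |
| `epochs` | 75 | — | training protocol |
| `dropout` | 0.5 | — | classifier regularization |
| `learning_rate` | 1e-3 | — | Adam default on small image batches |
| `batch_size` | 32 | — | CPU-friendly minibatch |

The delay is converted to samples at the upsampled rate,
`tau_samples = round(tau_ms * fs * 10 / 1000)`, so at 1 kSa/s every delay
from 2 to 36 ms is exact.

## The synthetic cohort generator

Real archival ECG cannot be redistributed with the package, so every stage
is exercised on synthetic cohorts (`make_subject()`, `synthesize_record()`,
`make_cohort()`) built to have the statistical structure the method relies
on:

- **Per-subject morphology.** Each beat is a sum of five Gaussians (P, Q,
  R, S, T) with subject-specific amplitudes, centers (fractions of the
  cardiac cycle) and widths drawn from normal lead-I ranges (R 0.8–1.5 mV,
  P 0.05–0.2 mV, T 0.1–0.4 mV, Q and S −0.3 to −0.05 mV). No U wave is
  modelled: it contributes no visible loop at these amplitudes. The width
  parameter is a wave's effective *duration*: the Gaussian standard
  deviation is width/4 for the sharp QRS deflections (8–20 ms durations)
  and width/2 for the smooth P and T waves (40–90 ms), which keeps Q/S
  tails from smearing into the R peak — with broader readings the record
  maximum no longer equals the R amplitude, which both the R-peak fiducial
  logic and the generator's ground-truth annotations assume.
- **Beat-to-beat variability.** Per-beat RR intervals are drawn from
  Normal(`mean_rr`, 30 ms); the whole beat is scaled by
  $1 + 0.05\,\sin(2\pi\,0.25\,t)$, a respiration-like amplitude
  modulation. Intra-beat intervals (P–R, R–T) scale with $\sqrt{RR}$
  rather than RR — the physiological QT–RR relation — so consecutive
  beats of one subject stay highly correlated (> 0.95 on band-limited
  beats at default variability) while still producing visible loop
  variation across a recording.
- **Noise.** 0.2 Hz sinusoidal baseline wander (0.05 mV) plus white noise
  (0.02 mV), levels typical of a clean resting recording.
- **Determinism.** Every generator output is a pure function of its seed;
  a global cohort seed fans out into per-subject sub-seeds through a
  counter scheme, so cohorts are reproducible and extensible.

What the generator does *not* emulate: pathological beats (ectopy,
bigeminy), realistic heart-rate-variability spectra, electrode artifacts,
12-lead geometry. Synthetic subjects are also more mutually distinct than
a large human cohort, so passing identification tests here demonstrates
that the pipeline works end-to-end and learns portrait geometry — not
that it would attain the same accuracy on archival clinical data.

## Numerical choices

- **Gaussian interpolation kernel**: σ = 0.5 original sample periods,
  truncated at ±4σ, weights renormalized to sum to one at each query
  point; query points that coincide with an input sample return it
  exactly, so the interpolant passes through the data.
- **Upsample before normalize**, in that order; the two nearly commute and
  the difference is below one grid cell at r ≤ 256.
- **Rasterization marks sample points only** — no line segments between
  consecutive points. At the ×10 upsampled rate consecutive points are
  near-adjacent, so gap cells can only appear on the steepest QRS slopes;
  accepted and documented rather than patched with line drawing.
- **Grid orientation**: column index `min(floor(x*r), r-1)`, row index
  `r-1 - min(floor(y*r), r-1)` (y up, matrix row 1 on top); boundary
  coordinates at 1 are clamped into the last cell. Classification is
  orientation-invariant as long as the convention is fixed.
- **Nearest-neighbour block resize** keeps portraits strictly binary and
  preserves the occupied fraction exactly; a bilinear resize would create
  gray values.
- **Cycle length = record median RR** (not per-beat RR): equal-length
  segments give portraits a consistent point budget per beat.
- **Training engine**: convolutions run as im2col gathers plus BLAS
  matrix products; max-pooling tracks argmax positions for gradient
  routing; the Adam update is a fused in-place C kernel (one pass per
  tensor) because elementwise updates of the 6.7M-parameter classifier
  dominated profile time. Backpropagation is validated against
  finite-difference gradients in the test suite. Weight initialization is
  fan-in-scaled Gaussian; softmax is folded into the cross-entropy loss
  during training and applied explicitly at inference.
- **Determinism**: initialization, per-epoch shuffling and dropout masks
  draw from one stream seeded by `experiment_config(seed=)`; identical
  configurations reproduce identical accuracy traces bit for bit.
- **Degenerate inputs**: constant beats are rejected at normalization;
  out-of-range rasterization coordinates are errors, not clamped (only
  the exact boundary value 1 is clamped); sweep cells that fail are
  recorded with their error message and never abort the sweep.

## Design choices where the design was open

- The fifth convolution of the original architecture is wired 384 → 256
  channels; the alternative reading of its printed input shape is
  inconsistent with the preceding layer and with the published parameter
  total, which this wiring reproduces exactly.
- The first pooling layer is 2 × 2 stride 2 as tabulated, although the
  AlexNet ancestor uses overlapping 3 × 3 pooling there.
- Verification thresholds (±20% RR, correlation 0.8, ±100 ms window) and
  screening rules (≥ 100 s duration, ≥ 125 verified beats) are fixed
  defaults exposed as arguments. Inside `run_sweep()` screening is
  relaxed to "enough beats to fill the 100/25 split", since synthetic
  records of 130 beats at fast heart rates legitimately run under 100 s.
- Recordings are screened on duration and beat count only; no automatic
  noise-quality judgement is attempted.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` size the experiments for a
single CPU: cohorts of 10 subjects × 130 beats (≥ 125 surviving
verification, matching the 100 training + 25 validation budget), the
scaled-down network on 32 × 32 portraits, 30 training epochs for the
end-to-end identification check (≥ 95% validation accuracy) and 5 epochs
× 3 seeds for the early-epoch ordering check (τ = 24 ms, r = 32 versus
τ = 2 ms, r = 16). Unit tests use 3-subject cohorts and a small
single-convolution network. The full 50-cell sweep at 75 epochs with the
original network is enumerated and interface-tested but not trained in
the suite; it is the configuration `run_sweep()` defaults to.

## Known limitations

- Occupancy is point-based; a pathologically fast deflection could leave
  single-cell gaps in a loop at r = 256.
- The WFDB reader supports format 16 single-file records (the layout of
  the target archive); other storage formats are out of scope.
- The engine is CPU-only and sized for desk-scale experiments; the
  original 72M-parameter network is runnable (and its parameter count and
  shapes are exactly verified) but training it at full sweep scale is a
  GPU-class workload.
- Accuracy figures obtained on synthetic cohorts are not comparable to
  accuracies on clinical databases; see the generator section above.
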