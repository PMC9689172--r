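---
title: "Staging hepatic fibrosis from ultrasound RF signals: methods and design"
author: "fibrocnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging hepatic fibrosis from ultrasound RF signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liver fibrosis is staged histologically on the METAVIR scale, F0 (no
fibrosis) to F4 (cirrhosis), from a biopsy — an invasive reference standard.
The raw radiofrequency (RF) echo signal received by an ultrasound
transducer, *before* envelope detection and image formation, retains phase
and spectral content that B-mode images discard, and the statistics of the
backscattered signal encode the sub-resolution microstructure of the
tissue. `fibrocnn` implements a pipeline that classifies fibrosis severity
directly from these raw signals: each axial scan line (A-line) segment is
classified by a compact one-dimensional convolutional neural network (CNN),
and a frame-level decision is made by majority vote over its 256 A-lines.

Four binary tasks dichotomize the METAVIR scale at successive cut-offs:
`geF1` (F0 vs F1–F4), `geF2` (F0–F1 vs F2–F4), `geF3` (F0–F2 vs F3–F4) and
`geF4` (F0–F3 vs F4). One model is trained per task.

## Pipeline

1. **Acquisition model.** A frame is 256 A-lines of 1247 samples, acquired
   at 12 MHz sampling with a 3 MHz convex-array transducer. Frames are
   stored as flat little-endian float32 binaries (axial-major) with a JSON
   sidecar; a cohort is a CSV manifest `case_id,stage,frame_path`.
2. **ROI.** A fixed 1100 × 256 (axial × lateral) region of interest is cut
   from each frame. The axial offset defaults to the centered position,
   `floor((1247 - 1100)/2) = 73`; an explicit `roi_spec()` emulates manual
   placement. B-mode reconstruction (analytic-signal envelope + log
   compression) is provided for visual inspection only — the classifier
   consumes RF, not images.
3. **Normalization.** Each window is min–max normalized,
   `X' = (X - X_min)/(X_max - X_min)`, with one global minimum and maximum
   per window (not per A-line): normalization is defined for a frame of ROI
   signals as a whole. This removes acquisition-dependent amplitude scale
   while preserving the relative envelope statistics within the window.
4. **Class-balancing augmentation.** With `N0` minority-class frames and
   `N1` majority-class frames, the minority class is augmented
   `N_aug = round(N1/N0)` times (ties round up, minimum 1) by sliding a
   1024 × 256 window through the ROI in steps of `(1100 - 1024)/N_aug`.
   Offsets are integerized as `floor(i * 76/N_aug)`, which guarantees
   exactly `N_aug` in-bounds windows; majority frames contribute a single
   window at offset 0. For the default cohort's `geF1` task (23 vs 207
   frames) this gives a 9-fold augmentation with offsets
   0, 8, 16, 25, 33, 42, 50, 59, 67.
5. **Split.** Windows are shuffled under a seed and divided 80%/10%/10%
   into training/validation/test, sizes `floor(0.8n)` and `floor(0.1n)`
   with the remainder in the test partition. The default granularity is
   per-window; because overlapping windows of one case are near-duplicates,
   `group_by_case = TRUE` is recommended when leakage matters, and
   `stratify = TRUE` guarantees both classes in every partition.
6. **Network.** Four stride-1 1-D convolutions (kernel 3, length-preserving
   padding, channels 1→4→8→16→16), each followed by Tanh and max-pooling of
   4 (1024 → 256 → 64 → 16 → 4 samples), a flatten to 64 features, three
   Tanh fully connected layers (128, 38, 4) and a linear 2-class output —
   14,692 trainable parameters in total, verified both by a closed-form
   counter and by tallying the instantiated weight arrays.
7. **Training.** Adam (learning rate 1e-3, betas 0.9/0.999), softmax
   cross-entropy, batch size 256, 100 epochs by default. Mini-batches are
   reshuffled every epoch under a seed; the last incomplete batch is kept;
   no weight decay, schedule or early stopping. The final-epoch model is
   used by default; `keep_best = TRUE` restores the lowest-validation-loss
   epoch instead.
8. **Prediction and evaluation.** Every A-line segment of a test window is
   classified by score argmax; the frame's positive-vote fraction is its
   score, and the frame is called positive under a *strict* majority
   (fraction > 0.5, so an exact 128/256 tie is a negative call). Frame-level
   ACC/SEN/SPE come from the 2 × 2 confusion table; the ROC is swept over
   the unique frame scores and the AUC integrated by the trapezoidal rule,
   with a DeLong 95% CI (bootstrap available).

## The synthetic phantom

The package is fully testable without clinical recordings: the
`synthetic_phantom` module generates scanner-realistic frames from a
scatterer-ensemble model. Per A-line, a Poisson number of point scatterers
(mean = density × depth / resolution cell) is placed uniformly over depth
with zero-mean Gaussian amplitudes, and the impulse train is convolved with
a Gaussian-modulated 3 MHz pulse (fractional −6 dB bandwidth 0.6, truncated
at ±3σ). The resolution cell is defined as the pulse's −6 dB envelope
duration (≈ 5.9 samples at 12 MHz), so density is expressed per cell and
the envelope-statistics regime is directly controllable.

The stage effect is encoded as a joint, monotone increase of scatterer
density (`2 + 3·stage` per cell) and amplitude SD (`1 + 0.25·stage`) — a
conventional quantitative-ultrasound surrogate for fibrosis-related
microstructural change, chosen once for clear class separability: per-sample
power grows with density × SD², and the envelope distribution moves from
pre-Rayleigh (F0, ~2 scatterers/cell) towards Rayleigh speckle (F4, ~14).
No claim of physiological calibration is made; clinical envelope statistics
for this scanner are not available to calibrate against. The phantom also
deliberately omits attenuation, depth-dependent gain, focusing and the
convex-array fan geometry — frames are rectangular grids. Passing tests
therefore demonstrate that the pipeline can learn a stage-dependent shift
in backscatter statistics, not that it reproduces clinical staging
accuracy.

Default per-stage case counts (23/46/51/49/61, 230 cases) mirror the
emulated study population so that the augmentation arithmetic exercised in
tests is the same as the real cohort's.

## Numerical choices

* **Rounding.** `N_aug` uses round-half-up (base R's `round()` is
  round-half-even); window offsets use `floor`, keeping the first offset at
  0 and the last within bounds.
* **Split remainder.** `floor`-based partition sizes put the remainder in
  the test set (n = 101 → 80/10/11).
* **Ties.** A frame vote fraction of exactly 0.5 is a negative call; ROC
  thresholds treat tied scores jointly, which makes the trapezoidal AUC
  equal the Mann–Whitney statistic `P(s+ > s−) + 0.5·P(s+ = s−)` exactly
  (property-tested against a brute-force pairwise oracle).
* **Degenerate inputs.** Constant windows cannot be min–max normalized,
  all-zero envelopes cannot be log-compressed, single-class test sets have
  no ROC, and zero-denominator metrics either error (strict mode) or
  return `NA` — each is an explicit error path, not silent propagation.
* **Envelope detection** forms the analytic signal in the frequency domain
  (negative frequencies zeroed, positive doubled) over all A-lines at once;
  the first/last ~16 samples carry edge effects and are excluded from
  envelope-accuracy assertions.
* **Initialisation.** Xavier-uniform weights (the conventional choice for
  Tanh networks) under a dedicated seed; training, splitting and simulation
  each consume their own seed derived from one master seed, so every run
  artifact is reproducible byte for byte.
* **Optimization backend.** The network is implemented directly on BLAS
  matrix products (im2col convolutions, argmax-routed max-pooling, full
  backpropagation, Adam); gradients are verified against central-difference
  numerical differentiation in the test suite.

## Open design points and how they were resolved

* The ROI is described both as manually delineated and as automatically
  fixed at 1100 × 256; the package implements the automatic fixed-size ROI
  as the tested default and accepts a user `roi_spec()` for manual
  placement.
* Published set sizes per task cannot be reconstructed exactly from the
  stated augmentation rule under any rounding convention; the stated rule
  (`N_aug = N1/N0`) is implemented faithfully and the tabulated set sizes
  are not used as a target.
* Whether the reported frame scores are vote fractions or mean softmax
  probabilities is not specified; the vote fraction is the default and
  `score = "mean_prob"` is available.
* Whether the final-epoch or best-validation model was evaluated is not
  specified; the final-epoch model is the default (`keep_best` switches).
* Stratification of the split is not specified; the default is
  unstratified with `stratify` as an explicit option.

## Problem sizes in the test suite

The suite exercises the full-scale geometry where the claim is about
geometry (1247 × 256 frames, 1024 × 256 windows, the 230-case default
cohort) and a reduced geometry (300 × 16 frames, 256-sample segments)
where the claim is about behaviour, keeping the default run lightweight.
The end-to-end learnability check trains on a 40-case stage-0 vs stage-4
cohort (the two ends of the stage grid) for 20 epochs with a stratified
split — chosen as the smallest configuration in which majority-vote
aggregation over 256 segments should cleanly separate the classes — and
asserts a frame-level test AUC of at least 0.9 with decreasing training
loss. Tests assert only quantities they compute at run time.

## Known limitations

* The phantom's stage separation is intentionally generous; clinical
  effect sizes are smaller and confounded (depth-dependent attenuation,
  operator variability, anatomy), so synthetic performance must not be read
  as a clinical estimate.
* Per-window splitting (the faithful default) lets overlapping windows of
  one case span partitions; use `group_by_case = TRUE` for honest
  generalization estimates.
* The architecture's layer widths are one exact solution to the published
  structural constraints (layer counts, input length, kernel "small", total
  parameter count), not a verified reconstruction of the original network.
* Training is single-threaded CPU R; it is intended for the package's
  desk-scale cohorts, not for large clinical datasets.
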