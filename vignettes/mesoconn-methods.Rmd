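---
title: "From raw widefield stacks to connectivity: the mesoconn processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw widefield stacks to connectivity: the mesoconn processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoconn)
```

## The problem

Widefield (mesoscale) calcium imaging records fluorescence from the whole
dorsal cortex of a behaving mouse at video rate — typically 256×256 pixels
at 30 Hz, 30–64 s per trial, tens of trials per session. Spontaneous
activity in such recordings carries functional-connectivity information:
after preprocessing, the zero-lag Pearson correlation between a seed
pixel's time course and every other pixel's (a seed-pixel correlation, SPC,
map), or between pairs of anatomically defined regions (a correlation
matrix), maps which cortical areas fluctuate together.

`mesoconn` implements the processing chain headlessly: every intermediate
stack is persisted to disk (NPY, float64, C order), every file's
manipulation history is tracked in a JSON manifest, and the whole chain is
a deterministic function of its inputs — running the same pipeline on the
same files twice produces bit-identical output, which the test suite
asserts.

## The reference pipeline

The documented reference order for spontaneous-activity analysis is

> import → trim → align → crop → bandpass → ΔF/F₀ → GSR → concat →
> SPC / correlation matrix.

The runner enforces no order (steps are a registry of named operations and
configurations are plain JSON/YAML lists), but the stages below are
designed around this order.

### Import

RAW recordings are headerless pixel-interleaved binaries (`R,G,B,R,G,B,…`
row-major, frames consecutive — the layout of RGB 24-bit camera output);
one channel is kept per import, and the frame count is inferred from the
file size, with any residual bytes a hard error. TIFF pages are taken in
file order as time with no OME metadata interpretation. Everything becomes
float64 immediately: downstream regression and correlation need the
precision, and one native representation keeps every later stage simple.
Undefined pixels — masked, or exposed by resampling — are `NaN`, and every
operation either propagates them or skips them explicitly; they are never
silently zero, because a zeroed border would leak into blurs, global means
and correlations.

### Trimming and registration

The first ~20 frames of a trial can carry mechanical settling of the
head-fixing mechanism and are dropped.

Trials are rigidly aligned (translation, rotation, scale — one transform
per stack, since within-trial movement is negligible for head-fixed
recordings) to a reference frame built from the session's vasculature:
frames of one stack are unsharp-masked and a 100-frame range (the
reference configuration uses frames 400–500) is averaged, which emphasises
stable blood vessels and washes out transient activity. The unsharp mask
is `f + (f − blur(f))` with a Gaussian blur; "kernel size k" is read as
standard deviation `k/2` on a `2⌊k/2⌋+1`-tap support, amount 1 — the
conventional parameterisation when only a kernel size is quoted.

The transform is estimated in the frequency domain (Reddy–Chatterji):
rotation and scale first, by phase-correlating the log-polar resampled
magnitude spectra of the Hann-windowed frames (translation drops out of
the magnitude; rotation becomes a circular angular shift, scale a
log-radial shift), then translation by subpixel phase correlation of the
de-rotated frame. Choices that matter for accuracy:

* log-polar grid of 384 radial × 720 angular samples over a half circle
  (the magnitude spectrum is π-periodic), with a difference-of-Hanning
  spectral emphasis and `log1p` magnitude compression;
* parabolic (three-point) subpixel interpolation of every correlation
  peak;
* robustness to spurious angular peaks (weakly textured frames put
  90°-harmonic energy into the log-polar correlation via their
  rectangular content boundary): the top three log-polar peaks are each
  tried, together with the 180° ambiguity inherent in magnitude spectra,
  and the candidate with the strongest translation-correlation peak
  wins;
* bilinear resampling on application, with out-of-frame pixels set
  undefined.

On synthetic vessel-like frames, planted motions of ±10 px, ±15°, scale
0.9–1.1 are recovered within ~0.25 px, ~0.05°, and ~0.002 in scale —
comfortably inside the 0.5 px / 1° / 0.02 tolerances the test suite
enforces. Purely within-stack (frame-by-frame) motion correction and
nonrigid warps are out of scope.

### Cropping and coordinates

The cortex border and the midline sinus are non-neuronal signal sources;
they are excluded by hand-drawn polygon RoIs (even–odd rule on pixel
centres, boundary pixels inside; masking is idempotent). No automated
midline exclusion is attempted — which pixels are trustworthy is an
anatomical judgement.

All anatomical coordinates are microns relative to bregma, with +x to the
animal's right and +y anterior; pixels are 0-based, x = column rightward,
y = row downward, so anterior maps to smaller row indices. The conversion
is `x_px = origin_x + x_um/s`, `y_px = origin_y − y_um/s` with `s` the
pixel width in µm (41 µm for a 10.5 mm field of view on a 256-pixel
sensor). The origin is the componentwise mean of repeated bregma clicks;
averaging five clicks reduces pointing error. Seed RoIs import from a CSV
(`name,length,x,y`) as squares of `length` pixels; fractional centres
round half-away-from-zero, so seed placement cannot depend on banker's
rounding. Per-stack origins can be stored, but the global origin wins
unless a per-stack origin is explicitly requested — cross-animal
comparisons need one shared frame, and the "shift across projects" step
translates stacks onto it.

### Temporal filtering

The bandpass is a type-I Chebyshev design (the reference configuration:
order 4, 0.1 dB maximum passband ripple, 0.3–3.0 Hz at 30 fps — the band
recommended for GCaMP6-slow indicators). "Ripple 0.1" is read as 0.1 dB,
the conventional unit for this design's ripple parameter. The filter is
applied forward–backward (zero phase) with odd-reflection padding and
steady-state initial conditions: zero-lag correlation downstream is only
meaningful if filtering itself introduces no lag. The forward–backward
pass squares the magnitude response, so the passband floor is
`10^(−0.1/20)² ≈ 0.977` and the stopband is doubly attenuated; the test
suite checks DC rejection below `1e−6`, ≥ 0.95 gain at 1 Hz and ≤ 0.05 at
10 Hz against the designed response. Filtering needs more than
`3 × (2·order + 1)` frames (the padding length); shorter stacks are
rejected rather than padded further.

ΔF/F₀ uses the per-pixel mean over all frames as F₀ and the output has
exactly zero temporal mean at every defined pixel; pixels with F₀ = 0
become undefined and are counted in a message. One subtlety makes the
reference order bandpass → ΔF/F₀ well-posed: a true bandpass has zero
gain at DC, so the temporal mean of its output — the F₀ the next step
divides by — would be numerically zero with an arbitrary sign, and ΔF/F₀
would explode with per-pixel sign flips. The pipeline's `bandpass` step
therefore adds each pixel's pre-filter temporal mean back after
filtering (`keep_baseline`, on by default in the pipeline step, off in
the bare `cheby_bandpass()` operation, whose contract is a pure
bandpass). Fluctuations are band-limited, the baseline survives, and
ΔF/F₀ retains its meaning of fractional change about the true baseline.

### Global signal regression

The global signal g is the per-frame mean over *defined* pixels only, so
masked borders cannot contaminate it. GSR fits, per pixel, ordinary least
squares on (intercept, g) and keeps the residuals. The intercept is
included because "general linear model" without one would force the
regression through the origin of raw intensities. Two algebraic
identities follow and are asserted in the tests: residuals are orthogonal
to g at every pixel, and the spatial mean of the residual stack is the
zero series. GSR heightens local structure at the cost of lowering all
correlations — the package's synthetic checks reproduce this direction
(adding a shared global component inflates between-region r; GSR brings
it back down).

### Concatenation and connectivity

Trials are concatenated post-GSR and correlated as one continuous series
across the boundary — more data, better correlation estimates. SPC maps
use standard zero-lag Pearson r; frames where either series is undefined
are dropped pairwise and the effective n is reported. Cross-trial
correlation matrices compute one RoI×RoI matrix per trial, then report
the mean and the sample (n−1) standard deviation across trials; the
population (divisor n) convention is used instead for the per-pixel
temporal standard-deviation map, where the frames are the whole
population of interest. Directionality (Granger-style analysis), lagged
correlation and partial correlation are out of scope.

## The synthetic-data generator

There is no deposited recording to regress against, so validation rests
on a generator whose ground truth is known exactly. It emulates the study
conditions — 256×256 at 30 Hz, 900-frame (30 s) trials, tens of trials
sharing region sources with independent noise — with disk-shaped regions
driven by band-limited Gaussian sources, plus three confounds: a shared
slow global component, a cardiac-band sinusoid (8 Hz default, inside the
murine cardiac range and above the 3 Hz passband edge), and per-pixel
white noise. Default amplitudes are 5% of baseline for sources and
global, 2% for heartbeat, 1% noise — the scale of strong GCaMP6 signals
over a bright baseline.

Sources are moving-average-smoothed white noise (window 8 frames at
30 fps keeps most power in the passband), then *empirically whitened* and
re-coloured with the symmetric square root of the target correlation
matrix. The realised zero-lag sample correlation therefore equals the
target exactly, not just in expectation. This is deliberate: smoothed
series have few effective degrees of freedom, and at 9,000 frames the
Monte-Carlo error of a correlation estimate would be comparable to the
`3/√n` recovery band being tested; exact colouring makes the recovery
tests measure the analysis path, not the generator's sampling noise. The
trade-off is that the generator cannot be used to study estimator
variance across realisations of the *sources* (noise realisations still
vary).

What passing these tests does *not* show about real data: the generator
has no hemodynamic contamination, no GCaMP decay kinetics, no
within-trial motion, no photobleaching, and its sources are stationary
Gaussian. Results on real recordings depend on those factors; the tests
establish that the implementation computes what it claims on data whose
truth is known.

## Numerical and design choices

* **NPY persistence** is implemented minimally in-package (v1.0 header,
  `<f8`, C order) so processed stacks remain readable by any NumPy-aware
  tool; reads reject any other dtype and truncated files.
* **Degenerate inputs** fail loudly: constant frames cannot be
  registered, constant series have no correlation, a constant global
  signal cannot be regressed out, over-trimming and sub-warm-up filtering
  are errors.
* **Manifest writes** are write-temp-then-rename, so a crash mid-step
  cannot corrupt the project; paths in the manifest are relative, so a
  project folder is portable by plain copy.
* **Reduce steps** (concatenation, evoked averaging) are flagged in the
  step registry; the runner fans the whole current file set into one
  output, replacing the GUI gesture of selecting multiple files.
* **Problem sizes in the test suite** were chosen as the smallest that
  still exercise the contract: determinism runs 5 trials × 900 frames at
  128×128 (the full pipeline, two runs compared by file hash);
  registration recovery uses 256×256 vessel frames; connectivity
  recovery uses 9,000 frames at 24×24 with planted ρ ∈ {−0.5, 0, 0.5,
  0.9}.

## Known limitations

* Registration assumes a single rigid transform per stack; slow drift
  within a trial is not corrected.
* The evoked average aligns trials by index only; trigger-time alignment
  metadata is not modelled.
* Seed positions are taken as given; the interactive practice of nudging
  a seed to maximise a remote correlation is a workflow, not an
  algorithm, and is not automated.
* `pearson_r` drops undefined frames pairwise; under heavy masking the
  effective n varies across pixel pairs, and the reported `n` attribute
  should be checked before comparing coefficients.
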