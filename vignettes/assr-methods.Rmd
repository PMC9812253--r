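---
title: "Methods: 40 Hz auditory steady-state responses and sustained fields at the source level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 40 Hz auditory steady-state responses and sustained fields at the source level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The two responses and why they are measured together

A tone whose amplitude is modulated at 40 Hz entrains neuronal populations
in and around the primary auditory cortex. Magnetoencephalography then
shows two simultaneous responses from the same cortical patch:

* the **40 Hz auditory steady-state response (ASSR)** — an oscillation
  phase-locked to the modulation, quantified by **inter-trial phase
  consistency** (ITPC, also called the phase-locking factor);
* the **sustained event-related field (ERF)** — a slow evoked deflection
  that rises after stimulus onset, plateaus from roughly 200 ms until
  stimulus offset, and is quantified by its baseline-normalized amplitude.

In school-age children the two responses move in opposite directions with
age: phase locking strengthens while the sustained amplitude declines, a
pattern usually attributed to maturation of GABAergic inhibition and the
excitation–inhibition balance. Measuring both in the *same* source-space
region of interest is what allows their coupling to be analyzed directly.
`assr40` implements that analysis chain and a synthetic cohort generator
with known ground truth for validating it.

## Stimulus

The stimulus is a 1 s amplitude-modulated tone sampled at 44.1 kHz,

$$A(t) = \sin(2\pi f_c t)\,\bigl(1 + m\cos(2\pi f_m t)\bigr),$$

with carrier $f_c = 1000$ Hz, modulation depth $m = 1$ and modulation rate
$f_m = 40$ Hz. `generate_am_tone()` evaluates this on the grid
$t_i = i/f_s$, $i = 0, 1, \dots$, with `round(duration * rate)` samples.
Its RMS is $\sqrt{3}/2$ and its spectrum concentrates at $f_c$ and the two
sidebands $f_c \pm f_m$, each carrying $m/2$ of the carrier magnitude —
`validate_spectrum()` checks exactly this. Audio export peak-normalizes to
0.95 full scale (presentation level is a hardware-calibration matter, not a
property of the waveform); no onset ramp is applied by default, and a
cosine ramp is available but off, since the stimulus definition does not
include one.

## Time–frequency decomposition and ITPC

Single-epoch source time courses are convolved with complex Morlet
wavelets. The stated *time resolution* of 0.3 s is interpreted as the
**FWHM of the Gaussian envelope at the central frequency** (40 Hz), the
convention of the major MEG toolboxes, so
$\sigma_t = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, and envelopes scale with
frequency as $\sigma_t(f) = \sigma_t(f_0)\, f_0/f$ (constant cycles —
12 cycles per FWHM at every grid frequency). This is the single most
consequential interpretation in the package and is pinned by a test that
measures the constructed kernel's envelope FWHM on the sample grid.

ITPC at one (vertex, frequency, time) bin is the resultant length of the
unit phase vectors across the $n$ trials,

$$\mathrm{ITPC} = \frac{1}{n}\left|\sum_{r=1}^{n} e^{i k_{tr}}\right| \in [0, 1],$$

with phases taken from the wavelet coefficients. Zero-magnitude
coefficients have no phase; the package errors by default and offers
per-bin exclusion with count adjustment (`zero_phase = "exclude"`), which
is needed only for pathological noise-free inputs.

The maps are then normalized as event-related perturbations: per vertex
and frequency, $(x - \bar b)/\bar b \times 100$, with $\bar b$ the mean
over the −500 to −200 ms baseline — chosen away from epoch edges. The
normalized 40 Hz ITPC of a subject and hemisphere is the mean over
39–41 Hz and 200–900 ms (entrainment stabilizes after ~200 ms of
stimulation) across that subject's selected vertices. The frequency grid
defaults to 35–45 Hz in 1 Hz steps so bins exist at exactly 39, 40 and
41 Hz. All window selections use closed intervals with membership by bin
center, and normalization precedes band/window averaging (the order
matters once baselines differ across frequencies; a test documents this).

### Edge handling and the two numerical engines

Coefficients within one envelope FWHM of an epoch edge are marked invalid
(`NA`); with 3 s epochs every analysis window is ≥ 0.6 s clear of the
edges, so invalid bins never intersect analysis. Two exact engines exist:

* an FFT convolution path (zero-padded, same-length output), with
  optional **exact decimation** of the output time axis by spectral
  folding — retained bins are bit-identical to the full transform;
* a **windowed direct-correlation path** (banded kernel matrix, two real
  BLAS products) used by the pipeline, which computes only the bins inside
  the baseline and analysis windows.

Tests pin all paths to each other at $10^{-12}$, and `compute_itpc()` to
an independent brute-force loop. The wavelet output has a ~0.3 s envelope,
so window means are insensitive to the 50 Hz decimated grid the pipeline
uses by default in tests.

## Sustained-field amplitude

Per trial and vertex, a DC offset (mean over −100 to −2 ms) is removed;
trials are averaged; the evoked time course is z-scored per vertex against
the −100 to −2 ms baseline (sample SD, $n-1$); and the amplitude is the
mean of $|z|$ over 200–1000 ms. Rectification before averaging (not
averaging before rectification) makes the measure polarity-free, which is
why the generator's choice of a unipolar positive sustained deflection is
immaterial downstream. Per-vertex amplitudes are smoothed with a Gaussian
kernel (FWHM 3 mm, weights renormalized to unit sum) using Euclidean
distances — the synthetic vertex cloud has no cortical mesh, so geodesic
distance is out of scope. Smoothing follows window averaging; the order is
exposed in the configuration. The ERF is read at the identical vertex set
selected by the ITPC criterion: the pipeline enforces vertex-set reuse
rather than independent ERF peak-picking.

## ROI selection and the analysis table

Within each hemisphere the `k = 15` vertices with the largest
window-averaged normalized 40 Hz ITPC are selected (30 across both
hemispheres), ties broken by ascending vertex id; hemispheres smaller than
`k` are taken whole with a warning. Per subject and hemisphere the ROI
summary is the arithmetic mean of ITPC, ERF amplitude and vertex
coordinates over the selected set — the per-child coordinate is the mean
of the 15 vertices, the natural reading of grand-average coordinate
reporting. The cohort table has exactly one row per subject × hemisphere.

## Statistical layer

The hemisphere/amplitude mixed model is

```
itpc ~ 1 + hemisphere / erf + (1 | subject)
```

with the **right hemisphere as reference**, expanding to {intercept,
1(left), erf × 1(left), erf × 1(right)} — the nested coding is spelled out
explicitly to avoid formula-dialect ambiguity. It is fitted by REML
(`lme4`, bobyqa optimizer). Because REML profiles out the fixed effects,
no explicit starting values for them exist or are needed. t-based p-values
use the residual degrees-of-freedom approximation ($n_{obs} - n_{fixed}$)
by default, with Satterthwaite available through `lmerTest`; the df choice
is reported in the object. ICC is $\tau^2/(\tau^2 + \sigma^2)$ exactly,
and $R^2$ marginal/conditional follow the Nakagawa variance decomposition.
Age associations use Pearson correlations with two-sided t tests:
ITPC/ERF correlations are reported unadjusted, coordinate correlations
Bonferroni-adjusted within the family of 6 tests (X, Y, Z × two
hemispheres).

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes — it
is a generative stand-in for source-reconstructed epochs, not a forward
model. Per subject:

$$x_{rv}(t) = G(v)\,\bigl[a_{\mathrm{erf}}^{(h)}\,\mathrm{env}(t - \delta_r)
 + a_{\mathrm{assr}}\,\mathrm{ramp}(t)\,\sin(2\pi \cdot 40\,t + \varphi_r^{(h)})\bigr]
 + \varepsilon_{rv}(t),$$

with trial phases $\varphi_r^{(h)} \sim \mathrm{vonMises}(0,
\kappa_h(\mathrm{age}))$ — the standard circular-statistics choice, with
closed-form expectations ($E[\mathrm{resultant}] = I_1(\kappa)/I_0(\kappa)$)
that tie the generator, the ITPC module and the evoked-averaging
attenuation to the same statistic. The envelope rises sigmoidally over
0–200 ms, plateaus to stimulus offset at 1 s, then falls; the steady-state
ramp rises linearly over the first 200 ms of stimulation. Noise is white
plus 1/f, independent across vertices. $G(v)$ is a Gaussian spatial
profile (FWHM 20 mm) centered on the subject's true peak vertex; the
right-hemisphere peak drifts posterior with age (−2 mm/year in Y).
Vertices sit on a jittered 5 mm lattice around per-hemisphere centroids at
canonical auditory-cortex MNI-scale locations, shared across subjects as
when individual maps are projected to a template.

Key default choices, and why:

* **Age model.** $\kappa$ grows linearly with age
  (`kappa0 = 0.5` at age 7, `+0.5`/year, right-hemisphere bonus `+0.8`),
  the sustained amplitude declines (`erf_amp0 = 3`, `−0.35`/year).
  Developmental change is **right-lateralized**
  (`age_effect_left_frac = 0.4` scales both slopes on the left): the
  left-hemisphere age effects are present but weak, which is what produces
  the right-only significance pattern and the right-nested negative
  ITPC–ERF coupling downstream. A symmetric generator cannot produce that
  coupling at all — the shared age component is absorbed by the subject
  random intercept.
* **Subject-level scatter.** A lognormal multiplier on $\kappa$ shared
  across hemispheres (SD 0.15) creates the between-subject correlation the
  random intercept models (ICC > 0); ERF amplitude scatter (SD 0.4) is
  drawn per hemisphere.
* **Effect sizes.** Defaults are set so that parameter recovery is clearly
  demonstrable: the realized age–ITPC correlation on the right is ~0.6–0.7
  at 30 subjects. This is deliberately stronger than the weakest effects
  reported for cohorts of this size, because the package's recovery and
  calibration tests need effects comfortably above the detection
  threshold; scaling `kappa_age_slope` down reproduces marginal regimes.
* **Spatial profile.** FWHM 20 mm reflects the centimeter-scale point
  spread of distributed minimum-norm source estimates, which makes source
  ITPC maps spatially smooth. With a much sharper profile most cloud
  vertices are noise-dominated and selection degrades — a genuine property
  of phase-locking measures, see below.
* **Sampling.** 500 Hz default (analysis at 40 Hz has a sixfold Nyquist
  margin); 1000 Hz available by configuration. Single master seed;
  per-subject streams derived by a fixed offset rule, so cohorts are
  reproducible subject by subject.
* **Baseline interval.** The pre-stimulus interval contains only noise; no
  induced baseline gamma is simulated, since its level in real recordings
  of this paradigm is not quantified anywhere we could anchor to.
* **ERF latency jitter** (±5 ms uniform by default, configurable to
  ±20 ms) keeps averaging attenuation realistic.

### What the generator does *not* emulate

Sensor-space physics (forward fields, gradiometer geometry), inverse
-solution error structure, spatially correlated noise, head movement,
ocular/cardiac artifacts, within-trial phase drift, or anatomical
parcellations. Consequently, passing recovery tests show that the
*analysis chain* extracts what the generative model encodes — not that the
chain is robust to every pathology of real MEG data. Real source epochs
can enter the identical pipeline through the documented plain-text epoch
container (`write_epochs()` / `read_epochs()`).

## Properties of the estimators worth knowing

Two facts discovered while validating the chain shape its statistical
behavior, and both carry over to real data:

* **ITPC is amplitude-invariant.** Phases carry no information about
  $G(v)$ when noise is absent, so a noise-free map is spatially flat and
  peak-vertex selection is driven entirely by the tie-break. Spatial
  selectivity of ITPC *requires* noise (weak-amplitude vertices lose phase
  coherence to it). Localization tests therefore run at realistic noise.
* **The percent-change denominator is heavy-tailed.** The baseline
  resultant of $n$ uniform phases has mean $\sqrt{\pi/(4n)}$ but a
  coefficient of variation of $\sqrt{(4-\pi)/\pi} \approx 0.52$ *per
  vertex and frequency, independent of trial count*, and the ~0.3 s
  baseline window contains roughly one independent wavelet sample.
  Averaging the normalized values over the selected vertices is the only
  effective noise reduction — which is precisely why the 15-vertex ROI
  mean exists. Because each trial contributes a single phase for the whole
  stimulation window, a subject's in-window resultant is essentially one
  draw, bounding the achievable subject-level precision.

## Problem sizes used in the test suite

Validation loops run at reduced scale, chosen as the smallest conditions
that leave the tested properties clearly expressed: recovery sweeps use 30
subjects with default trial counts, 16 vertices per hemisphere, 150 Hz
sampling, 2.2 s epochs, a 39–41 Hz grid and `k = 12` over 100 seeds;
type-I calibration uses 12-subject null cohorts over 400 seeds; the
table-shape check runs 30 subjects at the full 500 Hz and 3 s epochs with
a reduced vertex cloud. `scripts/acceptance.R` runs 30 subjects at 250 Hz
with 20 vertices per hemisphere and the default analysis windows.

## Known limitations

* Euclidean rather than geodesic smoothing distances; no cortical mesh.
* The ERF "amplitude" floor: the rectified mean of pure $N(0,1)$ noise is
  $\sqrt{2/\pi} \approx 0.8$, so z-unit amplitudes never reach 0.
* Degrees of freedom for mixed-model t tests use the residual
  approximation by default; for the 60-observation balanced design the
  difference from Satterthwaite is small but not zero.
* `kappa = Inf` (perfect locking) with exactly zero noise produces
  zero-magnitude pre-stimulus coefficients whose phase is undefined; the
  shipped perfect-locking fixture adds a $10^{-8}$ noise floor so the
  default pipeline runs, and the zero-noise case is handled via
  `zero_phase = "exclude"`.
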