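# assr40

Source-level analysis of **40 Hz auditory steady-state responses (ASSR)**
and **sustained event-related fields (ERF)** for developmental MEG
cohorts, with a fully seeded synthetic-cohort generator for validation.

Amplitude-modulated tones at 40 Hz evoke two simultaneous responses in
auditory cortex: a steady-state gamma oscillation phase-locked to the
modulation, and a slow sustained field that plateaus during stimulation.
In school-age children the phase locking strengthens with age while the
sustained amplitude declines — a pattern linked to maturing GABAergic
inhibition. Studying their coupling requires measuring both in the *same*
source-space region of interest per child. This package implements that
pipeline for researchers working with source-reconstructed epochs (or
validating analysis choices on synthetic data):

* **Stimulus synthesis** — `generate_am_tone()` builds the
  amplitude-modulated tone
  `A(t) = sin(2π f_c t) (1 + m cos(2π f_m t))`
  (`f_c` = 1000 Hz, `m` = 1, `f_m` = 40 Hz, 1 s at 44.1 kHz), with
  spectral QC (`validate_spectrum()`) and WAV export.
* **Phase locking** — Morlet-wavelet decomposition (40 Hz center, 0.3 s
  envelope FWHM) and inter-trial phase consistency
  `ITPC = n⁻¹ |Σ_r exp(i k_tr)| ∈ [0, 1]`, normalized per vertex and
  frequency as percent change from the −500…−200 ms baseline and averaged
  over 39–41 Hz × 200–900 ms.
* **Sustained field** — DC offset correction (−100…−2 ms), epoch
  averaging, per-vertex z-scoring against the pre-stimulus baseline, mean
  |z| over 200–1000 ms, Gaussian spatial smoothing (FWHM 3 mm).
* **Individual ROIs** — per child and hemisphere, the 15 vertices with the
  highest normalized 40 Hz ITPC; the ERF is read at the identical vertex
  set; coordinates summarized as the mean over the selection.
* **Statistics** — the linear mixed model
  `itpc ~ 1 + hemisphere/erf + (1|subject)` (right-hemisphere reference,
  ERF slope nested within hemisphere, REML) with ICC and
  marginal/conditional R², plus Pearson age correlations (coordinates
  Bonferroni-corrected within a family of 6).
* **Synthetic cohorts** — `simulate_cohort()` draws children with
  age-increasing, right-dominant von Mises phase concentration κ (ITPC
  expectation `I₁(κ)/I₀(κ)`), age-decreasing sustained amplitude, a
  posterior age drift of the right response peak, Gaussian spatial
  profiles over an MNI-scale vertex cloud, and white + 1/f noise — with
  per-subject ground truth for parameter-recovery tests.

Real data enter through a documented plain-text epoch container
(`write_epochs()` / `read_epochs()`); externally preprocessed source
epochs run through the identical pipeline.

## Worked example

```r
library(assr40)

p   <- cohort_params(n_subjects = 8, n_vertices_per_hemisphere = 12,
                     epoch_window_s = c(-0.9, 1.3), sample_rate_hz = 150,
                     seed = 42)
cfg <- assr_config(morlet = morlet_spec(freq_grid_hz = 39:41),
                   k_vertices = 8, time_decim = 3)
res <- run_assr(p, cfg)
print(res)
```

```
ASSR analysis: 16 observations (8 subjects x hemisphere), config 2da46538
 hemisphere n mean_itpc  sd_itpc mean_erf   sd_erf
       left 8  567.6927 138.2046 14.11887 2.860851
      right 8  903.9644 163.8211 10.61042 3.016511
Linear mixed model: itpc ~ 1 + hemisphere/erf + (1 | subject)  [REML]
  16 observations, 8 subjects; ddf: residual
                term estimate std_error t_value df   p_value
         (Intercept)  1014.00   102.200   9.929 12 3.867e-07
      hemisphereleft  -742.10   167.200  -4.439 12 8.085e-04
 hemisphereright:erf   -10.41     8.344  -1.248 12 2.359e-01
  hemisphereleft:erf    20.92     8.798   2.378 12 3.489e-02
  sigma^2 = 2262, tau00 = 1.854e+04, ICC = 0.891
  Marginal R2 / Conditional R2 = 0.608 / 0.957
Age correlations (Pearson):
 hemisphere variable n          r        p_raw   p_adjusted family_size  method
       left     itpc 8  0.9396398 0.0005251964 0.0005251964           1 pearson
       left      erf 8  0.2139401 0.6109343582 0.6109343582           1 pearson
      right     itpc 8  0.8151274 0.0136871214 0.0136871214           1 pearson
      right      erf 8 -0.7618764 0.0280142982 0.0280142982           1 pearson
```

Reading the output: normalized ITPC is in percent change from baseline, so
a right-hemisphere mean of ~904 means the in-stimulus 40 Hz phase locking
sits ~10× above its pre-stimulus baseline; the negative `hemisphereleft`
estimate is the left-minus-right difference under right-reference coding
(right-hemisphere dominance); ITPC rises with age while the right
sustained field declines (r = −0.76); and the right-nested ERF slope is
negative (higher phase locking with weaker sustained fields) while the
left is not. At 8 subjects per-seed variability is substantial — the
defaults for a real-scale run are 30 subjects (`cohort_params()`).
`plot(res)` draws the age scatter per hemisphere; `assr_report(res, dir)`
writes JSON + markdown reports; `write_epochs()` serializes the cohort.

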