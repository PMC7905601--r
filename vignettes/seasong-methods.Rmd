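---
title: "Methods: seasonal song, brain densitometry and the statistics layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal song, brain densitometry and the statistics layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasong)
```

# What this package computes

Male black redstarts (*Phoenicurus ochruros*) defend territories across
three life-cycle stages — breeding, molt and nonbreeding autumn — while
singing only in two of them. Field studies of this system combine three
very different measurement chains: bioacoustic analysis of song strophes,
autoradiogram densitometry of steroid-receptor mRNA expression in song and
aggression nuclei (HVC, lMAN, preoptic area, posterior hypothalamus), and a
statistics layer relating stage, behavior, plasma testosterone and brain
measures. `seasong` implements all three chains as testable code, and adds
a synthetic-data generator that produces audio, section images and
per-individual tables with known ground truth, so each stage of the
pipeline has a recovery test that does not depend on the original field
recordings.

The black redstart strophe has a fixed gross structure: part A (a series
of elements), a pause of variable length, part B (always a single atonal,
noise-like element), and part C (a second element series). This structure
is what the segmentation module parses and what the repertoire analysis is
built around.

# Bioacoustic chain

## Envelope, events and elements

All detection operates on a short-time RMS envelope (5-ms window, 1-ms
hop, dB re full scale). Two rules, with different roles:

* **Event detection** (`detect_events()`) extracts sounds above an
  absolute amplitude trigger, merging regions separated by silences
  shorter than 10 ms — the separation used for syllable extraction. The
  trigger is deliberately a parameter (default −40 dBFS): in the original
  workflow it was set by the operator per recording, and the right value
  depends on the noise floor. Event boundaries are corrected for the
  half-window bias of the envelope, placing them within about one hop
  (1 ms) of the true sound edges on clean recordings.
* **Element counting** (`count_elements()`) implements the automatic
  single-element separation rule: excursions above `peak − 20 dB`, where
  sub-threshold dips shorter than the 5-ms hold time do not split an
  element. Trills whose sub-gaps are below the hold time therefore count
  as one element, which is the intended behavior.

Because the envelope window is 5 ms wide, a silent dip shorter than the
window never even registers as sub-threshold; the hold-time logic matters
for dips of roughly 5–10 ms. The test suite pins both regimes exactly.

## Strophe parsing

The part assignment in the original analyses was visual. The parser
codifies it: part B is the event immediately following the longest
internal gap, *provided* that gap exceeds a minimum pause (default 100 ms)
and the candidate is atonal — its mean per-frame Wiener entropy must
exceed −2 (white noise sits near −0.6, pure tones below −4). Strophes
violating these conditions (too few events, no credible pause, tonal B
candidate) raise a typed `unparseable` error carrying diagnostics rather
than guessing; incomplete songs in real recordings should be triaged by
the caller.

## Spectral measurements

Two spectrogram presets are shipped: `display` (512-point FFT, Hanning,
70% overlap), used for band-limit measurements, and `measure` (256-point
FFT, Hamming, 50% overlap), used for the syllable descriptor. Band limits
use a −20 dB criterion relative to the loudest point of the measured
interval: the highest and lowest bins that any frame pushes above that
threshold. A relative criterion makes the result exactly invariant to
recording gain, and its resolution is one FFT bin (43 Hz at 22,050 Hz /
512 points); tests assert the one-bin bound on bin-centered tones and on
2→6 kHz chirps. The whole-strophe band is reported as the union of the
per-part bands: a relative threshold applied across the whole strophe
would let a loud tonal part mask a quieter broadband part B, violating the
natural expectation that the overall band contains each part's band.

## The syllable descriptor

Each extracted syllable is summarized by nine quantities from its 256-point
sonogram: average frequency (magnitude-weighted mean), modal frequency,
fundamental frequency (first spectral peak above 500 Hz and above −25 dB
of the peak), Wiener entropy, duration, and the frame-wise standard
deviations of the four spectral quantities. Two numerical choices matter
in practice:

* Modal and fundamental frequency default to *frame-wise* estimates
  averaged across frames (`spectrum = "frames"`). The alternative reading
  — the peak of the time-averaged spectrum — is exposed as
  `spectrum = "averaged"`, but the single peak of a time-averaged sweep or
  trill spectrum is ill-defined (the band is nearly flat and the argmax
  hops between ripple maxima), which destabilizes clustering.
* Frame statistics are energy-weighted. With unweighted statistics, the
  set of analyzed frames flips with sub-hop alignment of the syllable
  against the frame grid, quantizing the descriptor; for trills this
  produced spurious "alignment-phase" clusters. Energy weighting makes
  low-energy edge frames (boundaries, trill sub-gaps) enter smoothly.

Wiener entropy — log of the ratio of geometric to arithmetic mean
spectral power — is 0 for flat spectra and strongly negative for tonal
ones; spectra are floored at $10^{-12}$ of their peak so the geometric
mean stays finite. It is exactly invariant to power scaling.

## Repertoire clustering

Syllables are clustered by incremental-split k-means: fit $k = 2$; split
the cluster with the largest within-cluster sum of squares with a local
2-means; use its two sub-centroids to seed a global refinement; keep the
step while a model-selection score improves, up to `k_max`. Features are
z-scored per column first, so the partition is invariant to affine
rescaling of any raw feature.

The original software stopped splitting when clusters "looked right"; a
reproducible surrogate is needed. The score used is the Gaussian
classification BIC with a *diagonal*, cluster-pooled covariance (one
variance per feature). A spherical score was tried first and rejected:
within-type measurement noise is strongly anisotropic — entropy jitter
dwarfs frequency jitter — and under a spherical likelihood every split
along the noisiest feature pays, so the procedure runs to `k_max`. The
diagonal model absorbs per-feature noise scales and stops where the
between-type structure ends. `k` can be forced for manual control, and
`apply_corrections()` implements the reviewed-and-corrected step of the
original workflow (relabel / merge / split, with an edit log).

Part B is excluded from clustering and from repertoire counts: it is by
definition a single atonal element, and spectral-peak features of
broadband noise are arbitrary, so including B would scatter it across
clusters without adding information. Repertoire sizes count distinct types
among part-A and part-C syllables (shared types count once in the total);
song types are distinct per-strophe label sequences after collapsing
verbatim full repeats, with an optional edit-distance-1 pooling rule.

# Densitometry chain

Sections are grey-value matrices with a physical pixel size; ROIs live in
millimetre coordinates and select pixels by center inclusion. "Optical
density" here is the scanned grey value, not −log transmittance, because
the autoradiograms are quantified directly from 16-bit scans; net OD is
region mean minus the mean of an equal-area control ROI placed adjacent to
the region (offset configurable), retained (and flagged) when negative.
Expression profiles average net OD across the analyzed sections of a
stack.

Volumes follow the serial-section estimator: delineated areas summed and
multiplied by the 0.2-mm spacing between analyzed sections. Delineation is
automated — threshold at background mean plus `c` background SDs
(default `c = 3`, background estimated from the image border), morphological
closing, largest connected component — because manual tracing is not
reproducible in software. The triplicate protocol is emulated by
`measure_nucleus_volume()`: three delineation passes with the threshold
constant jittered between passes, averaged. On a noiseless cylinder
phantom (r = 0.5 mm, 5 sections) the reconstructed volume is within
rasterization error (<1%) of π·0.25·1.0 ≈ 0.785 mm³, and the acceptance
suite requires 5%.

# Statistics layer

The layer mirrors the study design:

* `fit_stage_lm()` — behaviors, testosterone, repertoire summaries:
  `y ~ stage` least squares after an optional sqrt/log transform, omnibus
  F, adjusted R² (adjusted, so values can be negative). A response with
  zero variance reports F = 0, p = 1 by convention.
* `fit_stage_area_lmm()` — mRNA expression: `value ~ stage * area +
  (1 | individual)` fitted by maximum likelihood; stage, area and the
  interaction are tested by likelihood-ratio χ² between nested fits (main
  effects against the additive model, interaction against the additive
  model), and a non-significant interaction is dropped from the reported
  model. Singular random-intercept fits are downgraded to fixed-effects
  fits with a warning.
* `fit_poisson_glm()` — song rate: log-link Poisson with deviance
  (likelihood-ratio) tests.
* `ancova_behavior()` — behavior on a hormonal/expression covariate plus
  stage, interaction screened then dropped, type-II F and partial R² for
  the covariate.
* `posthoc_pairwise()` — all stage contrasts via estimated marginal means,
  Bonferroni or Benjamini–Hochberg adjusted. Contrasts are reported on the
  transformed scale when a transform was applied.
* Effect sizes: `cohens_d()` (pooled n−1 SD; noncentral-t CI by default,
  normal approximation as option and automatically far in the tails where
  the noncentral CDF loses precision; Hedges correction off by default),
  and `pearson_r_ci()` (Fisher z CI, with a sign-flip hook for measures
  where smaller raw values mean stronger expression of the trait, e.g.
  approach latency).

## Calibration

Type-I error of each family is verified on 2000 null-generated tables:
the exact-F families (stage LM, ANCOVA) at the study's own sample sizes
(9/10/14 per stage); the likelihood-ratio families at sizes where their
asymptotic χ² reference is the intended approximation (30 per stage for
the mixed-model interaction test). At the study's own n the mixed-model
LRT is mildly anticonservative (empirical size ≈ 0.06–0.065) — a known
property of small-sample likelihood-ratio tests, worth remembering when
reading χ² p-values near 0.05 from designs of this size. Pearson CI
coverage is checked at n = 18, ρ = 0.5 (Fisher z coverage ≈ 0.94–0.95).

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Audio** — strophes are built from a pool of 8 tonal/trilled syllable
  types (3 for part A, 5 for part C) plus an atonal part-B burst; elements
  are separated by 15–40 ms gaps, the A–B pause is 150–350 ms, and white
  Gaussian noise is added at a configurable SNR (RMS of the clean strophe
  vs noise; tests span 20–60 dB). Trill sub-elements are separated by
  3-ms gaps, below the 5-ms hold time, deliberately exercising the
  element counter's merge logic. Default sampling rate 22,050 Hz; sessions
  default to 20 strophes per individual, the number analyzed per bird.
* **Section stacks** — uniform background (100) plus added signal (40)
  inside a cylindrical region (r = 0.5 mm) across 5 sections at 0.2-mm
  spacing, optional Gaussian pixel noise; truth volume is the rasterized
  mask area times spacing.
* **Stage tables** — one row per individual at the field sample sizes
  (9 breeding / 10 molt / 14 nonbreeding). Continuous variables are
  Gaussian, generated on the transformed scale the statistics layer uses
  (sqrt for time in the 5-m radius, log for closest approach); counts
  (nodding, song rate) are Poisson; brain ODs share an individual-level
  random intercept within their measurement group, which is what the
  mixed models assume. Default effect sizes follow the reported seasonal
  pattern: testosterone elevated at breeding (d = 1.6 vs molt, 1.5 vs
  nonbreeding), AR elevated at breeding in POA and hypothalamus
  (d 1.5–2.1), aromatase elevated at breeding (d 2.1 POA / 1.2 H), ER
  flat, non-vocal behaviors flat, song rate ≈ 0 at molt (Poisson rate
  0.1: about one singing molt male per draw), and AR in HVC suppressed at
  molt by 2.4 pooled SDs with lMAN flat. Field-reported pairwise d values
  for HVC in this system (2.4 vs breeding, 1.4 vs nonbreeding, 0.05
  breeding-vs-nonbreeding) are mutually inconsistent under a common SD,
  so the generator realizes the qualitative pattern — suppressed at molt
  only — at the largest contrast.

What the generator does *not* emulate: realistic redstart timbre,
reverberation or transmission effects, overlapping singers, amplitude
variation with distance, anatomical section-to-section shape variation, or
missing data. Passing recovery tests therefore demonstrates that the
algorithms are correct under their stated assumptions, not that they are
robust to every property of field recordings; the user-set trigger level
in particular must be chosen per recording against its noise floor (the
acceptance runs use −40 dBFS down to 40 dB SNR and −25 dBFS at 20 dB
SNR).

# Problem sizes used in the shipped checks

Tests and the acceptance script use: 50 strophes per SNR level for
segmentation recovery; 20 synthetic individuals × 20 strophes for
repertoire recovery; 2000 null tables per statistical family; 500
replicates for effect-size calibration at n = 200 per stage; 200
replicate studies for the end-to-end seasonal pattern. These sizes give
binomial standard errors well inside the asserted bands while keeping a
full run in the minutes range on one CPU.

# Known limitations

* The amplitude trigger, the atonality threshold and the minimum pause
  are config, not estimated; recordings with atypical structure need
  operator judgment, exactly as the original interactive workflow did.
* The incremental k-means explores one greedy split path; the acceptance
  suite checks it against an exhaustive k-sweep oracle on small sets, but
  adversarial geometries can in principle defeat the greedy order.
* Densitometry assumes sections are already aligned and background is
  locally flat; no registration or illumination correction is attempted.
* The mixed-model χ² tests are asymptotic; at n ≈ 11–16 individuals they
  run slightly hot (see Calibration above).
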