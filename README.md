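# seasong

Seasonal analysis of birdsong structure, brain receptor densitometry, and
territorial behavior — an R implementation of the full computational chain
used in field studies of song and territoriality in male black redstarts
(*Phoenicurus ochruros*), driven end-to-end by a synthetic-data generator
with known ground truth.

## Who this is for

Behavioral ecologists and neuroendocrinologists working with:

* **song recordings** of species with structured strophes (here: part A —
  pause — single atonal part B — part C), needing reproducible element
  counting, strophe parsing, spectral measurements and syllable-repertoire
  estimation;
* **in-situ-hybridization autoradiograms**, needing ROI optical densities
  with adjacent-background subtraction and serial-section nucleus volume
  reconstruction;
* **small seasonal field designs**, needing the standard statistics layer
  (stage linear models, stage × brain-area mixed models with
  likelihood-ratio χ², Poisson song-rate models, Bonferroni/FDR post hocs,
  Cohen's d and Pearson r with confidence intervals).

## The core methods

* Sound events are extracted by an amplitude trigger on a 5-ms RMS
  envelope, merging silences < 10 ms; elements are counted with the
  *threshold −20 dB / hold time 5 ms* rule (dips shorter than the hold
  time never split an element).
* Strophes are parsed by the *longest-gap + atonality* rule: part B is the
  event after the longest internal gap, accepted only if its Wiener
  entropy (log GM/AM of spectral power, 0 = white noise) marks it atonal.
* Band limits (max/min frequency) use a −20 dB relative-to-peak criterion
  on the spectrogram, exact to one FFT bin (43 Hz at 22,050 Hz / 512).
* Each syllable gets a nine-quantity sonogram descriptor (average, modal,
  fundamental frequency, Wiener entropy, duration + frame-wise SDs);
  repertoires are estimated by **incremental-split k-means** — start at
  k = 2, repeatedly bisect the cluster with the largest within-cluster sum
  of squares, keep splits while a diagonal-Gaussian BIC improves — with a
  manual-corrections API mirroring the reviewed-clusters workflow.
* Nucleus volume = Σ(delineated section areas) × 0.2 mm spacing, run in
  triplicate and averaged; net OD = region mean − adjacent control mean.

## Worked example

```r
library(seasong)

# one synthetic strophe: A(4) - 250 ms pause - atonal B - C(5), 40 dB SNR
ty <- list(a1 = syllable_spec(1, "tone", 2500, 2500, 90),
           a2 = syllable_spec(2, "sweep", 3000, 5000, 120),
           a3 = syllable_spec(3, "trill", 4000, 4600, 160, n_subelements = 4),
           b  = syllable_spec(9, "atonal-noise", duration_ms = 80),
           c1 = syllable_spec(4, "tone", 6000, 6000, 80),
           c2 = syllable_spec(5, "sweep", 7000, 4500, 110))
spec <- strophe_spec(list(ty$a1, ty$a1, ty$a2, ty$a3), ty$b,
                     list(ty$c1, ty$c2, ty$c1, ty$c2, ty$c1))
st <- synth_strophe(spec, snr_db = 40, seed = 1)

res <- process_strophe(st$audio, st$sample_rate)
res$strophe
#> <song_strophe> A: 4 elements, B: 1, C: 5 | pause A-B 0.251 s, total 1.409 s
round(res$measures$max_freq_A)   # design maximum of part A is 5000 Hz
#> [1] 5082
round(res$measures$pause_ab_s, 3)
#> [1] 0.251
```

The parse recovers the designed 4/1/5 element structure, the 250-ms pause
to within a millisecond, and the part-A maximum frequency to within two
FFT bins (86 Hz) of the 5-kHz design value.

```r
# a synthetic three-stage study and its statistics
tab <- synth_stage_table(seed = 1)           # 9 + 10 + 14 individuals
study <- run_seasonal_study(tab)
subset(study$results, response %in% c("testosterone", "er_hypo") & term == "stage")
#>        response         family  term statistic df          p
#>    testosterone             lm stage 4.5364458  2 0.01899702
#>         er_hypo lmm_downgraded stage 0.4973416  2 0.77983664
```

Testosterone shows the designed breeding elevation (generated at
d = 1.6); estrogen receptor expression is generated flat and stays flat
(on this draw its random-intercept variance estimated to zero, so the
model was downgraded to a fixed-effects fit, as the `family` column
records).

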