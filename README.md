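# microdyn

Resting-state EEG microstate analysis with a validated synthetic test bed.

EEG microstates are quasi-stable scalp topographies, conventionally four
classes A–D, that tile the resting-state signal in runs of a few tens of
milliseconds. Group differences between clinical cohorts show up less in the
maps themselves than in their *dynamics*: dwell durations, occurrence rates,
transition probabilities, and the memory structure of the label sequence.
`microdyn` implements the full chain for scientists running such comparisons:

* **Segmentation** — average reference, zero-phase 2–20 Hz FIR, global field
  power `GFP(t) = sqrt(mean_c (v_c - v̄)²)`, 5-point Gaussian GFP smoothing,
  peak picking, random subsampling to ≤ 10,000 peaks, and polarity-invariant
  AAHC clustering into k = 4 templates with the global explained variance
  `GEV = Σ(GFP_t · corr(v_t, T_a(t)))² / ΣGFP_t²`.
* **Group templates** — exhaustive permutation-and-sign alignment across
  subjects, canonical A–D ordering.
* **Back-fitting** — per-sample assignment by absolute spatial correlation,
  optional correlation floor, peak interpolation, and majority-vote label
  smoothing; durations/occurrence from interior segments; transition matrices
  in per-sample and segment counting modes.
* **Sequence statistics** — likelihood-ratio G tests of Markov order 0/1/2
  (`G = 2 Σ n_ij ln(n_ij n / n_i· n_·j)` and its stratified higher-order
  analogues, Williams-corrected), transition-matrix stationarity over 2–40 s
  blocks, transition symmetry, and the autoinformation function
  `I(τ) = H(X_t) + H(X_{t+τ}) − H(X_t, X_{t+τ})` in bits, globally and per
  state, with a closed-form Markov-chain oracle `diag(π)·T^τ`.
* **Cohort statistics** — pooled-variance t-tests (`df = n1 + n2 − 2`),
  Bonferroni–Holm correction within feature families, Cohen's d, and numeric
  normality diagnostics.
* **Synthetic generator** — planted topographies driven by a semi-Markov
  sequence (geometric or gamma dwell, mean 80 ms) under a 10 Hz carrier with
  calibrated SNR, plus two-cohort generation with a planted transition-matrix
  effect; every downstream stage is tested against this ground truth.

## Worked example

Simulate one minute of a subject with known structure, segment it, back-fit,
and test the sequence:

```r
library(microdyn)
cfg <- simulation_config(duration = 60, snr = 8, dwell_dist = "gamma",
                         seed = 42)
sim <- simulate_recording(cfg)
seg <- segment_subject(sim$recording, pipeline_config(seed = 1))
tmpl <- order_canonical(seg$templates, canonical = sim$truth$templates)
lab <- smooth_labels(backfit(seg$filtered, tmpl), window_ms = 16)
microstate_properties(lab)
markov_order1_test(lab)
```

which prints:

```
1201 GFP peaks clustered, GEV = 0.962
  state mean_duration_ms occurrence_per_s coverage
1     A             85.1             2.93    0.249
2     B             91.3             3.06    0.278
3     C             83.2             2.86    0.237
4     D             79.7             2.93    0.236
<markov_test> markov_order1: G = 52.544, df = 36, p = 0.0369 (alpha = 0.01)
```

The recovered durations track the planted 80 ms mean dwell, coverage is
near-uniform as planted, and the maximum fitted-vs-planted segment
transition-probability error on this subject is 0.078. One minute of data
is underpowered for the order-1 Markov test at alpha = 0.01 (p = 0.037
here); the cohort analyses below use longer recordings, where gamma-dwell
sequences reject low-order Markovianity essentially always.

## Analysis workflow

`analysis/01_simulate.R` … `05_group_comparison.R` are thin numbered drivers
over the package that reproduce a two-cohort study end to end: 12 + 12
subjects (120 s, snr 8, gamma dwell), a planted 0.10 deficit in group 2's
B→D jump probability, segmentation, group templates, back-fitting,
information-theoretic testing, and the Holm-corrected cohort comparison.
Each stage writes its tables under `results/`; regenerable per-subject EEG
lives under `scratch/`. Run them in order from the repository root after
installing the package. In the shipped run the comparison flags `Tr(B->D)`
(t(22) = 6.32, Holm p = 2.8e-05, d = +2.58, reference group higher) together
with its renormalization echo `Tr(B->A)` and an occurrence difference for
state D — exactly the signature of the planted effect.

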