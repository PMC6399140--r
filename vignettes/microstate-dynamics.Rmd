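---
title: "EEG microstate segmentation and temporal dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate segmentation and temporal dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state EEG spends most of its time in a handful of quasi-stable scalp
topographies — microstates — each lasting a few tens of milliseconds before
switching to the next. Conventionally four classes (A–D) are extracted, and
group differences are sought not in the maps themselves but in the *dynamics*
of the label sequence: how long each state lasts, how often it occurs, how
states hand over to each other, and how much memory the sequence carries.
`microdyn` implements that full analysis chain — segmentation, back-fitting,
temporal properties, sequence statistics, cohort comparison — together with a
synthetic-EEG generator that plants known structure, so every stage can be
validated against ground truth.

## Segmentation model

For an average-referenced recording $v_c(t)$ over $C$ channels the global
field power is the spatial standard deviation
$\mathrm{GFP}(t) = \sqrt{\tfrac1C \sum_c (v_c(t) - \bar v(t))^2}$
(the divide-by-$C$ population convention; the defining formula is stated
explicitly because conventions differ). Moments of high GFP have the best
topographic signal-to-noise, so maps are sampled at GFP peaks:

1. average reference, then zero-phase band-pass 2–20 Hz
   (linear-phase Hamming FIR; transition band a quarter of each edge
   frequency, floored at 2 Hz; applied by centred convolution with
   odd-reflection padding, so there is no group delay);
2. GFP smoothed with a 5-tap Gaussian moving average
   ($\sigma = 1$ sample, kernel $\approx [0.054, 0.244, 0.403, 0.244,
   0.054]$; the window length is conventional, the $\sigma$ is this
   package's documented choice), reflected at the edges;
3. local maxima picked with a strict left / weak right rule
   ($g_{t-1} < g_t \ge g_{t+1}$), so a plateau contributes its first
   sample and endpoints never count;
4. at most 10,000 peaks retained by uniform random subsampling
   (seed-deterministic);
5. the peak maps — taken from the *filtered, unsmoothed* recording at the
   smoothed-GFP peak indices — are clustered.

Indices are 1-based inside the package (idiomatic R); label files on disk
use 0-based state integers with −1 for unassigned samples.

## AAHC clustering

Atomize-and-agglomerate hierarchical clustering is polarity-invariant:
topographies equal up to sign are the same microstate, so every similarity is
the absolute spatial (Pearson) correlation. Each peak map starts as its own
cluster; the cluster with the smallest contribution to the global explained
variance,

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \cdot
  \mathrm{corr}(v_t, T_{a(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$

is dissolved, its members are re-assigned to the surviving cluster of highest
squared correlation (exact ties to the lowest cluster index), and affected
templates are recomputed as the dominant eigenvector of the members'
outer-product sum — a polarity-free mean that keeps every template unit-norm
and average-referenced. Iteration stops at $k = 4$. The schedule is
deterministic for a fixed input order.

Greedy AAHC attains the exhaustive-enumeration optimum on separable,
equal-weight inputs (the test suite checks this against all 2-block
partitions of 8 maps); with strongly unequal GFP weights the
lowest-contribution rule can dissolve a coherent low-power cluster near the
end of the schedule and land in a suboptimal partition. That regime is a
documented property of the algorithm, not of this implementation.

Group templates are built by iterative permutation alignment rather than a
second-level clustering: with $k = 4$ the $4! = 24$ permutations can be
searched exhaustively, making the alignment exact and deterministic. Each
subject's set is matched to a running reference by the permutation and signs
maximizing total spatial correlation; the reference is recomputed as the
aligned mean and the loop repeats until the matching stabilizes. Canonical
labels A–D are then attached by exhaustively matching against packaged
synthetic stand-ins for the literature topographies (A: left-posterior to
right-anterior; B: mirrored; C: occipital; D: fronto-central, on an
idealized 31-channel 10–20 montage). These canonical maps fix *label names
only*; no numeric result depends on them. In simulation studies the same
mechanism is pointed at the planted template set instead, so output labels
mean planted states.

## Back-fitting and temporal properties

Every sample of the filtered recording is assigned the template of highest
absolute spatial correlation (ties to the lowest state index); a correlation
floor (`min_corr`, default 0) can leave samples unassigned. Two optional
post-processing modes exist, both **off by default**:

* *peak interpolation* — label only GFP peaks and give every sample the
  label of its nearest peak;
* *majority smoothing* — replace each label by the most frequent label in a
  short centred window.

The reason they exist is visible in the synthetic model and equally in any
oscillatory signal: wherever the instantaneous amplitude passes through
zero, the topography is undefined and sample-wise assignment is pure noise,
which fragments dwell segments. A 16 ms majority window heals those one-to-
three-sample error bursts while leaving genuine segments intact; the
parameter-recovery tests use it when dwell fidelity is being measured.
Peak interpolation is coarser (it quantizes switches to the roughly 50 ms
inter-peak grid and absorbs short dwells) and is provided for comparability
with peak-only analyses.

Durations and occurrence rates use *interior* segments only — the first and
last runs are truncated by the recording edges and would bias both
statistics. A state absent from the interior is reported as missing, not
zero, for durations; occurrence treats it as 0 events. Transition matrices
come in two counting modes, both computed by the pipeline: `per_sample`
(all consecutive pairs, self-transitions included — the
$P(X_{t+1}\,|\,X_t)$ formalism used by the sequence statistics) and
`segment` (consecutive distinct segments, zero diagonal — the mode compared
between cohorts). Unassigned samples break pairs in both modes.

## Sequence statistics

With $X_t \in \{A, B, C, D\}$ the label process, likelihood-ratio $G$
statistics test:

* **Markov order 0** — $P(X_{t+1}) = P(X_{t+1}|X_t)$:
  $G = 2\sum_{ij} n_{ij}\ln\frac{n_{ij}\,n}{n_{i\cdot}n_{\cdot j}}$,
  $df = (K-1)^2$;
* **order 1** — $P(X_{t+1}|X_t,X_{t-1}) = P(X_{t+1}|X_t)$, summed over one
  independence stratum per conditioning state, $df = K(K-1)^2$;
* **order 2** — the analogue over quadruples, $df = K^2(K-1)^2$;
* **stationarity** — block transition counts against the pooled matrix over
  non-overlapping blocks of length $L$ on a 2–40 s grid,
  $df = (B-1)K(K-1)$;
* **symmetry** — $P(X_{t+1}{=}j|X_t{=}i) = P(X_{t+1}{=}i|X_t{=}j)$ via
  $G = 2\sum_{i\ne j} n_{ij}\ln\frac{2n_{ij}}{n_{ij}+n_{ji}}$.

Zero-count cells contribute 0 (the $x\ln x \to 0$ limit). Two calibration
choices deserve explanation, both verified by simulation in the test suite:

* **Williams' correction.** At moderate sequence lengths (thousands of
  samples) the order-1/2 tables are large ($K^3$, $K^4$ cells) and the raw
  $G$ runs mildly hot against its $\chi^2$ reference. Each independence
  stratum is therefore divided by Williams' (1976) factor
  $q = 1 + \frac{(n\sum_r 1/n_{r\cdot} - 1)(n\sum_c 1/n_{\cdot c} - 1)}
  {6\,n\,df}$, which vanishes as $n$ grows and leaves the eight-minute
  cohort analyses numerically unchanged.
* **Symmetry degrees of freedom.** Along a single trajectory every state's
  in- and out-transition counts agree up to the endpoints, which removes
  $K-1$ of the $K(K-1)/2$ antisymmetric degrees of freedom; the correct
  reference is $\chi^2$ with the cycle-space dimension $(K-1)(K-2)/2$
  (3 for $K=4$). With the naive tabular df the test rejects far below its
  nominal level under reversible-chain nulls. The test requires $K \ge 3$;
  for two states the counts are deterministically tied.

Blocks for the stationarity test are non-overlapping by default even though
overlapping blocks are a common description, because overlap breaks the
independence assumption underlying the $\chi^2$ reference; an `overlap`
flag provides the literal half-step reading for comparison.

Tests run at $\alpha = 0.01$; cohort tables report the *fraction of
subjects consistent* with each property (1 − rejection fraction), and
stationarity profiles additionally use $p < 0.05$ per block length.

## Autoinformation

The autoinformation function is the time-lagged mutual information of the
label sequence, $I(\tau) = H(X_t) + H(X_{t+\tau}) - H(X_t, X_{t+\tau})$,
estimated by plug-in from all valid sample pairs, in bits (log base 2 — the
base is this package's choice; it only scales the curve). $I(0)$ is the
marginal entropy. Per-state curves are the AIF of the binary indicator
$1\{X_t = s\}$, whose $I(0)$ is the binary entropy of that state's coverage.
The closed-form AIF of a stationary first-order chain — joint distribution
$\mathrm{diag}(\pi)\,T^{\tau}$ — serves as an independent oracle: the
plug-in estimator must match it uniformly over lags on simulated chains.
The plug-in estimator is biased upward by $O(1/n)$; at the sequence
lengths used (tens of thousands of samples and more) the bias is far below
the 0.01-bit tolerance the tests enforce.

## Cohort statistics

Feature tables (4 durations, 4 occurrence rates, 12 off-diagonal segment
transitions per subject) are compared with pooled-variance Student t-tests —
the printed degrees of freedom of the motivating analyses
($df = n_1 + n_2 - 2 = 111$ for 52 vs 61) force the pooled rather than the
Welch form — plus Cohen's d with $n-1$ pooled weights. The sign convention
is group 1 minus group 2 with group 1 the reference cohort, so a positive d
means the reference group is larger. Bonferroni–Holm correction is applied
*within families*: the 12 transitions together, the 4 durations together,
the 4 occurrences together. Significance is adjusted $p < 0.05$. Normality
is checked numerically (skewness, excess kurtosis, Shapiro–Wilk) in place of
visual Q–Q inspection.

## The synthetic generator

The generator emulates the recording situation the pipeline targets:
31-channel 10–20 EEG at 250 Hz, eight minutes per subject. $K = 4$ planted
unit-norm, zero-mean topographies (random, pairwise $|r| < 0.5$) are
activated by a semi-Markov sequence: jumps follow a zero-diagonal
row-stochastic matrix (uniform off-diagonal by default), dwells are i.i.d.
with mean 80 ms — geometric (memoryless, hence first-order Markov at the
sample level) or gamma with shape 2 (age-dependent hazard, hence genuinely
non-Markovian, the regime matching empirical microstate sequences, and the
default for cohort emulation). The active map is amplitude-modulated by a
10 Hz sinusoidal carrier scaled to unit RMS, so GFP maxima arrive at twice
the alpha frequency; the carrier is *signed* — its rectified magnitude is
the classical $|\sin|$ envelope, but keeping the oscillation at the carrier
frequency keeps the signal inside the 2–20 Hz analysis band, whereas a
rectified carrier concentrates its power at DC and $2f$ and would be
destroyed by the pipeline's own filter. Polarity is invisible to every
downstream operation. Gaussian channel noise is scaled to a configured
signal-RMS/noise-RMS ratio; noise calibration is tested to 1%.

Cohorts apply an entrywise delta to the jump matrix of group 2 (rows
renormalized), with per-subject seeds derived from one master seed. What
the generator does *not* emulate: volume conduction and realistic spatial
noise correlation, MR/ballistocardiogram or ocular artifacts, non-alpha
broadband dynamics, inter-subject topography variability beyond noise, and
amplitude envelopes that avoid exact zeros. Passing tests therefore show
the algorithms are correct and well-calibrated under controlled conditions;
they do not certify effect sizes on real recordings.

## Problem sizes

The test suite and the analysis scripts are scaled for a desktop run:
type-I calibration uses 1000 sequences of length 5000; parameter-recovery
runs use single 480 s subjects (transition matrices, at snr 8) and three
120 s subjects (group templates, at snr 4); detection-power replicates use
20 cohorts of 52 + 61 subjects at the label-sequence level; the worked
analysis in `analysis/` uses 12 + 12 subjects of 120 s at snr 8. The
acceptance script reruns all of these from scratch under one seed.

## Known limitations

* Greedy AAHC is not globally optimal off the separable regime (above).
* Back-fitted durations are systematically shortened by amplitude nulls
  unless label smoothing is enabled; with 16 ms smoothing a small upward
  bias (a few ms) replaces the large downward one.
* The stationarity test's block grid treats the recording as exactly
  divisible into blocks; a trailing remainder shorter than one block is
  ignored.
* Plug-in AIF carries the usual upward small-sample bias; no bias
  correction or surrogate confidence bands are provided.
* The EDF and BrainVision readers cover the common subset of those formats
  (16-bit EDF with a uniform rate; multiplexed binary BrainVision in
  INT_16 or IEEE_FLOAT_32), not every variant in the wild.
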