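---
title: "Methods: call structure and context specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: call structure and context specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalarm)
```

This vignette is the package's account of its own methods: the measurement
and statistical models, the parameters that matter, the numerical choices
made where a published procedure is under-specified, and what the
synthetic calibration does and does not establish.

## The analysis problem

Vervet monkeys give alarm calls to leopards, eagles, and snakes, and
similar sounding calls during within- and between-group aggression. Two
quantitative questions structure the pipeline: do the calls fall into
discrete types when no context information is used (unsupervised), and
how well does acoustic structure predict context when it is used
(supervised)? Both must be answered from compound, multi-element calls
recorded from known individuals — which makes caller identity a
confounder that the significance test has to control.

## Feature extraction

A call is processed as: high-pass filter → (down)sampling
standardisation → element segmentation → short-time spectral analysis →
the ten-variable feature vector.

* **High-pass filter** (`highpass_filter()`, cutoff 100 Hz): removes
  low-frequency background below the calls' energy. Implemented as a
  4th-order Butterworth applied forward and backward (zero phase); the
  double pass gives roughly 48 dB attenuation one octave below cutoff
  and a flat passband.
* **Sampling rate** (`resample_to_22k05()`): all analysis runs at
  22.05 kHz; the calls carry no energy above 11 kHz, and the common rate
  fixes one spectral geometry for every call. Upsampling is refused
  rather than silently interpolated.
* **Spectrogram** (`call_spectrogram()`): 1024-point FFT, Hamming
  window, 64-sample hop (93.75% overlap) — bin spacing 21.5 Hz
  (22050/1024) and a 2.9 ms time step. Note the Hamming *effective
  bandwidth* of such a window is about 28 Hz; tolerances in the test
  suite are therefore expressed in bins, not in that nominal bandwidth.
  All spectral statistics exclude bins below 100 Hz, mirroring the
  filter.
* **Segmentation** (`segment_elements()`): elements are intervals where
  the 5 ms smoothed RMS envelope exceeds −30 dB relative to the call
  maximum; gaps < 10 ms are merged, runs < 5 ms discarded. Field
  workflows label element boundaries by hand; the automatic segmenter
  exists so the pipeline runs unattended, and externally supplied label
  tracks (`read_label_track()`) always take precedence. The *main
  element* is the one with the highest envelope peak — the same envelope
  statistic the segmenter uses, so manual and automatic paths agree on
  what "highest amplitude" means.

The ten analysis variables (`call_feature_vars()`) split by scope:
temporal measures on the compound call (number of elements, mean element
duration), spectral measures of the main element (peak frequency, first
quartile, PF jump, frequency range, FP1, FP1A), and averages over all
elements (Wiener entropy, second quartile). The all-element mean peak
frequency is additionally exported (`mean_pf_all_hz`); which granularity
feeds clustering is a configuration choice defaulting to the main
element.

Operationalizations that a legacy analysis tool would fix internally are
stated here and kept configurable:

* **Wiener entropy**: geometric / arithmetic mean of the *linear*
  magnitudes, giving values in [0, 1]; the linear ratio convention is
  used because the reference descriptive values (0.37–0.72) live on that
  scale, not on the log form.
* **PF jump**: maximal absolute change of the per-frame peak frequency
  between successive frames *within* an element (jumps across silent
  gaps are not meaningful).
* **Frequency range**: span of frequencies whose mean main-element
  magnitude exceeds −24 dB of the spectral maximum (configurable).
* **FP1/FP1A**: per frame, the lowest-frequency local maximum of the
  3-bin smoothed spectrum exceeding 10% of the frame maximum; FP1A is
  reported *relative* to the frame's smoothed maximum, in permille. The
  relative form makes the measure independent of recording level and of
  exactly which edge frames fall inside an element — the absolute mean
  magnitude failed that robustness requirement in testing.
* **Inter-call interval** is defined only between successive calls of a
  bout and excluded listwise from multivariate stages; it is not among
  the ten clustering variables.

Fundamental-frequency and harmonic descriptors are deliberately absent:
many of these calls lack harmonic structure, so the variables describe
the energy distribution instead.

## Two-step clustering

`fit_twostep()` reconstructs the BIC-driven two-step procedure with every
rule stated explicitly, because the commercial implementation it follows
is under-documented:

* Variables are z-transformed; the log-likelihood distance between
  clusters is `d(a,b) = xi_a + xi_b - xi_{a∪b}` with
  `xi_c = -N_c Σ_v ½ log(σ_v² + σ_cv²)`, where `σ_v²` is the overall
  variance (a regularizer that keeps singleton clusters finite) and
  `σ_cv²` the biased within-cluster variance.
* The CF-tree pre-clustering pass of the commercial tool is replaced by
  direct agglomeration from singletons: at desk scale (hundreds of
  calls) the asymptotic behaviour is identical and the procedure becomes
  exactly reproducible. Ties in the minimum merge distance are broken by
  the lowest pair index, for determinism.
* `BIC(J) = -2 Σ_j xi_j + 2JV log N` over the J-cluster level of the
  hierarchy. The auto-k rule: if `BIC(2) ≥ BIC(1)`, k = 1 (no support
  for any clustering); otherwise screening keeps the largest J whose
  `|ΔBIC(J)|` is still > 4% of `|ΔBIC(2)|`, and among the survivors k
  maximizes the ratio of successive minimum merge distances
  `m(k−1)/m(k)`, required to exceed 1.15 (else k = 1). Both thresholds
  are arguments.
* The silhouette coefficient uses Euclidean distance on the standardized
  variables (not the log-likelihood distance), keeping `S_C` in [−1, 1]
  and matching the cohesion/separation convention under which reference
  values like 0.5 are quoted. Singleton clusters and zero-distance
  configurations contribute 0. The implementation is the package's own
  (the conventions above are fixed by contract); the `cluster` package
  serves as an independent cross-check in the test suite.

Degenerate inputs are defined: all-identical rows give k = 1; a
zero-variance variable is an error naming the variable; `k_max` larger
than the row count is reduced with a warning.

A known behaviour worth stating: with clusters arranged *collinearly*
(a graded series), the merge-distance ratio favours the two ends of the
chain and the BIC gain from splitting tight, regularized clusters is
bounded, so the procedure prefers coarse solutions. That is not a bug —
graded variation genuinely lacks discrete boundaries — but the
recovery guarantees quoted below are for mixtures in general position.

## Discriminant analysis

`fit_lda()` implements canonical LDA (eigen-decomposition of
`W⁻¹B` via Cholesky whitening, axes scaled to unit within-class
variance); all variables enter together, with equal priors by default —
the convention of the reference workflow, and the conservative choice
given unbalanced context samples (the imbalance itself is addressed by
the pDFA, not by prior tuning). Conditioning is judged on the
within-class *correlation* matrix, so affine rescaling of a variable
cannot trigger the ridge fallback (1e-8 on the diagonal, logged) — this
keeps the classifier exactly affine-invariant, which the test suite
asserts. `MASS::lda` is the independent oracle in the tests, never the
implementation, since the discriminant machinery is itself under test
here.

`classify_loo()` refits the model for every held-out call — an exact
jackknife, no downdating shortcut; at n ≤ ~500 the cost is irrelevant
and correctness is easier to audit. Confusion tables are reported as
counts plus row percentages rounded half-up to one decimal, the
convention of published classification tables; the arithmetic is checked
exactly against the built-in reference count tables (overall 71.4% for
the five-context female table, 93.2% for the three-context male table).

## Nested permuted DFA

DFA classification percentages cannot be tested against chance
per-call: calls from one individual are correlated, and individuals
contribute unequally. `run_pdfa()` therefore:

1. applies the subject-selection rule (`pdfa_select_subset()`): an
   individual enters from exactly one context, and only if it has at
   least `min_calls_per_level` (default 3) calls there; individuals
   qualifying in several contexts are assigned one uniformly at random
   per selection replicate (default 100 replicates; selection is
   deterministic when no individual qualifies twice);
2. z-transforms the variables within the selected subset;
3. computes the observed statistic — percent correct under
   resubstitution by default (the convention of the nested-pDFA
   literature; leave-one-out is available), with equal priors;
4. builds the null by permuting the individual→context assignment,
   preserving the number of individuals per context; every individual's
   calls move as a block, which the test suite asserts structurally;
5. reports `p = (1 + #{null ≥ observed}) / (1 + n_permutations)` per
   selection (the add-one rule includes the identity assignment, so p is
   never exactly 0), averaged over selection replicates, with the full
   per-selection distribution retained.

The defining calibration, run in the acceptance suite: on null data with
strong individual effects (intercept SD twice the residual SD, three
contexts, five individuals each, four calls per individual) the nested
test's empirical type-I error at α = 0.05 stays near nominal, while the
naive per-call permutation on the same data exceeds it several-fold —
the quantitative demonstration of why nesting is required. Power is
checked on a strong context effect (adjacent context means 5 residual-SD
apart on one variable). The power design uses *three* contexts: with two
contexts of five individuals the permutation space collapses to 252
labelled assignments and p ≤ 0.01 is unreachable at the 200-permutation
scale the simulations use.

## The synthetic-data module

The generator exists at two levels, both with retained ground truth.

**Feature level** (`synthesize_feature_table()`): each variable is drawn
independently per call from a normal distribution truncated at 0 (Wiener
entropy also at 1), with an additive per-individual random intercept
(scale expressed as a multiplier of the per-call SD). The pre-truncation
location is solved numerically so the *truncated* mean equals the target
mean — without this, low-mean variables such as the terrestrial element
count (mean 1.4) would be biased upward by the truncation. Per-call SDs
are derived from the reference tables as `SEM × sqrt(n)` with the
per-context call counts of the study sample (216/53/38/33/164 female,
21/41/175 male), since the published SEMs are per-context over calls.
Variables are generated independently — no published covariances exist,
and independence is the minimal assumption; a covariance structure can
be layered on by the user.

**Waveform level** (`synthesize_call()`): a call is a sequence of
elements — band-limited noise plus a phase-continuous tone, mixed by
`tonality` — separated by silent gaps, with raised-cosine 5 ms ramps to
avoid spectral splatter corrupting the bandwidth features. Profile
parameters derive from the reference tables: centre frequency = mean
peak frequency, bandwidth = twice the interquartile spread, tonality =
1 − mean Wiener entropy, drift = mean PF jump; the 50 ms inter-element
gap and the 10–15% log-normal jitters on durations, gaps, and amplitudes
are package choices at field-realistic scales. Two constructions make
the ground truth exact rather than approximate: drift offsets are
centred within each element, so the mean instantaneous frequency equals
the profile centre by construction (frequency *differences*, hence PF
jump, are unaffected); and the generator derives its own noise-floor
level by solving the idealised spectral-flatness equation
`r^(1−f) / (f + (1−f) r) = 1.26 × (1 − tonality)` for the floor `r`
(`f` the occupied band fraction), where 1.26 is a fixed calibration
constant absorbing the geometric-mean penalty of realized Rayleigh noise
spectra and the tone's share of the arithmetic mean.

What the generator does *not* emulate: source–filter vocal-tract
acoustics, harmonic stacks, amplitude modulation within elements,
reverberation, wind or overlapping-signal noise, and cross-variable
covariance. Passing tests therefore establish that the *statistical
machinery* is correct and calibrated — not that the feature extractor
would agree with a legacy tool on real recordings, nor that real calls
satisfy the generative assumptions. Quantities that only exist in the
original field data (its silhouette value, its exact classification
rates from audio) are treated as non-reproducible context, and the
built-in count tables are carried as fixed *arithmetic* references, not
as recomputable results.

## Problem sizes and runtime choices

The validation suite runs at the scale of the study it emulates
(hundreds of calls): parameter recovery uses 50 calls per context;
clustering recovery 50 seeded replicates of 4 × 40-call mixtures
(mutually equidistant contexts, 6 within-SD component separation);
pDFA calibration 200 null datasets at 200 permutations with a single
selection replicate (the nested designs used are deterministic under the
selection rule). The acceptance script reports the same quantities at
20–60 replicates. Defaults for real analyses remain 1000 permutations
and 100 selection replicates.

## Known limitations

* The exact definitions of PF jump, frequency range, and FP1/FP1A in
  legacy analysis software are not public; the operationalizations here
  are stated, configurable, and calibrated only against the synthetic
  generator.
* The auto-k rule is a published-threshold reconstruction (0.04 BIC
  screen, 1.15 distance-ratio), not a byte-level reimplementation of the
  commercial procedure.
* The pDFA supports the nested design only (one control factor, caller
  identity); crossed designs are out of scope.
* Bout-level subsampling (cap 16 calls per bout) assumes bout labels are
  correct; no acoustic bout detection is attempted.
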