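---
title: "Lempel-Ziv signal diversity for multichannel EEG: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lempel-Ziv signal diversity for multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measures

This package quantifies the diversity of ongoing EEG with two
Lempel-Ziv measures computed on 10-s epochs.

**LZs (single-channel diversity).** Each channel of an epoch is
conditioned by subtracting its mean, dividing by its standard
deviation, and removing a least-squares linear trend — in that order.
The instantaneous amplitude is then estimated as the modulus of the
analytic signal (Hilbert envelope), computed on the full epoch with no
padding or tapering, and binarized at the envelope mean: samples above
the mean map to 1, all others to 0. The binary string is parsed into
its LZ76 exhaustive history — each "word" is the shortest prefix of the
remaining string that cannot be copied from anywhere earlier
(self-overlapping copies allowed) — and the number of words is the raw
score. Finally, the raw score is divided by the score of the same
string randomly permuted in time; since a shuffle preserves the symbol
content but destroys all temporal structure, this surrogate is the
maximal-diversity reference for the same bit budget, and the normalized
score lies in [0, 1]. A channel-mean LZs per epoch is the arithmetic
mean of the normalized per-channel scores.

**LZc (spatio-temporal diversity).** The same per-channel binarization
is applied, but the binary channel x time matrix is concatenated
observation-by-observation (all channels at time 1, then all channels
at time 2, ...) into a single string before parsing and surrogate
normalization. Duplicated or strongly coupled channels make the
concatenated string compressible, so LZc is sensitive to spatial
redundancy in a way LZs is not.

Numerical conventions worth stating explicitly:

* **Tie rule.** Envelope samples exactly equal to the threshold map to
  0. Ties have probability zero for real signals but the convention is
  decisive for constructed test inputs.
* **Cap at 1.** A lucky shuffle can be *less* complex than the
  original string, so the ratio is capped at 1. Degenerate (constant)
  strings are flagged: their shuffle is an identity and the ratio is 1
  by construction.
* **Surrogates.** The default is a single seeded shuffle per score;
  averaging over `n_surrogates > 1` is available for variance
  reduction. For LZc the default surrogate permutes the whole
  concatenated string, destroying space and time symmetrically; a
  within-channel shuffle (preserving the spatial layout) is available
  behind `surrogate = "within_channel"`.
* **Word counting.** The exhaustive-history parser counts the final,
  possibly still-copyable word. The C++ implementation computes the
  longest-previous-factor array from a suffix array in O(n log n) and
  is pinned, exhaustively for all strings up to length 12 and on random
  strings, to a naive brute-force parser kept in the test suite.

## The preprocessing chain

Continuous recordings pass through a linear-phase FIR bank — highpass
1 Hz (order 1650), band-stop 45-55 Hz (order 826), lowpass 100 Hz
(order 66), all Hamming-window designs — are decimated by two
(500 to 250 Hz), cut into non-overlapping 10-s epochs tiled within each
annotated presentation (remainders dropped; epochs never span
presentation boundaries), screened by automated amplitude and flatline
rules, and re-referenced (channel average, or linked ears A1/A2) with
inverse-distance interpolation of bad channels from their 4 nearest
neighbours.

Choices made where the procedure was genuinely open:

* The published orders do not determine the design window; we use a
  Hamming window, the common default, and keep it configurable.
* Zero net delay is achieved by compensating the order/2-sample group
  delay of a single forward pass rather than filtering
  forward-backward, honouring the stated orders literally (a
  forward-backward pass would square the magnitude response).
* Visual artifact screening is replaced by explicit rules — reject an
  epoch if any sample exceeds 100 µV in absolute value or any channel's
  peak-to-peak falls below a flatline threshold. The published
  per-subject rejection counts are data-dependent properties of the
  original recordings and are not reproduction targets.
* ICA-based artifact removal is out of scope: component selection is
  inherently visual and subjective. The pipeline accepts pre-cleaned
  data or the generator's clean output.
* Filters are applied before channel removal, matching the listed
  order of steps in the source procedure.

## The synthetic session generator

No public recording accompanies the study design this package models,
so the generator stands in for raw data. It is first-class, tested
code, not a fixture. A session is a randomized order of (condition,
repetition) presentations — by default 7 conditions x 4 presentations
x 90 s, i.e. 2,520 s and, after 10-s epoching, 252 epochs per subject —
and each presentation is an independent segment of:

* a 1/f^alpha broadband background (alpha = 1 by default), shaped in
  the frequency domain and flattened below 0.5 Hz so slow drifts do not
  dominate the variance;
* a narrowband Gaussian process centred at 10 Hz (2 Hz bandwidth)
  whose *variance share* per condition is the control knob: a more
  rhythmic signal has a more regular envelope, hence a lower LZ score.
  This mechanism is the package's own stand-in — the measures' source
  analyses specify no generative model — and its defaults were chosen
  once as representative of resting EEG (alpha-band bursts over a pink
  background at ~20 µV RMS with a 2% sensor-noise floor);
* linear source mixing across channels (row-normalized mixing matrix,
  so with unit-variance sources the implied channel correlation is
  M M');
* an optional linear drift of the narrowband share per presentation
  index, emulating a session-long vigilance decline as the simplest
  model at the granularity of a quartile analysis;
* a white sensor-noise floor that keeps every channel non-degenerate
  even at narrowband share 1.

Generation is a pure function of (design, config): the same pair gives
a bit-identical recording. Planted condition effects and drifts are
injected by regenerating from modified configuration, which leaves
untouched conditions bit-identical because each presentation consumes a
fixed number of random draws.

What the generator does *not* emulate: eye blinks and EMG (beyond an
optional square transient used to exercise rejection), volume
conduction geometry, non-stationarity within a presentation, and
subject-specific spectra. Tests passing on synthetic sessions therefore
demonstrate the pipeline's statistical behaviour under controlled
effects, not the physiological validity of any particular recording.

## The statistical battery

Per-subject condition summaries are means over non-rejected epochs
(medians available). Any normalization of condition values for display
(e.g. subtracting each subject's reference-condition value) is a
plotting transform and never precedes testing.

* **Normality screening** standardizes the sample and applies a
  one-sample Kolmogorov-Smirnov test against the standard normal. The
  null parameters are estimated from the same sample, which makes the
  screen conservative (the Lilliefors caveat); it only gates the
  parametric/non-parametric branch at alpha = 0.05.
* **Friedman omnibus** with within-subject midranks, tie correction,
  and a chi-square reference with k - 1 degrees of freedom. (Rank-based
  omnibus results are sometimes printed in F(df1, df2) notation in the
  applied literature; this package reports the chi-square form.) The
  implementation is cross-checked against `stats::friedman.test` and,
  on a small design, against exhaustive enumeration of all within-row
  rank permutations.
* **Wilcoxon signed-rank post hocs**, two-sided, zero differences
  dropped. Up to 15 informative pairs the p value is exact (dynamic
  program over sign assignments of the midranks); above that, the
  normal approximation with continuity and tie correction. The Z
  statistic is reported in both regimes. The Bonferroni-Holm step-down
  correction is applied within each model's post-hoc family.
* **Paired JZS Bayes factors** with a Cauchy(0, 0.707) prior on the
  standardized effect, computed by adaptive quadrature over the
  g-representation of the Cauchy prior to a relative tolerance well
  below 1e-4, and verified against an independent high-density
  quadrature of the noncentral-t mixture representation. Interpretation
  bands: <= 0.1 strong null, (0.1, 0.33] moderate null, (0.33, 3]
  inconclusive, (3, 10] moderate alternative, > 10 strong alternative;
  boundaries fall to the lower band (they have measure zero).
* **One-way repeated-measures Bayes factor** under default mixed
  g-priors (scale 0.5 for condition effects, 1.0 for subjects).
  Conditional on the two g parameters the marginal likelihood has a
  closed form via the Kronecker eigenstructure of the
  compound-symmetric covariance, and the g integrals are estimated by
  seeded Monte Carlo (>= 10,000 draws) with a reported Monte Carlo
  standard error. Agreement with any particular GUI implementation to
  within Monte Carlo error on simulated data is the contract; exact
  numerical agreement is a non-goal because samplers differ.
* **Time-on-task model**: each subject's epochs are split by session
  order into quartiles Q1-Q4 (sizes differing by at most one, remainder
  to the earliest quartiles), and the quartile means enter the same
  Friedman + post-hoc battery.
* **Cluster-based permutation topography**: per-channel one-sample t
  values on paired condition differences; channels with |t| above the
  two-sided critical value at `cluster_alpha = 0.05` form same-sign
  clusters under a distance-based adjacency graph (neighbours within
  0.4 of the maximum inter-electrode distance on the packaged
  schematic extended 10-20 montage); cluster mass is the sum of |t|,
  and the familywise-correct p value compares each observed mass to the
  permutation null of the maximum mass under random sign flips of whole
  subjects (default 5,000 flips; the +1 convention keeps p in (0, 1]).

## Calibration and problem sizes

The test suite verifies, among other properties: exhaustive LZ76 oracle
equivalence; spectral-slope recovery within ±0.2; mixing-implied
channel correlation within ±0.05; strict decrease of mean LZs along a
narrowband-share grid; Friedman type-I error within [0.03, 0.07] at
alpha = 0.05 over 2,000 null simulations; cluster-permutation
familywise error within [0.01, 0.10] over 200 null datasets (1,000
sign flips each); and end-to-end recovery of planted effects.

For the planted rest-vs-task effect, "0.5 within-subject SD" is defined
against the epoch-to-epoch SD of channel-mean LZs. A seeded pilot
simulation estimates that SD and the local LZs-per-narrowband-share
slope, and the offset realizing the target effect is derived from the
two — the calibration is part of the tested pipeline, not a tuned
constant. The power studies use 19-subject cohorts with one 90-s
presentation per condition, 2 channels for the meaning model and 4 for
the drift (LZc) model, at 250 Hz; epoch arithmetic and detection rates
are channel-count-invariant at these sizes, and the reduced sizes keep
the full suite within ordinary desktop runtimes. Where spec-level
examples quote "100 seeded runs", the suite runs 100 cohorts for the
headline recovery rates and 30-60 replicates for secondary
distributional checks.

## Known limitations

* The generator's diversity knob is a single narrowband share; real
  condition effects may express through bandwidth, topography, or
  non-sinusoidal waveform changes the knob does not model.
* The schematic montage preserves neighbourhood topology, not true
  scalp geometry; adjacency is therefore denser than on a measured
  cap, which makes cluster inference slightly more conservative about
  isolated channels.
* The EDF and BrainVision readers cover the subset of each format the
  package writes (16-bit EDF with equal samples per record; multiplexed
  float32/int16 BrainVision), not the formats' full generality.
* Whether per-channel LZs should be averaged before or after surrogate
  normalization is not determined by the published description; this
  package averages normalized scores, matching the reading of
  "averaged over all channels", and the alternative would differ only
  by a smooth monotone reweighting.
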