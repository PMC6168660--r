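# lzdiversity

Lempel-Ziv signal diversity analysis for multichannel EEG.

Brain signal diversity — how unpredictable a neural time series is —
tracks global states of consciousness: it falls in sleep, anesthesia
and disorders of consciousness, and rises in psychedelic states. The
workhorse measures are **LZs**, the normalized Lempel-Ziv (LZ76) word
count of a single channel's binarized Hilbert envelope within a 10-s
epoch, and **LZc**, the same count applied to the channel-major
concatenation of all channels' binarized envelopes, which is
additionally sensitive to spatial redundancy. This package implements
both measures and everything needed to run condition-level studies
with them:

* **Diversity core** — per-epoch standardization (demean, scale,
  detrend), Hilbert-envelope binarization at the envelope mean, LZ76
  exhaustive-history word counting (O(n log n), oracle-pinned), and
  shuffle-surrogate normalization so scores live in [0, 1].
* **Preprocessing** — linear-phase FIR bank (1 Hz highpass order 1650,
  45-55 Hz notch order 826, 100 Hz lowpass order 66), decimation
  500 → 250 Hz, presentation-aligned 10-s epoching, automated
  amplitude/flatline epoch rejection, re-referencing (average or
  linked ears) with bad-channel interpolation.
* **Synthetic session generator** — seeded multichannel sessions with
  a 1/f background, a condition-controlled narrowband (alpha-band)
  variance share that lowers diversity as it grows, channel mixing,
  and a session-long vigilance drift; used for calibration and power
  studies in place of unavailable raw data.
* **Statistics** — Friedman omnibus, Wilcoxon signed-rank post hocs
  with Bonferroni-Holm correction, paired JZS Bayes factors
  (Cauchy scale 0.707) with conventional interpretation bands, a
  one-way repeated-measures Bayes factor under mixed g-priors,
  session-order quartile (time-on-task) analysis, and Maris-Oostenveld
  cluster-based permutation topography tests.
* **I/O** — minimal EDF and BrainVision (.vhdr/.vmrk/.eeg) writers and
  readers plus a plain-text TSV/JSON fixture format.

## Worked example

Simulate a three-condition cohort in which the resting state is less
rhythmic (lower narrowband share, hence higher diversity) than two
listening conditions, score it, and run the condition model:

```r
library(lzdiversity)

scores <- simulate_cohort_scores(
  n_subjects = 6,
  conditions = c("100%", "backward", "resting-state"),
  narrowband_fraction = c("100%" = 0.4, "backward" = 0.4,
                          "resting-state" = 0.2),
  presentation_duration_s = 40, n_channels = 4,
  seed = 1, measures = "lzs")

run_model(scores, "meaning", "LZs_mean")
```

```
<stat_report> model 'meaning' on LZs_mean
  omnibus: chi2(2) = 9.333, p = 0.009404
  post hoc (Wilcoxon, Holm-adjusted):
    100% vs backward             Z =   1.05  p = 0.3125 (adj 0.3125)  BF10 = 0.506 (inconclusive)
    100% vs resting-state        Z =  -2.10  p = 0.03125 (adj 0.09375)  BF10 = 416 (strong evidence for the alternative)
    backward vs resting-state    Z =  -2.10  p = 0.03125 (adj 0.09375)  BF10 = 2.43e+04 (strong evidence for the alternative)
```

The omnibus Friedman test flags a condition effect on channel-mean
LZs; the post-hoc rows compare condition pairs (negative Z: the first
condition scores lower), and each paired Bayes factor carries its
evidential band. With only 6 subjects the exact Wilcoxon p values
cannot pass the Holm-corrected 0.05 bar despite the large planted
effect — the Bayes factors, which are not sample-size-floored in the
same way, already indicate strong evidence. The matching
`run_model(scores, "time", ...)` variant tests session-order quartiles,
and `run_topography()` compares two conditions channel-by-channel with
cluster-based permutation inference.

A full study-sized session (7 conditions x 4 presentations x 90 s)
comes from `build_design()` + `generate_session()`, preprocesses with
`fir_filter_bank()`, `resample_half()`, `epoch_segments()`,
`reject_epochs_auto()` and `rereference_and_interpolate()`, and scores
with `score_epochs()`.

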