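test_that("the default design reproduces the study layout", {
  d <- build_design(seed = 1)
  expect_s3_class(d, "session_design")
  expect_equal(nrow(d$annotations), 7 * 4)
  expect_true(all(table(d$annotations$condition) == 4))
  expect_equal(sum(d$annotations$duration_s), 2520)
  # half-open tiling: onsets are contiguous multiples of the duration
  expect_equal(d$annotations$onset_s, (seq_len(28) - 1) * 90)
  # every (condition, repetition) pair appears exactly once
  key <- paste(d$annotations$condition, d$annotations$repetition)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("degenerate single-presentation designs are handled", {
  d <- build_design(conditions = "only", presentations_per_condition = 1,
                    presentation_duration_s = 10, sampling_rate_hz = 100,
                    n_channels = 2, seed = 5)
  expect_equal(nrow(d$annotations), 1L)
  expect_equal(d$annotations$onset_s, 0)
  expect_equal(d$annotations$duration_s, 10)
})

test_that("design randomization is seed-reproducible", {
  d1 <- build_design(seed = 11)
  d2 <- build_design(seed = 11)
  d3 <- build_design(seed = 12)
  expect_identical(d1$presentation_order, d2$presentation_order)
  expect_false(identical(d1$presentation_order, d3$presentation_order))
})

test_that("invalid design parameters are rejected", {
  expect_error(build_design(presentations_per_condition = 0), "invalid design")
  expect_error(build_design(presentation_duration_s = -1), "invalid design")
  expect_error(build_design(n_channels = 0), "invalid design")
  expect_error(build_design(conditions = c("a", "a")), "invalid design")
})

test_that("generation is a pure function of (design, config)", {
  d <- build_design(conditions = c("a", "b"), presentations_per_condition = 1,
                    presentation_duration_s = 10, sampling_rate_hz = 250,
                    n_channels = 3, seed = 2)
  cfg <- generator_config(seed = 3)
  r1 <- generate_session(d, cfg)
  r2 <- generate_session(d, cfg)
  expect_identical(r1$signal, r2$signal)
  r3 <- generate_session(d, generator_config(seed = 4))
  expect_false(identical(r1$signal, r3$signal))
})

test_that("background spectral slope is recovered from the periodogram", {
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 120, sampling_rate_hz = 250,
                    n_channels = 1, seed = 3)
  r <- generate_session(d, generator_config(narrowband_fraction = 0,
                                            noise_floor = 1e-4, seed = 4))
  sp <- stats::spec.pgram(stats::ts(r$signal[1, ], frequency = 250),
                          plot = FALSE, taper = 0)
  sel <- sp$freq >= 1 & sp$freq <= 40
  slope <- unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("channel mixing induces the implied correlation", {
  M <- rbind(c(1, 0), c(0.6, 0.8)) # rows unit norm; implied corr = 0.6
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 90, sampling_rate_hz = 250,
                    n_channels = 2, seed = 5)
  r <- generate_session(d, generator_config(channel_mixing = M,
                                            noise_floor = 1e-6, seed = 6))
  expect_lt(abs(cor(r$signal[1, ], r$signal[2, ]) - 0.6), 0.05)
  # mismatched mixing dimensions are a config error
  expect_error(generate_session(d, generator_config(channel_mixing = diag(3))),
               "config error")
})

test_that("condition effects lower diversity monotonically across seeds", {
  conds <- c("c0", "c1", "c2")
  hits_worst <- 0L
  hits_order <- 0L
  n_runs <- 60L
  for (i in seq_len(n_runs)) {
    d <- build_design(conditions = conds, presentations_per_condition = 1,
                      presentation_duration_s = 20, sampling_rate_hz = 250,
                      n_channels = 2, seed = 7000 + i)
    base <- generate_session(d, generator_config(
      narrowband_fraction = c(c0 = 0.2, c1 = 0.2, c2 = 0.2),
      seed = 7500 + i))
    rec <- inject_condition_effects(base, c(c1 = 0.15, c2 = 0.3))
    sc <- score_epochs(epoch_segments(rec, 10), measures = "lzs",
                       seed = 7900 + i, keep_channels = FALSE)
    mns <- tapply(sc$normalized, sc$condition, mean)[conds]
    if (mns[["c2"]] < mns[["c0"]]) hits_worst <- hits_worst + 1L
    if (mns[["c0"]] > mns[["c1"]] && mns[["c1"]] > mns[["c2"]])
      hits_order <- hits_order + 1L
  }
  expect_gte(hits_worst / n_runs, 0.95)
  expect_gte(hits_order / n_runs, 0.90)
})

test_that("zero condition offsets reproduce the input exactly", {
  d <- build_design(conditions = c("a", "b"), presentations_per_condition = 1,
                    presentation_duration_s = 10, sampling_rate_hz = 250,
                    n_channels = 2, seed = 8)
  r <- generate_session(d, generator_config(
    narrowband_fraction = c(a = 0.3, b = 0.3), seed = 9))
  r0 <- inject_condition_effects(r, c(a = 0, b = 0))
  expect_identical(r0$signal, r$signal)
})

test_that("condition offsets outside [0, 1] raise a range error", {
  d <- build_design(conditions = "a", presentations_per_condition = 1,
                    presentation_duration_s = 10, sampling_rate_hz = 250,
                    n_channels = 1, seed = 10)
  r <- generate_session(d, generator_config(narrowband_fraction = c(a = 0.8),
                                            seed = 11))
  expect_error(inject_condition_effects(r, c(a = 0.5)), "range error")
  expect_error(inject_condition_effects(r, c(a = -0.9)), "range error")
})

test_that("vigilance drift is linear in presentation index and range-checked", {
  d <- build_design(conditions = "a", presentations_per_condition = 4,
                    presentation_duration_s = 20, sampling_rate_hz = 250,
                    n_channels = 2, seed = 12)
  r <- generate_session(d, generator_config(narrowband_fraction = 0.3,
                                            seed = 13))
  # zero drift leaves the session bit-identical
  expect_identical(inject_vigilance_drift(r, 0)$signal, r$signal)
  # drift strong enough to leave [0, 1] is a range error
  expect_error(inject_vigilance_drift(r, 0.3), "range error")
  expect_error(inject_vigilance_drift(r, -0.15), "range error")
})

test_that("zero drift leaves early and late epochs exchangeable", {
  diffs <- vapply(1:30, function(i) {
    sc <- simulate_cohort_scores(n_subjects = 1, conditions = "x",
                                 narrowband_fraction = 0.3,
                                 presentations_per_condition = 4,
                                 presentation_duration_s = 20,
                                 n_channels = 2, drift_slope = 0,
                                 seed = 400 + i, measures = "lzs")
    q <- quartile_split(sc$session_order)
    mean(sc$normalized[q == "Q4"]) - mean(sc$normalized[q == "Q1"])
  }, numeric(1))
  # centred on zero: mean within 2 standard errors
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("mean LZs decreases strictly along the narrowband grid", {
  mns <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    d <- build_design(conditions = "x", presentations_per_condition = 1,
                      presentation_duration_s = 250, sampling_rate_hz = 250,
                      n_channels = 2, seed = 20)
    r <- generate_session(d, generator_config(narrowband_fraction = f,
                                              seed = 21))
    sc <- score_epochs(epoch_segments(r, 10), measures = "lzs", seed = 22,
                       keep_channels = FALSE)
    mean(sc$normalized)
  }, numeric(1))
  expect_true(all(diff(mns) < 0))
})

test_that("transient injection plants a localized artifact", {
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 30, sampling_rate_hz = 250,
                    n_channels = 2, seed = 30)
  r <- generate_session(d, generator_config(seed = 31))
  r2 <- inject_transient(r, at_s = 15, amplitude_uv = 500, channel = 2)
  changed <- which(r2$signal[2, ] != r$signal[2, ])
  expect_true(all(changed >= 15 * 250 & changed <= 15.3 * 250 + 1))
  expect_identical(r2$signal[1, ], r$signal[1, ])
})
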