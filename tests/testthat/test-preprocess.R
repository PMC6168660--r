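make_sine_recording <- function(freq, dur = 30, srate = 500, n_ch = 1) {
  tt <- seq(1 / srate, dur, by = 1 / srate)
  sig <- matrix(rep(sin(2 * pi * freq * tt), n_ch), nrow = n_ch, byrow = TRUE)
  raw_recording(sig, srate,
                annotations = data.frame(onset_s = 0, duration_s = dur,
                                         condition = "x", repetition = 1L))
}

interior_power <- function(rec, skip_s = 5) {
  n <- ncol(rec$signal)
  skip <- round(skip_s * rec$srate)
  mean(rec$signal[1, skip:(n - skip)]^2)
}

test_that("the default bank attenuates stopbands and preserves the passband", {
  # input sinusoids have power 1/2
  r01 <- fir_filter_bank(make_sine_recording(0.1))
  expect_lt(interior_power(r01) / 0.5, 0.01)
  r50 <- fir_filter_bank(make_sine_recording(50))
  expect_lt(interior_power(r50) / 0.5, 0.01)
  r10 <- fir_filter_bank(make_sine_recording(10))
  expect_lt(abs(sqrt(interior_power(r10) / 0.5) - 1), 0.05)
})

test_that("filtering preserves length and rejects too-short signals", {
  r <- make_sine_recording(10, dur = 20)
  out <- fir_filter_bank(r)
  expect_equal(ncol(out$signal), ncol(r$signal))
  short <- make_sine_recording(10, dur = 2) # 1000 samples < order 1650
  expect_error(fir_filter_bank(short), "length error")
})

test_that("the filter bank is linear", {
  set.seed(41)
  dur <- 12; srate <- 500
  x <- rnorm(dur * srate); y <- rnorm(dur * srate)
  mk <- function(v) raw_recording(matrix(v, nrow = 1), srate)
  spec <- list(filter_spec("highpass", 1, 1650))
  fx <- fir_filter_bank(mk(x), spec)$signal[1, ]
  fy <- fir_filter_bank(mk(y), spec)$signal[1, ]
  fxy <- fir_filter_bank(mk(2 * x - 3 * y), spec)$signal[1, ]
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-8)
})

test_that("filter specifications are validated", {
  expect_error(filter_spec("highpass", 1, 0), "positive")
  expect_error(filter_spec("highpass", 1, 13), "even")
  expect_error(filter_spec("notch", 45, 826), "length-2")
  expect_error(filter_spec("lowpass", c(1, 2), 66), "single cutoff")
})

test_that("downsampling halves the count and rate and keeps amplitudes", {
  r <- raw_recording(matrix(rnorm(5000), nrow = 1), 500)
  out <- resample_half(r)
  expect_equal(ncol(out$signal), 2500)
  expect_equal(out$srate, 250)
  r10 <- make_sine_recording(10, dur = 10)
  out10 <- resample_half(r10)
  expect_equal(ncol(out10$signal), 2500)
  expect_lt(abs(sd(out10$signal[1, ]) / sd(r10$signal[1, ]) - 1), 0.02)
  expect_error(resample_half(raw_recording(matrix(rnorm(100), 1), 125)),
               "config error")
})

test_that("epoch tiling drops remainders and never crosses presentations", {
  srate <- 100
  ann <- data.frame(onset_s = c(0, 95), duration_s = c(95, 8),
                    condition = c("a", "b"), repetition = c(1L, 1L))
  rec <- raw_recording(matrix(rnorm(2 * 103 * srate), nrow = 2), srate,
                       annotations = ann)
  expect_warning(ep <- epoch_segments(rec, 10), "shorter than one epoch")
  expect_equal(dim(ep$data)[1], 9L) # 95 s -> 9 epochs, 5 s dropped; 8 s -> 0
  expect_true(all(ep$labels$condition == "a"))
  # sample conservation per presentation: kept + remainder = available
  kept <- sum(ep$labels$condition == "a") * 10 * srate
  expect_equal(kept + 5 * srate, 95 * srate)
  # session order is strictly increasing
  expect_true(all(diff(ep$labels$session_order) > 0))
})

test_that("epoching requires annotations", {
  rec <- raw_recording(matrix(rnorm(1000), 1), 100)
  expect_error(epoch_segments(rec, 10), "annotation error")
})

test_that("amplitude and flatline rejection flag exactly the planted epochs", {
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 60, sampling_rate_hz = 250,
                    n_channels = 3, seed = 50)
  rec <- generate_session(d, generator_config(seed = 51))
  ep0 <- reject_epochs_auto(epoch_segments(rec, 10), amp_threshold_uv = 1000)
  expect_equal(sum(ep0$rejected), 0L)

  rec2 <- inject_transient(rec, at_s = 25, amplitude_uv = 5000, channel = 2)
  ep <- epoch_segments(rec2, 10)
  ep <- reject_epochs_auto(ep, amp_threshold_uv = 1000)
  expect_equal(which(ep$rejected), 3L) # the 20-30 s epoch

  # flatline: zero out one channel in one epoch
  ep2 <- epoch_segments(rec, 10)
  ep2$data[5, 1, ] <- 0
  ep2 <- reject_epochs_auto(ep2, amp_threshold_uv = 1000,
                            flat_threshold_uv = 0.1)
  expect_equal(which(ep2$rejected), 5L)

  # idempotence: same thresholds, same mask
  ep3 <- reject_epochs_auto(ep2, amp_threshold_uv = 1000,
                            flat_threshold_uv = 0.1)
  expect_identical(ep3$rejected, ep2$rejected)
  expect_identical(ep3$data, ep2$data)

  expect_error(reject_epochs_auto(ep2, amp_threshold_uv = -1), "positive")
})

test_that("average and linked-ears references zero the right combinations", {
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 20, sampling_rate_hz = 250,
                    n_channels = 64, seed = 52)
  ep <- epoch_segments(generate_session(d, generator_config(seed = 53)), 10)
  avg <- rereference_and_interpolate(ep, scheme = "average")
  expect_lt(max(abs(colMeans(avg$data[1, , ]))), 1e-10)
  ears <- rereference_and_interpolate(ep, scheme = "linked_ears")
  ix <- match(c("A1", "A2"), ears$channel_labels)
  expect_lt(max(abs(colMeans(ears$data[2, ix, ]))), 1e-10)
})

test_that("interpolation of a bad channel amid identical neighbours is exact", {
  sig <- matrix(rep(sin(2 * pi * 5 * seq(0.004, 10, by = 0.004)), 64),
                nrow = 64, byrow = TRUE)
  rec <- raw_recording(sig, 250,
                       annotations = data.frame(onset_s = 0, duration_s = 10,
                                                condition = "x",
                                                repetition = 1L))
  ep <- epoch_segments(rec, 10)
  ep$data[1, 5, ] <- 999
  fixed <- rereference_and_interpolate(ep, bad_channels = ep$channel_labels[5],
                                       scheme = "average")
  expect_lt(max(abs(fixed$data[1, 5, ] - fixed$data[1, 6, ])), 1e-9)
})

test_that("re-referencing guards its preconditions", {
  d <- build_design(conditions = "x", presentations_per_condition = 1,
                    presentation_duration_s = 10, sampling_rate_hz = 250,
                    n_channels = 8, seed = 54)
  ep <- epoch_segments(generate_session(d, generator_config(seed = 55)), 10)
  expect_error(rereference_and_interpolate(ep, scheme = "linked_ears"),
               "channel error") # generic ChNN labels lack A1/A2
  expect_error(
    rereference_and_interpolate(ep, bad_channels = ep$channel_labels[1:3]),
    "quality error")
  expect_error(rereference_and_interpolate(ep, bad_channels = "nope"),
               "channel error")
})
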