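#' FIR filter specification
#'
#' @param kind One of "highpass", "lowpass", "notch".
#' @param cutoff Cutoff frequency in Hz (length 2 for notch).
#' @param order Filter order (number of taps minus one).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "notch"), cutoff, order) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  if (order %% 2 != 0)
    stop("even `order` required so the group delay is an integer number of samples")
  if (kind == "notch" && length(cutoff) != 2)
    stop("notch filters need a length-2 cutoff (band edges in Hz)")
  if (kind != "notch" && length(cutoff) != 1)
    stop("highpass/lowpass filters need a single cutoff in Hz")
  if (any(cutoff <= 0)) stop("cutoffs must be positive")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order)),
            class = "filter_spec")
}

#' The default three-filter bank
#'
#' Highpass 1 Hz (order 1650), notch 45-55 Hz (order 826), lowpass
#' 100 Hz (order 66): the filter chain applied to the continuous signal
#' before downsampling. All are linear-phase Hamming-window FIR designs.
#'
#' @return List of three \code{filter_spec}s.
#' @export
default_filter_bank <- function() {
  list(filter_spec("highpass", 1, 1650),
       filter_spec("notch", c(45, 55), 826),
       filter_spec("lowpass", 100, 66))
}

# Design the taps of a filter_spec at sampling rate srate (Hamming window).
design_fir <- function(spec, srate) {
  nyq <- srate / 2
  if (any(spec$cutoff >= nyq))
    stop(sprintf("cutoff %s Hz at or above Nyquist (%g Hz)",
                 paste(spec$cutoff, collapse = "-"), nyq))
  w <- spec$cutoff / nyq
  type <- switch(spec$kind, highpass = "high", lowpass = "low", notch = "stop")
  as.numeric(signal::fir1(spec$order, w, type = type))
}

# Zero-net-delay application of linear-phase FIR taps b (odd length) to a
# vector: FFT convolution, then removal of the order/2-sample group delay
# so output aligns with input and has the same length.
apply_fir <- function(x, b) {
  n <- length(x)
  ord <- length(b) - 1L
  half <- ord %/% 2L
  y <- convolve(x, rev(b), type = "open") # length n + ord
  y[(half + 1L):(half + n)]
}

#' Apply an FIR filter bank to a recording
#'
#' Applies each filter in turn to every channel. Filters are
#' linear-phase FIR (Hamming window) applied in a single pass with the
#' group delay compensated by shifting order/2 samples, so the output
#' has zero net delay and the same length as the input.
#'
#' @param recording A \code{raw_recording}.
#' @param specs List of \code{filter_spec}s (default
#'   \code{\link{default_filter_bank}()}).
#' @return The filtered \code{raw_recording}.
#' @export
fir_filter_bank <- function(recording, specs = default_filter_bank()) {
  stopifnot(inherits(recording, "raw_recording"))
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  n <- ncol(recording$signal)
  maxord <- max(vapply(specs, function(s) s$order, numeric(1)))
  if (n <= maxord)
    stop(sprintf("length error: signal has %d samples but the filter order is %d", n, maxord))
  taps <- lapply(specs, design_fir, srate = recording$srate)
  sig <- recording$signal
  for (b in taps)
    for (ch in seq_len(nrow(sig)))
      sig[ch, ] <- apply_fir(sig[ch, ], b)
  recording$signal <- sig
  recording
}

#' Downsample a recording by a factor of two
#'
#' Keeps every second sample and halves the sampling-rate metadata.
#' Anti-aliasing is assumed to have been provided by the preceding
#' 100 Hz lowpass of the default filter bank.
#'
#' @param recording A \code{raw_recording} with an even division by 2
#'   (any rate is accepted; the canonical use is 500 -> 250 Hz).
#' @return The decimated \code{raw_recording}.
#' @export
resample_half <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  if (recording$srate %% 2 != 0)
    stop("config error: sampling rate must be divisible by 2")
  idx <- seq(1L, ncol(recording$signal), by = 2L)
  recording$signal <- recording$signal[, idx, drop = FALSE]
  recording$srate <- recording$srate / 2
  recording
}

#' Fixed-length epochs with condition labels
#'
#' Container for the unit of diversity scoring: an epochs x channels x
#' samples array plus per-epoch labels (condition, repetition,
#' session-order index), the sampling rate, channel labels/positions,
#' and a per-epoch rejection mask.
#'
#' @param data epochs x channels x samples array (microvolts).
#' @param srate Sampling rate in Hz.
#' @param epoch_length_s Epoch length in seconds.
#' @param labels data.frame with one row per epoch: \code{epoch},
#'   \code{presentation}, \code{condition}, \code{repetition},
#'   \code{session_order}.
#' @param channel_labels,positions As in \code{\link{raw_recording}}.
#' @param subject Subject identifier.
#' @return An object of class \code{epoch_set}.
#' @export
epoch_set <- function(data, srate, epoch_length_s, labels,
                      channel_labels = NULL, positions = NULL,
                      subject = NA_character_) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != round(epoch_length_s * srate))
    stop("every epoch must have exactly epoch_length_s * srate samples")
  if (nrow(labels) != dim(data)[1])
    stop("one label row per epoch required")
  if (is.null(channel_labels)) channel_labels <- default_channel_labels(dim(data)[2])
  structure(list(data = data, srate = srate, epoch_length_s = epoch_length_s,
                 labels = labels, channel_labels = channel_labels,
                 positions = positions, rejected = rep(FALSE, dim(data)[1]),
                 subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz), %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_length_s, x$srate, sum(x$rejected)))
  invisible(x)
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping epochs are tiled within each annotated presentation
#' starting at its onset; remainder samples at the end of a presentation
#' are dropped, and no epoch ever spans a presentation boundary.
#' Presentations shorter than one epoch contribute none (with a
#' warning). Epoch labels carry the condition, repetition and a strict
#' session-order index.
#'
#' @param recording An annotated \code{raw_recording}.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @return An \code{\link{epoch_set}}.
#' @export
epoch_segments <- function(recording, epoch_length_s = 10) {
  stopifnot(inherits(recording, "raw_recording"))
  if (is.null(recording$annotations))
    stop("annotation error: recording has no condition annotations")
  if (epoch_length_s <= 0) stop("`epoch_length_s` must be positive")
  srate <- recording$srate
  L <- round(epoch_length_s * srate)
  ann <- recording$annotations
  slices <- list()
  lab <- list()
  short <- 0L
  k <- 0L
  for (p in seq_len(nrow(ann))) {
    start <- round(ann$onset_s[p] * srate) # 0-based sample offset
    avail <- round(ann$duration_s[p] * srate)
    avail <- min(avail, ncol(recording$signal) - start)
    n_ep <- avail %/% L
    if (n_ep == 0L) { short <- short + 1L; next }
    for (e in seq_len(n_ep)) {
      k <- k + 1L
      i0 <- start + (e - 1L) * L + 1L
      slices[[k]] <- recording$signal[, i0:(i0 + L - 1L), drop = FALSE]
      lab[[k]] <- data.frame(epoch = k, presentation = p,
                             condition = ann$condition[p],
                             repetition = ann$repetition[p],
                             session_order = k,
                             stringsAsFactors = FALSE)
    }
  }
  if (short > 0L)
    warning(sprintf("%d presentation(s) shorter than one epoch contributed no epochs", short))
  if (k == 0L) stop("no epochs could be cut from the recording")
  n_ch <- nrow(recording$signal)
  data <- array(0, dim = c(k, n_ch, L))
  for (e in seq_len(k)) data[e, , ] <- slices[[e]]
  epoch_set(data, srate, epoch_length_s, do.call(rbind, lab),
            channel_labels = recording$channel_labels,
            positions = recording$positions,
            subject = recording$subject)
}

#' Automated epoch rejection
#'
#' Flags epochs containing any sample beyond \code{amp_threshold_uv} in
#' absolute value, or any channel whose peak-to-peak amplitude within
#' the epoch falls below \code{flat_threshold_uv} (flatline). The data
#' are retained; only the rejection mask is set, so the operation is
#' idempotent. This is the package's documented automated stand-in for
#' visual artifact screening.
#'
#' @param epochs An \code{epoch_set}.
#' @param amp_threshold_uv Absolute amplitude threshold, microvolts.
#' @param flat_threshold_uv Minimum peak-to-peak amplitude, microvolts.
#' @return The \code{epoch_set} with its \code{rejected} mask updated.
#' @export
reject_epochs_auto <- function(epochs, amp_threshold_uv = 100,
                               flat_threshold_uv = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (amp_threshold_uv <= 0 || flat_threshold_uv <= 0)
    stop("thresholds must be positive")
  n_ep <- dim(epochs$data)[1]
  rej <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    ptp <- apply(m, 1, function(r) max(r) - min(r))
    rej[e] <- max(abs(m)) > amp_threshold_uv || any(ptp < flat_threshold_uv)
  }
  epochs$rejected <- rej
  if (all(rej)) message("all epochs rejected by the automatic criteria")
  epochs
}

#' Re-reference epochs and interpolate bad channels
#'
#' Bad channels are replaced by the inverse-distance-weighted mean of
#' their 4 nearest good neighbors (by 3D electrode distance), then the
#' reference is subtracted: the across-channel mean per time point for
#' \code{scheme = "average"}, or the mean of the A1/A2 ear electrodes
#' for \code{scheme = "linked_ears"}.
#'
#' @param epochs An \code{epoch_set} with electrode positions.
#' @param bad_channels Character vector of channel labels to
#'   interpolate (must be fewer than 25\% of channels).
#' @param scheme Reference scheme.
#' @return The re-referenced \code{epoch_set}.
#' @export
rereference_and_interpolate <- function(epochs, bad_channels = character(0),
                                        scheme = c("average", "linked_ears")) {
  stopifnot(inherits(epochs, "epoch_set"))
  scheme <- match.arg(scheme)
  labs <- epochs$channel_labels
  n_ch <- length(labs)
  if (!all(bad_channels %in% labs))
    stop("channel error: unknown channel in `bad_channels`")
  if (length(bad_channels) > 0.25 * n_ch)
    stop("quality error: more than 25% of channels marked bad")
  if (scheme == "linked_ears" && !all(c("A1", "A2") %in% labs))
    stop("channel error: linked_ears reference requires A1 and A2 channels")

  if (length(bad_channels) > 0) {
    if (is.null(epochs$positions))
      stop("channel error: interpolation requires electrode positions")
    good <- setdiff(labs, bad_channels)
    for (bc in bad_channels) {
      d <- sqrt(colSums((t(epochs$positions[good, , drop = FALSE]) -
                           epochs$positions[bc, ])^2))
      nb <- names(sort(d))[seq_len(min(4L, length(d)))]
      w <- 1 / pmax(d[nb], 1e-9)
      w <- w / sum(w)
      bi <- match(bc, labs)
      ni <- match(nb, labs)
      for (e in seq_len(dim(epochs$data)[1])) {
        epochs$data[e, bi, ] <-
          as.numeric(w %*% epochs$data[e, ni, , drop = TRUE])
      }
    }
  }

  ref_idx <- if (scheme == "average") seq_len(n_ch) else match(c("A1", "A2"), labs)
  for (e in seq_len(dim(epochs$data)[1])) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    ref <- colMeans(m[ref_idx, , drop = FALSE])
    epochs$data[e, , ] <- sweep(m, 2, ref)
  }
  epochs
}

#' Rejection report
#'
#' @param epochs An \code{epoch_set} after
#'   \code{\link{reject_epochs_auto}}.
#' @return data.frame with one row per epoch: labels plus
#'   \code{rejected}.
#' @export
rejection_report <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  cbind(epochs$labels, rejected = epochs$rejected)
}
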