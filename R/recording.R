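#' Construct a continuous multichannel recording
#'
#' The in-memory container for continuous EEG: a channels x samples
#' signal matrix in microvolts plus sampling rate, channel labels,
#' optional 3D electrode positions, and a condition annotation table
#' (onset_s, duration_s, condition, repetition). Generated recordings
#' additionally carry their \code{session_design} and
#' \code{generator_config} provenance.
#'
#' @param signal Numeric matrix, channels x samples, microvolts.
#' @param srate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param positions Optional channels x 3 matrix of unit-sphere
#'   electrode positions (rownames = labels).
#' @param annotations Optional data.frame with columns onset_s,
#'   duration_s, condition, repetition.
#' @param design,config Optional generator provenance.
#' @param subject Subject identifier.
#' @return An object of class \code{raw_recording}.
#' @export
raw_recording <- function(signal, srate, channel_labels = NULL,
                          positions = NULL, annotations = NULL,
                          design = NULL, config = NULL, subject = NA_character_) {
  signal <- as.matrix(signal)
  if (srate <= 0) stop("`srate` must be positive")
  if (is.null(channel_labels))
    channel_labels <- default_channel_labels(nrow(signal))
  if (length(channel_labels) != nrow(signal))
    stop("channel error: one label per signal row required")
  if (is.null(positions)) positions <- montage_positions(channel_labels)
  if (!is.null(annotations)) {
    need <- c("onset_s", "duration_s", "condition", "repetition")
    if (!all(need %in% names(annotations)))
      stop("annotation error: annotations need columns onset_s, duration_s, condition, repetition")
  }
  structure(list(signal = signal, srate = srate,
                 channel_labels = channel_labels,
                 positions = positions,
                 annotations = annotations,
                 design = design, config = config,
                 subject = subject, units = "uV"),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$signal), ncol(x$signal), x$srate,
              ncol(x$signal) / x$srate,
              if (!is.na(x$subject)) paste0(", subject ", x$subject) else ""))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotated presentations (%s)\n", nrow(x$annotations),
                paste(unique(x$annotations$condition), collapse = ", ")))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x A \code{raw_recording}.
#' @return Number of samples (\code{n_samples}) or seconds
#'   (\code{duration_s}).
#' @export
n_samples <- function(x) ncol(x$signal)

#' @rdname n_samples
#' @export
duration_s <- function(x) ncol(x$signal) / x$srate
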