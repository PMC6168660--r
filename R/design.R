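#' Condition labels of the auditory-speed study design
#'
#' Five presentation speeds of the audio material (percent of original
#' speed), a backward (unintelligible) presentation, and a resting-state
#' condition with no stimulation.
#'
#' @return Character vector of the seven condition labels.
#' @export
study_conditions <- function() {
  c("65%", "83%", "100%", "117%", "135%", "backward", "resting-state")
}

#' Build a session design
#'
#' Defines the layout of one recording session: which conditions are
#' presented, how often, for how long, and in what (randomized) order.
#' The default arguments reproduce the study design this package models:
#' 7 conditions x 4 presentations x 90 s, 64 channels. The presentation
#' order is a seeded random permutation of all (condition, repetition)
#' pairs, and the annotation table gives 0-based half-open
#' \code{[onset, onset + duration)} intervals in seconds.
#'
#' @param conditions Character vector of condition labels.
#' @param presentations_per_condition Number of presentations of each
#'   condition.
#' @param presentation_duration_s Duration of one presentation, seconds.
#' @param sampling_rate_hz Sampling rate of the recording to generate.
#' @param n_channels Number of channels.
#' @param seed RNG seed for the presentation-order permutation.
#' @return An object of class \code{session_design} with fields
#'   \code{conditions}, \code{presentations_per_condition},
#'   \code{presentation_duration_s}, \code{sampling_rate_hz},
#'   \code{n_channels}, \code{presentation_order} (data.frame of
#'   condition, repetition), \code{annotations} (data.frame of
#'   onset_s, duration_s, condition, repetition), \code{seed}.
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d$annotations)        # 28 presentations
#' sum(d$annotations$duration_s)  # 2520 s total
#' @export
build_design <- function(conditions = study_conditions(),
                         presentations_per_condition = 4,
                         presentation_duration_s = 90,
                         sampling_rate_hz = 250,
                         n_channels = 64,
                         seed = 1) {
  if (length(conditions) < 1 || anyDuplicated(conditions))
    stop("invalid design: `conditions` must be non-empty and unique")
  if (presentations_per_condition < 1 ||
      presentations_per_condition != round(presentations_per_condition))
    stop("invalid design: `presentations_per_condition` must be a positive integer")
  if (presentation_duration_s <= 0)
    stop("invalid design: `presentation_duration_s` must be positive")
  if (sampling_rate_hz <= 0)
    stop("invalid design: `sampling_rate_hz` must be positive")
  if (n_channels < 1 || n_channels != round(n_channels))
    stop("invalid design: `n_channels` must be a positive integer")

  pairs <- expand.grid(repetition = seq_len(presentations_per_condition),
                       condition = conditions,
                       stringsAsFactors = FALSE)[, c("condition", "repetition")]
  ord <- with_rng(seed, sample.int(nrow(pairs)))
  order_df <- pairs[ord, , drop = FALSE]
  rownames(order_df) <- NULL

  onset <- (seq_len(nrow(order_df)) - 1L) * presentation_duration_s
  ann <- data.frame(onset_s = onset,
                    duration_s = presentation_duration_s,
                    condition = order_df$condition,
                    repetition = order_df$repetition,
                    stringsAsFactors = FALSE)

  structure(list(conditions = conditions,
                 presentations_per_condition = presentations_per_condition,
                 presentation_duration_s = presentation_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 n_channels = n_channels,
                 presentation_order = order_df,
                 annotations = ann,
                 seed = seed),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %d conditions x %d presentations x %g s @ %g Hz, %d channels\n",
              length(x$conditions), x$presentations_per_condition,
              x$presentation_duration_s, x$sampling_rate_hz, x$n_channels))
  cat(sprintf("  total duration %g s, seed %s\n",
              sum(x$annotations$duration_s), format(x$seed)))
  invisible(x)
}

total_duration_s <- function(design) sum(design$annotations$duration_s)
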