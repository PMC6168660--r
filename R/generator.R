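#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the statistical structure the diversity
#' analysis is sensitive to: a 1/f^alpha broadband background, a
#' narrowband (alpha-band by default) oscillatory component whose
#' variance share is set per condition, linear source mixing across
#' channels, an optional linear vigilance drift over the session, and a
#' small white sensor-noise floor. A higher narrowband share makes the
#' Hilbert envelope more regular and therefore lowers Lempel-Ziv
#' diversity; this is the control knob for planted condition effects.
#'
#' @param spectral_exponent Power-law slope alpha of the background
#'   spectrum (power ~ 1/f^alpha). Default 1 (pink).
#' @param osc_freq_hz Center frequency of the narrowband component (Hz).
#' @param osc_bandwidth_hz Full width of the narrowband component (Hz);
#'   a small bandwidth gives a slowly fluctuating, burst-like rhythm.
#' @param osc_amplitude Relative gain of the narrowband component after
#'   the variance mix; 1 keeps \code{narrowband_fraction} an exact
#'   variance fraction.
#' @param narrowband_fraction Named numeric vector (by condition label)
#'   or single number in \[0, 1\]: the variance share of the narrowband
#'   component per condition.
#' @param channel_mixing \code{n_channels x n_sources} mixing matrix, or
#'   NULL for identity (independent channels). Rows are L2-normalized so
#'   channel variance is preserved; with unit-variance sources the
#'   implied channel correlation matrix is \code{M \%*\% t(M)}.
#' @param drift_slope Additive change of narrowband fraction per
#'   presentation index (0-based); models a vigilance drift.
#' @param amplitude_uv Overall channel RMS amplitude in microvolts.
#' @param noise_floor White-noise floor relative to \code{amplitude_uv}.
#' @param seed RNG seed of the generator stream.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(spectral_exponent = 1,
                             osc_freq_hz = 10,
                             osc_bandwidth_hz = 2,
                             osc_amplitude = 1,
                             narrowband_fraction = 0.3,
                             channel_mixing = NULL,
                             drift_slope = 0,
                             amplitude_uv = 20,
                             noise_floor = 0.02,
                             seed = 1) {
  if (any(narrowband_fraction < 0 | narrowband_fraction > 1))
    stop("range error: `narrowband_fraction` must lie in [0, 1]")
  if (osc_freq_hz <= 0 || osc_bandwidth_hz <= 0)
    stop("config error: oscillation frequency and bandwidth must be positive")
  if (!is.null(channel_mixing)) {
    channel_mixing <- as.matrix(channel_mixing)
    nrm <- sqrt(rowSums(channel_mixing^2))
    if (any(nrm == 0)) stop("config error: zero row in `channel_mixing`")
    channel_mixing <- channel_mixing / nrm
  }
  structure(list(spectral_exponent = spectral_exponent,
                 osc_freq_hz = osc_freq_hz,
                 osc_bandwidth_hz = osc_bandwidth_hz,
                 osc_amplitude = osc_amplitude,
                 narrowband_fraction = narrowband_fraction,
                 channel_mixing = channel_mixing,
                 drift_slope = drift_slope,
                 amplitude_uv = amplitude_uv,
                 noise_floor = noise_floor,
                 seed = seed),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> 1/f^%g background + %g Hz narrowband (bw %g Hz)\n",
              x$spectral_exponent, x$osc_freq_hz, x$osc_bandwidth_hz))
  cat(sprintf("  narrowband fraction: %s; drift %g/presentation; seed %s\n",
              paste(format(x$narrowband_fraction), collapse = ", "),
              x$drift_slope, format(x$seed)))
  invisible(x)
}

# Unit-variance noise with power spectrum ~ 1/f^alpha, shaped in the
# frequency domain. The shaping is flattened below 0.5 Hz so very slow
# drifts do not dominate the variance (the real pipeline highpasses at
# 1 Hz anyway).
colored_noise <- function(n, srate, alpha) {
  w <- rnorm(n)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * srate / n # folded freqs
  amp <- pmax(f, 0.5)^(-alpha / 2)
  amp[1] <- 0 # no DC
  x <- Re(fft(fft(w) * amp, inverse = TRUE)) / n
  x / sd(x)
}

# Unit-variance narrowband Gaussian noise centred at f0 with Gaussian
# spectral profile of s.d. bw/2. Its envelope fluctuates on the ~1/bw
# time scale, giving the burst-like rhythmicity that lowers LZ scores.
narrowband_noise <- function(n, srate, f0, bw) {
  w <- rnorm(n)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * srate / n
  amp <- exp(-(f - f0)^2 / (2 * (bw / 2)^2))
  amp[1] <- 0
  x <- Re(fft(fft(w) * amp, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) stop("config error: narrowband profile has no support on the frequency grid")
  x / s
}

# Effective narrowband fraction for a presentation, with range check.
effective_fraction <- function(cfg, condition, pres_index0) {
  nf <- cfg$narrowband_fraction
  base <- if (length(nf) == 1L && is.null(names(nf))) unname(nf)
          else if (!is.null(names(nf)) && condition %in% names(nf)) unname(nf[[condition]])
          else if (length(nf) == 1L) unname(nf)
          else stop(sprintf("config error: no narrowband fraction for condition '%s'", condition))
  f <- base + cfg$drift_slope * pres_index0
  if (f < 0 || f > 1)
    stop(sprintf(paste0("range error: narrowband fraction %.3f outside [0, 1] ",
                        "at presentation %d (condition '%s')"), f, pres_index0 + 1L, condition))
  f
}

#' Generate a synthetic multichannel EEG session
#'
#' Produces a continuous recording realizing a \code{\link{build_design}}
#' session under a \code{\link{generator_config}}: each presentation is
#' an independent segment of mixed 1/f background and narrowband
#' oscillation, with the narrowband variance share set by the
#' presentation's condition plus the vigilance drift. Generation is a
#' pure function of (design, config): the same pair always yields a
#' bit-identical recording.
#'
#' @param design A \code{session_design}.
#' @param cfg A \code{generator_config}.
#' @param subject Optional subject identifier stored in the recording.
#' @return A \code{\link{raw_recording}}.
#' @export
generate_session <- function(design, cfg = generator_config(), subject = "S01") {
  stopifnot(inherits(design, "session_design"), inherits(cfg, "generator_config"))
  n_ch <- design$n_channels
  M <- cfg$channel_mixing
  if (is.null(M)) {
    n_src <- n_ch
  } else {
    if (nrow(M) != n_ch)
      stop(sprintf("config error: channel_mixing has %d rows but design has %d channels",
                   nrow(M), n_ch))
    n_src <- ncol(M)
  }
  srate <- design$sampling_rate_hz
  ann <- design$annotations
  len <- round(design$presentation_duration_s * srate)
  total <- len * nrow(ann)

  # validate all fractions up front so a range error precedes any work
  for (p in seq_len(nrow(ann)))
    effective_fraction(cfg, ann$condition[p], p - 1L)

  sig <- matrix(0, nrow = n_ch, ncol = total)
  with_rng(cfg$seed + 8191 * design$seed, {
    for (p in seq_len(nrow(ann))) {
      f <- effective_fraction(cfg, ann$condition[p], p - 1L)
      src <- matrix(0, nrow = n_src, ncol = len)
      for (s in seq_len(n_src)) {
        bg <- colored_noise(len, srate, cfg$spectral_exponent)
        nb <- narrowband_noise(len, srate, cfg$osc_freq_hz, cfg$osc_bandwidth_hz)
        src[s, ] <- sqrt(1 - f) * bg + sqrt(f) * cfg$osc_amplitude * nb
      }
      chan <- if (is.null(M)) src else M %*% src
      chan <- chan * cfg$amplitude_uv +
        cfg$noise_floor * cfg$amplitude_uv *
          matrix(rnorm(n_ch * len), nrow = n_ch)
      cols <- ((p - 1L) * len + 1L):(p * len)
      sig[, cols] <- chan
    }
  })

  labels <- default_channel_labels(n_ch)
  raw_recording(signal = sig, srate = srate, channel_labels = labels,
                positions = montage_positions(labels),
                annotations = ann, design = design, config = cfg,
                subject = subject)
}

#' Shift the narrowband fraction of selected conditions
#'
#' Plants (or removes) condition-level diversity effects by offsetting
#' the narrowband variance share of the named conditions and
#' regenerating the session from its stored design and configuration.
#' A positive offset makes the condition more rhythmic and hence lowers
#' its expected diversity. With all offsets zero the output is
#' bit-identical to the input.
#'
#' @param recording A \code{raw_recording} produced by
#'   \code{\link{generate_session}}.
#' @param effect_map Named numeric vector: condition label -> offset of
#'   the narrowband fraction.
#' @return A new \code{raw_recording}.
#' @export
inject_condition_effects <- function(recording, effect_map) {
  stopifnot(inherits(recording, "raw_recording"))
  cfg <- recording$config
  design <- recording$design
  if (is.null(cfg) || is.null(design))
    stop("recording carries no generator provenance; effects can only be injected into generated sessions")
  if (length(effect_map) && is.null(names(effect_map)))
    stop("`effect_map` must be named by condition")
  nf <- cfg$narrowband_fraction
  if (length(nf) == 1L && is.null(names(nf))) {
    nf <- stats::setNames(rep(unname(nf), length(design$conditions)), design$conditions)
  }
  for (cond in names(effect_map)) {
    if (!cond %in% names(nf))
      stop(sprintf("unknown condition '%s' in effect_map", cond))
    nf[[cond]] <- nf[[cond]] + effect_map[[cond]]
    if (nf[[cond]] < 0 || nf[[cond]] > 1)
      stop(sprintf("range error: offset pushes narrowband fraction of '%s' to %.3f, outside [0, 1]",
                   cond, nf[[cond]]))
  }
  cfg$narrowband_fraction <- nf
  generate_session(design, cfg, subject = recording$subject)
}

#' Impose a linear vigilance drift on a generated session
#'
#' Sets the session-long linear drift of the narrowband fraction (per
#' presentation index) and regenerates the recording. A positive slope
#' makes later presentations more rhythmic, i.e. less diverse, emulating
#' a time-on-task vigilance decline. \code{drift_slope = 0} leaves the
#' session stationary (and reproduces the input bit-for-bit when it had
#' no drift).
#'
#' @param recording A generated \code{raw_recording}.
#' @param drift_slope Change of narrowband fraction per presentation.
#' @return A new \code{raw_recording}.
#' @export
inject_vigilance_drift <- function(recording, drift_slope) {
  stopifnot(inherits(recording, "raw_recording"))
  cfg <- recording$config
  design <- recording$design
  if (is.null(cfg) || is.null(design))
    stop("recording carries no generator provenance; drift can only be injected into generated sessions")
  cfg$drift_slope <- drift_slope
  # range check across the whole session happens inside generate_session
  generate_session(design, cfg, subject = recording$subject)
}

#' Add a high-amplitude transient to a recording
#'
#' Utility for exercising the automated epoch rejection: adds a brief
#' square pulse of the given amplitude on one channel.
#'
#' @param recording A \code{raw_recording}.
#' @param at_s Onset of the transient in seconds.
#' @param amplitude_uv Pulse amplitude in microvolts.
#' @param duration_s Pulse duration in seconds.
#' @param channel Channel index.
#' @return The modified \code{raw_recording}.
#' @export
inject_transient <- function(recording, at_s, amplitude_uv = 500,
                             duration_s = 0.2, channel = 1L) {
  stopifnot(inherits(recording, "raw_recording"))
  i0 <- round(at_s * recording$srate) + 1L
  i1 <- min(ncol(recording$signal), i0 + round(duration_s * recording$srate) - 1L)
  if (i0 < 1L || i0 > ncol(recording$signal))
    stop("transient onset outside the recording")
  recording$signal[channel, i0:i1] <- recording$signal[channel, i0:i1] + amplitude_uv
  recording
}
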