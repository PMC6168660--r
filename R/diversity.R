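#' Standardize a single-channel epoch
#'
#' Applies, in order: subtract the mean, divide by the standard
#' deviation, and remove a least-squares linear trend. This is the
#' fixed conditioning applied to every 10-s channel segment before
#' envelope binarization.
#'
#' @param x Numeric vector of samples (length >= 3, non-constant).
#' @return Standardized numeric vector of the same length.
#' @export
standardize_segment <- function(x) {
  n <- length(x)
  if (n < 3) stop("segment too short: need at least 3 samples")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate signal: zero standard deviation")
  z <- (x - mean(x)) / s
  t <- seq_len(n)
  tc <- t - mean(t)
  beta <- sum(tc * z) / sum(tc^2)
  z - (mean(z) + beta * tc)
}

# Analytic signal via the frequency-domain construction: zero the
# negative frequencies, double the positive ones, keep DC (and Nyquist
# for even n), inverse-transform. Computed on the full segment with no
# padding or tapering.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Binarize a standardized segment by its Hilbert envelope
#'
#' Computes the analytic signal on the full segment (no padding or
#' tapering), takes its modulus as the instantaneous envelope, and
#' thresholds at the envelope mean: samples whose envelope exceeds the
#' mean map to 1, all others (including exact ties) to 0.
#'
#' @param x Standardized samples (see \code{\link{standardize_segment}}).
#' @param origin Optional identifier (epoch/channel) stored with the
#'   sequence.
#' @return An object of class \code{binary_sequence}: list with
#'   \code{bits} (integer 0/1, same length as \code{x}),
#'   \code{threshold_value} (the envelope mean) and \code{origin}.
#' @export
binarize_hilbert <- function(x, origin = NULL) {
  env <- Mod(analytic_signal(as.numeric(x)))
  thr <- mean(env)
  structure(list(bits = as.integer(env > thr),
                 threshold_value = thr,
                 origin = origin),
            class = "binary_sequence")
}

#' @export
print.binary_sequence <- function(x, ...) {
  cat(sprintf("<binary_sequence> %d bits, %.1f%% ones, threshold %.4g\n",
              length(x$bits), 100 * mean(x$bits), x$threshold_value))
  invisible(x)
}

as_bits <- function(b) {
  bits <- if (inherits(b, "binary_sequence")) b$bits
          else if (is.character(b) && length(b) == 1L)
            as.integer(strsplit(b, "")[[1]])
          else as.integer(b)
  if (length(bits) == 0L) stop("empty sequence")
  if (anyNA(bits) || any(bits != 0L & bits != 1L))
    stop("sequence must contain only 0/1 symbols")
  bits
}

#' Lempel-Ziv (1976) word count
#'
#' Parses a binary sequence into its exhaustive history — each word is
#' the shortest prefix of the remaining string not reproducible from
#' the prior history — and returns the number of words
#' (Kaspar-Schuster production counting; the final, possibly
#' non-exhaustive word is counted). This count is the raw diversity
#' score of the sequence.
#'
#' @param b A \code{binary_sequence}, a 0/1 vector, or a "0101..."
#'   string.
#' @return Positive integer word count.
#' @examples
#' lz76_count("0")          # 1
#' lz76_count("0000000000") # 2
#' lz76_count("0001101001000101") # 6
#' @export
lz76_count <- function(b) {
  .lz76_count_cpp(as_bits(b))
}

#' Surrogate (shuffle) normalization of a raw word count
#'
#' Divides the raw LZ76 count by the mean count of \code{n_surrogates}
#' seeded uniform random permutations of the same bits, capping the
#' ratio at 1. A time-shuffled string retains the symbol distribution
#' but destroys all temporal structure, so its count is the
#' maximal-diversity reference for that bit content. Constant strings
#' are flagged degenerate (shuffling is the identity, the ratio is 1 by
#' construction).
#'
#' @param raw_count LZ76 count of \code{b} (see
#'   \code{\link{lz76_count}}).
#' @param b The same binary sequence.
#' @param n_surrogates Number of random permutations averaged
#'   (default 1).
#' @param seed RNG seed for the permutations.
#' @param kind Score tag: "LZs_channel", "LZs_mean" or "LZc".
#' @return An object of class \code{diversity_score}: list with
#'   \code{raw_count}, \code{surrogate_count}, \code{normalized} in
#'   \[0, 1\], \code{kind}, \code{degenerate_flag}.
#' @export
surrogate_normalize <- function(raw_count, b, n_surrogates = 1, seed = 1,
                                kind = "LZs_channel") {
  bits <- as_bits(b)
  if (n_surrogates < 1) stop("`n_surrogates` must be >= 1")
  degenerate <- length(unique(bits)) == 1L
  if (degenerate) {
    surr <- as.numeric(raw_count)
  } else {
    counts <- with_rng(seed, {
      vapply(seq_len(n_surrogates),
             function(i) .lz76_count_cpp(sample(bits)),
             integer(1))
    })
    surr <- mean(counts)
  }
  norm <- min(1, raw_count / surr)
  structure(list(raw_count = raw_count, surrogate_count = surr,
                 normalized = norm, kind = kind,
                 degenerate_flag = degenerate),
            class = "diversity_score")
}

#' @export
print.diversity_score <- function(x, ...) {
  cat(sprintf("<diversity_score> %s: raw %d / surrogate %.2f = %.4f%s\n",
              x$kind, x$raw_count, x$surrogate_count, x$normalized,
              if (x$degenerate_flag) " [degenerate]" else ""))
  invisible(x)
}

# standardize -> binarize -> count -> normalize for one channel vector
score_channel <- function(x, n_surrogates, seed, origin = NULL) {
  b <- binarize_hilbert(standardize_segment(x), origin = origin)
  raw <- .lz76_count_cpp(b$bits)
  surrogate_normalize(raw, b, n_surrogates = n_surrogates, seed = seed,
                      kind = "LZs_channel")
}

#' Single-channel Lempel-Ziv diversity of one epoch
#'
#' Scores every channel of a channels x samples epoch independently
#' (standardize, Hilbert-envelope binarize, LZ76 count, surrogate
#' normalize) and reports the per-channel normalized scores and their
#' arithmetic mean (the channel-mean LZs of the epoch).
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param n_surrogates,seed Passed to
#'   \code{\link{surrogate_normalize}}; the seed is offset per channel.
#' @param channel_labels Optional labels for the rows.
#' @return List with \code{per_channel} (data.frame: channel, raw,
#'   surrogate, normalized, degenerate) and \code{channel_mean}.
#' @export
lzs_epoch <- function(epoch, n_surrogates = 1, seed = 1,
                      channel_labels = NULL) {
  epoch <- as.matrix(epoch)
  n_ch <- nrow(epoch)
  if (is.null(channel_labels)) channel_labels <- default_channel_labels(n_ch)
  sds <- apply(epoch, 1, sd)
  if (any(sds == 0))
    stop(sprintf("degenerate signal: constant channel(s) %s",
                 paste(channel_labels[sds == 0], collapse = ", ")))
  rows <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    sc <- score_channel(epoch[ch, ], n_surrogates, seed + ch - 1L,
                        origin = channel_labels[ch])
    rows[[ch]] <- data.frame(channel = channel_labels[ch],
                             raw = sc$raw_count,
                             surrogate = sc$surrogate_count,
                             normalized = sc$normalized,
                             degenerate = sc$degenerate_flag,
                             stringsAsFactors = FALSE)
  }
  per_channel <- do.call(rbind, rows)
  list(per_channel = per_channel,
       channel_mean = mean(per_channel$normalized))
}

#' Spatio-temporal Lempel-Ziv diversity of one epoch
#'
#' Binarizes each channel exactly as for LZs, then concatenates the
#' binary matrix observation-by-observation (channel-major within each
#' time step: the first \code{n_channels} digits are all channels at
#' time 1, the next \code{n_channels} at time 2, ...) and applies the
#' LZ76 count and surrogate normalization to the concatenated string.
#' The default surrogate permutes the whole concatenated string,
#' destroying spatial and temporal structure symmetrically;
#' \code{surrogate = "within_channel"} instead shuffles each channel's
#' bits in time before concatenating, preserving the spatial layout.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param n_surrogates,seed As in \code{\link{surrogate_normalize}}.
#' @param surrogate Surrogate scheme, "full" (default) or
#'   "within_channel".
#' @return A \code{diversity_score} of kind "LZc".
#' @export
lzc_epoch <- function(epoch, n_surrogates = 1, seed = 1,
                      surrogate = c("full", "within_channel")) {
  surrogate <- match.arg(surrogate)
  epoch <- as.matrix(epoch)
  sds <- apply(epoch, 1, sd)
  if (any(sds == 0))
    stop(sprintf("degenerate signal: constant channel(s) %s",
                 paste(which(sds == 0), collapse = ", ")))
  B <- t(vapply(seq_len(nrow(epoch)),
                function(ch) binarize_hilbert(standardize_segment(epoch[ch, ]))$bits,
                integer(ncol(epoch))))
  if (nrow(epoch) == 1L) B <- matrix(B, nrow = 1)
  bits <- as.integer(B) # column-major = channel-major within each time step
  raw <- .lz76_count_cpp(bits)
  if (surrogate == "full") {
    surrogate_normalize(raw, bits, n_surrogates = n_surrogates, seed = seed,
                        kind = "LZc")
  } else {
    degenerate <- length(unique(bits)) == 1L
    if (degenerate) {
      surr <- as.numeric(raw)
    } else {
      counts <- with_rng(seed, {
        vapply(seq_len(n_surrogates), function(i) {
          Bs <- t(apply(B, 1, sample))
          .lz76_count_cpp(as.integer(Bs))
        }, integer(1))
      })
      surr <- mean(counts)
    }
    structure(list(raw_count = raw, surrogate_count = surr,
                   normalized = min(1, raw / surr), kind = "LZc",
                   degenerate_flag = degenerate),
              class = "diversity_score")
  }
}

#' Score all epochs of an epoch set
#'
#' Runs the requested diversity measures over every non-rejected epoch
#' and returns a long-format score table with one row per (epoch,
#' channel) for per-channel LZs, one "ALL" row per epoch for the
#' channel-mean LZs, and one "ALL" row per epoch for LZc.
#'
#' @param epochs An \code{epoch_set}.
#' @param measures Character subset of \code{c("lzs", "lzc")}.
#' @param n_surrogates,seed Surrogate settings; the per-epoch surrogate
#'   seed is \code{seed + session_order}.
#' @param keep_channels Keep the per-channel LZs rows (default TRUE).
#' @return data.frame with columns subject, epoch, session_order,
#'   condition, repetition, channel, measure, raw, surrogate,
#'   normalized, degenerate.
#' @export
score_epochs <- function(epochs, measures = c("lzs", "lzc"),
                         n_surrogates = 1, seed = 1, keep_channels = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  measures <- match.arg(measures, c("lzs", "lzc"), several.ok = TRUE)
  out <- list()
  k <- 0L
  for (e in which(!epochs$rejected)) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    lab <- epochs$labels[e, ]
    eseed <- seed + lab$session_order
    base <- data.frame(subject = epochs$subject, epoch = lab$epoch,
                       session_order = lab$session_order,
                       condition = lab$condition, repetition = lab$repetition,
                       stringsAsFactors = FALSE)
    if ("lzs" %in% measures) {
      sc <- lzs_epoch(m, n_surrogates = n_surrogates, seed = eseed,
                      channel_labels = epochs$channel_labels)
      if (keep_channels) {
        k <- k + 1L
        out[[k]] <- cbind(base[rep(1, nrow(sc$per_channel)), ],
                          channel = sc$per_channel$channel, measure = "LZs",
                          raw = sc$per_channel$raw,
                          surrogate = sc$per_channel$surrogate,
                          normalized = sc$per_channel$normalized,
                          degenerate = sc$per_channel$degenerate)
      }
      k <- k + 1L
      out[[k]] <- cbind(base, channel = "ALL", measure = "LZs_mean",
                        raw = NA_real_, surrogate = NA_real_,
                        normalized = sc$channel_mean, degenerate = FALSE)
    }
    if ("lzc" %in% measures) {
      sc <- lzc_epoch(m, n_surrogates = n_surrogates, seed = eseed)
      k <- k + 1L
      out[[k]] <- cbind(base, channel = "ALL", measure = "LZc",
                        raw = sc$raw_count, surrogate = sc$surrogate_count,
                        normalized = sc$normalized,
                        degenerate = sc$degenerate_flag)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(all(res$normalized >= 0 & res$normalized <= 1)) # hard contract
  res
}
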