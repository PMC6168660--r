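#' Load a recording from disk
#'
#' Dispatches on the file extension: \code{.edf} via
#' \code{\link{read_edf}}, \code{.vhdr} via
#' \code{\link{read_brainvision}}, anything else is treated as a
#' fixture basepath for \code{\link{read_fixture}}.
#'
#' @param path File path.
#' @return A \code{raw_recording}.
#' @export
load_recording <- function(path) {
  lower <- tolower(path)
  if (endsWith(lower, ".edf")) read_edf(path)
  else if (endsWith(lower, ".vhdr")) read_brainvision(path)
  else read_fixture(sub("\\.(json|data\\.tsv)$", "", path))
}

# subject x condition matrix of per-subject condition means from a
# score table (rows channel == "ALL" of the requested measure)
condition_matrix <- function(scores, conditions, measure, aggregator = mean) {
  sc <- scores[scores$channel == "ALL" & scores$measure == measure &
                 scores$condition %in% conditions, ]
  if (nrow(sc) == 0) stop("design error: no scores for the requested measure/conditions")
  subjects <- sort(unique(sc$subject))
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(conditions),
              dimnames = list(subjects, conditions))
  for (i in seq_along(subjects)) {
    for (j in seq_along(conditions)) {
      v <- sc$normalized[sc$subject == subjects[i] & sc$condition == conditions[j]]
      if (length(v)) m[i, j] <- aggregator(v)
    }
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("design error: subject %s lacks condition '%s'",
                 subjects[miss[1, 1]], conditions[miss[1, 2]]))
  }
  m
}

posthoc_table <- function(m, cauchy_scale = 0.707) {
  k <- ncol(m)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(ix) {
    i <- pairs[1, ix]; j <- pairs[2, ix]
    w <- wilcoxon_signed_rank(m[, i], m[, j])
    bf <- jzs_bf_paired(m[, i], m[, j], cauchy_scale)
    data.frame(pair = paste(colnames(m)[i], "vs", colnames(m)[j]),
               z = w$z, p_raw = w$p, bf10 = bf,
               bf_band = interpret_bf(bf), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- holm_adjust(tab$p_raw)
  tab[, c("pair", "z", "p_raw", "p_holm", "bf10", "bf_band")]
}

#' Run one of the three statistical models on a score table
#'
#' \describe{
#'   \item{speed}{Friedman omnibus over the five presentation-speed
#'     conditions plus the one-way repeated-measures Bayes factor.}
#'   \item{meaning}{Friedman omnibus over \{100\%, backward,
#'     resting-state\} plus pairwise Wilcoxon post hocs with Holm
#'     correction and paired JZS Bayes factors.}
#'   \item{time}{Each subject's epochs are split into session-order
#'     quartiles (\code{\link{quartile_split}}); Friedman over Q1-Q4
#'     plus the same post-hoc battery.}
#' }
#' Per-subject condition summaries are means over non-rejected epochs
#' (medians by \code{aggregator = median}); any normalization for
#' display happens at plot time, never before testing.
#'
#' @param scores Score table from \code{\link{score_epochs}} (rows of
#'   one or more subjects).
#' @param model "speed", "meaning" or "time".
#' @param measure "LZs_mean" or "LZc".
#' @param conditions Conditions used by the model (defaults per
#'   model).
#' @param aggregator Epoch aggregator per subject x condition.
#' @param cauchy_scale Prior scale of the paired Bayes factors.
#' @param bf_draws,seed Monte Carlo settings of the omnibus Bayes
#'   factor (speed model).
#' @return An object of class \code{stat_report}: list with
#'   \code{model}, \code{measure}, \code{omnibus} (statistic, df, p),
#'   \code{bf10}/\code{bf_band} (omnibus-level, speed model),
#'   \code{posthoc} (data.frame or NULL), \code{condition_means},
#'   \code{matrix}.
#' @export
run_model <- function(scores, model = c("speed", "meaning", "time"),
                      measure = c("LZs_mean", "LZc"),
                      conditions = NULL, aggregator = mean,
                      cauchy_scale = 0.707, bf_draws = 10000, seed = 1) {
  model <- match.arg(model)
  measure <- match.arg(measure)

  if (model == "time") {
    sc <- scores[scores$channel == "ALL" & scores$measure == measure, ]
    if (nrow(sc) == 0) stop("design error: no scores for the requested measure")
    subjects <- sort(unique(sc$subject))
    qlab <- paste0("Q", 1:4)
    m <- matrix(NA_real_, nrow = length(subjects), ncol = 4,
                dimnames = list(subjects, qlab))
    for (i in seq_along(subjects)) {
      si <- sc[sc$subject == subjects[i], ]
      q <- quartile_split(si$session_order)
      for (j in 1:4) m[i, j] <- aggregator(si$normalized[q == qlab[j]])
    }
    if (anyNA(m)) stop("design error: a subject has an empty quartile")
  } else {
    if (is.null(conditions)) {
      conditions <- if (model == "speed")
        c("65%", "83%", "100%", "117%", "135%")
      else c("100%", "backward", "resting-state")
    }
    m <- condition_matrix(scores, conditions, measure, aggregator)
  }

  om <- friedman_test(m)
  rep_ <- list(model = model, measure = measure, omnibus = om,
               condition_means = colMeans(m), matrix = m,
               posthoc = NULL, bf10 = NULL, bf_band = NULL)

  if (model == "speed") {
    bf <- bf_one_way_rm(m, draws = bf_draws, seed = seed)
    rep_$bf10 <- bf$bf10
    rep_$bf_mcse_log <- bf$mcse_log
    rep_$bf_band <- interpret_bf(bf$bf10)
  } else {
    rep_$posthoc <- posthoc_table(m, cauchy_scale)
  }
  structure(rep_, class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> model '%s' on %s\n", x$model, x$measure))
  cat(sprintf("  omnibus: chi2(%d) = %.3f, p = %.4g\n",
              x$omnibus$df, x$omnibus$statistic, x$omnibus$p))
  if (!is.null(x$bf10))
    cat(sprintf("  BF10 = %.3g (%s)\n", x$bf10, x$bf_band))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Wilcoxon, Holm-adjusted):\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %-28s Z = %6.2f  p = %.4g (adj %.4g)  BF10 = %.3g (%s)\n",
                  x$posthoc$pair[i], x$posthoc$z[i], x$posthoc$p_raw[i],
                  x$posthoc$p_holm[i], x$posthoc$bf10[i], x$posthoc$bf_band[i]))
  }
  invisible(x)
}

#' Topographic comparison of two conditions
#'
#' Builds each subject's per-channel mean LZs for the two conditions,
#' forms the per-subject channel difference (first minus second), and
#' runs the cluster-based permutation test on the montage.
#'
#' @param scores Score table with per-channel LZs rows (measure
#'   "LZs").
#' @param conditions Length-2 character vector (difference is
#'   first - second; default resting-state minus 100\%).
#' @param positions channels x 3 electrode positions; defaults to the
#'   packaged montage for the channel labels present.
#' @param ... Passed to \code{\link{cluster_permutation_test}}.
#' @return A \code{topography_result} with an extra
#'   \code{condition_means} channels x 2 matrix attached.
#' @export
run_topography <- function(scores, conditions = c("resting-state", "100%"),
                           positions = NULL, ...) {
  stopifnot(length(conditions) == 2)
  sc <- scores[scores$measure == "LZs" & scores$channel != "ALL" &
                 scores$condition %in% conditions, ]
  if (nrow(sc) == 0) stop("design error: no per-channel LZs scores for these conditions")
  channels <- unique(sc$channel)
  subjects <- sort(unique(sc$subject))
  if (is.null(positions)) positions <- montage_positions(channels)
  if (nrow(positions) != length(channels) ||
      (!is.null(rownames(positions)) && !setequal(rownames(positions), channels)))
    stop("channel error: positions do not match the channels in the score table")
  positions <- positions[channels, , drop = FALSE]

  per <- function(cond) {
    m <- matrix(NA_real_, nrow = length(subjects), ncol = length(channels),
                dimnames = list(subjects, channels))
    for (i in seq_along(subjects))
      for (j in seq_along(channels)) {
        v <- sc$normalized[sc$subject == subjects[i] & sc$channel == channels[j] &
                             sc$condition == cond]
        if (length(v)) m[i, j] <- mean(v)
      }
    if (anyNA(m)) stop(sprintf("design error: missing channel scores for condition '%s'", cond))
    m
  }
  m1 <- per(conditions[1])
  m2 <- per(conditions[2])
  res <- cluster_permutation_test(m1 - m2, positions, ...)
  res$condition_means <- cbind(colMeans(m1), colMeans(m2))
  colnames(res$condition_means) <- conditions
  res
}

#' Bundle model reports into machine- and human-readable output
#'
#' Serializes a named list of \code{stat_report} /
#' \code{topography_result} objects (plus the run metadata) to a JSON
#' bundle and a markdown summary in which every reported Bayes factor
#' carries its interpretation sentence.
#'
#' @param reports Named list of report objects.
#' @param meta Optional list of run metadata (seeds, config) stored
#'   verbatim in the bundle.
#' @param path Optional output basepath; writes \code{<path>.json} and
#'   \code{<path>.md}.
#' @return List with \code{bundle} (the serializable list) and
#'   \code{summary} (character vector of markdown lines).
#' @export
make_report <- function(reports, meta = list(), path = NULL) {
  if (length(reports) == 0) stop("need at least one model report")
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    names(reports) <- paste0("model", seq_along(reports))

  ser <- function(r) {
    if (inherits(r, "stat_report")) {
      list(kind = "stat_report", model = r$model, measure = r$measure,
           omnibus = r$omnibus, bf10 = r$bf10, bf_band = r$bf_band,
           condition_means = as.list(r$condition_means),
           posthoc = r$posthoc)
    } else if (inherits(r, "topography_result")) {
      list(kind = "topography_result",
           t = unname(r$t), mean_diff = unname(r$mean_diff),
           clusters = r$clusters, n_perm = r$n_perm, alpha = r$alpha)
    } else r
  }
  bundle <- list(meta = meta, reports = lapply(reports, ser))

  lines <- c("# Signal diversity analysis report", "")
  for (nm in names(reports)) {
    r <- reports[[nm]]
    lines <- c(lines, sprintf("## %s", nm))
    if (inherits(r, "stat_report")) {
      lines <- c(lines, sprintf(
        "Omnibus (Friedman): chi2(%d) = %.3f, p = %.4g.",
        r$omnibus$df, r$omnibus$statistic, r$omnibus$p))
      if (!is.null(r$bf10))
        lines <- c(lines, sprintf("BF10 = %.3g, indicating %s.", r$bf10, r$bf_band))
      if (!is.null(r$posthoc))
        for (i in seq_len(nrow(r$posthoc)))
          lines <- c(lines, sprintf(
            "%s: Z = %.2f, p = %.4g (Holm-adjusted %.4g); BF10 = %.3g, indicating %s.",
            r$posthoc$pair[i], r$posthoc$z[i], r$posthoc$p_raw[i],
            r$posthoc$p_holm[i], r$posthoc$bf10[i], r$posthoc$bf_band[i]))
    } else if (inherits(r, "topography_result")) {
      if (nrow(r$clusters) == 0) {
        lines <- c(lines, "No supra-threshold channel clusters.")
      } else {
        for (i in seq_len(nrow(r$clusters)))
          lines <- c(lines, sprintf(
            "Cluster %d (%s): mass %.2f, p = %.4g%s (channels: %s).",
            i, if (r$clusters$sign[i] > 0) "positive" else "negative",
            r$clusters$mass[i], r$clusters$p[i],
            if (r$clusters$significant[i]) ", significant" else "",
            r$clusters$channels[i]))
      }
    }
    lines <- c(lines, "")
  }

  if (!is.null(path)) {
    jsonlite::write_json(bundle, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    writeLines(lines, paste0(path, ".md"))
  }
  list(bundle = bundle, summary = lines)
}

#' Simulate and score a cohort of synthetic subjects
#'
#' Convenience wrapper used for calibration and power studies:
#' generates one synthetic session per subject under a shared design
#' and per-condition narrowband fractions, epochs it, and returns the
#' combined epoch-level score table.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Condition labels.
#' @param narrowband_fraction Named per-condition narrowband fractions
#'   (or one number).
#' @param presentations_per_condition,presentation_duration_s,n_channels,sampling_rate_hz
#'   Design parameters (see \code{\link{build_design}}).
#' @param drift_slope Vigilance drift per presentation.
#' @param measures,n_surrogates Passed to \code{\link{score_epochs}}.
#' @param epoch_length_s Epoch length (default 10 s).
#' @param seed Cohort seed; subject s uses design seed
#'   \code{seed * 1000 + s} and generator seed \code{seed * 1000 + 500 + s}.
#' @param keep_channels Keep per-channel LZs rows (default FALSE; the
#'   cohort-level models need only the "ALL" rows).
#' @return Combined score table over subjects.
#' @export
simulate_cohort_scores <- function(n_subjects, conditions,
                                   narrowband_fraction,
                                   presentations_per_condition = 1,
                                   presentation_duration_s = 90,
                                   n_channels = 4,
                                   sampling_rate_hz = 250,
                                   drift_slope = 0,
                                   measures = "lzs",
                                   n_surrogates = 1,
                                   epoch_length_s = 10,
                                   seed = 1,
                                   keep_channels = FALSE) {
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    design <- build_design(conditions = conditions,
                           presentations_per_condition = presentations_per_condition,
                           presentation_duration_s = presentation_duration_s,
                           sampling_rate_hz = sampling_rate_hz,
                           n_channels = n_channels,
                           seed = seed * 1000 + s)
    cfg <- generator_config(narrowband_fraction = narrowband_fraction,
                            drift_slope = drift_slope,
                            seed = seed * 1000 + 500 + s)
    rec <- generate_session(design, cfg, subject = sprintf("S%02d", s))
    ep <- epoch_segments(rec, epoch_length_s)
    out[[s]] <- score_epochs(ep, measures = measures,
                             n_surrogates = n_surrogates,
                             seed = seed * 1000 + s,
                             keep_channels = keep_channels)
  }
  do.call(rbind, out)
}
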