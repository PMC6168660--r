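# Cohort-level simulation helpers for the power and calibration
# studies. The rest-vs-task effect is specified in units of the
# within-subject epoch-to-epoch SD of the channel-mean LZs; a seeded
# pilot run estimates that SD and the LZs-per-narrowband-fraction
# slope, from which the narrowband offset realizing a target effect is
# derived. The pilot runs once per session and is cached.

.calib_cache <- new.env(parent = emptyenv())

meaning_conditions <- c("100%", "backward", "resting-state")

# Pilot: estimate sigma_epoch (within subject x condition SD of
# channel-mean LZs) and the local dLZs/dfraction slope around the task
# operating point, under the same cohort settings used by the power
# studies.
pilot_effect_calibration <- function(base_fraction = 0.35, probe_offset = 0.1,
                                     n_subjects = 6, seed = 971) {
  key <- paste(base_fraction, probe_offset, n_subjects, seed, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  sc <- simulate_cohort_scores(
    n_subjects = n_subjects,
    conditions = c("task", "probe"),
    narrowband_fraction = c(task = base_fraction,
                            probe = base_fraction - probe_offset),
    presentation_duration_s = 90, n_channels = 2,
    seed = seed, measures = "lzs")
  per <- aggregate(normalized ~ subject + condition, sc, mean)
  sds <- aggregate(normalized ~ subject + condition, sc, sd)
  wide <- reshape(per, idvar = "subject", timevar = "condition",
                  direction = "wide")
  delta <- mean(wide$normalized.probe - wide$normalized.task)
  out <- list(sigma_epoch = mean(sds$normalized),
              slope_per_fraction = delta / probe_offset)
  .calib_cache[[key]] <- out
  out
}

# Narrowband-fraction offset that plants a rest-vs-task LZs effect of
# `effect_sd` within-subject SDs (rest = lower fraction = higher LZs).
calibrated_rest_offset <- function(effect_sd = 0.5, base_fraction = 0.35) {
  cal <- pilot_effect_calibration(base_fraction = base_fraction)
  effect_sd * cal$sigma_epoch / cal$slope_per_fraction
}

# One meaning-design cohort (three conditions, single presentation of
# the study's 90-s duration each) with the planted rest effect.
simulate_meaning_cohort <- function(seed, rest_offset, n_subjects = 19,
                                    base_fraction = 0.35) {
  nf <- c(base_fraction, base_fraction, base_fraction - rest_offset)
  names(nf) <- meaning_conditions
  simulate_cohort_scores(
    n_subjects = n_subjects, conditions = meaning_conditions,
    narrowband_fraction = nf,
    presentation_duration_s = 90, n_channels = 2,
    seed = seed, measures = "lzs")
}

# Per-subject session with a vigilance drift, scored with LZc.
simulate_drift_cohort <- function(seed, drift_slope = 0.06, n_subjects = 6,
                                  base_fraction = 0.2) {
  simulate_cohort_scores(
    n_subjects = n_subjects, conditions = "task",
    narrowband_fraction = base_fraction,
    presentations_per_condition = 4, presentation_duration_s = 40,
    n_channels = 4, drift_slope = drift_slope,
    seed = seed, measures = "lzc")
}

# Score-level null cohort: epoch-level tables with no condition effect,
# for exercising run_model's statistics directly.
score_table_cohort <- function(seed, n_subjects = 19,
                               conditions = meaning_conditions,
                               epochs_per_condition = 8,
                               effect = stats::setNames(
                                 rep(0, length(conditions)), conditions),
                               measure = "LZs_mean", sd_epoch = 0.02) {
  withr::with_seed(seed, {
    rows <- list()
    k <- 0L
    for (s in seq_len(n_subjects)) {
      subj_mean <- 0.85 + rnorm(1, 0, 0.02)
      order_ix <- sample(length(conditions) * epochs_per_condition)
      i <- 0L
      for (cond in conditions) {
        for (e in seq_len(epochs_per_condition)) {
          i <- i + 1L
          k <- k + 1L
          rows[[k]] <- data.frame(
            subject = sprintf("S%02d", s), epoch = i,
            session_order = order_ix[i], condition = cond, repetition = 1L,
            channel = "ALL", measure = measure, raw = NA_real_,
            surrogate = NA_real_,
            normalized = subj_mean + effect[[cond]] + rnorm(1, 0, sd_epoch),
            degenerate = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
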