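# Column-oriented plain-text fixture format: a samples x channels TSV
# (one column per channel), a JSON sidecar with the metadata, and an
# annotations TSV. Epoch sets use the same layout with epochs stacked
# and a labels TSV.

#' Write a recording in the TSV + JSON fixture format
#'
#' Creates \code{<basepath>.data.tsv} (samples x channels, one column
#' per channel label), \code{<basepath>.json} (sampling rate, labels,
#' units, subject, seeds), and \code{<basepath>.annotations.tsv}.
#'
#' @param recording A \code{raw_recording}.
#' @param basepath Output path without extension.
#' @return \code{basepath}, invisibly.
#' @export
write_fixture <- function(recording, basepath) {
  stopifnot(inherits(recording, "raw_recording"))
  df <- as.data.frame(t(recording$signal))
  names(df) <- recording$channel_labels
  write.table(df, paste0(basepath, ".data.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate_hz = recording$srate,
               channel_labels = recording$channel_labels,
               units = recording$units,
               subject = recording$subject,
               design_seed = if (!is.null(recording$design)) recording$design$seed else NULL,
               generator_seed = if (!is.null(recording$config)) recording$config$seed else NULL)
  jsonlite::write_json(meta, paste0(basepath, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(recording$annotations))
    write.table(recording$annotations, paste0(basepath, ".annotations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(basepath)
}

#' Read a recording from the TSV + JSON fixture format
#'
#' @param basepath Path without extension, as given to
#'   \code{\link{write_fixture}}.
#' @return A \code{raw_recording}.
#' @export
read_fixture <- function(basepath) {
  dpath <- paste0(basepath, ".data.tsv")
  jpath <- paste0(basepath, ".json")
  if (!file.exists(dpath)) stop(sprintf("file not found: %s", dpath))
  if (!file.exists(jpath)) stop(sprintf("file not found: %s", jpath))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  df <- read.table(dpath, header = TRUE, sep = "\t", check.names = FALSE)
  ann <- NULL
  apath <- paste0(basepath, ".annotations.tsv")
  if (file.exists(apath))
    ann <- read.table(apath, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  labels <- as.character(meta$channel_labels)
  raw_recording(t(as.matrix(df)), meta$sampling_rate_hz,
                channel_labels = labels,
                positions = montage_positions(labels),
                annotations = ann,
                subject = if (is.null(meta$subject)) NA_character_ else meta$subject)
}

#' Write an epoch set in the fixture format
#'
#' \code{<basepath>.data.tsv} holds the epochs stacked in time order
#' (samples x channels), \code{<basepath>.labels.tsv} one row per
#' epoch (labels + rejection flag), \code{<basepath>.json} the
#' metadata.
#'
#' @param epochs An \code{epoch_set}.
#' @param basepath Output path without extension.
#' @return \code{basepath}, invisibly.
#' @export
write_epoch_set <- function(epochs, basepath) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(0, nrow = d[1] * d[3], ncol = d[2])
  for (e in seq_len(d[1]))
    flat[((e - 1) * d[3] + 1):(e * d[3]), ] <- t(epochs$data[e, , ])
  df <- as.data.frame(flat)
  names(df) <- epochs$channel_labels
  write.table(df, paste0(basepath, ".data.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(rejection_report(epochs), paste0(basepath, ".labels.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate_hz = epochs$srate,
               epoch_length_s = epochs$epoch_length_s,
               n_epochs = d[1],
               channel_labels = epochs$channel_labels,
               subject = epochs$subject)
  jsonlite::write_json(meta, paste0(basepath, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(basepath)
}

#' Read an epoch set written by \code{\link{write_epoch_set}}
#'
#' @param basepath Path without extension.
#' @return An \code{epoch_set}.
#' @export
read_epoch_set <- function(basepath) {
  meta <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  df <- read.table(paste0(basepath, ".data.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  lab <- read.table(paste0(basepath, ".labels.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  L <- round(meta$epoch_length_s * meta$sampling_rate_hz)
  n_ep <- meta$n_epochs
  labels <- as.character(meta$channel_labels)
  data <- array(0, dim = c(n_ep, length(labels), L))
  m <- as.matrix(df)
  for (e in seq_len(n_ep))
    data[e, , ] <- t(m[((e - 1) * L + 1):(e * L), , drop = FALSE])
  es <- epoch_set(data, meta$sampling_rate_hz, meta$epoch_length_s,
                  lab[, setdiff(names(lab), "rejected"), drop = FALSE],
                  channel_labels = labels,
                  positions = montage_positions(labels),
                  subject = if (is.null(meta$subject)) NA_character_ else meta$subject)
  es$rejected <- as.logical(lab$rejected)
  es
}
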