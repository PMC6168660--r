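# Minimal EDF (European Data Format) writer/reader: 16-bit integer
# samples, one data record per second, fixed-width ASCII header.
# Annotations travel in a sidecar TSV (onset_s, duration_s, condition,
# repetition) next to the .edf file, written/read automatically.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' 16-bit EDF with one data record per second; a trailing partial
#' second of signal is dropped. Physical scaling is per channel from
#' the data range. Condition annotations, if present, are written to a
#' \code{<path>.annotations.tsv} sidecar.
#'
#' @param recording A \code{raw_recording}.
#' @param path Output file path (.edf).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  srate <- recording$srate
  if (srate != round(srate)) stop("EDF writer requires an integer sampling rate")
  sig <- recording$signal
  n_ch <- nrow(sig)
  n_rec <- ncol(sig) %/% srate
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  sig <- sig[, seq_len(n_rec * srate), drop = FALSE]

  pmin_ <- apply(sig, 1, min)
  pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)                       # version
  wr(ifelse(is.na(recording$subject), "X", recording$subject), 80)
  wr("lzdiversity synthetic/processed EEG", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (n_ch + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)                       # record duration, seconds
  wr(n_ch, 4)
  for (lb in recording$channel_labels) wr(lb, 16)
  for (i in seq_len(n_ch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.8g", v), 8)
  for (v in pmax_) wr(sprintf("%.8g", v), 8)
  for (i in seq_len(n_ch)) wr(dmin, 8)
  for (i in seq_len(n_ch)) wr(dmax, 8)
  for (i in seq_len(n_ch)) wr("HP:1Hz LP:100Hz N:45-55Hz", 80)
  for (i in seq_len(n_ch)) wr(srate, 8)
  for (i in seq_len(n_ch)) wr("", 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * srate + 1):(r * srate)
    for (ch in seq_len(n_ch)) {
      dig <- as.integer(pmax(pmin(round((sig[ch, cols] - pmin_[ch]) * scale[ch] + dmin),
                                  dmax), dmin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }

  if (!is.null(recording$annotations))
    write.table(recording$annotations,
                paste0(path, ".annotations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a 16-bit EDF file written by \code{\link{write_edf}} (or any
#' plain EDF with equal samples-per-record across channels), rescales
#' to physical units, and attaches annotations from the
#' \code{<path>.annotations.tsv} sidecar when present.
#'
#' @param path Path to the .edf file.
#' @return A \code{raw_recording}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0") stop(sprintf("parse error: unsupported EDF version field '%s'", ver))
  subject <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch < 1) stop("parse error: invalid channel count field")
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)
  units <- vapply(seq_len(n_ch), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  for (i in seq_len(n_ch)) rd(80)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("parse error: differing samples-per-record across channels not supported")
  if (any(units != "uV" & units != ""))
    stop(sprintf("unit error: expected uV, found '%s'", units[units != "uV"][1]))
  srate <- spr[1] / rec_dur

  sig <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2L,
                     endian = "little", signed = TRUE)
      cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
      sig[ch, cols] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }

  ann <- NULL
  side <- paste0(path, ".annotations.tsv")
  if (file.exists(side))
    ann <- read.table(side, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

  raw_recording(sig, srate, channel_labels = labels,
                positions = montage_positions(labels),
                annotations = ann,
                subject = if (subject == "X") NA_character_ else subject)
}
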