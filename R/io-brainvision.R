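# Minimal BrainVision triplet support: .vhdr (INI-style header),
# .vmrk (markers), .eeg (little-endian binary, multiplexed). Supports
# IEEE_FLOAT_32 and INT_16 binary formats. Condition annotations map
# to Stimulus markers with description "condition|repetition".

#' Write a recording as a BrainVision triplet
#'
#' @param recording A \code{raw_recording}.
#' @param basepath Path without extension; .vhdr/.vmrk/.eeg are
#'   created.
#' @param format Binary sample format.
#' @return The .vhdr path, invisibly.
#' @export
write_brainvision <- function(recording, basepath,
                              format = c("float32", "int16")) {
  stopifnot(inherits(recording, "raw_recording"))
  format <- match.arg(format)
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg <- paste0(basepath, ".eeg")
  base <- basename(basepath)
  n_ch <- nrow(recording$signal)
  res <- 0.1 # uV per int16 unit

  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", n_ch),
           paste0("SamplingInterval=", format(1e6 / recording$srate, scientific = FALSE)),
           "[Binary Infos]",
           paste0("BinaryFormat=",
                  if (format == "float32") "IEEE_FLOAT_32" else "INT_16"),
           "[Channel Infos]",
           sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch),
                   recording$channel_labels,
                   if (format == "int16") format(res) else "1"))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (!is.null(recording$annotations)) {
    a <- recording$annotations
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s|%d,%d,%d,0",
                        seq_len(nrow(a)) + 1L,
                        a$condition, a$repetition,
                        round(a$onset_s * recording$srate) + 1L,
                        round(a$duration_s * recording$srate)))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  mux <- as.numeric(recording$signal) # column-major = multiplexed
  if (format == "float32") {
    writeBin(mux, con, size = 4L, endian = "little")
  } else {
    dig <- as.integer(pmax(pmin(round(mux / res), 32767), -32768))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  sec <- ""
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) { sec <- gsub("\\[|\\]", "", ln); next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0) {
      key <- substr(ln, 1, eq - 1)
      kv[[paste(sec, key, sep = "/")]] <- substr(ln, eq + 1, nchar(ln))
    }
  }
  kv
}

#' Read a BrainVision triplet
#'
#' Resolves the data and marker files from the .vhdr header, reads the
#' multiplexed binary samples in the declared format (IEEE float32 or
#' int16 with per-channel resolution), and converts Stimulus markers
#' with "condition|repetition" descriptions back into an annotation
#' table.
#'
#' @param path Path to the .vhdr file.
#' @return A \code{raw_recording}.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  kv <- parse_vhdr_ini(readLines(path, warn = FALSE))
  get <- function(key) {
    v <- kv[[key]]
    if (is.null(v)) stop(sprintf("parse error: missing header field %s", key))
    v
  }
  datafile <- file.path(dirname(path), get("Common Infos/DataFile"))
  if (!file.exists(datafile))
    stop(sprintf("parse error: data file '%s' referenced by header is missing",
                 basename(datafile)))
  n_ch <- as.integer(get("Common Infos/NumberOfChannels"))
  srate <- 1e6 / as.numeric(get("Common Infos/SamplingInterval"))
  fmt <- get("Binary Infos/BinaryFormat")
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop(sprintf("parse error: unsupported BinaryFormat '%s'", fmt))
  orient <- kv[["Common Infos/DataOrientation"]]
  if (!is.null(orient) && orient != "MULTIPLEXED")
    stop(sprintf("parse error: unsupported DataOrientation '%s'", orient))

  labels <- character(n_ch)
  res <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- kv[[sprintf("Channel Infos/Ch%d", i)]]
    if (is.null(entry)) stop(sprintf("parse error: missing Channel Infos/Ch%d", i))
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }

  sz <- file.size(datafile)
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(con, numeric(), n = sz %/% 4, size = 4L, endian = "little")
  } else {
    vals <- readBin(con, integer(), n = sz %/% 2, size = 2L,
                    endian = "little", signed = TRUE)
  }
  n_samp <- length(vals) %/% n_ch
  sig <- matrix(vals[seq_len(n_samp * n_ch)], nrow = n_ch) # un-multiplex
  if (fmt == "INT_16") sig <- sig * res

  ann <- NULL
  mfile <- file.path(dirname(path), kv[["Common Infos/MarkerFile"]])
  if (!is.null(kv[["Common Infos/MarkerFile"]]) && file.exists(mfile)) {
    mlines <- readLines(mfile, warn = FALSE)
    stim <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
    if (length(stim)) {
      rows <- lapply(stim, function(ln) {
        body <- sub("^Mk[0-9]+=", "", ln)
        parts <- strsplit(body, ",", fixed = TRUE)[[1]]
        desc <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
        data.frame(onset_s = (as.numeric(parts[3]) - 1) / srate,
                   duration_s = as.numeric(parts[4]) / srate,
                   condition = desc[1],
                   repetition = if (length(desc) > 1) as.integer(desc[2]) else 1L,
                   stringsAsFactors = FALSE)
      })
      ann <- do.call(rbind, rows)
    }
  }

  raw_recording(sig, srate, channel_labels = labels,
                positions = montage_positions(labels),
                annotations = ann)
}
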