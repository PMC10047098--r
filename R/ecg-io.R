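# Readers and writers for the two on-disk dialects: PhysioNet-style WFDB
# header/signal pairs (format 16 only, as used by Apnea-ECG) and plain
# delimited text (one sample per line) with a "<minute> <N|A>" label sidecar.

parseWfdbHeader <- function(headerPath) {
  lines <- readLines(headerPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stopf("empty WFDB header: %s", headerPath)
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L)
    stopf("malformed WFDB record line in %s", headerPath)
  recName <- sub("/.*$", "", rec[1L])
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(sub("/.*$", "", rec[3L]))  # strip counter frequency
  nsamp <- if (length(rec) >= 4L) as.numeric(rec[4L]) else NA_real_
  if (is.na(nsig) || is.na(fs))
    stopf("malformed WFDB record line in %s", headerPath)
  if (length(lines) < 1L + nsig)
    stopf("WFDB header %s declares %d signals but lists fewer", headerPath, nsig)
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- sub("[x:+].*$", "", tok[2L])
    gainSpec <- if (length(tok) >= 3L) tok[3L] else "200"
    units <- sub("^[^/]*/?", "", gainSpec)
    gb <- sub("/.*$", "", gainSpec)
    baseline <- if (grepl("\\(", gb)) as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gb)) else NA_real_
    gain <- as.numeric(sub("\\(.*$", "", gb))
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    adczero <- if (length(tok) >= 5L) as.numeric(tok[5L]) else 0
    if (is.na(baseline)) baseline <- adczero
    list(file = tok[1L], format = fmt, gain = gain, baseline = baseline,
         units = if (nzchar(units)) units else "mV")
  })
  list(record = recName, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a WFDB record (format 16) into an EcgRecord
#'
#' Parses the `.hea` header, reads the companion 16-bit little-endian signal
#' file, and scales ADC units to physical mV as `(adu - baseline) / gain`.
#' Only the plain format-16 single- or multi-channel layout used by the
#' Apnea-ECG database is supported; other storage formats are rejected.
#'
#' @param headerPath Path to the `.hea` header file.
#' @param channel 1-based channel to extract when the record is
#'   multi-channel. Required in that case.
#' @param annotationPath Optional path to a minute-label sidecar file (see
#'   [readMinuteAnnotations()]); labels for all complete minutes are attached.
#' @return An [EcgRecord-class].
#' @export
readWfdbRecord <- function(headerPath, channel = NULL, annotationPath = NULL) {
  if (!file.exists(headerPath)) stopf("header file not found: %s", headerPath)
  hdr <- parseWfdbHeader(headerPath)
  if (hdr$nsig > 1L && is.null(channel))
    stopf("record '%s' has %d channels; pass `channel` to select one",
          hdr$record, hdr$nsig)
  channel <- if (is.null(channel)) 1L else as.integer(channel)
  if (channel < 1L || channel > hdr$nsig)
    stopf("channel %d out of range 1..%d", channel, hdr$nsig)
  fmts <- unique(vapply(hdr$signals, `[[`, "", "format"))
  if (!identical(fmts, "16"))
    stopf("unsupported WFDB storage format(s) %s (only format 16 is supported)",
          paste(fmts, collapse = ","))
  datFiles <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(datFiles) != 1L)
    stopf("multi-file WFDB records are not supported")
  datPath <- file.path(dirname(headerPath), datFiles)
  if (!file.exists(datPath))
    stopf("companion signal file not found: %s", datPath)
  raw <- readBin(datPath, "integer", n = file.size(datPath) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
  nPerSig <- length(raw) %/% hdr$nsig
  if (!is.na(hdr$nsamp) && nPerSig < hdr$nsamp)
    stopf("signal file %s holds %d samples/channel but header declares %g",
          datPath, nPerSig, hdr$nsamp)
  if (!is.na(hdr$nsamp)) nPerSig <- hdr$nsamp
  adu <- raw[seq.int(channel, by = hdr$nsig, length.out = nPerSig)]
  sig <- hdr$signals[[channel]]
  phys <- (adu - sig$baseline) / sig$gain
  labels <- character(0)
  if (!is.null(annotationPath)) {
    nmin <- floor(nPerSig / (60 * hdr$fs))
    labels <- readMinuteAnnotations(annotationPath, nmin)
  }
  EcgRecord(phys, fs = hdr$fs, labels = labels, recordId = hdr$record)
}

#' Write an EcgRecord as a WFDB format-16 header/signal pair
#'
#' Minimal writer used to produce fixtures and round-trip tests: samples are
#' quantised at the given ADC gain to 16-bit integers. Quantisation error is
#' at most `1/(2*gain)` mV (one part in 2^15 of the representable range).
#'
#' @param record An [EcgRecord-class].
#' @param basePath Output path without extension; `.hea` and `.dat` are
#'   written next to each other.
#' @param gain ADC units per mV.
#' @return `basePath`, invisibly.
#' @export
writeWfdbRecord <- function(record, basePath, gain = 200) {
  x <- ecgSamples(record)
  adu <- as.integer(round(x * gain))
  if (any(abs(adu) > 32767L))
    stopf("samples exceed the 16-bit ADC range at gain %g", gain)
  datName <- paste0(basename(basePath), ".dat")
  hea <- c(sprintf("%s 1 %g %d", recordId(record), samplingRate(record),
                   length(x)),
           sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 ECG", datName, gain,
                   if (length(adu)) adu[1L] else 0L))
  writeLines(hea, paste0(basePath, ".hea"))
  writeBin(adu, paste0(basePath, ".dat"), size = 2L, endian = "little")
  invisible(basePath)
}

#' Read per-minute apnea annotations
#'
#' Reads a label sidecar with one `"<minute> <N|A>"` pair per line (0-based
#' minutes). Minutes absent from the file are returned as `unlabeled` with a
#' warning, as are labels outside the `N`/`A` alphabet.
#'
#' @param path Path to the annotation text file.
#' @param nMinutes Number of minutes the record holds.
#' @return Factor of length `nMinutes` over `normal`/`apnea`/`unlabeled`.
#' @export
readMinuteAnnotations <- function(path, nMinutes) {
  if (nMinutes < 0L) stopf("nMinutes must be >= 0")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labels <- rep("unlabeled", nMinutes)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    minute <- suppressWarnings(as.integer(tok[1L]))
    if (length(tok) != 2L || is.na(minute))
      stopf("malformed annotation at line %d of %s: '%s'", i, path, lines[i])
    if (minute < 0L || minute >= nMinutes) {
      warnf("annotation line %d refers to minute %d outside 0..%d; ignored",
            i, minute, nMinutes - 1L)
      next
    }
    labels[minute + 1L] <- switch(tok[2L], N = "normal", A = "apnea", {
      warnf("unknown label '%s' at line %d of %s; minute left unlabeled",
            tok[2L], i, path)
      "unlabeled"
    })
  }
  n.unlab <- sum(labels == "unlabeled")
  if (n.unlab > 0L)
    warnf("%d of %d minutes have no N/A annotation and are unlabeled",
          n.unlab, nMinutes)
  asMinuteLabels(labels)
}

#' Write per-minute annotations
#'
#' Inverse of [readMinuteAnnotations()]: writes one `"<minute> <N|A>"` line
#' per labelled minute; unlabeled minutes are omitted.
#'
#' @param labels Factor or character vector of per-minute labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMinuteAnnotations <- function(labels, path) {
  labels <- asMinuteLabels(labels)
  keep <- which(labels %in% c("normal", "apnea"))
  writeLines(sprintf("%d %s", keep - 1L,
                     ifelse(labels[keep] == "apnea", "A", "N")), path)
  invisible(path)
}

#' Read a delimited-text signal (one sample per line)
#'
#' @param path Path to the text file.
#' @param fs Sampling frequency in Hz of the stored samples.
#' @param recordId Identifier for the resulting record.
#' @param annotationPath Optional minute-label sidecar.
#' @return An [EcgRecord-class]. Trailing blank lines are tolerated;
#'   non-numeric tokens raise a parse error naming the line.
#' @export
readDelimitedSignal <- function(path, fs, recordId = NULL,
                                annotationPath = NULL) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x))
    stopf("non-numeric sample at line %d of %s: '%s'",
          which(is.na(x))[1L], path, lines[which(is.na(x))[1L]])
  if (is.null(recordId))
    recordId <- sub("\\.[^.]*$", "", basename(path))
  labels <- character(0)
  if (!is.null(annotationPath))
    labels <- readMinuteAnnotations(annotationPath, floor(length(x) / (60 * fs)))
  EcgRecord(x, fs = fs, labels = labels, recordId = recordId)
}

#' Write a signal as delimited text
#'
#' One sample per line at 9 significant decimal digits, which round-trips
#' exactly through [readDelimitedSignal()] at that precision.
#'
#' @param record An [EcgRecord-class].
#' @param path Output path.
#' @param annotationPath Optional path for the label sidecar; written only
#'   when the record carries labels.
#' @return `path`, invisibly.
#' @export
writeDelimitedSignal <- function(record, path, annotationPath = NULL) {
  writeLines(formatC(ecgSamples(record), digits = 9, format = "g"), path)
  if (!is.null(annotationPath) && length(minuteLabels(record)))
    writeMinuteAnnotations(minuteLabels(record), annotationPath)
  invisible(path)
}
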