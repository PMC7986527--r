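## BrainVision triplet I/O (.vhdr / .vmrk / .eeg).
##
## Data file: IEEE float32, little-endian, MULTIPLEXED (all channels of
## sample 1, then sample 2, ...). Marker positions in .vmrk are 1-based
## data points; the package API is 0-based, converted on read/write.
## Round trips are lossless to float32 precision for signals and exact
## for markers.

#' Write a session to a BrainVision triplet
#'
#' @param rec A [Recording-class].
#' @param events An [EventList-class] (may have zero trials).
#' @param basePath Path without extension; `.vhdr`, `.vmrk` and `.eeg`
#'   files are written next to each other.
#' @param unit Signal unit string recorded in the header (informational).
#' @return `basePath.vhdr`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, events, basePath, unit = "µV") {
  vhdr <- paste0(basePath, ".vhdr")
  vmrk <- paste0(basePath, ".vmrk")
  dat <- paste0(basePath, ".eeg")
  base <- basename(basePath)

  labs <- channelLabels(rec)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nChannels(rec)),
    paste0("SamplingInterval=", format(1e6 / samplingRate(rec), digits = 15)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,%s", seq_along(labs), labs, unit)
  )
  writeLines(hdr, vhdr)

  starts <- trialStarts(events)
  presses <- pedalPresses(events)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (length(starts)) {
    pos <- as.vector(rbind(starts, presses)) + 1L  # 1-based data points
    desc <- rep(c("trial_start", "pedal_press"), length(starts))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_along(pos) + 1L, desc, pos))
  }
  writeLines(mk, vmrk)

  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.vector(signalData(rec)), con, size = 4, endian = "little")
  invisible(vhdr)
}

parseVhdrSection <- function(lines, section) {
  hits <- grep(paste0("^\\[", section, "\\]"), lines)
  if (!length(hits)) return(character())
  from <- hits[1] + 1L
  rest <- lines[from:length(lines)]
  stopAt <- grep("^\\[", rest)
  if (length(stopAt)) rest <- rest[seq_len(stopAt[1] - 1L)]
  rest[nzchar(rest) & !startsWith(rest, ";")]
}

parseKeyVals <- function(entries) {
  kv <- regmatches(entries, regexpr("=", entries), invert = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Read a session from a BrainVision triplet
#'
#' Parses the header, binary data file and marker file, pairs the
#' `trial_start` / `pedal_press` stimulus markers into trials, and returns
#' the signal with 0-based event sample indices.
#'
#' @param path Path to the `.vhdr` file (or the base path without
#'   extension).
#' @param kind `"eeg"` or `"accel"`; EEG is re-referenced to the common
#'   average on load, accelerometer data are returned untouched.
#' @return A list with elements `recording` ([Recording-class]) and
#'   `events` ([EventList-class]).
#' @export
readRecording <- function(path, kind = c("eeg", "accel")) {
  kind <- match.arg(kind)
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  if (!file.exists(path)) stop("cannot read header file: ", path)
  lines <- readLines(path, warn = FALSE)
  common <- parseKeyVals(parseVhdrSection(lines, "Common Infos"))
  binInfo <- parseKeyVals(parseVhdrSection(lines, "Binary Infos"))
  if (!identical(unname(common["DataFormat"]), "BINARY") ||
      !identical(unname(binInfo["BinaryFormat"]), "IEEE_FLOAT_32") ||
      !identical(unname(common["DataOrientation"]), "MULTIPLEXED"))
    stop("unsupported BrainVision variant (need BINARY/IEEE_FLOAT_32/MULTIPLEXED)")
  nch <- as.integer(common["NumberOfChannels"])
  fs <- 1e6 / as.numeric(common["SamplingInterval"])
  chEntries <- parseKeyVals(parseVhdrSection(lines, "Channel Infos"))
  labels <- vapply(strsplit(unname(chEntries), ",", fixed = TRUE), `[`, "", 1L)

  dir <- dirname(path)
  datPath <- file.path(dir, common["DataFile"])
  nBytes <- file.info(datPath)$size
  con <- file(datPath, "rb")
  raw <- readBin(con, "numeric", n = nBytes / 4, size = 4, endian = "little")
  close(con)
  if (length(raw) %% nch != 0)
    stop("data file length is not a multiple of the channel count")
  mat <- matrix(raw, nrow = nch)
  rec <- Recording(mat, fs, labels)
  if (kind == "eeg") rec <- commonAverageReference(rec)

  mrkPath <- file.path(dir, common["MarkerFile"])
  mlines <- readLines(mrkPath, warn = FALSE)
  entries <- parseVhdrSection(mlines, "Marker Infos")
  fields <- strsplit(sub("^Mk[0-9]+=", "", entries), ",")
  desc <- vapply(fields, `[`, "", 2L)
  pos <- as.integer(vapply(fields, `[`, "", 3L)) - 1L  # to 0-based
  keep <- desc %in% c("trial_start", "pedal_press")
  desc <- desc[keep]; pos <- pos[keep]
  if (!length(desc)) stop("no trial_start/pedal_press markers found in ", mrkPath)
  ord <- order(pos)
  desc <- desc[ord]; pos <- pos[ord]
  expected <- rep(c("trial_start", "pedal_press"), length.out = length(desc))
  if (length(desc) %% 2L != 0L || !all(desc == expected))
    stop("mismatched marker pairing: expected alternating trial_start/pedal_press")
  events <- EventList(pos[c(TRUE, FALSE)], pos[c(FALSE, TRUE)])
  list(recording = rec, events = events)
}
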