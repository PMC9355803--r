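# Readers and writers for the formats the pipeline touches: WAV audio,
# EEG (BrainVision triplet or flat binary with JSON-style sidecar), pitch
# tracks, word alignments (CSV or Praat TextGrid), feature tables and
# score tables. All CSV outputs carry a provenance header comment.

.provenanceHeader <- function(extra = NULL) {
  paste0("# speechFFR ", as.character(packageVersion("speechFFR")),
         if (!is.null(extra)) paste0(" | ", extra) else "")
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16-bit PCM and 32/64-bit IEEE
#' float, mono or multichannel (channels averaged to mono on request).
#'
#' @param path file path.
#' @param toMono average channels to a single waveform (default TRUE).
#' @return numeric waveform in `[-1, 1]` with attribute `"fs"`.
#' @export
readWave <- function(path, toMono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        nChannels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt$audioFormat == 1 && fmt$bits == 16) {
        dat <- readBin(con, "integer", sz / 2, 2, endian = "little") / 32768
      } else if (fmt$audioFormat == 3 && fmt$bits %in% c(32, 64)) {
        dat <- readBin(con, "double", sz / (fmt$bits / 8), fmt$bits / 8,
                       endian = "little")
      } else stop("unsupported WAV encoding (format ", fmt$audioFormat,
                  ", ", fmt$bits, " bits)")
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(dat)) stop("no data chunk found in ", path)
  if (fmt$nChannels > 1) {
    m <- matrix(dat, ncol = fmt$nChannels, byrow = TRUE)
    dat <- if (toMono) rowMeans(m) else m
  }
  structure(dat, fs = fmt$fs)
}

#' Write a WAV file
#'
#' @param x waveform (values clipped to `[-1, 1]` for PCM16).
#' @param path output path.
#' @param fs sampling rate (Hz).
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return invisibly, the path.
#' @export
writeWave <- function(x, path, fs, bits = 16) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes <- bits / 8
  dataSize <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmtCode <- if (bits == 16) 1L else 3L
  writeBin(fmtCode, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}

# --- EEG --------------------------------------------------------------------

#' Write an EEG recording
#'
#' Two containers: BrainVision (`.vhdr` text header + `.vmrk` marker file
#' + `.eeg` IEEE float-32 multiplexed binary) or the package's flat
#' float-64 binary with a text sidecar (`.dat` + `.json`). Lossless up to
#' the float precision of the container.
#'
#' @param rec an [EEGRecording-class].
#' @param path base path; the appropriate extensions are appended.
#' @param format `"brainvision"` or `"flat"`.
#' @return invisibly, the header path.
#' @export
writeEEG <- function(rec, path, format = c("brainvision", "flat")) {
  format <- match.arg(format)
  stopifnot(is(rec, "EEGRecording"))
  base <- sub("\\.(vhdr|dat|eeg|json)$", "", path)
  if (format == "brainvision") {
    dataFile <- paste0(basename(base), ".eeg")
    hdr <- c(
      "Brain Vision Data Exchange Header File Version 1.0",
      "[Common Infos]",
      paste0("DataFile=", dataFile),
      paste0("MarkerFile=", basename(base), ".vmrk"),
      "DataFormat=BINARY",
      "DataOrientation=MULTIPLEXED",
      paste0("NumberOfChannels=", ncol(rec@data)),
      paste0("SamplingInterval=", format(1e6 / rec@fs, scientific = FALSE)),
      "[Binary Infos]",
      "BinaryFormat=IEEE_FLOAT_32",
      "[Channel Infos]",
      sprintf("Ch%d=%s,,1,µV", seq_len(ncol(rec@data)), rec@channels))
    writeLines(hdr, paste0(base, ".vhdr"))
    writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
                 "[Common Infos]", paste0("DataFile=", dataFile)),
               paste0(base, ".vmrk"))
    con <- file(paste0(base, ".eeg"), "wb")
    writeBin(as.numeric(t(rec@data)), con, size = 4, endian = "little")
    close(con)
    invisible(paste0(base, ".vhdr"))
  } else {
    con <- file(paste0(base, ".dat"), "wb")
    writeBin(as.numeric(rec@data), con, size = 8, endian = "little")
    close(con)
    meta <- sprintf(
      '{"fs": %g, "nChannels": %d, "nSamples": %d, "reference": "%s", "channels": [%s], "order": "column-major"}',
      rec@fs, ncol(rec@data), nrow(rec@data), rec@reference,
      paste(sprintf('"%s"', rec@channels), collapse = ", "))
    writeLines(meta, paste0(base, ".json"))
    invisible(paste0(base, ".dat"))
  }
}

# tiny flat JSON parser for the sidecar (scalars and string arrays)
.readSidecar <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  get1 <- function(key) {
    m <- regmatches(txt, regexpr(paste0('"', key, '":\\s*[^,}\\[]+'), txt))
    if (!length(m)) return(NULL)
    gsub('^.*:\\s*|"', "", m)
  }
  arr <- regmatches(txt, regexpr('"channels":\\s*\\[[^]]*\\]', txt))
  channels <- if (length(arr))
    gsub('"', "", strsplit(gsub("^.*\\[|\\]", "", arr), ",\\s*")[[1]])
  list(fs = as.numeric(get1("fs")),
       nChannels = as.integer(get1("nChannels")),
       nSamples = as.integer(get1("nSamples")),
       reference = get1("reference"), channels = channels)
}

#' Read an EEG recording
#'
#' Accepts a BrainVision `.vhdr` header (with its binary IEEE float data
#' file) or the package's flat `.dat` + `.json` sidecar.
#'
#' @param path path to the `.vhdr` or `.dat` file.
#' @param expectedFs if given, error when the container rate differs.
#' @return an [EEGRecording-class].
#' @export
readEEG <- function(path, expectedFs = NULL) {
  if (grepl("\\.vhdr$", path)) {
    lines <- readLines(path, warn = FALSE)
    getVal <- function(key) {
      m <- grep(paste0("^", key, "="), lines, value = TRUE)
      if (!length(m)) stop("BrainVision header missing ", key)
      sub(paste0("^", key, "="), "", m[1])
    }
    if (!identical(getVal("DataFormat"), "BINARY") ||
        !identical(getVal("DataOrientation"), "MULTIPLEXED") ||
        !identical(getVal("BinaryFormat"), "IEEE_FLOAT_32"))
      stop("only BINARY/MULTIPLEXED/IEEE_FLOAT_32 BrainVision files are supported")
    nCh <- as.integer(getVal("NumberOfChannels"))
    fs <- 1e6 / as.numeric(getVal("SamplingInterval"))
    chLines <- grep("^Ch[0-9]+=", lines, value = TRUE)
    channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chLines), ","),
                       `[`, "", 1)
    if (length(channels) != nCh)
      stop("channel label count (", length(channels),
           ") does not match NumberOfChannels (", nCh, ")")
    dataFile <- file.path(dirname(path), getVal("DataFile"))
    sz <- file.size(dataFile)
    con <- file(dataFile, "rb")
    raw <- readBin(con, "double", sz / 4, size = 4, endian = "little")
    close(con)
    M <- matrix(raw, ncol = nCh, byrow = TRUE)
  } else if (grepl("\\.dat$", path)) {
    meta <- .readSidecar(sub("\\.dat$", ".json", path))
    con <- file(path, "rb")
    raw <- readBin(con, "double", meta$nSamples * meta$nChannels, size = 8,
                   endian = "little")
    close(con)
    M <- matrix(raw, ncol = meta$nChannels)
    fs <- meta$fs
    channels <- meta$channels
    if (length(channels) != meta$nChannels)
      stop("channel label count does not match nChannels in sidecar")
    rec <- eegRecording(M, fs, channels, meta$reference)
    if (!is.null(expectedFs) && fs != expectedFs)
      stop("sampling rate ", fs, " does not match expected ", expectedFs)
    return(rec)
  } else {
    stop("unknown EEG format for ", path,
         "; supported: BrainVision (.vhdr) and flat binary (.dat + .json)")
  }
  if (!is.null(expectedFs) && fs != expectedFs)
    stop("sampling rate ", fs, " does not match expected ", expectedFs)
  eegRecording(M, fs, channels, "as-recorded")
}

# --- text tables ------------------------------------------------------------

#' Read/write a pitch track as CSV
#'
#' Columns `time_s,f0_hz`; empty f0 marks unvoiced frames.
#'
#' @param path CSV path.
#' @return [readPitchTrack()]: a [PitchTrack-class].
#' @export
readPitchTrack <- function(path) {
  d <- read.csv(path, comment.char = "#")
  pitchTrack(d$time_s, d$f0_hz)
}

#' @rdname readPitchTrack
#' @param pitch a [PitchTrack-class] to write.
#' @export
writePitchTrack <- function(pitch, path) {
  lines <- c(.provenanceHeader(), "time_s,f0_hz",
             sprintf("%.6f,%s", pitch@times,
                     ifelse(is.na(pitch@f0), "", sprintf("%.3f", pitch@f0))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a word alignment
#'
#' CSV with columns `word,onset_s,offset_s`, or a Praat TextGrid with an
#' interval tier of words (empty labels are gaps).
#'
#' @param path file path.
#' @param tier TextGrid tier name holding the words (default the first
#'   interval tier).
#' @return data.frame (word, onset, offset).
#' @export
readAlignment <- function(path, tier = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- read.csv(path, comment.char = "#")
    return(data.frame(word = d$word, onset = d$onset_s, offset = d$offset_s))
  }
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(sub(".*=\\s*", "", s))
  str <- function(s) gsub('.*=\\s*"|"\\s*$', "", s)
  tierStarts <- grep("item \\[[0-9]+\\]", lines)
  if (!length(tierStarts)) stop("no tiers found in TextGrid ", path)
  tierStarts <- c(tierStarts, length(lines) + 1)
  for (ti in seq_len(length(tierStarts) - 1)) {
    block <- lines[tierStarts[ti]:(tierStarts[ti + 1] - 1)]
    cls <- str(grep("class", block, value = TRUE)[1])
    nm <- str(grep("name", block, value = TRUE)[1])
    if (cls != "IntervalTier") next
    if (!is.null(tier) && nm != tier) next
    xmin <- num(grep("xmin", block, value = TRUE))
    xmax <- num(grep("xmax", block, value = TRUE))
    text <- str(grep("text", block, value = TRUE))
    # first xmin/xmax describe the tier itself
    d <- data.frame(word = text, onset = xmin[-1][seq_along(text)],
                    offset = xmax[-1][seq_along(text)])
    d <- d[nzchar(trimws(d$word)), , drop = FALSE]
    rownames(d) <- NULL
    return(d)
  }
  stop("no matching interval tier in TextGrid ", path)
}

#' Write a word alignment as CSV
#'
#' @param words data.frame with `word`, `onset`, `offset` columns.
#' @param path output path.
#' @export
writeAlignment <- function(words, path) {
  lines <- c(.provenanceHeader(), "word,onset_s,offset_s",
             sprintf("%s,%.6f,%.6f", words$word, words$onset, words$offset))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tidy table with a provenance header comment
#'
#' Used for feature tables, score matrices and regression tables. The
#' first line is a `#` comment carrying the package version and an
#' optional configuration hash so outputs are traceable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param configHash optional string identifying the generating config.
#' @export
writeTableWithProvenance <- function(df, path, configHash = NULL) {
  con <- file(path, "w")
  writeLines(.provenanceHeader(
    if (!is.null(configHash)) paste0("config ", configHash)), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read/write stimulus features as CSV
#'
#' Header comment declares the sampling rate; columns `f1,f2`.
#'
#' @param path CSV path.
#' @return [readStimulusFeatures()]: a [StimulusFeatures-class].
#' @export
readStimulusFeatures <- function(path) {
  first <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=", "", first))
  d <- read.csv(path, comment.char = "#")
  stimulusFeatures(d$f1, d$f2, fs)
}

#' @rdname readStimulusFeatures
#' @param features a [StimulusFeatures-class] to write.
#' @export
writeStimulusFeatures <- function(features, path) {
  con <- file(path, "w")
  writeLines(paste0(.provenanceHeader(), " fs=", features@fs), con)
  write.csv(data.frame(f1 = features@f1, f2 = features@f2), con,
            row.names = FALSE)
  close(con)
  invisible(path)
}

#' Export a regression table in the printed-table layout
#'
#' Columns Feature, Coeff., SE, 95% CI, z, p (FDR).
#'
#' @param tab output of [stepwiseHierarchical()].
#' @param path output path.
#' @param configHash optional provenance string.
#' @export
writeRegressionTable <- function(tab, path, configHash = NULL) {
  out <- data.frame(
    Feature = tab$feature,
    Coeff. = round(tab$coeff, 3),
    SE = round(tab$se, 3),
    `95% CI` = sprintf("(%.3f;%.3f)", tab$ciLo, tab$ciHi),
    z = round(tab$z, 3),
    `p (FDR)` = signif(tab$pFdr, 2),
    check.names = FALSE)
  writeTableWithProvenance(out, path, configHash)
}
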