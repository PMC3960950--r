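# Minimal RIFF WAV I/O (mono PCM16 / float32) and annotation-table reading.
# No WAV reader ships with the supported dependency set, so the chunk
# parsing is done directly with readBin.

#' Read a mono WAV file
#'
#' Supports uncompressed RIFF/WAVE with 16-bit PCM or 32-bit IEEE float
#' samples, single channel. PCM samples are scaled to [-1, 1).
#'
#' @param path file path.
#' @return list with \code{samples} (numeric) and \code{sampleRate}.
#' @export
readWaveFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop(path, ": not a RIFF file")
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop(path, ": not a WAVE file")
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop(path, ": data chunk before fmt chunk")
      if (fmt$channels != 1L) stop(path, ": only mono WAV is supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", size %/% 2L, 2L, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size %/% 4L, 4L, endian = "little")
      } else {
        stop(path, ": unsupported sample format (need PCM16 or float32)")
      }
      break
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (padded)
    }
  }
  if (is.null(samples)) stop(path, ": no data chunk found")
  list(samples = samples, sampleRate = fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in [-1, 1]; values outside are clipped.
#' @param sampleRate sampling rate in Hz.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeWaveFile <- function(samples, sampleRate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")            # PCM, mono
  writeBin(as.integer(sampleRate), con, 4L, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")           # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Read a release-annotation table
#'
#' Tab-separated with header columns \code{file}, \code{syllable_id},
#' \code{realization_index}, \code{release_time_seconds}.
#'
#' @param path annotation file path.
#' @return data.frame.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("file", "syllable_id", "realization_index", "release_time_seconds")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop(path, ": missing annotation column(s): ", paste(miss, collapse = ", "))
  ann
}

#' Load an annotated WAV corpus
#'
#' Reads every annotated WAV and attaches its release position (converted
#' from seconds to a 1-based sample index).
#'
#' @param wavDir directory containing the WAV files named in the annotation
#'   table.
#' @param annotationFile path of the annotation table
#'   (see [readAnnotations()]).
#' @return list of [speechRecord()] objects.
#' @export
readSpeechCorpus <- function(wavDir, annotationFile) {
  ann <- readAnnotations(annotationFile)
  lapply(seq_len(nrow(ann)), function(i) {
    p <- file.path(wavDir, ann$file[i])
    if (!file.exists(p)) stop("annotated WAV not found: ", p)
    w <- readWaveFile(p)
    speechRecord(w$samples, w$sampleRate,
                 release = max(1L, 1L + round(ann$release_time_seconds[i] *
                                                w$sampleRate)),
                 syllableId = ann$syllable_id[i],
                 realization = ann$realization_index[i])
  })
}
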