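# Auditory preprocessing: annotated syllable waveforms to 24-Bark x time
# unit-interval neural representations.
#
# Pipeline (per corpus): first-order derivative (6 dB/oct high-pass against
# F0 interference) -> release-aligned zero-padding to the corpus maxima ->
# per-signal amplitude normalization -> short-time magnitude spectrum
# (256-sample Hamming frames, hop 45, zero-padded to a 2048-point FFT) ->
# dB conversion re 2e-5 clipped to [60, 100] -> per-signal normalization ->
# Bark-band / 10-frame pooling -> final per-signal normalization.

# Zwicker critical-band edges in Hz; 24 bands spanning 0 - 15.5 kHz.
.barkEdges <- c(0, 100, 200, 300, 400, 510, 630, 770, 920, 1080, 1270, 1480,
                1720, 2000, 2320, 2700, 3150, 3700, 4400, 5300, 6400, 7700,
                9500, 12000, 15500)

#' A speech record
#'
#' Lightweight container (a plain list) for one annotated syllable
#' recording: samples, sample rate, 1-based release-of-obstruction sample
#' index, syllable label and realization index.
#'
#' @param samples numeric vector.
#' @param sampleRate sampling rate in Hz (the recordings this pipeline
#'   targets use 44100).
#' @param release 1-based sample index of the obstruction release.
#' @param syllableId,realization labels.
#' @return list of class "SpeechRecord".
#' @export
speechRecord <- function(samples, sampleRate = 44100, release = 1L,
                         syllableId = "", realization = 1L) {
  release <- as.integer(release)
  if (release < 1L || release > length(samples))
    stop("release index must fall inside the signal")
  structure(list(samples = as.numeric(samples), sampleRate = sampleRate,
                 release = release, syllableId = syllableId,
                 realization = as.integer(realization)),
            class = "SpeechRecord")
}

#' First-order derivative filter
#'
#' Replaces sample i by \code{s[i] - s[i-1]}, shortening the signal by one
#' sample and shifting the release index accordingly. Acts as a 6 dB/oct
#' high-pass, suppressing the fundamental-frequency region.
#'
#' @param record a [speechRecord()].
#' @return the filtered SpeechRecord.
#' @export
derivativeFilter <- function(record) {
  if (length(record$samples) < 2L) stop("signal too short to differentiate")
  record$samples <- diff(record$samples)
  record$release <- max(1L, record$release - 1L)
  record
}

#' Release-aligned zero padding
#'
#' Aligns all records on their release positions and pads with zeros: the
#' pre-release span of each record is front-padded to the corpus maximum
#' pre-release duration and the post-release span is back-padded to the
#' maximum post-release duration, so that every output has equal length and
#' the same release index. Comparable representations therefore exist only
#' within one corpus (the maxima are corpus-global).
#'
#' @param records list of [speechRecord()] objects.
#' @return list of SpeechRecords of equal length.
#' @export
alignAndPad <- function(records) {
  if (!length(records)) stop("no records to align")
  pre <- vapply(records, function(r) r$release - 1L, integer(1))
  post <- vapply(records, function(r) length(r$samples) - r$release + 1L,
                 integer(1))
  maxPre <- max(pre); maxPost <- max(post)
  lapply(records, function(r) {
    r$samples <- c(numeric(maxPre - (r$release - 1L)), r$samples,
                   numeric(maxPost - (length(r$samples) - r$release + 1L)))
    r$release <- maxPre + 1L
    r
  })
}

#' Short-time magnitude spectrum
#'
#' Frames of 256 samples, Hamming-windowed, taken every 45 samples (window
#' about 5.8 ms, hop about 1 ms at 44.1 kHz), each zero-padded to a
#' 2048-point FFT; the magnitudes of the DC and positive-frequency bins are
#' retained. Frame count is \code{floor((L - 256) / 45) + 1}.
#'
#' @param record a [speechRecord()] (or plain numeric vector).
#' @param windowLength,hop,nfft framing parameters; defaults 256 / 45 /
#'   2048.
#' @return numeric magnitude matrix, (nfft/2 + 1) x frames.
#' @export
spectrogramFrames <- function(record, windowLength = 256L, hop = 45L,
                              nfft = 2048L) {
  x <- if (inherits(record, "SpeechRecord")) record$samples else as.numeric(record)
  if (length(x) < windowLength)
    stop("signal shorter than one analysis window (", windowLength, " samples)")
  nFrames <- (length(x) - windowLength) %/% hop + 1L
  win <- as.numeric(signal::hamming(windowLength))
  frames <- matrix(0, nrow = nfft, ncol = nFrames)
  for (f in seq_len(nFrames)) {
    i0 <- (f - 1L) * hop
    frames[seq_len(windowLength), f] <- x[i0 + seq_len(windowLength)] * win
  }
  abs(stats::mvfft(frames))[seq_len(nfft / 2L + 1L), , drop = FALSE]
}

#' Convert magnitudes to clipped dB
#'
#' \code{20 * log10(v / 2e-5)}, clipped to the [60, 100] dB window; zero
#' amplitudes map to the lower bound. The 2e-5 reference is the standard
#' threshold-of-hearing amplitude.
#'
#' @param magnitudes non-negative numeric matrix (or vector).
#' @param lower,upper clip boundaries in dB, defaults 60 and 100.
#' @return matrix of the same shape, values in [lower, upper].
#' @export
toDecibel <- function(magnitudes, lower = 60, upper = 100) {
  db <- 20 * log10(magnitudes / 2e-5)
  db[!is.finite(db)] <- lower
  pmin(pmax(db, lower), upper)
}

#' Bark-band and time pooling
#'
#' Groups FFT bins into the 24 Zwicker critical bands (edges 0, 100, ...,
#' 15500 Hz; bins at or above 15.5 kHz are discarded) and averages the
#' member bins of each band; along time, consecutive groups of
#' \code{timePool} frames are averaged (the final partial group over its
#' actual size).
#'
#' @param dbMatrix numeric matrix, (nfft/2 + 1) x frames (bin rows ordered
#'   from DC upward).
#' @param sampleRate sampling rate in Hz.
#' @param nfft FFT length the bins came from (default 2048).
#' @param timePool frames per pooled time step (default 10).
#' @return numeric matrix, 24 x ceiling(frames / timePool).
#' @export
barkTimePool <- function(dbMatrix, sampleRate = 44100, nfft = 2048L,
                         timePool = 10L) {
  freqs <- (seq_len(nrow(dbMatrix)) - 1L) * sampleRate / nfft
  band <- findInterval(freqs, .barkEdges)
  keep <- band >= 1L & band <= 24L & freqs < max(.barkEdges)
  if (length(unique(band[keep])) < 24L)
    stop("internal error: empty Bark band at sample rate ", sampleRate)
  pooledF <- rowsum(dbMatrix[keep, , drop = FALSE], band[keep]) /
    as.vector(table(band[keep]))
  nT <- ncol(pooledF)
  grp <- (seq_len(nT) - 1L) %/% timePool + 1L
  pooledT <- t(rowsum(t(pooledF), grp) / as.vector(table(grp)))
  dimnames(pooledT) <- NULL
  pooledT
}

#' Local linear normalization to [0, 1]
#'
#' \code{(v - min) / (max - min)} elementwise; a constant input maps to all
#' zeros (silence semantics).
#'
#' @param m numeric matrix or vector.
#' @return same shape, values in [0, 1].
#' @export
normalizeLocal <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Full waveform-to-neural-representation pipeline
#'
#' Runs the complete preprocessing over a corpus of annotated records and
#' returns one 24 x T unit-interval activation matrix per record, with T
#' determined by the corpus' release-aligned padded length (57 for a corpus
#' whose padded signals span about 25,880 samples at 44.1 kHz).
#'
#' @param records list of [speechRecord()] objects (the whole corpus: the
#'   padding maxima are corpus-global).
#' @return list of 24 x T matrices, named by "syllableId.realization".
#' @export
wavToNeural <- function(records) {
  recs <- alignAndPad(lapply(records, derivativeFilter))
  out <- lapply(recs, function(r) {
    x <- normalizeLocal(r$samples)
    mag <- spectrogramFrames(x)
    db <- normalizeLocal(toDecibel(mag))
    normalizeLocal(barkTimePool(db, sampleRate = r$sampleRate))
  })
  names(out) <- vapply(records, function(r)
    paste(r$syllableId, r$realization, sep = "."), character(1))
  out
}
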