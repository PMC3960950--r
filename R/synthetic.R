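# Synthetic acoustic-semantic corpus generator: activation-space syllable
# templates with formant-like band structure and duration contrasts,
# hierarchical binary semantic features with the singleton-pruning rule,
# and a seeded bijective sound-meaning pairing. A small waveform mode
# exists solely to exercise the audio preprocessing end to end.

#' Synthetic corpus configuration
#'
#' Defaults describe a realistic single-speaker syllable corpus: 70
#' syllable types (5 V + 45 CV + 20 CCV built from 5 vowels and 9
#' consonants) x 3 realizations as 24 x 57 activation matrices, 70 words
#' in 9 semantic categories, and a bijective pairing. \code{featuresPerCategory} = 25 and
#' \code{featuresPerWord} = 2 give 365 raw features, of the same order as a
#' hand-built feature set for 70 nouns; sparse cross-category bits
#' (\code{crossFeatureProb}) keep categories overlapping but separable.
#'
#' @param nVowels,nConsonants phoneme inventory sizes (defaults 5, 9).
#' @param nSyllables number of syllable types (default 70).
#' @param nRealizations realizations per syllable (default 3).
#' @param nCategories semantic categories (default 9).
#' @param featuresPerCategory shared features per category (default 25).
#' @param featuresPerWord word-specific features (default 2).
#' @param crossFeatureProb probability of a sparse cross-category bit
#'   (default 0.02).
#' @param noiseSd Gaussian activation noise per realization (default 0.02).
#' @param timeShift logical: apply a random +/- 1 column shift per
#'   realization (default TRUE).
#' @param timeFrames time columns per activation matrix (default 57,
#'   minimum 8).
#' @param seed integer seed.
#' @return list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(nVowels = 5L, nConsonants = 9L, nSyllables = 70L,
                            nRealizations = 3L, nCategories = 9L,
                            featuresPerCategory = 25L, featuresPerWord = 2L,
                            crossFeatureProb = 0.02, noiseSd = 0.02,
                            timeShift = TRUE, timeFrames = 57L, seed = 1L) {
  if (timeFrames < 8L)
    stop("timeFrames must be at least 8 to host onset, transition and vowel")
  if (nSyllables < 1L || nRealizations < 1L || nCategories < 1L)
    stop("corpus dimensions must be positive")
  if (nCategories > nSyllables)
    stop("cannot have more categories than words")
  structure(list(nVowels = as.integer(nVowels),
                 nConsonants = as.integer(nConsonants),
                 nSyllables = as.integer(nSyllables),
                 nRealizations = as.integer(nRealizations),
                 nWords = as.integer(nSyllables),
                 nCategories = as.integer(nCategories),
                 featuresPerCategory = as.integer(featuresPerCategory),
                 featuresPerWord = as.integer(featuresPerWord),
                 crossFeatureProb = crossFeatureProb, noiseSd = noiseSd,
                 timeShift = isTRUE(timeShift),
                 timeFrames = as.integer(timeFrames),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Syllable s -> phonological makeup: type (V / CV / CCV), vowel index,
# consonant indices. V syllables come first, then all CV combinations,
# then CCV; indices cycle if nSyllables exceeds the inventory.
.syllablePlan <- function(cfg) {
  nV <- cfg$nVowels; nC <- cfg$nConsonants
  lapply(seq_len(cfg$nSyllables), function(s) {
    if (s <= nV) {
      list(type = "V", vowel = s, cons = integer(0))
    } else if (s <= nV + nC * nV) {
      i <- s - nV - 1L
      list(type = "CV", vowel = i %% nV + 1L, cons = i %/% nV %% nC + 1L)
    } else {
      i <- s - nV - nC * nV - 1L
      c1 <- (i %/% nV) %% nC + 1L
      list(type = "CCV", vowel = i %% nV + 1L,
           cons = c(c1, c1 %% nC + 1L))
    }
  })
}

# Formant-analog band center rows for vowel v (rows 1..24, low frequencies
# at row 1): low vowels get high F1 rows, high vowels low F1 rows.
.vowelRows <- function(v, nV) {
  sp <- if (nV > 1L) (v - 1L) / (nV - 1L) else 0
  c(f1 = 2 + round(6 * sp), f2 = 20 - round(9 * sp))
}

# Onset band rows per consonant: manner class cycles plosive/nasal/lateral,
# with a small within-class offset to keep consonants distinct.
.consRows <- function(ci) {
  off <- (ci - 1L) %/% 3L
  switch(((ci - 1L) %% 3L) + 1L,
         list(manner = "plosive", rows = c(4 + off, 18 - off), burst = TRUE),
         list(manner = "nasal", rows = c(2 + off, 12 + off), burst = FALSE),
         list(manner = "lateral", rows = c(5 + off, 15 + off), burst = FALSE))
}

# Add a Gaussian-profile horizontal band segment to matrix m.
.addBand <- function(m, centers, colsIdx, amp = 0.9, width = 1.2) {
  rows <- seq_len(nrow(m))
  for (k in seq_along(colsIdx)) {
    prof <- amp * exp(-(rows - centers[k])^2 / (2 * width^2))
    m[, colsIdx[k]] <- pmin(1, m[, colsIdx[k]] + prof)
  }
  m
}

#' Generate noise-free syllable templates
#'
#' Each syllable becomes a 24 x timeFrames activation matrix built from
#' 2-3 Gaussian-profile horizontal bands: vowel identity fixes the band
#' rows of the steady portion, consonant manner (plosive burst, nasal or
#' lateral band patterns) fixes the onset, and band centers move linearly
#' through the transition. Active spans grow from V to CV to CCV (duration
#' is a category cue); remaining columns are zero.
#'
#' @param config a [syntheticConfig()].
#' @return named list of 24 x timeFrames matrices ("s01", "s02", ...).
#' @export
genSyllableTemplates <- function(config) {
  Tn <- config$timeFrames
  plan <- .syllablePlan(config)
  span <- c(V = round(0.4 * Tn), CV = round(0.6 * Tn), CCV = round(0.85 * Tn))
  out <- lapply(seq_along(plan), function(s) {
    p <- plan[[s]]
    m <- matrix(0, 24L, Tn)
    act <- span[[p$type]]
    vr <- .vowelRows(p$vowel, config$nVowels)
    nOn <- length(p$cons)
    onLen <- if (nOn) max(1L, round(0.18 * act)) else max(1L, round(0.08 * act))
    trLen <- max(2L, round(0.2 * act))
    cursor <- 1L
    startRows <- vr
    if (nOn == 0L) {
      # glottal-stop analog: brief broadband onset
      m[3:22, seq_len(onLen)] <- pmin(1, m[3:22, seq_len(onLen)] + 0.5)
      cursor <- cursor + onLen
    } else {
      for (ci in p$cons) {
        cr <- .consRows(ci)
        idx <- cursor:(cursor + onLen - 1L)
        if (cr$burst) {
          m[3:22, idx[1L]] <- pmin(1, m[3:22, idx[1L]] + 0.6)
          if (length(idx) > 1L)
            m <- .addBand(m, rep(cr$rows[1L], length(idx) - 1L), idx[-1L], amp = 0.5)
          m <- .addBand(m, rep(cr$rows[2L], length(idx) - 1L),
                        if (length(idx) > 1L) idx[-1L] else integer(0), amp = 0.5)
        } else {
          m <- .addBand(m, rep(cr$rows[1L], length(idx)), idx, amp = 0.8)
          m <- .addBand(m, rep(cr$rows[2L], length(idx)), idx, amp = 0.8)
        }
        startRows <- cr$rows
        cursor <- cursor + onLen
      }
    }
    # linear formant transition from the last onset rows to the vowel rows
    trIdx <- cursor:min(cursor + trLen - 1L, act)
    a <- seq(0, 1, length.out = length(trIdx))
    m <- .addBand(m, (1 - a) * startRows[1L] + a * vr["f1"], trIdx, amp = 0.85)
    m <- .addBand(m, (1 - a) * startRows[2L] + a * vr["f2"], trIdx, amp = 0.85)
    cursor <- max(trIdx) + 1L
    if (cursor <= act) {
      vIdx <- cursor:act
      m <- .addBand(m, rep(vr["f1"], length(vIdx)), vIdx, amp = 0.95)
      m <- .addBand(m, rep(vr["f2"], length(vIdx)), vIdx, amp = 0.95)
    }
    m
  })
  names(out) <- sprintf("s%02d", seq_along(plan))
  out
}

#' Realize noisy audio tokens from templates
#'
#' Each realization is its template plus i.i.d. Gaussian activation noise
#' and (optionally) a random time shift of -1, 0 or +1 columns, clamped to
#' [0, 1]. Uses the caller's RNG stream.
#'
#' @param templates output of [genSyllableTemplates()].
#' @param config a [syntheticConfig()].
#' @return numeric matrix (24*timeFrames) x (nSyllables*nRealizations),
#'   tokens syllable-major, realization-minor.
#' @export
genAudioTokens <- function(templates, config) {
  d <- 24L * config$timeFrames
  n <- length(templates) * config$nRealizations
  out <- matrix(0, d, n)
  j <- 0L
  for (tm in templates) {
    for (r in seq_len(config$nRealizations)) {
      j <- j + 1L
      m <- tm
      if (config$timeShift) {
        sh <- sample(-1:1, 1L)
        if (sh == 1L) m <- cbind(0, m[, -ncol(m)])
        if (sh == -1L) m <- cbind(m[, -1L], 0)
      }
      if (config$noiseSd > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = config$noiseSd),
                        nrow(m), ncol(m))
      out[, j] <- pmin(1, pmax(0, as.vector(m)))
    }
  }
  out
}

#' Generate hierarchical binary semantic vectors
#'
#' Words are partitioned into balanced categories. Each word's vector sets
#' its category's shared feature block, its own word-specific features, and
#' sparse random bits in other categories' shared blocks; all vectors are
#' pairwise distinct (guaranteed by the word-specific features). Uses the
#' caller's RNG stream.
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{matrix} (words x features, 0/1, word rownames)
#'   and \code{category} (named character wordId -> category label).
#' @export
genSemanticVectors <- function(config) {
  nW <- config$nWords; nCat <- config$nCategories
  fpc <- config$featuresPerCategory; fpw <- config$featuresPerWord
  if (fpw < 1L)
    stop("featuresPerWord must be >= 1 to guarantee distinct vectors")
  cat <- (seq_len(nW) - 1L) %% nCat + 1L
  nF <- nCat * fpc + nW * fpw
  m <- matrix(0, nW, nF)
  for (w in seq_len(nW)) {
    m[w, (cat[w] - 1L) * fpc + seq_len(fpc)] <- 1
    m[w, nCat * fpc + (w - 1L) * fpw + seq_len(fpw)] <- 1
    other <- which(rep(seq_len(nCat), each = fpc) != cat[w])
    cross <- other[stats::runif(length(other)) < config$crossFeatureProb]
    m[w, cross] <- 1
  }
  rownames(m) <- sprintf("w%02d", seq_len(nW))
  colnames(m) <- sprintf("f%03d", seq_len(nF))
  if (anyDuplicated(m) > 0)
    stop("could not generate pairwise distinct semantic vectors")
  list(matrix = m,
       category = stats::setNames(sprintf("cat%d", cat), rownames(m)))
}

#' Drop singleton features while keeping words distinguishable
#'
#' Iterates over features in column order and drops any feature carried by
#' exactly one word, unless the deletion would leave two words with
#' identical vectors, in which case the feature is retained.
#'
#' @param m binary matrix, words x features, pairwise distinct rows.
#' @return the pruned matrix.
#' @examples
#' m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' pruneFeatures(m)  # drops nothing: each singleton is a sole distinguisher
#' @export
pruneFeatures <- function(m) {
  if (!nrow(m)) stop("empty feature matrix")
  if (anyDuplicated(m) > 0) stop("input rows must be pairwise distinct")
  j <- 1L
  while (j <= ncol(m)) {
    if (sum(m[, j]) == 1) {
      reduced <- m[, -j, drop = FALSE]
      if (anyDuplicated(reduced) == 0L) {
        m <- reduced
        next
      }
    }
    j <- j + 1L
  }
  m
}

#' Assemble the paired corpus
#'
#' Draws a seeded random bijection from syllables to words (uses the
#' caller's RNG stream); the realizations of one syllable all share the
#' same pairing. Tokens are listed syllable-major, realization-minor.
#'
#' @param audio token matrix from [genAudioTokens()].
#' @param semantics list from [genSemanticVectors()] (optionally pruned).
#' @param config a [syntheticConfig()].
#' @return an [IGsomCorpus-class].
#' @export
buildPairs <- function(audio, semantics, config) {
  sylls <- sprintf("s%02d", seq_len(config$nSyllables))
  words <- rownames(semantics$matrix)
  if (length(sylls) != length(words))
    stop("need exactly one word per syllable")
  pairing <- stats::setNames(sample(words), sylls)
  tokSyll <- rep(sylls, each = config$nRealizations)
  new("IGsomCorpus", audio = audio, semantic = semantics$matrix,
      syllableId = tokSyll, wordId = unname(pairing[tokSyll]),
      realization = rep(seq_len(config$nRealizations), config$nSyllables),
      pairing = pairing, categoryOf = semantics$category,
      timeFrames = config$timeFrames)
}

#' Generate a complete synthetic corpus
#'
#' Runs template generation, token realization, semantic-vector generation
#' with singleton pruning, and pairing under one seed; fully reproducible
#' from the configuration.
#'
#' @param config a [syntheticConfig()].
#' @param prune logical: apply [pruneFeatures()] to the semantic matrix
#'   (default TRUE).
#' @return an [IGsomCorpus-class].
#' @examples
#' corp <- syntheticCorpus(syntheticConfig(nSyllables = 10, nCategories = 3,
#'                                         timeFrames = 20, seed = 42))
#' nTokens(corp)  # 30
#' @export
syntheticCorpus <- function(config = syntheticConfig(), prune = TRUE) {
  .withSeed(config$seed, {
    templates <- genSyllableTemplates(config)
    audio <- genAudioTokens(templates, config)
    sem <- genSemanticVectors(config)
    if (prune) sem$matrix <- pruneFeatures(sem$matrix)
    buildPairs(audio, sem, config)
  })
}

#' Synthetic annotated waveforms
#'
#' A small set of artificial consonant-vowel-like waveforms (band-limited
#' noise burst before the release, two-sine formant analog after it) with
#' known release positions, used to exercise the waveform preprocessing
#' pipeline end to end. Synthetic stand-ins, not recordings.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param sampleRate sampling rate in Hz (default 44100).
#' @return list of [speechRecord()] objects.
#' @export
syntheticWaveRecords <- function(n = 6L, seed = 1L, sampleRate = 44100) {
  .withSeed(seed, lapply(seq_len(n), function(i) {
    pre <- round(stats::runif(1, 0.04, 0.07) * sampleRate)
    post <- round(stats::runif(1, 0.10, 0.16) * sampleRate)
    f1 <- stats::runif(1, 300, 800)
    f2 <- stats::runif(1, 1200, 2500)
    tPre <- seq_len(pre) / sampleRate
    burst <- stats::rnorm(pre, sd = 0.1) * sin(pi * seq_len(pre) / pre) *
      sin(2 * pi * 3000 * tPre)
    tPost <- seq_len(post) / sampleRate
    env <- sin(pi * seq_len(post) / post)
    vowel <- env * (0.5 * sin(2 * pi * f1 * tPost) +
                      0.3 * sin(2 * pi * f2 * tPost))
    speechRecord(c(burst, vowel), sampleRate, release = pre + 1L,
                 syllableId = sprintf("syn%02d", i), realization = 1L)
  }))
}
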