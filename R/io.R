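# Serialization: versioned plain-text model archives, corpus directories,
# schedule / synthetic configuration YAML, and the per-step metrics CSV.
# Doubles are written with 17 significant digits so that load(save(x))
# reproduces every weight bit for bit.

.fmtNum <- function(x) sprintf("%.17g", x)

.ARCHIVE_VERSION <- 1L

#' Save an I-GSOM model to a text archive
#'
#' A versioned, diffable tab-separated archive: scalar header, one node
#' line per map node (row, col, accumulated error, weight components) and
#' one line per link. Weights round-trip exactly.
#'
#' @param model an [IGsomModel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  a <- model@auditory; s <- model@semantic; l <- model@links
  nodeLines <- function(m) {
    vapply(seq_len(nNodes(m)), function(i)
      paste(c(m@positions[i, 1L], m@positions[i, 2L], .fmtNum(m@errors[i]),
              .fmtNum(m@weights[, i])), collapse = "\t"), character(1))
  }
  linkLines <- if (length(l@weight)) {
    vapply(seq_along(l@weight), function(i)
      paste(c(l@audioPos[i, 1L], l@audioPos[i, 2L], l@semPos[i, 1L],
              l@semPos[i, 2L], .fmtNum(l@weight[i])), collapse = "\t"),
      character(1))
  } else character(0)
  lines <- c(
    paste("igsom-model", .ARCHIVE_VERSION, sep = "\t"),
    paste("audioDim", a@inputDim, sep = "\t"),
    paste("semDim", s@inputDim, sep = "\t"),
    paste("prevPossible", l@prevPossible, sep = "\t"),
    paste("increment", .fmtNum(l@increment), sep = "\t"),
    paste("initWeight", .fmtNum(l@initWeight), sep = "\t"),
    paste("[auditory]", nNodes(a), sep = "\t"), nodeLines(a),
    paste("[semantic]", nNodes(s), sep = "\t"), nodeLines(s),
    paste("[links]", length(l@weight), sep = "\t"), linkLines)
  writeLines(lines, path)
  invisible(path)
}

#' Load an I-GSOM model archive
#'
#' @param path archive written by [saveModel()].
#' @return an [IGsomModel-class].
#' @export
loadModel <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr[1L], "igsom-model"))
    stop(path, ": not an igsom model archive")
  if (as.integer(hdr[2L]) != .ARCHIVE_VERSION)
    stop(path, ": archive version ", hdr[2L], " not supported (expected ",
         .ARCHIVE_VERSION, ")")
  kv <- function(key, i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!identical(f[1L], key)) stop(path, ": expected field ", key)
    f[2L]
  }
  audioDim <- as.integer(kv("audioDim", 2L))
  semDim <- as.integer(kv("semDim", 3L))
  prevPossible <- as.integer(kv("prevPossible", 4L))
  increment <- as.numeric(kv("increment", 5L))
  initWeight <- as.numeric(kv("initWeight", 6L))
  i <- 7L
  readMap <- function(tag, dim) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!identical(f[1L], tag)) stop(path, ": expected section ", tag)
    n <- as.integer(f[2L])
    pos <- matrix(0L, n, 2L); err <- numeric(n); w <- matrix(0, dim, n)
    for (k in seq_len(n)) {
      v <- strsplit(lines[i + k], "\t", fixed = TRUE)[[1L]]
      pos[k, ] <- as.integer(v[1:2])
      err[k] <- as.numeric(v[3L])
      w[, k] <- as.numeric(v[-(1:3)])
    }
    i <<- i + n + 1L
    new("GrowingMap", positions = pos, weights = w, errors = err,
        inputDim = dim)
  }
  am <- readMap("[auditory]", audioDim)
  sm <- readMap("[semantic]", semDim)
  f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  if (!identical(f[1L], "[links]")) stop(path, ": expected section [links]")
  k <- as.integer(f[2L])
  apos <- matrix(0L, k, 2L); spos <- matrix(0L, k, 2L); lw <- numeric(k)
  for (j in seq_len(k)) {
    v <- strsplit(lines[i + j], "\t", fixed = TRUE)[[1L]]
    apos[j, ] <- as.integer(v[1:2]); spos[j, ] <- as.integer(v[3:4])
    lw[j] <- as.numeric(v[5L])
  }
  links <- new("LinkRegistry", audioPos = apos, semPos = spos, weight = lw,
               prevPossible = prevPossible, increment = increment,
               initWeight = initWeight)
  new("IGsomModel", auditory = am, semantic = sm, links = links)
}

#' Write a corpus to a directory
#'
#' Plain-text layout: \code{audio.tsv} (one token per row, full precision),
#' \code{semantic.tsv} (words x features, 0/1, word rownames),
#' \code{pairing.tsv} (syllable_id, realization_index, word_id, category)
#' and \code{meta.yaml}.
#'
#' @param corpus an [IGsomCorpus-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  audioLines <- vapply(seq_len(nTokens(corpus)), function(t)
    paste(.fmtNum(corpus@audio[, t]), collapse = "\t"), character(1))
  writeLines(audioLines, file.path(dir, "audio.tsv"))
  sem <- corpus@semantic
  utils::write.table(sem, file.path(dir, "semantic.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  pairing <- data.frame(syllable_id = corpus@syllableId,
                        realization_index = corpus@realization,
                        word_id = corpus@wordId,
                        category = unname(corpus@categoryOf[corpus@wordId]),
                        stringsAsFactors = FALSE)
  utils::write.table(pairing, file.path(dir, "pairing.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(timeFrames = corpus@timeFrames,
                        audioDim = nrow(corpus@audio)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a corpus directory
#'
#' @param dir directory written by [writeCorpus()].
#' @return an [IGsomCorpus-class].
#' @export
readCorpus <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  audio <- t(as.matrix(utils::read.table(file.path(dir, "audio.tsv"),
                                         sep = "\t")))
  dimnames(audio) <- NULL
  sem <- as.matrix(utils::read.table(file.path(dir, "semantic.tsv"),
                                     sep = "\t", header = TRUE,
                                     row.names = 1L, check.names = FALSE))
  pairing <- utils::read.table(file.path(dir, "pairing.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  firstReal <- pairing[!duplicated(pairing$syllable_id), ]
  pairMap <- stats::setNames(firstReal$word_id, firstReal$syllable_id)
  wordCat <- pairing[!duplicated(pairing$word_id), ]
  new("IGsomCorpus", audio = audio, semantic = sem,
      syllableId = pairing$syllable_id, wordId = pairing$word_id,
      realization = as.integer(pairing$realization_index),
      pairing = pairMap,
      categoryOf = stats::setNames(wordCat$category, wordCat$word_id),
      timeFrames = as.integer(meta$timeFrames))
}

#' Write / read a schedule configuration as YAML
#'
#' @param config a [ScheduleConfig-class].
#' @param path YAML file path.
#' @return `writeScheduleConfig`: the path, invisibly.
#' @export
writeScheduleConfig <- function(config, path) {
  pp <- function(p) list(initialLearningRate = p@initialLearningRate,
                         initialNeighborhood = p@initialNeighborhood,
                         growthThreshold = p@growthThreshold,
                         alpha = p@alpha, beta = p@beta, gamma = p@gamma,
                         Q = p@Q)
  yaml::write_yaml(list(
    growing = pp(config@growing), reinforcing = pp(config@reinforcing),
    reviewing = pp(config@reviewing),
    reinforcingByLink = pp(config@reinforcingByLink),
    fundamentalCycles = config@fundamentalCycles,
    experimentCycles = config@experimentCycles,
    withLinkTraining = config@withLinkTraining,
    densityThreshold = config@densityThreshold,
    distanceThreshold = config@distanceThreshold,
    linkCheckFraction = config@linkCheckFraction,
    countRealizations = config@countRealizations,
    seed = config@seed), path)
  invisible(path)
}

#' @rdname writeScheduleConfig
#' @return `readScheduleConfig`: a [ScheduleConfig-class].
#' @export
readScheduleConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- function(l) phaseParams(l$initialLearningRate, l$initialNeighborhood,
                                l$growthThreshold, l$alpha, l$beta, l$gamma,
                                l$Q)
  new("ScheduleConfig",
      growing = pp(y$growing), reinforcing = pp(y$reinforcing),
      reviewing = pp(y$reviewing), reinforcingByLink = pp(y$reinforcingByLink),
      fundamentalCycles = as.integer(y$fundamentalCycles),
      experimentCycles = as.integer(y$experimentCycles),
      withLinkTraining = isTRUE(y$withLinkTraining),
      densityThreshold = as.integer(y$densityThreshold),
      distanceThreshold = as.numeric(y$distanceThreshold),
      linkCheckFraction = as.numeric(y$linkCheckFraction),
      countRealizations = isTRUE(y$countRealizations),
      seed = as.integer(y$seed))
}

#' Write the per-step metrics table
#'
#' One CSV row per completed phase: the quantities behind the standard
#' training curves (node counts, solid nodes, boundary ratios, items per
#' solid node, link count and accuracy).
#'
#' @param metrics data.frame from [runFundamentalTraining()] /
#'   [runExperiment()].
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeMetrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
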