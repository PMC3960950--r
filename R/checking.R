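# Non-mutating checking (calibration): BMU assignment of a corpus to both
# maps, per-node density/distance statistics, perceiving-path link marks
# and the summary metrics behind the training curves.

.nodeKey <- function(r, c) paste(r, c, sep = ",")

#' Assign a corpus to the model's maps
#'
#' The calibration half of the checking process: every token is assigned to
#' its best matching unit in the auditory map, and every distinct word to
#' its BMU in the semantic map (all realizations of a syllable share one
#' word vector). Per-node statistics count distinct represented items
#' (syllables on the auditory map, words on the semantic map) and the mean
#' node-to-item Euclidean distance. The model is not modified.
#'
#' @param model an [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @return an [IGsomCheck-class] with assignments and node statistics
#'   (link marks and metrics still empty).
#' @export
checkMaps <- function(model, corpus) {
  n <- nTokens(corpus)
  if (!n) stop("corpus holds no tokens")
  coreA <- .mapCore(model@auditory)
  coreS <- .mapCore(model@semantic)

  rowA <- colA <- integer(n); distA <- numeric(n)
  for (t in seq_len(n)) {
    b <- .coreBMU(coreA, corpus@audio[, t])
    rowA[t] <- coreA$pos[b$idx, 1L]; colA[t] <- coreA$pos[b$idx, 2L]
    distA[t] <- b$dist
  }
  audioAssign <- data.frame(token = seq_len(n), syllableId = corpus@syllableId,
                            wordId = corpus@wordId, row = rowA, col = colA,
                            dist = distA, stringsAsFactors = FALSE)

  words <- rownames(corpus@semantic)
  rowS <- colS <- integer(length(words)); distS <- numeric(length(words))
  for (k in seq_along(words)) {
    b <- .coreBMU(coreS, corpus@semantic[k, ])
    rowS[k] <- coreS$pos[b$idx, 1L]; colS[k] <- coreS$pos[b$idx, 2L]
    distS[k] <- b$dist
  }
  semAssign <- data.frame(wordId = words, row = rowS, col = colS, dist = distS,
                          stringsAsFactors = FALSE)

  aSplit <- split(seq_len(n), .nodeKey(rowA, colA))
  audioNodeStats <- do.call(rbind, lapply(aSplit, function(ix) {
    data.frame(row = rowA[ix[1L]], col = colA[ix[1L]],
               items = length(unique(corpus@syllableId[ix])),
               tokens = length(ix), meanDist = mean(distA[ix]))
  }))
  rownames(audioNodeStats) <- NULL

  sSplit <- split(seq_along(words), .nodeKey(rowS, colS))
  semNodeStats <- do.call(rbind, lapply(sSplit, function(ix) {
    data.frame(row = rowS[ix[1L]], col = colS[ix[1L]],
               items = length(ix), meanDist = mean(distS[ix]))
  }))
  rownames(semNodeStats) <- NULL

  new("IGsomCheck", audioAssign = audioAssign, semAssign = semAssign,
      audioNodeStats = audioNodeStats, semNodeStats = semNodeStats,
      linkMarks = data.frame(), metrics = list())
}

#' Check perceiving-path link correctness
#'
#' For every solid auditory node (a node hosting at least one audio item),
#' the winner link is the maximum-weight link leaving that node, taken over
#' the top-\code{fraction} highest-weight links in the registry. The winner
#' is marked incorrect when it connects to a semantic node hosting no
#' words, or only words not paired with any syllable hosted at the source
#' node; correct otherwise. A solid node without any (retained) outgoing
#' link is marked incorrect: perceiving retrieves nothing for it.
#'
#' @param model an [IGsomModel-class].
#' @param check an [IGsomCheck-class] from [checkMaps()].
#' @param corpus the same [IGsomCorpus-class] (supplies the
#'   syllable-to-word pairing).
#' @param fraction numeric in (0, 1]: link filter, 1 = no filtering.
#' @return the [IGsomCheck-class] with \code{linkMarks} filled.
#' @export
checkLinks <- function(model, check, corpus, fraction = 1) {
  lc <- .linkCore(model@links)
  use <- .coreTopIdx(lc, fraction)
  if (!length(use)) {
    # no links exist at all: accuracy is undefined, not zero
    check@linkMarks <- data.frame(row = integer(), col = integer(),
                                  targetRow = integer(),
                                  targetCol = integer(), correct = logical())
    return(check)
  }
  aStats <- check@audioNodeStats
  wordsAtNode <- split(check@semAssign$wordId,
                       .nodeKey(check@semAssign$row, check@semAssign$col))
  syllsAtNode <- split(check@audioAssign$syllableId,
                       .nodeKey(check@audioAssign$row, check@audioAssign$col))
  k <- nrow(aStats)
  tr <- tc <- rep(NA_integer_, k)
  correct <- logical(k)
  for (i in seq_len(k)) {
    win <- .coreWinner(lc, aStats$row[i], aStats$col[i], use)
    if (is.na(win)) next  # no outgoing link: incorrect
    tr[i] <- lc$s[win, 1L]; tc[i] <- lc$s[win, 2L]
    hosted <- wordsAtNode[[.nodeKey(tr[i], tc[i])]]
    if (is.null(hosted)) next  # empty semantic node: incorrect
    sylls <- unique(syllsAtNode[[.nodeKey(aStats$row[i], aStats$col[i])]])
    paired <- unname(corpus@pairing[sylls])
    correct[i] <- length(intersect(hosted, paired)) > 0L
  }
  check@linkMarks <- data.frame(row = aStats$row, col = aStats$col,
                                targetRow = tr, targetCol = tc,
                                correct = correct)
  check
}

#' Summarize a checking pass
#'
#' Fills the metrics slot: total and solid node counts per map, boundary
#' ratios, average items per solid node (unique audio sequences for the
#' auditory map, words for the semantic map; 70 words on 70 solid nodes
#' gives 1), maximum items on any single node, link count, and -- if link
#' marks are present -- link accuracy as correct / marked.
#'
#' @param model the checked [IGsomModel-class].
#' @param check an [IGsomCheck-class] (after [checkMaps()], optionally
#'   [checkLinks()]).
#' @return the [IGsomCheck-class] with \code{metrics} filled.
#' @export
summarizeCheck <- function(model, check) {
  aStats <- check@audioNodeStats
  sStats <- check@semNodeStats
  # unique items: every audio sequence (realization) is its own item on the
  # auditory map; words are the items on the semantic map
  nAudioItems <- nrow(check@audioAssign)
  nWords <- nrow(check@semAssign)
  marks <- check@linkMarks
  check@metrics <- list(
    nodesAudio = nNodes(model@auditory),
    nodesSem = nNodes(model@semantic),
    solidAudio = nrow(aStats),
    solidSem = nrow(sStats),
    boundaryRatioAudio = boundaryRatio(model@auditory),
    boundaryRatioSem = boundaryRatio(model@semantic),
    avgItemsAudio = nAudioItems / nrow(aStats),
    avgItemsSem = nWords / nrow(sStats),
    maxItemsAudio = max(aStats$tokens),
    maxItemsSem = max(sStats$items),
    linkCount = length(model@links@weight),
    linkAccuracy = if (nrow(marks)) mean(marks$correct) else NA_real_)
  check
}

#' Metrics of a summarized check
#'
#' @param check a summarized [IGsomCheck-class].
#' @return named list of summary metrics.
#' @export
checkMetrics <- function(check) check@metrics
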