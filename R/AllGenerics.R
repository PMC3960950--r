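# Generics and accessors for the core classes; slot access stays internal.

#' Number of nodes in a map
#' @param x a [GrowingMap-class].
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "GrowingMap", function(x) nrow(x@positions))

#' Node positions of a map
#' @param x a [GrowingMap-class].
#' @return integer matrix n x 2 (row, col).
#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))

#' @rdname nodePositions
#' @export
setMethod("nodePositions", "GrowingMap", function(x) x@positions)

#' Node weight matrix of a map
#' @param x a [GrowingMap-class].
#' @return numeric matrix inputDim x n (one column per node).
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))

#' @rdname nodeWeights
#' @export
setMethod("nodeWeights", "GrowingMap", function(x) x@weights)

#' Accumulated errors of a map's nodes
#' @param x a [GrowingMap-class].
#' @return numeric vector of length n.
#' @export
setGeneric("nodeErrors", function(x) standardGeneric("nodeErrors"))

#' @rdname nodeErrors
#' @export
setMethod("nodeErrors", "GrowingMap", function(x) x@errors)

#' Input dimension of a map
#' @param x a [GrowingMap-class].
#' @return integer.
#' @export
setGeneric("inputDim", function(x) standardGeneric("inputDim"))

#' @rdname inputDim
#' @export
setMethod("inputDim", "GrowingMap", function(x) x@inputDim)

#' Component accessors of an I-GSOM model
#' @param x an [IGsomModel-class].
#' @return the auditory [GrowingMap-class].
#' @export
setGeneric("auditoryMap", function(x) standardGeneric("auditoryMap"))

#' @rdname auditoryMap
#' @export
setMethod("auditoryMap", "IGsomModel", function(x) x@auditory)

#' @rdname auditoryMap
#' @return for `semanticMap`, the semantic [GrowingMap-class].
#' @export
setGeneric("semanticMap", function(x) standardGeneric("semanticMap"))

#' @rdname auditoryMap
#' @export
setMethod("semanticMap", "IGsomModel", function(x) x@semantic)

#' @rdname auditoryMap
#' @return for `linkRegistry`, the [LinkRegistry-class].
#' @export
setGeneric("linkRegistry", function(x) standardGeneric("linkRegistry"))

#' @rdname auditoryMap
#' @export
setMethod("linkRegistry", "IGsomModel", function(x) x@links)

#' Links as a data frame
#' @param x a [LinkRegistry-class] or [IGsomModel-class].
#' @return data.frame with columns audioRow, audioCol, semRow, semCol, weight.
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @rdname linkTable
#' @export
setMethod("linkTable", "LinkRegistry", function(x) {
  data.frame(audioRow = x@audioPos[, 1L], audioCol = x@audioPos[, 2L],
             semRow = x@semPos[, 1L], semCol = x@semPos[, 2L],
             weight = x@weight)
})

#' @rdname linkTable
#' @export
setMethod("linkTable", "IGsomModel", function(x) linkTable(x@links))

#' Number of tokens in a corpus
#' @param x an [IGsomCorpus-class].
#' @return integer.
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))

#' @rdname nTokens
#' @export
setMethod("nTokens", "IGsomCorpus", function(x) ncol(x@audio))

#' Semantic feature matrix of a corpus
#' @param x an [IGsomCorpus-class].
#' @return binary matrix, words x features.
#' @export
setGeneric("semanticMatrix", function(x) standardGeneric("semanticMatrix"))

#' @rdname semanticMatrix
#' @export
setMethod("semanticMatrix", "IGsomCorpus", function(x) x@semantic)

#' Per-token audio activation vectors
#' @param x an [IGsomCorpus-class].
#' @return numeric matrix, (24*timeFrames) x nTokens.
#' @export
setGeneric("audioMatrix", function(x) standardGeneric("audioMatrix"))

#' @rdname audioMatrix
#' @export
setMethod("audioMatrix", "IGsomCorpus", function(x) x@audio)

# ---- show methods ---------------------------------------------------------

setMethod("show", "GrowingMap", function(object) {
  cat(sprintf("GrowingMap: %d nodes, input dimension %d\n",
              nNodes(object), inputDim(object)))
  cat(sprintf("  boundary ratio %.3f, total accumulated error %.3f\n",
              boundaryRatio(object), sum(object@errors)))
})

setMethod("show", "IGsomModel", function(object) {
  cat("IGsomModel\n")
  cat(sprintf("  auditory map: %d nodes (dim %d)\n",
              nNodes(object@auditory), inputDim(object@auditory)))
  cat(sprintf("  semantic map: %d nodes (dim %d)\n",
              nNodes(object@semantic), inputDim(object@semantic)))
  cat(sprintf("  links: %d (possible %d)\n", length(object@links@weight),
              nNodes(object@auditory) * nNodes(object@semantic)))
})

setMethod("show", "LinkRegistry", function(object) {
  cat(sprintf("LinkRegistry: %d links, L = %g, init weight = %g\n",
              length(object@weight), object@increment, object@initWeight))
})

setMethod("show", "PhaseParams", function(object) {
  cat(sprintf(
    "PhaseParams: R_learn %.2g, sigma %.2g, T_grow %.2g, alpha %.2g, beta %.2g, gamma %.2g, Q %.2g\n",
    object@initialLearningRate, object@initialNeighborhood,
    object@growthThreshold, object@alpha, object@beta, object@gamma, object@Q))
})

setMethod("show", "IGsomCorpus", function(object) {
  cat(sprintf(
    "IGsomCorpus: %d tokens (%d syllables x %d realizations), %d words x %d features, %d time frames\n",
    nTokens(object), length(object@pairing),
    if (length(object@pairing)) max(object@realization) else 0L,
    nrow(object@semantic), ncol(object@semantic), object@timeFrames))
})

setMethod("show", "IGsomCheck", function(object) {
  m <- object@metrics
  cat("IGsomCheck\n")
  if (length(m)) {
    cat(sprintf("  auditory: %d nodes, %d solid, boundary ratio %.3f, avg items/solid %.3f\n",
                m$nodesAudio, m$solidAudio, m$boundaryRatioAudio, m$avgItemsAudio))
    cat(sprintf("  semantic: %d nodes, %d solid, boundary ratio %.3f, avg items/solid %.3f\n",
                m$nodesSem, m$solidSem, m$boundaryRatioSem, m$avgItemsSem))
    cat(sprintf("  link accuracy: %s\n",
                if (is.na(m$linkAccuracy)) "not checked" else sprintf("%.4f", m$linkAccuracy)))
  }
})
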