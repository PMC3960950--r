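#' @import methods
NULL

# ---------------------------------------------------------------------------
# PhaseParams
# ---------------------------------------------------------------------------

#' Per-phase training parameters
#'
#' Bundles the tunables of one training regime: the initial learning rate
#' \eqn{R_{learn}}, the initial neighborhood size \eqn{\sigma}, the growth
#' threshold \eqn{T_{grow}} that a node's accumulated quantization error must
#' exceed before new nodes are spawned, the per-iteration reduction factors
#' \eqn{\alpha} (learning rate) and \eqn{\beta} (neighborhood), the error
#' distribution factor \eqn{\gamma}, and the learning-rate constant \eqn{Q}
#' entering \eqn{\phi(n) = 1 - Q/n}.
#'
#' @slot initialLearningRate numeric in (0, 1].
#' @slot initialNeighborhood positive numeric, in lattice units.
#' @slot growthThreshold positive numeric (\eqn{T_{grow}}).
#' @slot alpha numeric in (0, 1), learning-rate reduction factor.
#' @slot beta numeric in (0, 1), neighborhood reduction factor.
#' @slot gamma numeric in (0, 1), error distribution factor.
#' @slot Q positive numeric, default 3.8 (just below the 4 starting nodes).
#'
#' @seealso [phaseParams()], [defaultSchedule()]
#' @export
setClass("PhaseParams",
  slots = c(
    initialLearningRate = "numeric",
    initialNeighborhood = "numeric",
    growthThreshold     = "numeric",
    alpha               = "numeric",
    beta                = "numeric",
    gamma               = "numeric",
    Q                   = "numeric"
  )
)

setValidity("PhaseParams", function(object) {
  msg <- character()
  r <- object@initialLearningRate
  if (length(r) != 1L || is.na(r) || r <= 0 || r > 1)
    msg <- c(msg, "initialLearningRate must be a single value in (0, 1]")
  if (length(object@initialNeighborhood) != 1L || object@initialNeighborhood <= 0)
    msg <- c(msg, "initialNeighborhood must be positive")
  if (length(object@growthThreshold) != 1L || object@growthThreshold <= 0)
    msg <- c(msg, "growthThreshold must be positive")
  for (nm in c("alpha", "beta", "gamma")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie strictly between 0 and 1", nm))
  }
  if (length(object@Q) != 1L || object@Q <= 0)
    msg <- c(msg, "Q must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct phase parameters
#'
#' @param initialLearningRate,initialNeighborhood,growthThreshold,alpha,beta,gamma,Q
#'   see [PhaseParams-class]. Defaults are the basic-growing regime
#'   (0.5, 2, 2, 0.9, 0.9, 0.5, Q = 3.8).
#' @return A [PhaseParams-class] object.
#' @examples
#' phaseParams()                          # growing / reviewing regime
#' phaseParams(initialLearningRate = 0.8, growthThreshold = 1)  # reinforcing
#' @export
phaseParams <- function(initialLearningRate = 0.5, initialNeighborhood = 2,
                        growthThreshold = 2, alpha = 0.9, beta = 0.9,
                        gamma = 0.5, Q = 3.8) {
  new("PhaseParams",
      initialLearningRate = as.numeric(initialLearningRate),
      initialNeighborhood = as.numeric(initialNeighborhood),
      growthThreshold = as.numeric(growthThreshold),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), Q = as.numeric(Q))
}

# ---------------------------------------------------------------------------
# GrowingMap
# ---------------------------------------------------------------------------

#' A growing self-organizing lattice
#'
#' An open rectangular lattice of nodes on the integer grid. Each node carries
#' a weight vector in \eqn{[0,1]^d} and a non-negative accumulated quantization
#' error. The lattice starts as a 2-by-2 block and only ever gains nodes, at
#' boundary positions (occupied positions with at least one free von Neumann
#' neighbor). Row/column coordinates are unbounded integers and may go
#' negative as the map grows outwards.
#'
#' Nodes are stored column-wise: \code{weights} is \code{inputDim x n} and
#' \code{positions} is \code{n x 2} (row, col). Node order is insertion order
#' and never changes, so node indices are stable identifiers.
#'
#' @slot positions integer matrix, n x 2 (row, col), unique rows.
#' @slot weights numeric matrix, inputDim x n, entries in [0, 1].
#' @slot errors non-negative numeric vector of length n.
#' @slot inputDim positive integer scalar.
#'
#' @seealso [initMap()], [findBMU()], [growNodes()]
#' @export
setClass("GrowingMap",
  slots = c(
    positions = "matrix",
    weights   = "matrix",
    errors    = "numeric",
    inputDim  = "integer"
  )
)

setValidity("GrowingMap", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "positions must have two columns (row, col)")
  if (!is.integer(object@positions))
    msg <- c(msg, "positions must be integer")
  if (ncol(object@weights) != n)
    msg <- c(msg, "weights must have one column per node")
  if (nrow(object@weights) != object@inputDim)
    msg <- c(msg, "weights row count must equal inputDim")
  if (length(object@errors) != n)
    msg <- c(msg, "errors must have one entry per node")
  if (any(object@errors < 0))
    msg <- c(msg, "accumulated errors must be non-negative")
  if (length(object@weights) && (min(object@weights) < 0 || max(object@weights) > 1))
    msg <- c(msg, "weight components must lie in [0, 1]")
  if (n && anyDuplicated(paste(object@positions[, 1L], object@positions[, 2L])))
    msg <- c(msg, "node positions must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GrowingMap from explicit node tables
#'
#' Low-level constructor, mainly for tests and deserialization; use
#' [initMap()] to start a map the standard way (four random nodes).
#'
#' @param positions integer matrix (n x 2) of (row, col) lattice coordinates.
#' @param weights numeric matrix, inputDim x n, entries in [0, 1].
#' @param errors non-negative numeric vector of length n (default all 0).
#' @return A [GrowingMap-class].
#' @export
GrowingMap <- function(positions, weights, errors = numeric(ncol(weights))) {
  storage.mode(positions) <- "integer"
  new("GrowingMap", positions = positions, weights = weights,
      errors = as.numeric(errors), inputDim = nrow(weights))
}

# ---------------------------------------------------------------------------
# LinkRegistry
# ---------------------------------------------------------------------------

#' Associative links between the auditory and semantic maps
#'
#' A store of weighted directed links, each joining one auditory-map node
#' position to one semantic-map node position. A link is created with weight
#' \code{initWeight} the first time its two endpoints are co-activated by a
#' paired token, and each further co-activation adds the constant increment
#' \code{L}. At every phase end all link weights are multiplicatively decayed
#' by the link-forgetting rule (see [forgettingRate()]). Positions are stable:
#' nodes never move, so links survive map growth unchanged.
#'
#' @slot audioPos integer matrix, k x 2, auditory-map (row, col) per link.
#' @slot semPos integer matrix, k x 2, semantic-map (row, col) per link.
#' @slot weight positive numeric vector of length k.
#' @slot prevPossible positive integer: the possible-link count
#'   \eqn{N_{link}} recorded at the previous phase end (16 at start).
#' @slot increment positive numeric, the reinforcement constant L (0.1).
#' @slot initWeight positive numeric, weight of a freshly created link (0.1).
#'
#' @seealso [reinforceLink()], [applyForgetting()], [winnerLink()]
#' @export
setClass("LinkRegistry",
  slots = c(
    audioPos     = "matrix",
    semPos       = "matrix",
    weight       = "numeric",
    prevPossible = "integer",
    increment    = "numeric",
    initWeight   = "numeric"
  )
)

setValidity("LinkRegistry", function(object) {
  msg <- character()
  k <- length(object@weight)
  if (nrow(object@audioPos) != k || nrow(object@semPos) != k)
    msg <- c(msg, "audioPos/semPos must have one row per link")
  if (any(object@weight <= 0))
    msg <- c(msg, "link weights must be strictly positive")
  if (k && anyDuplicated(paste(object@audioPos[, 1L], object@audioPos[, 2L],
                               object@semPos[, 1L], object@semPos[, 2L])))
    msg <- c(msg, "at most one link per (audio, semantic) position pair")
  if (object@prevPossible < 1L)
    msg <- c(msg, "prevPossible must be positive")
  if (object@increment <= 0 || object@initWeight <= 0)
    msg <- c(msg, "increment and initWeight must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an (empty) link registry
#'
#' @param prevPossible initial possible-link count; 16 for two fresh 4-node
#'   maps.
#' @param increment reinforcement constant L, default 0.1.
#' @param initWeight initial weight of a new link, default 0.1.
#' @return A [LinkRegistry-class] with no links.
#' @export
LinkRegistry <- function(prevPossible = 16L, increment = 0.1, initWeight = 0.1) {
  new("LinkRegistry",
      audioPos = matrix(integer(), 0L, 2L), semPos = matrix(integer(), 0L, 2L),
      weight = numeric(), prevPossible = as.integer(prevPossible),
      increment = increment, initWeight = initWeight)
}

# ---------------------------------------------------------------------------
# IGsomModel
# ---------------------------------------------------------------------------

#' The interconnected growing self-organizing map model
#'
#' Two [GrowingMap-class] lattices (auditory and semantic) plus the
#' [LinkRegistry-class] of associative links between them.
#'
#' @slot auditory [GrowingMap-class] trained on flattened auditory
#'   activation matrices.
#' @slot semantic [GrowingMap-class] trained on binary semantic feature
#'   vectors.
#' @slot links [LinkRegistry-class].
#'
#' @seealso [igsomModel()], [trainToken()], [runFundamentalTraining()]
#' @export
setClass("IGsomModel",
  slots = c(auditory = "GrowingMap", semantic = "GrowingMap",
            links = "LinkRegistry")
)

#' Initialize a fresh I-GSOM model
#'
#' Both maps start as 2-by-2 blocks with uniformly random weights in [0, 1]
#' and zero accumulated error; the link registry starts empty with the
#' possible-link count 4 x 4 = 16.
#'
#' @param audioDim input dimension of the auditory map (e.g. 24 x 57 = 1368).
#' @param semanticDim input dimension of the semantic map (number of binary
#'   features).
#' @param seed integer seed for the random weight initialization.
#' @return An [IGsomModel-class].
#' @examples
#' m <- igsomModel(8, 5, seed = 1)
#' nNodes(auditoryMap(m))  # 4
#' @export
igsomModel <- function(audioDim, semanticDim, seed) {
  am <- initMap(audioDim, seed = seed)
  sm <- initMap(semanticDim, seed = seed + 1L)
  new("IGsomModel", auditory = am, semantic = sm,
      links = LinkRegistry(prevPossible = nNodes(am) * nNodes(sm)))
}

# ---------------------------------------------------------------------------
# ScheduleConfig
# ---------------------------------------------------------------------------

#' Full training-schedule configuration
#'
#' Holds the four per-regime parameter bundles and the schedule-level knobs:
#' the number of reinforcing/reviewing cycles in fundamental training, the
#' number of experiment cycles, whether reinforcing-by-link phases are run,
#' the high-density selection thresholds, and the top-fraction link filter
#' used during checking when link training is active.
#'
#' @slot growing,reinforcing,reviewing,reinforcingByLink [PhaseParams-class]
#'   per regime; defaults are (0.5, 2, 2, 0.9, 0.9, 0.5) for growing and
#'   reviewing and (0.8, 2, 1, 0.9, 0.9, 0.5) for the two reinforcing
#'   regimes.
#' @slot fundamentalCycles integer, reinforcing+reviewing cycles after the
#'   basic growing step (default 15, i.e. 31 steps in total).
#' @slot experimentCycles integer, cycles in the follow-on experiment
#'   (default 15).
#' @slot withLinkTraining logical: prepend a reinforcing-by-link phase to each
#'   experiment cycle and apply the top-fraction link filter when checking.
#' @slot densityThreshold integer: a node is high-density when it represents
#'   more than this many distinct items (default 4).
#' @slot distanceThreshold numeric: ... or when its mean node-to-item distance
#'   exceeds this (default 2.5).
#' @slot linkCheckFraction numeric in (0, 1]: fraction of top-weighted links
#'   considered during checking when \code{withLinkTraining} (default 0.2).
#' @slot countRealizations logical: if TRUE the auditory density rule counts
#'   individual realizations instead of distinct syllables (default FALSE).
#' @slot seed integer seed controlling model initialization.
#'
#' @seealso [defaultSchedule()]
#' @export
setClass("ScheduleConfig",
  slots = c(
    growing = "PhaseParams", reinforcing = "PhaseParams",
    reviewing = "PhaseParams", reinforcingByLink = "PhaseParams",
    fundamentalCycles = "integer", experimentCycles = "integer",
    withLinkTraining = "logical", densityThreshold = "integer",
    distanceThreshold = "numeric", linkCheckFraction = "numeric",
    countRealizations = "logical", seed = "integer"
  )
)

setValidity("ScheduleConfig", function(object) {
  msg <- character()
  if (object@fundamentalCycles < 0L) msg <- c(msg, "fundamentalCycles must be >= 0")
  if (object@experimentCycles < 0L) msg <- c(msg, "experimentCycles must be >= 0")
  if (object@densityThreshold < 1L) msg <- c(msg, "densityThreshold must be >= 1")
  if (object@distanceThreshold <= 0) msg <- c(msg, "distanceThreshold must be > 0")
  f <- object@linkCheckFraction
  if (length(f) != 1L || f <= 0 || f > 1)
    msg <- c(msg, "linkCheckFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Default training schedule
#'
#' The standard configuration: growing/reviewing at (R_learn 0.5, sigma 2,
#' T_grow 2, alpha 0.9, beta 0.9, gamma 0.5), reinforcing and
#' reinforcing-by-link at (0.8, 2, 1, 0.9, 0.9, 0.5); 15 fundamental cycles
#' (31 steps), 15 experiment cycles; selection thresholds: more than 4 items
#' per node or mean represented distance above 2.5; top-20% link filter when
#' link training is on.
#'
#' @param seed integer seed.
#' @param withLinkTraining logical, default FALSE.
#' @param fundamentalCycles,experimentCycles override cycle counts.
#' @param linkCheckFraction override the checking link filter fraction.
#' @return A [ScheduleConfig-class].
#' @examples
#' cfg <- defaultSchedule(seed = 1)
#' cfg@reinforcing
#' @export
defaultSchedule <- function(seed = 1L, withLinkTraining = FALSE,
                            fundamentalCycles = 15L, experimentCycles = 15L,
                            linkCheckFraction = 0.2) {
  grow <- phaseParams(0.5, 2, 2, 0.9, 0.9, 0.5)
  reinf <- phaseParams(0.8, 2, 1, 0.9, 0.9, 0.5)
  new("ScheduleConfig",
      growing = grow, reinforcing = reinf, reviewing = grow,
      reinforcingByLink = reinf,
      fundamentalCycles = as.integer(fundamentalCycles),
      experimentCycles = as.integer(experimentCycles),
      withLinkTraining = isTRUE(withLinkTraining),
      densityThreshold = 4L, distanceThreshold = 2.5,
      linkCheckFraction = as.numeric(linkCheckFraction),
      countRealizations = FALSE, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# IGsomCorpus
# ---------------------------------------------------------------------------

#' A paired acoustic-semantic training corpus
#'
#' Holds the training tokens: one column of \code{audio} per token (a
#' flattened 24 x T activation matrix in [0, 1]), the words-by-features
#' binary semantic matrix, per-token syllable/word/realization labels, the
#' bijective syllable-to-word pairing, and the word-to-category assignment.
#' All realizations of one syllable share one pairing, so a corpus of S
#' syllables with R realizations has S x R tokens and S words.
#'
#' @slot audio numeric matrix, (24*timeFrames) x nTokens, entries in [0, 1].
#' @slot semantic binary numeric matrix, words x features, unique rownames.
#' @slot syllableId character, per token.
#' @slot wordId character, per token (the paired word).
#' @slot realization integer, per token.
#' @slot pairing named character: syllableId -> wordId, a bijection.
#' @slot categoryOf named character: wordId -> category label.
#' @slot timeFrames integer, number of time columns per activation matrix.
#'
#' @seealso [syntheticCorpus()], [runFundamentalTraining()]
#' @export
setClass("IGsomCorpus",
  slots = c(
    audio = "matrix", semantic = "matrix",
    syllableId = "character", wordId = "character", realization = "integer",
    pairing = "character", categoryOf = "character", timeFrames = "integer"
  )
)

setValidity("IGsomCorpus", function(object) {
  msg <- character()
  n <- ncol(object@audio)
  if (length(object@syllableId) != n || length(object@wordId) != n ||
      length(object@realization) != n)
    msg <- c(msg, "per-token labels must match the number of audio columns")
  if (length(object@audio) && (min(object@audio) < 0 || max(object@audio) > 1))
    msg <- c(msg, "audio activations must lie in [0, 1]")
  if (!all(object@semantic %in% c(0, 1)))
    msg <- c(msg, "semantic matrix must be binary")
  if (is.null(rownames(object@semantic)))
    msg <- c(msg, "semantic matrix needs word rownames")
  if (anyDuplicated(object@semantic) > 0)
    msg <- c(msg, "semantic word vectors must be pairwise distinct")
  if (anyDuplicated(paste(object@syllableId, object@realization)))
    msg <- c(msg, "(syllableId, realization) must be unique")
  p <- object@pairing
  if (anyDuplicated(p) || anyDuplicated(names(p)))
    msg <- c(msg, "pairing must be a bijection syllable -> word")
  if (!all(object@wordId %in% rownames(object@semantic)))
    msg <- c(msg, "every token wordId must have a semantic vector")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# IGsomCheck
# ---------------------------------------------------------------------------

#' Result of a checking (calibration) pass
#'
#' Produced by [checkMaps()] and optionally completed by [checkLinks()]; the
#' model itself is never modified. Assignments map every token to its best
#' matching unit in each map; node statistics give, per occupied node
#' position, the number of distinct represented items and the mean distance
#' to them; \code{linkMarks} flags, per solid auditory node, whether its
#' winner link retrieves a correctly paired word.
#'
#' @slot audioAssign data.frame: token, syllableId, wordId, row, col, dist.
#' @slot semAssign data.frame: wordId, row, col, dist (one row per distinct
#'   word).
#' @slot audioNodeStats data.frame: row, col, items, tokens, meanDist.
#' @slot semNodeStats data.frame: row, col, items, meanDist.
#' @slot linkMarks data.frame: row, col, targetRow, targetCol, correct
#'   (empty until [checkLinks()] is run).
#' @slot metrics named list of summary metrics (see [summarizeCheck()]).
#'
#' @export
setClass("IGsomCheck",
  slots = c(audioAssign = "data.frame", semAssign = "data.frame",
            audioNodeStats = "data.frame", semNodeStats = "data.frame",
            linkMarks = "data.frame", metrics = "list")
)
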