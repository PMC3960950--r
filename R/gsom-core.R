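# Core growing-lattice machinery.
#
# Exported functions operate on GrowingMap objects and identify nodes by
# lattice position; the internal `.core` helpers work on a plain list
# (pos, w, err) with integer node indices so that the training loops can
# run without repeated S4 slot reassignment.

# ---- seeded RNG helper ----------------------------------------------------

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- internal core representation -----------------------------------------

.mapCore <- function(map) list(pos = map@positions, w = map@weights, err = map@errors)

.coreMap <- function(core, dim = nrow(core$w)) {
  new("GrowingMap", positions = core$pos, weights = core$w,
      errors = core$err, inputDim = as.integer(dim))
}

# von Neumann neighbors of (r, c) in lexicographic (row, col) order
.adjacentPos <- function(r, c) {
  cbind(row = c(r - 1L, r, r, r + 1L), col = c(c, c - 1L, c + 1L, c))
}

.coreFindIdx <- function(core, r, c) {
  hit <- which(core$pos[, 1L] == r & core$pos[, 2L] == c)
  if (length(hit)) hit[1L] else NA_integer_
}

.coreIsBoundary <- function(core, i) {
  adj <- .adjacentPos(core$pos[i, 1L], core$pos[i, 2L])
  for (k in 1:4)
    if (is.na(.coreFindIdx(core, adj[k, 1L], adj[k, 2L]))) return(TRUE)
  FALSE
}

# BMU by squared distance; exact ties broken lexicographically by (row, col)
.coreBMU <- function(core, x) {
  d2 <- .colDist2(core$w, x)
  m <- min(d2)
  cand <- which(d2 == m)
  if (length(cand) > 1L)
    cand <- cand[order(core$pos[cand, 1L], core$pos[cand, 2L])]
  list(idx = cand[1L], dist = sqrt(m))
}

# Weight of a node grown at (nr, nc) adjacent to BMU i: extrapolate across
# the BMU from the opposite neighbor if present, else from the first other
# occupied direct neighbor in (row, col) order, else copy the BMU.
.coreNewWeight <- function(core, i, nr, nc) {
  br <- core$pos[i, 1L]; bc <- core$pos[i, 2L]
  wb <- core$w[, i]
  oppIdx <- .coreFindIdx(core, br - (nr - br), bc - (nc - bc))
  if (!is.na(oppIdx)) return(pmin(1, pmax(0, 2 * wb - core$w[, oppIdx])))
  adj <- .adjacentPos(br, bc)
  for (k in 1:4) {
    if (adj[k, 1L] == nr && adj[k, 2L] == nc) next
    j <- .coreFindIdx(core, adj[k, 1L], adj[k, 2L])
    if (!is.na(j)) return(pmin(1, pmax(0, 2 * wb - core$w[, j])))
  }
  wb
}

# Grow new nodes at every free neighbor of boundary BMU i; reset its error.
.coreGrow <- function(core, i) {
  adj <- .adjacentPos(core$pos[i, 1L], core$pos[i, 2L])
  added <- integer(0)
  for (k in 1:4) {
    if (!is.na(.coreFindIdx(core, adj[k, 1L], adj[k, 2L]))) next
    wNew <- .coreNewWeight(core, i, adj[k, 1L], adj[k, 2L])
    core$pos <- rbind(core$pos, adj[k, , drop = FALSE])
    core$w <- cbind(core$w, wNew)
    core$err <- c(core$err, 0)
    added <- c(added, nrow(core$pos))
  }
  core$err[i] <- 0
  dimnames(core$w) <- NULL
  dimnames(core$pos) <- NULL
  list(core = core, added = added)
}

# Gaussian neighborhood update around BMU i (lattice distance <= ceil(sigma))
.coreUpdate <- function(core, i, x, rate, sigma) {
  dr <- core$pos[, 1L] - core$pos[i, 1L]
  dc <- core$pos[, 2L] - core$pos[i, 2L]
  gd2 <- dr * dr + dc * dc
  sel <- which(gd2 <= ceiling(sigma)^2)
  h <- rate * exp(-gd2[sel] / (2 * sigma * sigma))
  for (k in seq_along(sel)) {
    j <- sel[k]
    core$w[, j] <- core$w[, j] + h[k] * (x - core$w[, j])
  }
  core
}

# Error distribution for a saturated non-boundary BMU
.coreDistribute <- function(core, i, Tg, gamma) {
  core$err[i] <- Tg / 2
  adj <- .adjacentPos(core$pos[i, 1L], core$pos[i, 2L])
  for (k in 1:4) {
    j <- .coreFindIdx(core, adj[k, 1L], adj[k, 2L])
    if (!is.na(j)) core$err[j] <- core$err[j] + gamma * Tg
  }
  core
}

.decayRate <- function(rate, n, alpha, Q) {
  phi <- 1 - Q / n
  if (phi <= 0) {
    warning("learning-rate factor 1 - Q/n non-positive (n = ", n,
            "); clamped to 0.01")
    phi <- 0.01
  }
  alpha * phi * rate
}

# ---- exported API ---------------------------------------------------------

#' Initialize a growing map
#'
#' Creates the starting 2-by-2 lattice: four nodes at (0,0), (0,1), (1,0),
#' (1,1) with weight components drawn uniformly from [0, 1] and accumulated
#' errors zero. All four starting nodes are boundary nodes, so the map is
#' free to grow in any direction.
#'
#' @param inputDimension positive integer, dimension of the input vectors.
#' @param seed integer seed for the uniform weight draw (the caller's RNG
#'   state is left untouched).
#' @return A [GrowingMap-class] with 4 nodes.
#' @examples
#' m <- initMap(3, seed = 7)
#' nNodes(m)          # 4
#' boundaryRatio(m)   # 1
#' @export
initMap <- function(inputDimension, seed) {
  inputDimension <- as.integer(inputDimension)
  if (length(inputDimension) != 1L || is.na(inputDimension) || inputDimension < 1L)
    stop("inputDimension must be a positive integer")
  w <- .withSeed(seed, matrix(stats::runif(4L * inputDimension),
                              nrow = inputDimension, ncol = 4L))
  pos <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  new("GrowingMap", positions = pos, weights = w, errors = numeric(4L),
      inputDim = inputDimension)
}

#' Find the best matching unit
#'
#' Returns the node whose weight vector has minimum Euclidean distance to
#' \code{x}; exact ties are broken by lexicographic (row, col) position.
#'
#' @param map a [GrowingMap-class].
#' @param x numeric vector of length \code{inputDim(map)}.
#' @return list with \code{position} (integer c(row, col)), \code{distance},
#'   and \code{index} (stable node index).
#' @examples
#' m <- GrowingMap(cbind(c(0L, 0L), c(0L, 1L)), cbind(c(0, 0), c(1, 1)))
#' findBMU(m, c(0.1, 0.1))$distance  # sqrt(0.02)
#' @export
findBMU <- function(map, x) {
  if (length(x) != map@inputDim)
    stop("input vector length ", length(x), " does not match map dimension ",
         map@inputDim)
  core <- .mapCore(map)
  b <- .coreBMU(core, as.numeric(x))
  list(position = core$pos[b$idx, ], distance = b$dist, index = b$idx)
}

#' Is a node a boundary node?
#'
#' A boundary node has at least one unoccupied directly adjacent (von
#' Neumann) position; growth can only happen at boundary nodes.
#'
#' @param map a [GrowingMap-class].
#' @param pos integer c(row, col) of an occupied position.
#' @return logical.
#' @export
isBoundary <- function(map, pos) {
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(pos[1L]), as.integer(pos[2L]))
  if (is.na(i)) stop("position (", pos[1L], ", ", pos[2L], ") is not occupied")
  .coreIsBoundary(core, i)
}

#' Ratio of boundary nodes to all nodes
#'
#' Reaches its minimum when the lattice is maximally compact (circular); the
#' fresh 2-by-2 map has ratio 1.
#'
#' @param map a [GrowingMap-class].
#' @return numeric in (0, 1].
#' @export
boundaryRatio <- function(map) {
  core <- .mapCore(map)
  n <- nrow(core$pos)
  sum(vapply(seq_len(n), function(i) .coreIsBoundary(core, i), logical(1))) / n
}

#' Grow new nodes around a boundary BMU
#'
#' Adds one node at every free directly adjacent position of \code{pos}.
#' Each new node's weight is set by [newNodeWeight()] (extrapolation across
#' the BMU), its accumulated error starts at 0, and the BMU's accumulated
#' error is reset to 0.
#'
#' @param map a [GrowingMap-class].
#' @param pos integer c(row, col): an occupied boundary position.
#' @return list with \code{map} (the grown map) and \code{newPositions}
#'   (integer matrix of added positions, possibly 0 rows).
#' @export
growNodes <- function(map, pos) {
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(pos[1L]), as.integer(pos[2L]))
  if (is.na(i)) stop("position (", pos[1L], ", ", pos[2L], ") is not occupied")
  if (!.coreIsBoundary(core, i))
    stop("growth requires a boundary node; (", pos[1L], ", ", pos[2L],
         ") has no free neighbor")
  res <- .coreGrow(core, i)
  list(map = .coreMap(res$core, map@inputDim),
       newPositions = res$core$pos[res$added, , drop = FALSE])
}

#' Weight of a prospective new node
#'
#' Implements the weight-distribution rule used when the lattice grows. For
#' a new position adjacent to the BMU: (i) if the node opposite the new
#' position across the BMU exists, extrapolate \code{2*w_bmu - w_opp};
#' (ii) otherwise extrapolate from the first other occupied direct neighbor
#' in (row, col) order; (iii) otherwise copy the BMU weight. Components are
#' clamped to [0, 1].
#'
#' @param map a [GrowingMap-class].
#' @param bmuPos integer c(row, col) of the (occupied) BMU.
#' @param newPos integer c(row, col): a free position adjacent to the BMU.
#' @return numeric weight vector.
#' @export
newNodeWeight <- function(map, bmuPos, newPos) {
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(bmuPos[1L]), as.integer(bmuPos[2L]))
  if (is.na(i)) stop("BMU position is not occupied")
  if (!is.na(.coreFindIdx(core, as.integer(newPos[1L]), as.integer(newPos[2L]))))
    stop("new position is already occupied")
  if (abs(newPos[1L] - bmuPos[1L]) + abs(newPos[2L] - bmuPos[2L]) != 1L)
    stop("new position must be directly adjacent to the BMU")
  .coreNewWeight(core, i, as.integer(newPos[1L]), as.integer(newPos[2L]))
}

#' Gaussian neighborhood weight update
#'
#' Moves every node within lattice (Euclidean grid) distance
#' \code{ceiling(neighborhoodSize)} of the BMU toward the input:
#' \code{w <- w + rate * exp(-d^2 / (2 * sigma^2)) * (x - w)}, with \code{d}
#' the grid distance of the node from the BMU (so the BMU itself moves with
#' h = 1). With \code{rate * h} in [0, 1] this is a convex combination, so
#' weights stay in [0, 1].
#'
#' @param map a [GrowingMap-class].
#' @param pos integer c(row, col) of the BMU.
#' @param x input vector.
#' @param learningRate numeric in (0, 1].
#' @param neighborhoodSize positive numeric (sigma).
#' @return the updated [GrowingMap-class].
#' @export
updateWeights <- function(map, pos, x, learningRate, neighborhoodSize) {
  if (length(x) != map@inputDim) stop("input vector dimension mismatch")
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(pos[1L]), as.integer(pos[2L]))
  if (is.na(i)) stop("position is not occupied")
  core <- .coreUpdate(core, i, as.numeric(x), learningRate, neighborhoodSize)
  .coreMap(core, map@inputDim)
}

#' Accumulate quantization error on a node
#'
#' @param map a [GrowingMap-class].
#' @param pos integer c(row, col) of the BMU.
#' @param distance non-negative numeric to add to the node's accumulated
#'   error.
#' @return the updated [GrowingMap-class].
#' @export
accumulateError <- function(map, pos, distance) {
  if (distance < 0) stop("distance must be non-negative")
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(pos[1L]), as.integer(pos[2L]))
  if (is.na(i)) stop("position is not occupied")
  core$err[i] <- core$err[i] + distance
  .coreMap(core, map@inputDim)
}

#' Distribute accumulated error from a saturated interior node
#'
#' For a non-boundary BMU whose accumulated error exceeds the growth
#' threshold: its error is reduced to \code{T_grow / 2} and each occupied
#' direct neighbor's error increases by \code{gamma * T_grow}.
#'
#' @param map a [GrowingMap-class].
#' @param pos integer c(row, col) of the (non-boundary) BMU.
#' @param params a [PhaseParams-class] supplying \code{growthThreshold} and
#'   \code{gamma}.
#' @return the updated [GrowingMap-class].
#' @export
distributeError <- function(map, pos, params) {
  core <- .mapCore(map)
  i <- .coreFindIdx(core, as.integer(pos[1L]), as.integer(pos[2L]))
  if (is.na(i)) stop("position is not occupied")
  if (.coreIsBoundary(core, i))
    stop("error distribution applies only to non-boundary nodes")
  core <- .coreDistribute(core, i, params@growthThreshold, params@gamma)
  .coreMap(core, map@inputDim)
}

#' Decay the learning rate
#'
#' \code{R(t+1) = alpha * (1 - Q/n) * R(t)} with \code{n} the current node
#' count of the map, so larger networks decay more slowly. Should
#' \code{1 - Q/n} be non-positive (impossible once the map holds its four
#' starting nodes and Q = 3.8), the factor is clamped to 0.01 with a
#' warning.
#'
#' @param rate current positive learning rate.
#' @param map the [GrowingMap-class] whose node count enters \eqn{\phi(n)}.
#' @param params a [PhaseParams-class] supplying \code{alpha} and \code{Q}.
#' @return the decayed rate.
#' @examples
#' m <- initMap(2, 1)
#' decayLearningRate(0.5, m, phaseParams())  # 0.9 * (1 - 3.8/4) * 0.5
#' @export
decayLearningRate <- function(rate, map, params) {
  .decayRate(rate, nNodes(map), params@alpha, params@Q)
}

#' Decay the neighborhood size
#'
#' \code{sigma(t) = beta * sigma(t-1)}; since \code{0 < beta < 1} the inner
#' training loop, which runs while \code{sigma >= 1}, always terminates.
#'
#' @param sigma current neighborhood size.
#' @param params a [PhaseParams-class] supplying \code{beta}.
#' @return the decayed sigma.
#' @export
decayNeighborhood <- function(sigma, params) params@beta * sigma
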