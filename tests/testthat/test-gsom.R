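# Core lattice operations: initialization, BMU search, boundary topology,
# growth, weight updates, error bookkeeping and schedule decays.

test_that("initMap builds the seeded four-node block", {
  m <- initMap(3, seed = 7)
  expect_s4_class(m, "GrowingMap")
  expect_equal(nNodes(m), 4L)
  expect_setequal(paste(nodePositions(m)[, 1], nodePositions(m)[, 2]),
                  c("0 0", "0 1", "1 0", "1 1"))
  w <- nodeWeights(m)
  expect_equal(dim(w), c(3L, 4L))
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(nodeErrors(m), rep(0, 4))
  expect_equal(boundaryRatio(m), 1)
  expect_identical(nodeWeights(initMap(3, seed = 7)), w)
  expect_false(identical(nodeWeights(initMap(3, seed = 8)), w))
  expect_error(initMap(0, seed = 1), "positive")
})

test_that("initMap leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  initMap(5, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("findBMU returns the nearest node with deterministic tie-break", {
  m <- GrowingMap(cbind(c(0L, 0L), c(0L, 1L)), cbind(c(0, 0), c(1, 1)))
  b <- findBMU(m, c(0.1, 0.1))
  expect_equal(unname(b$position), c(0L, 0L))
  expect_equal(b$distance, sqrt(0.02))
  # identity case
  b2 <- findBMU(m, c(1, 1))
  expect_equal(unname(b2$position), c(0L, 1L))
  expect_equal(b2$distance, 0)
  # exact tie between (0,0) and (0,1) resolves to the lex-smaller position
  b3 <- findBMU(m, c(0.5, 0.5))
  expect_equal(unname(b3$position), c(0L, 0L))
  expect_error(findBMU(m, c(1, 2, 3)), "dimension")
})

test_that("findBMU agrees with an exhaustive linear scan", {
  for (s in 1:4) {
    m <- randomMap(30L, 5L, seed = s)
    w <- nodeWeights(m)
    pos <- nodePositions(m)
    set.seed(s + 100)
    for (k in 1:25) {
      x <- runif(5)
      d <- sqrt(colSums((w - x)^2))                 # brute-force oracle
      best <- which(d == min(d))
      best <- best[order(pos[best, 1], pos[best, 2])][1]
      b <- findBMU(m, x)
      expect_equal(b$index, best)
      expect_equal(b$distance, d[best])
    }
  }
})

test_that("boundary detection matches von Neumann occupancy", {
  m <- initMap(2, seed = 1)
  for (i in 1:4) expect_true(isBoundary(m, nodePositions(m)[i, ]))
  # full 3x3 block: only the center is interior
  pos <- as.matrix(expand.grid(row = 0:2, col = 0:2))
  full <- GrowingMap(pos, matrix(runif(9), 1, 9))
  expect_false(isBoundary(full, c(1, 1)))
  expect_true(isBoundary(full, c(0, 0)))
  # remove corner (2,2): its neighbors (1,2) and (2,1) become boundary
  keep <- !(pos[, 1] == 2 & pos[, 2] == 2)
  gap <- GrowingMap(pos[keep, ], matrix(runif(8), 1, 8))
  expect_true(isBoundary(gap, c(1, 2)))
  expect_true(isBoundary(gap, c(2, 1)))
  expect_false(isBoundary(gap, c(1, 1)))
  expect_error(isBoundary(m, c(5, 5)), "not occupied")
})

test_that("growth fills exactly the free adjacent positions", {
  m <- initMap(2, seed = 3)
  g <- growNodes(m, c(0, 0))
  expect_equal(nNodes(g$map), 6L)
  expect_setequal(paste(g$newPositions[, 1], g$newPositions[, 2]),
                  c("-1 0", "0 -1"))
  # new nodes start with zero error; the grown BMU's error is reset
  errs <- nodeErrors(g$map)
  expect_equal(errs[5:6], c(0, 0))
  expect_equal(errs[1], 0)
  # no occupied position was overwritten
  expect_equal(anyDuplicated(paste(nodePositions(g$map)[, 1],
                                   nodePositions(g$map)[, 2])), 0L)
  # one free neighbor -> exactly one new node
  pos <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 0L))
  m2 <- GrowingMap(pos, matrix(runif(5), 1, 5))
  g2 <- growNodes(m2, c(0, 0))
  expect_equal(nrow(g2$newPositions), 1L)
  expect_equal(unname(g2$newPositions[1, ]), c(0L, -1L))
  # growing a non-boundary node is a precondition violation
  full <- GrowingMap(as.matrix(expand.grid(0:2, 0:2)), matrix(runif(9), 1, 9))
  expect_error(growNodes(full, c(1, 1)), "boundary")
})

test_that("grown positions pass an exhaustive boundary recheck", {
  m <- initMap(3, seed = 11)
  g <- growNodes(m, c(1, 1))
  map <- g$map
  keys <- paste(nodePositions(map)[, 1], nodePositions(map)[, 2])
  for (i in seq_len(nrow(g$newPositions))) {
    p <- g$newPositions[i, ]
    adj <- rbind(p + c(-1, 0), p + c(1, 0), p + c(0, -1), p + c(0, 1))
    free <- !(paste(adj[, 1], adj[, 2]) %in% keys)   # occupancy oracle
    expect_equal(isBoundary(map, p), any(free))
  }
})

test_that("new-node weights follow the extrapolation fallback chain", {
  # case (i): opposite neighbor exists
  m <- GrowingMap(cbind(c(0L, 0L), c(0L, 1L)), cbind(0.6, 0.4))
  expect_equal(newNodeWeight(m, c(0, 0), c(0, -1)), 0.8)
  # clamping at 1
  m2 <- GrowingMap(cbind(c(0L, 0L), c(0L, 1L)), cbind(0.9, 0.1))
  expect_equal(newNodeWeight(m2, c(0, 0), c(0, -1)), 1)
  # case (ii): no opposite, first other neighbor in (row, col) order
  m3 <- GrowingMap(rbind(c(0L, 0L), c(1L, 0L)), cbind(0.6, 0.2))
  expect_equal(newNodeWeight(m3, c(0, 0), c(0, -1)), 1)  # clamp(2*0.6 - 0.2)
  # case (iii): isolated BMU copies its own weight
  m4 <- GrowingMap(matrix(c(0L, 0L), 1, 2), cbind(c(0.3, 0.7)))
  expect_equal(newNodeWeight(m4, c(0, 0), c(0, 1)), c(0.3, 0.7))
  expect_error(newNodeWeight(m, c(0, 0), c(0, 1)), "occupied")
  expect_error(newNodeWeight(m, c(0, 0), c(2, 2)), "adjacent")
})

test_that("Gaussian neighborhood update moves BMU and neighbors correctly", {
  m <- GrowingMap(cbind(c(0L, 0L), c(0L, 1L)), cbind(0, 0))
  u <- updateWeights(m, c(0, 0), x = 1, learningRate = 0.5,
                     neighborhoodSize = 2)
  expect_equal(nodeWeights(u)[1, 1], 0.5)                     # h(0) = 1
  expect_equal(nodeWeights(u)[1, 2], 0.5 * exp(-1 / 8))       # d = 1, sigma = 2
  # zero rate changes nothing
  u0 <- updateWeights(m, c(0, 0), x = 1, learningRate = 0,
                      neighborhoodSize = 2)
  expect_identical(nodeWeights(u0), nodeWeights(m))
  # convexity keeps weights in [0, 1]; BMU strictly approaches x
  m2 <- randomMap(12L, 4L, seed = 5)
  x <- runif(4)
  b <- findBMU(m2, x)
  u2 <- updateWeights(m2, b$position, x, 0.9, 2)
  expect_true(all(nodeWeights(u2) >= 0 & nodeWeights(u2) <= 1))
  expect_lt(sqrt(sum((nodeWeights(u2)[, b$index] - x)^2)), b$distance)
})

test_that("error accumulation is additive and validated", {
  m <- initMap(2, seed = 1)
  m <- accumulateError(m, c(0, 0), 1.5)
  expect_equal(nodeErrors(m)[1], 1.5)
  m <- accumulateError(m, c(0, 0), 1)
  m <- accumulateError(m, c(0, 0), 2)
  expect_equal(nodeErrors(m)[1], 4.5)
  m2 <- accumulateError(m, c(0, 0), 0)
  expect_identical(nodeErrors(m2), nodeErrors(m))
  expect_error(accumulateError(m, c(0, 0), -1), "non-negative")
})

test_that("error distribution halves the BMU error and loads the neighbors", {
  plus <- rbind(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  m <- GrowingMap(plus, matrix(runif(5), 1, 5), errors = c(3, 0, 0, 0, 0))
  d <- distributeError(m, c(0, 0), phaseParams())     # T_grow 2, gamma 0.5
  expect_equal(nodeErrors(d), c(1, 1, 1, 1, 1))
  # total error changed by exactly (T/2 - E_old) + k * gamma * T
  expect_equal(sum(nodeErrors(d)) - sum(nodeErrors(m)),
               (2 / 2 - 3) + 4 * 0.5 * 2)
  # reinforcing regime: T_grow 1, gamma 0.5
  m2 <- GrowingMap(plus, matrix(runif(5), 1, 5), errors = c(3, 0, 0, 0, 0))
  d2 <- distributeError(m2, c(0, 0),
                        phaseParams(initialLearningRate = 0.8,
                                    growthThreshold = 1))
  expect_equal(nodeErrors(d2), c(0.5, 0.5, 0.5, 0.5, 0.5))
  # boundary nodes never distribute
  expect_error(distributeError(m, c(0, 1), phaseParams()), "non-boundary")
})

test_that("learning-rate and neighborhood decays follow the closed forms", {
  p <- phaseParams()
  m4 <- initMap(2, seed = 1)
  expect_equal(decayLearningRate(0.5, m4, p), 0.9 * (1 - 3.8 / 4) * 0.5)
  m38 <- randomMap(38L, 2L, seed = 2)
  expect_equal(decayLearningRate(1, m38, p), 0.9 * 0.9)
  expect_equal(decayNeighborhood(2, p), 1.8)
  sigma <- 2
  for (i in 1:7) sigma <- decayNeighborhood(sigma, p)
  expect_equal(sigma, 2 * 0.9^7)
  expect_lt(sigma, 1)           # the inner loop terminates after 7 iterations
  # beta = 1 (which would never terminate) is rejected by validity
  expect_error(phaseParams(beta = 1), "beta")
})

test_that("map invariants hold along a random operation sequence", {
  m <- initMap(3, seed = 21)
  p <- phaseParams()
  set.seed(22)
  lastN <- nNodes(m)
  for (i in 1:40) {
    x <- runif(3)
    b <- findBMU(m, x)
    m <- updateWeights(m, b$position, x, 0.3, 1.5)
    m <- accumulateError(m, b$position, findBMU(m, x)$distance)
    if (nodeErrors(m)[b$index] > p@growthThreshold &&
        isBoundary(m, b$position)) {
      m <- growNodes(m, b$position)$map
    }
    expect_gte(nNodes(m), lastN)
    lastN <- nNodes(m)
    expect_true(all(nodeWeights(m) >= 0 & nodeWeights(m) <= 1))
  }
  # the occupied region stays 4-connected: breadth-first reachability
  pos <- nodePositions(m)
  keys <- paste(pos[, 1], pos[, 2])
  seen <- keys[1]
  frontier <- keys[1]
  while (length(frontier)) {
    nxt <- character(0)
    for (k in frontier) {
      rc <- as.integer(strsplit(k, " ")[[1]])
      adj <- paste(rc[1] + c(-1, 1, 0, 0), rc[2] + c(0, 0, -1, 1))
      nxt <- c(nxt, setdiff(intersect(adj, keys), seen))
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  expect_setequal(seen, keys)
})
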