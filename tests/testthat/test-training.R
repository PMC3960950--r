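# Token-level training rule and the phase schedules.

test_that("the sigma-driven inner loop runs exactly 7 iterations at defaults", {
  # sigma stays >= 1 at 2, 1.8, ..., 2*0.9^6 ~ 1.063; the link between the
  # two BMUs is reinforced once per iteration: 0.1 + 6 * 0.1
  m <- igsomModel(4, 3, seed = 5)
  r <- trainToken(m, runif(4), c(1, 0, 1), phaseParams())
  expect_equal(linkTable(r$model)$weight, 0.7)
  expect_equal(nrow(linkTable(r$model)), 1L)
  # both BMUs accumulated error
  expect_gt(sum(nodeErrors(auditoryMap(r$model))), 0)
  expect_gt(sum(nodeErrors(semanticMap(r$model))), 0)
  expect_false(r$grewAudio || r$grewSemantic)
  expect_error(trainToken(m, runif(3), c(1, 0, 1), phaseParams()),
               "dimensions")
})

test_that("repeated presentation eventually triggers a growth event", {
  m <- igsomModel(4, 3, seed = 5)
  x <- c(0.9, 0.1, 0.9, 0.1)
  s <- c(1, 0, 1)
  grew <- FALSE
  errBefore <- 0
  for (i in 1:50) {
    r <- trainToken(m, x, s, phaseParams())
    m <- r$model
    if (r$grewAudio) { grew <- TRUE; break }
    errBefore <- max(nodeErrors(auditoryMap(m)))
  }
  expect_true(grew)
  # growth required the accumulated error to exceed T_grow = 2 beforehand
  expect_gt(errBefore, 2)
  expect_gt(nNodes(auditoryMap(m)), 4L)
})

test_that("training is deterministic given the seed", {
  corp <- tinyCorpus()
  run <- function() {
    m <- igsomModel(nrow(audioMatrix(corp)), ncol(semanticMatrix(corp)),
                    seed = 3)
    cfg <- defaultSchedule(seed = 3, fundamentalCycles = 2)
    runFundamentalTraining(m, corp, cfg)
  }
  a <- run(); b <- run()
  expect_identical(nodeWeights(auditoryMap(a$model)),
                   nodeWeights(auditoryMap(b$model)))
  expect_identical(linkTable(a$model), linkTable(b$model))
  expect_identical(a$metrics, b$metrics)
})

test_that("runPhase applies phase-end forgetting from possible-link growth", {
  corp <- tinyCorpus()
  m <- igsomModel(nrow(audioMatrix(corp)), ncol(semanticMatrix(corp)),
                  seed = 1)
  # unreachable growth threshold: no growth, so no forgetting
  ph <- runPhase(m, corp, params = phaseParams(growthThreshold = 1e6))
  expect_equal(ph$report$growthEvents, 0L)
  expect_equal(ph$report$forgettingRate, 0)
  expect_equal(ph$report$nodesAudioAfter, 4L)
  # default growing phase: maps grow and the rate matches the closed form
  ph2 <- runPhase(m, corp, params = phaseParams())
  poss <- ph2$report$nodesAudioAfter * ph2$report$nodesSemAfter
  expect_gt(ph2$report$growthEvents, 0L)
  expect_equal(ph2$report$forgettingRate, (poss - 16) / poss)
  expect_gte(ph2$report$nodesAudioAfter, ph2$report$nodesAudioBefore)
  expect_error(runPhase(m, corp, integer(0), phaseParams()), "non-empty")
})

test_that("reinforcing selection triggers on density and distance rules", {
  corp <- handCheckCorpus()
  model <- handCheckModel()
  # perfect calibration: every item on its own node at distance 0
  expect_length(selectReinforcingTokens(model, corp), 0L)
  # all three audio tokens collapse onto one node -> density rule fires
  amCollapsed <- GrowingMap(nodePositions(auditoryMap(model)),
                            cbind(c(0.5, 0.5), c(0.5, 0.5) + 1e-9,
                                  c(0.9, 0.9), c(0.95, 0.95)))
  m2 <- new("IGsomModel", auditory = amCollapsed,
            semantic = semanticMap(model), links = LinkRegistry())
  expect_equal(selectReinforcingTokens(m2, corp, densityThreshold = 2L),
               1:3)
  # distance rule: word vectors far (> 2.5) from every semantic node
  smFar <- GrowingMap(nodePositions(semanticMap(model)),
                      matrix(0, 3, 4))
  semFar <- rbind(w01 = c(1, 1, 1), w02 = c(1, 1, 0), w03 = c(0, 1, 1))
  corpFar <- corp
  corpFar@semantic <- semFar
  m3 <- new("IGsomModel", auditory = auditoryMap(model), semantic = smFar,
            links = LinkRegistry())
  # sqrt(3) < 2.5: nothing selected at the default threshold
  expect_length(selectReinforcingTokens(m3, corpFar), 0L)
  # with a tight distance threshold the semantic rule selects all tokens
  sel <- selectReinforcingTokens(m3, corpFar, distanceThreshold = 1)
  expect_equal(sel, 1:3)
  # a token triggering both rules appears once
  m4 <- new("IGsomModel", auditory = amCollapsed, semantic = smFar,
            links = LinkRegistry())
  sel4 <- selectReinforcingTokens(m4, corpFar, densityThreshold = 2L,
                                  distanceThreshold = 1)
  expect_equal(sel4, 1:3)
  expect_equal(anyDuplicated(sel4), 0L)
})

test_that("link-token selection returns tokens at incorrectly linked nodes", {
  corp <- handCheckCorpus()
  model <- handCheckModel()
  reg <- LinkRegistry()
  reg <- forgeLink(reg, c(0, 0), c(0, 0), 0.5)   # correct: w01 paired s01
  reg <- forgeLink(reg, c(0, 1), c(0, 1), 0.5)   # correct: w02 paired s02
  reg <- forgeLink(reg, c(1, 0), c(1, 1), 0.5)   # incorrect: empty target
  model@links <- reg
  expect_equal(selectLinkTokens(model, corp, fraction = 1), 3L)
  # all winner links correct -> empty selection
  regGood <- LinkRegistry()
  regGood <- forgeLink(regGood, c(0, 0), c(0, 0), 0.5)
  regGood <- forgeLink(regGood, c(0, 1), c(0, 1), 0.5)
  regGood <- forgeLink(regGood, c(1, 0), c(1, 0), 0.5)
  model@links <- regGood
  expect_length(selectLinkTokens(model, corp, fraction = 1), 0L)
})

test_that("fundamental training yields 31 step reports with the right shape", {
  corp <- tinyCorpus()
  m <- igsomModel(nrow(audioMatrix(corp)), ncol(semanticMatrix(corp)),
                  seed = 1)
  res <- runFundamentalTraining(m, corp, defaultSchedule(seed = 1))
  expect_equal(nrow(res$metrics), 31L)
  expect_equal(res$metrics$phase,
               c("growing", rep(c("reinforcing", "reviewing"), 15)))
  # reviewing phases always use the complete training set
  expect_true(all(res$metrics$tokensUsed[res$metrics$phase == "reviewing"] ==
                    nTokens(corp)))
  # node counts never decrease across steps
  expect_true(all(diff(res$metrics$nodesAudio) >= 0))
  expect_true(all(diff(res$metrics$nodesSem) >= 0))
  # boundary ratio drops from its initial 1.0
  expect_lt(res$metrics$boundaryRatioAudio[31], 1)
  expect_lt(res$metrics$boundaryRatioSem[31], 1)
})

test_that("experiment cycles follow the configured structure", {
  corp <- tinyCorpus()
  m <- igsomModel(nrow(audioMatrix(corp)), ncol(semanticMatrix(corp)),
                  seed = 2)
  cfg <- defaultSchedule(seed = 2, fundamentalCycles = 3, experimentCycles = 3)
  fund <- runFundamentalTraining(m, corp, cfg)
  e1 <- runExperiment(fund$model, corp, cfg)             # no link training
  expect_equal(nrow(e1$metrics), 6L)
  expect_equal(unique(e1$metrics$phase), c("reinforcing", "reviewing"))
  cfg2 <- cfg; cfg2@withLinkTraining <- TRUE
  e2 <- runExperiment(fund$model, corp, cfg2)
  expect_equal(nrow(e2$metrics), 9L)
  expect_equal(e2$metrics$phase[1:3],
               c("reinforcing-by-link", "reinforcing", "reviewing"))
  acc <- e2$metrics$linkAccuracy
  expect_true(all(is.na(acc) | (acc >= 0 & acc <= 1)))
  # step labels continue from the fundamental numbering
  expect_equal(e1$metrics$step[1], 32L)
})
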