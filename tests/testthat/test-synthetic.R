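# Synthetic corpus generator: templates, noisy tokens, semantic structure,
# pruning, pairing.

test_that("templates encode duration and vowel structure", {
  cfg <- syntheticConfig(nSyllables = 70L, timeFrames = 57L, seed = 1)
  tpl <- genSyllableTemplates(cfg)
  expect_length(tpl, 70L)
  expect_true(all(vapply(tpl, function(m) all(dim(m) == c(24, 57)),
                         logical(1))))
  expect_true(all(vapply(tpl, function(m) min(m) >= 0 && max(m) <= 1,
                         logical(1))))
  active <- vapply(tpl, function(m) sum(colSums(m) > 0), integer(1))
  # V syllables (1..5) are strictly shorter than CCV syllables (51..70)
  expect_lt(max(active[1:5]), min(active[51:70]))
  # determinism
  expect_identical(genSyllableTemplates(cfg), tpl)
  expect_error(syntheticConfig(timeFrames = 5), "at least 8")
})

test_that("shared-vowel syllables are more similar in their vowel portion", {
  cfg <- syntheticConfig(nSyllables = 50L, timeFrames = 57L, seed = 1)
  tpl <- genSyllableTemplates(cfg)
  # CV syllables 6..50: vowel v = (i - 6) %% 5 + 1; compare steady tails
  tail20 <- function(m) {
    act <- which(colSums(m) > 0)
    as.vector(m[, act[(length(act) - 4):length(act)]])
  }
  cosSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sameV <- cosSim(tail20(tpl[[6]]), tail20(tpl[[11]]))    # both vowel 1
  crossV <- cosSim(tail20(tpl[[6]]), tail20(tpl[[9]]))    # vowels 1 vs 4
  expect_gt(sameV, crossV)
})

test_that("token realization adds bounded noise and preserves identity", {
  cfg0 <- syntheticConfig(nSyllables = 10L, nCategories = 3L,
                          timeFrames = 20L, noiseSd = 0, timeShift = FALSE,
                          seed = 2)
  tpl <- genSyllableTemplates(cfg0)
  tok0 <- genAudioTokens(tpl, cfg0)
  expect_equal(tok0[, 1], as.vector(tpl[[1]]))            # zero-noise identity
  expect_equal(tok0[, 3], as.vector(tpl[[1]]))
  expect_equal(ncol(tok0), 30L)
  # default shape: 70 syllables x 3 realizations = 210 tokens
  cfgFull <- syntheticConfig(seed = 3)
  tokFull <- genAudioTokens(genSyllableTemplates(cfgFull), cfgFull)
  expect_equal(ncol(tokFull), 210L)
  expect_true(all(tokFull >= 0 & tokFull <= 1))
  # at noise_sd = 0.05 nearly every realization stays nearest its template
  cfgN <- syntheticConfig(nSyllables = 10L, nCategories = 3L,
                          timeFrames = 20L, noiseSd = 0.05, seed = 4)
  tplN <- genSyllableTemplates(cfgN)
  set.seed(4)
  tokN <- genAudioTokens(tplN, cfgN)
  tplMat <- vapply(tplN, as.vector, numeric(24 * 20))
  own <- rep(seq_len(10), each = 3)
  hits <- vapply(seq_len(30), function(j) {
    d <- colSums((tplMat - tokN[, j])^2)
    which.min(d) == own[j]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("semantic vectors carry hierarchical category structure", {
  cfg <- syntheticConfig(seed = 5)
  set.seed(5)
  sem <- genSemanticVectors(cfg)
  m <- sem$matrix
  expect_equal(dim(m), c(70L, 9L * 25L + 70L * 2L))
  expect_equal(anyDuplicated(m), 0L)
  expect_length(unique(sem$category), 9L)
  ham <- as.matrix(dist(m, method = "manhattan"))
  sameCat <- outer(sem$category, sem$category, "==") & upper.tri(ham)
  crossCat <- !outer(sem$category, sem$category, "==") & upper.tri(ham)
  expect_lt(mean(ham[sameCat]), mean(ham[crossCat]))
  expect_error(genSemanticVectors(syntheticConfig(featuresPerWord = 0)),
               "featuresPerWord")
})

test_that("pruning drops only safely removable singleton features", {
  # f1 shared (kept), f2 droppable singleton, f3 singleton that is b's only
  # remaining distinguisher after f2 goes (kept)
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  colnames(m) <- c("f1", "f2", "f3")
  p <- pruneFeatures(m)
  expect_equal(colnames(p), c("f1", "f3"))
  # feature carried by two words is never a singleton
  m2 <- rbind(a = c(1, 1), b = c(1, 0))
  expect_equal(ncol(pruneFeatures(m2)), 2L)  # f2 is a's sole distinguisher
  m3 <- rbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0), c = c(0, 1, 1, 1))
  p3 <- pruneFeatures(m3)
  expect_equal(anyDuplicated(p3), 0L)
  expect_lte(ncol(p3), 4L)
  expect_error(pruneFeatures(rbind(c(1, 0), c(1, 0))), "distinct")
  # rows stay pairwise distinct on the generated set too
  cfg <- syntheticConfig(nSyllables = 10L, nCategories = 3L, seed = 6)
  set.seed(6)
  sem <- genSemanticVectors(cfg)
  expect_equal(anyDuplicated(pruneFeatures(sem$matrix)), 0L)
})

test_that("pairing is a seeded bijection shared by all realizations", {
  corp <- tinyCorpus()
  expect_equal(nTokens(corp), 30L)
  expect_equal(anyDuplicated(corp@pairing), 0L)
  expect_length(corp@pairing, 10L)
  # all realizations of one syllable share one word
  for (s in unique(corp@syllableId)) {
    expect_length(unique(corp@wordId[corp@syllableId == s]), 1L)
  }
  # each word receives exactly nRealizations tokens
  expect_true(all(table(corp@wordId) == 3L))
  # syllable-major, realization-minor ordering
  expect_equal(corp@syllableId[1:6], rep(c("s01", "s02"), each = 3))
  expect_equal(corp@realization[1:6], rep(1:3, 2))
})

test_that("corpus generation is reproducible and fast at reduced scale", {
  t0 <- Sys.time()
  a <- syntheticCorpus(syntheticConfig(nSyllables = 10L, nCategories = 3L,
                                       timeFrames = 20L, seed = 7))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 1)
  b <- syntheticCorpus(syntheticConfig(nSyllables = 10L, nCategories = 3L,
                                       timeFrames = 20L, seed = 7))
  expect_identical(audioMatrix(a), audioMatrix(b))
  expect_identical(semanticMatrix(a), semanticMatrix(b))
  expect_identical(a@pairing, b@pairing)
  c2 <- syntheticCorpus(syntheticConfig(nSyllables = 10L, nCategories = 3L,
                                        timeFrames = 20L, seed = 8))
  expect_false(identical(a@pairing, c2@pairing) &&
                 identical(audioMatrix(a), audioMatrix(c2)))
})

test_that("the default corpus has the documented default shape", {
  corp <- syntheticCorpus(syntheticConfig(seed = 11))
  expect_equal(nTokens(corp), 210L)
  expect_equal(nrow(audioMatrix(corp)), 24L * 57L)
  expect_equal(nrow(semanticMatrix(corp)), 70L)
  expect_length(unique(corp@categoryOf), 9L)
})
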