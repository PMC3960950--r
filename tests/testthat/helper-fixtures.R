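# Shared fixtures, all built in code.

# Small corpus driving the training/checking tests; memoised because corpus
# generation is deterministic given the config.
.tinyCache <- new.env(parent = emptyenv())
tinyCorpus <- function(seed = 42L) {
  key <- as.character(seed)
  if (is.null(.tinyCache[[key]])) {
    .tinyCache[[key]] <- syntheticCorpus(syntheticConfig(
      nSyllables = 10L, nCategories = 3L, timeFrames = 20L, seed = seed))
  }
  .tinyCache[[key]]
}

# A random map over a 4-connected region grown by random walk.
randomMap <- function(n, dim, seed) {
  set.seed(seed)
  pos <- matrix(c(0L, 0L), 1L, 2L)
  keys <- "0,0"
  while (nrow(pos) < n) {
    from <- pos[sample(nrow(pos), 1L), ]
    step <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))[sample(4L, 1L), ]
    cand <- from + step
    k <- paste(cand[1L], cand[2L], sep = ",")
    if (!k %in% keys) {
      pos <- rbind(pos, cand)
      keys <- c(keys, k)
    }
  }
  GrowingMap(pos, matrix(runif(dim * n), dim, n))
}

# Hand-built 3-syllable corpus with known geometry: audio tokens sit exactly
# on distinct auditory node weights, word vectors on distinct semantic node
# weights (see handCheckModel for the matching maps).
handCheckCorpus <- function() {
  sem <- rbind(w01 = c(1, 0, 0), w02 = c(0, 1, 0), w03 = c(0, 0, 1))
  colnames(sem) <- c("f1", "f2", "f3")
  new("IGsomCorpus",
      audio = cbind(c(0, 0), c(1, 0), c(0, 1)),
      semantic = sem,
      syllableId = c("s01", "s02", "s03"),
      wordId = c("w01", "w02", "w03"),
      realization = c(1L, 1L, 1L),
      pairing = c(s01 = "w01", s02 = "w02", s03 = "w03"),
      categoryOf = c(w01 = "a", w02 = "a", w03 = "b"),
      timeFrames = 1L)
}

# Maps matched to handCheckCorpus: auditory nodes at the three token vectors
# plus one extra; semantic nodes at the three word vectors plus one empty.
handCheckModel <- function() {
  am <- GrowingMap(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)),
                   cbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  sm <- GrowingMap(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)),
                   cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  new("IGsomModel", auditory = am, semantic = sm, links = LinkRegistry())
}

# Add a link with a given weight by create + repeated reinforcement.
forgeLink <- function(registry, audioPos, semPos, weight) {
  r <- reinforceLink(registry, audioPos, semPos)
  k <- round((weight - r$registry@initWeight) / r$registry@increment)
  for (i in seq_len(k)) r <- reinforceLink(r$registry, audioPos, semPos)
  r$registry
}
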