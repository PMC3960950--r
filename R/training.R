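# Token-level training and the phase schedules: basic growing, cyclical
# reinforcing / reviewing, reinforcing-by-link, with link forgetting at
# every phase end.

.ppList <- function(params) {
  list(r0 = params@initialLearningRate, s0 = params@initialNeighborhood,
       Tg = params@growthThreshold, alpha = params@alpha, beta = params@beta,
       gamma = params@gamma, Q = params@Q)
}

.modelCore <- function(model) {
  list(A = .mapCore(model@auditory), S = .mapCore(model@semantic),
       L = .linkCore(model@links))
}

.coreModel <- function(core, model) {
  new("IGsomModel",
      auditory = .coreMap(core$A, model@auditory@inputDim),
      semantic = .coreMap(core$S, model@semantic@inputDim),
      links = .coreRegistry(core$L))
}

# Semantic input vectors per token: features x nTokens
.semTokenMatrix <- function(corpus) {
  t(corpus@semantic)[, match(corpus@wordId, rownames(corpus@semantic)),
                     drop = FALSE]
}

# One token through both maps: BMUs found once; a saturated boundary BMU
# grows (and sits out the inner loop); otherwise the sigma-driven inner loop
# runs -- weight update + error accumulation while E_acc <= T_grow, error
# distribution for a saturated interior BMU, one link reinforcement per
# iteration in which at least one map updated, then learning-rate and sigma
# decay. The loop stops when sigma drops below 1 (7 iterations at the
# default sigma0 = 2, beta = 0.9).
.coreTrainToken <- function(core, xa, xs, pp) {
  bA <- .coreBMU(core$A, xa)
  bS <- .coreBMU(core$S, xs)
  grewA <- grewS <- FALSE
  if (core$A$err[bA$idx] > pp$Tg && .coreIsBoundary(core$A, bA$idx)) {
    core$A <- .coreGrow(core$A, bA$idx)$core
    grewA <- TRUE
  }
  if (core$S$err[bS$idx] > pp$Tg && .coreIsBoundary(core$S, bS$idx)) {
    core$S <- .coreGrow(core$S, bS$idx)$core
    grewS <- TRUE
  }
  if (!(grewA && grewS)) {
    rateA <- rateS <- pp$r0
    sigma <- pp$s0
    posA <- core$A$pos[bA$idx, ]
    posS <- core$S$pos[bS$idx, ]
    while (sigma >= 1) {
      updated <- FALSE
      if (!grewA) {
        if (core$A$err[bA$idx] <= pp$Tg) {
          core$A <- .coreUpdate(core$A, bA$idx, xa, rateA, sigma)
          d <- sqrt(sum((core$A$w[, bA$idx] - xa)^2))
          core$A$err[bA$idx] <- core$A$err[bA$idx] + d
          updated <- TRUE
        } else if (!.coreIsBoundary(core$A, bA$idx)) {
          core$A <- .coreDistribute(core$A, bA$idx, pp$Tg, pp$gamma)
        }
      }
      if (!grewS) {
        if (core$S$err[bS$idx] <= pp$Tg) {
          core$S <- .coreUpdate(core$S, bS$idx, xs, rateS, sigma)
          d <- sqrt(sum((core$S$w[, bS$idx] - xs)^2))
          core$S$err[bS$idx] <- core$S$err[bS$idx] + d
          updated <- TRUE
        } else if (!.coreIsBoundary(core$S, bS$idx)) {
          core$S <- .coreDistribute(core$S, bS$idx, pp$Tg, pp$gamma)
        }
      }
      if (updated) core$L <- .coreReinforce(core$L, posA, posS)
      rateA <- .decayRate(rateA, ncol(core$A$w), pp$alpha, pp$Q)
      rateS <- .decayRate(rateS, ncol(core$S$w), pp$alpha, pp$Q)
      sigma <- pp$beta * sigma
    }
  }
  list(core = core, grewA = grewA, grewS = grewS)
}

# Sequential presentation of the chosen tokens followed by phase-end link
# forgetting driven by possible-link growth.
.corePhase <- function(core, audioM, semM, idx, pp) {
  growth <- 0L
  for (t in idx) {
    r <- .coreTrainToken(core, audioM[, t], semM[, t], pp)
    core <- r$core
    growth <- growth + r$grewA + r$grewS
  }
  ncurr <- as.numeric(ncol(core$A$w)) * ncol(core$S$w)
  frate <- (ncurr - core$L$prev) / ncurr
  core$L$w <- core$L$w * (1 - frate)
  core$L$prev <- ncurr
  list(core = core, growthEvents = growth, forgettingRate = frate)
}

#' Train the model on a single paired token
#'
#' Presents one audio activation vector to the auditory map and the paired
#' binary semantic vector to the semantic map: learning rate and
#' neighborhood size are reset to the phase's initial values, the BMU is
#' identified once in each map, a saturated boundary BMU grows immediately
#' (skipping the inner loop for that map), and otherwise the inner loop runs
#' while \code{sigma >= 1}: Gaussian neighborhood weight update and error
#' accumulation when the BMU's accumulated error is within the growth
#' threshold, error distribution when a saturated BMU is interior, one
#' associative-link reinforcement between the two BMUs per iteration, then
#' learning-rate and neighborhood decay.
#'
#' @param model an [IGsomModel-class].
#' @param audio numeric vector matching the auditory map's input dimension.
#' @param semantic numeric (binary) vector matching the semantic map's
#'   input dimension.
#' @param params a [PhaseParams-class].
#' @return list with \code{model} (updated), \code{grewAudio},
#'   \code{grewSemantic} (logical growth flags).
#' @export
trainToken <- function(model, audio, semantic, params) {
  if (length(audio) != model@auditory@inputDim ||
      length(semantic) != model@semantic@inputDim)
    stop("token vector dimensions do not match the model's maps")
  core <- .modelCore(model)
  r <- .coreTrainToken(core, as.numeric(audio), as.numeric(semantic),
                       .ppList(params))
  list(model = .coreModel(r$core, model), grewAudio = r$grewA,
       grewSemantic = r$grewS)
}

#' Run one training phase
#'
#' Presents the selected tokens sequentially (in the given order) via the
#' token-level rule, then applies the phase-end link-forgetting step: the
#' forgetting rate is computed from the growth of the possible-link count
#' since the previous phase end and every link weight is scaled by
#' \code{1 - rate}.
#'
#' @param model an [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @param tokens integer token indices (default: all tokens in corpus
#'   order).
#' @param params a [PhaseParams-class].
#' @return list with \code{model} and \code{report} (node counts before and
#'   after per map, growth events, link count, forgetting rate).
#' @export
runPhase <- function(model, corpus, tokens = seq_len(nTokens(corpus)), params) {
  if (!length(tokens)) stop("token list must be non-empty")
  core <- .modelCore(model)
  before <- c(audio = ncol(core$A$w), semantic = ncol(core$S$w))
  res <- .corePhase(core, corpus@audio, .semTokenMatrix(corpus),
                    as.integer(tokens), .ppList(params))
  out <- .coreModel(res$core, model)
  list(model = out,
       report = list(
         nodesAudioBefore = unname(before["audio"]),
         nodesSemBefore = unname(before["semantic"]),
         nodesAudioAfter = nNodes(out@auditory),
         nodesSemAfter = nNodes(out@semantic),
         growthEvents = res$growthEvents,
         linkCount = length(out@links@weight),
         forgettingRate = res$forgettingRate))
}

#' Select tokens for a reinforcing phase
#'
#' Runs a (non-mutating) checking pass and returns, in original corpus
#' order and without duplicates, every token hosted by a high-density node
#' on either map: an auditory node representing more than
#' \code{densityThreshold} distinct syllables (or realizations, see
#' \code{countRealizations}) or whose mean distance to its represented audio
#' items exceeds \code{distanceThreshold}; analogously for words on the
#' semantic map.
#'
#' @param model an [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @param densityThreshold integer, default 4.
#' @param distanceThreshold numeric, default 2.5.
#' @param countRealizations logical: count token realizations instead of
#'   distinct syllables on the auditory map (default FALSE).
#' @param check optionally a precomputed [IGsomCheck-class] for this model
#'   and corpus (avoids recomputing the assignment pass).
#' @return integer vector of token indices (possibly empty).
#' @export
selectReinforcingTokens <- function(model, corpus, densityThreshold = 4L,
                                    distanceThreshold = 2.5,
                                    countRealizations = FALSE, check = NULL) {
  if (is.null(check)) check <- checkMaps(model, corpus)
  aStats <- check@audioNodeStats
  aCount <- if (countRealizations) aStats$tokens else aStats$items
  aBad <- aStats[aCount > densityThreshold |
                   aStats$meanDist > distanceThreshold, c("row", "col")]
  sStats <- check@semNodeStats
  sBad <- sStats[sStats$items > densityThreshold |
                   sStats$meanDist > distanceThreshold, c("row", "col")]
  aKey <- paste(check@audioAssign$row, check@audioAssign$col)
  tokA <- check@audioAssign$token[aKey %in% paste(aBad$row, aBad$col)]
  sKeyWord <- paste(check@semAssign$row, check@semAssign$col)
  badWords <- check@semAssign$wordId[sKeyWord %in% paste(sBad$row, sBad$col)]
  tokS <- which(corpus@wordId %in% badWords)
  sort(unique(c(tokA, tokS)))
}

#' Select tokens for a reinforcing-by-link phase
#'
#' Runs checking including perceiving-path link marks (with the
#' top-\code{fraction} weight filter) and returns, deduplicated and in
#' original order, every token whose auditory BMU carries an incorrect
#' winner link.
#'
#' @param model an [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @param fraction numeric in (0, 1]: link filter used during checking.
#' @param check optionally a precomputed, link-checked [IGsomCheck-class].
#' @return integer vector of token indices (possibly empty).
#' @export
selectLinkTokens <- function(model, corpus, fraction = 0.2, check = NULL) {
  if (is.null(check)) {
    check <- checkMaps(model, corpus)
    check <- checkLinks(model, check, corpus, fraction = fraction)
  }
  marks <- check@linkMarks
  bad <- marks[!marks$correct, c("row", "col")]
  aKey <- paste(check@audioAssign$row, check@audioAssign$col)
  sort(unique(check@audioAssign$token[aKey %in% paste(bad$row, bad$col)]))
}

# One metrics row (data.frame) for the current model state; `check` is the
# link-checked IGsomCheck for this state.
.metricsRow <- function(step, cycle, phase, tokensUsed, report, check) {
  m <- check@metrics
  data.frame(
    step = step, cycle = cycle, phase = phase, tokensUsed = tokensUsed,
    growthEvents = report$growthEvents, forgettingRate = report$forgettingRate,
    nodesAudio = m$nodesAudio, nodesSem = m$nodesSem,
    solidAudio = m$solidAudio, solidSem = m$solidSem,
    boundaryRatioAudio = m$boundaryRatioAudio,
    boundaryRatioSem = m$boundaryRatioSem,
    avgItemsAudio = m$avgItemsAudio, avgItemsSem = m$avgItemsSem,
    maxItemsAudio = m$maxItemsAudio, maxItemsSem = m$maxItemsSem,
    linkCount = m$linkCount, linkAccuracy = m$linkAccuracy,
    stringsAsFactors = FALSE)
}

.checkedState <- function(model, corpus, fraction) {
  check <- checkMaps(model, corpus)
  check <- checkLinks(model, check, corpus, fraction = fraction)
  summarizeCheck(model, check)
}

.emptyReport <- list(growthEvents = 0L, forgettingRate = 0)

#' Fundamental training: basic growing plus cyclical reinforcing/reviewing
#'
#' Step 1 trains the fresh model on the full corpus with the growing
#' parameters. Each following cycle runs a reinforcing phase on the tokens
#' selected by the high-density rules (skipped as a no-op when the
#' selection is empty) and a reviewing phase on the complete corpus. With
#' the default 15 cycles this yields 31 steps. After every phase a checking
#' pass records the summary metrics (node counts, solid nodes, boundary
#' ratios, items per solid node, link count and perceiving-path link
#' accuracy).
#'
#' @param model a fresh [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @param config a [ScheduleConfig-class].
#' @param verbose logical: report phase transitions via [message()].
#' @return list with \code{model} (trained) and \code{metrics} (one
#'   data.frame row per step).
#' @export
runFundamentalTraining <- function(model, corpus, config = defaultSchedule(),
                                   verbose = FALSE) {
  rows <- vector("list", 1L + 2L * config@fundamentalCycles)
  step <- 1L
  if (verbose) message("step 1: basic growing phase (", nTokens(corpus), " tokens)")
  ph <- runPhase(model, corpus, params = config@growing)
  model <- ph$model
  check <- .checkedState(model, corpus, fraction = 1)
  rows[[1L]] <- .metricsRow(1L, 0L, "growing", nTokens(corpus), ph$report, check)
  for (cyc in seq_len(config@fundamentalCycles)) {
    sel <- selectReinforcingTokens(model, corpus,
                                   densityThreshold = config@densityThreshold,
                                   distanceThreshold = config@distanceThreshold,
                                   countRealizations = config@countRealizations,
                                   check = check)
    step <- step + 1L
    if (length(sel)) {
      if (verbose) message("step ", step, ": reinforcing phase (", length(sel), " tokens)")
      ph <- runPhase(model, corpus, sel, config@reinforcing)
      model <- ph$model
      check <- .checkedState(model, corpus, fraction = 1)
      rows[[step]] <- .metricsRow(step, cyc, "reinforcing", length(sel),
                                  ph$report, check)
    } else {
      if (verbose) message("step ", step, ": reinforcing phase skipped (empty selection)")
      rows[[step]] <- .metricsRow(step, cyc, "reinforcing", 0L, .emptyReport,
                                  check)
    }
    step <- step + 1L
    if (verbose) message("step ", step, ": reviewing phase (", nTokens(corpus), " tokens)")
    ph <- runPhase(model, corpus, params = config@reviewing)
    model <- ph$model
    check <- .checkedState(model, corpus, fraction = 1)
    rows[[step]] <- .metricsRow(step, cyc, "reviewing", nTokens(corpus),
                                ph$report, check)
  }
  list(model = model, metrics = do.call(rbind, rows))
}

#' Follow-on experiment cycles, with or without reinforcing-by-link
#'
#' Starting from a fundamentally trained model, runs
#' \code{config@experimentCycles} cycles. Without link training each cycle
#' is a reinforcing phase (high-density selection) followed by a reviewing
#' phase on the full corpus. With link training, a reinforcing-by-link
#' phase on the tokens implicated in incorrect winner links precedes the
#' pair, and checking applies the top-\code{linkCheckFraction} link filter.
#' Link accuracy is recorded after every phase.
#'
#' @param model a trained [IGsomModel-class].
#' @param corpus an [IGsomCorpus-class].
#' @param config a [ScheduleConfig-class]; \code{withLinkTraining} selects
#'   the cycle structure.
#' @param startStep integer label for the first emitted step row (default
#'   32, continuing the 31 fundamental steps).
#' @param verbose logical.
#' @return list with \code{model} and \code{metrics} (one row per phase;
#'   the reviewing row closes each cycle).
#' @export
runExperiment <- function(model, corpus, config, startStep = 32L,
                          verbose = FALSE) {
  frac <- if (config@withLinkTraining) config@linkCheckFraction else 1
  rows <- list()
  step <- startStep - 1L
  check <- .checkedState(model, corpus, fraction = frac)
  for (cyc in seq_len(config@experimentCycles)) {
    if (config@withLinkTraining) {
      sel <- selectLinkTokens(model, corpus, fraction = frac, check = check)
      step <- step + 1L
      if (length(sel)) {
        if (verbose) message("step ", step, ": reinforcing-by-link phase (",
                             length(sel), " tokens)")
        ph <- runPhase(model, corpus, sel, config@reinforcingByLink)
        model <- ph$model
        check <- .checkedState(model, corpus, fraction = frac)
        rows[[length(rows) + 1L]] <-
          .metricsRow(step, cyc, "reinforcing-by-link", length(sel),
                      ph$report, check)
      } else {
        if (verbose) message("step ", step, ": reinforcing-by-link skipped")
        rows[[length(rows) + 1L]] <-
          .metricsRow(step, cyc, "reinforcing-by-link", 0L, .emptyReport, check)
      }
    }
    sel <- selectReinforcingTokens(model, corpus,
                                   densityThreshold = config@densityThreshold,
                                   distanceThreshold = config@distanceThreshold,
                                   countRealizations = config@countRealizations,
                                   check = check)
    step <- step + 1L
    if (length(sel)) {
      if (verbose) message("step ", step, ": reinforcing phase (", length(sel), " tokens)")
      ph <- runPhase(model, corpus, sel, config@reinforcing)
      model <- ph$model
      check <- .checkedState(model, corpus, fraction = frac)
      rows[[length(rows) + 1L]] <-
        .metricsRow(step, cyc, "reinforcing", length(sel), ph$report, check)
    } else {
      if (verbose) message("step ", step, ": reinforcing phase skipped")
      rows[[length(rows) + 1L]] <-
        .metricsRow(step, cyc, "reinforcing", 0L, .emptyReport, check)
    }
    step <- step + 1L
    if (verbose) message("step ", step, ": reviewing phase (", nTokens(corpus), " tokens)")
    ph <- runPhase(model, corpus, params = config@reviewing)
    model <- ph$model
    check <- .checkedState(model, corpus, fraction = frac)
    rows[[length(rows) + 1L]] <-
      .metricsRow(step, cyc, "reviewing", nTokens(corpus), ph$report, check)
  }
  list(model = model, metrics = do.call(rbind, rows))
}
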