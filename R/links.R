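# Associative links between the two maps: reinforcement, forgetting,
# winner-link selection and the top-fraction checking filter.

.linkKey <- function(ar, ac, sr, sc) paste(ar, ac, sr, sc, sep = ",")

.linkCore <- function(reg) {
  list(a = reg@audioPos, s = reg@semPos, w = reg@weight,
       keys = .linkKey(reg@audioPos[, 1L], reg@audioPos[, 2L],
                       reg@semPos[, 1L], reg@semPos[, 2L]),
       prev = reg@prevPossible, L = reg@increment, w0 = reg@initWeight)
}

.coreRegistry <- function(lc) {
  new("LinkRegistry", audioPos = lc$a, semPos = lc$s, weight = lc$w,
      prevPossible = as.integer(lc$prev), increment = lc$L, initWeight = lc$w0)
}

.coreReinforce <- function(lc, apos, spos) {
  key <- .linkKey(apos[1L], apos[2L], spos[1L], spos[2L])
  i <- match(key, lc$keys)
  if (is.na(i)) {
    lc$a <- rbind(lc$a, as.integer(apos))
    lc$s <- rbind(lc$s, as.integer(spos))
    lc$w <- c(lc$w, lc$w0)
    lc$keys <- c(lc$keys, key)
  } else {
    lc$w[i] <- lc$w[i] + lc$L
  }
  lc
}

#' Reinforce (or create) an associative link
#'
#' If a link between the two node positions exists its weight increases by
#' the constant \code{L}; otherwise a new link is created with the initial
#' weight (0.1 by default).
#'
#' @param registry a [LinkRegistry-class].
#' @param audioPos integer c(row, col) in the auditory map.
#' @param semanticPos integer c(row, col) in the semantic map.
#' @return list with \code{registry} (updated) and \code{weight} (the
#'   resulting link weight).
#' @examples
#' r <- LinkRegistry()
#' r <- reinforceLink(r, c(0, 0), c(1, 1))$registry
#' reinforceLink(r, c(0, 0), c(1, 1))$weight  # 0.2
#' @export
reinforceLink <- function(registry, audioPos, semanticPos) {
  lc <- .linkCore(registry)
  lc <- .coreReinforce(lc, as.integer(audioPos), as.integer(semanticPos))
  key <- .linkKey(audioPos[1L], audioPos[2L], semanticPos[1L], semanticPos[2L])
  list(registry = .coreRegistry(lc), weight = lc$w[match(key, lc$keys)])
}

#' Number of possible links between two maps
#'
#' The product of the two maps' node counts; 4 x 4 = 16 at initialization.
#' Its relative growth between phase ends drives the forgetting rate.
#'
#' @param auditory,semantic [GrowingMap-class] objects.
#' @return positive integer (as numeric to avoid overflow on large maps).
#' @export
possibleLinkCount <- function(auditory, semantic) {
  as.numeric(nNodes(auditory)) * nNodes(semantic)
}

#' Link-forgetting rate from possible-link growth
#'
#' \code{(n_curr - n_prev) / n_curr}: zero when no node was added since the
#' previous phase end, approaching 1 under explosive growth. Maps never
#' shrink, so \code{n_curr < n_prev} is an error.
#'
#' @param nPrev possible-link count at the previous phase end.
#' @param nCurr current possible-link count.
#' @return numeric in [0, 1).
#' @examples
#' forgettingRate(16, 20)  # 0.2
#' @export
forgettingRate <- function(nPrev, nCurr) {
  if (nPrev < 1 || nCurr < nPrev)
    stop("need nCurr >= nPrev >= 1 (maps never shrink)")
  (nCurr - nPrev) / nCurr
}

#' Apply link forgetting
#'
#' Multiplies every link weight by \code{1 - rate} and records the current
#' possible-link count as the new baseline. Relative weight order is
#' preserved and weights stay strictly positive (no pruning).
#'
#' @param registry a [LinkRegistry-class].
#' @param rate numeric in [0, 1).
#' @param currentPossible the possible-link count to record as the new
#'   \code{prevPossible} baseline (defaults to keeping the old one, for
#'   isolated use of the decay itself).
#' @return the updated [LinkRegistry-class].
#' @export
applyForgetting <- function(registry, rate,
                            currentPossible = registry@prevPossible) {
  if (rate < 0 || rate >= 1) stop("forgetting rate must lie in [0, 1)")
  registry@weight <- registry@weight * (1 - rate)
  registry@prevPossible <- as.integer(currentPossible)
  registry
}

# Winner link on the core: index of max-weight link from audio node
# (ar, ac) among link indices `use`; ties broken by lexicographic semantic
# position. Returns NA if none.
.coreWinner <- function(lc, ar, ac, use = seq_along(lc$w)) {
  from <- use[lc$a[use, 1L] == ar & lc$a[use, 2L] == ac]
  if (!length(from)) return(NA_integer_)
  mw <- max(lc$w[from])
  cand <- from[lc$w[from] == mw]
  if (length(cand) > 1L)
    cand <- cand[order(lc$s[cand, 1L], lc$s[cand, 2L])]
  cand[1L]
}

#' Winner link of an auditory node
#'
#' Among all links originating at the given auditory-map position, the one
#' with maximum weight (ties broken by lexicographic semantic position);
#' \code{NULL} if the node has no outgoing links.
#'
#' @param registry a [LinkRegistry-class].
#' @param audioPos integer c(row, col).
#' @return \code{NULL}, or a list with \code{audioPos}, \code{semanticPos},
#'   \code{weight}.
#' @export
winnerLink <- function(registry, audioPos) {
  lc <- .linkCore(registry)
  i <- .coreWinner(lc, as.integer(audioPos[1L]), as.integer(audioPos[2L]))
  if (is.na(i)) return(NULL)
  list(audioPos = lc$a[i, ], semanticPos = lc$s[i, ], weight = lc$w[i])
}

# Indices of the ceil(fraction * k) highest-weight links, deterministic
# tie-break by (audio pos, semantic pos) lexicographic order.
.coreTopIdx <- function(lc, fraction) {
  k <- length(lc$w)
  if (k == 0L) return(integer(0))
  keep <- ceiling(fraction * k)
  ord <- order(-lc$w, lc$a[, 1L], lc$a[, 2L], lc$s[, 1L], lc$s[, 2L])
  sort(ord[seq_len(keep)])  # registry order, view semantics
}

#' Top-fraction link filter
#'
#' Returns the \code{ceiling(fraction * k)} highest-weight links as a new
#' registry view (the input registry is unchanged). Ties at the cutoff are
#' resolved deterministically by lexicographic position order. Used during
#' checking when many weak links would otherwise dilute winner-link
#' selection.
#'
#' @param registry a [LinkRegistry-class].
#' @param fraction numeric in (0, 1]; 1 keeps everything.
#' @return a [LinkRegistry-class] holding only the retained links.
#' @export
topFractionFilter <- function(registry, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  lc <- .linkCore(registry)
  idx <- .coreTopIdx(lc, fraction)
  new("LinkRegistry",
      audioPos = lc$a[idx, , drop = FALSE], semPos = lc$s[idx, , drop = FALSE],
      weight = lc$w[idx], prevPossible = registry@prevPossible,
      increment = registry@increment, initWeight = registry@initWeight)
}
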