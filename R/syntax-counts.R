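#' First-order transition counts of a coded corpus
#'
#' Counts every observable transition type over \code{\link{USV_STATES}} for
#' one animal in one context. Each coded sequence \code{a1...aL} contributes
#' silence-to-a1, the L-1 internal transitions, and aL-to-silence — L+1
#' transitions in total. The silence-to-silence cell is structurally excluded
#' (\code{NA}), leaving the 24 transition types.
#'
#' @param coded character vector of coded sequences (strings over s/d/u/m).
#' @param animalId,context identifiers stored on the result.
#' @return A \linkS4class{TransitionCounts}.
#' @examples
#' transCounts(transitionCounts("ssdm"))
#' @export
transitionCounts <- function(coded, animalId = NA_character_,
                             context = NA_character_) {
  m <- matrix(0L, 5L, 5L, dimnames = list(USV_STATES, USV_STATES))
  labels <- parseCoded(coded[nzchar(coded)])
  for (labs in labels) {
    path <- c("X", labs, "X")
    for (i in seq_len(length(path) - 1L))
      m[path[i], path[i + 1L]] <- m[path[i], path[i + 1L]] + 1L
  }
  m["X", "X"] <- NA_integer_
  new("TransitionCounts", counts = m, animalId = animalId, context = context)
}

#' Conditional transition probabilities (row normalization)
#'
#' The probability of each transition type given its starting state: each
#' count divided by the total count of transitions with the same start.
#' Start states never observed yield undefined (\code{NA}) rows.
#'
#' @param counts a \linkS4class{TransitionCounts}.
#' @return A \linkS4class{TransitionProbabilities}.
#' @export
conditionalProbabilities <- function(counts) {
  m <- counts@counts
  tot <- rowSums(m, na.rm = TRUE)
  p <- matrix(NA_real_, 5L, 5L, dimnames = dimnames(m))
  for (a in USV_STATES) {
    if (tot[a] > 0) {
      p[a, ] <- m[a, ] / tot[a]
      if (a == "X") p["X", "X"] <- NA_real_
    }
  }
  new("TransitionProbabilities", probs = p, rowTotals = as.numeric(tot),
      animalId = counts@animalId, context = counts@context)
}

#' Per-animal probability matrices from a corpus list
#'
#' Convenience wrapper: coded corpora (one character vector per animal) to a
#' list of conditional probability matrices.
#'
#' @param corpora named list of coded-sequence character vectors, one per
#'   animal.
#' @param context context label stored on the results.
#' @return named list of \linkS4class{TransitionProbabilities}.
#' @export
animalProbabilities <- function(corpora, context = NA_character_) {
  ids <- names(corpora)
  if (is.null(ids)) ids <- paste0("animal", seq_along(corpora))
  out <- lapply(seq_along(corpora), function(i)
    conditionalProbabilities(
      transitionCounts(corpora[[i]], animalId = ids[i], context = context)))
  names(out) <- ids
  out
}

#' Group-mean conditional probabilities
#'
#' Cellwise unweighted mean over animals, excluding per row the animals for
#' which that row is undefined (no transitions from that start state).
#'
#' @param matrices list of \linkS4class{TransitionProbabilities} (or plain
#'   5 x 5 matrices).
#' @return list with \code{mean} (5 x 5 matrix, NA where no animal
#'   contributes) and \code{n} (contributing animals per cell).
#' @export
groupMeanProbabilities <- function(matrices) {
  mats <- lapply(matrices, function(x)
    if (is(x, "TransitionProbabilities")) x@probs else x)
  arr <- array(unlist(mats), dim = c(5L, 5L, length(mats)))
  mu <- apply(arr, c(1L, 2L), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  n <- apply(arr, c(1L, 2L), function(v) sum(!is.na(v)))
  dimnames(mu) <- dimnames(n) <- list(USV_STATES, USV_STATES)
  n["X", "X"] <- 0L
  mu["X", "X"] <- NA_real_
  list(mean = mu, n = n)
}

#' Rectangular p-value table of a syntax comparison
#'
#' Rows are start states plus a combined "to" margin, columns end states plus
#' a combined "from" margin; the corner holds the global p-value. Written as
#' plotted in transition heat maps: inner cells are local test p-values,
#' margins the combined to/from tests.
#'
#' @param result a \linkS4class{SyntaxTestResult}.
#' @param adjusted use BH-adjusted margin p-values (default FALSE).
#' @return 6 x 6 data.frame.
#' @export
heatmapTable <- function(result, adjusted = FALSE) {
  local <- result@localP
  toV <- if (adjusted) result@toPAdj else result@toP
  fromV <- if (adjusted) result@fromPAdj else result@fromP
  out <- rbind(cbind(local, from_combined = fromV),
               to_combined = c(toV, result@globalP))
  as.data.frame(out)
}
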