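#' Export a syntax diagram in Graphviz DOT format
#'
#' Renders a group-context conditional-probability matrix as a directed graph:
#' nodes are the four syllable types and silence, edges the transitions with
#' probability strictly above the cutoff (0.05 by default, so that only
#' transitions the animals commonly produce appear). Edge pen width is
#' proportional to the conditional probability; probabilities are annotated
#' as edge labels to two decimals.
#'
#' @param probs 5 x 5 conditional probability matrix over
#'   \code{\link{USV_STATES}} (e.g. \code{groupMeanProbabilities(...)$mean}),
#'   or a \linkS4class{TransitionProbabilities}.
#' @param cutoff edges require probability strictly greater than this
#'   (default 0.05).
#' @param thickness pen-width scale in pixels per unit probability
#'   (default 8).
#' @param splitSilence draw separate begin-silence and end-silence nodes
#'   (some published diagrams split them; default FALSE, one silence node).
#' @param name graph name.
#' @return character scalar: the DOT document.
#' @examples
#' p <- conditionalProbabilities(transitionCounts(c("ssdm", "ssd")))
#' cat(syntaxDot(p))
#' @export
syntaxDot <- function(probs, cutoff = 0.05, thickness = 8,
                      splitSilence = FALSE, name = "syntax") {
  stopifnot(cutoff >= 0, cutoff <= 1, thickness > 0)
  if (is(probs, "TransitionProbabilities")) probs <- probs@probs
  nodeName <- function(st, role) {
    if (st != "X") return(st)
    if (!splitSilence) return("silence")
    if (role == "from") "begin_silence" else "end_silence"
  }
  nodes <- if (splitSilence)
    c("begin_silence", setdiff(USV_STATES, "X"), "end_silence")
  else c(setdiff(USV_STATES, "X"), "silence")
  lines <- c(sprintf("digraph %s {", name),
             "  rankdir=LR;",
             sprintf("  %s [shape=circle];", nodes))
  for (a in USV_STATES) for (b in USV_STATES) {
    if (a == "X" && b == "X") next
    p <- probs[a, b]
    if (is.na(p) || p <= cutoff) next
    lines <- c(lines, sprintf(
      "  %s -> %s [penwidth=%.3f, label=\"%.2f\"];",
      nodeName(a, "from"), nodeName(b, "to"), p * thickness, p))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Count the edges a DOT syntax diagram contains
#'
#' Structural helper used for checking diagrams.
#'
#' @param dot DOT document from \code{\link{syntaxDot}}.
#' @return integer edge count.
#' @export
dotEdgeCount <- function(dot) {
  length(gregexpr("->", dot, fixed = TRUE)[[1L]]) -
    (gregexpr("->", dot, fixed = TRUE)[[1L]][1L] == -1L)
}
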