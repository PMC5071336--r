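#' Inter-syllable interval distribution
#'
#' Gaps between consecutive syllables (onset of the next minus offset of the
#' previous), with a histogram on log-spaced bins for inspecting the short /
#' medium / long interval structure of a session.
#'
#' @param events data.frame with \code{onset_s} and \code{offset_s}, sorted by
#'   onset and non-overlapping (e.g. from \code{\link{detectSyllableEvents}}).
#' @param nBins number of log-spaced histogram bins.
#' @return list with \code{gaps_ms} (numeric, empty when fewer than two
#'   events), \code{breaks_ms} and \code{counts} of the log-binned histogram.
#' @export
isiDistribution <- function(events, nBins = 30L) {
  if (nrow(events) < 2L)
    return(list(gaps_ms = numeric(), breaks_ms = numeric(),
                counts = integer()))
  stopifnot(!is.unsorted(events$onset_s))
  gaps <- (events$onset_s[-1L] - events$offset_s[-nrow(events)]) * 1000
  pos <- gaps[gaps > 0]
  if (!length(pos))
    return(list(gaps_ms = gaps, breaks_ms = numeric(), counts = integer()))
  breaks <- exp(seq(log(min(pos)) - 1e-9, log(max(pos)) + 1e-9,
                    length.out = nBins + 1L))
  h <- hist(pos, breaks = breaks, plot = FALSE)
  list(gaps_ms = gaps, breaks_ms = breaks, counts = h$counts)
}

#' Segment syllable events into song sequences
#'
#' A new sequence (song bout) starts whenever the silent gap before a syllable
#' reaches the break threshold; the field-standard break is 250 ms, and a gap
#' exactly at the threshold splits ("250 ms or more"). Unclassified syllables
#' must already have been removed.
#'
#' @param events data.frame with \code{onset_s}, \code{offset_s},
#'   \code{label}; sorted, non-overlapping.
#' @param breakMs sequence-break threshold in ms (default 250).
#' @return \code{events} with an added integer column \code{bout_index}.
#' @examples
#' ev <- data.frame(onset_s = c(0, 0.1, 0.5, 0.6),
#'                  offset_s = c(0.05, 0.15, 0.55, 0.65),
#'                  label = c("s", "s", "d", "m"))
#' segmentIntoSequences(ev, breakMs = 250)
#' @export
segmentIntoSequences <- function(events, breakMs = 250) {
  if (!nrow(events)) {
    events$bout_index <- integer()
    return(events)
  }
  stopifnot(!is.unsorted(events$onset_s))
  gaps <- c(Inf, (events$onset_s[-1L] - events$offset_s[-nrow(events)]) * 1000)
  events$bout_index <- cumsum(gaps >= breakMs)
  events
}

#' Letter-code segmented sequences
#'
#' One string over the syllable alphabet per sequence; the silence separating
#' sequences is implicit in the string boundaries (each coded sequence starts
#' and ends at silence).
#'
#' @param events segmented events (output of
#'   \code{\link{segmentIntoSequences}}).
#' @return character vector, one coded string per bout, named by bout index.
#' @export
letterCode <- function(events) {
  if (!nrow(events)) return(character())
  bad <- setdiff(unique(events$label), setdiff(USV_STATES, "X"))
  if (length(bad))
    stop("unknown syllable label(s): ", paste(bad, collapse = ", "),
         " (unclassified syllables must be removed before coding)")
  vapply(split(events$label, events$bout_index),
         paste, character(1L), collapse = "")
}

#' Parse coded sequences back into per-syllable labels
#'
#' Inverse of \code{\link{letterCode}}.
#'
#' @param coded character vector of coded sequences.
#' @return list of character vectors of single-letter labels.
#' @export
parseCoded <- function(coded) {
  out <- strsplit(coded, "")
  bad <- setdiff(unique(unlist(out)), setdiff(USV_STATES, "X"))
  if (length(bad))
    stop("unknown syllable label(s) in coded corpus: ",
         paste(bad, collapse = ", "))
  out
}

#' Ratio of complex to simple song sequences
#'
#' Number of sequences containing at least two "m" (multi-jump) syllables
#' divided by the number containing one or none. Sequences of two syllables
#' or fewer are excluded from both counts. An undefined ratio (no simple
#' sequences) is returned as \code{NA} with the counts intact.
#'
#' @param coded character vector of coded sequences.
#' @return list with \code{ratio}, \code{nComplex}, \code{nSimple},
#'   \code{nEligible}.
#' @examples
#' complexSimpleRatio(c("smm", "smmm", "sss", "ssm", "sds", "mm"))
#' @export
complexSimpleRatio <- function(coded) {
  eligible <- coded[nchar(coded) >= 3L]
  mCount <- vapply(strsplit(eligible, ""), function(x) sum(x == "m"),
                   integer(1L))
  nComplex <- sum(mCount >= 2L)
  nSimple <- sum(mCount <= 1L)
  list(ratio = if (nSimple > 0L) nComplex / nSimple else NA_real_,
       nComplex = nComplex, nSimple = nSimple,
       nEligible = length(eligible))
}

#' Per-session summary statistics
#'
#' Syllable production rate, repertoire composition over the four classified
#' categories, sequence count and mean sequence length (syllables per
#' sequence, regardless of duration), and the complex/simple sequence ratio.
#'
#' @param events segmented classified events (with \code{bout_index}).
#' @param sessionMinutes session duration in minutes.
#' @param animalId,context identifiers copied into the output.
#' @return one-row data.frame.
#' @export
sessionSummary <- function(events, sessionMinutes,
                           animalId = NA_character_,
                           context = NA_character_) {
  stopifnot(sessionMinutes > 0)
  total <- nrow(events)
  coded <- letterCode(events)
  props <- if (total > 0L) {
    tab <- table(factor(events$label, levels = c("s", "d", "u", "m")))
    as.numeric(tab) / total
  } else rep(NA_real_, 4L)
  csr <- complexSimpleRatio(coded)
  data.frame(
    animal_id = animalId, context = context,
    session_minutes = sessionMinutes,
    total_syllables = total,
    syllable_rate = total / sessionMinutes,
    prop_s = props[1L], prop_d = props[2L], prop_u = props[3L],
    prop_m = props[4L],
    n_sequences = length(coded),
    mean_seq_length = if (length(coded)) total / length(coded) else NA_real_,
    complex_simple_ratio = csr$ratio)
}

#' Correlation between sequence length and syllable rate across animals
#'
#' Spearman rank correlation (mid-ranks for ties) of per-animal mean sequence
#' length against syllable production rate within one context.
#'
#' @param summaries data.frame of per-animal session summaries (needs
#'   \code{mean_seq_length} and \code{syllable_rate}).
#' @return list with \code{rho} and \code{p}.
#' @export
rateLengthCorrelation <- function(summaries) {
  ok <- stats::complete.cases(summaries[, c("mean_seq_length",
                                            "syllable_rate")])
  x <- summaries$mean_seq_length[ok]
  y <- summaries$syllable_rate[ok]
  if (length(x) < 3L)
    stop("at least 3 animals with defined rate and length are required")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
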