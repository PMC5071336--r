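#' @import methods
NULL

#' Syllable states used throughout the package
#'
#' The four classified syllable categories plus \code{"X"}, the silence state
#' that begins and ends every song sequence. The silence-to-silence pair is
#' structurally excluded, leaving 24 observable transition types.
#'
#' @format Character vector of length 5: \code{c("s","d","u","m","X")}.
#' @export
USV_STATES <- c("s", "d", "u", "m", "X")

## number of observable first-order transition types: 5 x 5 minus (X,X)
N_TRANSITION_TYPES <- length(USV_STATES)^2 - 1L

#' Sonogram analysis configuration
#'
#' Holds every tunable of the syllable detection stage: spectrogram geometry,
#' analysis band, noise-floor rule, temporal criteria and the pitch-jump
#' classification threshold.
#'
#' @slot blockSize samples per transform block (default 256).
#' @slot overlap fraction of a block shared by consecutive blocks (default 0.5).
#' @slot bandLowKHz,bandHighKHz analysis band in kHz (defaults 35 and 125).
#' @slot noiseK multiplier k of the per-row robust noise rule: cells below
#'   \code{exp(median(log p) + k * mad(log p))} are zeroed (default 5).
#' @slot dynamicRangeDb absolute floor: cells more than this many dB below the
#'   sonogram's peak cell are zeroed regardless of the row rule (default 80).
#' @slot minSilenceMs minimum silent gap separating two syllables (default 10).
#' @slot minSyllableMs minimum syllable duration (default 3).
#' @slot pitchJumpMinKHz minimum instantaneous peak-frequency step counted as a
#'   pitch jump (default 10).
#' @slot window analysis window, \code{"rectangular"} or \code{"hann"}.
#' @slot bridgeFrames pitch-track gaps of at most this many missing frames are
#'   bridged when scoring jumps (default 3).
#' @slot minDefinedFraction syllables whose fraction of defined pitch frames is
#'   below this are labelled unclassified (default 0.5).
#' @slot minPurity syllables with spectral purity below this are labelled
#'   unclassified as broadband noise (default 0.1).
#' @export
setClass("SonogramConfig", representation(
  blockSize = "integer",
  overlap = "numeric",
  bandLowKHz = "numeric",
  bandHighKHz = "numeric",
  noiseK = "numeric",
  dynamicRangeDb = "numeric",
  minSilenceMs = "numeric",
  minSyllableMs = "numeric",
  pitchJumpMinKHz = "numeric",
  window = "character",
  bridgeFrames = "integer",
  minDefinedFraction = "numeric",
  minPurity = "numeric"
))

setValidity("SonogramConfig", function(object) {
  msg <- character()
  if (object@blockSize <= 0L) msg <- c(msg, "blockSize must be positive")
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must be in [0, 1)")
  if (object@bandLowKHz >= object@bandHighKHz)
    msg <- c(msg, "bandLowKHz must be below bandHighKHz")
  if (object@minSilenceMs <= 0) msg <- c(msg, "minSilenceMs must be positive")
  if (object@minSyllableMs <= 0) msg <- c(msg, "minSyllableMs must be positive")
  if (object@pitchJumpMinKHz <= 0)
    msg <- c(msg, "pitchJumpMinKHz must be positive")
  if (!object@window %in% c("rectangular", "hann"))
    msg <- c(msg, "window must be 'rectangular' or 'hann'")
  if (length(msg)) msg else TRUE
})

#' Create a sonogram configuration
#'
#' @param blockSize samples per block.
#' @param overlap fraction of block overlap between consecutive frames.
#' @param bandLowKHz,bandHighKHz analysis band (kHz).
#' @param noiseK robust-threshold multiplier (see \linkS4class{SonogramConfig}).
#' @param dynamicRangeDb absolute dB floor below the sonogram peak.
#' @param minSilenceMs minimum silence separating syllables (ms).
#' @param minSyllableMs minimum syllable duration (ms).
#' @param pitchJumpMinKHz minimum frequency step scored as a pitch jump (kHz).
#' @param window "rectangular" (default) or "hann".
#' @param bridgeFrames maximum missing-frame run bridged when scoring jumps.
#' @param minDefinedFraction unclassified threshold on defined-frame fraction.
#' @param minPurity unclassified threshold on spectral purity.
#' @return A \linkS4class{SonogramConfig} object.
#' @examples
#' cfg <- sonogramConfig()
#' cfg
#' @export
sonogramConfig <- function(blockSize = 256L, overlap = 0.5,
                           bandLowKHz = 35, bandHighKHz = 125,
                           noiseK = 5, dynamicRangeDb = 80,
                           minSilenceMs = 10, minSyllableMs = 3,
                           pitchJumpMinKHz = 10, window = "rectangular",
                           bridgeFrames = 3L, minDefinedFraction = 0.5,
                           minPurity = 0.1) {
  new("SonogramConfig", blockSize = as.integer(blockSize), overlap = overlap,
      bandLowKHz = bandLowKHz, bandHighKHz = bandHighKHz, noiseK = noiseK,
      dynamicRangeDb = dynamicRangeDb, minSilenceMs = minSilenceMs,
      minSyllableMs = minSyllableMs, pitchJumpMinKHz = pitchJumpMinKHz,
      window = window, bridgeFrames = as.integer(bridgeFrames),
      minDefinedFraction = minDefinedFraction, minPurity = minPurity)
}

setMethod("show", "SonogramConfig", function(object) {
  cat("SonogramConfig\n",
      "  block ", object@blockSize, " samples, overlap ", object@overlap,
      ", window ", object@window, "\n",
      "  band ", object@bandLowKHz, "-", object@bandHighKHz, " kHz\n",
      "  noise rule: log-median + ", object@noiseK, " * log-MAD, floor ",
      object@dynamicRangeDb, " dB below peak\n",
      "  min silence ", object@minSilenceMs, " ms, min syllable ",
      object@minSyllableMs, " ms, pitch jump >= ", object@pitchJumpMinKHz,
      " kHz\n", sep = "")
})

#' Sonogram (power spectrogram)
#'
#' @slot power nonnegative power matrix, frequency bins x time frames.
#' @slot freqsKHz bin centre frequencies (kHz), strictly increasing.
#' @slot timesS frame centre times (s), constant step.
#' @slot frameStepS hop duration in seconds.
#' @export
setClass("Sonogram", representation(
  power = "matrix",
  freqsKHz = "numeric",
  timesS = "numeric",
  frameStepS = "numeric"
))

setValidity("Sonogram", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
  if (nrow(object@power) != length(object@freqsKHz))
    msg <- c(msg, "freqsKHz length must match power rows")
  if (ncol(object@power) != length(object@timesS))
    msg <- c(msg, "timesS length must match power columns")
  if (length(object@freqsKHz) > 1 && any(diff(object@freqsKHz) <= 0))
    msg <- c(msg, "freqsKHz must be strictly increasing")
  if (length(object@timesS) > 1 && any(diff(object@timesS) <= 0))
    msg <- c(msg, "timesS must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Masked (denoised, band-limited) sonogram
#'
#' Produced by \code{\link{denoiseSonogram}}. \code{power} holds the
#' thresholded in-band power used for voicing decisions and peak picking;
#' \code{rawPower} keeps the pre-threshold in-band power from which spectral
#' purity and amplitude are computed.
#'
#' @slot rawPower in-band power before thresholding.
#' @slot rowThreshold the per-row noise threshold actually applied.
#' @slot floorPower the absolute dynamic-range floor actually applied.
#' @export
setClass("MaskedSonogram", contains = "Sonogram", representation(
  rawPower = "matrix",
  rowThreshold = "numeric",
  floorPower = "numeric"
))

setMethod("show", "Sonogram", function(object) {
  cat(class(object), ": ", nrow(object@power), " bins x ",
      ncol(object@power), " frames, ",
      round(min(object@freqsKHz), 2), "-", round(max(object@freqsKHz), 2),
      " kHz, step ", signif(object@frameStepS * 1000, 4), " ms\n", sep = "")
})

#' Per-frame pitch track of one syllable
#'
#' @slot freqKHz per-frame peak frequency (kHz); \code{NA} where no in-band
#'   power survived thresholding.
#' @slot peakPower raw power at the peak bin per frame.
#' @slot totalPower raw total in-band power per frame.
#' @slot timesS frame centre times.
#' @slot frames frame indices into the parent sonogram.
#' @export
setClass("PitchTrack", representation(
  freqKHz = "numeric",
  peakPower = "numeric",
  totalPower = "numeric",
  timesS = "numeric",
  frames = "integer"
))

setValidity("PitchTrack", function(object) {
  n <- length(object@freqKHz)
  if (length(object@peakPower) != n || length(object@totalPower) != n ||
      length(object@timesS) != n || length(object@frames) != n)
    return("all PitchTrack slots must have equal length")
  TRUE
})

setMethod("show", "PitchTrack", function(object) {
  def <- sum(!is.na(object@freqKHz))
  cat("PitchTrack: ", length(object@freqKHz), " frames (", def, " defined)",
      if (def) paste0(", ", round(min(object@freqKHz, na.rm = TRUE), 1), "-",
                      round(max(object@freqKHz, na.rm = TRUE), 1), " kHz"),
      "\n", sep = "")
})

#' Transition counts for one animal in one context
#'
#' A 5 x 5 matrix of first-order transition counts over
#' \code{\link{USV_STATES}}; the structurally impossible silence-to-silence
#' cell is \code{NA}.
#'
#' @slot counts integer count matrix (rows = start state, cols = end state).
#' @slot animalId,context identifiers.
#' @export
setClass("TransitionCounts", representation(
  counts = "matrix",
  animalId = "character",
  context = "character"
))

setValidity("TransitionCounts", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(5L, 5L)))
    return("counts must be a 5 x 5 matrix")
  if (!identical(rownames(m), USV_STATES) || !identical(colnames(m), USV_STATES))
    return("counts must be indexed by USV_STATES")
  if (!is.na(m["X", "X"])) return("the silence-to-silence cell must be NA")
  v <- m[!is.na(m)]
  if (any(v < 0) || any(v != round(v)))
    return("counts must be nonnegative integers")
  TRUE
})

setMethod("show", "TransitionCounts", function(object) {
  cat("TransitionCounts for animal ", object@animalId, " (", object@context,
      "), total ", sum(object@counts, na.rm = TRUE), " transitions\n", sep = "")
  print(object@counts)
})

#' Conditional transition probabilities
#'
#' Row-normalized transition counts: the probability of each transition type
#' given its starting state. Rows with zero total count are undefined
#' (\code{NA}).
#'
#' @slot probs 5 x 5 probability matrix over \code{\link{USV_STATES}}.
#' @slot rowTotals total transitions per start state.
#' @slot animalId,context identifiers.
#' @export
setClass("TransitionProbabilities", representation(
  probs = "matrix",
  rowTotals = "numeric",
  animalId = "character",
  context = "character"
))

setValidity("TransitionProbabilities", function(object) {
  m <- object@probs
  if (!identical(dim(m), c(5L, 5L)))
    return("probs must be a 5 x 5 matrix")
  if (!identical(rownames(m), USV_STATES) || !identical(colnames(m), USV_STATES))
    return("probs must be indexed by USV_STATES")
  rs <- rowSums(m, na.rm = TRUE)
  defined <- apply(m, 1L, function(r) any(!is.na(r)))
  if (any(abs(rs[defined] - 1) > 1e-9))
    return("every defined row must sum to 1 within 1e-9")
  v <- m[!is.na(m)]
  if (any(v < -1e-12 | v > 1 + 1e-12))
    return("probabilities must lie in [0, 1]")
  TRUE
})

setMethod("show", "TransitionProbabilities", function(object) {
  cat("TransitionProbabilities for animal ", object@animalId, " (",
      object@context, ")\n", sep = "")
  print(round(object@probs, 3))
})

#' Result of a two-stage syntax comparison
#'
#' Local two-sided rank-test p-values for the 24 transition types, combined
#' to/from/global truncated-product statistics with permutation Monte Carlo
#' p-values, and BH-adjusted margin p-values.
#'
#' @slot comparison "two-sample" or "paired".
#' @slot localP 5 x 5 matrix of local p-values (NA at silence-to-silence and
#'   wherever too few defined values exist).
#' @slot toP,fromP named length-5 combined p-values per end / start state.
#' @slot globalP combined p-value over all 24 transition types.
#' @slot toPAdj,fromPAdj BH-adjusted margin p-values.
#' @slot nPerm,seed,tau test parameters.
#' @export
setClass("SyntaxTestResult", representation(
  comparison = "character",
  localP = "matrix",
  toP = "numeric",
  fromP = "numeric",
  globalP = "numeric",
  toPAdj = "numeric",
  fromPAdj = "numeric",
  nPerm = "integer",
  seed = "integer",
  tau = "numeric"
))

setValidity("SyntaxTestResult", function(object) {
  ok <- function(p) all(is.na(p) | (p > 0 & p <= 1))
  if (!ok(object@localP) || !ok(object@toP) || !ok(object@fromP) ||
      !ok(object@globalP))
    return("all p-values must lie in (0, 1] or be NA")
  if (any(!is.na(object@toPAdj) & object@toPAdj < object@toP - 1e-12) ||
      any(!is.na(object@fromPAdj) & object@fromPAdj < object@fromP - 1e-12))
    return("adjusted p-values must not be below raw ones")
  TRUE
})

setMethod("show", "SyntaxTestResult", function(object) {
  cat("SyntaxTestResult (", object@comparison, "), ", object@nPerm,
      " permutations, tau = ", object@tau, "\n", sep = "")
  cat("  global p = ", format.pval(object@globalP, digits = 4), "\n", sep = "")
  cat("  to:   ", paste(names(object@toP), format.pval(object@toP, digits = 3),
                        sep = "=", collapse = "  "), "\n", sep = "")
  cat("  from: ", paste(names(object@fromP),
                        format.pval(object@fromP, digits = 3),
                        sep = "=", collapse = "  "), "\n", sep = "")
})

#' Synthetic two-group cohort specification
#'
#' Generative parameters for a synthetic study: a baseline first-order syllable
#' chain, per-animal Dirichlet dispersion around the (possibly effect-modified)
#' group chain, and planted group effects.
#'
#' @slot nAnimals animals per group.
#' @slot contexts context labels to simulate.
#' @slot baseline row-stochastic 5 x 5 transition matrix over
#'   \code{\link{USV_STATES}} (silence-to-silence NA/0).
#' @slot concentration Dirichlet concentration applied rowwise: each animal row
#'   is drawn from Dirichlet(concentration * group row).
#' @slot toSilenceShift per-group additive probability shift toward silence
#'   applied to every syllable row (named numeric, one entry per group).
#' @slot mFactor per-group multiplicative factor on transitions into "m"
#'   (named numeric).
#' @slot seqPerAnimal sequences generated per animal-context.
#' @slot maxLength cap on the syllable count of a single generated sequence.
#' @export
setClass("SyntheticCohortSpec", representation(
  nAnimals = "integer",
  contexts = "character",
  baseline = "matrix",
  concentration = "numeric",
  toSilenceShift = "numeric",
  mFactor = "numeric",
  seqPerAnimal = "integer",
  maxLength = "integer"
))
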