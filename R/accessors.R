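#' Accessors for usvsyntax objects
#'
#' Slot access for the package's S4 classes without reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sonoPower", function(x) standardGeneric("sonoPower"))
#' @rdname accessors
#' @export
setMethod("sonoPower", "Sonogram", function(x) x@power)

#' @rdname accessors
#' @export
setGeneric("rawPower", function(x) standardGeneric("rawPower"))
#' @rdname accessors
#' @export
setMethod("rawPower", "MaskedSonogram", function(x) x@rawPower)

#' @rdname accessors
#' @export
setGeneric("sonoFreqs", function(x) standardGeneric("sonoFreqs"))
#' @rdname accessors
#' @export
setMethod("sonoFreqs", "Sonogram", function(x) x@freqsKHz)

#' @rdname accessors
#' @export
setGeneric("sonoTimes", function(x) standardGeneric("sonoTimes"))
#' @rdname accessors
#' @export
setMethod("sonoTimes", "Sonogram", function(x) x@timesS)

#' @rdname accessors
#' @export
setGeneric("frameStep", function(x) standardGeneric("frameStep"))
#' @rdname accessors
#' @export
setMethod("frameStep", "Sonogram", function(x) x@frameStepS)

#' @rdname accessors
#' @export
setGeneric("noiseThreshold", function(x) standardGeneric("noiseThreshold"))
#' @rdname accessors
#' @export
setMethod("noiseThreshold", "MaskedSonogram", function(x) x@rowThreshold)

#' @rdname accessors
#' @export
setGeneric("pitchFreqs", function(x) standardGeneric("pitchFreqs"))
#' @rdname accessors
#' @export
setMethod("pitchFreqs", "PitchTrack", function(x) x@freqKHz)

#' @rdname accessors
#' @export
setGeneric("transCounts", function(x) standardGeneric("transCounts"))
#' @rdname accessors
#' @export
setMethod("transCounts", "TransitionCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("transProbs", function(x) standardGeneric("transProbs"))
#' @rdname accessors
#' @export
setMethod("transProbs", "TransitionProbabilities", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("localP", function(x) standardGeneric("localP"))
#' @rdname accessors
#' @export
setMethod("localP", "SyntaxTestResult", function(x) x@localP)

#' @rdname accessors
#' @export
setGeneric("toP", function(x) standardGeneric("toP"))
#' @rdname accessors
#' @export
setMethod("toP", "SyntaxTestResult", function(x) x@toP)

#' @rdname accessors
#' @export
setGeneric("fromP", function(x) standardGeneric("fromP"))
#' @rdname accessors
#' @export
setMethod("fromP", "SyntaxTestResult", function(x) x@fromP)

#' @rdname accessors
#' @export
setGeneric("globalP", function(x) standardGeneric("globalP"))
#' @rdname accessors
#' @export
setMethod("globalP", "SyntaxTestResult", function(x) x@globalP)

#' @rdname accessors
#' @export
setGeneric("toPAdjusted", function(x) standardGeneric("toPAdjusted"))
#' @rdname accessors
#' @export
setMethod("toPAdjusted", "SyntaxTestResult", function(x) x@toPAdj)

#' @rdname accessors
#' @export
setGeneric("fromPAdjusted", function(x) standardGeneric("fromPAdjusted"))
#' @rdname accessors
#' @export
setMethod("fromPAdjusted", "SyntaxTestResult", function(x) x@fromPAdj)
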