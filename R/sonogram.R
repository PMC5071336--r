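#' Compute the power sonogram of a waveform
#'
#' Short-time power spectrum over sliding blocks (default 256 samples with half
#' overlap), the first stage of syllable detection. Frame timestamps are block
#' centres; the frame step is \code{blockSize * (1 - overlap) / rate}.
#'
#' @param wave numeric waveform.
#' @param rate sampling rate in Hz; must be at least twice the upper analysis
#'   band edge so the song band sits below Nyquist.
#' @param config a \code{\link{sonogramConfig}}.
#' @return A \linkS4class{Sonogram} covering 0 to Nyquist (band truncation
#'   happens in \code{\link{denoiseSonogram}}).
#' @examples
#' t <- seq(0, 0.05, by = 1 / 250000)
#' sono <- computeSonogram(sin(2 * pi * 70000 * t), 250000)
#' sono
#' @export
computeSonogram <- function(wave, rate, config = sonogramConfig()) {
  validObject(config)
  if (length(wave) == 0L)
    stop("empty waveform")
  minRate <- 2 * config@bandHighKHz * 1000
  if (rate < minRate)
    stop("sampling rate ", rate, " Hz is too low for a ", config@bandHighKHz,
         " kHz analysis band; at least ", minRate, " Hz is required")
  block <- config@blockSize
  if (length(wave) < block)
    stop("waveform shorter than one block (", block, " samples)")
  hop <- as.integer(round(block * (1 - config@overlap)))
  if (hop < 1L) stop("overlap too large: frame step below one sample")
  nFrames <- (length(wave) - block) %/% hop + 1L
  idx <- outer(seq_len(block), (seq_len(nFrames) - 1L) * hop, "+")
  frames <- matrix(wave[idx], nrow = block)
  if (config@window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(block) - 1L) / block)
    frames <- frames * w
  }
  sp <- stats::mvfft(frames)
  nBins <- block %/% 2L + 1L
  power <- Mod(sp[seq_len(nBins), , drop = FALSE])^2
  new("Sonogram",
      power = power,
      freqsKHz = (seq_len(nBins) - 1L) * rate / block / 1000,
      timesS = ((seq_len(nFrames) - 1L) * hop + block / 2) / rate,
      frameStepS = hop / rate)
}

## full-scale reference power: a unit-amplitude bin-centred sine under the
## configured window concentrates (sum(w)/2)^2 power in its bin
fullScalePower <- function(config) {
  block <- config@blockSize
  if (config@window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(block) - 1L) / block)
    (sum(w) / 2)^2
  } else {
    (block / 2)^2
  }
}

#' Band-limit a sonogram and zero the noise floor
#'
#' Truncates the sonogram to the USV song band and zeroes cells attributable
#' to noise. The threshold is robust and per frequency row: on the log-power
#' scale, cells below \code{median + noiseK * MAD} of their row are zeroed
#' (the MAD is one-sided, estimated from deviations below the row median, so
#' that syllable energy in a row cannot inflate its own threshold)
#' (power is clipped at a dynamic-range floor, \code{dynamicRangeDb} below the
#' sonogram peak, before the row statistics are taken; cells below that floor
#' are always zeroed). The log scale matters: spectrogram noise power is
#' approximately exponential, so a linear-scale MAD rule would leave several
#' percent of noise cells standing.
#'
#' @param sonogram a \linkS4class{Sonogram} from \code{\link{computeSonogram}}.
#' @param config a \code{\link{sonogramConfig}}.
#' @return A \linkS4class{MaskedSonogram}: thresholded in-band power plus the
#'   raw in-band power and the thresholds applied.
#' @export
denoiseSonogram <- function(sonogram, config = sonogramConfig()) {
  keep <- sonogram@freqsKHz >= config@bandLowKHz &
    sonogram@freqsKHz <= config@bandHighKHz
  if (!any(keep))
    stop("analysis band ", config@bandLowKHz, "-", config@bandHighKHz,
         " kHz lies outside the sonogram frequency range")
  raw <- sonogram@power[keep, , drop = FALSE]
  peak <- max(raw)
  if (peak == 0) {
    return(new("MaskedSonogram", power = raw, rawPower = raw,
               freqsKHz = sonogram@freqsKHz[keep], timesS = sonogram@timesS,
               frameStepS = sonogram@frameStepS,
               rowThreshold = numeric(nrow(raw)), floorPower = 0))
  }
  floorPower <- peak * 10^(-config@dynamicRangeDb / 10)
  lp <- log(pmax(raw, floorPower))
  med <- apply(lp, 1L, stats::median)
  ## one-sided (lower-half) MAD: syllable energy inflates only the upper tail,
  ## so the scale of the noise floor is estimated from deviations below the
  ## row median
  dev <- vapply(seq_len(nrow(lp)), function(r) {
    x <- lp[r, ]
    stats::median(med[r] - x[x <= med[r]]) * 1.4826
  }, numeric(1L))
  ## never let a row threshold sit at the clip floor itself: when most of a
  ## row clips there the scale estimate degenerates to zero and ambient noise
  ## just above the floor would survive
  thr <- pmax(exp(med + config@noiseK * dev), floorPower * 10)
  masked <- raw
  masked[raw < thr] <- 0
  new("MaskedSonogram", power = masked, rawPower = raw,
      freqsKHz = sonogram@freqsKHz[keep], timesS = sonogram@timesS,
      frameStepS = sonogram@frameStepS, rowThreshold = thr,
      floorPower = floorPower)
}

#' Detect syllables on a masked sonogram
#'
#' Frames with any surviving in-band power are voiced. Voiced runs separated
#' by silent gaps shorter than \code{minSilenceMs} are merged into one
#' syllable; merged runs shorter than \code{minSyllableMs} are discarded.
#'
#' Intervals are half-open in frame indexing (\code{offsetFrame} is one past
#' the last voiced frame). In seconds, \code{onset_s} and \code{offset_s} are
#' the centres of the first and last voiced frames: voicing spreads about half
#' a frame outward past the true edges of a sound, so frame centres are the
#' unbiased boundary estimate.
#'
#' @param masked a \linkS4class{MaskedSonogram}.
#' @param config a \code{\link{sonogramConfig}}.
#' @return data.frame with columns \code{onsetFrame}, \code{offsetFrame},
#'   \code{onset_s}, \code{offset_s}; zero rows when nothing is voiced.
#' @export
detectSyllables <- function(masked, config = sonogramConfig()) {
  voiced <- colSums(masked@power) > 0
  empty <- data.frame(onsetFrame = integer(), offsetFrame = integer(),
                      onset_s = numeric(), offset_s = numeric())
  if (!any(voiced)) return(empty)
  step <- masked@frameStepS
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  gaps <- data.frame(start = starts[!r$values], end = ends[!r$values])
  ## merge across internal silent gaps shorter than minSilenceMs
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gapFrames <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gapFrames * step * 1000 < config@minSilenceMs) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  dur <- (merged$end - merged$start + 1L) * step * 1000
  merged <- merged[dur >= config@minSyllableMs, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(onsetFrame = merged$start,
             offsetFrame = merged$end + 1L,
             onset_s = masked@timesS[merged$start],
             offset_s = masked@timesS[merged$end])
}

#' Extract the peak-frequency track of one syllable
#'
#' Per frame, the peak frequency is the in-band bin with maximal surviving
#' (thresholded) power; frames where no power survived are marked missing.
#' Peak and total power are taken from the raw (un-thresholded) in-band power
#' so that spectral purity keeps its meaning for noisy sounds; the peak power
#' covers the peak bin and its two neighbours, the tone's lobe at the
#' transform's frequency resolution.
#'
#' @param masked a \linkS4class{MaskedSonogram}.
#' @param onsetFrame,offsetFrame half-open frame interval of the syllable.
#' @return A \linkS4class{PitchTrack}.
#' @export
extractPitchTrack <- function(masked, onsetFrame, offsetFrame) {
  if (offsetFrame <= onsetFrame)
    stop("empty interval: offsetFrame must exceed onsetFrame")
  if (onsetFrame < 1L || offsetFrame > ncol(masked@power) + 1L)
    stop("interval outside sonogram time range")
  frames <- seq.int(onsetFrame, offsetFrame - 1L)
  sub <- masked@power[, frames, drop = FALSE]
  rawSub <- masked@rawPower[, frames, drop = FALSE]
  anyPow <- colSums(sub) > 0
  bin <- rep(NA_integer_, length(frames))
  bin[anyPow] <- apply(sub[, anyPow, drop = FALSE], 2L, which.max)
  freq <- ifelse(is.na(bin), NA_real_, masked@freqsKHz[bin])
  ## peak power = power in the peak lobe (peak bin and its two neighbours):
  ## at the transform's resolution a tone's power lands in a bin plus the
  ## leakage of the adjacent ones
  peakPow <- rep(NA_real_, length(frames))
  nb <- nrow(rawSub)
  for (j in which(anyPow)) {
    b <- bin[j]
    peakPow[j] <- sum(rawSub[max(1L, b - 1L):min(nb, b + 1L), j])
  }
  new("PitchTrack", freqKHz = freq, peakPower = peakPow,
      totalPower = colSums(rawSub), timesS = masked@timesS[frames],
      frames = as.integer(frames))
}

#' Classify a syllable from its pitch track
#'
#' A pitch jump is an instantaneous peak-frequency change of at least
#' \code{pitchJumpMinKHz} between consecutive defined frames. Runs of at most
#' \code{bridgeFrames} missing frames are bridged (the change is measured
#' across the gap); longer missing runs split the track into notes across
#' which no jump is scored. Labels follow the four-category scheme:
#' \code{"s"} no jumps, \code{"u"} exactly one upward jump, \code{"d"} exactly
#' one downward jump, \code{"m"} two or more jumps.
#'
#' @param track a \linkS4class{PitchTrack}.
#' @param config a \code{\link{sonogramConfig}}.
#' @return list with \code{label} (one of s/d/u/m/unclassified),
#'   \code{nJumps}, and \code{directions} (character vector of "up"/"down").
#' @export
classifySyllable <- function(track, config = sonogramConfig()) {
  f <- track@freqKHz
  def <- which(!is.na(f))
  if (!length(def))
    return(list(label = "unclassified", nJumps = NA_integer_,
                directions = character()))
  if (length(def) / length(f) < config@minDefinedFraction)
    return(list(label = "unclassified", nJumps = NA_integer_,
                directions = character()))
  directions <- character()
  if (length(def) > 1L) {
    for (i in seq_len(length(def) - 1L)) {
      gap <- def[i + 1L] - def[i] - 1L   # missing frames between the two
      if (gap > config@bridgeFrames) next
      d <- f[def[i + 1L]] - f[def[i]]
      if (abs(d) >= config@pitchJumpMinKHz)
        directions <- c(directions, if (d > 0) "up" else "down")
    }
  }
  n <- length(directions)
  label <- if (n == 0L) "s"
  else if (n == 1L && directions == "up") "u"
  else if (n == 1L) "d"
  else "m"
  list(label = label, nJumps = as.integer(n), directions = directions)
}

#' Acoustic features of one syllable
#'
#' Frequency statistics come from defined pitch-track frames; spectral purity
#' is the per-frame ratio of peak power to total in-band power averaged over
#' defined frames (1 for a pure tone, near 0 for white noise); amplitude is
#' the mean in-band power over the syllable in dB relative to the power of a
#' full-scale bin-centred sine.
#'
#' @param track a \linkS4class{PitchTrack}.
#' @param config a \code{\link{sonogramConfig}}.
#' @param frameStepS frame step in seconds (taken from the parent sonogram).
#' @return one-row data.frame with columns \code{duration_ms},
#'   \code{mean_freq_khz}, \code{min_freq_khz}, \code{max_freq_khz},
#'   \code{start_freq_khz}, \code{end_freq_khz}, \code{freq_modulation_khz},
#'   \code{spectral_purity}, \code{amplitude_db}, \code{bandwidth_khz}.
#' @export
extractFeatures <- function(track, config = sonogramConfig(),
                            frameStepS = diff(track@timesS[1:2])) {
  f <- track@freqKHz
  def <- which(!is.na(f))
  if (!length(def))
    stop("no defined pitch frames: syllable should have been unclassified")
  fd <- f[def]
  ratio <- track@peakPower[def] / track@totalPower[def]
  ratio <- ratio[is.finite(ratio)]
  meanPow <- mean(track@totalPower)
  data.frame(
    duration_ms = length(f) * frameStepS * 1000,
    mean_freq_khz = mean(fd),
    min_freq_khz = min(fd),
    max_freq_khz = max(fd),
    start_freq_khz = fd[1L],
    end_freq_khz = fd[length(fd)],
    freq_modulation_khz = max(fd) - min(fd),
    spectral_purity = if (length(ratio)) mean(ratio) else NA_real_,
    amplitude_db = 10 * log10(meanPow / fullScalePower(config)),
    bandwidth_khz = max(fd) - min(fd))
}

#' Detect, classify and annotate every syllable in a waveform
#'
#' End-to-end acoustics stage: sonogram, noise masking and band limiting,
#' syllable detection, pitch tracking, pitch-jump classification and feature
#' extraction. Syllables with too few defined pitch frames or spectral purity
#' below \code{minPurity} (broadband mechanical noise) are labelled
#' \code{"unclassified"}; downstream sequence analyses drop them.
#'
#' @param wave numeric waveform in [-1, 1].
#' @param rate sampling rate (Hz).
#' @param config a \code{\link{sonogramConfig}}.
#' @param file optional file name recorded in the output.
#' @return data.frame, one row per detected syllable, with the timing, label,
#'   jump count and acoustic feature columns.
#' @examples
#' syn <- synthWaveform(list(list(freqKHz = c(60, 80), durationMs = c(20, 20))),
#'                      gapMs = 30, snrDb = 40, seed = 1)
#' detectSyllableEvents(syn$wave, syn$rate)
#' @export
detectSyllableEvents <- function(wave, rate, config = sonogramConfig(),
                                 file = NA_character_) {
  sono <- computeSonogram(wave, rate, config)
  masked <- denoiseSonogram(sono, config)
  iv <- detectSyllables(masked, config)
  out <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    track <- extractPitchTrack(masked, iv$onsetFrame[i], iv$offsetFrame[i])
    cls <- classifySyllable(track, config)
    hasDef <- any(!is.na(track@freqKHz))
    feats <- if (hasDef) extractFeatures(track, config, masked@frameStepS)
    else data.frame(duration_ms = NA_real_, mean_freq_khz = NA_real_,
                    min_freq_khz = NA_real_, max_freq_khz = NA_real_,
                    start_freq_khz = NA_real_, end_freq_khz = NA_real_,
                    freq_modulation_khz = NA_real_, spectral_purity = NA_real_,
                    amplitude_db = NA_real_, bandwidth_khz = NA_real_)
    label <- cls$label
    if (!is.na(feats$spectral_purity) && feats$spectral_purity < config@minPurity)
      label <- "unclassified"
    out[[i]] <- cbind(
      data.frame(file = file, onset_s = iv$onset_s[i],
                 offset_s = iv$offset_s[i], label = label),
      feats,
      data.frame(n_pitch_jumps = cls$nJumps))
  }
  if (!length(out)) {
    return(data.frame(file = character(), onset_s = numeric(),
                      offset_s = numeric(), label = character(),
                      duration_ms = numeric(), mean_freq_khz = numeric(),
                      min_freq_khz = numeric(), max_freq_khz = numeric(),
                      start_freq_khz = numeric(), end_freq_khz = numeric(),
                      freq_modulation_khz = numeric(),
                      spectral_purity = numeric(), amplitude_db = numeric(),
                      bandwidth_khz = numeric(), n_pitch_jumps = integer()))
  }
  do.call(rbind, out)
}
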