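## evaluate expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Default baseline syllable transition matrix
#'
#' A row-stochastic first-order chain over \code{\link{USV_STATES}} used as the
#' synthetic cohort baseline. Its topology mimics what wildtype males commonly
#' show — sequences mostly start with "s", the "s"/"d"/"m" types self-loop,
#' "u" effectively does not — but the values are invented synthetic defaults,
#' not measurements.
#'
#' @return 5 x 5 matrix, rows summing to 1, silence-to-silence 0.
#' @export
defaultBaselineMatrix <- function() {
  m <- rbind(
    s = c(0.55, 0.15, 0.05, 0.05, 0.20),
    d = c(0.20, 0.35, 0.05, 0.10, 0.30),
    u = c(0.28, 0.15, 0.02, 0.10, 0.45),
    m = c(0.20, 0.20, 0.05, 0.25, 0.30),
    X = c(0.70, 0.10, 0.10, 0.10, 0.00))
  colnames(m) <- USV_STATES
  m[USV_STATES, ]
}

#' Apply planted group effects to a transition matrix
#'
#' Effects act on the probability scale with proportional renormalization of
#' the remaining row mass, so a planted shift stays interpretable as an
#' absolute probability change: first every row's transition into "m" is
#' multiplied by \code{mFactor} (freed mass spread proportionally over the
#' row's other entries), then \code{toSilenceShift} is added to every syllable
#' row's transition to silence (other entries scaled down proportionally).
#'
#' @param mat row-stochastic 5 x 5 matrix over \code{\link{USV_STATES}}.
#' @param toSilenceShift additive probability shift toward silence.
#' @param mFactor multiplicative factor on transitions into "m".
#' @return modified row-stochastic matrix.
#' @export
applyCohortEffect <- function(mat, toSilenceShift = 0, mFactor = 1) {
  m <- mat
  if (mFactor != 1) {
    for (a in USV_STATES) {
      pm <- m[a, "m"]
      if (pm == 0) next
      newPm <- pm * mFactor
      rest <- setdiff(USV_STATES, "m")
      restMass <- sum(m[a, rest])
      if (restMass > 0)
        m[a, rest] <- m[a, rest] * (1 - newPm) / restMass
      m[a, "m"] <- newPm
    }
  }
  if (toSilenceShift != 0) {
    for (a in setdiff(USV_STATES, "X")) {
      pX <- m[a, "X"]
      newPX <- pX + toSilenceShift
      if (newPX < 0 || newPX > 1)
        stop("toSilenceShift pushes row '", a, "' silence probability to ",
             round(newPX, 3), ", outside [0, 1]")
      rest <- setdiff(USV_STATES, "X")
      restMass <- sum(m[a, rest])
      if (restMass > 0)
        m[a, rest] <- m[a, rest] * (1 - newPX) / restMass
      m[a, "X"] <- newPX
    }
  }
  if (any(m < -1e-12))
    stop("effect pushed a transition probability negative")
  m / rowSums(m)
}

#' Specify a synthetic two-group cohort
#'
#' @param nAnimals animals per group (default 8, matching a typical study arm).
#' @param contexts context labels (default "LF").
#' @param baseline baseline chain, see \code{\link{defaultBaselineMatrix}}.
#' @param concentration Dirichlet concentration of per-animal row dispersion
#'   around the group chain (default 50: per-animal probabilities vary by a few
#'   percentage points around the group mean, comparable to animal-to-animal
#'   variability in real cohorts).
#' @param toSilenceShift named numeric, one additive to-silence shift per
#'   group; names define the groups (default \code{c(g1 = 0, g2 = 0)}).
#' @param mFactor named numeric, multiplicative suppression of transitions
#'   into "m" per group (default 1 for both groups).
#' @param seqPerAnimal sequences per animal and context (default 200).
#' @param maxLength cap on generated sequence length (default 200).
#' @return A \linkS4class{SyntheticCohortSpec}.
#' @export
cohortSpec <- function(nAnimals = 8L, contexts = "LF",
                       baseline = defaultBaselineMatrix(),
                       concentration = 50,
                       toSilenceShift = c(g1 = 0, g2 = 0),
                       mFactor = 1,
                       seqPerAnimal = 200L, maxLength = 200L) {
  if (is.null(names(toSilenceShift)))
    stop("toSilenceShift must be named by group")
  if (is.null(names(mFactor))) {
    mFactor <- stats::setNames(
      rep(as.numeric(mFactor), length.out = length(toSilenceShift)),
      names(toSilenceShift))
  } else if (!setequal(names(mFactor), names(toSilenceShift))) {
    stop("mFactor group names must match toSilenceShift")
  }
  mFactor <- mFactor[names(toSilenceShift)]
  new("SyntheticCohortSpec", nAnimals = as.integer(nAnimals),
      contexts = contexts, baseline = baseline,
      concentration = concentration, toSilenceShift = toSilenceShift,
      mFactor = mFactor, seqPerAnimal = as.integer(seqPerAnimal),
      maxLength = as.integer(maxLength))
}

## Dirichlet draw proportional to alpha (zero alphas stay exactly zero)
rdirichletRow <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

## one Markov walk from silence until absorption back at silence
markovWalk <- function(probRows, maxLength) {
  labels <- character(maxLength)
  state <- 5L   # X
  n <- 0L
  repeat {
    state <- sample.int(5L, 1L, prob = probRows[state, ])
    if (state == 5L) break
    n <- n + 1L
    labels[n] <- USV_STATES[state]
    if (n >= maxLength) break
  }
  list(coded = paste(labels[seq_len(n)], collapse = ""), truncated = n >= maxLength)
}

#' Sample a synthetic cohort of coded song corpora
#'
#' For each animal and context, transition-matrix rows are drawn from a
#' Dirichlet centred on the group's effect-modified chain, and sequences are
#' emitted by Markov walks that start and end at silence. Every sequence
#' therefore contributes exactly its length + 1 transitions, reproducing the
#' structural identity the transition-count stage relies on.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return list with \code{corpora} (group -> animal -> context -> character
#'   vector of coded sequences), \code{animalMatrices} (the drawn per-animal
#'   transition rows, same nesting), and \code{groupMatrices} (the
#'   effect-modified group chains).
#' @examples
#' cohort <- sampleCohort(cohortSpec(nAnimals = 2, seqPerAnimal = 5), seed = 1)
#' cohort$corpora$g1$g1_a1$LF
#' @export
sampleCohort <- function(spec, seed) {
  groups <- names(spec@toSilenceShift)
  groupMatrices <- lapply(stats::setNames(groups, groups), function(g)
    applyCohortEffect(spec@baseline, spec@toSilenceShift[[g]],
                      spec@mFactor[[g]]))
  withSeed(seed, {
    truncated <- FALSE
    corpora <- list()
    animalMatrices <- list()
    for (g in groups) {
      gm <- groupMatrices[[g]]
      corpora[[g]] <- list()
      animalMatrices[[g]] <- list()
      for (a in seq_len(spec@nAnimals)) {
        id <- paste0(g, "_a", a)
        corpora[[g]][[id]] <- list()
        animalMatrices[[g]][[id]] <- list()
        for (ctx in spec@contexts) {
          rows <- gm
          for (st in USV_STATES)
            rows[st, ] <- rdirichletRow(spec@concentration * gm[st, ])
          seqs <- character(spec@seqPerAnimal)
          for (k in seq_len(spec@seqPerAnimal)) {
            w <- markovWalk(rows, spec@maxLength)
            if (w$truncated) truncated <- TRUE
            seqs[k] <- w$coded
          }
          seqs <- seqs[nzchar(seqs)]   # X -> X immediately yields no syllable
          corpora[[g]][[id]][[ctx]] <- seqs
          animalMatrices[[g]][[id]][[ctx]] <- rows
        }
      }
    }
    if (truncated)
      warning("some generated sequences were truncated at maxLength = ",
              spec@maxLength)
    list(corpora = corpora, animalMatrices = animalMatrices,
         groupMatrices = groupMatrices)
  })
}

#' Synthesize a waveform of frequency-plateau syllables
#'
#' Renders each syllable from a note plan — a list of constant-frequency
#' plateaus \code{(freqKHz, durationMs)} — as sinusoids with raised-cosine
#' onset/offset ramps, separated by silent gaps, with additive white Gaussian
#' noise at a stated signal-to-noise ratio. The exact syllable boundaries and
#' the label implied by the plan's pitch jumps are returned as ground truth.
#'
#' @param plans list of note plans; each is a list with numeric vectors
#'   \code{freqKHz} and \code{durationMs} of equal length.
#' @param gapMs silent gap before each syllable and after the last (scalar or
#'   vector recycled across syllables), default 50.
#' @param rate sampling rate in Hz (default 250000).
#' @param snrDb signal-to-noise ratio in dB; \code{Inf} for noise-free.
#' @param amplitude peak amplitude of the tone (default 0.5).
#' @param rampMs raised-cosine ramp length at each note edge (default 0.5).
#' @param jumpMinKHz jump threshold used to derive the ground-truth label
#'   (default 10, matching the analysis default).
#' @param seed RNG seed for the noise.
#' @return list with \code{wave}, \code{rate}, and \code{truth}, a data.frame
#'   of ground-truth \code{onset_s}, \code{offset_s}, \code{label}.
#' @export
synthWaveform <- function(plans, gapMs = 50, rate = 250000, snrDb = Inf,
                          amplitude = 0.5, rampMs = 0.5, jumpMinKHz = 10,
                          seed = NULL) {
  n <- length(plans)
  gaps <- rep(gapMs, length.out = max(n, 1L))
  pieces <- list()
  truth <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      label = character())
  t0 <- 0
  for (i in seq_len(n)) {
    gapSamples <- round(gaps[i] / 1000 * rate)
    pieces[[length(pieces) + 1L]] <- numeric(gapSamples)
    t0 <- t0 + gapSamples / rate
    plan <- plans[[i]]
    stopifnot(length(plan$freqKHz) == length(plan$durationMs),
              all(plan$durationMs > 0))
    if (any(plan$freqKHz * 1000 > rate / 2))
      stop("note frequency above Nyquist for rate ", rate)
    syl <- unlist(lapply(seq_along(plan$freqKHz), function(j) {
      ns <- round(plan$durationMs[j] / 1000 * rate)
      x <- amplitude * sin(2 * pi * plan$freqKHz[j] * 1000 *
                             seq_len(ns) / rate)
      nr <- min(round(rampMs / 1000 * rate), ns %/% 2L)
      if (nr > 0) {
        ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
        x[seq_len(nr)] <- x[seq_len(nr)] * ramp
        x[ns - nr + seq_len(nr)] <- x[ns - nr + seq_len(nr)] * rev(ramp)
      }
      x
    }))
    pieces[[length(pieces) + 1L]] <- syl
    jumps <- diff(plan$freqKHz)
    jumps <- jumps[abs(jumps) >= jumpMinKHz]
    label <- if (length(jumps) == 0L) "s"
    else if (length(jumps) == 1L && jumps > 0) "u"
    else if (length(jumps) == 1L) "d"
    else "m"
    truth <- rbind(truth, data.frame(
      onset_s = t0, offset_s = t0 + length(syl) / rate, label = label))
    t0 <- t0 + length(syl) / rate
  }
  pieces[[length(pieces) + 1L]] <-
    numeric(round(gaps[length(gaps)] / 1000 * rate))
  wave <- unlist(pieces)
  if (is.finite(snrDb)) {
    sigPower <- amplitude^2 / 2
    noiseSd <- sqrt(sigPower / 10^(snrDb / 10))
    wave <- wave + withSeed(seed, stats::rnorm(length(wave), 0, noiseSd))
  }
  list(wave = wave, rate = rate, truth = truth)
}

#' Generate a randomized suite of syllable note plans
#'
#' Plans spanning all four syllable categories with pitch jumps of at least
#' \code{jumpKHz} (default 20, twice the classification threshold) and
#' plateau frequencies inside the analysis band.
#'
#' @param n number of syllables.
#' @param seed RNG seed.
#' @param jumpKHz minimum planned jump magnitude (kHz).
#' @param freqRangeKHz range plateau frequencies are drawn from.
#' @param noteMs range of plateau durations (ms).
#' @return list of note plans; the implied label of plan \code{i} is
#'   \code{attr(plans, "labels")[i]}.
#' @export
syllablePlanSuite <- function(n = 100L, seed = NULL, jumpKHz = 20,
                              freqRangeKHz = c(45, 110), noteMs = c(15, 35)) {
  withSeed(seed, {
    types <- rep(c("s", "u", "d", "m"), length.out = n)
    plans <- lapply(types, function(ty) {
      dur <- function(k) stats::runif(k, noteMs[1], noteMs[2])
      base <- stats::runif(1, freqRangeKHz[1], freqRangeKHz[2])
      jump <- function(from, dir) {
        lo <- freqRangeKHz[1]; hi <- freqRangeKHz[2]
        if (dir > 0) stats::runif(1, min(from + jumpKHz, hi - 1), hi)
        else stats::runif(1, lo, max(from - jumpKHz, lo + 1))
      }
      if (ty == "s") {
        list(freqKHz = base, durationMs = dur(1))
      } else if (ty == "u") {
        base <- stats::runif(1, freqRangeKHz[1], freqRangeKHz[2] - jumpKHz - 2)
        list(freqKHz = c(base, jump(base, +1)), durationMs = dur(2))
      } else if (ty == "d") {
        base <- stats::runif(1, freqRangeKHz[1] + jumpKHz + 2, freqRangeKHz[2])
        list(freqKHz = c(base, jump(base, -1)), durationMs = dur(2))
      } else {
        f1 <- stats::runif(1, freqRangeKHz[1], freqRangeKHz[2] - jumpKHz - 2)
        f2 <- jump(f1, +1)
        f3 <- jump(f2, -1)
        list(freqKHz = c(f1, f2, f3), durationMs = dur(3))
      }
    })
    attr(plans, "labels") <- types
    plans
  })
}
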