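test_that("sonogram geometry follows block size, overlap and rate", {
  wave <- sin(2 * pi * 70000 * seq_len(25000) / 250000)
  sono <- computeSonogram(wave, 250000)
  expect_equal(diff(sonoFreqs(sono)[1:2]) * 1000, 976.5625)
  expect_equal(frameStep(sono) * 1000, 0.512)
  expect_equal(nrow(sonoPower(sono)), 129L)   # full range up to Nyquist
  expect_equal(max(sonoFreqs(sono)), 125)
})

test_that("a constant-zero waveform yields an all-zero power matrix", {
  sono <- computeSonogram(numeric(2000), 250000)
  expect_true(all(sonoPower(sono) == 0))
})

test_that("a bin-centred sinusoid matches a direct DFT and concentrates in one row", {
  ## bin 72 of a 256-sample block at 250 kHz: 72 * 976.5625 Hz = 70312.5 Hz
  f <- 72 * 250000 / 256
  wave <- sin(2 * pi * f * (seq_len(2560) - 1L) / 250000)
  sono <- computeSonogram(wave, 250000)
  ## oracle: direct DFT summation of the first block
  block <- wave[1:256]
  direct <- vapply(0:128, function(k)
    Mod(sum(block * exp(-2i * pi * k * (0:255) / 256)))^2, numeric(1))
  expect_equal(sonoPower(sono)[, 1L], direct, tolerance = 1e-10)
  inBand <- sonoFreqs(sono) >= 35 & sonoFreqs(sono) <= 125
  p <- sonoPower(sono)[inBand, ]
  peakRow <- which.max(rowSums(p))
  expect_gt(sum(p[peakRow, ]) / sum(p), 1 - 1e-12)
})

test_that("preconditions are enforced with informative errors", {
  expect_error(computeSonogram(numeric(0), 250000), "empty")
  expect_error(computeSonogram(rnorm(100), 250000), "block")
  expect_error(computeSonogram(rnorm(1000), 96000), "250000")
  sono <- computeSonogram(rnorm(1000), 250000,
                          sonogramConfig(bandHighKHz = 125))
  cfg <- sonogramConfig(bandLowKHz = 130, bandHighKHz = 140)
  expect_error(sonogramConfig(bandLowKHz = 120, bandHighKHz = 90))
})

test_that("denoising zeroes white noise but keeps a strong ridge", {
  withr::with_seed(3, wave <- rnorm(250000 %/% 2, 0, 0.05))
  masked <- denoiseSonogram(computeSonogram(wave, 250000))
  inBandCells <- length(sonoPower(masked))
  expect_gte(mean(sonoPower(masked) == 0), 0.95)

  ## ridge 40 dB above the noise floor at 70 kHz over the middle 40 %
  withr::with_seed(4, {
    noise <- rnorm(250000 %/% 2, 0, 0.002)
  })
  n <- length(noise)
  ridgeIdx <- seq.int(round(0.3 * n), round(0.7 * n))
  tone <- numeric(n)
  tone[ridgeIdx] <- 0.2 * sin(2 * pi * 70312.5 * seq_along(ridgeIdx) / 250000)
  masked2 <- denoiseSonogram(computeSonogram(noise + tone, 250000))
  ridgeRow <- which.min(abs(sonoFreqs(masked2) - 70.3125))
  ridgeFrames <- sonoTimes(masked2) > 0.31 * n / 250000 &
    sonoTimes(masked2) < 0.69 * n / 250000
  expect_true(all(sonoPower(masked2)[ridgeRow, ridgeFrames] > 0))
  offRows <- abs(sonoFreqs(masked2) - 70.3125) > 5
  expect_gt(mean(sonoPower(masked2)[offRows, ] == 0), 0.99)
})

test_that("an all-zero sonogram denoises to zero with zero threshold", {
  masked <- denoiseSonogram(computeSonogram(numeric(2000), 250000))
  expect_true(all(sonoPower(masked) == 0))
  expect_true(all(noiseThreshold(masked) == 0))
})

test_that("syllable detection merges short gaps and drops short runs", {
  ## frame step 0.5 ms: 20 ms / 5 ms / 15 ms voiced-gap-voiced pattern
  v <- c(rep(FALSE, 20), rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 30),
         rep(FALSE, 20))
  iv <- detectSyllables(voicedSonogram(v))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$offsetFrame - iv$onsetFrame, 80L)   # ~40 ms merged

  ## a 12 ms gap is not merged
  v2 <- c(rep(FALSE, 10), rep(TRUE, 40), rep(FALSE, 24), rep(TRUE, 40),
          rep(FALSE, 10))
  iv2 <- detectSyllables(voicedSonogram(v2))
  expect_equal(nrow(iv2), 2L)

  ## an isolated 2 ms run is below the minimum duration
  v3 <- c(rep(FALSE, 40), rep(TRUE, 4), rep(FALSE, 40))
  expect_equal(nrow(detectSyllables(voicedSonogram(v3))), 0L)

  ## empty sonogram -> empty list
  expect_equal(nrow(detectSyllables(voicedSonogram(rep(FALSE, 50)))), 0L)
})

test_that("detection is idempotent on its own output", {
  withr::with_seed(5, {
    plans <- syllablePlanSuite(12)
    syn <- synthWaveform(plans, gapMs = 150, snrDb = 35)
  })
  masked <- denoiseSonogram(computeSonogram(syn$wave, syn$rate))
  iv <- detectSyllables(masked)
  keep <- unlist(mapply(seq.int, iv$onsetFrame, iv$offsetFrame - 1L,
                        SIMPLIFY = FALSE))
  power2 <- sonoPower(masked)
  power2[, setdiff(seq_len(ncol(power2)), keep)] <- 0
  masked2 <- new("MaskedSonogram", power = power2,
                 rawPower = rawPower(masked), freqsKHz = sonoFreqs(masked),
                 timesS = sonoTimes(masked), frameStepS = frameStep(masked),
                 rowThreshold = noiseThreshold(masked),
                 floorPower = masked@floorPower)
  iv2 <- detectSyllables(masked2)
  expect_equal(iv2, iv)
})

test_that("pitch tracks report plateaus, steps and missing frames", {
  syn <- synthWaveform(list(list(freqKHz = c(60, 80),
                                 durationMs = c(20, 20))),
                       gapMs = 50, snrDb = Inf)
  masked <- denoiseSonogram(computeSonogram(syn$wave, syn$rate))
  iv <- detectSyllables(masked)
  tr <- extractPitchTrack(masked, iv$onsetFrame, iv$offsetFrame)
  f <- pitchFreqs(tr)
  d <- f[!is.na(f)]
  expect_lt(max(abs(d[1:20] - 60)), 1)
  expect_lt(max(abs(d[(length(d) - 19):length(d)] - 80)), 1)
  ## exactly one step of ~20 kHz between consecutive defined frames
  steps <- diff(d)
  expect_equal(sum(abs(steps) >= 10), 1L)

  ## a frame with no surviving power is marked missing
  power2 <- sonoPower(masked)
  mid <- floor((iv$onsetFrame + iv$offsetFrame) / 2)
  power2[, mid] <- 0
  masked2 <- new("MaskedSonogram", power = power2,
                 rawPower = rawPower(masked), freqsKHz = sonoFreqs(masked),
                 timesS = sonoTimes(masked), frameStepS = frameStep(masked),
                 rowThreshold = noiseThreshold(masked),
                 floorPower = masked@floorPower)
  tr2 <- extractPitchTrack(masked2, iv$onsetFrame, iv$offsetFrame)
  expect_true(is.na(pitchFreqs(tr2)[mid - iv$onsetFrame + 1L]))

  expect_error(extractPitchTrack(masked, 10L, 10L), "empty")
})

test_that("pitch-jump classification follows the four-category scheme", {
  mkTrack <- function(f) new("PitchTrack", freqKHz = f,
                             peakPower = rep(1, length(f)),
                             totalPower = rep(1, length(f)),
                             timesS = seq_along(f) * 5e-4,
                             frames = seq_along(f))
  expect_equal(classifySyllable(mkTrack(c(70, 70, 70)))$label, "s")
  u <- classifySyllable(mkTrack(c(60, 60, 80, 80)))
  expect_equal(u$label, "u")
  expect_equal(u$directions, "up")
  m <- classifySyllable(mkTrack(c(60, 80, 80, 60)))
  expect_equal(m$label, "m")
  expect_equal(m$directions, c("up", "down"))
  expect_equal(classifySyllable(mkTrack(c(80, 80, 65, 65)))$label, "d")
  ## sub-threshold drift is not a jump
  expect_equal(classifySyllable(mkTrack(c(60, 65, 69, 72)))$label, "s")
  ## all frames missing -> unclassified
  expect_equal(classifySyllable(mkTrack(rep(NA_real_, 5)))$label,
               "unclassified")
  ## bridging: a jump across <= 3 missing frames is scored, longer gaps not
  expect_equal(classifySyllable(
    mkTrack(c(60, 60, NA, NA, 80, 80, 80, 80)))$label, "u")
  expect_equal(classifySyllable(
    mkTrack(c(60, 60, 60, 60, NA, NA, NA, NA, 80, 80, 80, 80)))$label, "s")
  ## mostly-missing tracks are unclassified
  expect_equal(classifySyllable(
    mkTrack(c(60, NA, NA, NA, NA, NA, NA, 60)))$label, "unclassified")
})

test_that("acoustic features respect their invariants on a constant tone", {
  syn <- synthWaveform(list(list(freqKHz = 70.3125, durationMs = 100)),
                       gapMs = 100, snrDb = Inf)
  masked <- denoiseSonogram(computeSonogram(syn$wave, syn$rate))
  iv <- detectSyllables(masked)
  tr <- extractPitchTrack(masked, iv$onsetFrame, iv$offsetFrame)
  ft <- extractFeatures(tr, frameStepS = frameStep(masked))
  expect_equal(ft$bandwidth_khz, 0)
  expect_equal(ft$freq_modulation_khz, 0)
  expect_equal(ft$start_freq_khz, 70.3125)
  expect_equal(ft$end_freq_khz, 70.3125)
  expect_equal(ft$mean_freq_khz, 70.3125)
  expect_lte(ft$min_freq_khz, ft$mean_freq_khz)
  expect_lte(ft$mean_freq_khz, ft$max_freq_khz)
  expect_gt(ft$spectral_purity, 0.99)
  expect_lte(ft$spectral_purity, 1)
})

test_that("spectral purity is scale-invariant and bounded in [0, 1]", {
  base <- synthWaveform(list(list(freqKHz = 70.3125, durationMs = 60)),
                        gapMs = 60, snrDb = Inf)
  pur <- function(wave) {
    detectSyllableEvents(wave, 250000)$spectral_purity
  }
  expect_equal(pur(base$wave), pur(base$wave * 0.05), tolerance = 1e-9)
  withr::with_seed(6, {
    plans <- syllablePlanSuite(8)
    syn <- synthWaveform(plans, gapMs = 150, snrDb = 30)
  })
  ev <- detectSyllableEvents(syn$wave, syn$rate)
  expect_true(all(ev$spectral_purity >= 0 & ev$spectral_purity <= 1))
})

test_that("a broadband noise burst has near-zero purity and is unclassified", {
  withr::with_seed(7, {
    wave <- rnorm(75000, 0, 0.002)
    wave[25000:37500] <- rnorm(12501, 0, 0.2)
  })
  ev <- detectSyllableEvents(wave, 250000)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$spectral_purity, 0.2)
  expect_equal(ev$label, "unclassified")
})

test_that("labels and boundaries are recovered on a small synthetic suite", {
  plans <- syllablePlanSuite(24, seed = 8)
  syn <- synthWaveform(plans, gapMs = 150, snrDb = 30, seed = 9)
  ev <- detectSyllableEvents(syn$wave, syn$rate)
  expect_equal(nrow(ev), nrow(syn$truth))
  expect_equal(ev$label, syn$truth$label)
  step <- 128 / 250000
  expect_lt(max(abs(ev$onset_s - syn$truth$onset_s)), step)
  expect_lt(max(abs(ev$offset_s - syn$truth$offset_s)), step)
})
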