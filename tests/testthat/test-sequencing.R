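mkEvents <- function(gapsMs, durMs = 30, labels = NULL) {
  n <- length(gapsMs) + 1L
  onsets <- numeric(n); offsets <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    onsets[i] <- t
    offsets[i] <- t + durMs / 1000
    if (i < n) t <- offsets[i] + gapsMs[i] / 1000
  }
  data.frame(onset_s = onsets, offset_s = offsets,
             label = if (is.null(labels)) rep("s", n) else labels)
}

test_that("inter-syllable intervals are the onset-offset gaps", {
  ev <- mkEvents(c(40, 300, 20))
  isi <- isiDistribution(ev)
  expect_equal(isi$gaps_ms, c(40, 300, 20))
  expect_equal(isiDistribution(ev[1, , drop = FALSE])$gaps_ms, numeric())
})

test_that("a planted bimodal gap mixture shows both histogram modes", {
  withr::with_seed(10, {
    gaps <- c(rnorm(400, 60, 5), rnorm(400, 400, 30))
  })
  ev <- mkEvents(sample(gaps))
  isi <- isiDistribution(ev, nBins = 25L)
  mids <- sqrt(isi$breaks_ms[-1] * isi$breaks_ms[-length(isi$breaks_ms)])
  ## the two most populated well-separated bins sit at the planted means
  ord <- order(isi$counts, decreasing = TRUE)
  top <- mids[ord[1]]
  other <- mids[ord][which(abs(log(mids[ord] / top)) > 0.8)[1]]
  modes <- sort(c(top, other))
  binWidth <- diff(log(isi$breaks_ms[1:2]))
  expect_lt(abs(log(modes[1] / 60)), 3 * binWidth)
  expect_lt(abs(log(modes[2] / 400)), 3 * binWidth)
})

test_that("sequence segmentation splits at gaps of 250 ms or more", {
  ev <- segmentIntoSequences(mkEvents(c(40, 260, 30)))
  expect_equal(unname(table(ev$bout_index)), array(c(2L, 2L)))

  ## a gap of exactly 250 ms splits
  evEq <- segmentIntoSequences(mkEvents(c(100, 250, 100)))
  expect_equal(length(unique(evEq$bout_index)), 2L)

  ## all gaps below threshold: one sequence
  evOne <- segmentIntoSequences(mkEvents(c(100, 240, 100)))
  expect_equal(length(unique(evOne$bout_index)), 1L)
})

test_that("segmentation conserves events and is monotone in the threshold", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      gaps <- runif(30, 10, 600)
      labels <- sample(c("s", "d", "u", "m"), 31, replace = TRUE)
      ev <- mkEvents(gaps, labels = labels)
      seg <- segmentIntoSequences(ev)
      ## conservation: concatenation of sequences restores the event list
      expect_equal(sum(nchar(letterCode(seg))), nrow(ev))
      expect_equal(unlist(strsplit(paste(letterCode(seg), collapse = ""),
                                   "")), ev$label)
      ## monotonicity: raising the threshold never adds sequences
      nSeq <- vapply(c(100, 250, 400, 1000), function(b)
        length(unique(segmentIntoSequences(ev, b)$bout_index)), numeric(1))
      expect_true(all(diff(nSeq) <= 0))
    }
  })
})

test_that("letter coding round-trips and rejects unknown labels", {
  ev <- segmentIntoSequences(
    mkEvents(c(40, 300, 20), labels = c("s", "s", "d", "m")))
  coded <- letterCode(ev)
  expect_equal(unname(coded), c("ss", "dm"))
  expect_equal(unname(parseCoded(coded)), list(c("s", "s"), c("d", "m")))
  expect_equal(letterCode(ev[0, ]), character())
  evBad <- ev; evBad$label[2] <- "unclassified"
  expect_error(letterCode(evBad), "unknown")
})

test_that("complex/simple ratio counts m-rich sequences among length >= 3", {
  ## m-counts per eligible sequence: 2, 3, 0, 1, 0 -> 2 complex / 3 simple
  coded <- c("smm", "mmm", "sss", "sdm", "uds")
  r <- complexSimpleRatio(coded)
  expect_equal(r$ratio, 2 / 3)
  ## sequences of length <= 2 are excluded even when m-rich
  r2 <- complexSimpleRatio(c(coded, "mm", "m"))
  expect_equal(r2$ratio, 2 / 3)
  expect_equal(r2$nEligible, 5L)
  ## all-complex: undefined, flagged, not an error
  r3 <- complexSimpleRatio(c("smm", "mmm"))
  expect_true(is.na(r3$ratio))
  expect_equal(r3$nComplex, 2L)
})

test_that("session summaries report rate, repertoire and sequence length", {
  labels <- c(rep("s", 5), rep("d", 3), "u", "m")
  ev <- segmentIntoSequences(mkEvents(rep(c(40, 300), length.out = 9),
                                      labels = labels))
  s <- sessionSummary(ev, sessionMinutes = 5)
  expect_equal(s$syllable_rate, 2)
  expect_equal(c(s$prop_s, s$prop_d, s$prop_u, s$prop_m),
               c(0.5, 0.3, 0.1, 0.1))
  expect_equal(s$prop_s + s$prop_d + s$prop_u + s$prop_m, 1)
  expect_equal(s$mean_seq_length, 10 / s$n_sequences)

  ## 120 syllables in 5 minutes -> 24 per minute
  ev120 <- segmentIntoSequences(mkEvents(rep(40, 119)))
  expect_equal(sessionSummary(ev120, 5)$syllable_rate, 24)

  ## zero syllables: zero rate, undefined proportions
  s0 <- sessionSummary(segmentIntoSequences(ev120[0, ]), 5)
  expect_equal(s0$syllable_rate, 0)
  expect_true(is.na(s0$prop_s))
})

test_that("rate-length correlation is Spearman with mid-ranks", {
  mkSum <- function(len, rate) data.frame(mean_seq_length = len,
                                          syllable_rate = rate)
  expect_equal(rateLengthCorrelation(mkSum(1:5, c(2, 4, 9, 12, 30)))$rho, 1)
  expect_equal(rateLengthCorrelation(mkSum(1:3, 3:1))$rho, -1)
  ## n = 5 with one swapped pair vs the direct rank formula
  len <- c(1, 2, 3, 4, 5); rate <- c(10, 20, 40, 30, 50)
  d <- rank(len) - rank(rate)
  rhoOracle <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(rateLengthCorrelation(mkSum(len, rate))$rho, rhoOracle)
  expect_error(rateLengthCorrelation(mkSum(1:2, 1:2)), "3")
})

test_that("mean sequence length is unbiased for a geometric chain", {
  ## continue probability 0.7: length ~ Geometric, mean 1/0.3
  base <- defaultBaselineMatrix()
  base["s", ] <- c(0.7, 0, 0, 0, 0.3)
  base["X", ] <- c(1, 0, 0, 0, 0)
  spec <- cohortSpec(nAnimals = 1, baseline = base, concentration = 1e9,
                     toSilenceShift = c(g = 0), mFactor = c(g = 1),
                     seqPerAnimal = 1000)
  cohort <- sampleCohort(spec, seed = 12)
  lens <- nchar(cohort$corpora$g$g_a1$LF)
  se <- sqrt(0.7) / 0.3 / sqrt(1000)
  expect_lt(abs(mean(lens) - 1 / 0.3), 3 * se)
})
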