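## shared fixtures, built in code

## per-animal probability matrices of one group/context from a sampled cohort
probsOf <- function(cohort, group, context = "LF") {
  lapply(cohort$corpora[[group]], function(a)
    conditionalProbabilities(transitionCounts(a[[context]])))
}

## plain 5x5 matrices with iid cell values (for rank-machinery checks where
## row-stochasticity is irrelevant)
iidMatrices <- function(n) {
  lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(25), 5, 5,
                dimnames = list(USV_STATES, USV_STATES))
    m["X", "X"] <- NA
    m
  })
}

## brute-force two-sided WSR p-value: enumerate all sign assignments
bruteWsrP <- function(d) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  eps <- 1e-9 * max(1, w)
  min(1, 2 * min(mean(dist <= w + eps), mean(dist >= w - eps)))
}

## brute-force two-sided WMW p-value: enumerate all group-label assignments
bruteWmwP <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  dist <- apply(combos, 2L, function(idx) sum(r[idx]))
  eps <- 1e-9 * max(1, w)
  min(1, 2 * min(mean(dist <= w + eps), mean(dist >= w - eps)))
}

## hand-built masked sonogram with a given voicing pattern (frame step 0.5 ms)
voicedSonogram <- function(voiced, nBins = 4L, frameStepS = 5e-4) {
  power <- matrix(0, nBins, length(voiced))
  power[2L, voiced] <- 1
  new("MaskedSonogram", power = power, rawPower = power,
      freqsKHz = 35 + seq_len(nBins), timesS = (seq_along(voiced) - 0.5) *
        frameStepS, frameStepS = frameStepS,
      rowThreshold = rep(0, nBins), floorPower = 0)
}
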