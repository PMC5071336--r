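## the 24 observable transition types, in fixed order
transitionCells <- function() {
  cells <- expand.grid(from = USV_STATES, to = USV_STATES,
                       stringsAsFactors = FALSE)
  cells[!(cells$from == "X" & cells$to == "X"), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Local rank tests.
##
## Both tests are exact by enumeration (with mid-ranks under ties) up to a
## combined sample size of `exactLimit`, and use the normal approximation with
## tie correction and 0.5 continuity correction beyond it. Two-sided p-values
## are 2 * min(lower tail, upper tail), capped at 1.

## exact null distribution of the signed-rank statistic W+ for given |d| ranks
wsrNullDistribution <- function(ranks) {
  dist <- 0
  for (r in ranks) dist <- c(dist, dist + r)
  sort(dist)
}

twoSidedFromDist <- function(dist, w) {
  eps <- 1e-9 * max(1, abs(w))
  pLe <- mean(dist <= w + eps)
  pGe <- mean(dist >= w - eps)
  min(1, 2 * min(pLe, pGe))
}

#' Exact / approximate Wilcoxon signed-rank p-value
#'
#' Two-sided paired test on differences, as used for the within-group
#' between-context comparison of each transition type. Zero differences are
#' dropped; mid-ranks are used under ties. Exact enumeration of all sign
#' assignments up to \code{exactLimit} informative pairs, normal approximation
#' with tie and continuity correction beyond.
#'
#' @param d numeric vector of paired differences (NAs removed).
#' @param exactLimit maximum n for exact enumeration (default 12).
#' @return two-sided p-value, or \code{NA} with fewer than 2 informative
#'   pairs.
#' @export
wsrPValue <- function(d, exactLimit = 12L) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exactLimit)
    return(twoSidedFromDist(wsrNullDistribution(r), w))
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  if (sigma == 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

## exact null distribution of the group-1 rank sum: all choose(N, n1) subsets
wmwNullDistribution <- function(ranks, n1) {
  combos <- utils::combn(length(ranks), n1)
  colSums(matrix(ranks[combos], nrow = n1))
}

#' Exact / approximate Wilcoxon-Mann-Whitney p-value
#'
#' Two-sided two-sample rank test, as used for the between-group comparison
#' of each transition type. Exact enumeration of all group-label assignments
#' (mid-ranks under ties) up to a combined \code{exactLimit} values, mid-rank
#' normal approximation with tie and continuity correction beyond.
#'
#' @param x,y numeric samples (NAs removed).
#' @param exactLimit maximum combined n for exact enumeration (default 12).
#' @return two-sided p-value, or \code{NA} when either group has fewer than
#'   2 values.
#' @export
wmwPValue <- function(x, y, exactLimit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  if (n1 + n2 <= exactLimit)
    return(twoSidedFromDist(wmwNullDistribution(r, n1), w1))
  N <- n1 + n2
  u <- w1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  if (sigma == 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

## ---------------------------------------------------------------------------
## Truncated product combination (Zaykin) and closed-form Fisher limit

#' Truncated product statistic
#'
#' Product of the p-values at or below the truncation point \code{tau};
#' p-values above \code{tau} and missing ones are ignored. An empty product is
#' 1 (no evidence). Smaller W means stronger combined evidence. With
#' \code{tau = 1} this is Fisher's product statistic.
#'
#' @param p numeric vector of p-values in (0, 1], possibly with NAs.
#' @param tau truncation point in (0, 1].
#' @return list with \code{W}, \code{k} (number of p-values entering the
#'   product), and \code{nUsed} (non-missing inputs).
#' @export
tpmStatistic <- function(p, tau = 0.05) {
  stopifnot(tau > 0, tau <= 1)
  p <- p[!is.na(p)]
  if (!length(p)) return(list(W = NA_real_, k = 0L, nUsed = 0L))
  sel <- p <= tau
  list(W = if (any(sel)) prod(p[sel]) else 1,
       k = sum(sel), nUsed = length(p))
}

#' Closed-form Fisher combined p-value
#'
#' Tail probability of the product of \code{k} independent uniform p-values:
#' the chi-square distribution with 2k degrees of freedom evaluated at
#' \code{-2 log W}. This is the independence limit of the truncated product
#' method at \code{tau = 1}; the permutation null in \code{\link{syntaxTest}}
#' replaces it when local tests are correlated.
#'
#' @param W product of the k p-values.
#' @param k number of p-values in the product.
#' @return combined p-value.
#' @export
fisherCombinedP <- function(W, k) {
  if (k == 0L) return(1)
  stats::pchisq(-2 * log(W), df = 2 * k, lower.tail = FALSE)
}

## ---------------------------------------------------------------------------
## Building per-animal value arrays

## list of TransitionProbabilities (or plain matrices) -> animals x 24 matrix
probArray <- function(matrices) {
  cells <- transitionCells()
  mats <- lapply(matrices, function(x)
    if (is(x, "TransitionProbabilities")) x@probs else x)
  V <- t(vapply(mats, function(m)
    m[cbind(cells$from, cells$to)], numeric(nrow(cells))))
  rownames(V) <- names(matrices)
  V
}

cellVectorToMatrix <- function(p) {
  cells <- transitionCells()
  m <- matrix(NA_real_, 5L, 5L, dimnames = list(USV_STATES, USV_STATES))
  m[cbind(cells$from, cells$to)] <- p
  m
}

#' Local paired tests for all 24 transition types
#'
#' Wilcoxon signed-rank test per transition type on per-animal probability
#' pairs from two contexts of the same animals.
#'
#' @param matrices1,matrices2 lists of \linkS4class{TransitionProbabilities}
#'   for the same animals (matched by name or position) in two contexts.
#' @param exactLimit see \code{\link{wsrPValue}}.
#' @return 5 x 5 matrix of two-sided p-values (NA where undefined).
#' @export
localTestsPaired <- function(matrices1, matrices2, exactLimit = 12L) {
  if (length(matrices1) != length(matrices2))
    stop("paired comparison requires the same animals in both contexts")
  if (!is.null(names(matrices1)) && !is.null(names(matrices2)) &&
      !identical(names(matrices1), names(matrices2)))
    stop("animal sets are not matched between the two contexts")
  V1 <- probArray(matrices1)
  V2 <- probArray(matrices2)
  d <- V1 - V2
  p <- apply(d, 2L, wsrPValue, exactLimit = exactLimit)
  cellVectorToMatrix(p)
}

#' Local two-sample tests for all 24 transition types
#'
#' Wilcoxon-Mann-Whitney test per transition type on per-animal probabilities
#' from two independent groups within one context.
#'
#' @param matrices1,matrices2 lists of \linkS4class{TransitionProbabilities}
#'   for the two groups.
#' @param exactLimit see \code{\link{wmwPValue}}.
#' @return 5 x 5 matrix of two-sided p-values (NA where undefined).
#' @export
localTestsTwoSample <- function(matrices1, matrices2, exactLimit = 12L) {
  V1 <- probArray(matrices1)
  V2 <- probArray(matrices2)
  p <- vapply(seq_len(ncol(V1)), function(j)
    wmwPValue(V1[, j], V2[, j], exactLimit = exactLimit), numeric(1L))
  cellVectorToMatrix(p)
}

## ---------------------------------------------------------------------------
## The permutation engine.
##
## The permutation unit is the animal: all 24 of an animal's probabilities
## move together under relabelling, which is what makes the Monte Carlo null
## account for the correlation among the local p-values. Transition types
## whose observed local p is missing are excluded from every combined
## statistic, observed and permuted alike.

## vectorized WMW p-values across cells for one label assignment.
## R: rank matrix (NA where undefined), computed once; ties fixed per cell.
wmwPVector <- function(R, g1, nDef, tieTerm, exactLimit, memo) {
  G <- R; G[!g1, ] <- NA
  w1 <- colSums(G, na.rm = TRUE)
  n1 <- colSums(!is.na(G))
  n2 <- nDef - n1
  N <- nDef
  p <- rep(NA_real_, ncol(R))
  ok <- n1 >= 2L & n2 >= 2L
  approx <- ok & N > exactLimit
  if (any(approx)) {
    u <- w1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1))))
    z <- u - mu
    zc <- (z - sign(z) * 0.5) / sigma
    pj <- pmin(1, 2 * pmin(stats::pnorm(zc),
                           stats::pnorm(zc, lower.tail = FALSE)))
    pj[sigma == 0] <- 1
    p[approx] <- pj[approx]
  }
  for (j in which(ok & !approx)) {
    key <- paste0(j, ":", n1[j])
    dist <- memo[[key]]
    if (is.null(dist)) {
      dist <- sort(wmwNullDistribution(R[!is.na(R[, j]), j], n1[j]))
      memo[[key]] <- dist
    }
    p[j] <- twoSidedFromDist(dist, w1[j])
  }
  p
}

## vectorized WSR p-values across cells for one sign-flip assignment.
## Rk: |d| rank matrix over informative pairs (NA elsewhere); sgn: sign(d).
wsrPVector <- function(Rk, sgn, flip, nInf, tieTerm, exactLimit, memo) {
  pos <- sweep(sgn, 1L, flip, "*") > 0
  w <- colSums(Rk * pos, na.rm = TRUE)
  n <- nInf
  p <- rep(NA_real_, ncol(Rk))
  ok <- n >= 2L
  approx <- ok & n > exactLimit
  if (any(approx)) {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tieTerm / 48)
    z <- w - mu
    zc <- (z - sign(z) * 0.5) / sigma
    pj <- pmin(1, 2 * pmin(stats::pnorm(zc),
                           stats::pnorm(zc, lower.tail = FALSE)))
    pj[sigma == 0] <- 1
    p[approx] <- pj[approx]
  }
  for (j in which(ok & !approx)) {
    dist <- memo[[as.character(j)]]
    if (is.null(dist)) {
      dist <- wsrNullDistribution(Rk[!is.na(Rk[, j]), j])
      memo[[as.character(j)]] <- dist
    }
    p[j] <- twoSidedFromDist(dist, w[j])
  }
  p
}

## truncated products for the 11 margin/global targets from one p vector
tpmAllTargets <- function(p, sets, tau) {
  vapply(sets, function(idx) {
    q <- p[idx]
    q <- q[!is.na(q) & q <= tau]
    if (length(q)) prod(q) else 1
  }, numeric(1L))
}

#' Two-stage syntax comparison with a permutation Monte Carlo null
#'
#' Tests whether first-order transition dynamics differ between two groups of
#' animals (two-sample, Wilcoxon-Mann-Whitney local tests) or between two
#' contexts of the same animals (paired, Wilcoxon signed-rank local tests).
#' Local two-sided p-values for the 24 transition types are combined by the
#' truncated product method into tests of the transitions \emph{to} each
#' state (columns), \emph{from} each state (rows), and globally. The null
#' distribution of each combined statistic comes from permutations of the
#' animal labels (two-sample: group-label shuffle; paired: independent
#' within-animal context swap), which preserves the dependence among the
#' local tests. Margin p-values are Benjamini-Hochberg adjusted as one family
#' of 10; the single global p is reported unadjusted.
#'
#' @param group1,group2 lists of \linkS4class{TransitionProbabilities} (or
#'   plain 5 x 5 matrices). For \code{type = "paired"}, the same animals in
#'   context 1 and context 2.
#' @param type "two-sample" or "paired".
#' @param tau truncation point of the combiner (default 0.05, the canonical
#'   truncated-product choice; \code{tau = 1} recovers Fisher's method).
#' @param nPerm number of Monte Carlo permutations (default 10000).
#' @param seed integer seed; identical seed and inputs give identical results.
#' @param exactLimit switch from exact enumeration to the normal
#'   approximation in the local tests (default 12).
#' @return A \linkS4class{SyntaxTestResult}.
#' @examples
#' cohort <- sampleCohort(cohortSpec(nAnimals = 4, seqPerAnimal = 30), seed = 2)
#' g1 <- lapply(cohort$corpora$g1, function(a) {
#'   conditionalProbabilities(transitionCounts(a$LF))
#' })
#' g2 <- lapply(cohort$corpora$g2, function(a) {
#'   conditionalProbabilities(transitionCounts(a$LF))
#' })
#' syntaxTest(g1, g2, nPerm = 200, seed = 1)
#' @export
syntaxTest <- function(group1, group2, type = c("two-sample", "paired"),
                       tau = 0.05, nPerm = 10000L, seed = NULL,
                       exactLimit = 12L) {
  type <- match.arg(type)
  stopifnot(tau > 0, tau <= 1, nPerm >= 1L)
  cells <- transitionCells()
  sets <- c(
    stats::setNames(lapply(USV_STATES, function(st) which(cells$to == st)),
                    paste0("to_", USV_STATES)),
    stats::setNames(lapply(USV_STATES, function(st) which(cells$from == st)),
                    paste0("from_", USV_STATES)),
    list(global = seq_len(nrow(cells))))
  nPerm <- as.integer(nPerm)

  if (type == "two-sample") {
    V1 <- probArray(group1); V2 <- probArray(group2)
    n1 <- nrow(V1); n2 <- nrow(V2)
    if (n1 < 2L || n2 < 2L)
      stop("the two-sample permutation test needs at least 2 animals ",
           "per group")
    V <- rbind(V1, V2)
    R <- apply(V, 2L, function(v) {
      r <- rep(NA_real_, length(v))
      r[!is.na(v)] <- rank(v[!is.na(v)])
      r
    })
    nDef <- colSums(!is.na(V))
    tieTerm <- apply(R, 2L, function(r) {
      t <- table(r[!is.na(r)]); sum(t^3 - t)
    })
    memo <- new.env(parent = emptyenv())
    g1Obs <- c(rep(TRUE, n1), rep(FALSE, n2))
    pObs <- wmwPVector(R, g1Obs, nDef, tieTerm, exactLimit, memo)
    wObs <- tpmAllTargets(ifelse(is.na(pObs), NA, pObs), sets, tau)
    exceed <- integer(length(sets))
    withSeed(seed, {
      for (b in seq_len(nPerm)) {
        g1b <- logical(n1 + n2)
        g1b[sample.int(n1 + n2, n1)] <- TRUE
        pb <- wmwPVector(R, g1b, nDef, tieTerm, exactLimit, memo)
        pb[is.na(pObs)] <- NA     # fixed inclusion pattern
        wb <- tpmAllTargets(pb, sets, tau)
        exceed <- exceed + (wb <= wObs * (1 + 1e-9))
      }
    })
  } else {
    if (length(group1) != length(group2))
      stop("paired comparison requires the same animals in both contexts")
    if (!is.null(names(group1)) && !is.null(names(group2)) &&
        !identical(names(group1), names(group2)))
      stop("animal sets are not matched between the two contexts")
    V1 <- probArray(group1); V2 <- probArray(group2)
    n <- nrow(V1)
    if (n < 2L)
      stop("the paired permutation test needs at least 2 animals")
    d <- V1 - V2
    informative <- !is.na(d) & d != 0
    Rk <- matrix(NA_real_, n, ncol(d))
    for (j in seq_len(ncol(d))) {
      idx <- which(informative[, j])
      Rk[idx, j] <- rank(abs(d[idx, j]))
    }
    sgn <- sign(d); sgn[!informative] <- NA
    nInf <- colSums(informative)
    tieTerm <- apply(Rk, 2L, function(r) {
      t <- table(r[!is.na(r)]); sum(t^3 - t)
    })
    memo <- new.env(parent = emptyenv())
    pObs <- wsrPVector(Rk, sgn, rep(1, n), nInf, tieTerm, exactLimit, memo)
    wObs <- tpmAllTargets(pObs, sets, tau)
    exceed <- integer(length(sets))
    withSeed(seed, {
      for (b in seq_len(nPerm)) {
        flip <- ifelse(stats::runif(n) < 0.5, 1, -1)
        pb <- wsrPVector(Rk, sgn, flip, nInf, tieTerm, exactLimit, memo)
        pb[is.na(pObs)] <- NA
        wb <- tpmAllTargets(pb, sets, tau)
        exceed <- exceed + (wb <= wObs * (1 + 1e-9))
      }
    })
  }

  pPerm <- (1 + exceed) / (1 + nPerm)
  toP <- stats::setNames(pPerm[1:5], USV_STATES)
  fromP <- stats::setNames(pPerm[6:10], USV_STATES)
  family <- c(toP, fromP)
  adj <- rep(NA_real_, 10L)
  ok <- !is.na(family)
  adj[ok] <- stats::p.adjust(family[ok], method = "BH")
  new("SyntaxTestResult",
      comparison = type,
      localP = cellVectorToMatrix(pObs),
      toP = toP, fromP = fromP,
      globalP = unname(pPerm[11L]),
      toPAdj = stats::setNames(adj[1:5], USV_STATES),
      fromPAdj = stats::setNames(adj[6:10], USV_STATES),
      nPerm = nPerm,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      tau = tau)
}

#' Benjamini-Hochberg adjustment of combined p-values
#'
#' Step-up false-discovery-rate adjustment over a family of combined tests
#' (the 5 to-margins and 5 from-margins form one family of 10 by default in
#' \code{\link{syntaxTest}}).
#'
#' @param p numeric vector of p-values (NAs preserved).
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}
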