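# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixtureTemplate <- function() {
  if (is.null(.fixtures$template))
    .fixtures$template <- syntheticSMUP(1.0, onset = 4.0, seed = 0)
  .fixtures$template
}

fixtureNormalPop <- function() populationFromHistogram(normalHistogram())

# a tiny corpus: 12 groups x 5 sets
fixtureSmallCorpus <- function() {
  if (is.null(.fixtures$smallCorpus)) {
    cfg <- simConfig(nPerGroup = 5L)
    .fixtures$smallCorpus <- buildCorpus(fixtureTemplate(), cfg, seed = 101)
  }
  .fixtures$smallCorpus
}

fixtureSmallSplit <- function() {
  if (is.null(.fixtures$smallSplit))
    .fixtures$smallSplit <- splitCorpus(fixtureSmallCorpus(),
                                        simConfig(nPerGroup = 5L),
                                        seed = 102)
  .fixtures$smallSplit
}

# a quickly-trained small model shared by model/evaluation/io tests
fixtureTinyModel <- function() {
  if (is.null(.fixtures$tinyModel)) {
    m <- buildModel(modelSpec("lstm", FALSE, 1L, hiddenUnits = 8L,
                              dropoutRate = 0), seed = 5)
    tc <- trainConfig(maxEpochs = 3L, batchSize = 16L, patience = 3L,
                      seed = 5L, standardize = TRUE)
    .fixtures$tinyModel <- trainModel(m, fixtureSmallSplit(), tc)
  }
  .fixtures$tinyModel
}

# independent per-axon superposition oracle: plain R loop, no shared code
# with the package's C++ kernel
oracleCMAP <- function(template, pop, config = simConfig()) {
  nOut <- as.integer(round(config@windowMs / config@dt)) + 1L
  out <- numeric(nOut)
  a <- amplitudes(template)
  ref <- (config@distalDistance + config@forearmDistance) / config@referenceCV
  for (i in seq_len(nAxons(pop))) {
    if (isBlocked(pop)[i]) next
    tau <- config@distalDistance / normalCV(pop)[i] +
      config@forearmDistance / forearmCV(pop)[i] - ref
    s <- floor(tau / config@dt + 0.5)
    for (j in seq_along(a)) {
      k <- j + s
      if (k >= 1 && k <= nOut) out[k] <- out[k] + a[j]
    }
  }
  out
}

# independent natural-cubic-spline oracle: solves the tridiagonal
# second-derivative system directly and evaluates piecewise
oracleNaturalSpline <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)  # second derivatives; natural ends stay 0
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    rhs <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      r <- i - 1
      A[r, r] <- 2 * (h[i - 1] + h[i])
      if (r > 1) A[r, r - 1] <- h[i - 1]
      if (r < n - 2) A[r, r + 1] <- h[i]
      rhs[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  vapply(xq, function(q) {
    i <- max(1L, min(n - 1L, findInterval(q, x)))
    t1 <- x[i + 1] - q; t2 <- q - x[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# random demyelinated population helper
randomPopulation <- function(seed, blockProb = 0.4) {
  pop <- fixtureNormalPop()
  pop <- applyDemyelination(pop, ((seed - 1) %% 6) + 1, seed = seed)
  applyConductionBlock(pop, blockProb, seed = seed + 7919)
}
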