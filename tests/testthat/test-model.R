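test_that("model construction matches closed-form parameter counts", {
  # unidirectional LSTM, 1 layer: 4H(I+H+1) + O(H+1)
  H <- 8L; O <- 28L
  m <- buildModel(modelSpec("lstm", FALSE, 1L, H), 1L, O, seed = 1)
  expect_identical(countParameters(m),
                   as.integer(4 * H * (1 + H + 1) + O * (H + 1)))
  # GRU layer carries 3 gates
  g <- buildModel(modelSpec("gru", FALSE, 1L, H), 1L, O, seed = 1)
  expect_identical(countParameters(g),
                   as.integer(3 * H * (1 + H + 1) + O * (H + 1)))
  # bidirectional wrapping strictly increases the count
  b <- buildModel(modelSpec("lstm", TRUE, 1L, H), 1L, O, seed = 1)
  expect_gt(countParameters(b), countParameters(m))
  # degenerate width still builds and predicts 28 outputs
  tiny <- buildModel(modelSpec("lstm", FALSE, 1L, 1L), seed = 2)
  expect_identical(tiny@outputDim, 28L)
  # the best-performing architecture builds with the right shapes
  best <- buildModel(modelSpec("lstm", TRUE, 2L, hiddenUnits = 16L),
                     seed = 3)
  expect_gt(countParameters(best), 0L)
  expect_identical(best@inputDim, 1L)
  expect_identical(best@outputDim, 28L)
})

test_that("unsupported architectures are rejected", {
  expect_error(modelSpec("simple_rnn", FALSE, 2L), "single layer")
  expect_error(modelSpec("transformer", FALSE, 1L), "cell")
  expect_error(modelSpec("lstm", FALSE, 4L), "nLayers")
  expect_error(modelSpec("lstm", FALSE, 1L, 0L), "hiddenUnits")
})

test_that("training reduces the loss on a small corpus", {
  m <- fixtureTinyModel()
  h <- trainingHistory(m)
  expect_true(all(is.finite(h$trainLoss)))
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])
  expect_true(all(h$trainAccuracy >= 0 & h$trainAccuracy <= 1))
  expect_true(all(h$valAccuracy >= 0 & h$valAccuracy <= 1))
  expect_lte(stoppedEpoch(m), 3L)
})

test_that("training is deterministic for a fixed seed", {
  run <- function() {
    m <- buildModel(modelSpec("gru", TRUE, 1L, 6L, dropoutRate = 0.3),
                    seed = 7)
    trainModel(m, fixtureSmallSplit(),
               trainConfig(maxEpochs = 3L, batchSize = 16L,
                           patience = 3L, seed = 7L))
  }
  a <- run(); b <- run()
  expect_identical(trainingHistory(a), trainingHistory(b))
  expect_identical(a@weights, b@weights)
})

test_that("early stopping fires when the training loss stops improving", {
  # an infinitesimal learning rate freezes the loss, so epoch 2 cannot
  # improve on epoch 1 and patience 0 stops there
  m <- buildModel(modelSpec("lstm", FALSE, 1L, 4L, dropoutRate = 0),
                  seed = 3)
  fit <- trainModel(m, fixtureSmallSplit(),
                    trainConfig(maxEpochs = 5L, batchSize = 64L,
                                patience = 0L, seed = 3L,
                                learningRate = 1e-300))
  expect_identical(stoppedEpoch(fit), 2L)
  # and the epoch cap is never exceeded
  expect_lte(nrow(trainingHistory(fit)), 5L)
})

test_that("training rejects inconsistent inputs before any epoch", {
  m <- buildModel(modelSpec("lstm", FALSE, 1L, 4L), seed = 1)
  empty <- fixtureSmallCorpus()[, integer(0)]
  expect_error(trainModel(m, list(train = empty, test = NULL)), "empty")
})

test_that("dominant-bin accuracy follows the argmax contract", {
  lab <- labelMatrix(fixtureSmallCorpus()) * 1.0
  expect_identical(dominantBinAccuracy(lab, lab), 1)
  # negation moves the argmax to the first empty bin, which never holds
  # the true maximum for count labels summing to 200
  expect_identical(dominantBinAccuracy(-lab, lab), 0)
  expect_error(dominantBinAccuracy(lab[, 1:27], lab), "shapes")
})

test_that("random predictions sit at chance level against uniform argmax labels", {
  set.seed(42)
  n <- 10000L
  lab <- matrix(0, n, 28)
  lab[cbind(seq_len(n), sample.int(28, n, replace = TRUE))] <- 1
  pred <- matrix(rnorm(n * 28), n, 28)
  expect_lt(abs(dominantBinAccuracy(pred, lab) - 1 / 28), 0.01)
})

test_that("predictions round half-away-from-zero and clip at zero", {
  r <- cmapnet:::roundCounts(c(0.4, 1.6, 2.5, -0.4, -1.7, -0.6))
  expect_identical(r, c(0, 2, 3, 0, 0, 0))
  m <- fixtureTinyModel()
  h <- predictHistogram(m, waveforms(testSet(fixtureSmallSplit()))[, 1])
  expect_s4_class(h, "CVHistogram")
  expect_true(all(axonCounts(h) >= 0L))
  expect_error(predictHistogram(buildModel(modelSpec(), seed = 1),
                                numeric(251)), "trained")
})

test_that("exact-match rate is stricter than dominant-bin accuracy", {
  lab <- labelMatrix(fixtureSmallCorpus()) * 1.0
  expect_identical(exactMatchRate(lab, lab), 1)
  off <- lab; off[, 2] <- off[, 2] + 1
  expect_identical(exactMatchRate(off, lab), 0)
  expect_gte(dominantBinAccuracy(off, lab), exactMatchRate(off, lab))
})
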