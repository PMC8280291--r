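test_that("latency shifts follow the two-segment geometry", {
  cfg <- simConfig()
  ref <- new("AxonPopulation", normalCV = 63L, forearmCV = 63L,
             blocked = FALSE, patternId = 0L, cbApplied = FALSE)
  expect_equal(axonLatencyShift(ref, cfg), 0)
  ax <- new("AxonPopulation", normalCV = 53L, forearmCV = 45L,
            blocked = FALSE, patternId = 0L, cbApplied = FALSE)
  # 70/53 + 200/45 - 270/63, hand-computed
  expect_equal(axonLatencyShift(ax, cfg), 1.479485, tolerance = 1e-6)
  # slowing the forearm segment strictly delays
  slower <- new("AxonPopulation", normalCV = 53L, forearmCV = 23L,
                blocked = FALSE, patternId = 0L, cbApplied = FALSE)
  expect_gt(axonLatencyShift(slower, cfg), axonLatencyShift(ax, cfg))
  # every normal-model shift is non-negative under the 63 m/s reference
  expect_true(all(axonLatencyShift(fixtureNormalPop(), cfg) >= 0))
})

test_that("single-axon and all-blocked CMAPs behave degenerately", {
  tpl <- fixtureTemplate()
  cfg <- simConfig()
  one <- new("AxonPopulation", normalCV = 63L, forearmCV = 63L,
             blocked = FALSE, patternId = 0L, cbApplied = FALSE)
  w <- synthesizeCMAP(tpl, one, cfg)
  expect_length(w, 251)
  expect_equal(w[1:150], amplitudes(tpl))
  expect_true(all(w[151:251] == 0))

  allb <- applyConductionBlock(fixtureNormalPop(), 1, seed = 2)
  expect_identical(synthesizeCMAP(tpl, allb, cfg), numeric(251))
})

test_that("superposition matches the per-axon loop oracle", {
  tpl <- fixtureTemplate()
  cfg <- simConfig()
  for (seed in seq(1, 40, by = 2)) {
    pop <- randomPopulation(seed)
    expect_equal(synthesizeCMAP(tpl, pop, cfg), oracleCMAP(tpl, pop, cfg),
                 tolerance = 1e-9)
  }
})

test_that("superposition is linear over disjoint subpopulations and bounded", {
  tpl <- fixtureTemplate()
  cfg <- simConfig()
  pop <- randomPopulation(21)
  n <- nAxons(pop)
  half <- seq_len(n %/% 2)
  sub <- function(i) new("AxonPopulation",
                         normalCV = normalCV(pop)[i],
                         forearmCV = forearmCV(pop)[i],
                         blocked = isBlocked(pop)[i],
                         patternId = patternId(pop),
                         cbApplied = TRUE)
  wA <- synthesizeCMAP(tpl, sub(half), cfg)
  wB <- synthesizeCMAP(tpl, sub(setdiff(seq_len(n), half)), cfg)
  expect_equal(wA + wB, synthesizeCMAP(tpl, pop, cfg), tolerance = 1e-12)
  expect_true(all(abs(synthesizeCMAP(tpl, pop, cfg)) <=
                    n * max(abs(amplitudes(tpl))) + 1e-12))
})

test_that("uniform forearm slowing weakly delays waveform onset", {
  tpl <- fixtureTemplate()
  cfg <- simConfig()
  pop <- applyDemyelination(fixtureNormalPop(), 4, seed = 3)
  slowed <- new("AxonPopulation", normalCV = normalCV(pop),
                forearmCV = pmax(forearmCV(pop) - 10L, 11L),
                blocked = isBlocked(pop), patternId = patternId(pop),
                cbApplied = FALSE)
  thr <- 0.5
  onset <- function(w) {
    i <- which(abs(w) > thr)
    if (length(i)) i[1] else length(w) + 1L
  }
  expect_gte(onset(synthesizeCMAP(tpl, slowed, cfg)),
             onset(synthesizeCMAP(tpl, pop, cfg)))
})

test_that("corpus construction yields labelled groups in the documented order", {
  corpus <- fixtureSmallCorpus()
  expect_identical(ncol(corpus), 60L)
  expect_identical(nrow(corpus), 251L)
  cd <- SummarizedExperiment::colData(corpus)
  expect_identical(cd$pattern, rep(rep(1:6, each = 5L), 2L))
  expect_identical(cd$block, rep(c(FALSE, TRUE), each = 30L))
  expect_true(all(rowSums(labelMatrix(corpus)) == 200L))
  expect_true(all(labelMatrix(corpus)[!cd$block, 1] == 0L))
  expect_identical(sort(unique(groupIds(corpus))), 1:12)
  # deterministic for a fixed seed
  again <- buildCorpus(fixtureTemplate(), simConfig(nPerGroup = 5L),
                       seed = 101)
  expect_identical(waveforms(again), waveforms(corpus))
  expect_identical(labelMatrix(again), labelMatrix(corpus))
})

test_that("label bins stay consistent with the slowing pattern per group", {
  corpus <- fixtureSmallCorpus()
  cd <- SummarizedExperiment::colData(corpus)
  lab <- labelMatrix(corpus)
  bins <- cvBins()
  # pattern 2 without block concentrates all 200 axons in 11-19 m/s
  sel <- cd$pattern == 2L & !cd$block
  expect_true(all(rowSums(lab[sel, bins >= 11 & bins <= 19]) == 200L))
  # pattern 3 without block stays within 21-35 m/s
  sel3 <- cd$pattern == 3L & !cd$block
  expect_true(all(rowSums(lab[sel3, bins >= 21 & bins <= 35]) == 200L))
})

test_that("splitting is disjoint, exhaustive, sized and reproducible", {
  corpus <- fixtureSmallCorpus()
  cfg <- simConfig(nPerGroup = 5L)
  colnames(corpus) <- paste0("s", seq_len(ncol(corpus)))
  sp <- splitCorpus(corpus, cfg, seed = 55)
  expect_identical(ncol(trainSet(sp)), 48L)
  expect_identical(ncol(testSet(sp)), 12L)
  ids <- c(colnames(trainSet(sp)), colnames(testSet(sp)))
  expect_identical(anyDuplicated(ids), 0L)       # disjoint
  expect_setequal(ids, colnames(corpus))          # exhaustive
  sp2 <- splitCorpus(corpus, cfg, seed = 55)
  expect_identical(waveforms(trainSet(sp2)), waveforms(trainSet(sp)))
  expect_error(splitCorpus(corpus, simConfig(trainFraction = 0.8,
                                             nPerGroup = 5L),
                           seed = 1), NA)
  bad <- simConfig(nPerGroup = 5L); bad@trainFraction <- 1.5
  expect_error(splitCorpus(corpus, bad, seed = 1), "trainFraction")
})
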