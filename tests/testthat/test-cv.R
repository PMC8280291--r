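test_that("the normal model reproduces the published healthy-nerve histogram", {
  h <- normalHistogram()
  k <- axonCounts(h); bins <- binCenters(h)
  expect_length(k, 28)
  expect_identical(sum(k), 200L)
  expect_identical(k[bins == 51], 42L)
  expect_identical(k[bins == 63], 1L)
  expect_identical(k[bins == 37], 1L)
  expect_identical(k[bins == 0], 0L)
  expect_true(all(k[bins > 0 & bins < 37] == 0L))
})

test_that("histogram <-> population round-trips and rejects blocked sources", {
  pop <- populationFromHistogram(normalHistogram())
  expect_identical(nAxons(pop), 200L)
  expect_false(any(isBlocked(pop)))
  expect_identical(normalCV(pop), forearmCV(pop))
  expect_identical(axonCounts(histogramFromPopulation(pop)),
                   axonCounts(normalHistogram()))

  one <- integer(28); one[cvBins() == 53] <- 1L
  p1 <- populationFromHistogram(CVHistogram(one))
  expect_identical(normalCV(p1), 53L)
  expect_identical(forearmCV(p1), 53L)
  expect_false(isBlocked(p1))

  bad <- integer(28); bad[1] <- 1L; bad[cvBins() == 53] <- 199L
  expect_error(populationFromHistogram(CVHistogram(bad)), "bin 0")
})

test_that("allowed CV sets follow the six slowing patterns", {
  expect_setequal(allowedCVs(4, 53), c(53, 51, 49, 47, 45))
  expect_setequal(allowedCVs(6, 53),
                  c(53, 51, 49, 47, 45, 19, 17, 15, 13, 11))
  expect_setequal(allowedCVs(1, 11), 11)
  expect_setequal(allowedCVs(1, 53), seq(53, 11, by = -2))
  expect_setequal(allowedCVs(2, 63), c(11, 13, 15, 17, 19))
  expect_setequal(allowedCVs(3, 37), seq(21, 35, by = 2))
  expect_setequal(allowedCVs(5, 53), seq(53, 33, by = -2))
  # pattern-6 duplicates collapse for slow originals
  expect_setequal(allowedCVs(6, 19), seq(19, 11, by = -2))
  expect_error(allowedCVs(7, 53), "pattern")
  expect_error(allowedCVs(1, 52), "odd")
  expect_error(allowedCVs(1, 65), "odd")
})

test_that("demyelination draws stay inside the allowed sets for all patterns", {
  base <- populationFromHistogram(normalHistogram())
  for (p in 1:6) {
    for (seed in c(1, 20, 300)) {
      pop <- applyDemyelination(base, p, seed = seed)
      expect_identical(normalCV(pop), normalCV(base))
      expect_identical(patternId(pop), as.integer(p))
      ok <- vapply(seq_len(nAxons(pop)), function(i)
        forearmCV(pop)[i] %in% allowedCVs(p, normalCV(pop)[i]),
        logical(1))
      expect_true(all(ok))
    }
  }
  # pattern 2 pins every forearm CV to the severe range
  pop2 <- applyDemyelination(base, 2, seed = 9)
  expect_true(all(forearmCV(pop2) %in% c(11, 13, 15, 17, 19)))
  # identical seeds give identical populations
  expect_identical(forearmCV(applyDemyelination(base, 4, seed = 77)),
                   forearmCV(applyDemyelination(base, 4, seed = 77)))
  # slowing is rejected after block
  blocked <- applyConductionBlock(base, 0.5, seed = 1)
  expect_error(applyDemyelination(blocked, 1), "before conduction block")
})

test_that("conduction block honours its probability at the extremes", {
  base <- applyDemyelination(populationFromHistogram(normalHistogram()),
                             1, seed = 2)
  expect_false(any(isBlocked(applyConductionBlock(base, 0, seed = 1))))
  allb <- applyConductionBlock(base, 1, seed = 1)
  expect_true(all(isBlocked(allb)))
  expect_true(all(synthesizeCMAP(fixtureTemplate(), allb) == 0))
  expect_error(applyConductionBlock(base, 1.2), "\\[0, 1\\]")
  expect_error(applyConductionBlock(base, -0.1), "\\[0, 1\\]")
  # block leaves the CVs untouched
  some <- applyConductionBlock(base, 0.4, seed = 3)
  expect_identical(forearmCV(some), forearmCV(base))
})

test_that("population histograms conserve axon counts and route blocked axons to bin 0", {
  for (seed in c(3, 14, 159)) {
    pop <- randomPopulation(seed)
    k <- axonCounts(histogramFromPopulation(pop))
    expect_identical(sum(k), 200L)
    expect_identical(k[1], sum(isBlocked(pop)))
    # brute-force recount per bin
    recount <- vapply(cvBins(), function(b) {
      if (b == 0) sum(isBlocked(pop))
      else sum(forearmCV(pop)[!isBlocked(pop)] == b)
    }, numeric(1))
    expect_identical(k, as.integer(recount))
  }
  allb <- applyConductionBlock(fixtureNormalPop(), 1, seed = 8)
  expect_identical(axonCounts(histogramFromPopulation(allb))[1], 200L)
})

test_that("histogram CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  h <- histogramFromPopulation(randomPopulation(5))
  writeCVHistogram(h, path)
  expect_identical(axonCounts(readCVHistogram(path)), axonCounts(h))
})
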