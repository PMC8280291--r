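test_that("synthetic templates are gated, deterministic and linear in amplitude", {
  tpl <- syntheticSMUP(1.0, onset = 4.0, seed = 0)
  t <- sampleTimes(tpl); a <- amplitudes(tpl)
  expect_length(a, 150)
  expect_equal(diff(t), rep(0.1, 149), tolerance = 1e-12)
  expect_true(all(a[t < 3.5] == 0))
  expect_true(all(a[t >= 12.1] == 0))
  expect_gt(max(abs(a)), 0)
  # biphasic, negative deflection first
  expect_lt(which.min(a), which.max(a))
  expect_lt(min(a), 0); expect_gt(max(a), 0)

  # determinism: same inputs and seed give bit-identical output
  expect_identical(a, amplitudes(syntheticSMUP(1.0, onset = 4.0, seed = 0)))
  # different seed gives a different (still valid) morphology
  expect_false(identical(a, amplitudes(syntheticSMUP(1.0, 4.0, seed = 1))))

  # amplitude scales the waveform pointwise
  a2 <- amplitudes(syntheticSMUP(2.0, onset = 4.0, seed = 0))
  nz <- a != 0
  expect_equal(a2[nz] / a[nz], rep(2.0, sum(nz)))

  expect_error(syntheticSMUP(-1, 4.0, 0), "positive")
  expect_error(syntheticSMUP(0, 4.0, 0), "positive")
  expect_error(syntheticSMUP(1, 2.0, 0), "gate window")
})

test_that("gating is idempotent and enforced by the class", {
  tpl <- syntheticSMUP(1.5, onset = 5.0, seed = 3)
  expect_identical(amplitudes(applyGate(tpl)), amplitudes(tpl))
  expect_identical(amplitudes(applyGate(applyGate(tpl))),
                   amplitudes(tpl))
  # construction gates raw amplitudes
  raw <- rep(1, 150)
  tpl2 <- SMUPTemplate(raw)
  expect_true(all(amplitudes(tpl2)[smupTimes() < 3.5] == 0))
  expect_true(all(amplitudes(tpl2)[smupTimes() >= 12.1] == 0))
  expect_true(all(amplitudes(tpl2)[smupTimes() >= 3.5 &
                                     smupTimes() < 12.05] == 1))
})

test_that("natural spline is exact at knots and reproduces linear data", {
  x <- seq(0, 2, by = 0.25)
  y <- 2 * x
  q <- seq(0, 2, by = 0.01)
  expect_equal(smoothSpline(x, y, q), 2 * q, tolerance = 1e-12)
  # exact at the knots for curved data too
  set.seed(4)
  y2 <- rnorm(length(x))
  expect_equal(smoothSpline(x, y2, x), y2, tolerance = 1e-12)
})

test_that("natural spline matches a brute-force tridiagonal oracle", {
  x <- seq(0, 1, by = 0.1)
  y <- x^3
  got <- smoothSpline(x, y, 0.05)
  expect_equal(got, oracleNaturalSpline(x, y, 0.05), tolerance = 1e-10)
  expect_lt(abs(got - 0.000125), 1e-3)
  set.seed(11)
  y3 <- rnorm(length(x))
  q <- runif(40, 0, 1)
  expect_equal(smoothSpline(x, y3, q), oracleNaturalSpline(x, y3, q),
               tolerance = 1e-9)
})

test_that("spline input validation rejects bad inputs", {
  expect_error(smoothSpline(c(0, 1, 2), c(1, 2, 3), 0.5), "4 points")
  expect_error(smoothSpline(c(0, 1, 1, 2), c(1, 2, 3, 4), 0.5),
               "increasing")
  expect_error(smoothSpline(0:4, rnorm(5), 4.5), "extrapolation")
})

test_that("CSV templates load, resample to 150 samples and gate", {
  tpl <- syntheticSMUP(1.0, onset = 4.0, seed = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSMUP(tpl, path)
  got <- loadSMUP(path)
  expect_length(amplitudes(got), 150)
  # spline through the grid points reproduces them inside the gate
  inside <- smupTimes() >= 3.5 & smupTimes() < 12.1
  expect_equal(amplitudes(got)[inside], amplitudes(tpl)[inside],
               tolerance = 1e-6)

  # all-zero input stays zero
  write.csv(data.frame(t = smupTimes(), a = 0), path, row.names = FALSE)
  expect_true(all(amplitudes(loadSMUP(path)) == 0))

  # denser 0.05 ms sampling still resamples to the 150-point grid
  tf <- seq(0, 14.95, by = 0.05)
  write.csv(data.frame(t = tf, a = sin(tf)), path, row.names = FALSE)
  expect_length(amplitudes(loadSMUP(path)), 150)
})

test_that("malformed sMUP files are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,0.0", "0.2,0.1", "0.1,0.2", "0.3,0.1"), path)
  expect_error(loadSMUP(path), "line 3")
  writeLines(c("0.0,0.0", "0.1,abc", "0.2,0.1"), path)
  expect_error(loadSMUP(path), "line 2")
  writeLines(character(), path)
  expect_error(loadSMUP(path), "empty")
})
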