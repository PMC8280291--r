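#' Create a simulation configuration
#'
#' @param distalDistance mm from wrist stimulation site to muscle (70).
#' @param forearmDistance mm from wrist to elbow (200).
#' @param dt sampling interval, ms (0.1).
#' @param windowMs closed CMAP window end, ms (25).
#' @param nAxons axons per population (200).
#' @param blockProb per-axon conduction-block probability (0.4).
#' @param nPerGroup sets per (pattern, block) group (1000).
#' @param trainFraction training share of the corpus (0.8).
#' @param referenceCV m/s whose two-segment latency defines shift zero (63).
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(distalDistance = 70, forearmDistance = 200, dt = 0.1,
                      windowMs = 25, nAxons = 200L, blockProb = 0.4,
                      nPerGroup = 1000L, trainFraction = 0.8,
                      referenceCV = 63) {
  new("SimConfig", distalDistance = distalDistance,
      forearmDistance = forearmDistance, dt = dt, windowMs = windowMs,
      nAxons = as.integer(nAxons), blockProb = blockProb,
      nPerGroup = as.integer(nPerGroup), trainFraction = trainFraction,
      referenceCV = referenceCV)
}

# number of CMAP samples in the closed window
windowSamples <- function(config) {
  as.integer(round(config@windowMs / config@dt)) + 1L
}

#' Per-axon latency shift relative to the reference axon
#'
#' The shift (ms) each axon's sMUP copy receives before superposition:
#' distal latency (distalDistance / normal CV) plus forearm latency
#' (forearmDistance / forearm CV), minus the latency of a reference axon
#' conducting at \code{referenceCV} in both segments. mm divided by m/s
#' gives ms. With the default 63 m/s reference the shift is non-negative.
#'
#' @param pop an \linkS4class{AxonPopulation}.
#' @param config a \linkS4class{SimConfig}.
#' @return Numeric vector, one shift in ms per axon (blocked axons
#'   included; the synthesizer ignores them).
#' @examples
#' pop <- populationFromHistogram(normalHistogram())
#' range(axonLatencyShift(pop, simConfig()))
#' @export
axonLatencyShift <- function(pop, config = simConfig()) {
  ncv <- as.numeric(pop@normalCV)
  fcv <- as.numeric(pop@forearmCV)
  if (any(ncv <= 0) || any(fcv <= 0)) stop("CVs must be positive")
  ref <- (config@distalDistance + config@forearmDistance) / config@referenceCV
  config@distalDistance / ncv + config@forearmDistance / fcv - ref
}

#' Synthesize a CMAP waveform from a population
#'
#' Each conducting axon contributes one copy of the sMUP template delayed
#' by its latency shift, rounded to the nearest 0.1 ms grid step; the
#' copies are summed over the closed [0, 25] ms window (251 samples) and
#' anything falling beyond the window is truncated. Blocked axons
#' contribute exactly zero, so an all-blocked population yields the zero
#' waveform.
#'
#' @param template an \linkS4class{SMUPTemplate} on the 0.1 ms grid.
#' @param pop an \linkS4class{AxonPopulation}.
#' @param config a \linkS4class{SimConfig}.
#' @return Numeric vector of 251 amplitudes (mV).
#' @export
synthesizeCMAP <- function(template, pop, config = simConfig()) {
  if (!is(template, "SMUPTemplate")) stop("template must be an SMUPTemplate")
  if (abs(config@dt - 0.1) > 1e-12)
    stop("template grid (0.1 ms) does not match config dt")
  nOut <- windowSamples(config)
  keep <- !pop@blocked
  if (!any(keep)) return(numeric(nOut))
  tau <- axonLatencyShift(pop, config)[keep]
  steps <- as.integer(floor(tau / config@dt + 0.5))
  as.numeric(cmap_superpose(steps, template@amplitudes, nOut))
}

#' Build the labeled training corpus
#'
#' For each of the 12 groups -- demyelination patterns 1--6 crossed with
#' conduction block absent/present -- \code{nPerGroup} populations are
#' drawn from the normal model, slowed, optionally blocked, and paired
#' with their 251-sample waveform and 28-bin label. With defaults this
#' yields 12,000 labeled sets. Deterministic given the seed.
#'
#' @param template an \linkS4class{SMUPTemplate}.
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer seed for the whole corpus.
#' @return A \linkS4class{CMAPCorpus} with 12 * nPerGroup columns, ordered
#'   block-absent patterns 1..6 then block-present patterns 1..6.
#' @export
buildCorpus <- function(template, config = simConfig(), seed = 1L) {
  base <- populationFromHistogram(normalHistogram())
  if (nAxons(base) != config@nAxons)
    base <- new("AxonPopulation",
                normalCV = rep(base@normalCV, length.out = config@nAxons),
                forearmCV = rep(base@forearmCV, length.out = config@nAxons),
                blocked = rep(FALSE, config@nAxons),
                patternId = 0L, cbApplied = FALSE)
  npg <- config@nPerGroup
  N <- 12L * npg
  nOut <- windowSamples(config)
  W <- matrix(0, nrow = nOut, ncol = N)
  L <- matrix(0L, nrow = N, ncol = 28L)
  pat <- integer(N); blk <- logical(N)
  withSeed(seed, {
    i <- 0L
    for (block in c(FALSE, TRUE)) {
      for (p in 1:6) {
        for (s in seq_len(npg)) {
          i <- i + 1L
          pop <- applyDemyelination(base, p)
          if (block)
            pop <- applyConductionBlock(pop, config@blockProb)
          W[, i] <- synthesizeCMAP(template, pop, config)
          L[i, ] <- axonCounts(histogramFromPopulation(pop))
          pat[i] <- p; blk[i] <- block
        }
      }
    }
  })
  CMAPCorpus(W, L, pat, blk, config)
}

#' Construct a labeled corpus from matrices
#'
#' @param waveforms numeric matrix, 251 rows (samples) by N columns (sets).
#' @param labels integer matrix, N rows by 28 columns.
#' @param pattern integer vector of demyelination patterns (1--6).
#' @param block logical vector of conduction-block flags.
#' @param config the generating \linkS4class{SimConfig}.
#' @return A \linkS4class{CMAPCorpus}.
#' @export
CMAPCorpus <- function(waveforms, labels, pattern, block,
                       config = simConfig()) {
  waveforms <- as.matrix(waveforms)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  cd <- S4Vectors::DataFrame(pattern = as.integer(pattern),
                             block = as.logical(block))
  cd$label <- labels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cmap = waveforms), colData = cd)
  S4Vectors::metadata(se)$config <- config
  new("CMAPCorpus", se)
}

#' @rdname CMAPCorpus-class
#' @export
setMethod("waveforms", "CMAPCorpus", function(x)
  SummarizedExperiment::assay(x, "cmap"))
#' @rdname CMAPCorpus-class
#' @export
setMethod("labelMatrix", "CMAPCorpus", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname CMAPCorpus-class
#' @details \code{groupIds} maps (pattern, block) to 1..12: patterns 1--6
#'   without block are groups 1--6, with block groups 7--12.
#' @export
setMethod("groupIds", "CMAPCorpus", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cd$pattern + 6L * as.integer(cd$block)
})

#' Human-readable group label
#' @param pattern integer 1--6.
#' @param block logical.
#' @return Character like "p4 CB+".
#' @export
groupLabel <- function(pattern, block) {
  paste0("p", pattern, ifelse(block, " CB+", " CB-"))
}

setMethod("show", "CMAPCorpus", function(object) {
  cat("CMAPCorpus: ", ncol(object), " labeled sets, ",
      nrow(object), " waveform samples, ",
      length(unique(groupIds(object))), " groups\n", sep = "")
})

#' Split a corpus into training and held-out portions
#'
#' Uniform random partition without replacement (no stratification by
#' group). The training size is \code{round(trainFraction * N)}.
#'
#' @param corpus a \linkS4class{CMAPCorpus}.
#' @param config a \linkS4class{SimConfig} (supplies trainFraction).
#' @param seed integer seed for the partition.
#' @return A \linkS4class{DatasetSplit}.
#' @export
splitCorpus <- function(corpus, config = simConfig(), seed = 1L) {
  N <- ncol(corpus)
  if (N == 0L) stop("corpus is empty")
  f <- config@trainFraction
  if (f <= 0 || f >= 1) stop("trainFraction must lie in (0, 1)")
  ntr <- as.integer(round(f * N))
  idx <- withSeed(seed, sample.int(N, ntr))
  new("DatasetSplit", train = corpus[, sort(idx)],
      test = corpus[, setdiff(seq_len(N), idx)],
      seed = as.integer(seed))
}

#' @rdname DatasetSplit-class
#' @export
setMethod("trainSet", "DatasetSplit", function(x) x@train)
#' @rdname DatasetSplit-class
#' @export
setMethod("testSet", "DatasetSplit", function(x) x@test)

setMethod("show", "DatasetSplit", function(object) {
  cat("DatasetSplit: ", ncol(object@train), " train / ",
      ncol(object@test), " test sets (seed ", object@seed, ")\n", sep = "")
})

#' Write / read a corpus as a directory of plain-text files
#'
#' \code{waveforms.csv} (one set per row, 251 columns), \code{labels.csv}
#' (one set per row, 28 columns), \code{groups.csv} (pattern, block) and
#' \code{config.json}.
#'
#' @param corpus a \linkS4class{CMAPCorpus}.
#' @param dir output directory (created if needed).
#' @return \code{writeCorpus}: invisibly, the directory.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(waveforms(corpus)),
                     file.path(dir, "waveforms.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(labelMatrix(corpus), file.path(dir, "labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  cd <- SummarizedExperiment::colData(corpus)
  utils::write.csv(data.frame(pattern = cd$pattern, block = cd$block),
                   file.path(dir, "groups.csv"), row.names = FALSE)
  cfg <- S4Vectors::metadata(corpus)$config
  jsonlite::write_json(configToList(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCorpus
#' @return \code{readCorpus}: a \linkS4class{CMAPCorpus}.
#' @export
readCorpus <- function(dir) {
  W <- as.matrix(utils::read.table(file.path(dir, "waveforms.csv"),
                                   sep = ","))
  L <- as.matrix(utils::read.table(file.path(dir, "labels.csv"),
                                   sep = ","))
  g <- utils::read.csv(file.path(dir, "groups.csv"))
  cfg <- configFromList(
    jsonlite::read_json(file.path(dir, "config.json"),
                        simplifyVector = TRUE))
  CMAPCorpus(t(unname(W)), unname(L), g$pattern, g$block, cfg)
}

configToList <- function(config) {
  list(distalDistance = config@distalDistance,
       forearmDistance = config@forearmDistance, dt = config@dt,
       windowMs = config@windowMs, nAxons = config@nAxons,
       blockProb = config@blockProb, nPerGroup = config@nPerGroup,
       trainFraction = config@trainFraction,
       referenceCV = config@referenceCV)
}

configFromList <- function(x) {
  do.call(simConfig, x)
}
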