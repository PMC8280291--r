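#' Single motor unit potential template
#'
#' The unit waveform every conducting axon contributes to the CMAP: 150
#' amplitude samples (mV) on the uniform 0.1 ms grid covering [0, 15) ms,
#' gated to exactly 0 mV outside the gate window (default 3.5--12.1 ms) so
#' that stimulus artifact and baseline noise regions never enter the
#' superposition.
#'
#' @slot times numeric(150), sample times in ms (0.1 ms spacing).
#' @slot amplitudes numeric(150), amplitudes in mV.
#' @slot gateWindow numeric(2), (start, end) of the non-zero window in ms;
#'   samples at t < start or t >= end are forced to 0.
#' @export
setClass("SMUPTemplate",
  representation(times = "numeric", amplitudes = "numeric",
                 gateWindow = "numeric"),
  prototype(times = numeric(), amplitudes = numeric(),
            gateWindow = c(3.5, 12.1)))

setValidity("SMUPTemplate", function(object) {
  t <- object@times; a <- object@amplitudes; gw <- object@gateWindow
  if (length(t) != 150L || length(a) != 150L)
    return("template must hold exactly 150 samples")
  if (max(abs(diff(t) - 0.1)) > 1e-9 || abs(t[1]) > 1e-9)
    return("sample times must be 0, 0.1, ..., 14.9 ms")
  if (length(gw) != 2L || gw[1] >= gw[2])
    return("gateWindow must be an increasing (start, end) pair")
  outside <- t < gw[1] - 1e-9 | t >= gw[2] - 1e-9
  if (any(a[outside] != 0))
    return("amplitudes must be exactly 0 outside the gate window")
  if (anyNA(a)) return("amplitudes contain NA")
  TRUE
})

#' Conduction-velocity histogram (axon counts per bin)
#'
#' Axon counts over the fixed 28 bins \code{cvBins()} = (0, 11, 13, ...,
#' 63) m/s. Bin 0 holds conduction-blocked axons. Histograms derived from an
#' \linkS4class{AxonPopulation} sum to the population size (200 by default);
#' rounded network predictions need not conserve that sum and the class does
#' not enforce it.
#'
#' @slot counts integer(28), non-negative axon counts.
#' @export
setClass("CVHistogram", representation(counts = "integer"))

setValidity("CVHistogram", function(object) {
  k <- object@counts
  if (length(k) != 28L) return("counts must have length 28")
  if (anyNA(k) || any(k < 0L)) return("counts must be non-negative integers")
  TRUE
})

#' A population of motor axons
#'
#' Each axon carries a normal-range conduction velocity (its distal-segment
#' CV, drawn from the normal-model histogram), a forearm-segment CV (equal
#' to the normal CV before demyelination, possibly slower after), and a
#' conduction-block flag. Velocities are odd integers in m/s.
#'
#' @slot normalCV integer vector, odd values in [37, 63] m/s.
#' @slot forearmCV integer vector, odd values in [11, 63] m/s.
#' @slot blocked logical vector, TRUE for axons failing to conduct.
#' @slot patternId integer(1), demyelination pattern 1--6, or 0 for the
#'   unmodified normal population.
#' @slot cbApplied logical(1), whether the conduction-block step has run.
#' @export
setClass("AxonPopulation",
  representation(normalCV = "integer", forearmCV = "integer",
                 blocked = "logical", patternId = "integer",
                 cbApplied = "logical"),
  prototype(patternId = 0L, cbApplied = FALSE))

setValidity("AxonPopulation", function(object) {
  n <- length(object@normalCV)
  if (length(object@forearmCV) != n || length(object@blocked) != n)
    return("normalCV, forearmCV and blocked must have equal length")
  if (any(object@normalCV %% 2L != 1L) || any(object@forearmCV %% 2L != 1L))
    return("conduction velocities must be odd integers")
  if (any(object@normalCV < 37L) || any(object@normalCV > 63L))
    return("normal CVs must lie in [37, 63] m/s")
  if (any(object@forearmCV < 11L) || any(object@forearmCV > 63L))
    return("forearm CVs must lie in [11, 63] m/s")
  if (!(object@patternId %in% 0:6)) return("patternId must be 0..6")
  TRUE
})

#' Simulation configuration
#'
#' Geometry, sampling and corpus-size parameters of the forward model.
#' Defaults reproduce the study conditions: 70 mm wrist-to-muscle distal
#' distance, 200 mm wrist-to-elbow forearm distance, 0.1 ms sampling over a
#' closed [0, 25] ms window (251 samples), 200 axons, 40% per-axon block
#' probability, 1,000 sets per group, 80% training fraction, and latency
#' shifts referenced to an axon conducting at 63 m/s in both segments.
#'
#' @slot distalDistance mm, wrist to abductor pollicis brevis.
#' @slot forearmDistance mm, wrist to elbow.
#' @slot dt ms, sampling interval.
#' @slot windowMs ms, closed CMAP window end; windowMs/dt + 1 samples.
#' @slot nAxons number of axons per population.
#' @slot blockProb per-axon conduction-block probability.
#' @slot nPerGroup sets generated per (pattern, block) group.
#' @slot trainFraction fraction of the corpus assigned to training.
#' @slot referenceCV m/s, the CV whose latency defines the zero shift.
#' @export
setClass("SimConfig",
  representation(distalDistance = "numeric", forearmDistance = "numeric",
                 dt = "numeric", windowMs = "numeric", nAxons = "integer",
                 blockProb = "numeric", nPerGroup = "integer",
                 trainFraction = "numeric", referenceCV = "numeric"),
  prototype(distalDistance = 70, forearmDistance = 200, dt = 0.1,
            windowMs = 25, nAxons = 200L, blockProb = 0.4,
            nPerGroup = 1000L, trainFraction = 0.8, referenceCV = 63))

setValidity("SimConfig", function(object) {
  if (object@distalDistance <= 0 || object@forearmDistance <= 0)
    return("distances must be positive")
  if (object@dt <= 0 || object@windowMs <= 0)
    return("dt and windowMs must be positive")
  if (abs(object@windowMs / object@dt - round(object@windowMs / object@dt)) > 1e-9)
    return("windowMs must be a multiple of dt")
  if (object@blockProb < 0 || object@blockProb > 1)
    return("blockProb must lie in [0, 1]")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  if (object@nAxons < 1L || object@nPerGroup < 1L)
    return("nAxons and nPerGroup must be positive")
  TRUE
})

#' Labeled CMAP corpus
#'
#' A \linkS4class{SummarizedExperiment} whose columns are simulated sets:
#' the \code{"cmap"} assay holds the 251-sample waveforms (mV, one column
#' per set), and \code{colData} carries the demyelination \code{pattern}
#' (1--6), the conduction-\code{block} flag, and the 28-bin axon-count
#' \code{label} matrix. The generating \linkS4class{SimConfig} is stored in
#' \code{metadata(x)$config}.
#'
#' @export
setClass("CMAPCorpus", contains = "SummarizedExperiment")

setValidity("CMAPCorpus", function(object) {
  if (!"cmap" %in% SummarizedExperiment::assayNames(object))
    return("corpus must carry a 'cmap' assay")
  if (nrow(object) != 251L)
    return("waveforms must have 251 samples (rows)")
  cd <- SummarizedExperiment::colData(object)
  need <- c("pattern", "block", "label")
  if (!all(need %in% colnames(cd)))
    return("colData must contain 'pattern', 'block' and 'label'")
  if (ncol(cd$label) != 28L)
    return("label matrix must have 28 columns")
  TRUE
})

#' Train/test partition of a corpus
#'
#' @slot train \linkS4class{CMAPCorpus} training portion.
#' @slot test \linkS4class{CMAPCorpus} held-out portion (also used as the
#'   validation set during training).
#' @slot seed integer seed that produced the partition.
#' @export
setClass("DatasetSplit",
  representation(train = "CMAPCorpus", test = "CMAPCorpus",
                 seed = "integer"))

#' Recurrent network architecture
#'
#' @slot cell one of "simple_rnn", "lstm", "gru".
#' @slot bidirectional logical; wrap each recurrent layer with a reversed
#'   twin and concatenate features.
#' @slot nLayers 1--3 recurrent layers (simple_rnn: 1 only).
#' @slot hiddenUnits units per layer per direction (default 1000).
#' @slot dropoutRate dropout applied to each recurrent layer's output
#'   during training (default 0.5).
#' @export
setClass("ModelSpec",
  representation(cell = "character", bidirectional = "logical",
                 nLayers = "integer", hiddenUnits = "integer",
                 dropoutRate = "numeric"),
  prototype(cell = "lstm", bidirectional = FALSE, nLayers = 1L,
            hiddenUnits = 1000L, dropoutRate = 0.5))

setValidity("ModelSpec", function(object) {
  if (!object@cell %in% c("simple_rnn", "lstm", "gru"))
    return("cell must be 'simple_rnn', 'lstm' or 'gru'")
  if (!(object@nLayers %in% 1:3)) return("nLayers must be 1, 2 or 3")
  if (object@cell == "simple_rnn" && object@nLayers != 1L)
    return("simple_rnn is only used with a single layer")
  if (object@hiddenUnits < 1L) return("hiddenUnits must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  TRUE
})

#' Training configuration
#'
#' Mirrors the fixed training recipe: mean-squared-error loss over the 28
#' outputs, Adam at its default rate, up to 1,000 epochs, batch size 2,048,
#' early stopping that monitors the training loss with patience 2.
#'
#' @slot maxEpochs upper bound on epochs (default 1000).
#' @slot batchSize minibatch size (default 2048).
#' @slot learningRate Adam step size (default 0.001, the framework default).
#' @slot patience epochs without training-loss improvement tolerated before
#'   stopping (default 2).
#' @slot seed integer; controls weight initialization, shuffling, dropout.
#' @slot standardize logical; if TRUE, waveforms are scaled by the global
#'   standard deviation of the training waveforms before entering the
#'   network (off by default; the raw mV scale is used).
#' @export
setClass("TrainConfig",
  representation(maxEpochs = "integer", batchSize = "integer",
                 learningRate = "numeric", patience = "integer",
                 seed = "integer", standardize = "logical"),
  prototype(maxEpochs = 1000L, batchSize = 2048L, learningRate = 0.001,
            patience = 2L, seed = 1L, standardize = FALSE))

setValidity("TrainConfig", function(object) {
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@patience < 0L) return("patience must be >= 0")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' Training history and final metrics
#'
#' @slot history data.frame with one row per completed epoch: epoch,
#'   trainLoss, trainAccuracy, valLoss, valAccuracy. Training loss/accuracy
#'   are averaged over the epoch's minibatches (dropout active); validation
#'   metrics are computed on the held-out set in evaluation mode.
#' @slot stoppedEpoch integer, the epoch at which training stopped.
#' @export
setClass("TrainResult",
  representation(history = "data.frame", stoppedEpoch = "integer"))

#' A recurrent sequence-to-vector regressor
#'
#' Weights live in a flat list of matrices (per layer and direction: input
#' kernel, recurrent kernel, bias; then the dense projection). Built by
#' \code{\link{buildModel}}, fitted by \code{\link{trainModel}}.
#'
#' @slot spec \linkS4class{ModelSpec} architecture.
#' @slot inputDim features per timestep (1 for a univariate waveform).
#' @slot outputDim regression outputs (28 histogram bins).
#' @slot weights list of numeric matrices/vectors.
#' @slot inputScale divisor applied to input waveforms (1 unless trained
#'   with standardize = TRUE).
#' @slot outputScale multiplier applied to the dense-layer outputs; the
#'   network is fitted in standardized label units (counts divided by the
#'   training labels' standard deviation) for numerical conditioning and
#'   predictions are rescaled to counts.
#' @slot trained logical.
#' @slot result \linkS4class{TrainResult} of the last fit (empty history
#'   when untrained).
#' @export
setClass("RNNModel",
  representation(spec = "ModelSpec", inputDim = "integer",
                 outputDim = "integer", weights = "list",
                 inputScale = "numeric", outputScale = "numeric",
                 trained = "logical", result = "TrainResult"),
  prototype(inputScale = 1, outputScale = 1, trained = FALSE))
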