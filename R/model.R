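#' Create a recurrent architecture specification
#'
#' @param cell "simple_rnn", "lstm" or "gru".
#' @param bidirectional wrap each layer with a reversed twin (default
#'   FALSE).
#' @param nLayers 1--3 recurrent layers (simple_rnn: 1 only).
#' @param hiddenUnits units per layer per direction (default 1000).
#' @param dropoutRate dropout on each recurrent layer's output (default
#'   0.5).
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("lstm", bidirectional = TRUE, nLayers = 2)
#' @export
modelSpec <- function(cell = "lstm", bidirectional = FALSE, nLayers = 1L,
                      hiddenUnits = 1000L, dropoutRate = 0.5) {
  new("ModelSpec", cell = cell, bidirectional = bidirectional,
      nLayers = as.integer(nLayers), hiddenUnits = as.integer(hiddenUnits),
      dropoutRate = dropoutRate)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: ", if (object@bidirectional) "bidirectional " else "",
      object@cell, ", ", object@nLayers, " layer(s), ",
      object@hiddenUnits, " units, dropout ", object@dropoutRate, "\n",
      sep = "")
})

#' Create a training configuration
#'
#' @param maxEpochs epoch cap (default 1000).
#' @param batchSize minibatch size (default 2048).
#' @param learningRate Adam step size (default 0.001).
#' @param patience epochs without training-loss improvement before early
#'   stop (default 2).
#' @param seed integer controlling shuffling and dropout.
#' @param standardize scale input waveforms by the training-set standard
#'   deviation (default FALSE).
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(maxEpochs = 1000L, batchSize = 2048L,
                        learningRate = 0.001, patience = 2L, seed = 1L,
                        standardize = FALSE) {
  new("TrainConfig", maxEpochs = as.integer(maxEpochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      patience = as.integer(patience), seed = as.integer(seed),
      standardize = standardize)
}

specToList <- function(spec, inputDim, outputDim) {
  list(cell = match(spec@cell, c("simple_rnn", "lstm", "gru")) - 1L,
       bidir = spec@bidirectional, layers = spec@nLayers,
       hidden = spec@hiddenUnits, input_dim = as.integer(inputDim),
       output_dim = as.integer(outputDim), dropout = spec@dropoutRate)
}

#' Build an untrained sequence-to-vector regressor
#'
#' Consumes a length-251 univariate sequence and emits 28 unconstrained
#' real outputs: a stack of recurrent layers (bidirectional twins when
#' flagged; intermediate layers return full sequences, the final layer its
#' last hidden state) followed by a dense projection. Input kernels use
#' Glorot-uniform initialization, recurrent kernels orthogonal blocks, and
#' the LSTM forget-gate bias starts at 1.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param inputDim features per timestep (default 1).
#' @param outputDim outputs (default 28).
#' @param seed integer controlling initialization.
#' @return An untrained \linkS4class{RNNModel}.
#' @examples
#' m <- buildModel(modelSpec("lstm", TRUE, 2, hiddenUnits = 8), seed = 1)
#' countParameters(m)
#' @export
buildModel <- function(spec, inputDim = 1L, outputDim = 28L, seed = 1L) {
  validObject(spec)
  w <- rnn_init_cpp(specToList(spec, inputDim, outputDim),
                    as.integer(seed))
  new("RNNModel", spec = spec, inputDim = as.integer(inputDim),
      outputDim = as.integer(outputDim), weights = w, inputScale = 1,
      outputScale = 1, trained = FALSE,
      result = new("TrainResult", history = emptyHistory(),
                   stoppedEpoch = 0L))
}

emptyHistory <- function() {
  data.frame(epoch = integer(), trainLoss = numeric(),
             trainAccuracy = numeric(), valLoss = numeric(),
             valAccuracy = numeric())
}

#' @rdname RNNModel-class
#' @export
setMethod("countParameters", "RNNModel", function(x)
  sum(vapply(x@weights, length, integer(1))))

setMethod("show", "RNNModel", function(object) {
  show(object@spec)
  cat("  ", countParameters(object), " parameters, input (",
      object@inputDim, " x T) -> output ", object@outputDim, "; ",
      if (object@trained) "trained" else "untrained", "\n", sep = "")
})

#' Fit a recurrent regressor on a dataset split
#'
#' Minimizes mean squared error over the 28 outputs with Adam. Training
#' stops at \code{maxEpochs} or when the training loss has not improved
#' for \code{patience} consecutive epochs. The held-out portion of the
#' split supplies the per-epoch validation metrics; "accuracy" is
#' dominant-bin (argmax) agreement, see
#' \code{\link{dominantBinAccuracy}}.
#'
#' @param model an \linkS4class{RNNModel}.
#' @param split a \linkS4class{DatasetSplit} (or a list with elements
#'   \code{train}/\code{test} of \linkS4class{CMAPCorpus}).
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print per-epoch metrics.
#' @return The trained \linkS4class{RNNModel}; its \code{result} slot
#'   holds the \linkS4class{TrainResult}.
#' @export
trainModel <- function(model, split, config = trainConfig(),
                       verbose = FALSE) {
  validObject(config)
  tr <- if (is(split, "DatasetSplit")) trainSet(split) else split$train
  te <- if (is(split, "DatasetSplit")) testSet(split) else split$test
  if (is.null(tr) || ncol(tr) == 0L) stop("empty training set")
  Xtr <- t(waveforms(tr))                     # sets x 251
  Ytr <- labelMatrix(tr)
  if (ncol(Xtr) == 0L || nrow(Xtr) != nrow(Ytr))
    stop("waveforms and labels are dimensionally inconsistent")
  scale <- 1
  if (config@standardize) {
    scale <- stats::sd(as.numeric(Xtr))
    if (!is.finite(scale) || scale == 0) scale <- 1
  }
  # the network is fitted in standardized label units; losses are
  # converted back to squared-count units below
  yscale <- stats::sd(as.numeric(Ytr))
  if (!is.finite(yscale) || yscale == 0) yscale <- 1
  Xva <- matrix(0, 0, ncol(Xtr)); Yva <- matrix(0, 0, ncol(Ytr))
  if (!is.null(te) && ncol(te) > 0L) {
    Xva <- t(waveforms(te)) / scale
    Yva <- labelMatrix(te) / yscale
  }
  fit <- rnn_train_cpp(model@weights,
                       specToList(model@spec, model@inputDim,
                                  model@outputDim),
                       Xtr / scale, Ytr / yscale, Xva, Yva,
                       config@maxEpochs, config@batchSize,
                       config@learningRate, config@patience,
                       config@seed, verbose)
  hist <- data.frame(epoch = seq_along(fit$train_loss),
                     trainLoss = fit$train_loss * yscale^2,
                     trainAccuracy = fit$train_acc,
                     valLoss = fit$val_loss * yscale^2,
                     valAccuracy = fit$val_acc)
  model@weights <- fit$params
  model@inputScale <- scale
  model@outputScale <- yscale
  model@trained <- TRUE
  model@result <- new("TrainResult", history = hist,
                      stoppedEpoch = as.integer(fit$stopped_epoch))
  model
}

#' @rdname TrainResult-class
#' @export
setMethod("trainResult", "RNNModel", function(x) x@result)
#' @rdname TrainResult-class
#' @export
setMethod("trainingHistory", "TrainResult", function(x) x@history)
#' @rdname TrainResult-class
#' @export
setMethod("trainingHistory", "RNNModel", function(x) x@result@history)
#' @rdname TrainResult-class
#' @export
setMethod("stoppedEpoch", "TrainResult", function(x) x@stoppedEpoch)
#' @rdname TrainResult-class
#' @export
setMethod("stoppedEpoch", "RNNModel", function(x) x@result@stoppedEpoch)

#' Final metrics of a training run
#' @param x a \linkS4class{TrainResult} or trained \linkS4class{RNNModel}.
#' @return Named numeric: trainLoss, trainAccuracy, valLoss, valAccuracy.
#' @export
finalMetrics <- function(x) {
  h <- trainingHistory(x)
  if (nrow(h) == 0L) stop("no training history")
  unlist(h[nrow(h), c("trainLoss", "trainAccuracy", "valLoss",
                      "valAccuracy")])
}

setMethod("show", "TrainResult", function(object) {
  h <- object@history
  cat("TrainResult: ", nrow(h), " epoch(s), stopped at ",
      object@stoppedEpoch, "\n", sep = "")
  if (nrow(h))
    cat("  final: ",
        paste(names(finalMetrics(object)),
              signif(finalMetrics(object), 4),
              sep = "=", collapse = " "), "\n", sep = "")
})

#' Raw network outputs for a batch of waveforms
#'
#' @param model a trained \linkS4class{RNNModel}.
#' @param waveforms numeric matrix, one 251-sample waveform per row (a
#'   single waveform vector is also accepted), or a
#'   \linkS4class{CMAPCorpus}.
#' @return Numeric matrix, one 28-vector of unrounded outputs per row.
#' @export
predictCounts <- function(model, waveforms) {
  if (!model@trained) stop("model has not been trained")
  if (is(waveforms, "CMAPCorpus")) waveforms <- t(waveforms(waveforms))
  if (is.null(dim(waveforms))) waveforms <- matrix(waveforms, nrow = 1)
  rnn_predict_cpp(model@weights,
                  specToList(model@spec, model@inputDim, model@outputDim),
                  as.matrix(waveforms) / model@inputScale) *
    model@outputScale
}

# half-away-from-zero rounding, then clip below at 0
roundCounts <- function(x) {
  pmax(sign(x) * floor(abs(x) + 0.5), 0)
}

#' Predict a CV histogram from one CMAP waveform
#'
#' Raw outputs are rounded half-away-from-zero to integers and clipped
#' below at zero. The rounded prediction is not forced to sum to the
#' population size: conservation is a property of true labels, not of the
#' regressor.
#'
#' @param model a trained \linkS4class{RNNModel}.
#' @param waveform numeric(251) amplitudes in mV.
#' @return A \linkS4class{CVHistogram}.
#' @export
predictHistogram <- function(model, waveform) {
  raw <- predictCounts(model, waveform)
  CVHistogram(roundCounts(raw[1, ]))
}

#' Dominant-bin accuracy
#'
#' Fraction of cases where the predicted histogram's largest bin is the
#' true histogram's largest bin (ties broken toward the first index on
#' both sides). This is the accuracy notion used for all reported
#' metrics; chance level is about 1/28 for labels whose dominant bin is
#' uniform over the 28 bins.
#'
#' @param predictions numeric matrix N x 28.
#' @param labels numeric matrix N x 28.
#' @return Fraction in [0, 1].
#' @export
dominantBinAccuracy <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  if (!all(dim(predictions) == dim(labels)))
    stop("predictions and labels must have matching shapes")
  if (nrow(predictions) < 1L) stop("need at least one case")
  mean(max.col(predictions, ties.method = "first") ==
         max.col(labels, ties.method = "first"))
}

#' Exact-match rate of rounded predictions
#'
#' The stricter companion metric: the fraction of cases whose rounded,
#' clipped prediction equals the true label in every one of the 28 bins.
#'
#' @inheritParams dominantBinAccuracy
#' @return Fraction in [0, 1].
#' @export
exactMatchRate <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  if (!all(dim(predictions) == dim(labels)))
    stop("predictions and labels must have matching shapes")
  mean(rowSums(roundCounts(predictions) != labels) == 0L)
}

#' Save / load model weights as plain text
#'
#' Writes the architecture to \code{spec.json} and each weight matrix to
#' its own CSV file in \code{dir}.
#'
#' @param model an \linkS4class{RNNModel}.
#' @param dir directory (created if needed).
#' @return \code{saveModel}: invisibly, the directory.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(cell = model@spec@cell,
               bidirectional = model@spec@bidirectional,
               nLayers = model@spec@nLayers,
               hiddenUnits = model@spec@hiddenUnits,
               dropoutRate = model@spec@dropoutRate,
               inputDim = model@inputDim, outputDim = model@outputDim,
               inputScale = model@inputScale,
               outputScale = model@outputScale, trained = model@trained,
               weightNames = names(model@weights))
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(model@weights))
    utils::write.table(model@weights[[nm]],
                       file.path(dir, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname saveModel
#' @return \code{loadModel}: an \linkS4class{RNNModel}.
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  spec <- modelSpec(meta$cell, meta$bidirectional, meta$nLayers,
                    meta$hiddenUnits, meta$dropoutRate)
  w <- lapply(meta$weightNames, function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                sep = ",")))
  w <- lapply(w, function(m) { dimnames(m) <- NULL; m })
  names(w) <- meta$weightNames
  new("RNNModel", spec = spec, inputDim = as.integer(meta$inputDim),
      outputDim = as.integer(meta$outputDim), weights = w,
      inputScale = meta$inputScale,
      outputScale = if (is.null(meta$outputScale)) 1 else meta$outputScale,
      trained = meta$trained,
      result = new("TrainResult", history = emptyHistory(),
                   stoppedEpoch = 0L))
}

#' Export a training history as CSV
#'
#' Columns: epoch, train_loss, train_acc, val_loss, val_acc.
#' @param x a \linkS4class{TrainResult} or trained \linkS4class{RNNModel}.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
writeTrainResult <- function(x, path) {
  h <- trainingHistory(x)
  names(h) <- c("epoch", "train_loss", "train_acc", "val_loss", "val_acc")
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
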