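#' The 13-architecture comparison grid
#'
#' One simple RNN (single layer) plus LSTM, bidirectional LSTM, GRU and
#' bidirectional GRU at one, two and three layers.
#'
#' @param hiddenUnits units per layer (default 1000).
#' @param dropoutRate dropout rate (default 0.5).
#' @return List of 13 \linkS4class{ModelSpec} objects.
#' @export
standardGrid <- function(hiddenUnits = 1000L, dropoutRate = 0.5) {
  specs <- list(modelSpec("simple_rnn", FALSE, 1L, hiddenUnits,
                          dropoutRate))
  for (cell in c("lstm", "gru"))
    for (bidir in c(FALSE, TRUE))
      for (nl in 1:3)
        specs <- c(specs, modelSpec(cell, bidir, nl, hiddenUnits,
                                    dropoutRate))
  specs
}

specLabel <- function(spec) {
  paste0(if (spec@bidirectional) "bi_" else "", spec@cell, "_",
         spec@nLayers, "L")
}

#' Train every architecture in a grid and tabulate final metrics
#'
#' Each spec is trained on the same split with the same training
#' configuration, and its final training/validation loss and dominant-bin
#' accuracy are collected. The best row maximizes validation accuracy,
#' breaking ties by minimal validation loss. A spec whose training fails
#' is kept as a row with NA metrics and the error message rather than
#' aborting the grid.
#'
#' @param split a \linkS4class{DatasetSplit}.
#' @param specs list of \linkS4class{ModelSpec} (default
#'   \code{standardGrid()}).
#' @param config a \linkS4class{TrainConfig}; its seed also seeds each
#'   model's initialization.
#' @param verbose print progress.
#' @return data.frame with one row per spec (cell, bidirectional, nLayers,
#'   trainLoss, trainAccuracy, valLoss, valAccuracy, stoppedEpoch, error)
#'   and attribute \code{best} giving the best row index; the fitted
#'   models are attached as attribute \code{models}.
#' @export
runNetworkGrid <- function(split, specs = standardGrid(),
                           config = trainConfig(), verbose = FALSE) {
  if (length(specs) < 1L) stop("need at least one spec")
  rows <- vector("list", length(specs))
  models <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (verbose) message("training ", specLabel(sp))
    row <- data.frame(cell = sp@cell, bidirectional = sp@bidirectional,
                      nLayers = sp@nLayers, trainLoss = NA_real_,
                      trainAccuracy = NA_real_, valLoss = NA_real_,
                      valAccuracy = NA_real_, stoppedEpoch = NA_integer_,
                      error = "")
    fit <- tryCatch({
      m <- buildModel(sp, seed = config@seed)
      trainModel(m, split, config, verbose = FALSE)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      row$error <- conditionMessage(fit)
    } else {
      fm <- finalMetrics(fit)
      row$trainLoss <- fm[["trainLoss"]]
      row$trainAccuracy <- fm[["trainAccuracy"]]
      row$valLoss <- fm[["valLoss"]]
      row$valAccuracy <- fm[["valAccuracy"]]
      row$stoppedEpoch <- stoppedEpoch(fit)
      models[[i]] <- fit
    }
    rows[[i]] <- row
  }
  report <- do.call(rbind, rows)
  ok <- !is.na(report$valAccuracy)
  best <- NA_integer_
  if (any(ok)) {
    cand <- which(ok & report$valAccuracy ==
                    max(report$valAccuracy[ok]))
    best <- cand[which.min(report$valLoss[cand])]
  }
  attr(report, "best") <- best
  attr(report, "models") <- models
  report
}

#' Loss and accuracy per (pattern, conduction-block) group
#'
#' Computes MSE loss and dominant-bin accuracy of one trained model
#' separately for each of the 12 simulation groups, on both the training
#' and held-out partitions. Groups absent from a partition yield NA
#' metrics with \code{missing = TRUE}.
#'
#' @param model a trained \linkS4class{RNNModel}.
#' @param split a \linkS4class{DatasetSplit}.
#' @return data.frame with columns pattern, block, n train/test counts and
#'   trainLoss, trainAccuracy, valLoss, valAccuracy, missing.
#' @export
evaluateByGroup <- function(model, split) {
  if (!model@trained) stop("model has not been trained")
  partMetrics <- function(corpus) {
    pred <- predictCounts(model, corpus)
    lab <- labelMatrix(corpus)
    gid <- groupIds(corpus)
    list(pred = pred, lab = lab, gid = gid)
  }
  tr <- partMetrics(trainSet(split))
  te <- partMetrics(testSet(split))
  rows <- lapply(1:12, function(g) {
    p <- (g - 1L) %% 6L + 1L
    blk <- g > 6L
    one <- function(part) {
      sel <- part$gid == g
      if (!any(sel)) return(c(NA_real_, NA_real_, 0))
      d <- part$pred[sel, , drop = FALSE] - part$lab[sel, , drop = FALSE]
      c(mean(d^2),
        dominantBinAccuracy(part$pred[sel, , drop = FALSE],
                            part$lab[sel, , drop = FALSE]),
        sum(sel))
    }
    a <- one(tr); b <- one(te)
    data.frame(pattern = p, block = blk, group = groupLabel(p, blk),
               nTrain = a[3], nTest = b[3],
               trainLoss = a[1], trainAccuracy = a[2],
               valLoss = b[1], valAccuracy = b[2],
               missing = a[3] == 0 | b[3] == 0)
  })
  do.call(rbind, rows)
}

#' Export true-versus-predicted histogram pairs
#'
#' For each selected set, writes \code{set_<i>_hist.csv} with 28 rows of
#' (bin_center_m_per_s, true_count, predicted_count) -- the prediction
#' rounded half-away-from-zero and clipped at zero -- and
#' \code{set_<i>_waveform.csv} with the 251 (time_ms, amplitude_mv)
#' samples. Inference is deterministic, so re-export produces identical
#' files.
#'
#' @param model a trained \linkS4class{RNNModel}.
#' @param corpus a \linkS4class{CMAPCorpus} holding the sets to export.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of histogram file paths.
#' @export
exportPredictionPairs <- function(model, corpus, dir) {
  if (!model@trained) stop("model has not been trained")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pred <- roundCounts(predictCounts(model, corpus))
  lab <- labelMatrix(corpus)
  W <- waveforms(corpus)
  paths <- character(ncol(corpus))
  for (i in seq_len(ncol(corpus))) {
    hp <- file.path(dir, sprintf("set_%d_hist.csv", i))
    utils::write.csv(
      data.frame(bin_center_m_per_s = cvBins(), true_count = lab[i, ],
                 predicted_count = as.integer(pred[i, ])),
      hp, row.names = FALSE)
    utils::write.csv(
      data.frame(time_ms = cmapTimes(), amplitude_mv = W[, i]),
      file.path(dir, sprintf("set_%d_waveform.csv", i)),
      row.names = FALSE)
    paths[i] <- hp
  }
  invisible(paths)
}
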