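#' @rdname SMUPTemplate-class
#' @param x,object an object.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname SMUPTemplate-class
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname SMUPTemplate-class
#' @export
setGeneric("gateWindow", function(x) standardGeneric("gateWindow"))

#' @rdname CVHistogram-class
#' @param x an object.
#' @export
setGeneric("axonCounts", function(x) standardGeneric("axonCounts"))
#' @rdname CVHistogram-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname AxonPopulation-class
#' @param x an object.
#' @export
setGeneric("nAxons", function(x) standardGeneric("nAxons"))
#' @rdname AxonPopulation-class
#' @export
setGeneric("normalCV", function(x) standardGeneric("normalCV"))
#' @rdname AxonPopulation-class
#' @export
setGeneric("forearmCV", function(x) standardGeneric("forearmCV"))
#' @rdname AxonPopulation-class
#' @export
setGeneric("isBlocked", function(x) standardGeneric("isBlocked"))
#' @rdname AxonPopulation-class
#' @export
setGeneric("patternId", function(x) standardGeneric("patternId"))

#' @rdname CMAPCorpus-class
#' @param x an object.
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))
#' @rdname CMAPCorpus-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname CMAPCorpus-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname DatasetSplit-class
#' @param x an object.
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))
#' @rdname DatasetSplit-class
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname RNNModel-class
#' @param x an object.
#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))
#' @rdname TrainResult-class
#' @export
setGeneric("trainResult", function(x) standardGeneric("trainResult"))
#' @rdname TrainResult-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname TrainResult-class
#' @export
setGeneric("stoppedEpoch", function(x) standardGeneric("stoppedEpoch"))
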