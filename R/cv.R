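#' Construct a CV histogram
#'
#' @param counts integer(28) axon counts over \code{cvBins()}.
#' @return A \linkS4class{CVHistogram}.
#' @export
CVHistogram <- function(counts) {
  if (length(counts) != 28L) stop("counts must have length 28")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be whole numbers")
  new("CVHistogram", counts = as.integer(round(counts)))
}

#' @rdname CVHistogram-class
#' @export
setMethod("axonCounts", "CVHistogram", function(x) x@counts)
#' @rdname CVHistogram-class
#' @export
setMethod("binCenters", "CVHistogram", function(x) cvBins())

setMethod("show", "CVHistogram", function(object) {
  k <- object@counts
  cat("CVHistogram: ", sum(k), " axons over 28 bins (0, 11..63 m/s)\n",
      sep = "")
  nz <- which(k > 0)
  if (length(nz))
    cat("  nonzero: ",
        paste0(cvBins()[nz], "m/s:", k[nz], collapse = " "), "\n", sep = "")
})

#' The normal-model CV histogram
#'
#' Axon counts per 2 m/s velocity bin for a healthy median nerve, scaled to
#' 200 axons (the motor unit number estimate used throughout): counts
#' 1, 2, 2, 6, 18, 30, 42, 39, 27, 17, 9, 4, 2, 1 at 63, 61, ..., 37 m/s.
#' All other bins, including the 0 m/s conduction-block bin, are zero.
#'
#' @return A \linkS4class{CVHistogram} summing to 200.
#' @examples
#' h <- normalHistogram()
#' sum(axonCounts(h))
#' @export
normalHistogram <- function() {
  bins <- cvBins()
  counts <- integer(28)
  descending <- c(1L, 2L, 2L, 6L, 18L, 30L, 42L, 39L, 27L, 17L, 9L, 4L,
                  2L, 1L)  # at 63, 61, ..., 37 m/s
  counts[match(seq(63L, 37L, by = -2L), bins)] <- descending
  CVHistogram(counts)
}

#' @rdname AxonPopulation-class
#' @export
setMethod("nAxons", "AxonPopulation", function(x) length(x@normalCV))
#' @rdname AxonPopulation-class
#' @export
setMethod("normalCV", "AxonPopulation", function(x) x@normalCV)
#' @rdname AxonPopulation-class
#' @export
setMethod("forearmCV", "AxonPopulation", function(x) x@forearmCV)
#' @rdname AxonPopulation-class
#' @export
setMethod("isBlocked", "AxonPopulation", function(x) x@blocked)
#' @rdname AxonPopulation-class
#' @export
setMethod("patternId", "AxonPopulation", function(x) x@patternId)

setMethod("show", "AxonPopulation", function(object) {
  cat("AxonPopulation: ", length(object@normalCV), " axons, pattern ",
      object@patternId, ", ", sum(object@blocked), " blocked\n", sep = "")
})

#' Expand a CV histogram into an axon population
#'
#' One unblocked axon per histogram unit, with the forearm CV equal to the
#' normal CV (the bin center). Round-trips with
#' \code{\link{histogramFromPopulation}}. The 0 m/s bin must be empty: a
#' source histogram has no blocked axons.
#'
#' @param hist a \linkS4class{CVHistogram} with zero count in bin 0.
#' @return An \linkS4class{AxonPopulation}.
#' @export
populationFromHistogram <- function(hist) {
  k <- axonCounts(hist)
  if (k[1] > 0L)
    stop("bin 0 must be empty: a source histogram has no blocked axons")
  cvs <- rep(as.integer(cvBins()[-1]), k[-1])
  new("AxonPopulation", normalCV = cvs, forearmCV = cvs,
      blocked = rep(FALSE, length(cvs)), patternId = 0L,
      cbApplied = FALSE)
}

#' Forearm CVs an axon may be slowed to under a demyelination pattern
#'
#' Pattern 1 ("entire range"): unchanged or any slower odd CV down to
#' 11 m/s. Pattern 2 ("severe"): 11--19 m/s. Pattern 3 ("moderate"):
#' 21--35 m/s. Pattern 4 ("mild"): up to 8 m/s slower. Pattern 5
#' ("moderate 2"): up to 20 m/s slower. Pattern 6 ("two distributions"):
#' the pattern-4 set plus 11--19 m/s.
#'
#' @param pattern integer 1--6.
#' @param originalCV odd integer in [37, 63] m/s.
#' @return Integer vector of allowed odd CVs (descending, duplicates
#'   removed).
#' @examples
#' allowedCVs(4, 53)
#' @export
allowedCVs <- function(pattern, originalCV) {
  if (!(pattern %in% 1:6)) stop("pattern must be 1..6")
  v <- as.integer(originalCV)
  if (length(v) != 1L || v %% 2L != 1L || v < 11L || v > 63L)
    stop("originalCV must be an odd integer in [11, 63] m/s")
  out <- switch(as.character(pattern),
    "1" = seq(v, 11L, by = -2L),
    "2" = seq(19L, 11L, by = -2L),
    "3" = seq(35L, 21L, by = -2L),
    "4" = seq(v, max(v - 8L, 11L), by = -2L),
    "5" = seq(v, max(v - 20L, 11L), by = -2L),
    "6" = c(seq(v, max(v - 8L, 11L), by = -2L), seq(19L, 11L, by = -2L)))
  unique(out)
}

# per-pattern lookup: row i = allowed set for normal CV 35 + 2i, NA-padded
patternTable <- local({
  cache <- new.env(parent = emptyenv())
  function(pattern) {
    key <- as.character(pattern)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cvs <- seq(37L, 63L, by = 2L)
    sets <- lapply(cvs, function(v) allowedCVs(pattern, v))
    M <- matrix(NA_integer_, nrow = length(cvs), ncol = max(lengths(sets)))
    for (i in seq_along(sets)) M[i, seq_along(sets[[i]])] <- sets[[i]]
    cache[[key]] <- list(M = M, k = lengths(sets))
    cache[[key]]
  }
})

#' Slow the forearm-segment CVs of a population
#'
#' Each conducting axon's forearm CV is redrawn uniformly at random from
#' \code{\link{allowedCVs}} for the given pattern and that axon's normal
#' CV; the normal (distal-segment) CV is unchanged. Slowing precedes
#' conduction block: an already-blocked population is rejected.
#'
#' @param pop an unblocked \linkS4class{AxonPopulation}.
#' @param pattern integer 1--6.
#' @param seed optional integer; when NULL the current RNG stream is used.
#' @param weights optional per-pattern probability weights over the allowed
#'   set positions (recycled per axon, longest set first); default uniform.
#' @return The slowed population, with \code{patternId} set.
#' @export
applyDemyelination <- function(pop, pattern, seed = NULL, weights = NULL) {
  if (pop@cbApplied || any(pop@blocked))
    stop("demyelination must be applied before conduction block")
  tab <- patternTable(pattern)
  n <- nAxons(pop)
  idx <- (pop@normalCV - 35L) %/% 2L
  k <- tab$k[idx]
  draw <- function() {
    if (is.null(weights)) {
      j <- pmin(pmax(ceiling(stats::runif(n) * k), 1L), k)
    } else {
      j <- vapply(seq_len(n), function(i) {
        w <- weights[seq_len(k[i])]
        sample.int(k[i], 1L, prob = w)
      }, integer(1))
    }
    tab$M[cbind(idx, as.integer(j))]
  }
  fore <- if (is.null(seed)) draw() else withSeed(seed, draw())
  new("AxonPopulation", normalCV = pop@normalCV, forearmCV = fore,
      blocked = pop@blocked, patternId = as.integer(pattern),
      cbApplied = FALSE)
}

#' Apply per-axon conduction block
#'
#' Each axon is independently blocked with probability \code{blockProb}
#' (default 0.4). Blocked axons keep their CVs but contribute nothing to
#' the CMAP and are counted in the 0 m/s histogram bin.
#'
#' @param pop an \linkS4class{AxonPopulation}.
#' @param blockProb probability in [0, 1].
#' @param seed optional integer; when NULL the current RNG stream is used.
#' @return The population with block flags set and \code{cbApplied = TRUE}.
#' @export
applyConductionBlock <- function(pop, blockProb = 0.4, seed = NULL) {
  if (!is.numeric(blockProb) || blockProb < 0 || blockProb > 1)
    stop("blockProb must lie in [0, 1]")
  n <- nAxons(pop)
  draw <- function() stats::runif(n) < blockProb
  blocked <- if (is.null(seed)) draw() else withSeed(seed, draw())
  new("AxonPopulation", normalCV = pop@normalCV,
      forearmCV = pop@forearmCV, blocked = blocked,
      patternId = pop@patternId, cbApplied = TRUE)
}

#' Label histogram of a population
#'
#' Blocked axons fall into the 0 m/s bin; conducting axons are counted at
#' their forearm CV. Counts always sum to the population size.
#'
#' @param pop an \linkS4class{AxonPopulation}.
#' @return A \linkS4class{CVHistogram}.
#' @export
histogramFromPopulation <- function(pop) {
  bins <- cvBins()
  idx <- match(pop@forearmCV, bins)
  if (anyNA(idx))
    stop("forearm CV not among the label bins; pattern logic is broken")
  idx[pop@blocked] <- 1L
  CVHistogram(tabulate(idx, nbins = 28L))
}

#' Read / write a CV histogram as two-column CSV
#'
#' Columns: bin_center_m_per_s, count.
#' @param hist a \linkS4class{CVHistogram}.
#' @param path CSV path.
#' @return \code{writeCVHistogram}: invisibly, the path.
#' @export
writeCVHistogram <- function(hist, path) {
  utils::write.csv(
    data.frame(bin_center_m_per_s = cvBins(), count = axonCounts(hist)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCVHistogram
#' @return \code{readCVHistogram}: a \linkS4class{CVHistogram}.
#' @export
readCVHistogram <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("histogram CSV needs two columns")
  if (!isTRUE(all.equal(as.numeric(d[[1]]), cvBins())))
    stop("histogram CSV bin centers must be cvBins()")
  CVHistogram(d[[2]])
}

#' Serialize a population to CSV (normal_cv, forearm_cv, blocked)
#'
#' @param pop an \linkS4class{AxonPopulation}.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
writePopulation <- function(pop, path) {
  utils::write.csv(
    data.frame(normal_cv = pop@normalCV, forearm_cv = pop@forearmCV,
               blocked = pop@blocked),
    path, row.names = FALSE)
  invisible(path)
}
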