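#' Construct an sMUP template from amplitudes on the standard grid
#'
#' Amplitudes are gated (forced to 0 mV outside the gate window) before the
#' object is built, so every template satisfies the class invariants.
#'
#' @param amplitudes numeric(150), mV on the grid \code{smupTimes()}.
#' @param gateWindow numeric(2), ms; samples at t < start or t >= end are
#'   zeroed. Default c(3.5, 12.1).
#' @return A \linkS4class{SMUPTemplate}.
#' @export
SMUPTemplate <- function(amplitudes, gateWindow = c(3.5, 12.1)) {
  t <- smupTimes()
  if (length(amplitudes) != length(t))
    stop("amplitudes must have length ", length(t))
  new("SMUPTemplate", times = t,
      amplitudes = gateAmplitudes(as.numeric(amplitudes), t, gateWindow),
      gateWindow = as.numeric(gateWindow))
}

# zero everything outside [start, end); idempotent
gateAmplitudes <- function(a, t, gw) {
  a[t < gw[1] - 1e-9 | t >= gw[2] - 1e-9] <- 0
  a
}

#' Re-apply a template's gate
#'
#' Forces amplitudes to 0 mV outside the gate window. Idempotent: templates
#' are already gated on construction, so this is a no-op unless the object
#' was manipulated directly.
#'
#' @param template an \linkS4class{SMUPTemplate}.
#' @return The gated template.
#' @export
applyGate <- function(template) {
  SMUPTemplate(template@amplitudes, template@gateWindow)
}

#' @rdname SMUPTemplate-class
#' @export
setMethod("sampleTimes", "SMUPTemplate", function(x) x@times)
#' @rdname SMUPTemplate-class
#' @export
setMethod("amplitudes", "SMUPTemplate", function(x) x@amplitudes)
#' @rdname SMUPTemplate-class
#' @export
setMethod("gateWindow", "SMUPTemplate", function(x) x@gateWindow)

setMethod("show", "SMUPTemplate", function(object) {
  a <- object@amplitudes
  cat("SMUPTemplate: 150 samples @ 0.1 ms, gate [",
      object@gateWindow[1], ", ", object@gateWindow[2], ") ms\n", sep = "")
  cat("  amplitude range: [", signif(min(a), 4), ", ", signif(max(a), 4),
      "] mV\n", sep = "")
})

#' Generate a synthetic biphasic sMUP
#'
#' A smooth surrogate for a surface-recorded single motor unit potential:
#' two opposed Gaussian lobes giving the conventional negative-then-positive
#' biphasic deflection, placed inside the gate window. The waveform scales
#' linearly with \code{peakAmplitude}; the seed jitters the lobe widths
#' slightly so distinct seeds give distinct but equally valid morphologies.
#'
#' @param peakAmplitude positive peak magnitude of the negative lobe, mV.
#' @param onset ms, approximate takeoff of the negative deflection; must lie
#'   inside the gate window and leave room for the waveform's support.
#' @param seed integer controlling the width jitter.
#' @param gateWindow numeric(2) ms, default c(3.5, 12.1).
#' @return A \linkS4class{SMUPTemplate}.
#' @examples
#' tpl <- syntheticSMUP(1.0, onset = 4.0, seed = 0)
#' range(amplitudes(tpl))
#' @export
syntheticSMUP <- function(peakAmplitude, onset = 4.0, seed = 0,
                          gateWindow = c(3.5, 12.1)) {
  if (!is.numeric(peakAmplitude) || peakAmplitude <= 0)
    stop("peakAmplitude must be positive")
  if (onset < gateWindow[1] || onset > gateWindow[2])
    stop("onset must lie inside the gate window")
  jitter <- withSeed(seed, stats::runif(2, -0.1, 0.1))
  s1 <- 0.5 * (1 + jitter[1])   # negative-lobe width, ms
  s2 <- 1.2 * (1 + jitter[2])   # positive-lobe width, ms
  m1 <- onset + 2 * s1
  m2 <- m1 + 1.5 * (s1 + s2)
  if (m2 + 2.5 * s2 > gateWindow[2])
    stop("waveform support would exceed the gate window; reduce onset")
  t <- smupTimes()
  shape <- -exp(-(t - m1)^2 / (2 * s1^2)) +
    0.45 * exp(-(t - m2)^2 / (2 * s2^2))
  a <- shape * (peakAmplitude / max(abs(shape)))
  SMUPTemplate(a, gateWindow)
}

#' Natural cubic-spline smoothing/interpolation
#'
#' Fits a natural cubic spline (second derivative zero at the end knots)
#' through (times, amplitudes) and evaluates it at \code{queryTimes}. Exact
#' at the knots; no extrapolation is performed.
#'
#' @param times strictly increasing knot times, ms (>= 4 points).
#' @param amplitudes knot amplitudes, mV.
#' @param queryTimes evaluation times within [min(times), max(times)].
#' @return Numeric vector of interpolated amplitudes.
#' @export
smoothSpline <- function(times, amplitudes, queryTimes) {
  if (length(times) < 4L) stop("need at least 4 points for a cubic spline")
  if (length(times) != length(amplitudes))
    stop("times and amplitudes must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(queryTimes < times[1] - 1e-12) ||
      any(queryTimes > times[length(times)] + 1e-12))
    stop("query times outside the input range; extrapolation is not supported")
  f <- stats::splinefun(times, amplitudes, method = "natural")
  f(queryTimes)
}

#' Load an sMUP template from a two-column CSV
#'
#' Reads (time ms, amplitude mV) points -- e.g. a digitized published
#' waveform -- smooths them with a natural cubic spline, resamples onto the
#' 0.1 ms grid over [0, 15) ms, and gates the result to 0 mV outside the
#' gate window. Grid points outside the file's time range are set to 0.
#'
#' @param path CSV path; a header row is detected and skipped if present.
#' @param gateWindow numeric(2) ms, default c(3.5, 12.1).
#' @return A \linkS4class{SMUPTemplate}.
#' @examples
#' path <- system.file("extdata", "synthetic_smup.csv", package = "cmapnet")
#' tpl <- loadSMUP(path)
#' range(amplitudes(tpl))
#' @export
loadSMUP <- function(path, gateWindow = c(3.5, 12.1)) {
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) stop("empty or unreadable sMUP file: ", path,
                             call. = FALSE))
  if (nrow(raw) == 0L) stop("empty sMUP file: ", path)
  if (ncol(raw) < 2L) stop("sMUP file must have >= 2 columns: ", path)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(raw[1, 1])))) start <- 2L
  if (nrow(raw) < start) stop("no data rows in sMUP file: ", path)
  tm <- suppressWarnings(as.numeric(raw[start:nrow(raw), 1]))
  am <- suppressWarnings(as.numeric(raw[start:nrow(raw), 2]))
  bad <- which(is.na(tm) | is.na(am))
  if (length(bad))
    stop("non-numeric sMUP data at line ", bad[1] + start - 1L,
         " of ", path)
  nonmono <- which(diff(tm) <= 0)
  if (length(nonmono))
    stop("times not strictly increasing at line ",
         nonmono[1] + start, " of ", path)
  grid <- smupTimes()
  inside <- grid >= tm[1] & grid <= tm[length(tm)]
  a <- numeric(length(grid))
  if (length(tm) >= 4L) {
    a[inside] <- smoothSpline(tm, am, grid[inside])
  } else {
    a[inside] <- stats::approx(tm, am, xout = grid[inside])$y
  }
  SMUPTemplate(a, gateWindow)
}

#' Write an sMUP template as a two-column CSV
#'
#' @param template an \linkS4class{SMUPTemplate}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeSMUP <- function(template, path) {
  utils::write.csv(
    data.frame(time_ms = template@times, amplitude_mv = template@amplitudes),
    path, row.names = FALSE)
  invisible(path)
}
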