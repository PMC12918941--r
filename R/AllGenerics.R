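#' Noise contrasts labelling the rows of a condition matrix
#' @param x a \linkS4class{ConditionMatrix}
#' @return numeric vector of noise standard deviations
#' @export
setGeneric("noiseContrasts", function(x) standardGeneric("noiseContrasts"))

#' Band center frequencies labelling the columns of a condition matrix
#' @param x a \linkS4class{ConditionMatrix} or \linkS4class{PyramidBands}
#' @return numeric vector, cycles/image
#' @export
setGeneric("bandFrequencies", function(x) standardGeneric("bandFrequencies"))

#' Fitted channel center frequency
#' @param x a fitted channel model
#' @return center frequency in cycles/image
#' @export
setGeneric("centerFrequency", function(x) standardGeneric("centerFrequency"))

#' Fitted channel tuning width (SD of the log2-Gaussian), in octaves
#' @param x a fitted channel model
#' @return tuning width in octaves
#' @export
setGeneric("tuningWidth", function(x) standardGeneric("tuningWidth"))

#' Full width at half maximum of a log2-Gaussian tuning curve
#'
#' For a Gaussian on the log2-frequency axis with standard deviation
#' \code{w} octaves, \eqn{FWHM = 2 \sqrt{2 \ln 2}\, w}.
#'
#' @param x a fitted channel model, or a numeric tuning width in octaves
#' @return bandwidth in octaves
#' @examples
#' fwhm(2 / (2 * sqrt(2 * log(2))))  # 2-octave-wide channel
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' Recognition bandwidth: full width of the threshold curve at twice its
#' minimum power
#'
#' The noise-power threshold curve is proportional to \eqn{1 / S(f)^2} for
#' a log2-Gaussian sensitivity \eqn{S}, so its full width at twice the
#' minimum is \eqn{2 w \sqrt{\ln 2}} octaves, independent of the
#' normalization and readout parameters. Corresponds to the spectral
#' bandwidth at half-power (3 dB) sensitivity.
#'
#' @param x a \linkS4class{DecodingFit}, or a numeric tuning width in octaves
#' @return bandwidth in octaves (NA, with a warning, if the threshold curve
#'   is nowhere finite)
#' @export
setGeneric("fw2m", function(x) standardGeneric("fw2m"))

setMethod("noiseContrasts", "ConditionMatrix", function(x) x@sigmas)
setMethod("bandFrequencies", "ConditionMatrix", function(x) x@freqs)
setMethod("bandFrequencies", "PyramidBands", function(x) x@centers)

setMethod("centerFrequency", "NoiseResponseFit", function(x) x@mu)
setMethod("centerFrequency", "DecodingFit", function(x) x@mu)
setMethod("tuningWidth", "NoiseResponseFit", function(x) x@w)
setMethod("tuningWidth", "DecodingFit", function(x) x@w)

#' Extract a condition matrix as a plain labelled matrix
#' @param x a \linkS4class{ConditionMatrix}
#' @param ... ignored
#' @return numeric matrix with sigma rownames and frequency colnames
#' @export
setMethod("as.matrix", "ConditionMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(sigma = format(x@sigmas, trim = TRUE),
                      freq = format(x@freqs, trim = TRUE))
  m
})

setMethod("show", "PyramidBands", function(object) {
  cat(sprintf("PyramidBands: %d octave bands on a %dx%d grid\n",
              object@nLevels, object@N, object@N))
  cat("  centers (cycles/image):",
      paste(format(object@centers, trim = TRUE), collapse = ", "), "\n")
})

setMethod("show", "ExperimentDesign", function(object) {
  nz <- sum(object@contrasts > 0)
  cat(sprintf("ExperimentDesign: %d categories, %d bands, %d contrasts\n",
              object@nCategories, length(object@bandCenters),
              length(object@contrasts)))
  cat(sprintf("  %d unique conditions; reps (sceneNoise, noiseOnly, sceneOnly, blank) = %s\n",
              (object@nCategories + 1L) *
                (length(object@bandCenters) * nz + 1L),
              paste(object@reps, collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d voxels, %d categories\n",
              nrow(object@prototypes), ncol(object@prototypes)))
  cat(sprintf("  response channel: mu = %.3g c/img, w = %.3g oct (FWHM %.3g), betaBase = %.3g, betaMax = %.3g, sigma50 = %.3g\n",
              object@muResp, object@wResp, 2 * sqrt(2 * log(2)) * object@wResp,
              object@betaBase, object@betaMax, object@sigma50))
  cat(sprintf("  recognition channel: mu = %.3g c/img, w = %.3g oct, kappa = %.3g, m = %.3g, b = %.3g\n",
              object@muDec, object@wDec, object@kappa, object@m, object@b))
  cat(sprintf("  sceneGain = %.3g, lambda = %.3g, tau = %.3g\n",
              object@sceneGain, object@lambda, object@tau))
})

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix (%s): %d contrasts x %d bands, %d voxels\n",
              if (object@normalized) "scene-normalized" else "raw",
              length(object@sigmas), length(object@freqs), object@nVoxels))
  print(round(as.matrix(object), 4))
})

setMethod("show", "AccuracyMatrix", function(object) {
  cat(sprintf("AccuracyMatrix: %d contrasts x %d bands; baseline %.3f (n = %d)\n",
              length(object@sigmas), length(object@freqs),
              object@baseline, object@baselineN))
  print(round(as.matrix(object), 3))
})

setMethod("show", "NoiseResponseFit", function(object) {
  cat(sprintf("NoiseResponseFit%s\n",
              if (object@identifiable) "" else " (UNIDENTIFIABLE)"))
  cat(sprintf("  mu = %.3g c/img, w = %.3g oct (FWHM %.3g oct)\n",
              object@mu, object@w, 2 * sqrt(2 * log(2)) * object@w))
  cat(sprintf("  betaBase = %.3g, betaMax = %.3g, sigma50 = %.3g%s\n",
              object@betaBase, object@betaMax, object@sigma50,
              if (object@normalized) " (scene-normalized scale)" else ""))
  cat(sprintf("  SSE = %.4g, R^2 = %.3f\n", object@sse, object@r2))
})

setMethod("show", "DecodingFit", function(object) {
  cat(sprintf("DecodingFit%s\n",
              if (object@identifiable) "" else " (UNIDENTIFIABLE)"))
  cat(sprintf("  mu = %.3g c/img, w = %.3g oct, kappa = %.3g, m = %.3g, b = %.3g\n",
              object@mu, object@w, object@kappa, object@m, object@b))
  cat(sprintf("  NLL = %.4g over %d trials\n", object@nll, object@nTrials))
})
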