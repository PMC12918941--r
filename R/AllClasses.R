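#' @import methods
#' @importFrom stats rnorm runif rbinom sd cor optim median fft quantile setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' PyramidBands: the seven octave-wide band filters of an image grid
#'
#' Describes the octave-band decomposition used to construct bandpass noise:
#' for an \code{N} x \code{N} grid (\code{N} a power of two), \code{nLevels}
#' one-octave-wide spatial-frequency bands with nominal center frequencies
#' \code{0.21875 * N / 2^(nLevels - 1 - level)} cycles/image
#' (\eqn{1.75, 3.5, 7, 14, 28, 56, 112} for \code{N = 512}).
#' Band operators are realized as bandpass levels of a Laplacian pyramid
#' built on a twofold-oversampled copy of the field, so that the finest band
#' is a proper octave band rather than the pyramid's residual highpass
#' (see the methods vignette).
#'
#' @slot N side length of the square grid (power of two)
#' @slot nLevels number of octave bands
#' @slot centers nominal band center frequencies, cycles/image, coarse to
#'   fine, indexed by \code{level = 0, ..., nLevels - 1}
#' @seealso [buildPyramidBands()], [applyBandFilter()], [makeBandpassNoise()]
#' @exportClass PyramidBands
setClass("PyramidBands",
  representation(N = "integer", nLevels = "integer", centers = "numeric"))

setValidity("PyramidBands", function(object) {
  msg <- character()
  if (length(object@N) != 1L || object@N < 4L ||
      bitwAnd(object@N, object@N - 1L) != 0L)
    msg <- c(msg, "N must be a single power of two >= 4")
  if (object@nLevels < 1L || object@nLevels > as.integer(log2(object@N)) - 1L)
    msg <- c(msg, "nLevels must be in 1 .. log2(N) - 1")
  if (length(object@centers) != object@nLevels)
    msg <- c(msg, "centers must have one entry per level")
  if (length(msg)) msg else TRUE
})

#' ExperimentDesign: categories x bands x contrasts and repetition scheme
#'
#' The canonical design has 10 object categories, 7 octave noise bands and
#' 5 noise contrasts (RMS noise standard deviations) \{0, 0.02, 0.04, 0.08,
#' 0.16\}, giving (10+1) x (7*4 + 1) = 319 unique stimulus conditions:
#' scenes in noise, noise alone, scenes alone, and blanks.
#'
#' @slot nCategories number of object categories C
#' @slot bandCenters noise band center frequencies, cycles/image
#' @slot contrasts noise standard deviations, including 0
#' @slot reps repetitions per unique stimulus, named
#'   \code{c(sceneNoise, noiseOnly, sceneOnly, blank)}
#' @seealso [experimentDesign()], [enumerateConditions()], [buildTrialTable()]
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(nCategories = "integer", bandCenters = "numeric",
                 contrasts = "numeric", reps = "integer"))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (object@nCategories < 1L) msg <- c(msg, "need at least one category")
  if (length(object@bandCenters) < 1L) msg <- c(msg, "need at least one band")
  if (!any(object@contrasts > 0))
    msg <- c(msg, "need at least one non-zero contrast")
  if (any(object@contrasts < 0)) msg <- c(msg, "contrasts must be >= 0")
  if (anyDuplicated(object@contrasts)) msg <- c(msg, "duplicate contrasts")
  if (length(object@reps) != 4L || any(object@reps < 0L))
    msg <- c(msg, "reps must be four non-negative counts")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generating parameters for the voxel-level forward model
#'
#' Bundles everything needed to simulate trial-wise beta weights and
#' behavioral outcomes: category prototype patterns, the scene gain,
#' the noise-response channel (Naka-Rushton contrast response times
#' log-Gaussian frequency tuning, plus baseline), an optional scene
#' suppression factor for the noise drive on scene trials, the measurement
#' noise level, and the recognition-channel parameters used to simulate
#' classification outcomes.
#'
#' @slot prototypes V x C matrix of category prototype patterns
#' @slot sceneGain scalar gain a applied to the prototype on scene trials
#' @slot betaBase baseline response (percent-signal-change-like units)
#' @slot betaMax response scale of the noise drive
#' @slot sigma50 semi-saturation contrast of the Naka-Rushton term
#' @slot muResp,wResp center (cycles/image) and width (octaves) of the
#'   noise-response tuning
#' @slot lambda multiplier in [0,1] on the noise drive when a scene is
#'   present; 1 means additive superposition, smaller values emulate
#'   scene suppression of the noise response
#' @slot tau i.i.d. measurement noise SD per voxel and trial
#' @slot muDec,wDec,kappa,m,b recognition-channel parameters: tuning
#'   center/width, divisive-normalization strength, logistic slope and
#'   threshold
#' @seealso [groundTruth()], [simulateTrialBetas()], [simulateBehavior()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(prototypes = "matrix", sceneGain = "numeric",
                 betaBase = "numeric", betaMax = "numeric",
                 sigma50 = "numeric", muResp = "numeric", wResp = "numeric",
                 lambda = "numeric", tau = "numeric",
                 muDec = "numeric", wDec = "numeric", kappa = "numeric",
                 m = "numeric", b = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (object@sigma50 <= 0) msg <- c(msg, "sigma50 must be > 0")
  if (object@wResp <= 0 || object@wDec <= 0)
    msg <- c(msg, "tuning widths must be > 0")
  if (object@betaMax < 0) msg <- c(msg, "betaMax must be >= 0")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@lambda < 0 || object@lambda > 1)
    msg <- c(msg, "lambda must be in [0, 1]")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@muResp <= 0 || object@muDec <= 0)
    msg <- c(msg, "tuning centers must be > 0")
  if (length(msg)) msg else TRUE
})

#' CbmExperiment: trial-wise voxel responses with voxel and trial metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding the
#' \code{"betas"} assay (voxels x trials, percent-signal-change-like
#' units), voxel metadata as \code{rowData} (\code{eccentricity} in degrees
#' of visual angle, \code{r2} GLM variance explained as a fraction) and the
#' trial table as \code{colData} (\code{kind}, \code{category},
#' \code{freq}, \code{sigma}, \code{run}).
#'
#' @seealso [CbmExperiment()], [simulateTrialBetas()], [selectVoxels()]
#' @exportClass CbmExperiment
setClass("CbmExperiment", contains = "SummarizedExperiment")

setValidity("CbmExperiment", function(object) {
  msg <- character()
  if (!"betas" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'betas' is required")
  need_col <- c("kind", "category", "freq", "sigma")
  miss <- setdiff(need_col, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  need_row <- c("eccentricity", "r2")
  missr <- setdiff(need_row, colnames(SummarizedExperiment::rowData(object)))
  if (length(missr))
    msg <- c(msg, paste0("rowData lacks: ", paste(missr, collapse = ", ")))
  if (length(msg) == 0 &&
      any(!is.finite(SummarizedExperiment::assay(object, "betas"))))
    msg <- c(msg, "betas must be finite")
  if (length(msg)) msg else TRUE
})

#' ConditionMatrix: a contrasts-by-frequencies condition summary
#'
#' Base class for the noise-response matrix and the decoding-accuracy
#' matrix: a numeric matrix with one row per noise contrast (sigma) and one
#' column per noise band center frequency, plus per-cell trial counts.
#' Cells with no trials are \code{NA} (missing marker) and are excluded
#' from model fits.
#'
#' @slot values contrasts x frequencies matrix
#' @slot sigmas noise standard deviations labelling the rows
#' @slot freqs band center frequencies labelling the columns, cycles/image
#' @slot nTrials per-cell trial counts
#' @exportClass ConditionMatrix
setClass("ConditionMatrix",
  representation(values = "matrix", sigmas = "numeric", freqs = "numeric",
                 nTrials = "matrix"))

setValidity("ConditionMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@sigmas) ||
      ncol(object@values) != length(object@freqs))
    msg <- c(msg, "values dimensions must match sigma/freq labels")
  if (!identical(dim(object@values), dim(object@nTrials)))
    msg <- c(msg, "nTrials must match values in shape")
  if (length(msg)) msg else TRUE
})

#' ResponseMatrix: mean BOLD response to noise alone per condition
#'
#' The noise-response matrix: for each noise condition (sigma, f), the mean
#' over noise-only trials of the mean beta weight across selected voxels.
#' The sigma = 0 row is missing by construction (there are no zero-contrast
#' noise-only trials). The matrix may be normalized by the scene-alone
#' response, in which case \code{reference} records the divisor and the
#' scene-alone response equals 1 on the normalized scale.
#'
#' @slot normalized logical, whether scene normalization was applied
#' @slot reference scene-alone mean response used as divisor (NA if raw)
#' @slot nVoxels number of voxels averaged
#' @seealso [noiseResponseMatrix()], [normalizeByScene()], [fitNoiseResponse()]
#' @exportClass ResponseMatrix
setClass("ResponseMatrix", contains = "ConditionMatrix",
  representation(normalized = "logical", reference = "numeric",
                 nVoxels = "integer"))

#' AccuracyMatrix: proportion of correctly classified trials per condition
#'
#' Decoding accuracy for each noise condition (sigma, f) in [0, 1], with
#' per-cell trial counts, plus the zero-noise baseline accuracy computed
#' with leave-one-out. The sigma = 0 row of \code{values} repeats the
#' (frequency-independent) baseline for convenient plotting.
#'
#' @slot baseline zero-noise decoding accuracy
#' @slot baselineN number of zero-noise trials
#' @seealso [accuracyMatrix()], [behavioralAccuracyMatrix()]
#' @exportClass AccuracyMatrix
setClass("AccuracyMatrix", contains = "ConditionMatrix",
  representation(baseline = "numeric", baselineN = "integer"))

setValidity("AccuracyMatrix", function(object) {
  v <- object@values[is.finite(object@values)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    "accuracies must lie in [0, 1]" else TRUE
})

#' NoiseResponseFit: fitted noise-response channel
#'
#' Parameters of the separable noise-response model
#' \deqn{\hat R(\sigma, f) = \beta_{base} + \beta_{max}
#'   \frac{\sigma}{\sigma + \sigma_{50}}
#'   \exp\left(-\frac{(\log_2 f - \log_2 \mu)^2}{2 w^2}\right)}
#' fit by least squares, with diagnostics.
#'
#' @slot betaBase,betaMax,sigma50,mu,w model parameters; \code{mu} in
#'   cycles/image, \code{w} in octaves
#' @slot sse,r2 sum of squared errors and variance explained of the fit
#' @slot normalized whether the fitted matrix was scene-normalized
#' @slot identifiable FALSE when the data were degenerate (e.g. constant),
#'   in which case \code{mu} and \code{w} are meaningless
#' @seealso [fitNoiseResponse()], [noiseResponsePredict()], [fwhm()],
#'   [noiseThreshold()]
#' @exportClass NoiseResponseFit
setClass("NoiseResponseFit",
  representation(betaBase = "numeric", betaMax = "numeric",
                 sigma50 = "numeric", mu = "numeric", w = "numeric",
                 sse = "numeric", r2 = "numeric", normalized = "logical",
                 identifiable = "logical"))

setValidity("NoiseResponseFit", function(object) {
  msg <- character()
  if (object@sigma50 <= 0) msg <- c(msg, "sigma50 must be > 0")
  if (object@w <= 0) msg <- c(msg, "w must be > 0")
  if (object@betaMax < 0) msg <- c(msg, "betaMax must be >= 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (length(msg)) msg else TRUE
})

#' DecodingFit: fitted recognition channel
#'
#' Parameters of the probabilistic decoding model: log-Gaussian frequency
#' sensitivity \eqn{S(f)}, noise drive \eqn{D = \sigma S(f)}, divisive
#' normalization \eqn{E = (1+\kappa) D / (D + \kappa)}, and logistic
#' readout \eqn{P(correct) = 1 / (1 + e^{-m (E - b)})}, fit by binomial
#' maximum likelihood to single-trial classification outcomes. On
#' well-formed data the fitted slope \code{m} is negative (accuracy falls
#' as the normalized noise response grows).
#'
#' @slot mu,w tuning center (cycles/image) and width (octaves)
#' @slot kappa divisive-normalization strength
#' @slot m,b logistic slope and threshold
#' @slot nll negative log-likelihood at the optimum
#' @slot nTrials number of outcomes in the fit
#' @slot identifiable FALSE for degenerate data (e.g. perfect separation)
#' @seealso [fitDecodingModel()], [decodingPredict()], [thresholdCurve()],
#'   [fw2m()], [noiseTolerance()]
#' @exportClass DecodingFit
setClass("DecodingFit",
  representation(mu = "numeric", w = "numeric", kappa = "numeric",
                 m = "numeric", b = "numeric", nll = "numeric",
                 nTrials = "integer", identifiable = "logical"))

setValidity("DecodingFit", function(object) {
  msg <- character()
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@w <= 0) msg <- c(msg, "w must be > 0")
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (length(msg)) msg else TRUE
})
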