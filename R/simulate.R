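#' Simulate voxel metadata
#'
#' Draws population-receptive-field eccentricities uniformly on [0, 8]
#' degrees (so roughly a quarter of voxels fall beyond the 6-degree
#' selection cut) and GLM variance explained uniformly on [0, 0.5].
#'
#' @param V number of voxels (>= 1)
#' @param seed integer RNG seed
#' @return data.frame with columns \code{voxel}, \code{eccentricity},
#'   \code{r2}
#' @export
simulateVoxels <- function(V, seed) {
  V <- as.integer(V)
  if (is.na(V) || V < 1L) stop("V must be >= 1")
  set.seed(as.integer(seed))
  data.frame(voxel = seq_len(V),
             eccentricity = runif(V, 0, 8),
             r2 = runif(V, 0, 0.5))
}

#' Construct generating parameters for the voxel-level forward model
#'
#' Prototype patterns are drawn i.i.d. N(1, \code{protoSd}^2) per voxel
#' and category, so scene presentation raises the mean response by
#' \code{sceneGain} above baseline (keeping scene normalization and the
#' noise threshold well defined) while between-category pattern contrast
#' -- hence decodability -- is controlled by
#' \code{sceneGain * protoSd} relative to the measurement noise
#' \code{tau} and the noise drive.
#'
#' Defaults describe a V1-like region: a 2-octave-wide (FWHM) response
#' channel centered at 14 cycles/image with a strong noise response, and a
#' 2-octave (FW2M) recognition channel centered at 19 cycles/image with
#' weak divisive normalization. See [regionPresets()] for the full set of
#' ventral-stream presets.
#'
#' @param V number of voxels
#' @param nCategories number of object categories
#' @param seed seed for the prototype draw
#' @param sceneGain scene gain a
#' @param protoSd between-category pattern SD of the prototypes
#' @param betaBase,betaMax,sigma50,muResp,wResp noise-response channel
#'   (baseline, response scale, semi-saturation contrast, center
#'   cycles/image, width octaves)
#' @param lambda scene suppression of the noise drive, in [0, 1]
#'   (1 = additive)
#' @param tau measurement noise SD
#' @param muDec,wDec,kappa,m,b recognition channel (center, width,
#'   normalization strength, logistic slope and threshold)
#' @return a \linkS4class{GroundTruth}
#' @examples
#' groundTruth(V = 50, seed = 1)
#' @export
groundTruth <- function(V, nCategories = 10L, seed = 1L,
                        sceneGain = 0.8, protoSd = 0.3,
                        betaBase = 0.2, betaMax = 2, sigma50 = 0.05,
                        muResp = 14, wResp = 2 / (2 * sqrt(2 * log(2))),
                        lambda = 1, tau = 1,
                        muDec = 19, wDec = 2 / (2 * sqrt(log(2))),
                        kappa = 0.1, m = -10, b = 0.35) {
  set.seed(as.integer(seed))
  proto <- matrix(rnorm(V * nCategories, mean = 1, sd = protoSd),
                  nrow = V, ncol = nCategories)
  new("GroundTruth", prototypes = proto, sceneGain = sceneGain,
      betaBase = betaBase, betaMax = betaMax, sigma50 = sigma50,
      muResp = muResp, wResp = wResp, lambda = lambda, tau = tau,
      muDec = muDec, wDec = wDec, kappa = kappa, m = m, b = b)
}

#' Ventral-stream region presets for the simulator
#'
#' Parameter sets for five synthetic regions emulating the qualitative
#' progression along the ventral stream: the noise-response channel widens
#' (FWHM 2 to 5 octaves) and shifts to lower frequencies while its
#' amplitude relative to the scene response falls (raising the noise
#' threshold); the recognition channel keeps its center (19 cycles/image)
#' and width (FW2M 2 octaves) but its divisive normalization strengthens,
#' raising noise tolerance; scene suppression of the noise drive
#' (\code{lambda}) grows downstream.
#'
#' @return named list of argument lists for [groundTruth()]
#' @export
regionPresets <- function() {
  gauss_w <- function(f) f / (2 * sqrt(2 * log(2)))  # FWHM -> w
  list(
    V1  = list(muResp = 14, wResp = gauss_w(2.0),  betaMax = 2.0,
               lambda = 1.0, kappa = 0.10),
    V2  = list(muResp = 11, wResp = gauss_w(2.75), betaMax = 1.6,
               lambda = 0.8, kappa = 0.14),
    V3  = list(muResp = 9,  wResp = gauss_w(3.5),  betaMax = 1.3,
               lambda = 0.6, kappa = 0.19),
    V4  = list(muResp = 8,  wResp = gauss_w(4.25), betaMax = 1.05,
               lambda = 0.4, kappa = 0.26),
    VTC = list(muResp = 7,  wResp = gauss_w(5.0),  betaMax = 0.875,
               lambda = 0.2, kappa = 0.36))
}

#' Build a CbmExperiment from its components
#'
#' @param betas voxels x trials matrix of beta weights
#' @param trials data.frame with one row per trial (columns \code{kind},
#'   \code{category}, \code{freq}, \code{sigma}, ...)
#' @param voxels data.frame with one row per voxel (columns
#'   \code{eccentricity}, \code{r2}, ...)
#' @return a \linkS4class{CbmExperiment}
#' @export
CbmExperiment <- function(betas, trials, voxels) {
  stopifnot(is.matrix(betas), nrow(betas) == nrow(voxels),
            ncol(betas) == nrow(trials))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(betas = betas),
    rowData = S4Vectors::DataFrame(voxels),
    colData = S4Vectors::DataFrame(trials))
  as(se, "CbmExperiment")
}

# Naka-Rushton x log-Gaussian noise drive; sigma = 0 (or missing f) -> 0
.noise_drive <- function(sigma, freq, betaMax, sigma50, mu, w) {
  g <- ifelse(is.na(freq) | sigma <= 0, 0,
              betaMax * (sigma / (sigma + sigma50)) *
                exp(-(log2(freq) - log2(mu))^2 / (2 * w^2)))
  as.numeric(g)
}

#' Simulate trial-wise beta weights under the forward model
#'
#' For trial t with condition (kind, category c, sigma, f), the simulated
#' voxel response vector is
#' \deqn{y_t = a \mu_c [scene] + g(\sigma, f)\, s_t\, n_t +
#'   \beta_{base} 1 + \epsilon_t}
#' where \eqn{g(\sigma, f) = \beta_{max} \frac{\sigma}{\sigma+\sigma_{50}}
#' \exp(-(\log_2 f - \log_2 \mu)^2 / (2 w^2))} is the noise drive,
#' \eqn{n_t} is a fresh unit-mean, unit-variance Gaussian pattern per
#' trial (unit mean so that the noise drive survives averaging across
#' voxels; unit variance so it interferes with the multivoxel pattern),
#' \eqn{s_t = \lambda} on scene trials and 1 on noise-only trials, and
#' \eqn{\epsilon_t} is i.i.d. N(0, \eqn{\tau^2}) measurement noise. The
#' expected voxel-mean response on noise-only trials is therefore
#' \eqn{\beta_{base} + g(\sigma, f)}, the separable channel model's
#' prediction.
#'
#' @param trials trial table from [buildTrialTable()]
#' @param truth a \linkS4class{GroundTruth}
#' @param voxels voxel metadata, e.g. from [simulateVoxels()]; must have
#'   as many rows as \code{truth@prototypes}
#' @param seed integer RNG seed; identical inputs give bit-identical output
#' @return a \linkS4class{CbmExperiment}
#' @export
simulateTrialBetas <- function(trials, truth, voxels, seed) {
  stopifnot(is(truth, "GroundTruth"), nrow(trials) >= 1L)
  validObject(truth)
  V <- nrow(truth@prototypes)
  C <- ncol(truth@prototypes)
  if (nrow(voxels) != V)
    stop("voxels has ", nrow(voxels), " rows but truth has ", V, " voxels")
  cat_idx <- trials$category
  bad <- !is.na(cat_idx) & (cat_idx < 1L | cat_idx > C)
  if (any(bad))
    stop("trial categories outside ground truth: ",
         paste(unique(cat_idx[bad]), collapse = ", "))
  n_t <- nrow(trials)
  scene <- !is.na(cat_idx)

  y <- matrix(truth@betaBase, nrow = V, ncol = n_t)
  if (any(scene))
    y[, scene] <- y[, scene] +
      truth@sceneGain * truth@prototypes[, cat_idx[scene], drop = FALSE]

  g <- .noise_drive(trials$sigma, trials$freq, truth@betaMax,
                    truth@sigma50, truth@muResp, truth@wResp)
  s_t <- ifelse(scene, truth@lambda, 1)
  drive <- g * s_t

  set.seed(as.integer(seed))
  noisy <- which(drive != 0)
  if (length(noisy)) {
    n_pat <- matrix(rnorm(V * length(noisy), mean = 1, sd = 1), nrow = V)
    y[, noisy] <- y[, noisy] + sweep(n_pat, 2, drive[noisy], "*")
  }
  if (truth@tau > 0)
    y <- y + matrix(rnorm(V * n_t, sd = truth@tau), nrow = V)

  CbmExperiment(y, trials, voxels)
}

#' Simulate behavioral classification outcomes from the recognition model
#'
#' Draws independent correct/incorrect outcomes with
#' \eqn{P(correct \mid \sigma, f)} given by the recognition channel
#' (log-Gaussian sensitivity, divisive normalization, logistic readout)
#' evaluated at each condition. At \eqn{\sigma = 0} the normalized drive is
#' 0 and accuracy equals the baseline \eqn{1/(1 + e^{m b})}.
#'
#' @param conditions data.frame with columns \code{sigma} and \code{freq}
#'   (freq may be NA where sigma is 0)
#' @param truth a \linkS4class{GroundTruth} (its recognition-channel slots
#'   are used)
#' @param nPerCondition trials per condition row (scalar or vector)
#' @param seed integer RNG seed
#' @return data.frame with columns \code{sigma}, \code{freq},
#'   \code{correct} (logical), one row per trial
#' @export
simulateBehavior <- function(conditions, truth, nPerCondition, seed) {
  stopifnot(is(truth, "GroundTruth"))
  if (any(nPerCondition < 1L)) stop("nPerCondition must be >= 1")
  n <- rep_len(as.integer(nPerCondition), nrow(conditions))
  p <- .decoding_prob(conditions$sigma, conditions$freq, truth@muDec,
                      truth@wDec, truth@kappa, truth@m, truth@b)
  set.seed(as.integer(seed))
  idx <- rep(seq_len(nrow(conditions)), n)
  data.frame(sigma = conditions$sigma[idx],
             freq = conditions$freq[idx],
             correct = rbinom(length(idx), 1L, p[idx]) == 1L)
}
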