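.LOG2 <- log(2)

# log2-Gaussian tuning; NA frequency (no-noise trials) contributes 0 drive
.gauss_tuning <- function(freq, mu, w) {
  s <- exp(-(log2(freq) - log2(mu))^2 / (2 * w^2))
  s[is.na(freq)] <- 0
  s
}

#' Construct noise-response channel parameters
#'
#' Convenience constructor returning a \linkS4class{NoiseResponseFit} with
#' empty diagnostics, for use in predictions and simulations.
#'
#' @param betaBase,betaMax,sigma50,mu,w model parameters (\code{mu} in
#'   cycles/image, \code{w} in octaves)
#' @param normalized whether the parameters live on the scene-normalized
#'   scale
#' @return a \linkS4class{NoiseResponseFit}
#' @export
noiseResponseParams <- function(betaBase, betaMax, sigma50, mu, w,
                                normalized = TRUE) {
  new("NoiseResponseFit", betaBase = betaBase, betaMax = betaMax,
      sigma50 = sigma50, mu = mu, w = w, sse = NA_real_, r2 = NA_real_,
      normalized = normalized, identifiable = TRUE)
}

#' Predict the noise response
#'
#' Evaluates the separable channel model
#' \eqn{\hat R(\sigma, f) = \beta_{base} + \beta_{max}
#' \frac{\sigma}{\sigma + \sigma_{50}} S(f)} with log2-Gaussian tuning
#' \eqn{S}. At \eqn{\sigma = 0} the prediction is \eqn{\beta_{base}}; at
#' \eqn{\sigma = \sigma_{50}, f = \mu} it is
#' \eqn{\beta_{base} + \beta_{max}/2}.
#'
#' @param p a \linkS4class{NoiseResponseFit}
#' @param sigma noise standard deviation(s), >= 0
#' @param freq noise band frequency(ies), cycles/image, > 0
#' @return predicted response(s)
#' @export
noiseResponsePredict <- function(p, sigma, freq) {
  stopifnot(is(p, "NoiseResponseFit"))
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (any(freq <= 0, na.rm = TRUE)) stop("freq must be > 0")
  p@betaBase + p@betaMax * (sigma / (sigma + p@sigma50)) *
    .gauss_tuning(freq, p@mu, p@w)
}

# SSE profile: for fixed (sigma50, mu, w) the model is linear in
# (betaBase, betaMax); solve the 2x2 normal equations, clamping betaMax >= 0
.nr_profile <- function(y, sigma, freq, sigma50, mu, w) {
  x <- (sigma / (sigma + sigma50)) * .gauss_tuning(freq, mu, w)
  vx <- sum((x - mean(x))^2)
  b1 <- if (vx > 0) sum((x - mean(x)) * (y - mean(y))) / vx else 0
  if (b1 < 0) b1 <- 0
  b0 <- mean(y) - b1 * mean(x)
  res <- y - (b0 + b1 * x)
  list(betaBase = b0, betaMax = b1, sse = sum(res^2))
}

#' Fit the noise-response channel model
#'
#' Minimizes the sum of squared errors between the separable channel model
#' and the observed noise-response matrix, over a multi-start bounded
#' search: candidate starts place \eqn{\mu} at each band center, \eqn{w}
#' in \{0.5, 1, 2\} octaves and \eqn{\sigma_{50}} at each non-zero design
#' contrast (the amplitude parameters are profiled out analytically at
#' each start), and the best starts are refined by bounded
#' quasi-Newton optimization with \eqn{\mu \in [0.875, 224]} cycles/image,
#' \eqn{w \in [0.05, 8]} octaves, \eqn{\sigma_{50} \in [10^{-4}, 1]}.
#'
#' A constant matrix leaves the tuning parameters unidentifiable; the fit
#' is then flagged (\code{@identifiable = FALSE}) with a warning.
#'
#' @param R a \linkS4class{ResponseMatrix} (canonically scene-normalized,
#'   so that the noise-threshold target is the scene response = 1)
#' @return a \linkS4class{NoiseResponseFit}
#' @seealso [noiseThreshold()], [fwhm()]
#' @export
fitNoiseResponse <- function(R) {
  stopifnot(is(R, "ResponseMatrix"))
  ok <- is.finite(R@values)
  if (sum(ok) < 5L)
    stop("need at least 5 non-missing cells, have ", sum(ok))
  sig <- matrix(R@sigmas, nrow(R@values), ncol(R@values))[ok]
  frq <- matrix(R@freqs, nrow(R@values), ncol(R@values), byrow = TRUE)[ok]
  if (length(unique(sig)) < 2L || length(unique(frq)) < 3L)
    stop("fit needs >= 2 contrasts and >= 3 frequencies")
  y <- R@values[ok]

  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    warning("constant response matrix: tuning parameters unidentifiable")
    return(new("NoiseResponseFit", betaBase = mean(y), betaMax = 0,
               sigma50 = 0.05, mu = exp(.LOG2 * mean(log2(frq))), w = 1,
               sse = 0, r2 = NA_real_, normalized = R@normalized,
               identifiable = FALSE))
  }

  grid <- expand.grid(mu = R@freqs, w = c(0.5, 1, 2),
                      sigma50 = sort(unique(sig)),
                      KEEP.OUT.ATTRS = FALSE)
  grid_sse <- vapply(seq_len(nrow(grid)), function(i) {
    .nr_profile(y, sig, frq, grid$sigma50[i], grid$mu[i], grid$w[i])$sse
  }, numeric(1))

  lb <- c(-Inf, 0, 1e-4, log2(0.875), 0.05)
  ub <- c(Inf, Inf, 1, log2(224), 8)
  obj <- function(th) {
    pred <- th[1] + th[2] * (sig / (sig + th[3])) *
      exp(-(log2(frq) - th[4])^2 / (2 * th[5]^2))
    sum((y - pred)^2)
  }
  best <- NULL
  for (i in order(grid_sse)[seq_len(min(3L, nrow(grid)))]) {
    pr <- .nr_profile(y, sig, frq, grid$sigma50[i], grid$mu[i], grid$w[i])
    th0 <- c(pr$betaBase, pr$betaMax, grid$sigma50[i],
             log2(grid$mu[i]), grid$w[i])
    fit <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 1000, factr = 1e2,
                           ndeps = rep(1e-6, 5L))),
      error = function(e) list(par = th0, value = obj(th0)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par
  new("NoiseResponseFit", betaBase = th[1], betaMax = th[2],
      sigma50 = th[3], mu = 2^th[4], w = th[5],
      sse = best$value, r2 = 1 - best$value / tss,
      normalized = R@normalized, identifiable = TRUE)
}

#' @rdname fwhm
#' @export
setMethod("fwhm", "NoiseResponseFit", function(x) {
  if (!x@identifiable)
    warning("fit flagged unidentifiable; FWHM is meaningless")
  2 * sqrt(2 * log(2)) * x@w
})

#' @rdname fwhm
#' @export
setMethod("fwhm", "numeric", function(x) 2 * sqrt(2 * log(2)) * x)

# recognition-channel probability of a correct classification
.decoding_prob <- function(sigma, freq, mu, w, kappa, m, b) {
  D <- sigma * .gauss_tuning(freq, mu, w)
  D[sigma <= 0] <- 0
  E <- (1 + kappa) * D / (D + kappa)
  1 / (1 + exp(-m * (E - b)))
}

#' Construct recognition-channel parameters
#'
#' @param mu,w tuning center (cycles/image) and width (octaves)
#' @param kappa divisive-normalization strength, > 0
#' @param m,b logistic slope and threshold (on well-formed data the fitted
#'   slope is negative: accuracy falls as the noise response grows)
#' @return a \linkS4class{DecodingFit} with empty diagnostics
#' @export
decodingParams <- function(mu, w, kappa, m, b) {
  new("DecodingFit", mu = mu, w = w, kappa = kappa, m = m, b = b,
      nll = NA_real_, nTrials = NA_integer_, identifiable = TRUE)
}

#' Predict the probability of correct classification
#'
#' Evaluates the recognition model: sensitivity
#' \eqn{S(f) = \exp(-(\log_2 f - \log_2 \mu)^2 / (2 w^2))}, noise drive
#' \eqn{D = \sigma S(f)}, divisive normalization
#' \eqn{E = (1+\kappa) D / (D + \kappa)} and logistic readout
#' \eqn{P = 1/(1 + e^{-m (E - b)})}. At \eqn{\sigma = 0}, \eqn{E = 0} and
#' \eqn{P = 1/(1 + e^{m b})} (the zero-noise baseline).
#'
#' @param p a \linkS4class{DecodingFit}
#' @param sigma noise standard deviation(s), >= 0
#' @param freq noise band frequency(ies), cycles/image (NA allowed where
#'   \code{sigma} is 0)
#' @return probability(ies) of a correct classification
#' @export
decodingPredict <- function(p, sigma, freq) {
  stopifnot(is(p, "DecodingFit"))
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (any(freq <= 0, na.rm = TRUE)) stop("freq must be > 0")
  .decoding_prob(sigma, freq, p@mu, p@w, p@kappa, p@m, p@b)
}

#' Fit the recognition channel by binomial maximum likelihood
#'
#' Minimizes the negative log-likelihood of single-trial classification
#' outcomes (correct vs. incorrect, binomial), over a multi-start bounded
#' search: \eqn{\mu} over the observed band centers, \eqn{w} in
#' \{0.5, 1, 2\} octaves, \eqn{\kappa} in \{0.1, 1, 10\}, and two logistic
#' starts; the best starts are refined by bounded quasi-Newton
#' optimization (\eqn{\mu \in [0.875, 224]}, \eqn{w \in [0.05, 8]},
#' \eqn{\kappa \in [10^{-2}, 10^{3}]}; the slope \code{m} is unconstrained
#' in sign). Zero-noise trials pin the baseline through \code{m} and
#' \code{b}.
#'
#' Perfectly separated data (all correct or all incorrect) are flagged
#' \code{@identifiable = FALSE} with a warning.
#'
#' @param outcomes data.frame with columns \code{sigma}, \code{freq}
#'   (NA where \code{sigma} is 0) and logical \code{correct}; e.g. from
#'   [decodeTrials()] or [simulateBehavior()]
#' @return a \linkS4class{DecodingFit}
#' @seealso [thresholdCurve()], [fw2m()], [noiseTolerance()]
#' @export
fitDecodingModel <- function(outcomes) {
  stopifnot(all(c("sigma", "freq", "correct") %in% names(outcomes)))
  correct <- as.logical(outcomes$correct)
  freqs <- sort(unique(outcomes$freq[!is.na(outcomes$freq)]))
  nz <- outcomes$sigma[outcomes$sigma > 0]
  if (length(freqs) < 3L || length(unique(nz)) < 2L)
    stop("fit needs outcomes at >= 3 frequencies and >= 2 non-zero contrasts")
  if (!any(outcomes$sigma == 0))
    stop("fit needs sigma = 0 trials to pin the baseline")

  # aggregate to condition counts: the binomial NLL only needs k / n
  key <- paste(outcomes$sigma, outcomes$freq)
  agg_n <- tapply(correct, key, length)
  agg_k <- tapply(correct, key, sum)
  first <- !duplicated(key)
  ord <- match(names(agg_n), key[first])
  sig <- outcomes$sigma[first][ord]
  frq <- outcomes$freq[first][ord]
  k <- as.numeric(agg_k)
  n <- as.numeric(agg_n)

  separated <- all(correct) || all(!correct)
  if (separated)
    warning("all outcomes identical (perfect separation): ",
            "parameters unidentifiable")

  nll <- function(th) {
    p <- .decoding_prob(sig, frq, 2^th[1], th[2], exp(th[3]), th[4], th[5])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  grid <- expand.grid(l2mu = log2(freqs), w = c(0.5, 1, 2),
                      lk = log(c(0.1, 1, 10)), m = c(-4, -16), b = c(0.35),
                      KEEP.OUT.ATTRS = FALSE)
  gvals <- vapply(seq_len(nrow(grid)), function(i) {
    nll(as.numeric(grid[i, ]))
  }, numeric(1))
  lb <- c(log2(0.875), 0.05, log(1e-2), -200, -5)
  ub <- c(log2(224), 8, log(1e3), 200, 5)
  best <- NULL
  for (i in order(gvals)[seq_len(min(3L, nrow(grid)))]) {
    th0 <- as.numeric(grid[i, ])
    fit <- tryCatch(
      optim(th0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 1000, factr = 1e2,
                           ndeps = rep(1e-6, 5L))),
      error = function(e) list(par = th0, value = nll(th0)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par
  new("DecodingFit", mu = 2^th[1], w = th[2], kappa = exp(th[3]),
      m = th[4], b = th[5], nll = best$value,
      nTrials = length(correct), identifiable = !separated)
}

#' Noise-power threshold curve of the recognition channel
#'
#' The noise power (variance \eqn{\sigma^2}) required at frequency f to
#' reduce the predicted accuracy to half the zero-noise baseline
#' \eqn{P_0 = 1/(1 + e^{m b})}. Closed form: solve the logistic for the
#' normalized drive \eqn{E^* = b - \log(1/(P_0/2) - 1)/m}, invert the
#' normalization to \eqn{D^* = \kappa E^* / ((1+\kappa) - E^*)}, and
#' return \eqn{\Theta(f) = (D^*/S(f))^2}. When the target accuracy is
#' unreachable (\eqn{E} is bounded above by \eqn{1+\kappa}) the curve is
#' flagged infinite.
#'
#' @param p a \linkS4class{DecodingFit} with \code{m != 0} (a zero slope
#'   means accuracy never falls and no threshold exists)
#' @param freq frequency(ies), cycles/image
#' @return noise power(s) \eqn{\sigma^2}; \code{Inf} where unreachable
#' @export
thresholdCurve <- function(p, freq) {
  stopifnot(is(p, "DecodingFit"))
  if (any(freq <= 0)) stop("freq must be > 0")
  if (p@m == 0)
    stop("m = 0: accuracy is constant, threshold undefined")
  P0 <- 1 / (1 + exp(p@m * p@b))
  Pstar <- P0 / 2
  Estar <- p@b - log(1 / Pstar - 1) / p@m
  if (Estar < 0)
    stop("accuracy rises with noise (m > 0 regime): threshold undefined")
  if (Estar >= 1 + p@kappa) return(rep(Inf, length(freq)))
  Dstar <- p@kappa * Estar / ((1 + p@kappa) - Estar)
  (Dstar / .gauss_tuning(freq, p@mu, p@w))^2
}

#' @rdname fw2m
#' @export
setMethod("fw2m", "DecodingFit", function(x) {
  th <- tryCatch(thresholdCurve(x, x@mu), error = function(e) NA_real_)
  if (!is.finite(th)) {
    warning("threshold curve is not finite at mu; FW2M undefined")
    return(NA_real_)
  }
  2 * x@w * sqrt(log(2))
})

#' @rdname fw2m
#' @export
setMethod("fw2m", "numeric", function(x) 2 * x * sqrt(log(2)))

#' Noise threshold of the noise-response channel
#'
#' The noise power at which the fitted response to noise alone, at its
#' most effective frequency \eqn{f = \mu}, equals the scene-alone response
#' (= 1 on the scene-normalized scale). Closed form:
#' \eqn{\sigma^* = \sigma_{50} (t - \beta_{base}) /
#' (\beta_{max} - (t - \beta_{base}))} with target t, returned as power
#' \eqn{\sigma^{*2}}. Flagged infinite when the asymptotic response
#' \eqn{\beta_{base} + \beta_{max}} cannot reach the target; an error when
#' \eqn{\beta_{base} \ge t} (the threshold would be zero or negative).
#'
#' @param p a \linkS4class{NoiseResponseFit}, canonically fit to a
#'   scene-normalized matrix
#' @param target response level defining the threshold (default 1, the
#'   scene-alone response on the normalized scale)
#' @return noise power \eqn{\sigma^{*2}}; \code{Inf} when unreachable
#' @export
noiseThreshold <- function(p, target = 1) {
  stopifnot(is(p, "NoiseResponseFit"))
  if (!p@normalized && target == 1)
    warning("fit is on the raw scale but target = 1 assumes the ",
            "scene-normalized scale")
  if (p@betaBase >= target)
    stop("betaBase >= target: degenerate (zero or negative) threshold")
  gap <- target - p@betaBase
  if (p@betaMax <= gap) return(Inf)
  (p@sigma50 * gap / (p@betaMax - gap))^2
}

#' Noise tolerance of the recognition channel
#'
#' The minimum of the threshold curve over frequency, attained at
#' \eqn{f = \mu}: the lowest noise power that halves decoding accuracy.
#'
#' @param p a \linkS4class{DecodingFit}
#' @return noise power \eqn{\Theta(\mu)}; \code{Inf} when unreachable
#' @export
noiseTolerance <- function(p) {
  thresholdCurve(p, p@mu)
}

#' Summarize fitted channels for one region
#'
#' Collects the derived band metrics from a noise-response fit and a
#' recognition fit into a one-row data.frame.
#'
#' @param respFit a \linkS4class{NoiseResponseFit}
#' @param decFit a \linkS4class{DecodingFit}
#' @param region optional region label
#' @return data.frame with columns \code{region},
#'   \code{centerResponse}, \code{fwhmResponse}, \code{noiseThreshold},
#'   \code{centerRecognition}, \code{fw2mRecognition},
#'   \code{noiseTolerance}, \code{r2Response}, \code{nllDecoding}
#' @export
bandSummary <- function(respFit, decFit, region = NA_character_) {
  stopifnot(is(respFit, "NoiseResponseFit"), is(decFit, "DecodingFit"))
  thr <- tryCatch(noiseThreshold(respFit), error = function(e) NA_real_)
  tol <- tryCatch(noiseTolerance(decFit), error = function(e) NA_real_)
  data.frame(region = region,
             centerResponse = respFit@mu,
             fwhmResponse = fwhm(respFit),
             noiseThreshold = thr,
             centerRecognition = decFit@mu,
             fw2mRecognition = suppressWarnings(fw2m(decFit)),
             noiseTolerance = tol,
             r2Response = respFit@r2,
             nllDecoding = decFit@nll)
}
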