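test_that("noise-response predictions satisfy the model identities", {
  p <- noiseResponseParams(betaBase = 0.1, betaMax = 1.2, sigma50 = 0.05,
                           mu = 7, w = 1)
  expect_equal(noiseResponsePredict(p, 0, 7), 0.1)
  expect_equal(noiseResponsePredict(p, 0.05, 7), 0.1 + 1.2 / 2)
  # log2 symmetry about mu
  expect_equal(noiseResponsePredict(p, 0.08, 7 * 2^1.3),
               noiseResponsePredict(p, 0.08, 7 * 2^-1.3))
  expect_error(noiseResponsePredict(p, 0.08, -1), "freq")
  expect_error(noiseResponsePredict(p, -0.1, 7), "sigma")
})

test_that("FWHM and FW2M closed forms match numeric root finding", {
  expect_equal(fwhm(0.8493218), 2, tolerance = 1e-6)
  expect_equal(fwhm(2.123305), 5, tolerance = 1e-6)
  expect_equal(fw2m(1.201122), 2, tolerance = 1e-6)
  expect_equal(fw2m(1) / fwhm(1), 1 / sqrt(2), tolerance = 1e-12)

  # numeric crossing of the tuning curve at half max
  for (w in c(0.3, 0.8493218, 2.5)) {
    tune <- function(x) exp(-x^2 / (2 * w^2))  # x octaves from center
    up <- uniroot(function(x) tune(x) - 0.5, c(0, 20 * w), tol = 1e-13)$root
    expect_equal(2 * up, fwhm(w), tolerance = 1e-9)
  }

  # numeric width of the threshold curve at twice its minimum:
  # theta(x) = theta_min / S(x)^2 with S the log2-Gaussian
  for (w in c(0.5, 1.201122, 3)) {
    theta <- function(x) 1 / exp(-x^2 / (2 * w^2))^2
    up <- uniroot(function(x) theta(x) - 2, c(0, 20 * w), tol = 1e-13)$root
    expect_equal(2 * up, fw2m(w), tolerance = 1e-9)
  }
})

test_that("the noise-response fit recovers exact model output", {
  gen <- noiseResponseParams(0.1, 1.2, 0.05, 7, 1.0)
  sigmas <- c(0, 0.02, 0.04, 0.08, 0.16)
  freqs <- c(1.75, 3.5, 7, 14, 28, 56, 112)
  vals <- outer(sigmas, freqs, function(s, f) noiseResponsePredict(gen, s, f))
  vals[1, ] <- NA  # no zero-contrast noise-only trials
  R <- new("ResponseMatrix", values = vals, sigmas = sigmas, freqs = freqs,
           nTrials = matrix(9L, 5, 7), normalized = TRUE,
           reference = 1, nVoxels = 100L)
  fit <- fitNoiseResponse(R)
  expect_equal(fit@betaBase, 0.1, tolerance = 1e-3)
  expect_equal(fit@betaMax, 1.2, tolerance = 1e-3)
  expect_equal(fit@sigma50, 0.05, tolerance = 1e-3)
  expect_equal(fit@mu, 7, tolerance = 1e-3)
  expect_equal(fit@w, 1, tolerance = 1e-3)
  expect_gt(fit@r2, 0.999999)

  # doubling the matrix doubles the amplitudes, leaves the channel alone
  R2 <- new("ResponseMatrix", values = vals * 2, sigmas = sigmas,
            freqs = freqs, nTrials = matrix(9L, 5, 7), normalized = FALSE,
            reference = NA_real_, nVoxels = 100L)
  fit2 <- fitNoiseResponse(R2)
  expect_equal(fit2@betaBase, 0.2, tolerance = 1e-3)
  expect_equal(fit2@betaMax, 2.4, tolerance = 1e-3)
  expect_equal(fit2@sigma50, fit@sigma50, tolerance = 1e-3)
  expect_equal(fit2@mu, fit@mu, tolerance = 1e-3)
  expect_equal(fit2@w, fit@w, tolerance = 1e-3)

  # degenerate, constant matrix is flagged
  Rc <- new("ResponseMatrix", values = matrix(c(rep(NA, 7), rep(1, 28)),
                                              5, 7, byrow = TRUE),
            sigmas = sigmas, freqs = freqs, nTrials = matrix(1L, 5, 7),
            normalized = TRUE, reference = 1, nVoxels = 10L)
  expect_warning(fc <- fitNoiseResponse(Rc), "unidentifiable")
  expect_false(fc@identifiable)
})

test_that("decoding predictions satisfy the model identities", {
  p <- decodingParams(mu = 19, w = 1.2, kappa = 1, m = -8, b = 0.5)
  expect_equal(decodingPredict(p, 0, 19), 1 / (1 + exp(-8 * 0.5)))
  # f = mu makes the drive sigma itself; check via the kappa -> Inf limit
  pk <- decodingParams(19, 1.2, kappa = 1e6, m = -8, b = 0.5)
  for (sg in c(0.02, 0.08, 0.16)) {
    E_direct <- sg  # E -> D = sigma at f = mu
    expect_equal(decodingPredict(pk, sg, 19),
                 1 / (1 + exp(8 * (E_direct - 0.5))), tolerance = 1e-5)
  }
})

test_that("the threshold curve matches its bisection oracle and the worked example", {
  p <- decodingParams(mu = 14, w = 1.2, kappa = 1, m = -8, b = 0.5)
  P0 <- decodingPredict(p, 0, 14)
  expect_equal(P0, 0.98201, tolerance = 1e-4)
  # bisection oracle on sigma -> P(correct) at f = mu
  f_target <- function(sg) decodingPredict(p, sg, 14) - P0 / 2
  sg_star <- uniroot(f_target, c(1e-9, 10), tol = 1e-13)$root
  expect_equal(thresholdCurve(p, 14), sg_star^2, tolerance = 1e-8)
  expect_equal(thresholdCurve(p, 14), 0.1138, tolerance = 1e-3)

  # symmetry about mu on the log2 axis
  expect_equal(thresholdCurve(p, 14 * 2^0.7), thresholdCurve(p, 14 * 2^-0.7))
  # minimum at mu equals the noise tolerance
  grid_f <- 14 * 2^seq(-3, 3, by = 0.01)
  expect_equal(min(thresholdCurve(p, grid_f)), noiseTolerance(p),
               tolerance = 1e-10)

  # unreachable target: E bounded above by 1 + kappa
  p_flat <- decodingParams(14, 1.2, kappa = 0.05, m = -0.2, b = -20)
  expect_equal(noiseTolerance(p_flat), Inf)
  expect_error(thresholdCurve(decodingParams(14, 1.2, 1, 0, 0.5), 14),
               "m = 0")

  # tolerance grows with the threshold b when accuracy falls with noise
  tol_b <- vapply(c(0.2, 0.35, 0.5, 0.65),
                  function(b) noiseTolerance(decodingParams(14, 1.2, 0.5,
                                                            -10, b)),
                  numeric(1))
  expect_true(all(diff(tol_b) > 0))
})

test_that("the noise threshold matches its closed form, oracle, and flags", {
  p <- noiseResponseParams(0.2, 1.6, 0.08, 14, 1, normalized = TRUE)
  expect_equal(noiseThreshold(p), 0.08^2, tolerance = 1e-12)
  # bisection oracle on the contrast-response curve at f = mu
  root <- uniroot(function(sg) noiseResponsePredict(p, sg, 14) - 1,
                  c(1e-12, 1), tol = 1e-14)$root
  expect_equal(noiseThreshold(p), root^2, tolerance = 1e-10)

  expect_equal(noiseThreshold(noiseResponseParams(0.2, 0.7, 0.08, 14, 1)),
               Inf)
  expect_error(noiseThreshold(noiseResponseParams(1.1, 1.6, 0.08, 14, 1)),
               "degenerate")
  expect_warning(noiseThreshold(noiseResponseParams(0.2, 1.6, 0.08, 14, 1,
                                                    normalized = FALSE)),
                 "raw scale")
})

test_that("the decoding fit is optimal on its own data and flags separation", {
  truth <- decodingParams(19, 1.2, 0.1, -10, 0.35)
  cond <- expand.grid(freq = c(1.75, 3.5, 7, 14, 28, 56, 112),
                      sigma = c(0.02, 0.04, 0.08, 0.16))
  cond <- rbind(cond, data.frame(freq = NA, sigma = 0))
  set.seed(3)
  p <- decodingPredict(truth, cond$sigma, cond$freq)
  idx <- rep(seq_len(nrow(cond)), 40)
  out <- data.frame(sigma = cond$sigma[idx], freq = cond$freq[idx],
                    correct = rbinom(length(idx), 1, p[idx]) == 1)
  fit <- fitDecodingModel(out)
  nll_at <- function(q) {
    pr <- pmin(pmax(decodingPredict(q, out$sigma, out$freq), 1e-12),
               1 - 1e-12)
    -sum(ifelse(out$correct, log(pr), log(1 - pr)))
  }
  expect_lte(fit@nll, nll_at(truth) + 1e-6)
  expect_true(fit@m < 0)

  sep <- out; sep$correct <- TRUE
  expect_warning(fs <- fitDecodingModel(sep), "separation")
  expect_false(fs@identifiable)

  expect_error(fitDecodingModel(out[out$sigma > 0, ]), "baseline")
})

test_that("both channel fits recover generating parameters from one simulated subject", {
  design <- experimentDesign()  # canonical budget: 28 x 9 noise-only
  tt <- buildTrialTable(design, 15, seed = 71)
  V <- 200
  vox <- simulateVoxels(V, 72)
  truth <- groundTruth(V = V, seed = 73)
  se <- simulateTrialBetas(tt, truth, vox, seed = 74)
  sel <- selectVoxels(se)
  fitR <- fitNoiseResponse(normalizeByScene(noiseResponseMatrix(se, sel),
                                            se, sel))
  expect_lt(abs(log2(fitR@mu) - log2(truth@muResp)), 0.25)
  expect_lt(abs(fwhm(fitR) - fwhm(truth@wResp)) / fwhm(truth@wResp), 0.2)

  cond <- enumerateConditions(design)
  cond <- cond[cond$kind %in% c("sceneNoise", "sceneOnly"), ]
  reps <- ifelse(cond$kind == "sceneNoise", 3L, 19L)
  out <- simulateBehavior(cond[, c("sigma", "freq")], truth, reps, seed = 75)
  fitD <- fitDecodingModel(out)
  expect_lt(abs(log2(fitD@mu) - log2(truth@muDec)), 0.5)
  expect_lt(abs(fw2m(fitD) - fw2m(truth@wDec)) / fw2m(truth@wDec), 0.3)
})
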