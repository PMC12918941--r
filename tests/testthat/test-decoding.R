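test_that("category prototypes average noiseless trials per category", {
  trials <- data.frame(kind = rep("sceneOnly", 3),
                       category = c(1L, 1L, 2L),
                       freq = NA_real_, sigma = 0)
  betas <- cbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5))
  se <- make_se(betas, trials)
  p <- categoryPrototypes(se, 1:3)
  expect_equal(unname(p[, "1"]), c(2, 2, 2))
  expect_equal(unname(p[, "2"]), c(5, 5, 5))

  # brute-force oracle on a random instance
  set.seed(7)
  trials2 <- data.frame(kind = "sceneOnly",
                        category = rep(1:4, each = 3),
                        freq = NA_real_, sigma = 0)
  B <- matrix(rnorm(8 * 12), 8)
  se2 <- make_se(B, trials2)
  p2 <- categoryPrototypes(se2, 1:8)
  for (k in 1:4) {
    manual <- rowMeans(B[, trials2$category == k, drop = FALSE])
    expect_equal(unname(p2[, as.character(k)]), manual, tolerance = 1e-12)
  }

  # missing noiseless trials are reported by category
  trials3 <- data.frame(kind = c("sceneOnly", "sceneNoise"),
                        category = c(1L, 2L), freq = c(NA, 7),
                        sigma = c(0, 0.08))
  expect_error(categoryPrototypes(make_se(betas[, 1:2], trials3), 1:3),
               "category 2")
})

test_that("nearest-prototype classification follows the Pearson correlation", {
  p <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(classifyTrial(c(0.9, 0.1, 0.05), p), 1L)
  expect_equal(classifyTrial(p[, 2], p), 2L)
  # positive affine invariance
  y <- c(0.2, 0.9, 0.4)
  expect_equal(classifyTrial(5 * y + 3, p), classifyTrial(y, p))
  # zero-variance prototype never wins; all-undefined errors
  pz <- cbind(c(1, 1, 1), c(0, 1, 0))
  expect_equal(classifyTrial(c(1, 1, 0.9), pz), 2L)
  expect_error(classifyTrial(c(1, 1, 1), cbind(c(1, 1, 1), c(2, 2, 2))),
               "undefined")
  # deterministic tie-break toward the lowest index
  pt <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(classifyTrial(c(1, 2, 3), pt), 1L)
})

test_that("brute-force classifier agrees with decodeTrials on a random instance", {
  set.seed(13)
  C <- 4; V <- 12
  proto_true <- matrix(rnorm(V * C), V)
  trials <- data.frame(
    kind = c(rep("sceneOnly", 2 * C), rep("sceneNoise", 40)),
    category = c(rep(1:C, each = 2), sample(1:C, 40, replace = TRUE)),
    freq = c(rep(NA, 2 * C), sample(c(7, 14), 40, replace = TRUE)),
    sigma = c(rep(0, 2 * C), sample(c(0.04, 0.16), 40, replace = TRUE)))
  betas <- 0.8 * proto_true[, trials$category] +
    matrix(rnorm(V * nrow(trials)), V)
  se <- make_se(betas, trials)
  dec <- decodeTrials(se, 1:V)

  proto <- categoryPrototypes(se, 1:V)
  for (i in seq_len(nrow(dec))) {
    t_i <- dec$trial[i]
    P <- proto
    if (trials$sigma[t_i] == 0) {
      k <- trials$category[t_i]
      peers <- setdiff(which(trials$category == k & trials$sigma == 0), t_i)
      P[, as.character(k)] <- rowMeans(betas[, peers, drop = FALSE])
    }
    rs <- apply(P, 2, function(pk) cor(betas[, t_i], pk))
    expect_equal(dec$predicted[i], as.integer(names(which.max(rs))))
  }
})

test_that("leave-one-out removes the circularity of noiseless-trial decoding", {
  set.seed(17)
  C <- 5; V <- 30; reps <- 6
  trials <- data.frame(kind = "sceneOnly",
                       category = rep(seq_len(C), each = reps),
                       freq = NA_real_, sigma = 0)
  # weak signal so that inclusion of the test trial matters
  proto_true <- matrix(rnorm(V * C), V)
  betas <- 0.25 * proto_true[, trials$category] +
    matrix(rnorm(V * nrow(trials)), V)
  se <- make_se(betas, trials)
  dec <- decodeTrials(se, 1:V)          # leave-one-out path
  proto <- categoryPrototypes(se, 1:V)  # prototypes including the trial
  in_sample <- vapply(seq_len(nrow(trials)), function(t) {
    as.integer(colnames(proto))[classifyTrial(betas[, t], proto)] ==
      trials$category[t]
  }, logical(1))
  expect_lte(mean(dec$correct), mean(in_sample))

  # a category with a single noiseless trial cannot be decoded LOO
  solo <- data.frame(kind = "sceneOnly", category = c(1L, 2L, 2L),
                     freq = NA_real_, sigma = 0)
  expect_error(decodeTrials(make_se(matrix(rnorm(9), 3), solo), 1:3),
               "leave-one-out")
})

test_that("accuracy matrices report proportions correct per condition", {
  out <- data.frame(sigma = rep(c(0, 0.08), each = 10),
                    freq = rep(c(NA, 14), each = 10),
                    correct = c(rep(TRUE, 10), rep(TRUE, 7), rep(FALSE, 3)))
  A <- behavioralAccuracyMatrix(out)
  expect_equal(A@values[A@sigmas == 0.08, ], 0.7)
  expect_equal(A@baseline, 1)
  expect_equal(A@values[A@sigmas == 0, ], 1)

  thirds <- data.frame(sigma = 0.04, freq = 7,
                       correct = c(TRUE, TRUE, FALSE))
  base <- data.frame(sigma = 0, freq = NA, correct = TRUE)
  A2 <- behavioralAccuracyMatrix(rbind(thirds, base))
  expect_equal(A2@values[A2@sigmas == 0.04, ], 2 / 3)
  expect_equal(A2@nTrials[A2@sigmas == 0.04, ], 3L)
})

test_that("category-free patterns decode at chance", {
  set.seed(23)
  C <- 10; V <- 40; n_scene <- 600
  trials <- data.frame(
    kind = c(rep("sceneOnly", 3 * C), rep("sceneNoise", n_scene)),
    category = c(rep(1:C, each = 3), sample(1:C, n_scene, replace = TRUE)),
    freq = c(rep(NA, 3 * C), rep(14, n_scene)),
    sigma = c(rep(0, 3 * C), rep(0.08, n_scene)))
  betas <- matrix(rnorm(V * nrow(trials)), V)  # no category structure
  dec <- decodeTrials(make_se(betas, trials), 1:V)
  acc <- mean(dec$correct[dec$sigma > 0])
  expect_lt(abs(acc - 1 / C), 3 * sqrt(0.1 * 0.9 / n_scene))
})
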