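#' Category prototype patterns
#'
#' The prototype of category c is the mean voxel pattern over that
#' category's noiseless (sigma = 0) scene trials.
#'
#' @param x a \linkS4class{CbmExperiment}
#' @param voxels voxel indices, e.g. from [selectVoxels()]
#' @return matrix, selected voxels x categories (columns named by
#'   category)
#' @export
categoryPrototypes <- function(x, voxels = selectVoxels(x)) {
  stopifnot(is(x, "CbmExperiment"))
  trials <- as.data.frame(SummarizedExperiment::colData(x))
  betas <- SummarizedExperiment::assay(x, "betas")[voxels, , drop = FALSE]
  cats <- sort(unique(trials$category[!is.na(trials$category)]))
  proto <- matrix(NA_real_, nrow(betas), length(cats),
                  dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    sel <- !is.na(trials$category) & trials$category == cats[k] &
      trials$sigma == 0
    if (!any(sel))
      stop("category ", cats[k], " has no noiseless trials")
    proto[, k] <- rowMeans(betas[, sel, drop = FALSE])
  }
  proto
}

# Pearson correlations of y against prototype columns; zero-variance
# pairings are undefined and never win (-Inf)
.proto_cor <- function(y, prototypes) {
  sds <- apply(prototypes, 2, sd)
  r <- rep(-Inf, ncol(prototypes))
  ok <- sds > 0
  if (sd(y) > 0 && any(ok))
    r[ok] <- as.numeric(cor(y, prototypes[, ok, drop = FALSE]))
  r
}

#' Classify one voxel pattern by nearest prototype correlation
#'
#' Predicts the category whose prototype has the highest Pearson
#' correlation with the test pattern. Undefined correlations
#' (zero-variance pattern or prototype) never win; if every pairing is
#' undefined an error is raised. Ties break deterministically toward the
#' lowest category index. Pearson correlation makes the prediction
#' invariant to positive affine transforms of the test pattern.
#'
#' @param y numeric test pattern (selected voxels)
#' @param prototypes voxels x categories matrix from
#'   [categoryPrototypes()]
#' @return predicted category (column index into \code{prototypes})
#' @examples
#' p <- cbind(c(1, 0, 0), c(0, 1, 0))
#' classifyTrial(c(0.9, 0.1, 0.05), p)  # 1
#' @export
classifyTrial <- function(y, prototypes) {
  stopifnot(length(y) == nrow(prototypes), ncol(prototypes) >= 2L)
  r <- .proto_cor(y, prototypes)
  if (all(!is.finite(r)))
    stop("all prototype correlations are undefined")
  which.max(r)
}

#' Decode every scene trial of an experiment
#'
#' Applies the nearest-prototype correlation classifier to each scene
#' trial (noise-only and blank trials carry no true category and are
#' excluded). For noiseless trials the test trial is removed from its own
#' category's prototype before correlating (leave-one-out), preventing
#' circularity.
#'
#' @param x a \linkS4class{CbmExperiment}
#' @param voxels voxel indices used for prototypes and patterns
#' @return data.frame with one row per scene trial: \code{trial},
#'   \code{sigma}, \code{freq}, \code{category}, \code{predicted},
#'   \code{correct}
#' @export
decodeTrials <- function(x, voxels = selectVoxels(x)) {
  stopifnot(is(x, "CbmExperiment"))
  trials <- as.data.frame(SummarizedExperiment::colData(x))
  betas <- SummarizedExperiment::assay(x, "betas")[voxels, , drop = FALSE]
  proto <- categoryPrototypes(x, voxels)
  cats <- as.integer(colnames(proto))
  scene_idx <- which(!is.na(trials$category))
  out <- data.frame(trial = scene_idx,
                    sigma = trials$sigma[scene_idx],
                    freq = trials$freq[scene_idx],
                    category = trials$category[scene_idx],
                    predicted = NA_integer_)
  for (i in seq_along(scene_idx)) {
    t_i <- scene_idx[i]
    y <- betas[, t_i]
    P <- proto
    if (trials$sigma[t_i] == 0) {
      # leave-one-out: rebuild this category's prototype without trial t_i
      k <- match(trials$category[t_i], cats)
      peers <- which(!is.na(trials$category) &
                       trials$category == trials$category[t_i] &
                       trials$sigma == 0)
      peers <- setdiff(peers, t_i)
      if (length(peers) == 0L)
        stop("category ", trials$category[t_i],
             " has a single noiseless trial; leave-one-out impossible")
      P[, k] <- rowMeans(betas[, peers, drop = FALSE])
    }
    out$predicted[i] <- cats[classifyTrial(y, P)]
  }
  out$correct <- out$predicted == out$category
  out
}

# assemble an AccuracyMatrix from labelled outcomes
.accuracy_from_outcomes <- function(sigma, freq, correct, sigmas, freqs) {
  A <- matrix(NA_real_, length(sigmas), length(freqs))
  n <- matrix(0L, length(sigmas), length(freqs))
  base_sel <- sigma == 0
  baseline <- if (any(base_sel)) mean(correct[base_sel]) else NA_real_
  for (i in seq_along(sigmas)) {
    for (j in seq_along(freqs)) {
      if (sigmas[i] == 0) {
        # zero-noise accuracy is frequency-independent
        A[i, j] <- baseline
        n[i, j] <- sum(base_sel)
      } else {
        sel <- sigma == sigmas[i] & !is.na(freq) & freq == freqs[j]
        n[i, j] <- sum(sel)
        if (n[i, j] > 0L) A[i, j] <- mean(correct[sel])
      }
    }
  }
  new("AccuracyMatrix", values = A, sigmas = sigmas, freqs = freqs,
      nTrials = n, baseline = baseline,
      baselineN = sum(base_sel))
}

#' Decoding-accuracy matrix
#'
#' The proportion of correctly classified scene trials per noise condition
#' (sigma, f). The sigma = 0 baseline is computed with leave-one-out
#' prototypes (see [decodeTrials()]) and repeated across the sigma = 0 row.
#'
#' @param x a \linkS4class{CbmExperiment}
#' @param voxels voxel indices
#' @return an \linkS4class{AccuracyMatrix}
#' @export
accuracyMatrix <- function(x, voxels = selectVoxels(x)) {
  trials <- as.data.frame(SummarizedExperiment::colData(x))
  dec <- decodeTrials(x, voxels)
  grid <- .condition_grid(trials)
  .accuracy_from_outcomes(dec$sigma, dec$freq, dec$correct,
                          grid$sigmas, grid$freqs)
}

#' Behavioral accuracy matrix
#'
#' Proportion correct per condition for labelled behavioral trials, e.g.
#' from [simulateBehavior()].
#'
#' @param outcomes data.frame with columns \code{sigma}, \code{freq},
#'   \code{correct}
#' @return an \linkS4class{AccuracyMatrix}
#' @export
behavioralAccuracyMatrix <- function(outcomes) {
  stopifnot(all(c("sigma", "freq", "correct") %in% names(outcomes)))
  sigmas <- sort(unique(outcomes$sigma))
  freqs <- sort(unique(outcomes$freq[!is.na(outcomes$freq)]))
  .accuracy_from_outcomes(outcomes$sigma, outcomes$freq,
                          as.logical(outcomes$correct), sigmas, freqs)
}
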