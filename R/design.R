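#' Construct an experiment design
#'
#' Defaults reproduce the canonical critical-band-masking design: 10 object
#' categories, 7 octave noise bands (centers 1.75 .. 112 cycles/image), 5
#' noise contrasts \{0, 0.02, 0.04, 0.08, 0.16\}, and per-stimulus
#' repetitions (3, 9, 19, 23) for scenes-in-noise, noise-only, scene-only
#' and blank trials, giving 319 unique conditions and 1305 trials.
#'
#' @param nCategories number of object categories
#' @param bandCenters noise band center frequencies (cycles/image), or a
#'   \linkS4class{PyramidBands} object
#' @param contrasts noise standard deviations, including 0
#' @param reps repetitions \code{c(sceneNoise, noiseOnly, sceneOnly, blank)}
#' @return an \linkS4class{ExperimentDesign}
#' @examples
#' experimentDesign()
#' @export
experimentDesign <- function(nCategories = 10L,
                             bandCenters = buildPyramidBands(512L, 7L),
                             contrasts = c(0, 0.02, 0.04, 0.08, 0.16),
                             reps = c(sceneNoise = 3L, noiseOnly = 9L,
                                      sceneOnly = 19L, blank = 23L)) {
  if (is(bandCenters, "PyramidBands")) bandCenters <- bandCenters@centers
  reps <- as.integer(reps)
  names(reps) <- c("sceneNoise", "noiseOnly", "sceneOnly", "blank")
  new("ExperimentDesign", nCategories = as.integer(nCategories),
      bandCenters = as.numeric(bandCenters),
      contrasts = as.numeric(contrasts), reps = reps)
}

#' Enumerate the unique stimulus conditions of a design
#'
#' The (C+1) image categories (C objects + blank) crossed with the
#' (|F| x |nonzero contrasts| + 1) noise conditions (plus no-noise) give
#' \eqn{(C+1)(|F||\Sigma \setminus 0| + 1)} unique conditions: 319 for the
#' canonical design. Noise-only rows carry a null (NA) category; zero-
#' contrast rows carry a null frequency.
#'
#' @param design an \linkS4class{ExperimentDesign}
#' @return data.frame with columns \code{kind} (one of "sceneNoise",
#'   "noiseOnly", "sceneOnly", "blank"), \code{category}, \code{freq},
#'   \code{sigma}
#' @examples
#' nrow(enumerateConditions(experimentDesign()))  # 319
#' @export
enumerateConditions <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  C <- design@nCategories
  f <- design@bandCenters
  sig <- sort(design@contrasts[design@contrasts > 0])
  noise_grid <- expand.grid(freq = f, sigma = sig,
                            KEEP.OUT.ATTRS = FALSE)
  cond <- list(
    data.frame(kind = "sceneNoise",
               category = rep(seq_len(C), each = nrow(noise_grid)),
               freq = rep(noise_grid$freq, C),
               sigma = rep(noise_grid$sigma, C)),
    data.frame(kind = "sceneOnly", category = seq_len(C),
               freq = NA_real_, sigma = 0),
    data.frame(kind = "noiseOnly", category = NA_integer_,
               freq = noise_grid$freq, sigma = noise_grid$sigma),
    data.frame(kind = "blank", category = NA_integer_,
               freq = NA_real_, sigma = 0))
  out <- do.call(rbind, cond)
  rownames(out) <- NULL
  out
}

#' Build a randomized trial table for a design
#'
#' Replicates each unique condition according to the design's repetition
#' scheme, shuffles the trials deterministically under \code{seed}, and
#' assigns them to runs round-robin (as even a split as possible). Each
#' trial carries its own stimulus seed, derived from the master seed by a
#' counter (\code{seed + trial index}).
#'
#' @param design an \linkS4class{ExperimentDesign}
#' @param nRuns number of runs (>= 1)
#' @param seed master seed for the shuffle and the per-trial seeds
#' @return data.frame with columns \code{trial}, \code{run}, \code{kind},
#'   \code{category}, \code{freq}, \code{sigma}, \code{seed}
#' @examples
#' d <- experimentDesign()  # reps (3, 9, 19, 23)
#' nrow(buildTrialTable(d, nRuns = 15, seed = 1))  # 1305
#' @export
buildTrialTable <- function(design, nRuns, seed) {
  stopifnot(is(design, "ExperimentDesign"))
  if (nRuns < 1L) stop("nRuns must be >= 1")
  cond <- enumerateConditions(design)
  nrep <- design@reps[as.character(cond$kind)]
  idx <- rep(seq_len(nrow(cond)), nrep)
  trials <- cond[idx, , drop = FALSE]
  n <- nrow(trials)
  if (n == 0L) {
    return(data.frame(trial = integer(), run = integer(),
                      kind = character(), category = integer(),
                      freq = numeric(), sigma = numeric(),
                      seed = integer()))
  }
  set.seed(as.integer(seed))
  trials <- trials[sample.int(n), , drop = FALSE]
  rownames(trials) <- NULL
  data.frame(trial = seq_len(n),
             run = rep_len(seq_len(nRuns), n),
             trials,
             seed = as.integer(seed) + seq_len(n))
}

#' Write a trial table to CSV
#' @param trials data.frame from [buildTrialTable()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
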