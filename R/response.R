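#' Select voxels by eccentricity and variance explained
#'
#' Keeps voxels whose pRF eccentricity lies in the closed interval
#' \code{eccRange} (canonically [0, 6] degrees) and, when \code{r2Min} is
#' given, whose GLM variance explained is strictly greater than
#' \code{r2Min} (the canonical VTC criterion is \code{r2Min = 0.05}).
#'
#' @param x a \linkS4class{CbmExperiment} or a voxel metadata data.frame
#'   with columns \code{eccentricity} and \code{r2}
#' @param eccRange closed eccentricity interval, degrees
#' @param r2Min optional strict lower bound on variance explained
#' @return integer vector of voxel indices (a warning is emitted when
#'   empty)
#' @examples
#' m <- data.frame(eccentricity = c(0.5, 5.9, 6, 7.2), r2 = rep(0.2, 4))
#' selectVoxels(m)  # 1 2 3 (interval is closed)
#' @export
selectVoxels <- function(x, eccRange = c(0, 6), r2Min = NULL) {
  meta <- if (is(x, "SummarizedExperiment")) {
    as.data.frame(SummarizedExperiment::rowData(x))
  } else {
    as.data.frame(x)
  }
  if (nrow(meta) == 0L) stop("no voxels")
  keep <- meta$eccentricity >= eccRange[1] & meta$eccentricity <= eccRange[2]
  if (!is.null(r2Min)) keep <- keep & meta$r2 > r2Min
  idx <- which(keep)
  if (length(idx) == 0L) warning("voxel selection is empty")
  idx
}

# condition grid of a trial table: all contrasts x all band frequencies
.condition_grid <- function(trials) {
  list(sigmas = sort(unique(trials$sigma)),
       freqs = sort(unique(trials$freq[!is.na(trials$freq)])))
}

# mean over selected voxels, per trial
.voxel_means <- function(x, voxels) {
  betas <- SummarizedExperiment::assay(x, "betas")
  colMeans(betas[voxels, , drop = FALSE])
}

#' Noise-response matrix
#'
#' For each noise condition (sigma, f), the mean over all noise-only
#' trials of the mean beta weight across the selected voxels. Cells with
#' no trials (including the whole sigma = 0 row, since zero-contrast noise
#' does not exist) are NA and are excluded from subsequent fits.
#'
#' @param x a \linkS4class{CbmExperiment}
#' @param voxels voxel indices, e.g. from [selectVoxels()]
#' @return a \linkS4class{ResponseMatrix} (raw scale; see
#'   [normalizeByScene()])
#' @export
noiseResponseMatrix <- function(x, voxels = selectVoxels(x)) {
  stopifnot(is(x, "CbmExperiment"))
  trials <- as.data.frame(SummarizedExperiment::colData(x))
  noise <- trials$kind == "noiseOnly"
  if (!any(noise)) stop("no noise-only trials")
  grid <- .condition_grid(trials)
  vm <- .voxel_means(x, voxels)
  R <- matrix(NA_real_, length(grid$sigmas), length(grid$freqs))
  n <- matrix(0L, length(grid$sigmas), length(grid$freqs))
  for (i in seq_along(grid$sigmas)) {
    for (j in seq_along(grid$freqs)) {
      sel <- noise & trials$sigma == grid$sigmas[i] &
        !is.na(trials$freq) & trials$freq == grid$freqs[j]
      n[i, j] <- sum(sel)
      if (n[i, j] > 0L) R[i, j] <- mean(vm[sel])
    }
  }
  new("ResponseMatrix", values = R, sigmas = grid$sigmas,
      freqs = grid$freqs, nTrials = n, normalized = FALSE,
      reference = NA_real_, nVoxels = length(voxels))
}

#' Normalize a response matrix by the scene-alone response
#'
#' Divides every cell by the mean voxel-mean response over scene-only
#' (sigma = 0) trials, so the scene-alone response equals 1 on the
#' normalized scale and the noise threshold target lives at 1.
#'
#' @param R a raw \linkS4class{ResponseMatrix}
#' @param x the \linkS4class{CbmExperiment} the matrix came from
#' @param voxels the same voxel indices used to build \code{R}
#' @return a normalized \linkS4class{ResponseMatrix} with the divisor in
#'   \code{@reference}
#' @export
normalizeByScene <- function(R, x, voxels = selectVoxels(x)) {
  stopifnot(is(R, "ResponseMatrix"), is(x, "CbmExperiment"))
  if (R@normalized) stop("matrix is already normalized")
  trials <- as.data.frame(SummarizedExperiment::colData(x))
  sel <- trials$kind == "sceneOnly"
  if (!any(sel)) stop("no scene-only trials to normalize by")
  ref <- mean(.voxel_means(x, voxels)[sel])
  if (!is.finite(ref) || ref == 0)
    stop("degenerate scene-alone reference (", ref, ")")
  new("ResponseMatrix", values = R@values / ref, sigmas = R@sigmas,
      freqs = R@freqs, nTrials = R@nTrials, normalized = TRUE,
      reference = ref, nVoxels = R@nVoxels)
}

#' Write a condition matrix to CSV
#'
#' Writes the sigma x frequency matrix with labelled header row/column.
#'
#' @param x a \linkS4class{ConditionMatrix}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeConditionMatrix <- function(x, path) {
  stopifnot(is(x, "ConditionMatrix"))
  m <- as.matrix(x)
  df <- data.frame(sigma = x@sigmas, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
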