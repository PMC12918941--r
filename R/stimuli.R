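#' Rescale an image's RMS contrast about a midgray level
#'
#' Re-centers the image on \code{midgray} and scales deviations so the
#' output RMS contrast (standard deviation of pixel intensities) is
#' \code{fraction} times the input's:
#' \code{out = midgray + fraction * (x - mean(x))}.
#' A constant input maps to a constant midgray image.
#'
#' @param image numeric matrix with values in [0, 1]
#' @param fraction contrast scaling in [0, 1] (canonically 0.2)
#' @param midgray target mean level (canonically 0.449)
#' @return rescaled matrix
#' @examples
#' img <- matrix(runif(64^2), 64)
#' out <- scaleContrast(img, 0.2)
#' sd(out) / sd(img)  # 0.2
#' @export
scaleContrast <- function(image, fraction = 0.2, midgray = 0.449) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(image < 0) || any(image > 1))
    stop("image values must lie in [0, 1]")
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  midgray + fraction * (image - mean(image))
}

#' Generate octave-band Gaussian noise at an exact RMS contrast
#'
#' Samples a Gaussian white-noise field, extracts one octave band with
#' [applyBandFilter()], and rescales the result to zero mean and sample
#' standard deviation exactly \code{sigma}. \code{sigma = 0} returns an
#' all-zero field. Identical \code{seed} and band arguments give a bit-identical
#' field.
#'
#' @param bands a \linkS4class{PyramidBands}
#' @param level band index, 0 (coarsest) to \code{nLevels - 1}
#' @param sigma noise standard deviation (RMS contrast in normalized
#'   intensity units), >= 0
#' @param seed integer RNG seed
#' @return zero-mean matrix of side \code{bands@N} with \code{sd = sigma}
#' @examples
#' b <- buildPyramidBands(128, 5)
#' n <- makeBandpassNoise(b, level = 2, sigma = 0.04, seed = 1)
#' sd(n)  # 0.04
#' @export
makeBandpassNoise <- function(bands, level, sigma, seed) {
  stopifnot(is(bands, "PyramidBands"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(matrix(0, bands@N, bands@N))
  set.seed(as.integer(seed))
  white <- matrix(rnorm(bands@N^2), bands@N, bands@N)
  n <- applyBandFilter(bands, white, level)
  n <- n - mean(n)
  n * (sigma / sd(n))
}

#' Compose a stimulus from a scene and a noise field
#'
#' Adds the noise field to the scene (or to a uniform midgray image when
#' \code{scene} is NULL, yielding a noise-only stimulus) and clips pixel
#' values to [0, 1]. The fraction of clipped pixels is recorded in the
#' \code{"clipFraction"} attribute.
#'
#' @param scene matrix in [0, 1], or NULL for noise-only
#' @param noise zero-mean noise matrix, same shape as \code{scene}
#' @param midgray background level used when \code{scene} is NULL
#' @return matrix in [0, 1] with attribute \code{clipFraction}
#' @export
composeStimulus <- function(scene = NULL, noise, midgray = 0.449) {
  stopifnot(is.matrix(noise))
  base <- if (is.null(scene)) {
    matrix(midgray, nrow(noise), ncol(noise))
  } else {
    if (!identical(dim(scene), dim(noise)))
      stop("scene and noise shapes differ: ",
           paste(dim(scene), collapse = "x"), " vs ",
           paste(dim(noise), collapse = "x"))
    scene
  }
  out <- base + noise
  clipped <- out < 0 | out > 1
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "clipFraction") <- mean(clipped)
  out
}

#' Orientation-pooled radial power spectrum
#'
#' 2-D power spectrum pooled over orientation into integer radial-frequency
#' bins (total power per annulus), for frequencies 1 .. Nyquist.
#'
#' @param image square numeric matrix
#' @return data.frame with columns \code{freq} (cycles/image) and
#'   \code{power}
#' @export
radialPowerSpectrum <- function(image) {
  stopifnot(is.matrix(image))
  n <- nrow(image)
  if (n != ncol(image)) stop("image must be square")
  P <- Mod(stats::fft(image))^2
  fr <- c(0:(n %/% 2), seq(n %/% 2 - 1, 1))
  r <- sqrt(outer(fr^2, fr^2, "+"))
  rb <- round(r)
  keep <- rb >= 1 & rb <= n %/% 2
  pw <- tapply(P[keep], rb[keep], sum)
  data.frame(freq = as.numeric(names(pw)), power = as.numeric(pw))
}

#' Radial spectral peak frequency
#'
#' The radial frequency bin maximizing the orientation-pooled power
#' spectrum; used to validate the measured center of each noise band. For
#' unfiltered white noise, annulus power grows with annulus area, so the
#' peak sits near the Nyquist region.
#'
#' @param image square numeric matrix; a constant image has no defined
#'   peak and raises an error
#' @return peak frequency in cycles/image
#' @examples
#' g <- outer(1:64, 1:64, function(i, j) sin(2 * pi * 8 * i / 64))
#' radialSpectralPeak(g)  # 8
#' @export
radialSpectralPeak <- function(image) {
  if (isTRUE(all.equal(max(image), min(image))))
    stop("constant image: spectral peak undefined")
  sp <- radialPowerSpectrum(image)
  sp$freq[which.max(sp$power)]
}

#' Write a stimulus as an 8-bit grayscale PNG with a JSON sidecar
#'
#' @param image matrix in [0, 1]
#' @param path output PNG path; the sidecar is written to
#'   \code{paste0(path, ".json")}
#' @param meta named list recorded in the sidecar (band, sigma, seed, ...);
#'   the clip fraction attribute of [composeStimulus()] output is added
#'   automatically when present
#' @return \code{path}, invisibly
#' @export
writeStimulusPNG <- function(image, path, meta = list()) {
  stopifnot(is.matrix(image))
  if (any(image < 0) || any(image > 1))
    stop("image values must lie in [0, 1]; compose/clip first")
  cf <- attr(image, "clipFraction")
  if (!is.null(cf) && is.null(meta$clipFraction)) meta$clipFraction <- cf
  png::writePNG(image, target = path)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bilinear resampling of a grayscale image
#'
#' @param image numeric matrix
#' @param size output side length
#' @return \code{size} x \code{size} matrix
#' @export
resampleImage <- function(image, size) {
  stopifnot(is.matrix(image), size >= 1)
  n <- nrow(image); m <- ncol(image)
  # map output pixel centers onto input pixel-center coordinates
  xi <- (seq_len(size) - 0.5) * (n / size) + 0.5 - 0.5
  yi <- (seq_len(size) - 0.5) * (m / size) + 0.5 - 0.5
  xi <- pmin(pmax(xi, 1), n)
  yi <- pmin(pmax(yi, 1), m)
  x0 <- pmin(floor(xi), n - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), m - 1L); fy <- yi - y0
  a <- image[x0, y0, drop = FALSE]
  b <- image[x0 + 1, y0, drop = FALSE]
  cc <- image[x0, y0 + 1, drop = FALSE]
  d <- image[x0 + 1, y0 + 1, drop = FALSE]
  wfx <- matrix(fx, size, size)
  wfy <- matrix(fy, size, size, byrow = TRUE)
  a * (1 - wfx) * (1 - wfy) + b * wfx * (1 - wfy) +
    cc * (1 - wfx) * wfy + d * wfx * wfy
}

#' Center crop of an image
#'
#' @param image numeric matrix
#' @param size crop side length, at most \code{min(dim(image))}
#' @return \code{size} x \code{size} matrix
#' @export
centerCrop <- function(image, size) {
  stopifnot(is.matrix(image), size <= min(dim(image)))
  r0 <- (nrow(image) - size) %/% 2L
  c0 <- (ncol(image) - size) %/% 2L
  image[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
}

#' Prepare a grayscale scene for the masking experiment
#'
#' Applies the standard preprocessing chain to any square grayscale
#' image: bilinear resample to 256, center-crop to 224, bilinear upsample
#' to the presentation size (default 512), then rescale contrast to
#' \code{fraction} of the original RMS about \code{midgray}.
#'
#' @param image numeric matrix in [0, 1]
#' @param size presentation side length (a power of two for the band
#'   decomposition)
#' @param fraction RMS contrast scaling (default 0.2)
#' @param midgray midgray level (default 0.449)
#' @return \code{size} x \code{size} matrix, low contrast about midgray
#' @export
prepareSceneImage <- function(image, size = 512L, fraction = 0.2,
                              midgray = 0.449) {
  out <- resampleImage(image, 256L)
  out <- centerCrop(out, 224L)
  out <- resampleImage(out, size)
  out <- pmin(pmax(out, 0), 1)
  scaleContrast(out, fraction = fraction, midgray = midgray)
}

#' Procedural grayscale texture standing in for a natural scene
#'
#' Synthesizes a 1/f^slope noise texture (natural images have
#' approximately 1/f amplitude spectra), mapped to [0, 1]. Useful as a
#' deterministic stand-in scene wherever a grayscale photograph would be
#' used.
#'
#' @param n side length (power of two)
#' @param seed integer RNG seed
#' @param slope spectral amplitude falloff exponent (default 1)
#' @return matrix in [0, 1]
#' @export
proceduralScene <- function(n = 512L, seed = 1L, slope = 1) {
  stopifnot(n >= 4)
  set.seed(as.integer(seed))
  fr <- c(0:(n %/% 2), seq(n %/% 2 - 1, 1))
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  rad[1, 1] <- 1
  amp <- 1 / rad^slope
  amp[1, 1] <- 0  # zero DC; mean set by the range mapping below
  phase <- matrix(complex(argument = runif(n * n, 0, 2 * pi)), n, n)
  field <- Re(stats::fft(amp * phase, inverse = TRUE)) / (n * n)
  (field - min(field)) / (max(field) - min(field))
}
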