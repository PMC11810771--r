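#' Generate a synthetic test image or stack
#'
#' Deterministic (seeded) generator for the three fixture families used
#' throughout benchmarking and testing: `"uniform-noise"` (i.i.d. values in
#' \[0, 1), the stand-in for the random benchmark images), `"spots"`
#' (Gaussian peaks on a dim background with mild noise, for visually
#' meaningful denoising demonstrations) and `"ramp"` (an exact linear field
#' `a*x + b*y + c`, for interpolation checks).
#'
#' @param height,width frame dimensions, >= 1.
#' @param frames number of time points; 1 returns a matrix, > 1 a
#'   T x H x W array.
#' @param kind one of `"uniform-noise"`, `"spots"`, `"ramp"`.
#' @param seed integer seed; identical seeds give identical arrays.
#' @param rampCoef numeric (a, b, c) for the ramp field, with x the 0-based
#'   column index and y the 0-based row index.
#' @return numeric matrix (frames == 1) or T x H x W array.
#' @examples
#' img <- generateImage(32, 32, kind = "spots", seed = 7)
#' @export
generateImage <- function(height, width, frames = 1,
                          kind = c("uniform-noise", "spots", "ramp"),
                          seed = NULL, rampCoef = c(0.5, 0.25, 1)) {
  kind <- match.arg(kind)
  if (height < 1 || width < 1 || frames < 1)
    stop("dimensions must be >= 1", call. = FALSE)
  height <- as.integer(height); width <- as.integer(width)
  frames <- as.integer(frames)
  gen <- function() {
    one <- function() switch(kind,
      "uniform-noise" = matrix(stats::runif(height * width), height, width),
      "spots" = spotsFrame(height, width),
      "ramp" = outer(0:(height - 1), 0:(width - 1), function(y, x)
        rampCoef[1] * x + rampCoef[2] * y + rampCoef[3]))
    if (frames == 1L) return(one())
    a <- array(0, dim = c(frames, height, width))
    for (t in seq_len(frames)) a[t, , ] <- one()
    a
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

spotsFrame <- function(height, width) {
  nSpots <- max(1L, as.integer(round(height * width / 200)))
  f <- matrix(0.1, height, width)
  cy <- stats::runif(nSpots, 1, height)
  cx <- stats::runif(nSpots, 1, width)
  amp <- stats::runif(nSpots, 0.5, 1)
  s <- stats::runif(nSpots, 1, max(2, min(height, width) / 10))
  ys <- matrix(seq_len(height), height, width)
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  for (k in seq_len(nSpots))
    f <- f + amp[k] * exp(-((ys - cy[k])^2 + (xs - cx[k])^2) / (2 * s[k]^2))
  f + matrix(stats::runif(height * width, 0, 0.05), height, width)
}
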