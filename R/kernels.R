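#' 2D convolution with edge clamping
#'
#' Cross-correlates an image with an odd-sided square kernel; reads outside
#' the image replicate the nearest edge pixel, so the output keeps the input's
#' shape. The value at pixel (i, j) is
#' `sum_{u,v} kernel[u,v] * image[clamp(i+u-K%/%2), clamp(j+v-K%/%2)]`.
#'
#' Three implementations ship: `"unthreaded"` (scalar C++ loops),
#' `"threaded"` (row-chunked parallel execution of the same core) and
#' `"vectorized"` (shifted-matrix accumulation in R). All produce numerically
#' equivalent outputs; accumulation order may differ, so agreement is within
#' floating-point tolerance rather than bit-exact across strategies.
#'
#' @param image numeric H x W matrix, all values finite.
#' @param kernel numeric K x K matrix, K odd, all values finite.
#' @param implId one of the registered implementations of `"conv2d"`.
#' @param registry registry to resolve `implId` in; defaults to the shipped
#'   registry.
#' @return numeric H x W matrix.
#' @examples
#' img <- generateImage(16, 16, kind = "uniform-noise", seed = 1)
#' k <- matrix(1, 3, 3)
#' out <- conv2d(img, k)
#' @export
conv2d <- function(image, kernel, implId = "unthreaded",
                   registry = defaultRegistry()) {
  e <- getImplementation(registry, "conv2d", implId, requireAvailable = TRUE)
  e@runner(image = image, kernel = kernel)
}

checkConvArgs <- function(image, kernel) {
  if (!is.matrix(image) || nrow(image) < 1L || ncol(image) < 1L)
    stop("image must be a matrix with H >= 1, W >= 1", call. = FALSE)
  stopIfNotFiniteImage(image)
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel))
    stop("kernel must be a square matrix", call. = FALSE)
  if (nrow(kernel) %% 2L == 0L)
    stop("kernel side must be odd, got ", nrow(kernel), call. = FALSE)
  stopIfNotFiniteImage(kernel, "kernel")
}

convRun <- function(image, kernel, strategy) {
  checkConvArgs(image, kernel)
  K <- nrow(kernel)
  r <- K %/% 2L
  P <- padReplicate(image, r)
  switch(strategy,
    unthreaded = conv2d_padded_cpp(P, kernel),
    threaded = {
      H <- nrow(image)
      blocks <- chunkRanges(H, chunkCores())
      parts <- chunkLapply(blocks, function(b)
        conv2d_padded_cpp(P[b[1]:(b[2] + 2L * r), , drop = FALSE], kernel))
      do.call(rbind, parts)
    },
    vectorized = {
      H <- nrow(image); W <- ncol(image)
      out <- matrix(0, H, W)
      for (u in seq_len(K))
        for (v in seq_len(K))
          out <- out + kernel[u, v] * P[u:(u + H - 1L), v:(v + W - 1L)]
      out
    },
    stop("unknown conv2d strategy '", strategy, "'", call. = FALSE))
}

#' Catmull-Rom integer-factor upsampling
#'
#' Upsamples each frame of a stack by an integer magnification using the
#' Catmull-Rom cubic convolution kernel
#' `w(t) = 1.5|t|^3 - 2.5|t|^2 + 1` for `|t| <= 1`,
#' `-0.5|t|^3 + 2.5|t|^2 - 4|t| + 2` for `1 < |t| <= 2`, and 0 beyond.
#' Output coordinate (i, j) (0-based) samples input position
#' `(i/magnification, j/magnification)` with pixel centers on the integer
#' grid; the 4x4 tap neighbourhood is edge-clamped. Catmull-Rom weights sum
#' to one at every fractional offset, so constant frames are reproduced
#' exactly and linear ramps are reproduced away from the clamped border.
#'
#' @param stack numeric T x H x W array, or an H x W matrix treated as a
#'   single frame.
#' @param magnification positive integer zoom factor.
#' @param implId,registry see [conv2d()].
#' @return numeric T x (mag*H) x (mag*W) array (matrix in, matrix out).
#' @export
catmullRomZoom <- function(stack, magnification, implId = "unthreaded",
                           registry = defaultRegistry()) {
  e <- getImplementation(registry, "catmull_rom_zoom", implId,
                         requireAvailable = TRUE)
  e@runner(stack = stack, magnification = magnification)
}

asStack <- function(stack) {
  if (is.matrix(stack))
    array(stack, dim = c(1L, nrow(stack), ncol(stack)))
  else if (is.array(stack) && length(dim(stack)) == 3L) stack
  else stop("stack must be an H x W matrix or a T x H x W array",
            call. = FALSE)
}

zoomRun <- function(stack, magnification, strategy) {
  if (length(magnification) != 1L || !is.finite(magnification) ||
      magnification < 1 || magnification != round(magnification))
    stop("magnification must be a positive integer", call. = FALSE)
  wasMatrix <- is.matrix(stack)
  a <- asStack(stack)
  stopIfNotFiniteImage(a, "stack")
  mag <- as.integer(magnification)
  Tn <- dim(a)[1]; H <- dim(a)[2]; W <- dim(a)[3]
  out <- array(0, dim = c(Tn, H * mag, W * mag))

  frames <- switch(strategy,
    unthreaded = lapply(seq_len(Tn), function(t)
      cr_zoom_rows_cpp(matrix(a[t, , ], H, W), mag, 0L, H * mag - 1L)),
    threaded = {
      # chunk over frames when there are several, otherwise over output rows
      if (Tn > 1L) {
        chunkLapply(seq_len(Tn), function(t)
          cr_zoom_rows_cpp(matrix(a[t, , ], H, W), mag, 0L, H * mag - 1L))
      } else {
        blocks <- chunkRanges(H * mag, chunkCores())
        parts <- chunkLapply(blocks, function(b)
          cr_zoom_rows_cpp(matrix(a[1, , ], H, W), mag, b[1] - 1L, b[2] - 1L))
        list(do.call(rbind, parts))
      }
    },
    vectorized = {
      Mr <- crWeightMatrix(H, mag)
      Mc <- crWeightMatrix(W, mag)
      lapply(seq_len(Tn), function(t)
        Mr %*% matrix(a[t, , ], H, W) %*% t(Mc))
    },
    stop("unknown catmull_rom_zoom strategy '", strategy, "'", call. = FALSE))

  for (t in seq_len(Tn)) out[t, , ] <- frames[[t]]
  if (wasMatrix) matrix(out[1, , ], H * mag, W * mag) else out
}

crKernelWeight <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t <= 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Dense (nIn*mag) x nIn interpolation operator; edge-clamped taps fold into
# the border columns, so M %*% f evaluates the 4-tap sum for every output row.
crWeightMatrix <- function(nIn, mag) {
  nOut <- nIn * mag
  M <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    x <- (i - 1) / mag
    b <- floor(x)
    for (n in 0:3) {
      tap <- b - 1 + n
      idx <- min(max(tap, 0), nIn - 1)
      M[i, idx + 1] <- M[i, idx + 1] + crKernelWeight(x - tap)
    }
  }
  M
}

#' Nonlocal-means parameters
#'
#' @param patchSize side length (pixels) of the comparison patch; even values
#'   are rounded up to the next odd integer so patches have a center pixel.
#' @param patchDistance search-window radius in pixels.
#' @param sigma assumed noise standard deviation (intensity units); the term
#'   `2*sigma^2` is subtracted from squared patch distances before weighting.
#' @param h cut-off distance (intensity units) controlling weight decay.
#' @return validated parameter list of class `NLMParams`.
#' @export
nlmParams <- function(patchSize = 7, patchDistance = 11, sigma = 0, h = 0.1) {
  if (patchSize < 1) stop("patchSize must be >= 1", call. = FALSE)
  if (patchDistance < 1) stop("patchDistance must be >= 1", call. = FALSE)
  if (!is.finite(h) || h <= 0)
    stop("h must be a positive cut-off distance", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  ps <- as.integer(patchSize)
  if (ps %% 2L == 0L) ps <- ps + 1L
  structure(list(patchSize = ps, patchDistance = as.integer(patchDistance),
                 sigma = sigma, h = h), class = "NLMParams")
}

#' Nonlocal-means denoising
#'
#' Replaces each pixel by a weighted average of the pixels within a square
#' search window of radius `patchDistance`. The weight between pixels i and j
#' is `exp(-max(d2 - 2*sigma^2, 0) / h^2)` where `d2` is the mean squared
#' difference between the edge-clamped patches of side `patchSize` centered
#' at i and j; weights are normalized to sum to one per pixel. The self
#' weight is not special-cased (the zero patch distance gives it weight 1
#' before normalization).
#'
#' @param image numeric H x W matrix.
#' @param params an `NLMParams` list from [nlmParams()] (a plain list with
#'   the same fields is accepted and validated).
#' @param implId,registry see [conv2d()].
#' @return denoised numeric H x W matrix.
#' @export
nlmDenoise <- function(image, params = nlmParams(), implId = "unthreaded",
                       registry = defaultRegistry()) {
  e <- getImplementation(registry, "nlm_denoise", implId,
                         requireAvailable = TRUE)
  e@runner(image = image, params = params)
}

nlmRun <- function(image, params, strategy) {
  if (!inherits(params, "NLMParams"))
    params <- nlmParams(params$patchSize, params$patchDistance, params$sigma,
                        params$h)
  if (!is.matrix(image) || nrow(image) < 1L || ncol(image) < 1L)
    stop("image must be a matrix with H >= 1, W >= 1", call. = FALSE)
  stopIfNotFiniteImage(image)
  d <- params$patchDistance
  pr <- params$patchSize %/% 2L
  halo <- d + pr
  P <- padReplicate(image, halo)
  H <- nrow(image); W <- ncol(image)
  switch(strategy,
    unthreaded = nlm_padded_cpp(P, H, W, d, pr, params$sigma, params$h),
    threaded = {
      blocks <- chunkRanges(H, chunkCores())
      parts <- chunkLapply(blocks, function(b)
        nlm_padded_cpp(P[b[1]:(b[2] + 2L * halo), , drop = FALSE],
                       b[2] - b[1] + 1L, W, d, pr, params$sigma, params$h))
      do.call(rbind, parts)
    },
    vectorized = nlmVectorized(P, H, W, d, pr, params$sigma, params$h),
    stop("unknown nlm_denoise strategy '", strategy, "'", call. = FALSE))
}

# Array-expression NLM: one pass per search offset. The squared-difference
# plane against the shifted image is box-filtered (cumulative sums) to obtain
# the mean patch distance for every pixel simultaneously.
nlmVectorized <- function(P, H, W, d, pr, sigma, h) {
  halo <- d + pr
  win <- 2L * pr + 1L
  pn <- win * win
  twoSigma2 <- 2 * sigma^2
  h2 <- h^2
  wsum <- matrix(0, H, W)
  vsum <- matrix(0, H, W)
  # rows/cols of P needed so the box filter covers patch taps of every pixel
  rr <- (halo - pr + 1L):(H + halo + pr)
  cc <- (halo - pr + 1L):(W + halo + pr)
  for (dx in -d:d) {
    for (dy in -d:d) {
      D <- (P[rr, cc] - P[rr + dy, cc + dx])^2
      S <- boxSum(D, win)
      w <- exp(-pmax(S / pn - twoSigma2, 0) / h2)
      V <- P[(1:H) + halo + dy, (1:W) + halo + dx, drop = FALSE]
      wsum <- wsum + w
      vsum <- vsum + w * V
    }
  }
  vsum / wsum
}

# Sum of every win x win window of m (valid positions only).
boxSum <- function(m, win) {
  cs <- apply(m, 2, cumsum)
  nr <- nrow(m)
  S1 <- cs[win:nr, , drop = FALSE]
  if (nr > win)
    S1[-1, ] <- S1[-1, , drop = FALSE] - cs[1:(nr - win), , drop = FALSE]
  cs2 <- t(apply(S1, 1, cumsum))
  if (nrow(S1) == 1L) cs2 <- matrix(cs2, 1L)
  nc <- ncol(m)
  S2 <- cs2[, win:nc, drop = FALSE]
  if (nc > win)
    S2[, -1] <- S2[, -1, drop = FALSE] - cs2[, 1:(nc - win), drop = FALSE]
  S2
}
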