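#' Read a microscopy-style image
#'
#' TIFF (single- or multi-page) and PNG (2D only) readers; intensities are
#' converted to doubles on load. Multi-page TIFFs return a T x H x W array,
#' single frames a matrix. Multi-channel pages are collapsed to grayscale by
#' channel averaging.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix or T x H x W array.
#' @export
readImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, collapseGray)
    if (length(frames) == 1L) return(frames[[1]])
    H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
    a <- array(0, dim = c(length(frames), H, W))
    for (t in seq_along(frames)) a[t, , ] <- frames[[t]]
    a
  } else if (ext == "png") {
    collapseGray(png::readPNG(path))
  } else {
    stop("unsupported image format '", ext, "'", call. = FALSE)
  }
}

collapseGray <- function(x) {
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  storage.mode(x) <- "double"
  x
}

#' Write a microscopy-style image
#'
#' TIFF output stores 32-bit samples (multi-page for stacks); PNG output
#' (2D only) stores 8-bit samples. Both formats encode intensities on
#' \[0, 1\]: data outside that range are min-max rescaled before writing
#' (a warning reports the original range).
#'
#' @param x numeric matrix or T x H x W array.
#' @param path destination ending in `.tif`, `.tiff` or `.png`.
#' @return (invisibly) `path`.
#' @export
writeImage <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    x <- (x - rng[1]) / span
    warning("intensities rescaled from [", signif(rng[1], 6), ", ",
            signif(rng[2], 6), "] to [0, 1] for storage", call. = FALSE)
  }
  if (ext %in% c("tif", "tiff")) {
    frames <- if (is.matrix(x)) list(x)
      else lapply(seq_len(dim(x)[1]), function(t)
        matrix(x[t, , ], dim(x)[2], dim(x)[3]))
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext == "png") {
    if (!is.matrix(x))
      stop("PNG supports 2D images only; use TIFF for stacks",
           call. = FALSE)
    png::writePNG(x, path)
  } else {
    stop("unsupported image format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}
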