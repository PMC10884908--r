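#' Scan image container
#'
#' A scan image is a plain numeric matrix of grayscale values in `[0, 1]`
#' carrying the physical pixel size in micrometres as an attribute. The
#' default pixel size is 10 um/px, the native resolution of a 2400-dpi
#' consumer flatbed scanner camera.
#'
#' Pixel coordinates throughout the package are 0-based `(row, col)` with the
#' origin at the top-left pixel centre and half-open pixel boxes, so pixel
#' `(r, c)` covers `[r, r+1) x [c, c+1)` in pixel units.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @return A `scan_image` object (a matrix with attributes).
#' @examples
#' img <- scan_image(matrix(runif(100), 10, 10))
#' pixel_size(img)
#' @export
scan_image <- function(pixels, pixel_size_um = 10) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("scan image contains non-finite pixel values", call. = FALSE)
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("scan image must have both dimensions >= 1", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("scan image values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a positive number", call. = FALSE)
  }
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            class = c("scan_image", "matrix", "array"))
}

#' @rdname scan_image
#' @param x object to query.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) 10 else ps
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

# strip class so arithmetic on the raw matrix is untouched by dispatch
as_pixels <- function(x) {
  y <- unclass(x)
  attr(y, "pixel_size_um") <- NULL
  y
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Gaussian blur with replicate borders
#'
#' Separable Gaussian convolution with the kernel truncated at `4 * sigma`
#' (radius `ceiling(4 * sigma)` pixels, renormalised to sum 1) and replicate
#' (nearest-edge) border handling. These two conventions are fixed because
#' the information volume map is defined in terms of this exact operator;
#' tests compare against a dense-convolution oracle under the same rule.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Matrix of the same dimensions.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), length(sigma) == 1, sigma > 0)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  out <- convolve_cols(x, k, r)
  t(convolve_cols(t(out), k, r))
}

gaussian_kernel_1d <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  i <- (-r):r
  k <- exp(-(i^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution down each column with replicate padding; stats::filter
# does the centred moving sum in C, the padding supplies the border rule
convolve_cols <- function(x, k, r) {
  n <- nrow(x)
  padded <- rbind(x[rep(1L, r), , drop = FALSE],
                  x,
                  x[rep(n, r), , drop = FALSE])
  # filter() correlates with the reversed kernel; symmetric k so no flip
  y <- stats::filter(padded, k, method = "convolution", sides = 2)
  matrix(y[(r + 1L):(r + n), ], n, ncol(x))
}

#' Read and write grayscale images
#'
#' Thin wrappers around the tiff and png packages. Images are stored as
#' 16-bit grayscale TIFF (scene artifacts, IVMs) or 8-bit PNG (masks).
#' Multi-channel input is averaged to one channel on read.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_um pixel size attached to the returned `scan_image`.
#' @return `read_gray()` returns a `scan_image`; `write_gray()` returns
#'   `path` invisibly.
#' @export
read_gray <- function(path, pixel_size_um = 10) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  scan_image(a, pixel_size_um)
}

#' @rdname read_gray
#' @param x matrix in `[0, 1]` to write.
#' @export
write_gray <- function(x, path) {
  x <- clamp01(as_pixels(x))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 16),
    png = png::writePNG(x, path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  invisible(path)
}
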