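#' Information volume map
#'
#' The information volume map (IVM) is a per-pixel object-likelihood image
#' computed from a scan. The scan is blurred with a Gaussian of sigma
#' `sigma_bg` to form a background estimate; the positive and negative parts
#' of the residual are each truncated at zero, blurred with sigma
#' `sigma_info`, and summed:
#'
#' `ivm = G_1.5(max(img - G_1.0(img), 0)) + G_1.5(max(G_1.0(img) - img, 0))`
#'
#' Gradual shading from the pattern sheet survives the background blur and
#' cancels; small sharp perturbations — cells, debris — do not, so they light
#' up in the map. Both blurs truncate their kernels at 4 sigma and use
#' replicate borders (see [gaussian_blur()]).
#'
#' @param img a `scan_image` or numeric matrix in `[0, 1]`.
#' @param sigma_bg background-blur sigma in pixels (default 1.0).
#' @param sigma_info information-blur sigma in pixels (default 1.5).
#' @return An `ivm` object: list with `pixels` (nonnegative matrix, same
#'   shape as `img`), `sigma_bg`, `sigma_info`, `pixel_size_um`.
#' @examples
#' img <- matrix(0.5, 15, 15); img[8, 8] <- 0.9
#' ivm <- compute_ivm(img)
#' max(ivm$pixels)
#' @export
compute_ivm <- function(img, sigma_bg = 1.0, sigma_info = 1.5) {
  px <- pixel_size(img)
  m <- as_pixels(img)
  stopifnot(is.matrix(m), sigma_bg > 0, sigma_info > 0)
  if (any(!is.finite(m))) {
    stop("image contains non-finite pixels", call. = FALSE)
  }
  bg <- gaussian_blur(m, sigma_bg)
  pos <- gaussian_blur(pmax(m - bg, 0), sigma_info)
  neg <- gaussian_blur(pmax(bg - m, 0), sigma_info)
  structure(list(pixels = pos + neg,
                 sigma_bg = sigma_bg, sigma_info = sigma_info,
                 pixel_size_um = px),
            class = "ivm")
}

#' @export
print.ivm <- function(x, ...) {
  cat(sprintf("<ivm> %d x %d px (sigma_bg %.2g, sigma_info %.2g), max %.3g\n",
              nrow(x$pixels), ncol(x$pixels), x$sigma_bg, x$sigma_info,
              max(x$pixels)))
  invisible(x)
}

#' Amplify and clip an IVM
#'
#' Raw IVM values are extremely small; for display they are multiplied by
#' 200, and by 100 when computing object contrast, with values above 1.0
#' (pure white) rounded down to 1.
#'
#' @param ivm an `ivm` object or nonnegative matrix.
#' @param factor positive amplification factor.
#' @return Matrix in `[0, 1]`.
#' @export
amplify_clip <- function(ivm, factor = 200) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  m <- if (inherits(ivm, "ivm")) ivm$pixels else ivm
  pmin(factor * m, 1)
}

#' Object contrast of an IVM
#'
#' The population variance (denominator `N`) of all pixel values of the IVM
#' after x100 amplification and clipping; an index of how easily objects
#' separate from the background.
#'
#' @param ivm an `ivm` object or nonnegative matrix.
#' @return Nonnegative scalar.
#' @export
object_contrast <- function(ivm) {
  a <- amplify_clip(ivm, 100)
  mean((a - mean(a))^2)
}

#' Brightness mean and deviation of a scan image
#'
#' Mean of all pixel values (overall image brightness) and their sample
#' standard deviation with denominator `N - 1` (the luminance spread induced
#' by the pattern sheet). A single-pixel image has deviation 0 by definition.
#'
#' @param img a `scan_image` or numeric matrix.
#' @return Named list `mean`, `deviation`.
#' @export
brightness_stats <- function(img) {
  m <- as_pixels(img)
  stopifnot(is.matrix(m))
  dev <- if (length(m) < 2) 0 else stats::sd(as.numeric(m))
  list(mean = mean(m), deviation = dev)
}

#' Local brightness difference
#'
#' Per pixel, the max-minus-min brightness over the disk neighbourhood of
#' the given radius (replicate borders). Cell visibility in pattern-sheet
#' scans rises with this quantity at a 10-pixel radius, which is therefore
#' the default.
#'
#' @param img a `scan_image` or numeric matrix.
#' @param radius_px disk radius in pixels (>= 1).
#' @return Matrix of the same shape.
#' @export
local_brightness_difference <- function(img, radius_px = 10) {
  m <- as_pixels(img)
  stopifnot(is.matrix(m), radius_px >= 1)
  nr <- nrow(m)
  nc <- ncol(m)
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, ]
  hi <- matrix(-Inf, nr, nc)
  lo <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(offs))) {
    ri <- pmin(pmax(seq_len(nr) + offs$dr[i], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + offs$dc[i], 1L), nc)
    sh <- m[ri, ci, drop = FALSE]
    hi <- pmax(hi, sh)
    lo <- pmin(lo, sh)
  }
  hi - lo
}

#' Pixel-wise binary cross-entropy between two region maps
#'
#' Measures how hard it is to predict one map's information from the other:
#' the mean over pixels of `-(p log q + (1 - p) log(1 - q))` with `q` clamped
#' to `[eps, 1 - eps]` and natural logarithms. The more similar the maps, the
#' lower the value; by Gibbs' inequality it is minimised over `q` at
#' `q = p`. Used to score an amplified IVM against the phase-contrast cell
#' region.
#'
#' @param p reference map (e.g. phase-derived cell region), values in `[0, 1]`.
#' @param q predicted map (e.g. x200 display IVM), values in `[0, 1]`.
#' @param eps clamp applied to `q` (default 1e-7).
#' @return Nonnegative scalar (nats).
#' @export
cross_entropy <- function(p, q, eps = 1e-7) {
  p <- as_pixels(p)
  q <- as_pixels(q)
  if (!identical(dim(p), dim(q))) {
    stop("`p` and `q` must have identical dimensions", call. = FALSE)
  }
  stopifnot(min(p) >= 0, max(p) <= 1, min(q) >= 0, max(q) <= 1)
  qc <- pmin(pmax(q, eps), 1 - eps)
  -mean(p * log(qc) + (1 - p) * log(1 - qc))
}
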