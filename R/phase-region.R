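#' Cell-region map from a phase-contrast image
#'
#' Reference segmentation used to score the IVM: the phase image is filtered
#' with a white top-hat (radius-1 disk structuring element, the 5-pixel
#' plus), Gaussian-blurred with sigma 0.75, intensity-enhanced by the power
#' transform `x^0.15`, binarized with Otsu's automatic global threshold, and
#' cleaned by removing 8-connected components of fewer than 2 pixels.
#'
#' The enhancement is applied before thresholding: applied after
#' binarization a power transform would be a no-op on a `{0,1}` image, so
#' this is the only order in which every step has an effect. The minor-area
#' rule removes objects with *fewer than* 2 pixels — isolated single-pixel
#' specks — where an object's size is measured on the raw top-hat (pixels
#' above the Otsu threshold mapped back through the enhancement), not on its
#' blurred halo: the blur spreads even a 1-px speck over several pixels, so
#' a halo-area rule could never fire.
#'
#' An all-constant input yields an empty region map (the threshold
#' degenerates); this is a documented outcome, not an error.
#'
#' @param phase a `scan_image` or numeric matrix in `[0, 1]`.
#' @param min_area_px components smaller than this many pixels are removed
#'   (default 2).
#' @param enhance_gamma exponent of the enhancement power transform
#'   (default 0.15).
#' @param blur_sigma Gaussian blur sigma in pixels (default 0.75).
#' @return A `region_map`: binary `{0,1}` matrix with attribute
#'   `source = "phase"`.
#' @export
cell_region_from_phase <- function(phase, min_area_px = 2,
                                   enhance_gamma = 0.15, blur_sigma = 0.75) {
  m <- as_pixels(phase)
  stopifnot(is.matrix(m), min(m) >= 0, max(m) <= 1)
  th_raw <- white_tophat_disk1(m)
  th <- gaussian_blur(th_raw, blur_sigma)
  enh <- pmin(pmax(th, 0), 1)^enhance_gamma
  if (diff(range(enh)) < .Machine$double.eps) {
    bin <- matrix(0, nrow(m), ncol(m))
  } else {
    thr <- EBImage::otsu(EBImage::Image(enh), range = c(0, 1))
    bin <- (enh > thr) * 1
    # minor-area rule on the underlying object, not its blurred halo: a
    # component survives only if at least `min_area_px` of its pixels are
    # above the same threshold in the raw top-hat (threshold mapped back
    # through the enhancement), so an isolated 1-px speck is deleted no
    # matter how far the blur spreads it
    core <- th_raw > thr^(1 / enhance_gamma)
    bin <- remove_small_core_components(bin, core, min_area_px)
  }
  region_map(bin, source = "phase")
}

#' @rdname cell_region_from_phase
#' @param pixels matrix of cell-likelihood values in `[0, 1]`.
#' @param source provenance label: `"phase"`, `"ivm"` or `"truth"`.
#' @export
region_map <- function(pixels, source = c("phase", "ivm", "truth")) {
  source <- match.arg(source)
  stopifnot(is.matrix(pixels), min(pixels) >= 0, max(pixels) <= 1)
  structure(pixels, source = source,
            class = c("region_map", "matrix", "array"))
}

# grayscale white top-hat with the 5-pixel plus ("disk radius 1"):
# x - opening(x) = x - dilate(erode(x))
white_tophat_disk1 <- function(x) {
  er <- plus_extremum(x, min = TRUE)
  op <- plus_extremum(er, min = FALSE)
  x - op
}

# min/max over the plus-shaped neighbourhood {(0,0),(±1,0),(0,±1)} with
# replicate borders
plus_extremum <- function(x, min = TRUE) {
  nr <- nrow(x)
  nc <- ncol(x)
  f <- if (min) pmin else pmax
  up <- x[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  dn <- x[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  lf <- x[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  rt <- x[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  f(x, f(up, f(dn, f(lf, rt))))
}

# drop 8-connected components with fewer than min_area pixels
remove_small_components <- function(bin, min_area) {
  if (!any(bin > 0)) return(bin)
  lab <- label8(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  (matrix(lab %in% keep, nrow(bin), ncol(bin))) * 1
}

# drop components whose core (pre-blur suprathreshold) pixel count is below
# min_area; components with no core at all are also dropped
remove_small_core_components <- function(bin, core, min_area) {
  if (!any(bin > 0)) return(bin)
  lab <- label8(bin)
  core_count <- tabulate(lab[core & lab > 0], nbins = max(lab))
  keep <- which(core_count >= min_area)
  (matrix(lab %in% keep, nrow(bin), ncol(bin))) * 1
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the few label pairs
label8 <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab)
  nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1])
    rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
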