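#' Pattern-sheet specification
#'
#' Describes a perforated opaque sheet: circular holes of one diameter on a
#' regular square or hexagonal lattice. The manufactured sheets studied with
#' the scanner had hole diameters of 280, 450, 700 and 850 um; any positive
#' diameter is accepted. `hole_diameter_um = Inf` denotes a fully open sheet
#' (no material), `pitch_um` larger than both sheet dimensions yields a sheet
#' with no holes at all; both degenerate cases are useful controls.
#'
#' @param hole_diameter_um hole diameter in micrometres (> 0, may be `Inf`).
#' @param pitch_um centre-to-centre hole spacing in micrometres; must be at
#'   least `hole_diameter_um` so holes do not overlap.
#' @param lattice `"hex"` (default) or `"square"` hole arrangement.
#' @param sheet_width_um,sheet_height_um sheet extent in micrometres.
#' @return A `pattern_spec` object (list).
#' @examples
#' pattern_spec(450, 900)
#' @export
pattern_spec <- function(hole_diameter_um = 450, pitch_um = 2 * hole_diameter_um,
                         lattice = c("hex", "square"),
                         sheet_width_um = 10000, sheet_height_um = 10000) {
  lattice <- match.arg(lattice)
  stopifnot(is.numeric(hole_diameter_um), length(hole_diameter_um) == 1,
            hole_diameter_um > 0,
            is.numeric(pitch_um), length(pitch_um) == 1, pitch_um > 0,
            is.numeric(sheet_width_um), sheet_width_um > 0,
            is.numeric(sheet_height_um), sheet_height_um > 0)
  if (is.finite(hole_diameter_um) && pitch_um < hole_diameter_um) {
    stop("`pitch_um` must be >= `hole_diameter_um` (non-overlapping holes)",
         call. = FALSE)
  }
  structure(list(hole_diameter_um = hole_diameter_um,
                 pitch_um = pitch_um,
                 lattice = lattice,
                 sheet_width_um = sheet_width_um,
                 sheet_height_um = sheet_height_um),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("<pattern_spec> holes %g um on %s lattice, pitch %g um, sheet %g x %g um\n",
              x$hole_diameter_um, x$lattice, x$pitch_um,
              x$sheet_width_um, x$sheet_height_um))
  invisible(x)
}

# Hole centres (x, y) in um for the lattice covering the sheet plus margin.
# Hex rows are spaced pitch*sqrt(3)/2 with alternate rows offset pitch/2.
hole_centers <- function(spec, margin_um = 0) {
  p <- spec$pitch_um
  w <- spec$sheet_width_um
  h <- spec$sheet_height_um
  safe_seq <- function(from, to, by) {
    if (from > to) numeric(0) else seq(from, to, by = by)
  }
  if (spec$lattice == "square") {
    xs <- safe_seq(p / 2, w - p / 2 + 1e-9, by = p)
    ys <- safe_seq(p / 2, h - p / 2 + 1e-9, by = p)
    if (!length(xs) || !length(ys)) {
      return(matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("x", "y"))))
    }
    g <- expand.grid(x = xs, y = ys)
    return(cbind(x = g$x, y = g$y))
  }
  dy <- p * sqrt(3) / 2
  ys <- safe_seq(dy / 2, h - dy / 2 + 1e-9, by = dy)
  if (!length(ys)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  rows <- lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) p / 2 else 0
    xs <- safe_seq(p / 2 + off, w - p / 2 + 1e-9, by = p)
    if (!length(xs)) return(NULL)
    cbind(x = xs, y = ys[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  }
  out
}

#' Rasterize a pattern sheet
#'
#' Renders the hole pattern as a logical matrix (`TRUE` = open hole) at a
#' given sampling pitch. A pixel is open when its centre lies inside a hole.
#' Pixel `(r, c)` (0-based) has its centre at `((c + 0.5) * px_um,
#' (r + 0.5) * px_um)` in sheet coordinates.
#'
#' @param spec a [pattern_spec()].
#' @param px_um raster sampling pitch in um/px; must be at most one quarter
#'   of the hole diameter so circles are adequately sampled.
#' @return Logical matrix of dimensions `sheet_height_um / px_um` by
#'   `sheet_width_um / px_um` (rounded).
#' @export
rasterize_pattern <- function(spec, px_um) {
  stopifnot(inherits(spec, "pattern_spec"),
            is.numeric(px_um), length(px_um) == 1, px_um > 0)
  nr <- max(1L, as.integer(round(spec$sheet_height_um / px_um)))
  nc <- max(1L, as.integer(round(spec$sheet_width_um / px_um)))
  if (!is.finite(spec$hole_diameter_um)) {
    return(matrix(TRUE, nr, nc))
  }
  if (px_um > spec$hole_diameter_um / 4) {
    stop(sprintf("raster too coarse: px_um = %g exceeds hole_diameter_um / 4 = %g",
                 px_um, spec$hole_diameter_um / 4), call. = FALSE)
  }
  mask <- matrix(FALSE, nr, nc)
  centers <- hole_centers(spec)
  if (!nrow(centers)) return(mask)
  rad <- spec$hole_diameter_um / 2
  rad_px <- rad / px_um
  for (i in seq_len(nrow(centers))) {
    # hole centre in (fractional) pixel index space, 1-based pixel centres
    cx <- centers[i, "x"] / px_um + 0.5
    cy <- centers[i, "y"] / px_um + 0.5
    rr <- max(1L, floor(cy - rad_px)):min(nr, ceiling(cy + rad_px))
    cc <- max(1L, floor(cx - rad_px)):min(nc, ceiling(cx + rad_px))
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - cy)^2, (cc - cx)^2, `+`)
    mask[rr, cc] <- mask[rr, cc] | (d2 <= rad_px^2)
  }
  mask
}

#' Visualization-band coverage ratio
#'
#' Cells become visible only within a band centred on each black-white
#' transition of the sheet's shading; the empirically measured band is about
#' 680 um wide, i.e. extends 340 um to either side of a hole boundary. The
#' coverage ratio is the fraction of sheet area lying within that band: the
#' fraction of pixels whose Euclidean distance to the nearest open/closed
#' boundary is at most `half_width_um`.
#'
#' Distances are measured to the open/closed interface: each pixel's
#' distance-transform value to the opposite phase, minus half a pixel, so
#' the raster estimate converges to the geometric value as `px_um` shrinks.
#'
#' @param mask logical matrix from [rasterize_pattern()] (`TRUE` = open).
#' @param half_width_um half-width of the visualization band (default 340).
#' @param px_um raster sampling pitch of `mask` in um/px.
#' @return Fraction in `[0, 1]`. A mask with no boundary at all (all open or
#'   all closed) returns 0 with a warning.
#' @export
coverage_ratio <- function(mask, half_width_um = 340, px_um) {
  stopifnot(is.matrix(mask), is.logical(mask),
            is.numeric(half_width_um), length(half_width_um) == 1,
            half_width_um > 0,
            is.numeric(px_um), length(px_um) == 1, px_um > 0)
  if (all(mask) || !any(mask)) {
    warning("mask has no open/closed boundary; coverage is 0", call. = FALSE)
    return(0)
  }
  storage.mode(mask) <- "double"
  # distance of open pixels to nearest closed pixel, and vice versa
  d_open <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
  d_closed <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask)))
  d_px <- ifelse(mask > 0, d_open, d_closed) - 0.5
  mean(d_px * px_um <= half_width_um)
}

#' Coverage sweep over hole diameters
#'
#' Computes the visualization-band coverage ratio for a set of hole
#' diameters, each laid out with a pitch given by `pitch_rule`. This is the
#' geometric selection criterion that favours the 450 um sheet among the
#' manufactured diameters, conditional on a layout.
#'
#' @param diameters_um numeric vector of hole diameters.
#' @param pitch_rule function mapping diameter to pitch (default doubles it).
#' @param px_um raster sampling pitch in um/px.
#' @param half_width_um band half-width (default 340 um).
#' @param lattice,sheet_width_um,sheet_height_um forwarded to [pattern_spec()].
#' @return A tibble with columns `hole_diameter_um`, `pitch_um`, `coverage`,
#'   sorted by diameter, with the argmax diameter in attribute `"best"`.
#' @export
coverage_sweep <- function(diameters_um = c(280, 450, 700, 850),
                           pitch_rule = function(d) 2 * d,
                           px_um = 5, half_width_um = 340,
                           lattice = "hex",
                           sheet_width_um = 10000, sheet_height_um = 10000) {
  stopifnot(is.numeric(diameters_um), length(diameters_um) >= 1,
            is.function(pitch_rule))
  diameters_um <- sort(diameters_um)
  res <- purrr::map_dfr(diameters_um, function(d) {
    spec <- pattern_spec(d, pitch_rule(d), lattice = lattice,
                         sheet_width_um = sheet_width_um,
                         sheet_height_um = sheet_height_um)
    mask <- rasterize_pattern(spec, px_um)
    tibble::tibble(hole_diameter_um = d,
                   pitch_um = spec$pitch_um,
                   coverage = coverage_ratio(mask, half_width_um, px_um))
  })
  attr(res, "best") <- res$hole_diameter_um[which.max(res$coverage)]
  res
}
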