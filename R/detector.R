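#' Detector configuration
#'
#' Rule-based cell detection on the x200 display IVM. Pixels at or above
#' `white_thresh` are certain-object seeds; components of the support at or
#' above `gray_thresh` that contain at least one seed are kept (hysteresis).
#' Components larger than `max_single_cell_area_px` are split at
#' distance-transform maxima separated by at least `split_min_distance_px`.
#' The default thresholds were calibrated once on the default synthetic
#' scene and stored here.
#'
#' @param white_thresh seed threshold on the display map, in `(0, 1]`.
#' @param gray_thresh support threshold, strictly below `white_thresh`.
#' @param min_area_px minimum component area kept, in pixels.
#' @param max_single_cell_area_px components above this area are candidates
#'   for splitting into multiple cells.
#' @param split_min_distance_px minimum separation of split peaks.
#' @return A `detector_config` object (list).
#' @export
detector_config <- function(white_thresh = 0.75, gray_thresh = 0.55,
                            min_area_px = 2, max_single_cell_area_px = 40,
                            split_min_distance_px = 3) {
  stopifnot(white_thresh > 0, white_thresh <= 1,
            gray_thresh > 0,
            min_area_px >= 1, max_single_cell_area_px >= 1,
            split_min_distance_px >= 1)
  if (gray_thresh >= white_thresh) {
    stop("`gray_thresh` must be strictly below `white_thresh`", call. = FALSE)
  }
  structure(list(white_thresh = white_thresh, gray_thresh = gray_thresh,
                 min_area_px = as.integer(min_area_px),
                 max_single_cell_area_px = as.integer(max_single_cell_area_px),
                 split_min_distance_px = as.integer(split_min_distance_px)),
            class = "detector_config")
}

#' Detect cells on a display IVM
#'
#' Hysteresis thresholding (white seeds grown into gray support), 8-connected
#' components, minimum-area filtering, and distance-transform peak splitting
#' of oversized components. Deterministic: ties in peak selection are broken
#' by peak height, then row, then column.
#'
#' @param ivm_display matrix in `[0, 1]`, typically
#'   `amplify_clip(compute_ivm(scan), 200)`.
#' @param cfg a [detector_config()].
#' @return A `detection_set` tibble with columns `row_px`, `col_px` (0-based
#'   intensity-weighted centroids) and `area_px`, plus attribute `config`.
#' @export
detect_cells <- function(ivm_display, cfg = detector_config()) {
  m <- as_pixels(ivm_display)
  stopifnot(is.matrix(m), inherits(cfg, "detector_config"),
            min(m) >= 0, max(m) <= 1)
  support <- m >= cfg$gray_thresh
  seeds <- m >= cfg$white_thresh
  empty <- detection_set(numeric(0), numeric(0), integer(0), cfg)
  if (!any(seeds)) return(empty)
  lab <- label8(support * 1)
  seed_labels <- setdiff(unique(lab[seeds]), 0L)
  if (!length(seed_labels)) return(empty)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- seed_labels[sizes[seed_labels] >= cfg$min_area_px]
  rows <- numeric(0)
  cols <- numeric(0)
  areas <- integer(0)
  for (l in keep) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) <= cfg$max_single_cell_area_px) {
      w <- m[idx]
      rows <- c(rows, sum(idx[, 1] * w) / sum(w) - 1)
      cols <- c(cols, sum(idx[, 2] * w) / sum(w) - 1)
      areas <- c(areas, nrow(idx))
      next
    }
    parts <- split_component(idx, m, cfg$split_min_distance_px)
    rows <- c(rows, parts$row)
    cols <- c(cols, parts$col)
    areas <- c(areas, parts$area)
  }
  ord <- order(rows, cols)
  detection_set(rows[ord], cols[ord], areas[ord], cfg)
}

# split an oversized component at its distance-transform peaks; idx is the
# 1-based (row, col) pixel index matrix of the component
split_component <- function(idx, display, min_dist) {
  rr <- range(idx[, 1])
  cc <- range(idx[, 2])
  sub <- matrix(0, diff(rr) + 3, diff(cc) + 3)  # 1-px zero border
  sub[cbind(idx[, 1] - rr[1] + 2L, idx[, 2] - cc[1] + 2L)] <- 1
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(sub)))
  # local maxima over the 8-neighbourhood (plateaus included)
  dil <- d
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    nr <- nrow(d)
    nc <- ncol(d)
    ri <- pmin(pmax(seq_len(nr) + o[1], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + o[2], 1L), nc)
    dil <- pmax(dil, d[ri, ci])
  }
  pk <- which(d > 0 & d >= dil, arr.ind = TRUE)
  ordp <- order(-d[pk], pk[, 1], pk[, 2])
  pk <- pk[ordp, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pk))) {
    if (!nrow(sel) ||
        all((sel[, 1] - pk[i, 1])^2 + (sel[, 2] - pk[i, 2])^2 >=
              min_dist^2)) {
      sel <- rbind(sel, pk[i, , drop = FALSE])
    }
  }
  sub_idx <- cbind(idx[, 1] - rr[1] + 2L, idx[, 2] - cc[1] + 2L)
  w_all <- display[idx]
  if (nrow(sel) <= 1) {
    return(list(row = sum(idx[, 1] * w_all) / sum(w_all) - 1,
                col = sum(idx[, 2] * w_all) / sum(w_all) - 1,
                area = nrow(idx)))
  }
  # nearest-peak assignment without the npix x npeaks matrix
  best_d2 <- rep(Inf, nrow(sub_idx))
  assign_to <- rep(1L, nrow(sub_idx))
  for (kk in seq_len(nrow(sel))) {
    d2 <- (sub_idx[, 1] - sel[kk, 1])^2 + (sub_idx[, 2] - sel[kk, 2])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    assign_to[upd] <- kk
  }
  out <- lapply(seq_len(nrow(sel)), function(k) {
    part <- idx[assign_to == k, , drop = FALSE]
    w <- w_all[assign_to == k]
    list(row = sum(part[, 1] * w) / sum(w) - 1,
         col = sum(part[, 2] * w) / sum(w) - 1,
         area = nrow(part))
  })
  list(row = vapply(out, `[[`, numeric(1), "row"),
       col = vapply(out, `[[`, numeric(1), "col"),
       area = vapply(out, `[[`, integer(1) * 1, "area"))
}

#' Detection set constructor
#'
#' @param row_px,col_px 0-based centroid coordinates.
#' @param area_px component areas in pixels.
#' @param config the [detector_config()] used.
#' @return A tibble of class `detection_set`.
#' @export
detection_set <- function(row_px, col_px, area_px, config = NULL) {
  stopifnot(length(row_px) == length(col_px),
            length(row_px) == length(area_px))
  out <- tibble::tibble(row_px = as.numeric(row_px),
                        col_px = as.numeric(col_px),
                        area_px = as.integer(area_px))
  class(out) <- c("detection_set", class(out))
  attr(out, "config") <- config
  out
}

#' Convert a count to a cell density
#'
#' The count divided by the physical area of the counted region:
#' `count / (area_px * (pixel_size_um * 1e-4)^2)` in cells per square
#' centimetre. A 1000 x 1000 px field at 10 um/px is exactly 1 cm^2.
#'
#' @param count nonnegative cell count.
#' @param area_px counted area in pixels (> 0).
#' @param pixel_size_um pixel size in micrometres.
#' @return Density in cells/cm^2.
#' @export
cell_density <- function(count, area_px, pixel_size_um = 10) {
  stopifnot(count >= 0, pixel_size_um > 0)
  if (area_px <= 0) stop("`area_px` must be positive", call. = FALSE)
  count / (area_px * (pixel_size_um * 1e-4)^2)
}

#' Count cells over a whole vessel
#'
#' Tiles the masked scan, computes the IVM and runs the detector per tile
#' (tiles overlap so blur borders never cut a cell), keeps each detection
#' exactly once by assigning it to the tile owning its centroid, and finally
#' merges any residual near-duplicates within `merge_radius_px`.
#'
#' @param scan a `scan_image`.
#' @param vessel_mask logical matrix, same shape as `scan`; `NULL` counts the
#'   full frame.
#' @param cfg a [detector_config()].
#' @param tile_px tile edge length in pixels.
#' @param overlap_px tile overlap in pixels.
#' @param merge_radius_px seam-duplicate merge radius in pixels.
#' @return A `detection_set` for the whole vessel; total count is its row
#'   count.
#' @export
count_whole_vessel <- function(scan, vessel_mask = NULL,
                               cfg = detector_config(),
                               tile_px = 512, overlap_px = 64,
                               merge_radius_px = 5) {
  m <- as_pixels(scan)
  if (is.null(vessel_mask)) vessel_mask <- matrix(TRUE, nrow(m), ncol(m))
  stopifnot(identical(dim(vessel_mask), dim(m)))
  if (!any(vessel_mask)) {
    warning("empty vessel mask: count is 0", call. = FALSE)
    return(detection_set(numeric(0), numeric(0), integer(0), cfg))
  }
  nr <- nrow(m)
  nc <- ncol(m)
  row_starts <- seq(1L, nr, by = tile_px)
  col_starts <- seq(1L, nc, by = tile_px)
  rows <- numeric(0)
  cols <- numeric(0)
  areas <- integer(0)
  tiles <- integer(0)
  tile_id <- 0L
  for (r0 in row_starts) {
    for (c0 in col_starts) {
      tile_id <- tile_id + 1L
      r1 <- min(r0 + tile_px - 1L, nr)
      c1 <- min(c0 + tile_px - 1L, nc)
      er0 <- max(1L, r0 - overlap_px)
      ec0 <- max(1L, c0 - overlap_px)
      er1 <- min(nr, r1 + overlap_px)
      ec1 <- min(nc, c1 + overlap_px)
      tile <- m[er0:er1, ec0:ec1, drop = FALSE]
      tmask <- vessel_mask[er0:er1, ec0:ec1, drop = FALSE]
      if (!any(tmask)) next
      disp <- amplify_clip(compute_ivm(tile), 200)
      disp[!tmask] <- 0
      det <- detect_cells(disp, cfg)
      if (!nrow(det)) next
      gr <- det$row_px + (er0 - 1L)  # back to 0-based whole-image coords
      gc <- det$col_px + (ec0 - 1L)
      core <- gr >= (r0 - 1L) & gr < r1 & gc >= (c0 - 1L) & gc < c1
      rows <- c(rows, gr[core])
      cols <- c(cols, gc[core])
      areas <- c(areas, det$area_px[core])
      tiles <- c(tiles, rep(tile_id, sum(core)))
    }
  }
  if (length(rows) > 1) {
    ord <- order(rows, cols)
    rows <- rows[ord]; cols <- cols[ord]; areas <- areas[ord]
    tiles <- tiles[ord]
    # residual seam duplicates can only come from different tiles;
    # detections within one tile are distinct by construction
    keep <- rep(TRUE, length(rows))
    for (i in seq_along(rows)) {
      if (!keep[i]) next
      j <- which(keep & seq_along(rows) > i & tiles != tiles[i] &
                   abs(rows - rows[i]) <= merge_radius_px)
      if (length(j)) {
        dup <- j[(rows[j] - rows[i])^2 + (cols[j] - cols[i])^2 <=
                   merge_radius_px^2]
        keep[dup] <- FALSE
      }
    }
    rows <- rows[keep]; cols <- cols[keep]; areas <- areas[keep]
  }
  detection_set(rows, cols, areas, cfg)
}
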