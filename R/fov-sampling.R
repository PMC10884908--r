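#' Place a 5x5 grid of microscope-sized fields
#'
#' Positions 25 rectangular fields (the size of a typical microscope image,
#' 640 x 480 px at 10 um/px by default) on a regular 5 x 5 grid over the
#' largest axis-aligned box inscribed in the vessel mask. Deterministic.
#'
#' @param vessel_mask logical matrix (`TRUE` inside the vessel).
#' @param field_w_px,field_h_px field size in pixels (width = columns).
#' @param n_side fields per grid side (default 5, i.e. 25 fields).
#' @param pixel_size_um pixel size, used for the physical areas.
#' @return A `field_grid`: tibble with 0-based half-open bounds `row0`,
#'   `row1`, `col0`, `col1` per field, with field/vessel areas (cm^2) in
#'   attributes.
#' @export
place_fields <- function(vessel_mask, field_w_px = 640, field_h_px = 480,
                         n_side = 5, pixel_size_um = 10) {
  stopifnot(is.matrix(vessel_mask), is.logical(vessel_mask), n_side >= 1)
  if (!any(vessel_mask)) stop("empty vessel mask", call. = FALSE)
  box <- inscribed_box(vessel_mask)
  if (box$height < n_side * field_h_px || box$width < n_side * field_w_px) {
    stop(sprintf(paste0("a %d x %d grid of %d x %d px fields does not fit ",
                        "the inscribed box (%d x %d px)"),
                 n_side, n_side, field_h_px, field_w_px,
                 box$height, box$width), call. = FALSE)
  }
  # field centres on a regular grid over the inscribed box
  rc <- box$row0 + (seq_len(n_side) - 0.5) / n_side * box$height
  cc <- box$col0 + (seq_len(n_side) - 0.5) / n_side * box$width
  g <- expand.grid(rc = rc, cc = cc)
  grid <- tibble::tibble(
    field = seq_len(nrow(g)),
    row0 = as.integer(round(g$rc - field_h_px / 2)),
    col0 = as.integer(round(g$cc - field_w_px / 2))
  )
  grid$row1 <- grid$row0 + as.integer(field_h_px)
  grid$col1 <- grid$col0 + as.integer(field_w_px)
  grid <- grid[, c("field", "row0", "row1", "col0", "col1")]
  # every field pixel must lie inside the vessel
  for (i in seq_len(nrow(grid))) {
    sub <- vessel_mask[(grid$row0[i] + 1):grid$row1[i],
                       (grid$col0[i] + 1):grid$col1[i]]
    if (!all(sub)) {
      stop("field ", i, " leaves the vessel mask", call. = FALSE)
    }
  }
  class(grid) <- c("field_grid", class(grid))
  attr(grid, "field_area_cm2") <-
    field_w_px * field_h_px * (pixel_size_um * 1e-4)^2
  attr(grid, "vessel_area_cm2") <- sum(vessel_mask) * (pixel_size_um * 1e-4)^2
  grid
}

# largest axis-aligned box inscribed in the mask, grown symmetrically from
# the mask centroid
inscribed_box <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  cr <- mean(idx[, 1])
  cc <- mean(idx[, 2])
  fits <- function(hh, hw) {
    r0 <- max(1, ceiling(cr - hh))
    r1 <- min(nr, floor(cr + hh))
    c0 <- max(1, ceiling(cc - hw))
    c1 <- min(nc, floor(cc + hw))
    all(mask[r0:r1, c0:c1])
  }
  # binary search on a symmetric scale factor of the mask's bounding box
  hh_max <- max(cr - min(idx[, 1]), max(idx[, 1]) - cr)
  hw_max <- max(cc - min(idx[, 2]), max(idx[, 2]) - cc)
  lo <- 0
  hi <- 1
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (fits(mid * hh_max, mid * hw_max)) lo <- mid else hi <- mid
  }
  hh <- lo * hh_max
  hw <- lo * hw_max
  list(row0 = max(1, ceiling(cr - hh)) - 1L,
       col0 = max(1, ceiling(cc - hw)) - 1L,
       height = floor(cr + hh) - max(1, ceiling(cr - hh)) + 1L,
       width = floor(cc + hw) - max(1, ceiling(cc - hw)) + 1L)
}

#' Count points per field
#'
#' @param points tibble with 0-based `row_px`, `col_px` (truth centroids or
#'   detections).
#' @param grid a `field_grid`.
#' @return Integer vector of counts, one per field.
#' @export
count_per_field <- function(points, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    sum(points$row_px >= grid$row0[i] & points$row_px < grid$row1[i] &
          points$col_px >= grid$col0[i] & points$col_px < grid$col1[i])
  }, integer(1))
}

#' Estimate the whole-vessel count from k fields
#'
#' The mean count over `k` sampled fields, scaled by vessel area over field
#' area, is the microscope-style estimate of the total; its percentage
#' discrepancy against the true total quantifies field-of-view sampling
#' bias. For `k = 1` all 25 single-field estimates are reported; for larger
#' `k`, `n_combos` random field subsets (drawn without replacement within
#' each subset, seeded).
#'
#' @param field_counts integer vector of per-field counts (see
#'   [count_per_field()]).
#' @param grid the `field_grid` the counts were taken on.
#' @param k number of fields per subset (1 to `nrow(grid)`).
#' @param true_total reference whole-vessel count (ground truth, or the
#'   whole-vessel detection count, whose own discrepancy is 0 by definition).
#' @param n_combos number of random subsets for `k > 1` (default 5).
#' @param seed seed for subset draws.
#' @return A `fov_result` tibble: `k`, `combo`, `fields` (list column),
#'   `estimated_total`, `true_total`, `discrepancy_pct` where
#'   `discrepancy_pct = 100 * (estimated - true) / true`.
#' @export
estimate_from_fields <- function(field_counts, grid, k, true_total,
                                 n_combos = 5, seed = 1L) {
  n_fields <- nrow(grid)
  if (k < 1 || k > n_fields) {
    stop("`k` must be between 1 and the number of fields", call. = FALSE)
  }
  stopifnot(length(field_counts) == n_fields, true_total > 0)
  field_area <- attr(grid, "field_area_cm2")
  vessel_area <- attr(grid, "vessel_area_cm2")
  combos <- if (k == 1) {
    lapply(seq_len(n_fields), identity)
  } else if (k == n_fields) {
    list(seq_len(n_fields))
  } else {
    with_seed(seed, {
      lapply(seq_len(n_combos), function(i) {
        sort(sample.int(n_fields, k))
      })
    })
  }
  est <- vapply(combos, function(ix) {
    mean(field_counts[ix]) / field_area * vessel_area
  }, numeric(1))
  out <- tibble::tibble(
    k = k,
    combo = seq_along(combos),
    fields = combos,
    estimated_total = est,
    true_total = true_total,
    discrepancy_pct = 100 * (est - true_total) / true_total
  )
  class(out) <- c("fov_result", class(out))
  out
}

#' FOV sampling discrepancy over a growth time series
#'
#' Runs [estimate_from_fields()] per frame of a [growth_series()] with fixed
#' field positions and, for each `k > 1`, fixed field subsets across frames,
#' mirroring time-lapse re-observation of the same microscope positions.
#'
#' @param series a `growth_series` (render not required; truth is used).
#' @param grid a `field_grid`.
#' @param ks vector of subset sizes (default `c(1, 3, 5, 10, 20)`).
#' @param n_combos subsets per `k > 1` (default 5).
#' @param seed seed for the subset draws.
#' @return A `fov_result` tibble with additional columns `frame` and
#'   `time_h`.
#' @export
timeseries_discrepancy <- function(series, grid, ks = c(1, 3, 5, 10, 20),
                                   n_combos = 5, seed = 1L) {
  stopifnot(inherits(series, "growth_series"))
  times_h <- attr(series, "times_h")
  dims <- lapply(series, function(f) dim(f$truth$dark_zone_mask))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("frames have inconsistent shapes", call. = FALSE)
  }
  out <- purrr::map_dfr(seq_along(series), function(f) {
    truth <- series[[f]]$truth$cells
    counts <- count_per_field(truth, grid)
    purrr::map_dfr(ks, function(k) {
      res <- estimate_from_fields(counts, grid, k,
                                  true_total = nrow(truth),
                                  n_combos = n_combos,
                                  seed = seed + match(k, ks))
      res$frame <- f
      res$time_h <- times_h[f]
      res
    })
  })
  class(out) <- c("fov_result", class(out))
  out
}

#' Summary of FOV discrepancies per k
#'
#' @param x a `fov_result`.
#' @param ... unused.
#' @return Tibble with max, min and mean discrepancy per `k` (and per frame
#'   when present), the presentation used for field-count comparisons.
#' @export
glance.fov_result <- function(x, ...) {
  grp <- intersect(c("k", "frame", "time_h"), names(x))
  dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(grp))),
    max_pct = max(.data$discrepancy_pct),
    min_pct = min(.data$discrepancy_pct),
    mean_pct = mean(.data$discrepancy_pct),
    .groups = "drop"
  )
}
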