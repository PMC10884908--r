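#' Match detections to ground-truth cells
#'
#' One-to-one greedy matching by ascending centroid distance; ties are broken
#' by truth index then detection index, and pairs farther apart than
#' `max_dist_px` are never matched. The default radius of 5 px (about 50 um
#' at scanner resolution) exceeds a cell footprint but stays below typical
#' nearest-neighbour spacing at the densities simulated.
#'
#' @param det a `detection_set` (or tibble with `row_px`, `col_px`).
#' @param truth tibble of true centroids with `row_px`, `col_px` (e.g.
#'   `scene$truth$cells`).
#' @param max_dist_px maximum matching distance in pixels (> 0).
#' @return List with `pairs` (tibble `truth_idx`, `det_idx`, `dist_px`),
#'   `unmatched_truth` and `unmatched_det` (integer index vectors).
#' @export
match_detections <- function(det, truth, max_dist_px = 5) {
  stopifnot(max_dist_px > 0)
  nd <- nrow(det)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(pairs = tibble::tibble(truth_idx = integer(0),
                                       det_idx = integer(0),
                                       dist_px = numeric(0)),
                unmatched_truth = seq_len(nt),
                unmatched_det = seq_len(nd)))
  }
  d <- sqrt(outer(truth$row_px, det$row_px, `-`)^2 +
              outer(truth$col_px, det$col_px, `-`)^2)
  cand <- which(d <= max_dist_px, arr.ind = TRUE)
  dimnames(cand) <- NULL
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  t_used <- logical(nt)
  d_used <- logical(nd)
  ti <- integer(0)
  di <- integer(0)
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]
    b <- cand[k, 2]
    if (!t_used[a] && !d_used[b]) {
      t_used[a] <- TRUE
      d_used[b] <- TRUE
      ti <- c(ti, a)
      di <- c(di, b)
    }
  }
  list(pairs = tibble::tibble(truth_idx = ti, det_idx = di,
                              dist_px = d[cbind(ti, di)]),
       unmatched_truth = which(!t_used),
       unmatched_det = which(!d_used))
}

#' Classify counting errors into the four-way taxonomy
#'
#' Unmatched detections (overdetection) are classified as *image-origin*
#' (within `debris_radius_px` of a debris centroid — debris or detached
#' cells) or *large-cell* (nearest true cell is already matched to another
#' detection, i.e. one large cell split into two); unmatched true cells
#' (underdetection) as *blind-spot* (centroid inside the dark-zone mask of
#' the shading pattern) or *lack of resolution* (at least one other true
#' cell within the crowd radius, i.e. a densely populated area). Precedence
#' when two rules apply: image-origin over large-cell, blind-spot over
#' resolution. Items matching no rule are counted as unclassified.
#'
#' @param matching result of [match_detections()].
#' @param det the `detection_set` that was matched.
#' @param truth tibble of true cell centroids with `diameter_um`.
#' @param scene_aux auxiliary ground truth: list with `debris` (tibble of
#'   centroids) and `dark_zone_mask` (logical matrix); a `synthetic_scene`
#'   `truth` element works directly.
#' @param debris_radius_px radius for the image-origin rule (default 5).
#' @param crowd_radius_px radius for the resolution rule; default
#'   `2 * median cell diameter` in pixels.
#' @param pixel_size_um pixel size used for the default crowd radius.
#' @return An `error_report` (list) with counts, percentages of `n_truth`,
#'   and the accounting identities
#'   `matched + over_image_origin + over_large_cell + unclassified_over ==
#'   n_detected` and
#'   `matched + under_blind_spot + under_resolution + unclassified_under ==
#'   n_truth`.
#' @export
classify_errors <- function(matching, det, truth, scene_aux,
                            debris_radius_px = 5, crowd_radius_px = NULL,
                            pixel_size_um = 10) {
  missing_aux <- setdiff(c("debris", "dark_zone_mask"), names(scene_aux))
  if (length(missing_aux)) {
    stop("scene_aux lacks ", paste(missing_aux, collapse = ", "),
         ": cannot classify ",
         if ("debris" %in% missing_aux) "image-origin " else "",
         if ("dark_zone_mask" %in% missing_aux) "blind-spot " else "",
         "errors", call. = FALSE)
  }
  if (is.null(crowd_radius_px)) {
    crowd_radius_px <- 2 * stats::median(truth$diameter_um) / pixel_size_um
  }
  n_truth <- nrow(truth)
  n_det <- nrow(det)
  matched <- nrow(matching$pairs)
  matched_truth <- matching$pairs$truth_idx

  over_img <- 0L
  over_large <- 0L
  uncls_over <- 0L
  over_rows <- list()
  for (i in matching$unmatched_det) {
    r <- det$row_px[i]
    c <- det$col_px[i]
    is_img <- nrow(scene_aux$debris) > 0 &&
      any((scene_aux$debris$row_px - r)^2 +
            (scene_aux$debris$col_px - c)^2 <= debris_radius_px^2)
    if (is_img) {
      over_img <- over_img + 1L
      over_rows[[length(over_rows) + 1L]] <-
        tibble::tibble(kind = "over_image_origin", row_px = r, col_px = c)
      next
    }
    d2t <- (truth$row_px - r)^2 + (truth$col_px - c)^2
    nearest <- if (n_truth) which.min(d2t) else integer(0)
    is_large <- length(nearest) && nearest %in% matched_truth &&
      sqrt(d2t[nearest]) <= 2 * debris_radius_px
    if (is_large) {
      over_large <- over_large + 1L
      over_rows[[length(over_rows) + 1L]] <-
        tibble::tibble(kind = "over_large_cell", row_px = r, col_px = c)
    } else {
      uncls_over <- uncls_over + 1L
      over_rows[[length(over_rows) + 1L]] <-
        tibble::tibble(kind = "unclassified_over", row_px = r, col_px = c)
    }
  }

  under_blind <- 0L
  under_res <- 0L
  uncls_under <- 0L
  under_rows <- list()
  dzm <- scene_aux$dark_zone_mask
  for (i in matching$unmatched_truth) {
    r <- truth$row_px[i]
    c <- truth$col_px[i]
    ri <- min(max(as.integer(round(r)) + 1L, 1L), nrow(dzm))
    ci <- min(max(as.integer(round(c)) + 1L, 1L), ncol(dzm))
    if (isTRUE(dzm[ri, ci])) {
      under_blind <- under_blind + 1L
      kind <- "under_blind_spot"
    } else {
      d2 <- (truth$row_px - r)^2 + (truth$col_px - c)^2
      d2[i] <- Inf
      if (any(d2 <= crowd_radius_px^2)) {
        under_res <- under_res + 1L
        kind <- "under_resolution"
      } else {
        uncls_under <- uncls_under + 1L
        kind <- "unclassified_under"
      }
    }
    under_rows[[length(under_rows) + 1L]] <-
      tibble::tibble(kind = kind, row_px = r, col_px = c)
  }

  pct <- function(x) if (n_truth > 0) 100 * x / n_truth else NA_real_
  structure(list(
    n_truth = n_truth, n_detected = n_det, matched = matched,
    over_image_origin = over_img, over_large_cell = over_large,
    under_blind_spot = under_blind, under_resolution = under_res,
    unclassified_over = uncls_over, unclassified_under = uncls_under,
    pct_image_origin = pct(over_img), pct_large_cell = pct(over_large),
    pct_blind_spot = pct(under_blind), pct_resolution = pct(under_res),
    items = dplyr::bind_rows(c(over_rows, under_rows))
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d truth, %d detected, %d matched\n",
              x$n_truth, x$n_detected, x$matched))
  cat(sprintf("  over:  image-origin %d (%.2f%%), large-cell %d (%.2f%%), unclassified %d\n",
              x$over_image_origin, x$pct_image_origin,
              x$over_large_cell, x$pct_large_cell, x$unclassified_over))
  cat(sprintf("  under: blind-spot %d (%.2f%%), resolution %d (%.2f%%), unclassified %d\n",
              x$under_blind_spot, x$pct_blind_spot,
              x$under_resolution, x$pct_resolution, x$unclassified_under))
  invisible(x)
}

#' Broom-style tidiers for error reports
#'
#' `tidy()` returns one row per error category with count and percentage of
#' the true cell number; `glance()` returns a one-row summary.
#'
#' @param x an `error_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.error_report <- function(x, ...) {
  tibble::tibble(
    category = c("over_image_origin", "over_large_cell",
                 "under_blind_spot", "under_resolution",
                 "unclassified_over", "unclassified_under"),
    direction = c("over", "over", "under", "under", "over", "under"),
    count = c(x$over_image_origin, x$over_large_cell,
              x$under_blind_spot, x$under_resolution,
              x$unclassified_over, x$unclassified_under),
    pct_of_truth = 100 * count / x$n_truth
  )
}

#' @rdname tidy.error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble::tibble(n_truth = x$n_truth, n_detected = x$n_detected,
                 matched = x$matched,
                 recall = x$matched / x$n_truth,
                 precision = if (x$n_detected > 0) {
                   x$matched / x$n_detected
                 } else NA_real_,
                 count_error_pct = 100 * (x$n_detected - x$n_truth) / x$n_truth)
}

#' Percent counting error against a reference density
#'
#' `100 * |detected - reference| / reference`, the accuracy measure used to
#' stratify performance by cell density with the nuclear stain as the
#' reference population.
#'
#' @param det_density detected density (cells/cm^2).
#' @param truth_density reference density (> 0).
#' @return Percent error (nonnegative).
#' @export
accuracy_by_density <- function(det_density, truth_density) {
  if (any(truth_density <= 0)) {
    stop("`truth_density` must be positive", call. = FALSE)
  }
  100 * abs(det_density - truth_density) / truth_density
}

#' Squared Pearson correlation
#'
#' R^2 between paired samples, the agreement statistic used when comparing
#' scanner counts with chamber and nuclear-stain counts.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return Scalar in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  stats::cor(x, y)^2
}
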