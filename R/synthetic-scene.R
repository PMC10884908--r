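#' Synthetic scene parameters
#'
#' Parameters for the seeded generator of matched scan / phase-contrast /
#' nuclear-stain image triplets with full ground truth. The defaults emulate
#' the study conditions of pattern-sheet scanner imaging: 10 um/px pixels, a
#' 450 um hole sheet on a 900 um hexagonal lattice, a shading blur chosen so
#' the black-to-white 10-90% transition spans about 680 um
#' (`2.5631 * shading_blur_um`), and cells of 15-20 um diameter whose
#' scan-image contrast scales with the local shading gradient.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size (default 10 um/px).
#' @param pattern a [pattern_spec()]; sheet extent is overridden to match the
#'   image.
#' @param shading_blur_um Gaussian blur applied to the rasterized sheet, in
#'   micrometres; the default 265.3 um makes the 10-90% transition width of a
#'   blurred step equal to 680 um.
#' @param black_level,white_level shading levels in `[0, 1]`, black < white.
#' @param n_cells number of cells to place.
#' @param cell_diameter_um length-2 range cells are drawn from (default
#'   15-20 um).
#' @param cell_amplitude peak scale of the zero-mean dipole perturbation a
#'   cell stamps into the scan image.
#' @param visibility_coupling in `[0, 1]`: 1 means cell contrast is fully
#'   proportional to the normalized local shading gradient (invisible in flat
#'   zones), 0 means uniform visibility.
#' @param n_debris number of debris particles (stamped in scan and phase but
#'   not in nuclei, so they act as image-origin false positives).
#' @param noise_sd additive Gaussian pixel noise on the scan image.
#' @param placement `"uniform"`, `"edge"` (cells crowd toward the border) or
#'   `"gradient_x"` (linear density ramp along columns).
#' @param dark_zone_quantile shading fraction of the black-white span below
#'   which a pixel belongs to the dark-zone (blind-spot) mask.
#' @param seed integer seed; identical parameters give bit-identical scenes.
#' @return A `scene_params` object (list).
#' @export
scene_params <- function(width_px = 1000, height_px = 1000,
                         pixel_size_um = 10,
                         pattern = pattern_spec(450, 900, "hex"),
                         shading_blur_um = 680 / (2 * qnorm(0.9)),
                         black_level = 0.15, white_level = 0.85,
                         n_cells = 200,
                         cell_diameter_um = c(15, 20),
                         cell_amplitude = 0.2,
                         visibility_coupling = 0.8,
                         n_debris = 0,
                         noise_sd = 0.002,
                         placement = c("uniform", "edge", "gradient_x"),
                         dark_zone_quantile = 0.2,
                         seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(width_px >= 1, height_px >= 1, pixel_size_um > 0,
            inherits(pattern, "pattern_spec"),
            shading_blur_um > 0,
            black_level >= 0, white_level <= 1, black_level < white_level,
            n_cells >= 0, length(cell_diameter_um) == 2,
            all(cell_diameter_um > 0),
            cell_amplitude > 0,
            visibility_coupling >= 0, visibility_coupling <= 1,
            n_debris >= 0, noise_sd >= 0,
            dark_zone_quantile > 0, dark_zone_quantile < 1)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 pattern = pattern,
                 shading_blur_um = shading_blur_um,
                 black_level = black_level, white_level = white_level,
                 n_cells = as.integer(n_cells),
                 cell_diameter_um = sort(as.numeric(cell_diameter_um)),
                 cell_amplitude = cell_amplitude,
                 visibility_coupling = visibility_coupling,
                 n_debris = as.integer(n_debris),
                 noise_sd = noise_sd,
                 placement = placement,
                 dark_zone_quantile = dark_zone_quantile,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# evaluate code under a private, restorable RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render the pattern-sheet shading field
#'
#' Rasterizes the hole pattern over the image extent, maps open/closed to
#' `white_level`/`black_level`, and low-passes with a Gaussian whose sigma is
#' `shading_blur_um` so each hole boundary becomes a smooth black-white
#' transition band. At the default blur the 10-90% transition width is about
#' 680 um, the empirically measured width of the cell-visualization band.
#'
#' @param pattern a [pattern_spec()]; sheet extent is overridden to the image.
#' @param params a [scene_params()].
#' @return A `scan_image` with values in `[black_level, white_level]`.
#' @export
render_shading <- function(pattern = params$pattern, params) {
  stopifnot(inherits(params, "scene_params"), inherits(pattern, "pattern_spec"))
  if (is.finite(pattern$hole_diameter_um) &&
      pattern$pitch_um < 2 * params$shading_blur_um) {
    stop(sprintf(paste0("pattern pitch (%g um) smaller than twice the shading",
                        " blur (%g um): transition bands would merge"),
                 pattern$pitch_um, 2 * params$shading_blur_um), call. = FALSE)
  }
  spec <- pattern
  spec$sheet_width_um <- params$width_px * params$pixel_size_um
  spec$sheet_height_um <- params$height_px * params$pixel_size_um
  open <- if (!is.finite(spec$hole_diameter_um)) {
    matrix(TRUE, params$height_px, params$width_px)
  } else if (nrow(hole_centers(spec)) == 0) {
    matrix(FALSE, params$height_px, params$width_px)
  } else {
    rasterize_pattern(spec, params$pixel_size_um)
  }
  lv <- params$black_level +
    (params$white_level - params$black_level) * (open * 1)
  if (all(open) || !any(open)) {
    return(scan_image(lv, params$pixel_size_um))
  }
  sigma_px <- params$shading_blur_um / params$pixel_size_um
  scan_image(gaussian_blur(lv, sigma_px), params$pixel_size_um)
}

# rejection-sampling placement: no two accepted points closer than one cell
# diameter; at most 100 candidate draws per requested point overall
place_points <- function(n, height, width, diam_px, placement, margin = 5) {
  if (n == 0) {
    return(list(rows = numeric(0), cols = numeric(0)))
  }
  if (height - 2 * margin <= 1 || width - 2 * margin <= 1) {
    stop("image too small to place cells with the required margin", call. = FALSE)
  }
  rows <- numeric(n)
  cols <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 100L * n
  half <- pmin(height, width) / 2
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    r <- runif(1, margin, height - margin)
    c <- runif(1, margin, width - margin)
    w <- switch(placement,
      uniform = 1,
      edge = exp(-4 * min(r, height - r, c, width - c) / half),
      gradient_x = 0.1 + 0.9 * c / width
    )
    if (w < 1 && runif(1) > w) next
    if (placed > 0L) {
      sep <- pmax(diam_px[placed + 1L], diam_px[seq_len(placed)])
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (any(d2 < sep^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- r
    cols[placed] <- c
  }
  if (placed < n) {
    stop(sprintf(paste0("could only place %d of %d cells without overlap ",
                        "after %d retries; reduce n_cells"),
                 placed, n, max_tries), call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

# normalized shading-gradient magnitude (central differences) and unit
# gradient direction; exactly zero in regions the truncated blur leaves flat
shading_gradient <- function(shading) {
  s <- as_pixels(shading)
  nr <- nrow(s)
  nc <- ncol(s)
  up <- s[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  dn <- s[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  lf <- s[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  rt <- s[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  gr <- (dn - up) / 2
  gc <- (rt - lf) / 2
  mag <- sqrt(gr^2 + gc^2)
  mx <- max(mag)
  list(mag = mag,
       norm = if (mx > 0) mag / mx else mag,
       gr = gr, gc = gc)
}

# additive stamp helpers ------------------------------------------------

stamp_add <- function(img, row, col, fun, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  # 0-based centroid -> 1-based pixel indices of the stamp window
  rr <- max(1L, floor(row + 1 - radius)):min(nr, ceiling(row + 1 + radius))
  cc <- max(1L, floor(col + 1 - radius)):min(nc, ceiling(col + 1 + radius))
  dr <- rr - 1 - row
  dc <- cc - 1 - col
  img[rr, cc] <- img[rr, cc] + fun(outer(dr, rep(1, length(dc))),
                                   outer(rep(1, length(dr)), dc))
  img
}

# zero-mean radial dipole: bright crescent + dark crescent along (gr, gc)
cell_dipole <- function(amp, s, gr, gc) {
  n <- sqrt(gr^2 + gc^2)
  if (n < .Machine$double.eps) {
    gr <- 0
    gc <- 1
  } else {
    gr <- gr / n
    gc <- gc / n
  }
  function(dr, dc) {
    u <- dr * gr + dc * gc
    amp * (u / s) * exp(-(dr^2 + dc^2) / (2 * s^2))
  }
}

#' Render a full synthetic scene
#'
#' Generates a scan image (shading plus cell dipole perturbations, debris and
#' noise), a phase-contrast-like image (bright cell bodies with halos on a
#' dark background), a nuclear-stain-like image (one Gaussian spot per cell)
#' and the complete ground truth. Each cell's dipole amplitude is
#' `cell_amplitude * (visibility_coupling * g + (1 - visibility_coupling))`
#' where `g` is the normalized shading-gradient magnitude at its centroid, so
#' with full coupling cells are invisible where the shading is flat — the
#' mechanism that makes pattern-sheet transitions necessary for detection.
#'
#' @param params a [scene_params()].
#' @return A `synthetic_scene`: list with elements `scan`, `phase`, `nuclei`
#'   (all `scan_image`), `truth` (see Details) and `params`. `truth` holds
#'   0-based `cells` and `debris` tibbles, the `dark_zone_mask`, the
#'   normalized `gradient_map`, per-cell stamped `amplitudes`, and
#'   `stamp_map`, the absolute cell-perturbation field.
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  shading <- render_shading(params$pattern, params)
  grad <- shading_gradient(shading)
  span <- params$white_level - params$black_level
  dark_zone <- as_pixels(shading) <=
    params$black_level + params$dark_zone_quantile * span
  with_seed(params$seed, {
    scene_from_shading(params, shading, grad, dark_zone)
  })
}

# body of render_scene, run under the scene RNG; split out so growth_series
# can reuse it with pre-drawn cell positions
scene_from_shading <- function(params, shading, grad, dark_zone,
                               cells = NULL) {
  px <- params$pixel_size_um
  nr <- params$height_px
  nc <- params$width_px
  if (is.null(cells)) {
    diam_um <- runif(params$n_cells, params$cell_diameter_um[1],
                     params$cell_diameter_um[2])
    pos <- place_points(params$n_cells, nr, nc, diam_um / px,
                        params$placement)
    cells <- tibble::tibble(row_px = pos$rows, col_px = pos$cols,
                            diameter_um = diam_um)
  }
  n_cells <- nrow(cells)

  perturb <- matrix(0, nr, nc)
  amplitudes <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    r <- cells$row_px[i]
    c <- cells$col_px[i]
    ri <- as.integer(round(r)) + 1L
    ci <- as.integer(round(c)) + 1L
    g <- grad$norm[ri, ci]
    amp <- params$cell_amplitude *
      (params$visibility_coupling * g + 1 - params$visibility_coupling)
    amplitudes[i] <- amp
    s <- (cells$diameter_um[i] / px + 2) / 4
    perturb <- stamp_add(perturb, r, c,
                         cell_dipole(amp, s, grad$gr[ri, ci], grad$gc[ri, ci]),
                         radius = ceiling(3 * s) + 1)
  }

  # debris: dark monopole specks in scan (and bright in phase), never nuclei
  debris <- tibble::tibble(row_px = numeric(0), col_px = numeric(0),
                           diameter_um = numeric(0))
  debris_perturb <- matrix(0, nr, nc)
  if (params$n_debris > 0) {
    d_diam <- runif(params$n_debris, 10, 25)
    d_pos <- place_points(params$n_debris, nr, nc, d_diam / px, "uniform")
    debris <- tibble::tibble(row_px = d_pos$rows, col_px = d_pos$cols,
                             diameter_um = d_diam)
    for (i in seq_len(params$n_debris)) {
      s <- (d_diam[i] / px + 2) / 4
      debris_perturb <- stamp_add(
        debris_perturb, d_pos$rows[i], d_pos$cols[i],
        function(dr, dc) {
          -params$cell_amplitude * exp(-(dr^2 + dc^2) / (2 * s^2))
        },
        radius = ceiling(3 * s) + 1
      )
    }
  }

  scan <- as_pixels(shading) + perturb + debris_perturb
  if (params$noise_sd > 0) {
    scan <- scan + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
  }
  scan <- clamp01(scan)

  phase <- matrix(0.05, nr, nc)
  for (i in seq_len(n_cells)) {
    s <- (cells$diameter_um[i] / px + 2) / 4
    phase <- stamp_add(
      phase, cells$row_px[i], cells$col_px[i],
      function(dr, dc) {
        r2 <- dr^2 + dc^2
        0.6 * exp(-(r2 / (2 * s^2))^2) +
          0.3 * exp(-((sqrt(r2) - 1.6 * s) / (0.6 * s))^2)
      },
      radius = ceiling(3 * s) + 2
    )
  }
  if (nrow(debris) > 0) {
    for (i in seq_len(nrow(debris))) {
      s <- (debris$diameter_um[i] / px + 2) / 4
      phase <- stamp_add(
        phase, debris$row_px[i], debris$col_px[i],
        function(dr, dc) 0.5 * exp(-(dr^2 + dc^2) / (2 * s^2)),
        radius = ceiling(3 * s) + 1
      )
    }
  }
  phase <- clamp01(phase)

  nuclei <- matrix(0, nr, nc)
  for (i in seq_len(n_cells)) {
    s <- cells$diameter_um[i] / px / 4
    nuclei <- stamp_add(
      nuclei, cells$row_px[i], cells$col_px[i],
      function(dr, dc) 0.8 * exp(-(dr^2 + dc^2) / (2 * s^2)),
      radius = ceiling(3 * s) + 1
    )
  }
  nuclei <- clamp01(nuclei)

  structure(list(
    scan = scan_image(scan, px),
    phase = scan_image(phase, px),
    nuclei = scan_image(nuclei, px),
    truth = list(cells = cells,
                 debris = debris,
                 dark_zone_mask = dark_zone,
                 gradient_map = grad$norm,
                 amplitudes = amplitudes,
                 stamp_map = abs(perturb)),
    params = params
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d cells, %d debris, seed %d\n",
              nrow(x$scan), ncol(x$scan), nrow(x$truth$cells),
              nrow(x$truth$debris), x$params$seed))
  invisible(x)
}

#' Growth-curve specification
#'
#' Exponential growth with a doubling time, optionally capped by a logistic
#' carrying capacity. `n0` cells at time 0 grow as
#' `n0 * 2^(t / doubling_time_h)` (exponential) or along the logistic curve
#' with rate `log(2) / doubling_time_h` when `capacity` is finite.
#'
#' @param n0 initial cell count (>= 1).
#' @param doubling_time_h doubling time in hours (> 0).
#' @param capacity optional logistic carrying capacity (default `Inf`).
#' @return A function of time in hours returning the (real-valued) count,
#'   with class `growth_spec`.
#' @export
growth_spec <- function(n0, doubling_time_h, capacity = Inf) {
  stopifnot(n0 >= 1, is.numeric(doubling_time_h), length(doubling_time_h) == 1)
  if (doubling_time_h <= 0) {
    stop("`doubling_time_h` must be positive", call. = FALSE)
  }
  stopifnot(capacity >= n0)
  rate <- log(2) / doubling_time_h
  f <- if (is.finite(capacity)) {
    function(t_h) capacity / (1 + (capacity / n0 - 1) * exp(-rate * t_h))
  } else {
    function(t_h) n0 * 2^(t_h / doubling_time_h)
  }
  structure(f, class = c("growth_spec", "function"),
            n0 = n0, doubling_time_h = doubling_time_h, capacity = capacity)
}

#' Time-lapse growth series of synthetic scenes
#'
#' Renders `n_frames` scenes at `interval_min` spacing; frame `t` has
#' `round(curve(t))` cells. Cell positions persist: earlier frames' cells are
#' a prefix of later frames', so a fixed image region sees a coherent time
#' series (new cells appear, none move or vanish). With 265 frames every 30
#' minutes the series spans 132 hours.
#'
#' @param params a [scene_params()]; `params$n_cells` is ignored in favour of
#'   the growth curve.
#' @param n_frames number of frames (>= 1).
#' @param interval_min frame spacing in minutes.
#' @param growth a [growth_spec()].
#' @param render if `FALSE`, frames carry ground truth only (no images);
#'   useful for long series where only counts and positions matter.
#' @return A `growth_series`: list of `synthetic_scene` frames with
#'   attributes `times_h` and `counts`.
#' @export
growth_series <- function(params, n_frames, interval_min, growth,
                          render = TRUE) {
  stopifnot(inherits(params, "scene_params"), n_frames >= 1,
            interval_min > 0, inherits(growth, "growth_spec"))
  times_h <- (seq_len(n_frames) - 1) * interval_min / 60
  counts <- as.integer(round(growth(times_h)))
  max_n <- max(counts)
  shading <- render_shading(params$pattern, params)
  grad <- shading_gradient(shading)
  span <- params$white_level - params$black_level
  dark_zone <- as_pixels(shading) <=
    params$black_level + params$dark_zone_quantile * span
  p_all <- params
  p_all$n_cells <- max_n
  frames <- with_seed(params$seed, {
    px <- params$pixel_size_um
    diam_um <- runif(max_n, params$cell_diameter_um[1],
                     params$cell_diameter_um[2])
    pos <- place_points(max_n, params$height_px, params$width_px,
                        diam_um / px, params$placement)
    cells_all <- tibble::tibble(row_px = pos$rows, col_px = pos$cols,
                                diameter_um = diam_um)
    lapply(seq_len(n_frames), function(f) {
      cells_f <- cells_all[seq_len(counts[f]), , drop = FALSE]
      if (render) {
        p_f <- params
        p_f$n_cells <- counts[f]
        scene_from_shading(p_f, shading, grad, dark_zone, cells = cells_f)
      } else {
        structure(list(scan = NULL, phase = NULL, nuclei = NULL,
                       truth = list(cells = cells_f,
                                    debris = tibble::tibble(
                                      row_px = numeric(0),
                                      col_px = numeric(0),
                                      diameter_um = numeric(0)),
                                    dark_zone_mask = dark_zone,
                                    gradient_map = grad$norm,
                                    amplitudes = numeric(0),
                                    stamp_map = NULL),
                       params = params),
                  class = "synthetic_scene")
      }
    })
  })
  structure(frames, class = "growth_series",
            times_h = times_h, counts = counts)
}

#' Write a synthetic scene to disk
#'
#' Writes `scan.tif`, `phase.tif`, `nuclei.tif` (16-bit grayscale),
#' `truth.csv` (columns `kind`, `row_px`, `col_px`, `diameter_um`; 0-based
#' pixel coordinates), `dark_zone.png` and `params.yaml`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gray(scene$scan, file.path(dir, "scan.tif"))
  write_gray(scene$phase, file.path(dir, "phase.tif"))
  write_gray(scene$nuclei, file.path(dir, "nuclei.tif"))
  truth <- dplyr::bind_rows(
    dplyr::mutate(scene$truth$cells, kind = "cell"),
    dplyr::mutate(scene$truth$debris, kind = "debris")
  )
  truth <- truth[, c("kind", "row_px", "col_px", "diameter_um")]
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  png::writePNG(scene$truth$dark_zone_mask * 1,
                file.path(dir, "dark_zone.png"))
  yaml::write_yaml(params_to_list(scene$params),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

params_to_list <- function(params) {
  p <- unclass(params)
  p$pattern <- unclass(p$pattern)
  p
}

params_from_list <- function(lst) {
  pat <- lst$pattern
  lst$pattern <- pattern_spec(pat$hole_diameter_um, pat$pitch_um, pat$lattice,
                              pat$sheet_width_um, pat$sheet_height_um)
  do.call(scene_params, lst)
}
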