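# shared scene fixtures, built once per test run and memoised
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, params) {
  if (!exists(key, .scene_cache)) {
    assign(key, render_scene(params), .scene_cache)
  }
  get(key, .scene_cache)
}

# the default 30-cell phase-evaluation scene
phase_scene <- function() {
  cached_scene("phase30",
               scene_params(width_px = 400, height_px = 400, n_cells = 30,
                            seed = 3))
}

# small general-purpose scene
small_scene <- function() {
  cached_scene("small20",
               scene_params(width_px = 300, height_px = 300, n_cells = 20,
                            seed = 9))
}

# stamp the generator's phase-image cell appearance at a 0-based centroid
stamp_phase_cell <- function(ph, row, col, diameter_um = 17,
                             pixel_size_um = 10) {
  s <- (diameter_um / pixel_size_um + 2) / 4
  rad <- ceiling(3 * s) + 2
  nr <- nrow(ph)
  nc <- ncol(ph)
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      rr <- row + 1 + dr
      cc <- col + 1 + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        r2 <- dr^2 + dc^2
        ph[rr, cc] <- ph[rr, cc] + 0.6 * exp(-(r2 / (2 * s^2))^2) +
          0.3 * exp(-((sqrt(r2) - 1.6 * s) / (0.6 * s))^2)
      }
    }
  }
  pmin(ph, 1)
}

# hand-built truth/detection fixture exercising all four error categories
# exactly once (see test-error-taxonomy.R for the layout)
four_error_fixture <- function() {
  truth <- tibble::tibble(
    row_px = c(50, 20, 80, 80),
    col_px = c(50, 20, 80, 83),
    diameter_um = c(30, 15, 15, 15)
  )
  det <- detection_set(
    row_px = c(50, 52, 80, 10),
    col_px = c(50, 50, 80, 90),
    area_px = c(20L, 8L, 12L, 6L)
  )
  dark <- matrix(FALSE, 100, 100)
  dark[15:25, 15:25] <- TRUE
  aux <- list(
    debris = tibble::tibble(row_px = 10, col_px = 90, diameter_um = 12),
    dark_zone_mask = dark
  )
  list(truth = truth, det = det, aux = aux)
}
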