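#' Snell refraction of a 2-D ray
#'
#' Refracts a unit direction vector at an interface with unit normal,
#' `n1 sin(theta1) = n2 sin(theta2)`. The normal may point to either side;
#' it is flipped internally to oppose the incoming ray. Total internal
#' reflection is reported via the `tir` flag instead of a direction.
#'
#' @param direction unit 2-vector (x, z) of the incoming ray.
#' @param normal unit 2-vector of the surface normal.
#' @param n1,n2 refractive indices on the incidence and transmission sides.
#' @return List with `direction` (unit 2-vector, or `NULL` under TIR) and
#'   logical `tir`.
#' @examples
#' r <- snell_refract(c(sin(pi / 6), cos(pi / 6)), c(0, -1), 1.0, 1.5)
#' asin(r$direction[1]) * 180 / pi  # 19.471 degrees
#' @export
snell_refract <- function(direction, normal, n1, n2) {
  stopifnot(length(direction) == 2, length(normal) == 2, n1 > 0, n2 > 0)
  if (sum(direction^2) < .Machine$double.eps ||
      sum(normal^2) < .Machine$double.eps) {
    stop("zero-length vector", call. = FALSE)
  }
  d <- direction / sqrt(sum(direction^2))
  n <- normal / sqrt(sum(normal^2))
  if (sum(d * n) > 0) n <- -n
  cosi <- -sum(d * n)
  eta <- n1 / n2
  sin2t <- eta^2 * (1 - cosi^2)
  if (sin2t > 1) {
    return(list(direction = NULL, tir = TRUE))
  }
  cost <- sqrt(1 - sin2t)
  t <- eta * d + (eta * cosi - cost) * n
  list(direction = t / sqrt(sum(t^2)), tir = FALSE)
}

# vectorised Snell over ray matrices: dx,dz direction components; nx,nz
# normals; returns list(dx, dz, tir)
snell_vec <- function(dx, dz, nx, nz, n1, n2) {
  dot <- dx * nx + dz * nz
  flip <- dot > 0
  nx[flip] <- -nx[flip]
  nz[flip] <- -nz[flip]
  cosi <- -(dx * nx + dz * nz)
  eta <- n1 / n2
  sin2t <- eta^2 * (1 - cosi^2)
  tir <- sin2t > 1
  cost <- sqrt(pmax(1 - sin2t, 0))
  tx <- eta * dx + (eta * cosi - cost) * nx
  tz <- eta * dz + (eta * cosi - cost) * nz
  nrm <- sqrt(tx^2 + tz^2)
  list(dx = tx / nrm, dz = tz / nrm, tir = tir)
}

#' Ray-tracer configuration
#'
#' A simplified 2-D (one lateral axis plus the optical axis) Monte-Carlo
#' model of the scanner: a diffuse source modeled as a row of point emitters
#' with uniform angular emission within a half-angle, an aperture sheet (the
#' pattern-sheet cross-section), refracting and diffusely scattering model
#' cells (refractive index 1.360, diffusion ratio 0.3) in culture-medium-like
#' surroundings (index 1.335, a configurable default the hardware study does
#' not print), and an ideal straight-line sensor mapping. The sheet can be
#' present (`"pattern"`), absent (`"none"`), or replaced by an 80% diffuser
#' (`"diffuser"`) that randomises ray direction with the given probability.
#'
#' @param n_rays number of Monte-Carlo rays (> 0).
#' @param seed integer seed; traces are deterministic per seed.
#' @param source_extent_um lateral extent of the emitter row.
#' @param n_source_points number of discrete point emitters.
#' @param source_half_angle_deg emission half-angle.
#' @param sheet one of `"pattern"`, `"none"`, `"diffuser"`, `"opaque"` (a
#'   sheet with no apertures at all; absorbs every ray).
#' @param pattern a [pattern_spec()] giving the aperture cross-section
#'   (holes of `hole_diameter_um` every `pitch_um`, centred on the axis).
#' @param diffuser_prob probability that the diffuser randomises a ray.
#' @param cells data frame with `center_um` and `radius_um` of model cells.
#' @param cell_ri,medium_ri refractive indices.
#' @param diffusion_ratio per-interaction probability that a cell scatters a
#'   ray into a uniform random direction instead of refracting it.
#' @param source_z,sheet_z,cells_z,sensor_z plane positions (strictly
#'   increasing).
#' @param sensor_extent_um lateral extent of the sensor.
#' @param n_bins number of sensor bins.
#' @return A `ray_sim_config` (list).
#' @export
ray_sim_config <- function(n_rays = 1e6, seed = 1L,
                           source_extent_um = 20000, n_source_points = 201,
                           source_half_angle_deg = 60,
                           sheet = c("pattern", "none", "diffuser", "opaque"),
                           pattern = pattern_spec(450, 1000),
                           diffuser_prob = 0.8,
                           cells = data.frame(
                             center_um = seq(-4000, 4000, by = 1000),
                             radius_um = 10),
                           cell_ri = 1.360, medium_ri = 1.335,
                           diffusion_ratio = 0.3,
                           source_z = 0, sheet_z = 1200, cells_z = 2000,
                           sensor_z = 2050,
                           sensor_extent_um = 10000, n_bins = 1000) {
  sheet <- match.arg(sheet)
  if (n_rays < 1) stop("`n_rays` must be positive", call. = FALSE)
  stopifnot(source_z < sheet_z, sheet_z < cells_z, cells_z < sensor_z,
            diffusion_ratio >= 0, diffusion_ratio <= 1,
            diffuser_prob >= 0, diffuser_prob <= 1,
            cell_ri > 0, medium_ri > 0,
            source_half_angle_deg > 0, source_half_angle_deg < 90,
            n_source_points >= 1, n_bins >= 1,
            is.data.frame(cells),
            all(c("center_um", "radius_um") %in% names(cells)))
  structure(list(n_rays = as.integer(n_rays), seed = as.integer(seed),
                 source_extent_um = source_extent_um,
                 n_source_points = as.integer(n_source_points),
                 source_half_angle_deg = source_half_angle_deg,
                 sheet = sheet, pattern = pattern,
                 diffuser_prob = diffuser_prob,
                 cells = cells, cell_ri = cell_ri, medium_ri = medium_ri,
                 diffusion_ratio = diffusion_ratio,
                 source_z = source_z, sheet_z = sheet_z, cells_z = cells_z,
                 sensor_z = sensor_z,
                 sensor_extent_um = sensor_extent_um,
                 n_bins = as.integer(n_bins)),
            class = "ray_sim_config")
}

# 1-D aperture intervals (cross-section of the hole pattern), centred on 0
aperture_intervals <- function(pattern, extent_um) {
  d <- pattern$hole_diameter_um
  p <- pattern$pitch_um
  if (!is.finite(d)) {
    return(cbind(lo = -extent_um, hi = extent_um))
  }
  kmax <- ceiling(extent_um / p) + 1
  centers <- (-kmax:kmax) * p
  cbind(lo = centers - d / 2, hi = centers + d / 2)
}

#' Trace rays through the scanner model
#'
#' Each ray is emitted from a random source point at a uniform random angle
#' within the half-angle, absorbed if it hits the opaque part of the sheet
#' (or randomised by the diffuser), and on hitting a model cell is either
#' scattered into a uniform random direction (probability `diffusion_ratio`)
#' or refracted by Snell's law at entry and exit; it is then propagated in a
#' straight line to the sensor plane and binned. Rays scattered backwards or
#' suffering total internal reflection at the cell exit are lost. Ray
#' accounting is exact:
#' `binned + out_of_sensor + absorbed_sheet + lost_scatter + lost_tir ==
#' n_rays`.
#'
#' @param config a [ray_sim_config()].
#' @return A `sensor_profile`: tibble with `bin_center_um` and `illuminance`
#'   (ray counts, arbitrary units), with the config and the ray accounting
#'   in attributes.
#' @export
trace_rays <- function(config) {
  stopifnot(inherits(config, "ray_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_rays
    src_x <- if (cfg$n_source_points == 1) {
      rep(0, n)
    } else {
      pts <- seq(-cfg$source_extent_um / 2, cfg$source_extent_um / 2,
                 length.out = cfg$n_source_points)
      pts[sample.int(cfg$n_source_points, n, replace = TRUE)]
    }
    ha <- cfg$source_half_angle_deg * pi / 180
    th <- runif(n, -ha, ha)
    dx <- sin(th)
    dz <- cos(th)
    x <- src_x
    z <- rep(cfg$source_z, n)
    absorbed <- 0L
    lost_scatter <- 0L
    lost_tir <- 0L

    # sheet plane
    slope <- dx / dz
    x <- x + slope * (cfg$sheet_z - z)
    z <- rep(cfg$sheet_z, n)
    if (cfg$sheet == "opaque") {
      absorbed <- length(x)
      x <- numeric(0); dx <- numeric(0); dz <- numeric(0); z <- numeric(0)
    } else if (cfg$sheet == "pattern") {
      iv <- aperture_intervals(cfg$pattern,
                               cfg$sensor_extent_um + cfg$source_extent_um)
      open <- rep(FALSE, n)
      for (k in seq_len(nrow(iv))) {
        open <- open | (x >= iv[k, "lo"] & x <= iv[k, "hi"])
      }
      absorbed <- sum(!open)
      x <- x[open]; dx <- dx[open]; dz <- dz[open]; z <- z[open]
    } else if (cfg$sheet == "diffuser") {
      diff_sel <- runif(n) < cfg$diffuser_prob
      th2 <- runif(sum(diff_sel), -pi / 2, pi / 2)
      dx[diff_sel] <- sin(th2)
      dz[diff_sel] <- cos(th2)
    }

    # model cells (single nearest interaction; cells are disjoint circles)
    nc <- nrow(cfg$cells)
    if (length(x) && nc > 0) {
      t_hit <- rep(Inf, length(x))
      hit_cell <- rep(0L, length(x))
      for (i in seq_len(nc)) {
        cx <- cfg$cells$center_um[i]
        cz <- cfg$cells_z
        rho <- cfg$cells$radius_um[i]
        # |(x,z) + t (dx,dz) - (cx,cz)|^2 = rho^2, unit direction
        ox <- x - cx
        oz <- z - cz
        b <- ox * dx + oz * dz
        disc <- b^2 - (ox^2 + oz^2 - rho^2)
        ok <- disc >= 0
        t1 <- -b - sqrt(pmax(disc, 0))
        sel <- ok & t1 > 0 & t1 < t_hit
        t_hit[sel] <- t1[sel]
        hit_cell[sel] <- i
      }
      hits <- which(hit_cell > 0L)
      if (length(hits)) {
        hx <- x[hits] + t_hit[hits] * dx[hits]
        hz <- z[hits] + t_hit[hits] * dz[hits]
        scat <- runif(length(hits)) < cfg$diffusion_ratio
        # scattered: uniform direction over the full circle, from entry point
        if (any(scat)) {
          phi <- runif(sum(scat), 0, 2 * pi)
          si <- hits[scat]
          x[si] <- hx[scat]
          z[si] <- hz[scat]
          dx[si] <- sin(phi)
          dz[si] <- cos(phi)
        }
        # refracted: Snell at entry, chord, Snell at exit
        ri <- hits[!scat]
        if (length(ri)) {
          cxs <- cfg$cells$center_um[hit_cell[ri]]
          rhos <- cfg$cells$radius_um[hit_cell[ri]]
          ex <- hx[!scat]
          ez <- hz[!scat]
          n1x <- (ex - cxs) / rhos
          n1z <- (ez - cfg$cells_z) / rhos
          r1 <- snell_vec(dx[ri], dz[ri], n1x, n1z,
                          cfg$medium_ri, cfg$cell_ri)
          vx <- ex - cxs
          vz <- ez - cfg$cells_z
          t2 <- -2 * (vx * r1$dx + vz * r1$dz)
          qx <- ex + t2 * r1$dx
          qz <- ez + t2 * r1$dz
          n2x <- (qx - cxs) / rhos
          n2z <- (qz - cfg$cells_z) / rhos
          r2 <- snell_vec(r1$dx, r1$dz, n2x, n2z,
                          cfg$cell_ri, cfg$medium_ri)
          lost_tir <- sum(r2$tir)
          x[ri] <- qx
          z[ri] <- qz
          dx[ri] <- r2$dx
          dz[ri] <- r2$dz
          if (any(r2$tir)) {
            drop <- ri[r2$tir]
            keep <- setdiff(seq_along(x), drop)
            x <- x[keep]; z <- z[keep]; dx <- dx[keep]; dz <- dz[keep]
          }
        }
      }
    }

    # backward-going rays never reach the sensor
    fwd <- dz > 0
    lost_scatter <- sum(!fwd)
    x <- x[fwd]; z <- z[fwd]; dx <- dx[fwd]; dz <- dz[fwd]

    xs <- x + (dx / dz) * (cfg$sensor_z - z)
    half <- cfg$sensor_extent_um / 2
    inside <- xs >= -half & xs <= half
    out_of_sensor <- sum(!inside)
    xs <- xs[inside]
    edges <- seq(-half, half, length.out = cfg$n_bins + 1)
    counts <- tabulate(findInterval(xs, edges, rightmost.closed = TRUE),
                       nbins = cfg$n_bins)
    prof <- tibble::tibble(
      bin_center_um = (edges[-1] + edges[-length(edges)]) / 2,
      illuminance = as.numeric(counts)
    )
    class(prof) <- c("sensor_profile", class(prof))
    attr(prof, "config") <- cfg
    attr(prof, "accounting") <- list(
      binned = sum(counts), out_of_sensor = out_of_sensor,
      absorbed_sheet = absorbed, lost_scatter = lost_scatter,
      lost_tir = lost_tir, n_rays = cfg$n_rays
    )
    prof
  })
}

#' Cell contrast of a sensor profile
#'
#' For each model cell, the bins under its geometric shadow are compared
#' with flanking background bins (between one and `flank_um` past the cell
#' radius, excluding any other cell's shadow). The pooled, sign-free
#' normalized difference `|mean(cell) - mean(background)| /
#' mean(background)` quantifies how visible the cells are: with the pattern
#' sheet the restricted illumination makes refraction and scattering carve
#' visible deficits, without it (or behind a strong diffuser) the angular
#' diversity of the light smears them out.
#'
#' @param profile a `sensor_profile` from [trace_rays()].
#' @param cells data frame with `center_um`, `radius_um`; defaults to the
#'   cells in the profile's config.
#' @param flank_um width of the flanking background annulus (default 100).
#' @return Nonnegative scalar contrast.
#' @export
cell_contrast <- function(profile, cells = NULL, flank_um = 100) {
  stopifnot(inherits(profile, "sensor_profile"))
  cfg <- attr(profile, "config")
  if (is.null(cells)) cells <- cfg$cells
  xb <- profile$bin_center_um
  in_cell <- rep(FALSE, length(xb))
  for (i in seq_len(nrow(cells))) {
    in_cell <- in_cell |
      abs(xb - cells$center_um[i]) <= cells$radius_um[i]
  }
  in_flank <- rep(FALSE, length(xb))
  for (i in seq_len(nrow(cells))) {
    d <- abs(xb - cells$center_um[i])
    in_flank <- in_flank |
      (d > cells$radius_um[i] & d <= cells$radius_um[i] + flank_um)
  }
  in_flank <- in_flank & !in_cell
  if (!any(in_flank) || !any(in_cell)) {
    stop("empty cell or background bin set; enlarge sensor bins or flank",
         call. = FALSE)
  }
  mb <- mean(profile$illuminance[in_flank])
  if (mb <= 0) stop("background illuminance is zero", call. = FALSE)
  mc <- mean(profile$illuminance[in_cell])
  abs(mc - mb) / mb
}
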