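test_that("degenerate patterns render constant shading", {
  p0 <- scene_params(width_px = 80, height_px = 80,
                     pattern = pattern_spec(450, 1e9, "square"))
  expect_true(all(render_shading(params = p0) == p0$black_level))
  p1 <- scene_params(width_px = 80, height_px = 80,
                     pattern = pattern_spec(Inf, 1000))
  expect_true(all(render_shading(params = p1) == p1$white_level))
})

test_that("pitch below twice the blur is rejected", {
  p <- scene_params(width_px = 80, height_px = 80,
                    pattern = pattern_spec(200, 400))
  expect_error(render_shading(params = p), "pitch")
})

test_that("10-90% transition width across an isolated boundary is ~680 um", {
  spec <- pattern_spec(2000, 4000, "square", 4000, 4000)
  p <- scene_params(width_px = 400, height_px = 400, pattern = spec)
  sh <- render_shading(spec, p)
  prof <- sh[200, ]  # through the single hole's centre
  lo <- p$black_level
  span <- p$white_level - p$black_level
  right <- prof[200:400]
  i10 <- which(right <= lo + 0.9 * span)[1]
  i90 <- which(right <= lo + 0.1 * span)[1]
  width_um <- (i90 - i10) * 10
  expect_gt(width_um, 680 * 0.8)
  expect_lt(width_um, 680 * 1.2)
})

test_that("scenes are bit-identical under a fixed seed", {
  p <- scene_params(width_px = 150, height_px = 150, n_cells = 15,
                    n_debris = 3, seed = 42)
  a <- render_scene(p)
  b <- render_scene(p)
  expect_identical(a$scan, b$scan)
  expect_identical(a$phase, b$phase)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("an empty noiseless scene reproduces the shading exactly", {
  p <- scene_params(width_px = 120, height_px = 120, n_cells = 0,
                    n_debris = 0, noise_sd = 0)
  sc <- render_scene(p)
  expect_equal(unclass(sc$scan), unclass(render_shading(params = p)),
               ignore_attr = TRUE)
})

test_that("scene layers share dimensions and truth stays in bounds", {
  sc <- small_scene()
  expect_identical(dim(sc$scan), dim(sc$phase))
  expect_identical(dim(sc$scan), dim(sc$nuclei))
  cells <- sc$truth$cells
  expect_equal(nrow(cells), length(sc$truth$amplitudes))
  expect_true(all(cells$row_px >= 0 & cells$row_px < nrow(sc$scan)))
  expect_true(all(cells$col_px >= 0 & cells$col_px < ncol(sc$scan)))
  expect_true(all(cells$diameter_um >= 15 & cells$diameter_um <= 20))
})

test_that("nuclei blobs recoverable by thresholding equal the cell count", {
  # conservation holds for placements whose nuclei spots cannot touch:
  # pick a sparse scene and assert that premise first
  sc <- cached_scene("sparse12",
                     scene_params(width_px = 400, height_px = 400,
                                  n_cells = 12, seed = 14))
  cells <- sc$truth$cells
  d <- as.matrix(stats::dist(cbind(cells$row_px, cells$col_px)))
  diag(d) <- Inf
  expect_gt(min(d), 6)  # spots have radius ~2 px
  # threshold below the worst-case sampled peak of a corner-centred spot
  lab <- sheetscan:::label8((unclass(sc$nuclei) > 0.1) * 1)
  expect_equal(max(lab), nrow(cells))
})

test_that("uniform placement matches the generator's sampling distribution", {
  # per-field counts from a few seeds are compared against a large
  # reference sample drawn from the same placement process (two-sample
  # chi-square of homogeneity over the 5x5 grid)
  n_side <- 5
  w <- 600
  field_of <- function(pts) {
    pmin(pmax(floor(pts$rows / (w / n_side)), 0), n_side - 1) * n_side +
      pmin(pmax(floor(pts$cols / (w / n_side)), 0), n_side - 1)
  }
  draw <- function(seed) {
    set.seed(seed)
    diam <- runif(200, 1.5, 2)
    sheetscan:::place_points(200, w, w, diam, "uniform")
  }
  obs <- rep(0, n_side^2)
  for (sd0 in 1:4) {
    obs <- obs + tabulate(field_of(draw(300 + sd0)) + 1, n_side^2)
  }
  ref <- rep(0, n_side^2)
  for (sd0 in 1:40) {
    ref <- ref + tabulate(field_of(draw(9000 + sd0)) + 1, n_side^2)
  }
  pval <- suppressWarnings(stats::chisq.test(rbind(obs, ref))$p.value)
  expect_gt(pval, 0.01)
})

test_that("overplacement fails with an informative error", {
  p <- scene_params(width_px = 60, height_px = 60, n_cells = 2000)
  expect_error(render_scene(p), "could only place")
})

test_that("fully gradient-coupled cells vanish in flat shading", {
  # no holes: shading is exactly constant, gradient exactly zero
  p <- scene_params(width_px = 150, height_px = 150, n_cells = 15,
                    visibility_coupling = 1, noise_sd = 0,
                    pattern = pattern_spec(450, 1e9, "square"), seed = 8)
  sc <- render_scene(p)
  expect_true(all(sc$truth$amplitudes == 0))
  expect_true(all(sc$truth$stamp_map == 0))
  # with a boundary present, transition-zone cells are stamped
  sc2 <- render_scene(scene_params(width_px = 300, height_px = 300,
                                   n_cells = 40, visibility_coupling = 1,
                                   seed = 8))
  expect_gt(mean(sc2$truth$stamp_map > 0), 0)
  expect_gt(max(sc2$truth$amplitudes), 0)
})

test_that("debris appears in scan and phase but never in nuclei", {
  p <- scene_params(width_px = 200, height_px = 200, n_cells = 0,
                    n_debris = 5, noise_sd = 0, seed = 17)
  sc <- render_scene(p)
  sh <- render_shading(params = p)
  expect_equal(nrow(sc$truth$debris), 5)
  expect_gt(sum(abs(unclass(sc$scan) - unclass(sh))), 0)
  expect_gt(max(sc$phase), 0.4)
  expect_true(all(sc$nuclei == 0))
})

test_that("growth series follows the curve and keeps cells persistent", {
  p <- scene_params(width_px = 200, height_px = 200, seed = 5)
  gs <- growth_series(p, 3, 60, growth_spec(10, 1))
  expect_equal(attr(gs, "counts"), c(10L, 20L, 40L))
  for (f in 2:3) {
    prev <- gs[[f - 1]]$truth$cells
    cur <- gs[[f]]$truth$cells
    expect_identical(prev, cur[seq_len(nrow(prev)), ])
  }
  # single frame is identical to render_scene
  p1 <- scene_params(width_px = 200, height_px = 200, n_cells = 10, seed = 5)
  g1 <- growth_series(p1, 1, 30, growth_spec(10, 1))
  expect_identical(g1[[1]]$scan, render_scene(p1)$scan)
})

test_that("a 265-frame half-hour series spans 132 hours", {
  gs <- growth_series(scene_params(width_px = 100, height_px = 100, seed = 6),
                      265, 30, growth_spec(5, 24), render = FALSE)
  expect_equal(length(gs), 265)
  expect_equal(max(attr(gs, "times_h")), 132)
})

test_that("negative doubling time is rejected", {
  expect_error(growth_spec(10, -2), "positive")
})

test_that("scene artifacts round-trip through disk", {
  sc <- render_scene(scene_params(width_px = 100, height_px = 100,
                                  n_cells = 8, n_debris = 2, seed = 30))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_setequal(list.files(dir),
                  c("scan.tif", "phase.tif", "nuclei.tif", "truth.csv",
                    "dark_zone.png", "params.yaml"))
  back <- read_gray(file.path(dir, "scan.tif"))
  expect_lt(max(abs(unclass(back) - unclass(sc$scan))), 1.1 / 65535)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(sum(truth$kind == "cell"), 8)
  expect_equal(sum(truth$kind == "debris"), 2)
})
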