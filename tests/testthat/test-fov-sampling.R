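square_grid <- function(side = 600, field = 100) {
  place_fields(matrix(TRUE, side, side), field, field)
}

test_that("a 5x5 grid of fields fits a square mask without overlap", {
  grid <- square_grid()
  expect_equal(nrow(grid), 25)
  expect_true(all(grid$row0 >= 0 & grid$row1 <= 600))
  # non-overlap: fields sorted by (row0, col0) never intersect
  for (i in 1:24) {
    for (j in (i + 1):25) {
      overlap <- grid$row0[i] < grid$row1[j] & grid$row0[j] < grid$row1[i] &
        grid$col0[i] < grid$col1[j] & grid$col0[j] < grid$col1[i]
      expect_false(overlap)
    }
  }
})

test_that("fields that cannot fit raise an error", {
  expect_error(place_fields(matrix(TRUE, 100, 100), 640, 480), "does not fit")
})

test_that("all 25 microscope fields fit inside a 10-cm dish", {
  # 10 cm dish at 40 um/px (2500 px across) with the same physical field
  # size as a 640x480 px microscope image at 10 um/px
  n <- 2500
  ctr <- (n + 1) / 2
  dish <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - ctr)^2 + (j - ctr)^2 <= (n / 2)^2)
  grid <- place_fields(dish, 160, 120, pixel_size_um = 40)
  expect_equal(nrow(grid), 25)
  for (i in 1:25) {
    corners_r <- c(grid$row0[i] + 1, grid$row1[i])
    corners_c <- c(grid$col0[i] + 1, grid$col1[i])
    expect_true(all(dish[corners_r, corners_c]))
  }
})

test_that("uniform analytic density gives zero discrepancy for every k", {
  grid <- square_grid()
  counts <- rep(12L, 25)  # exactly proportional to (equal) field areas
  dens <- 12 / attr(grid, "field_area_cm2")
  true_total <- dens * attr(grid, "vessel_area_cm2")
  for (k in c(1, 3, 25)) {
    res <- estimate_from_fields(counts, grid, k, true_total, seed = 2)
    expect_true(all(abs(res$discrepancy_pct) < 1e-9))
  }
})

test_that("k = 25 reduces to the exhaustive mean", {
  grid <- square_grid()
  set.seed(41)
  counts <- rpois(25, 20)
  res <- estimate_from_fields(counts, grid, 25, true_total = 500, seed = 1)
  expect_equal(nrow(res), 1)
  want <- mean(counts) / attr(grid, "field_area_cm2") *
    attr(grid, "vessel_area_cm2")
  expect_equal(res$estimated_total, want)
  expect_error(estimate_from_fields(counts, grid, 26, 500), "between")
})

test_that("sampled k = 3 subsets live inside the exhaustive enumeration", {
  grid <- square_grid()
  set.seed(43)
  counts <- rpois(25, 15) + seq_len(25)  # a gradient so values are distinct
  res <- estimate_from_fields(counts, grid, 3, true_total = 900,
                              n_combos = 5, seed = 7)
  all_means <- apply(utils::combn(25, 3), 2, function(ix) mean(counts[ix]))
  scale <- attr(grid, "vessel_area_cm2") / attr(grid, "field_area_cm2")
  all_disc <- 100 * (all_means * scale - 900) / 900
  for (d in res$discrepancy_pct) {
    expect_true(any(abs(all_disc - d) < 1e-9))
  }
})

test_that("the subset estimator is unbiased by full enumeration", {
  grid <- square_grid()
  set.seed(44)
  counts <- rpois(25, 30)
  scale <- attr(grid, "vessel_area_cm2") / attr(grid, "field_area_cm2")
  full_est <- mean(counts) * scale
  for (k in 1:3) {
    subset_means <- apply(utils::combn(25, k), 2,
                          function(ix) mean(counts[ix]))
    expect_equal(mean(subset_means) * scale, full_est, tolerance = 1e-12)
  }
})

test_that("subset-mean variance follows the finite-population correction", {
  grid <- square_grid()
  set.seed(45)
  counts <- rpois(25, 40)
  k <- 5
  res <- estimate_from_fields(counts, grid, k, true_total = 1000,
                              n_combos = 600, seed = 9)
  scale <- attr(grid, "vessel_area_cm2") / attr(grid, "field_area_cm2")
  emp_var <- stats::var(res$estimated_total / scale)
  pop_var <- oracle_pop_var(counts)
  want <- (pop_var / k) * (25 - k) / (25 - 1)
  expect_lt(abs(emp_var - want) / want, 0.2)
})

test_that("discrepancy spread narrows from k = 1 to k = 20 when cells cluster", {
  sc <- cached_scene(
    "edge300",
    scene_params(width_px = 600, height_px = 600, n_cells = 300,
                 placement = "edge", seed = 55)
  )
  grid <- place_fields(matrix(TRUE, 600, 600), 110, 110)
  counts <- count_per_field(sc$truth$cells, grid)
  r1 <- estimate_from_fields(counts, grid, 1, 300, seed = 3)
  r20 <- estimate_from_fields(counts, grid, 20, 300, n_combos = 5, seed = 3)
  spread <- function(r) max(r$discrepancy_pct) - min(r$discrepancy_pct)
  expect_gt(spread(r1), spread(r20))
})

test_that("low-count frames spread wider than high-count frames", {
  p <- scene_params(width_px = 600, height_px = 600, seed = 66)
  series <- growth_series(p, 2, 60 * 100, growth_spec(40, 30),
                          render = FALSE)
  grid <- place_fields(matrix(TRUE, 600, 600), 110, 110)
  res <- timeseries_discrepancy(series, grid, ks = 3, n_combos = 25,
                                seed = 4)
  s <- vapply(split(res$discrepancy_pct, res$frame), stats::sd, numeric(1))
  expect_gt(s[["1"]], s[["2"]])  # frame 1 has ~40 cells, frame 2 ~400
})

test_that("a single-frame series reduces to estimate_from_fields", {
  p <- scene_params(width_px = 600, height_px = 600, seed = 67)
  series <- growth_series(p, 1, 30, growth_spec(200, 24), render = FALSE)
  grid <- place_fields(matrix(TRUE, 600, 600), 110, 110)
  res <- timeseries_discrepancy(series, grid, ks = 3, n_combos = 5, seed = 8)
  counts <- count_per_field(series[[1]]$truth$cells, grid)
  direct <- estimate_from_fields(counts, grid, 3, 200, n_combos = 5,
                                 seed = 8 + 1)
  expect_equal(res$estimated_total, direct$estimated_total)
  gl <- glance(res)
  expect_true(all(c("max_pct", "min_pct", "mean_pct") %in% names(gl)))
})
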