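test_that("identical centroid lists match perfectly", {
  pts <- tibble::tibble(row_px = c(1, 10, 30), col_px = c(2, 12, 5))
  det <- detection_set(pts$row_px, pts$col_px, rep(4L, 3))
  m <- match_detections(det, pts, 5)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unmatched_truth, 0)
  expect_length(m$unmatched_det, 0)
  expect_true(all(m$pairs$dist_px == 0))
})

test_that("equidistant ties go to the lower truth index", {
  truth <- tibble::tibble(row_px = c(0, 0), col_px = c(0, 10))
  det <- detection_set(0, 5, 4L)
  m <- match_detections(det, truth, 5)
  expect_equal(m$pairs$truth_idx, 1L)
  expect_equal(m$unmatched_truth, 2L)
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  set.seed(77)
  n_diverge <- 0
  for (rep in 1:12) {
    truth <- tibble::tibble(row_px = runif(4, 0, 20),
                            col_px = runif(4, 0, 20))
    det <- detection_set(runif(4, 0, 20), runif(4, 0, 20), rep(4L, 4))
    m <- match_detections(det, truth, 8)
    o <- oracle_assignment(truth, det, 8)
    # greedy is maximal but not always maximum under a distance cap
    expect_lte(nrow(m$pairs), o$n)
    greedy_cost <- sum(m$pairs$dist_px)
    if (nrow(m$pairs) == o$n && abs(greedy_cost - o$cost) < 1e-9) {
      expect_setequal(pair_key(m$pairs$truth_idx, m$pairs$det_idx),
                      pair_key(o$pairs[, 1], o$pairs[, 2]))
    } else {
      n_diverge <- n_diverge + 1  # documented divergence from the optimum
      if (nrow(m$pairs) == o$n) expect_gte(greedy_cost, o$cost)
    }
  }
  expect_lt(n_diverge, 12)
})

test_that("perfect detection yields an all-zero error report", {
  truth <- tibble::tibble(row_px = c(5, 20, 40), col_px = c(5, 25, 10),
                          diameter_um = c(16, 17, 18))
  det <- detection_set(truth$row_px, truth$col_px, rep(5L, 3))
  aux <- list(debris = tibble::tibble(row_px = numeric(0),
                                      col_px = numeric(0)),
              dark_zone_mask = matrix(FALSE, 50, 50))
  rep_ <- classify_errors(match_detections(det, truth, 5), det, truth, aux)
  expect_equal(rep_$matched, 3)
  expect_equal(rep_$over_image_origin + rep_$over_large_cell +
                 rep_$under_blind_spot + rep_$under_resolution +
                 rep_$unclassified_over + rep_$unclassified_under, 0)
})

test_that("a debris-driven extra detection is an image-origin error at 1%", {
  set.seed(78)
  truth <- tibble::tibble(row_px = seq(5, 495, length.out = 100),
                          col_px = rep(seq(10, 490, length.out = 10), 10),
                          diameter_um = rep(16, 100))
  det <- detection_set(c(truth$row_px, 250.5), c(truth$col_px, 250.5),
                       rep(5L, 101))
  aux <- list(debris = tibble::tibble(row_px = 251, col_px = 251),
              dark_zone_mask = matrix(FALSE, 500, 500))
  rep_ <- classify_errors(match_detections(det, truth, 5), det, truth, aux)
  expect_equal(rep_$over_image_origin, 1)
  expect_equal(rep_$pct_image_origin, 1.0)
})

test_that("the constructed fixture hits every error category exactly once", {
  fx <- four_error_fixture()
  m <- match_detections(fx$det, fx$truth, 5)
  rep_ <- classify_errors(m, fx$det, fx$truth, fx$aux,
                          debris_radius_px = 5)
  expect_equal(rep_$over_image_origin, 1)
  expect_equal(rep_$over_large_cell, 1)
  expect_equal(rep_$under_blind_spot, 1)
  expect_equal(rep_$under_resolution, 1)
  expect_equal(rep_$unclassified_over + rep_$unclassified_under, 0)
  # accounting identities
  expect_equal(rep_$matched + rep_$over_image_origin + rep_$over_large_cell +
                 rep_$unclassified_over, rep_$n_detected)
  expect_equal(rep_$matched + rep_$under_blind_spot + rep_$under_resolution +
                 rep_$unclassified_under, rep_$n_truth)
  td <- tidy(rep_)
  expect_equal(sum(td$count), 4)
  expect_equal(td$pct_of_truth, 100 * td$count / 4)
  gl <- glance(rep_)
  expect_equal(gl$recall, 0.5)
})

test_that("missing auxiliary layers fail loudly", {
  fx <- four_error_fixture()
  m <- match_detections(fx$det, fx$truth, 5)
  expect_error(classify_errors(m, fx$det, fx$truth,
                               list(debris = fx$aux$debris)),
               "dark_zone_mask")
})

test_that("density accuracy is the symmetric absolute percent error", {
  expect_equal(accuracy_by_density(100, 100), 0)
  expect_equal(accuracy_by_density(110, 100), 10)
  expect_equal(accuracy_by_density(90, 100), 10)
  expect_error(accuracy_by_density(50, 0), "positive")
})

test_that("r_squared matches hand computation and is permutation-invariant", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 3, 2)), 0.25)  # r = 0.5 by hand
  set.seed(79)
  x2 <- runif(20)
  y2 <- runif(20)
  perm <- sample.int(20)
  expect_equal(r_squared(x2, y2), r_squared(x2[perm], y2[perm]))
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  expect_error(r_squared(1:2, 2:3), "at least 3")
})

test_that("blind-spot errors grow with the dark-zone area fraction", {
  pooled <- vapply(c(0.2, 0.4), function(q) {
    blind <- 0
    for (sd0 in 1:3) {
      sc <- render_scene(scene_params(width_px = 300, height_px = 300,
                                      n_cells = 80, cell_amplitude = 0.12,
                                      dark_zone_quantile = q,
                                      seed = 300 + sd0))
      det <- detect_cells(amplify_clip(compute_ivm(sc$scan), 200))
      m <- match_detections(det, sc$truth$cells, 5)
      rep_ <- classify_errors(m, det, sc$truth$cells, sc$truth)
      blind <- blind + rep_$under_blind_spot
    }
    blind
  }, numeric(1))
  expect_gte(pooled[2], pooled[1])
})
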