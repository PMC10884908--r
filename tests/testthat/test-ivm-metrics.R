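test_that("IVM of a constant image is zero to machine precision", {
  for (lv in c(0, 0.3, 1)) {
    ivm <- compute_ivm(matrix(lv, 12, 17))
    expect_lte(max(ivm$pixels), 1e-14)
  }
})

test_that("IVM matches the dense-convolution oracle on an impulse", {
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  got <- compute_ivm(img)$pixels
  want <- oracle_ivm(img)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_true(all(got >= 0))
})

test_that("IVM is invariant under intensity inversion", {
  set.seed(11)
  img <- matrix(runif(20 * 24, 0.1, 0.9), 20, 24)
  a <- compute_ivm(img)$pixels
  b <- compute_ivm(1 - img)$pixels
  expect_equal(a, b, tolerance = 1e-13)
})

test_that("IVM rejects non-finite input", {
  img <- matrix(0.5, 5, 5)
  img[2, 2] <- NA
  expect_error(compute_ivm(img), "non-finite")
})

test_that("amplify_clip multiplies then clips at pure white", {
  expect_equal(amplify_clip(matrix(0.004, 1, 1), 200), matrix(0.8, 1, 1))
  expect_equal(amplify_clip(matrix(0.02, 1, 1), 100), matrix(1, 1, 1))
  expect_equal(amplify_clip(matrix(0, 3, 3), 500), matrix(0, 3, 3))
})

test_that("object contrast is the population variance of the x100 map", {
  expect_equal(object_contrast(matrix(0.007, 9, 9)), 0)
  two_point <- matrix(c(rep(0, 8), rep(0.005, 8)), 4, 4)
  expect_equal(object_contrast(two_point), 0.0625)  # var of {0, 0.5}
  set.seed(12)
  m <- matrix(runif(400, 0, 0.02), 20, 20)
  got <- object_contrast(m)
  want <- oracle_pop_var(pmin(100 * m, 1))
  expect_lt(abs(got - want) / want, 1e-12)
})

test_that("brightness stats match closed forms and the naive oracle", {
  bs <- brightness_stats(matrix(0.3, 6, 6))
  expect_equal(bs$mean, 0.3)
  expect_equal(bs$deviation, 0)
  bs2 <- brightness_stats(matrix(c(0, 1), 2, 1))
  expect_equal(bs2$mean, 0.5)
  expect_equal(bs2$deviation, sqrt(0.5))
  expect_equal(brightness_stats(matrix(0.7, 1, 1))$deviation, 0)
  set.seed(13)
  m <- matrix(runif(300), 15, 20)
  o <- oracle_mean_sd(m)
  bs3 <- brightness_stats(m)
  expect_lt(abs(bs3$mean - o$mean), 1e-12)
  expect_lt(abs(bs3$deviation - o$sd), 1e-12)
})

test_that("local brightness difference is the disk max-min", {
  expect_true(all(local_brightness_difference(matrix(0.4, 25, 25), 5) == 0))
  # ideal step edge of height h: value h within the radius, 0 elsewhere
  step <- matrix(0.2, 30, 30)
  step[, 16:30] <- 0.9
  lbd <- local_brightness_difference(step, 4)
  expect_true(all(abs(lbd[, 12:19] - 0.7) < 1e-12))
  expect_true(all(lbd[, 1:10] == 0))
  expect_true(all(lbd[, 21:30] == 0))
  # linear ramp of slope s: interior value = s * 2 * radius along the axis
  ramp <- matrix(rep(seq(0, 0.29, by = 0.01), each = 20), 20, 30)
  lbd2 <- local_brightness_difference(ramp, 3)
  expect_equal(lbd2[10, 10], 0.01 * 6, tolerance = 1e-12)
  # random map against the per-pixel scan oracle
  set.seed(14)
  m <- matrix(runif(15 * 12), 15, 12)
  expect_equal(local_brightness_difference(m, 3), oracle_disk_maxmin(m, 3),
               tolerance = 1e-14)
})

test_that("cross-entropy matches hand arithmetic and obeys Gibbs", {
  half <- matrix(0.5, 4, 4)
  expect_equal(cross_entropy(half, half), log(2), tolerance = 1e-12)
  p <- matrix(c(1, 0), 1, 2)
  q <- matrix(c(0.8, 0.1), 1, 2)
  expect_equal(cross_entropy(p, q), -(log(0.8) + log(0.9)) / 2,
               tolerance = 1e-12)
  expect_error(cross_entropy(matrix(0.5, 2, 2), matrix(0.5, 3, 2)),
               "dimensions")
  set.seed(15)
  for (i in 1:25) {
    p <- matrix(runif(36), 6, 6)
    q <- matrix(runif(36), 6, 6)
    expect_gte(cross_entropy(p, q), cross_entropy(p, p))
  }
})

test_that("object contrast is nondecreasing in stamped cell amplitude", {
  oc <- vapply(c(0.05, 0.1, 0.2, 0.3), function(a) {
    sc <- render_scene(scene_params(width_px = 200, height_px = 200,
                                    n_cells = 30, cell_amplitude = a,
                                    seed = 5))
    object_contrast(compute_ivm(sc$scan))
  }, numeric(1))
  expect_false(is.unsorted(oc))
})

test_that("IVM at cell sites tracks local brightness difference (Spearman)", {
  mk <- function(pat) {
    render_scene(scene_params(width_px = 300, height_px = 300, n_cells = 40,
                              visibility_coupling = 1, pattern = pat,
                              seed = 4))
  }
  pats <- list(pattern_spec(450, 900, "hex"),
               pattern_spec(2000, 3000, "square", 3000, 3000),
               pattern_spec(450, 1e9, "square"))  # no holes: constant sheet
  iv <- c()
  lb <- c()
  for (pat in pats) {
    sc <- mk(pat)
    ivm <- compute_ivm(sc$scan)$pixels
    lbd <- local_brightness_difference(sc$scan, 10)
    ci <- cbind(round(sc$truth$cells$row_px) + 1,
                round(sc$truth$cells$col_px) + 1)
    for (i in seq_len(nrow(ci))) {
      rr <- max(1, ci[i, 1] - 3):min(300, ci[i, 1] + 3)
      cc <- max(1, ci[i, 2] - 3):min(300, ci[i, 2] + 3)
      iv <- c(iv, mean(ivm[rr, cc]))
      lb <- c(lb, lbd[ci[i, 1], ci[i, 2]])
    }
  }
  expect_gt(stats::cor(iv, lb, method = "spearman"), 0.5)
})
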