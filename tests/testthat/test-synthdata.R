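test_that("the truth generator is a pure function of its seed", {
  a <- gen_truth_series(15, 20, 4, rank = 2, mode_scales = c(5, 1),
                        seed = 77)
  b <- gen_truth_series(15, 20, 4, rank = 2, mode_scales = c(5, 1),
                        seed = 77)
  c <- gen_truth_series(15, 20, 4, rank = 2, mode_scales = c(5, 1),
                        seed = 78)
  expect_identical(a$scenes[[2]]$values, b$scenes[[2]]$values)
  expect_false(identical(a$scenes[[2]]$values, c$scenes[[2]]$values))
})

test_that("a noiseless rank-1 series is one spatial pattern rescaled", {
  tr <- gen_truth_series(12, 14, 5, rank = 1, mode_scales = 4,
                         noise_sd = 0, land_fraction = 0.15, seed = 3)
  truth <- attr(tr, "truth")
  sea <- !truth$land_mask
  v1 <- tr$scenes[[1]]$values[sea]
  for (t in 2:5) {
    vt <- tr$scenes[[t]]$values[sea]
    ratio <- truth$temporal[t, 1] / truth$temporal[1, 1]
    expect_equal(vt, v1 * ratio, tolerance = 1e-10)
  }
})

test_that("the unfolded truth shows the declared dominant mode scales", {
  tr <- gen_truth_series(30, 24, 12, rank = 3, mode_scales = c(100, 10, 1),
                         noise_sd = 0.01, land_fraction = 0.1, seed = 5)
  d <- svd(build_matrix(tr)$X)$d
  # three dominant values, each >= 10x the noise floor
  expect_gt(d[3], 10 * d[4])
  expect_equal(d[1] / d[2], 10, tolerance = 0.05)
  expect_equal(d[2] / d[3], 10, tolerance = 0.05)
})

test_that("sensor degradation applies gaps, bias and noise as declared", {
  tr <- gen_truth_series(24, 30, 3, rank = 2, mode_scales = c(5, 1),
                         noise_sd = 0, land_fraction = 0.1, seed = 7)
  # gap_fraction 0, zero noise: identity up to the declared bias
  cfg0 <- sensor_config("clean", "block", gap_fraction = 0, bias = 0.7)
  deg0 <- degrade_by_sensor(tr, cfg0)
  expect_identical(deg0$scenes[[1]]$valid_mask, tr$scenes[[1]]$valid_mask)
  m <- tr$scenes[[1]]$valid_mask
  expect_equal(deg0$scenes[[1]]$values[m] - tr$scenes[[1]]$values[m],
               rep(0.7, sum(m)))

  # requested gap fraction is hit exactly on sea pixels
  for (style in c("diagonal-stripe", "block", "random-patch")) {
    cfg <- sensor_config(style, style, gap_fraction = 0.4, seed = 9)
    deg <- degrade_by_sensor(tr, cfg)
    sea <- !tr$scenes[[1]]$land_mask
    got <- 1 - sum(deg$scenes[[1]]$valid_mask) / sum(sea)
    expect_equal(got, 0.4, tolerance = 1 / sum(sea))
  }
  expect_error(sensor_config("x", "spiral"), "swath_style")
})

test_that("a four-sensor constellation jointly covers more than any one", {
  tr <- gen_truth_series(30, 40, 2, rank = 2, mode_scales = c(5, 1),
                         noise_sd = 0, land_fraction = 0.1, seed = 11)
  degs <- lapply(default_sensors(seed = 2), function(cf) {
    degrade_by_sensor(tr, cf)
  })
  masks <- lapply(degs, function(d) d$scenes[[1]]$valid_mask)
  union <- Reduce(`|`, masks)
  for (mk in masks) expect_gt(sum(union), sum(mk))
})

test_that("cloud masks hit the requested sea coverage exactly", {
  land <- matrix(FALSE, 40, 50); land[, 45:50] <- TRUE
  n_sea <- sum(!land)
  expect_equal(sum(gen_cloud_mask(40, 50, 0, seed = 1, land_mask = land)), 0)
  for (cov in c(0.2, 0.3, 0.5)) {
    mk <- gen_cloud_mask(40, 50, cov, corr_length = 5, seed = 4,
                         land_mask = land)
    expect_false(any(mk & land))                  # clouds only over sea
    expect_equal(sum(mk) / n_sea, cov, tolerance = 0.005)
  }
  m1 <- gen_cloud_mask(40, 50, 0.3, seed = 8)
  m2 <- gen_cloud_mask(40, 50, 0.3, seed = 8)
  expect_identical(m1, m2)
})

test_that("cloud masks are blobs, not salt-and-pepper", {
  mk <- gen_cloud_mask(60, 60, 0.3, corr_length = 8, seed = 13)
  # neighbour agreement far above the 0.3 chance level of an iid mask
  same <- mean(mk[-1, ] == mk[-60, ])
  expect_gt(same, 0.9)
})

test_that("composites average valid observations per pixel", {
  v1 <- matrix(c(2, NA, 1, NA), 2, 2)
  v2 <- matrix(c(4, NA, 1, 6), 2, 2)
  ss <- scene_series(list(
    scene(v1, timestamp = "2020-01-01"),
    scene(v2, timestamp = "2020-01-03")))
  comp <- make_composite(ss)
  expect_equal(comp$values[1, 1], 3)              # mean of 2 and 4
  expect_equal(comp$values[2, 2], 6)              # single observation
  expect_true(is.na(comp$values[2, 1]))           # never observed
  expect_false(comp$valid_mask[2, 1])

  # constant fully-valid series -> the constant everywhere
  cs <- scene_series(list(scene(matrix(5, 3, 3), timestamp = "2020-01-01"),
                          scene(matrix(5, 3, 3), timestamp = "2020-01-02")))
  expect_true(all(make_composite(cs)$values == 5))
})

test_that("daily sensor masks whose union is complete give a hole-free composite", {
  tr <- gen_truth_series(20, 24, 6, rank = 2, mode_scales = c(5, 1),
                         noise_sd = 0.01, land_fraction = 0.1, seed = 15)
  # alternate complementary block gaps so the union covers all sea
  degraded <- scene_series(lapply(seq_along(tr$scenes), function(t) {
    s <- tr$scenes[[t]]
    gap <- matrix(FALSE, 20, 24)
    if (t %% 2 == 0) gap[, 1:12] <- TRUE else gap[, 13:24] <- TRUE
    v <- s$values; v[gap] <- NA
    scene(v, valid_mask = s$valid_mask & !gap, land_mask = s$land_mask,
          timestamp = s$timestamp)
  }))
  comp <- make_composite(degraded)
  sea <- !tr$scenes[[1]]$land_mask
  expect_true(all(comp$valid_mask[sea]))
})
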