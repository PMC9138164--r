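small_series <- function(H = 6, W = 8, T = 5, miss = 0.3, seed = 1,
                         land_frac = 0.1, noise = 0.05) {
  truth <- gen_truth_series(H, W, T, rank = 2, mode_scales = c(10, 3),
                            noise_sd = noise, land_fraction = land_frac,
                            seed = seed)
  list(truth = truth, masked = mcar_series(truth, miss, seed + 1000))
}

test_that("build_matrix keeps observed sea pixels and centres exactly", {
  # 4 x 4 grid with 6 land pixels and all sea observed: L = 10 rows
  land <- matrix(FALSE, 4, 4); land[1:6] <- TRUE
  v <- matrix(rnorm(16), 4, 4); v[land] <- NA
  s1 <- scene(v, valid_mask = !land, land_mask = land,
              timestamp = "2020-01-01")
  s2 <- scene(v + 1, valid_mask = !land, land_mask = land,
              timestamp = "2020-01-02")
  dm <- build_matrix(scene_series(list(s1, s2)))
  expect_equal(nrow(dm$X), 10)
  expect_equal(nrow(dm$excluded_rows), 0)

  # constant field: anomalies all zero, mean recovered
  c0 <- 4.2
  sc <- scene(matrix(c0, 3, 3), timestamp = "2020-01-01")
  sc2 <- scene(matrix(c0, 3, 3), timestamp = "2020-01-02")
  dmc <- build_matrix(scene_series(list(sc, sc2)))
  expect_equal(dmc$center, c0)
  expect_true(all(dmc$X == 0))
  expect_error(build_matrix(scene_series(list(sc))), "T >= 2")
})

test_that("de-centering the matrix reproduces observed entries exactly", {
  z <- small_series(seed = 7)
  dm <- build_matrix(z$masked)
  back <- eofill:::matrix_to_series(dm, dm$X)
  for (t in seq_along(z$masked$scenes)) {
    m <- z$masked$scenes[[t]]$valid_mask
    expect_equal(back$scenes[[t]]$values[m], z$masked$scenes[[t]]$values[m])
  }
})

test_that("never-observed pixels are excluded and reported", {
  z <- small_series(seed = 9, miss = 0.2)
  masked <- z$masked
  # blank one sea pixel at every date
  px <- which(!masked$scenes[[1]]$land_mask, arr.ind = TRUE)[3, ]
  masked <- scene_series(lapply(masked$scenes, function(s) {
    v <- s$values; v[px[1], px[2]] <- NA
    vm <- s$valid_mask; vm[px[1], px[2]] <- FALSE
    scene(v, valid_mask = vm, land_mask = s$land_mask,
          timestamp = s$timestamp)
  }))
  dm <- build_matrix(masked)
  expect_true(any(dm$excluded_rows[, 1] == px[1] &
                  dm$excluded_rows[, 2] == px[2]))
  res <- dineof_fill(masked, dineof_params(nev = 3, ncv = 5, seed = 2))
  expect_false(res$series$scenes[[1]]$valid_mask[px[1], px[2]])
})

test_that("the cross-validation draw is seeded, sized and row-safe", {
  z <- small_series(H = 10, W = 12, T = 6, seed = 11)
  dm <- build_matrix(z$masked)
  cv1 <- select_cv_points(dm, cv_fraction = 0.05, seed = 42)
  cv2 <- select_cv_points(dm, cv_fraction = 0.05, seed = 42)
  expect_identical(cv1, cv2)
  expect_equal(sum(cv1), round(0.05 * sum(dm$obs_mask)))
  expect_true(all(cv1[!dm$obs_mask] == FALSE))      # only observed entries
  kept <- dm$obs_mask & !cv1
  expect_true(all(rowSums(kept) >= 1))              # no emptied rows
  # explicit n_points and the degenerate empty draw
  expect_equal(sum(select_cv_points(dm, seed = 1, n_points = 17)), 17)
  expect_equal(sum(select_cv_points(dm, seed = 1, n_points = 0)), 0)
})

test_that("full-rank reconstruction of a complete matrix is immediate", {
  z <- small_series(miss = 0, seed = 13)
  dm <- build_matrix(z$truth)
  k <- min(nrow(dm$X), ncol(dm$X))
  fit <- reconstruct_fixed_k(dm, k, toliter = 1e-6, nitemax = 10)
  expect_equal(fit$n_iter, 1)
  expect_true(fit$converged)
  expect_equal(fit$X, dm$X, tolerance = 1e-10)
  expect_error(reconstruct_fixed_k(dm, 0), "k out of range")
})

test_that("a noiseless rank-1 matrix is completed to high precision", {
  truth <- gen_truth_series(12, 10, 6, rank = 1, mode_scales = 5,
                            noise_sd = 0, land_fraction = 0, seed = 17)
  masked <- mcar_series(truth, 0.2, 18)
  dm <- build_matrix(masked)
  fit <- reconstruct_fixed_k(dm, 1, toliter = 1e-10, nitemax = 500)
  tru <- build_matrix(truth)
  miss <- !dm$obs_mask
  est <- fit$X + dm$center
  expect_lt(max(abs(est[miss] - (tru$X[miss] + tru$center))), 1e-6)
})

test_that("observed entries are never modified by the completion", {
  z <- small_series(seed = 19)
  dm <- build_matrix(z$masked)
  cv <- select_cv_points(dm, 0.05, seed = 3)
  fit <- reconstruct_fixed_k(dm, 2, toliter = 1e-4, nitemax = 50,
                             cv_mask = cv)
  keepmask <- dm$obs_mask & !cv
  expect_identical(fit$X[keepmask], dm$X[keepmask])
  # convergence bookkeeping: declared converged iff last delta < toliter
  expect_equal(fit$converged, tail(fit$deltas, 1) < 1e-4)
})

test_that("temporal filter is conservative and local", {
  V <- matrix(rnorm(5 * 2), 5, 2)
  times <- as.Date("2020-01-01") + 0:4
  expect_identical(temporal_filter(V, times, 0, 5), V)      # alpha = 0
  expect_identical(temporal_filter(V, times, 2, 0), V)      # numit = 0
  expect_error(temporal_filter(V, times, -1, 1), "alpha")

  # constant column is a fixed point
  Vc <- matrix(3, 5, 1)
  expect_equal(temporal_filter(Vc, times, 0.4, 7), Vc)

  # single spike spreads only to adjacent dates in one sweep; mass kept
  sp <- c(0, 0, 1, 0, 0)
  f1 <- temporal_filter(sp, times, 0.2, 1)
  expect_equal(sum(f1), 1)                      # column sum preserved
  expect_equal(f1, c(0, 0.2, 0.6, 0.2, 0))      # hand-computed diffusion
  expect_equal(f1[c(1, 5)], c(0, 0))

  # a wider date gap couples more weakly
  times2 <- as.Date("2020-01-01") + c(0, 1, 2, 3, 10)
  f2 <- temporal_filter(sp, times2, 0.2, 1)
  expect_lt(f2[4] - 0, f1[4] + 1e-12)           # spike still local
  g <- temporal_filter(c(0, 0, 0, 1, 0), times2, 0.2, 1)
  expect_lt(g[5], 0.2)                          # gap-weakened transfer
  expect_equal(sum(g), 1)
})

test_that("dineof_fill preserves observations and reports its scan", {
  z <- small_series(H = 12, W = 12, T = 6, miss = 0.3, seed = 23)
  res <- dineof_fill(z$masked, dineof_params(nev = 4, ncv = 6, seed = 5,
                                             toliter = 1e-4))
  for (t in seq_along(z$masked$scenes)) {
    m <- z$masked$scenes[[t]]$valid_mask
    expect_equal(res$series$scenes[[t]]$values[m],
                 z$masked$scenes[[t]]$values[m])
    # every sea pixel observed at least once is now complete
    sea_obs <- !z$masked$scenes[[t]]$land_mask
    sea_obs[dm_excluded(res)] <- FALSE
    expect_true(all(res$series$scenes[[t]]$valid_mask[sea_obs]))
  }
  expect_true(res$k_selected >= 1 && res$k_selected <= 4)
  evaluated <- res$cv_rmse_by_k[is.finite(res$cv_rmse_by_k)]
  expect_equal(min(evaluated), res$cv_rmse_by_k[[res$k_selected]])
})

test_that("a series with no missing sea entries passes through", {
  z <- small_series(miss = 0, seed = 29)
  res <- dineof_fill(z$truth, dineof_params(nev = 3, ncv = 5, seed = 7))
  for (t in seq_along(z$truth$scenes)) {
    m <- z$truth$scenes[[t]]$valid_mask
    expect_equal(res$series$scenes[[t]]$values[m],
                 z$truth$scenes[[t]]$values[m])
  }
})

test_that("rec = 1 replaces all entries with the smoothed reconstruction", {
  z <- small_series(H = 10, W = 10, T = 6, miss = 0.3, seed = 31,
                    noise = 0.5)
  res <- dineof_fill(z$masked, dineof_params(nev = 2, ncv = 4, seed = 9,
                                             rec = 1))
  t1 <- 1
  m <- z$masked$scenes[[t1]]$valid_mask
  expect_false(isTRUE(all.equal(res$series$scenes[[t1]]$values[m],
                                z$masked$scenes[[t1]]$values[m])))
})
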