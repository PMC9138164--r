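# Fixture builders and independent brute-force oracles used across tests.

# random scene with given missing fraction (MCAR) and optional land block
random_scene <- function(H, W, miss_frac = 0.4, land_frac = 0,
                         seed = 1L, date = as.Date("2018-02-01")) {
  set.seed(seed)
  land <- matrix(FALSE, H, W)
  if (land_frac > 0) {
    wl <- max(1L, round(W * land_frac))
    land[, (W - wl + 1L):W] <- TRUE
  }
  v <- matrix(rnorm(H * W, mean = 5), H, W)
  valid <- !land & (matrix(runif(H * W), H, W) >= miss_frac)
  v[!valid] <- NA
  scene(v, valid_mask = valid, land_mask = land, timestamp = date)
}

# drop a fraction of valid pixels completely at random from every scene
mcar_series <- function(series, frac, seed) {
  set.seed(seed)
  d <- dim(series$scenes[[1]]$values)
  scene_series(lapply(seq_along(series$scenes), function(t) {
    s <- series$scenes[[t]]
    drop <- s$valid_mask & (matrix(runif(prod(d)), d[1], d[2]) < frac)
    v <- s$values
    v[drop] <- NA
    scene(v, valid_mask = s$valid_mask & !drop, land_mask = s$land_mask,
          timestamp = s$timestamp, sensor_id = s$sensor_id)
  }))
}

# brute-force per-pixel sliding-window mean: the oracle for slide_fill
oracle_slide_fill <- function(scn, m, min_neighbors = 3L) {
  H <- nrow(scn$values); W <- ncol(scn$values)
  h <- (m - 1L) %/% 2L
  out <- scn$values
  valid <- scn$valid_mask
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (scn$land_mask[i, j] || valid[i, j]) next
      ri <- max(1L, i - h):min(H, i + h)
      ci <- max(1L, j - h):min(W, j + h)
      vals <- c()
      for (ii in ri) for (jj in ci) {
        if (ii == i && jj == j) next
        if (valid[ii, jj] && !scn$land_mask[ii, jj]) {
          vals <- c(vals, scn$values[ii, jj])
        }
      }
      if (length(vals) >= min_neighbors) out[i, j] <- mean(vals)
    }
  }
  out
}

# brute-force IDW seam adjustment: the oracle for idw_adjust
oracle_idw <- function(merged, provenance, power = 2, max_radius = 10L) {
  H <- nrow(merged$values); W <- ncol(merged$values)
  out <- merged$values
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (provenance[i, j] <= 0L) next
      wsum <- 1; vsum <- merged$values[i, j]
      for (dir in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        for (d in seq_len(max_radius)) {
          ii <- i + dir[1] * d; jj <- j + dir[2] * d
          if (ii < 1 || ii > H || jj < 1 || jj > W) break
          if (provenance[ii, jj] == 0L) {
            w <- 1 / d^power
            wsum <- wsum + w
            vsum <- vsum + w * merged$values[ii, jj]
            break
          }
        }
      }
      out[i, j] <- vsum / wsum
    }
  }
  out
}

# independently coded reference for the fixed-rank completion: full SVD
# every iteration, scalar offset re-estimation, ridge polish -- the same
# declared algorithm with none of the package's bookkeeping shared
oracle_reconstruct <- function(X_obs, obs_mask, k, toliter, nitemax) {
  L <- nrow(X_obs); T <- ncol(X_obs)
  X <- X_obs
  X[!obs_mask] <- 0
  obs_rms <- sqrt(mean(X_obs[obs_mask]^2))
  if (!is.finite(obs_rms) || obs_rms == 0) obs_rms <- 1
  off <- 0
  sv <- NULL
  for (it in seq_len(nitemax)) {
    sv <- svd(X - off)
    rec <- sv$u[, 1:k, drop = FALSE] %*%
      diag(sv$d[1:k], nrow = k) %*% t(sv$v[, 1:k, drop = FALSE])
    off <- mean(X[obs_mask] - rec[obs_mask])
    model <- rec + off
    delta <- sqrt(mean((model[!obs_mask] - X[!obs_mask])^2)) / obs_rms
    X[!obs_mask] <- model[!obs_mask]
    if (delta < toliter) break
  }
  V <- sv$v[, 1:k, drop = FALSE]
  dk <- sv$d[1:k]
  recf <- sv$u[, 1:k, drop = FALSE] %*% diag(dk, nrow = k) %*% t(V)
  sig2 <- mean((X_obs[obs_mask] - (recf + off)[obs_mask])^2)
  lam <- sig2 * L / pmax(dk, 1e-12 * max(dk, 1))^2
  for (i in seq_len(L)) {
    o <- obs_mask[i, ]
    if (all(o) || !any(o)) next
    Vo <- V[o, , drop = FALSE]
    beta <- tryCatch(
      solve(crossprod(Vo) + diag(lam, nrow = k),
            crossprod(Vo, X_obs[i, o] - off)),
      error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) next
    X[i, !o] <- off + drop(V[!o, , drop = FALSE] %*% beta)
  }
  X
}

# series whose modes live in separate quadrants of the grid, for
# tiled-vs-whole comparisons
localized_series <- function(H = 48, W = 48, T = 12, noise_sd = 0.05,
                             seed = 1L) {
  set.seed(seed)
  bump <- function(cy, cx, s) {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  }
  sp <- list(bump(H * 0.25, W * 0.25, H / 8),
             bump(H * 0.25, W * 0.75, H / 8),
             bump(H * 0.75, W * 0.5, H / 8))
  sp <- lapply(sp, function(f) f / sqrt(mean(f^2)))
  scales <- c(50, 20, 8)
  tt <- seq_len(T)
  tm <- lapply(1:3, function(r) sqrt(2) * sin(2 * pi * r * tt / T + r))
  scenes <- lapply(seq_len(T), function(t) {
    v <- matrix(0, H, W)
    for (r in 1:3) v <- v + scales[r] * sp[[r]] * tm[[r]][t]
    v <- v + matrix(rnorm(H * W, sd = noise_sd), H, W)
    scene(v, valid_mask = matrix(TRUE, H, W),
          land_mask = matrix(FALSE, H, W),
          timestamp = as.Date("2018-01-01") + t - 1)
  })
  scene_series(scenes)
}

# pixels excluded by a reconstruction (never observed), as a logical mask
dm_excluded <- function(res) {
  ex <- res$excluded_rows
  d <- dim(res$series$scenes[[1]]$values)
  out <- matrix(FALSE, d[1], d[2])
  if (nrow(ex)) out[cbind(ex[, 1], ex[, 2])] <- TRUE
  out
}

# missing-entry RMSE of a filled series against the truth series
hidden_rmse <- function(truth, masked, filled) {
  e2 <- unlist(lapply(seq_along(truth$scenes), function(t) {
    hid <- truth$scenes[[t]]$valid_mask & !masked$scenes[[t]]$valid_mask
    hid <- hid & filled$scenes[[t]]$valid_mask
    (filled$scenes[[t]]$values[hid] - truth$scenes[[t]]$values[hid])^2
  }))
  if (!length(e2)) return(NA_real_)
  sqrt(mean(e2))
}
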