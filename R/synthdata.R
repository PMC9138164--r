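# Seeded generators of desk-scale stand-ins for multi-sensor ocean-colour
# data: low-rank truth series, per-sensor degraded copies with swath gaps,
# correlated cloud masks at a target coverage, and monthly composites.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# separable Gaussian blur with edge renormalisation, used for smooth random
# fields (spatial modes, cloud masks, patchy swaths)
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      if (abs(o) >= n) next
      ri <- max(1, 1 + o):min(n, n + o)
      out[ri, ] <- out[ri, ] + kern[o + r + 1] * m[ri - o, , drop = FALSE]
      wt[ri, ] <- wt[ri, ] + kern[o + r + 1]
    }
    out / wt
  }
  t(smooth1(t(smooth1(x))))
}

#' Generate a low-rank ground-truth scene series
#'
#' Values are a sum of `rank` separable space-time modes,
#' `sum_r scale_r * S_r(y, x) * P_r(t)`, plus white Gaussian noise.  The
#' spatial modes `S_r` are smooth seeded random fields, orthogonalised and
#' normalised to unit RMS over sea; the temporal modes `P_r` are Fourier
#' harmonics of distinct integer frequency with random phase (unit RMS,
#' zero mean, mutually orthogonal), so the empirical singular values of
#' the unfolded series follow `mode_scales`.  A contiguous land block along the eastern
#' edge occupies `land_fraction` of the grid.  The exact noise-free field,
#' the modes and the land mask are attached as attribute `truth` for
#' oracle checks.
#'
#' @param H,W grid height and width in pixels.
#' @param T number of daily time steps.
#' @param rank number of modes.
#' @param mode_scales numeric vector of length `rank`; mode `r` has
#'   amplitude `mode_scales[r]` (so variances scale with its square).
#' @param noise_sd standard deviation of the additive noise.
#' @param land_fraction fraction of the grid covered by land, in [0, 1).
#' @param seed integer seed; the generator is a pure function of it.
#' @param start_date date of the first scene.
#' @return A [scene_series] with attribute `truth` (list: `field`
#'   H x W x T array without noise, `spatial` H*W x rank, `temporal`
#'   T x rank, `land_mask`).
#' @export
gen_truth_series <- function(H, W, T, rank = 3L,
                             mode_scales = c(100, 10, 1)[seq_len(rank)],
                             noise_sd = 0.01, land_fraction = 0.1,
                             seed = 1L, start_date = as.Date("2018-01-01")) {
  stopifnot(length(mode_scales) == rank, T >= 1, rank >= 1)
  with_seed(seed, {
    land <- matrix(FALSE, H, W)
    if (land_fraction > 0) {
      wl <- max(1L, round(W * land_fraction))
      land[, (W - wl + 1L):W] <- TRUE
    }
    sea <- !land
    # smooth spatial modes, orthogonalised over sea so the empirical
    # singular-value ratios follow mode_scales as announced
    spatial <- matrix(0, H * W, rank)
    for (r in seq_len(rank)) {
      f <- as.vector(gauss_smooth(matrix(stats::rnorm(H * W), H, W),
                                  sigma = max(2, min(H, W) / 10)))
      if (r > 1) {
        for (q in seq_len(r - 1L)) {
          f <- f - spatial[, q] *
            (sum(f[sea] * spatial[sea, q]) / sum(spatial[sea, q]^2))
        }
      }
      spatial[, r] <- f / sqrt(mean(f[sea]^2))
    }
    # temporal modes: distinct Fourier harmonics with random phase --
    # smooth, periodic, exactly zero-mean and mutually orthogonal
    tt <- seq_len(T)
    temporal <- matrix(0, T, rank)
    for (r in seq_len(rank)) {
      phase <- stats::runif(1, 0, 2 * pi)
      p <- sin(2 * pi * r * tt / T + phase)
      temporal[, r] <- if (stats::sd(p) > 1e-12) p / sqrt(mean(p^2)) else
        rep(1, T)
    }
    field <- array(0, dim = c(H, W, T))
    for (r in seq_len(rank)) {
      field <- field + mode_scales[r] *
        outer(matrix(spatial[, r], H, W), temporal[, r])
    }
    scenes <- vector("list", T)
    for (t in seq_len(T)) {
      v <- field[, , t] + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
      scenes[[t]] <- scene(v, valid_mask = sea, land_mask = land,
                           timestamp = start_date + t - 1,
                           sensor_id = "truth")
    }
    out <- scene_series(scenes)
    attr(out, "truth") <- list(field = field, spatial = spatial,
                               temporal = temporal, land_mask = land)
    out
  })
}

#' Sensor configuration for the degradation model
#'
#' @param sensor_id label.
#' @param swath_style one of `"diagonal-stripe"` (an oriented band of
#'   missing data through the image centre, the MODIS-like pattern),
#'   `"block"` (a solid rectangle) or `"random-patch"` (correlated random
#'   blobs).
#' @param gap_fraction fraction of sea pixels removed by the swath mask,
#'   in [0, 1).
#' @param bias additive per-sensor bias.
#' @param noise_sd per-sensor additive noise sd.
#' @param angle stripe orientation in degrees (diagonal-stripe only).
#' @param seed seed for the sensor's stochastic components.
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(sensor_id, swath_style = "diagonal-stripe",
                          gap_fraction = 0.3, bias = 0, noise_sd = 0,
                          angle = 45, seed = 1L) {
  if (!swath_style %in% c("diagonal-stripe", "block", "random-patch")) {
    stop("unknown swath_style: ", swath_style)
  }
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("gap_fraction must lie in [0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(sensor_id = sensor_id, swath_style = swath_style,
                 gap_fraction = gap_fraction, bias = bias,
                 noise_sd = noise_sd, angle = angle,
                 seed = as.integer(seed)),
            class = "sensor_config")
}

swath_mask <- function(H, W, sea, cfg) {
  # TRUE = removed; built so the removed SEA fraction equals gap_fraction
  if (cfg$gap_fraction == 0) return(matrix(FALSE, H, W))
  score <- switch(cfg$swath_style,
    "diagonal-stripe" = {
      th <- cfg$angle * pi / 180
      yy <- matrix(seq_len(H) - (H + 1) / 2, H, W)
      xx <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
      -abs(xx * sin(th) + yy * cos(th))     # highest near the centre line
    },
    "block" = {
      yy <- matrix(seq_len(H) - (H + 1) / 2, H, W)
      xx <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
      -pmax(abs(yy) / H, abs(xx) / W)
    },
    "random-patch" = with_seed(cfg$seed,
      gauss_smooth(matrix(stats::rnorm(H * W), H, W),
                   sigma = max(2, min(H, W) / 12))))
  mask_by_quantile(score, sea, cfg$gap_fraction)
}

mask_by_quantile <- function(score, sea, fraction) {
  # remove exactly round(fraction * n_sea) sea pixels, the highest scores
  n_take <- round(fraction * sum(sea))
  m <- matrix(FALSE, nrow(score), ncol(score))
  if (n_take < 1) return(m)
  sea_scores <- score[sea]
  ord <- order(sea_scores, decreasing = TRUE)[seq_len(n_take)]
  sea_idx <- which(sea)
  m[sea_idx[ord]] <- TRUE
  m
}

#' Degrade a truth series as seen by one sensor
#'
#' Applies the sensor's swath-gap mask (one mask per day for the stochastic
#' style, a fixed geometry for stripe/block with a per-day jitter of the
#' stripe offset), then adds the sensor bias and noise on the surviving
#' pixels.
#'
#' @param truth a [scene_series] of complete scenes.
#' @param cfg a [sensor_config].
#' @return A [scene_series] of degraded scenes labelled with the sensor id.
#' @export
degrade_by_sensor <- function(truth, cfg) {
  stopifnot(is_scene_series(truth), inherits(cfg, "sensor_config"))
  H <- nrow(truth$scenes[[1]]$values); W <- ncol(truth$scenes[[1]]$values)
  land <- truth$scenes[[1]]$land_mask
  sea <- !land
  scenes <- vector("list", length(truth))
  for (t in seq_along(truth$scenes)) {
    day_cfg <- cfg
    day_cfg$seed <- cfg$seed + 7919L * t
    day_cfg$angle <- cfg$angle + with_seed(day_cfg$seed,
                                           stats::runif(1, -5, 5))
    gap <- swath_mask(H, W, sea, day_cfg)
    s <- truth$scenes[[t]]
    valid <- s$valid_mask & !gap
    v <- s$values + cfg$bias
    if (cfg$noise_sd > 0) {
      v <- v + with_seed(day_cfg$seed + 1L,
                         matrix(stats::rnorm(H * W, sd = cfg$noise_sd),
                                H, W))
    }
    v[!valid] <- NA_real_
    scenes[[t]] <- scene(v, valid_mask = valid, land_mask = land,
                         timestamp = s$timestamp,
                         sensor_id = cfg$sensor_id)
  }
  scene_series(scenes)
}

#' Generate a correlated cloud mask at a target sea coverage
#'
#' A seeded Gaussian random field is smoothed to autocorrelation scale
#' `corr_length` and thresholded at the empirical quantile that masks
#' exactly `round(coverage * n_sea)` sea pixels, giving cloud-like blobs
#' whose sea-pixel coverage matches the request to within half a
#' percentage point by construction.
#'
#' @param H,W grid dimensions.
#' @param coverage target masked fraction of sea pixels, in [0, 1].
#' @param corr_length blob scale in pixels.
#' @param seed integer seed.
#' @param land_mask optional logical land mask (clouds are only counted
#'   over sea).
#' @return Logical H x W matrix, `TRUE` = clouded.
#' @export
gen_cloud_mask <- function(H, W, coverage, corr_length = 6, seed = 1L,
                           land_mask = NULL) {
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  if (is.null(land_mask)) land_mask <- matrix(FALSE, H, W)
  sea <- !land_mask
  if (coverage > 0 && !any(sea)) {
    warning("no sea pixels available; masking everything")
    return(sea)
  }
  field <- with_seed(seed,
                     gauss_smooth(matrix(stats::rnorm(H * W), H, W),
                                  sigma = corr_length / 2))
  mask_by_quantile(field, sea, coverage)
}

#' Per-pixel temporal composite of a series
#'
#' The composite value of a pixel is the mean of its valid observations
#' across the series; a pixel observed on no date is missing in the
#' composite.  This is how hole-free monthly validation images are built
#' from daily scenes.
#'
#' @param series a [scene_series].
#' @return A [scene] dated at the first time step.
#' @export
make_composite <- function(series) {
  stopifnot(is_scene_series(series))
  d <- dim(series$scenes[[1]]$values)
  ssum <- matrix(0, d[1], d[2])
  cnt <- matrix(0, d[1], d[2])
  for (s in series$scenes) {
    v <- s$values
    v[!s$valid_mask] <- 0
    ssum <- ssum + v
    cnt <- cnt + s$valid_mask
  }
  v <- ifelse(cnt > 0, ssum / cnt, NA_real_)
  scene(v, valid_mask = cnt > 0, land_mask = series$scenes[[1]]$land_mask,
        timestamp = series$times[1],
        sensor_id = paste0(series$scenes[[1]]$sensor_id, "+composite"))
}

#' Default four-sensor constellation
#'
#' Two MODIS-like sensors with oppositely oriented diagonal swath bands
#' and two VIIRS-like sensors with patchier, smaller gaps, mirroring the
#' qualitative gap geometry of the MODIS-Aqua / MODIS-Terra /
#' VIIRS-SNPP / VIIRS-JPSS-1 constellation.
#'
#' @param seed base seed; each sensor derives its own from it.
#' @param noise_sd common per-sensor noise sd.
#' @return List of four [sensor_config] objects.
#' @export
default_sensors <- function(seed = 1L, noise_sd = 0.05) {
  list(
    sensor_config("modis-aqua", "diagonal-stripe", gap_fraction = 0.65,
                  bias = 0.10, noise_sd = noise_sd, angle = 55,
                  seed = seed + 101L),
    sensor_config("modis-terra", "diagonal-stripe", gap_fraction = 0.62,
                  bias = -0.08, noise_sd = noise_sd, angle = 125,
                  seed = seed + 202L),
    sensor_config("viirs-snpp", "random-patch", gap_fraction = 0.58,
                  bias = 0.04, noise_sd = noise_sd, seed = seed + 303L),
    sensor_config("viirs-jpss1", "random-patch", gap_fraction = 0.55,
                  bias = 0.00, noise_sd = noise_sd, seed = seed + 404L))
}
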