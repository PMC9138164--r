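# Segmentation of an orthomosaic series into a J x K grid of tiles and
# lossless reassembly, plus the operation-count model that motivates it.

#' Plan a J x K tiling of an H x W grid
#'
#' The grid is divided as evenly as possible: the nominal tile size is
#' `(floor(H/J), floor(W/K))` and the remainder rows/columns (`H mod J`,
#' `W mod K`) are given one each to the first tiles in order, so the real
#' tiles always partition the grid exactly.  For square divisions
#' (`J == K`) the tile aspect ratio matches the parent grid's by
#' construction.
#'
#' @param H,W parent grid height and width in pixels.
#' @param halvings successive binary halvings: `J = K = 2^halvings`.
#'   Ignored when `J`/`K` are given explicitly.
#' @param J,K explicit tile-grid dimensions.
#' @return A `tile_plan`: list with `J`, `K`, `H`, `W`, `nominal`
#'   (floor tile size, `c(h, w)`) and `tiles`, a data frame with one row
#'   per tile (`j`, `k`, `row0`, `col0`, `height`, `width`; offsets
#'   0-based).
#' @export
plan_tiles <- function(H, W, halvings = NULL, J = NULL, K = NULL) {
  H <- as.integer(H); W <- as.integer(W)
  if (is.null(J) || is.null(K)) {
    if (is.null(halvings) || halvings < 0) {
      stop("give either halvings >= 0 or explicit J and K")
    }
    J <- K <- 2L^as.integer(halvings)
  }
  J <- as.integer(J); K <- as.integer(K)
  if (J < 1L || K < 1L) stop("J and K must be >= 1")
  if (J > H || K > W) stop("more tiles than pixels: J > H or K > W")
  split1 <- function(n, parts) {
    base <- n %/% parts
    sizes <- rep(base, parts)
    extra <- n %% parts
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
  }
  hs <- split1(H, J); ws <- split1(W, K)
  r0 <- cumsum(c(0L, hs[-J])); c0 <- cumsum(c(0L, ws[-K]))
  tiles <- expand.grid(k = seq_len(K), j = seq_len(J))[, c("j", "k")]
  tiles$row0 <- r0[tiles$j]
  tiles$col0 <- c0[tiles$k]
  tiles$height <- hs[tiles$j]
  tiles$width <- ws[tiles$k]
  structure(list(J = J, K = K, H = H, W = W,
                 nominal = c(H %/% J, W %/% K), tiles = tiles),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d x %d tiles of %d x %d grid, nominal %d x %d\n",
              x$J, x$K, x$H, x$W, x$nominal[1], x$nominal[2]))
  invisible(x)
}

crop_scene <- function(s, row0, col0, height, width) {
  ri <- row0 + seq_len(height); ci <- col0 + seq_len(width)
  scene(s$values[ri, ci, drop = FALSE],
        valid_mask = s$valid_mask[ri, ci, drop = FALSE],
        land_mask = s$land_mask[ri, ci, drop = FALSE],
        timestamp = s$timestamp, sensor_id = s$sensor_id, geo = s$geo)
}

#' Split a scene series into per-tile sub-series
#'
#' @param series a [scene_series] with the plan's parent shape.
#' @param plan a [plan_tiles()] result.
#' @return List of [scene_series], one per tile, in the plan's row-major
#'   tile order.
#' @export
split_series <- function(series, plan) {
  stopifnot(is_scene_series(series), inherits(plan, "tile_plan"))
  d <- dim(series$scenes[[1]]$values)
  if (d[1] != plan$H || d[2] != plan$W) {
    stop("series shape does not match the tile plan")
  }
  lapply(seq_len(nrow(plan$tiles)), function(n) {
    tl <- plan$tiles[n, ]
    scene_series(lapply(series$scenes, crop_scene,
                        row0 = tl$row0, col0 = tl$col0,
                        height = tl$height, width = tl$width))
  })
}

#' Reassemble per-tile sub-series into the parent grid
#'
#' Assembly depends only on each sub-series' tile indices, so tiles may be
#' processed in any order or concurrently.  Each tile of the plan must be
#' supplied exactly once.
#'
#' @param subresults list of [scene_series]; element `n` carries tile `n`
#'   of the plan unless `tile_index` says otherwise.
#' @param plan the [plan_tiles()] result used to split.
#' @param tile_index optional integer vector mapping `subresults` positions
#'   to plan tile rows (for shuffled or out-of-order results).
#' @return The reassembled [scene_series].
#' @export
assemble_series <- function(subresults, plan, tile_index = NULL) {
  stopifnot(inherits(plan, "tile_plan"))
  NS <- nrow(plan$tiles)
  if (is.null(tile_index)) tile_index <- seq_along(subresults)
  if (length(tile_index) != length(subresults)) {
    stop("tile_index must match subresults in length")
  }
  seen <- rep(FALSE, NS)
  for (ti in tile_index) {
    if (ti < 1 || ti > NS) stop("tile index out of range: ", ti)
    if (seen[ti]) {
      stop(sprintf("duplicated tile (j=%d, k=%d)",
                   plan$tiles$j[ti], plan$tiles$k[ti]))
    }
    seen[ti] <- TRUE
  }
  if (!all(seen)) {
    miss <- which(!seen)[1]
    stop(sprintf("missing tile (j=%d, k=%d)",
                 plan$tiles$j[miss], plan$tiles$k[miss]))
  }
  T <- length(subresults[[1]])
  vals <- lapply(seq_len(T), function(t) matrix(NA_real_, plan$H, plan$W))
  vmask <- lapply(seq_len(T), function(t) matrix(FALSE, plan$H, plan$W))
  land <- matrix(FALSE, plan$H, plan$W)
  times <- subresults[[1]]$times
  sid <- subresults[[1]]$scenes[[1]]$sensor_id
  for (n in seq_along(subresults)) {
    tl <- plan$tiles[tile_index[n], ]
    sub <- subresults[[n]]
    if (length(sub) != T) stop("sub-series disagree on T")
    if (!identical(dim(sub$scenes[[1]]$values),
                   c(as.integer(tl$height), as.integer(tl$width)))) {
      stop(sprintf("tile (j=%d, k=%d) has the wrong shape", tl$j, tl$k))
    }
    ri <- tl$row0 + seq_len(tl$height); ci <- tl$col0 + seq_len(tl$width)
    land[ri, ci] <- sub$scenes[[1]]$land_mask
    for (t in seq_len(T)) {
      vals[[t]][ri, ci] <- sub$scenes[[t]]$values
      vmask[[t]][ri, ci] <- sub$scenes[[t]]$valid_mask
    }
  }
  scene_series(lapply(seq_len(T), function(t) {
    scene(vals[[t]], valid_mask = vmask[[t]], land_mask = land,
          timestamp = times[t], sensor_id = sid)
  }))
}

#' Operation-count model for the reconstruction
#'
#' The iterative SVD of the L x T data matrix costs on the order of L*T^2
#' operations per pass, and the mode-validation cycle repeats it up to Q
#' times, giving Q*L*T^2 in total.  Splitting the grid into NS equal tiles
#' divides L, and hence the per-tile count, by NS.
#'
#' @param L number of pixels (grid cells) in the matrix.
#' @param T number of time steps.
#' @param Q maximum number of validation iterations (the `nitemax`
#'   parameter; default 300).
#' @return The operation count `Q * L * T^2` as a double.
#' @export
op_count <- function(L, T, Q = 300) {
  if (any(c(L, T, Q) < 1)) stop("L, T and Q must be positive")
  as.numeric(Q) * as.numeric(L) * as.numeric(T)^2
}
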