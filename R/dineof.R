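# DINEOF engine: EM-style truncated-SVD completion of the L x T space-time
# matrix with cross-validated selection of the number of EOF modes and an
# optional gap-aware diffusion filter on the temporal modes.

#' Unfold a scene series into an L x T data matrix
#'
#' Rows are the sea pixels with at least one valid observation across the
#' series, columns are time steps.  Land pixels and never-observed sea
#' pixels are excluded (the latter listed in `excluded_rows`, as pixel
#' coordinates).  The overall mean of the observed entries is removed, and
#' with `norm = 1` the anomalies are additionally scaled to unit standard
#' deviation; unobserved entries start at 0 in anomaly space.
#'
#' @param series a [scene_series] with `T >= 2`.
#' @param norm 1 to normalise anomalies to unit sd, 0 (default) to leave
#'   them in data units.
#' @return A `data_matrix`: list with `X` (L x T anomalies), `obs_mask`
#'   (L x T logical), `row_index` (L x 2 matrix of pixel row/col),
#'   `center` (scalar mean removed), `scale` (scalar divisor, 1 unless
#'   `norm`), `excluded_rows` (never-observed sea pixels, n x 2),
#'   `land_mask`, `times` and `shape`.
#' @export
build_matrix <- function(series, norm = 0L) {
  stopifnot(is_scene_series(series))
  T <- length(series)
  if (T < 2) stop("need T >= 2 time steps")
  d <- dim(series$scenes[[1]]$values)
  land <- series$scenes[[1]]$land_mask
  sea_idx <- which(!land, arr.ind = TRUE)
  L0 <- nrow(sea_idx)
  X <- matrix(NA_real_, L0, T)
  M <- matrix(FALSE, L0, T)
  flat <- (sea_idx[, 2] - 1L) * d[1] + sea_idx[, 1]
  for (t in seq_len(T)) {
    s <- series$scenes[[t]]
    M[, t] <- s$valid_mask[flat]
    X[, t] <- s$values[flat]
  }
  ever <- rowSums(M) > 0
  if (!any(ever)) stop("series has zero observed sea entries")
  excluded <- sea_idx[!ever, , drop = FALSE]
  X <- X[ever, , drop = FALSE]
  M <- M[ever, , drop = FALSE]
  row_index <- sea_idx[ever, , drop = FALSE]
  ctr <- mean(X[M])
  scl <- 1
  if (norm == 1L) {
    scl <- stats::sd(X[M])
    if (!is.finite(scl) || scl == 0) scl <- 1
  }
  X <- (X - ctr) / scl
  X[!M] <- 0
  structure(list(X = X, obs_mask = M, row_index = row_index,
                 center = ctr, scale = scl, excluded_rows = excluded,
                 land_mask = land, times = series$times, shape = d),
            class = "data_matrix")
}

#' Draw the cross-validation subset of observed entries
#'
#' A seeded uniform random subset of the observed entries, of size
#' `round(cv_fraction * N_obs)`, is flagged for withholding: treated as
#' missing during fitting and used only to score the expected error.  Draws
#' that would strip every observation from some pixel row are repaired by
#' resampling (bounded retries).
#'
#' @param dm a [build_matrix()] result.
#' @param cv_fraction fraction of observed entries to withhold, in
#'   (0, 0.5).
#' @param seed integer RNG seed; the same seed always yields the same mask.
#' @param n_points optional explicit subset size overriding the fraction.
#' @return Logical L x T matrix, `TRUE` at withheld entries.
#' @export
select_cv_points <- function(dm, cv_fraction = 0.01, seed = 243435L,
                             n_points = NULL) {
  stopifnot(inherits(dm, "data_matrix"))
  if (is.null(n_points)) {
    if (cv_fraction <= 0 || cv_fraction >= 0.5) {
      stop("cv_fraction must lie in (0, 0.5)")
    }
    n_points <- round(cv_fraction * sum(dm$obs_mask))
  }
  cv <- matrix(FALSE, nrow(dm$X), ncol(dm$X))
  if (n_points < 1) return(cv)
  obs_idx <- which(dm$obs_mask)
  n_points <- min(n_points, length(obs_idx))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  take <- sample(obs_idx, n_points)
  cv[take] <- TRUE
  # rows must keep at least one fitted observation: release one withheld
  # entry from any fully-withheld row and re-draw it from rows with slack
  for (retry in seq_len(100L)) {
    kept <- dm$obs_mask & !cv
    bad <- which(rowSums(kept) == 0 & rowSums(dm$obs_mask) > 0)
    if (length(bad) == 0) break
    for (r in bad) {
      row_cv <- which(cv[r, ])
      cv[r, row_cv[sample.int(length(row_cv), 1L)]] <- FALSE
      slack <- matrix(rowSums(dm$obs_mask & !cv) > 1, nrow(cv), ncol(cv))
      pool <- which(dm$obs_mask & !cv & slack)
      if (length(pool) > 0) cv[pool[sample.int(length(pool), 1L)]] <- TRUE
    }
  }
  kept <- dm$obs_mask & !cv
  if (any(rowSums(kept) == 0 & rowSums(dm$obs_mask) > 0)) {
    stop("could not withhold a CV subset leaving every row observed")
  }
  cv
}

top_k_svd <- function(X, k) {
  # thin matrices (T << L) make the dense decomposition the fast, robust
  # backend; k only truncates the triplets kept
  sv <- svd(X, nu = k, nv = k)
  list(u = sv$u, d = sv$d[seq_len(k)], v = sv$v)
}

#' Gap-aware diffusion filter on temporal modes
#'
#' Applies `numit` sweeps of a conservative three-point diffusion smoother
#' along the time axis of `V` (T x k temporal modes).  The coupling between
#' consecutive dates scales with the inverse squared date gap (in units of
#' the median gap), so widely separated dates exchange little mass;
#' `alpha` scales all couplings, and the flux form preserves every column
#' sum exactly.  `alpha = 0` or `numit = 0` returns `V` unchanged.
#'
#' @param V numeric T x k matrix (or length-T vector) of temporal modes.
#' @param times the series dates (or any numeric time coordinate).
#' @param alpha filter strength, >= 0.
#' @param numit number of sweeps, >= 0.
#' @return The filtered matrix, same shape as `V`.
#' @export
temporal_filter <- function(V, times, alpha, numit) {
  if (alpha < 0) stop("alpha must be >= 0")
  vec <- is.null(dim(V))
  if (vec) V <- matrix(V, ncol = 1)
  T <- nrow(V)
  if (alpha == 0 || numit == 0 || T < 2) {
    return(if (vec) drop(V) else V)
  }
  dt <- diff(as.numeric(times))
  if (length(dt) != T - 1 || any(dt <= 0)) {
    stop("times must be strictly increasing and match nrow(V)")
  }
  ref <- stats::median(dt)
  cc <- alpha * (ref / dt)^2
  cc <- pmin(cc, 0.45)      # explicit-scheme stability bound
  for (it in seq_len(numit)) {
    flux <- cc * (V[-1, , drop = FALSE] - V[-T, , drop = FALSE])
    V[-T, ] <- V[-T, , drop = FALSE] + flux
    V[-1, ] <- V[-1, , drop = FALSE] - flux
  }
  if (vec) drop(V) else V
}

#' Fixed-rank EM/truncated-SVD completion
#'
#' Iterates: take the rank-`k` truncated SVD of the current matrix, then
#' replace the missing (and withheld) entries by their rank-`k`
#' reconstruction, until the RMS change of those entries, relative to the
#' RMS of the observed anomalies, drops below `toliter` or `nitemax`
#' iterations elapse.  Observed non-withheld entries are never modified.
#'
#' The model is `offset + rank-k`: a scalar offset is re-estimated from
#' the observed residuals each iteration.  The initial centering of
#' [build_matrix()] uses the mean of the observed entries only, which
#' under missingness differs from the true field mean by a sampling
#' offset; left uncorrected, that offset is a rank-one term the
#' truncated SVD would have to spend a mode on.
#'
#' After the cycle stops, each partially observed row is re-projected onto
#' the converged temporal modes by ridge-regularised least squares.  Rows
#' with little redundancy (around `k` observations) make the plain
#' replace-and-decompose cycle contract extremely slowly, and an
#' unregularised solve there amplifies noise without bound; the ridge uses
#' the converged spectrum as the per-mode prior (variance `d_r^2 / L` for
#' mode `r`) and the residual variance of the observed fit as the noise
#' level, so it reduces to the exact projection as the residuals vanish
#' and shrinks ill-determined loadings otherwise.
#'
#' @param dm a [build_matrix()] result.
#' @param k target rank, `1 <= k <= min(L, T)`.
#' @param toliter relative stopping precision.
#' @param nitemax maximum iterations.
#' @param cv_mask optional logical matrix of withheld entries, treated as
#'   missing during the iteration.
#' @param X0 optional warm-start matrix (missing entries pre-filled with
#'   estimates from a previous rank).
#' @param alpha,numit,times optional temporal-filter controls; when
#'   `alpha > 0` the filter is applied to the temporal modes each
#'   iteration before reconstructing.
#' @return List with `X` (completed matrix), `model` (the rank-k-plus-
#'   offset reconstruction of every entry), `n_iter`, `converged`,
#'   `deltas` (per-iteration relative RMS change), `svd` (the final
#'   truncated triplets) and `offset` (the fitted scalar offset).
#' @export
reconstruct_fixed_k <- function(dm, k, toliter = 1e-3, nitemax = 300L,
                                cv_mask = NULL, X0 = NULL,
                                alpha = 0, numit = 0L, times = NULL) {
  stopifnot(inherits(dm, "data_matrix"))
  L <- nrow(dm$X); T <- ncol(dm$X)
  if (k < 1 || k > min(L, T)) stop("k out of range 1..min(L, T)")
  fit_mask <- dm$obs_mask
  if (!is.null(cv_mask)) fit_mask <- fit_mask & !cv_mask
  X <- if (is.null(X0)) dm$X else X0
  X[fit_mask] <- dm$X[fit_mask]       # observed entries are authoritative
  miss <- !fit_mask
  X[miss & is.na(X)] <- 0
  obs_rms <- sqrt(mean(dm$X[fit_mask]^2))
  if (!is.finite(obs_rms) || obs_rms == 0) obs_rms <- 1
  if (is.null(times)) times <- seq_len(T)
  deltas <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  sv <- NULL
  offset <- 0
  for (it in seq_len(nitemax)) {
    n_iter <- it
    sv <- top_k_svd(X - offset, k)
    V <- sv$v
    if (alpha > 0 && numit > 0) V <- temporal_filter(V, times, alpha, numit)
    rec <- sv$u %*% (sv$d * t(V))
    offset <- mean(X[fit_mask] - rec[fit_mask])
    model <- rec + offset
    delta <- if (any(miss)) {
      sqrt(mean((model[miss] - X[miss])^2)) / obs_rms
    } else {
      0
    }
    X[miss] <- model[miss]
    deltas <- c(deltas, delta)
    if (delta < toliter) { converged <- TRUE; break }
  }
  # ridge polish: project each row's missing entries onto the converged
  # temporal modes, shrinking by the noise-to-signal ratio per mode
  V <- sv$v
  if (alpha > 0 && numit > 0) V <- temporal_filter(V, times, alpha, numit)
  rec_fin <- sv$u %*% (sv$d * t(V))
  sigma2 <- mean((dm$X[fit_mask] - (rec_fin + offset)[fit_mask])^2)
  lambda <- sigma2 * L / pmax(sv$d, 1e-12 * max(sv$d, 1))^2
  for (i in seq_len(L)) {
    o <- fit_mask[i, ]
    if (all(o) || !any(o)) next
    Vo <- V[o, , drop = FALSE]
    A <- crossprod(Vo) + diag(lambda, nrow = k)
    beta <- tryCatch(solve(A, crossprod(Vo, X[i, o] - offset)),
                     error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) next
    X[i, !o] <- offset + drop(V[!o, , drop = FALSE] %*% beta)
  }
  list(X = X, model = rec_fin + offset, n_iter = n_iter,
       converged = converged, deltas = deltas, svd = sv, offset = offset)
}

matrix_to_series <- function(dm, X, fill_only = TRUE) {
  T <- ncol(X)
  d <- dm$shape
  vals <- X * dm$scale + dm$center
  scenes <- vector("list", T)
  flat <- (dm$row_index[, 2] - 1L) * d[1] + dm$row_index[, 1]
  for (t in seq_len(T)) {
    v <- matrix(NA_real_, d[1], d[2])
    vm <- matrix(FALSE, d[1], d[2])
    v[flat] <- vals[, t]
    vm[flat] <- TRUE
    scenes[[t]] <- scene(v, valid_mask = vm, land_mask = dm$land_mask,
                         timestamp = dm$times[t], sensor_id = "dineof")
  }
  scene_series(scenes)
}

#' Fill a scene series by DINEOF
#'
#' The full reconstruction: unfold the series ([build_matrix()]), withhold
#' a seeded cross-validation subset ([select_cv_points()]), then for each
#' candidate mode count `k = neini..nev` run the fixed-rank completion
#' ([reconstruct_fixed_k()]), warm-starting from the previous `k`, and
#' score the RMSE on the withheld entries (the expected error).  The scan
#' stops early after two consecutive increases of the expected error; ties
#' prefer the smaller `k`.  A final pass at the selected `k` refits with
#' the withheld entries restored as observations.  Pixels never observed
#' stay missing and are reported in `excluded_rows`.
#'
#' @param series a [scene_series] with `T >= 2`.
#' @param params a [dineof_params].
#' @return A `reconstruction_result`: list with `series` (filled
#'   [scene_series]), `k_selected`, `cv_rmse_by_k` (named numeric, data
#'   units), `iterations_by_k`, `converged` (at the selected k),
#'   `excluded_rows`, `cv_n` and, when `params$eof == 1`, `modes`
#'   (spatial/temporal singular triplets).
#' @export
dineof_fill <- function(series, params = dineof_params()) {
  stopifnot(inherits(params, "dineof_params"))
  dm <- build_matrix(series, norm = params$norm)
  L <- nrow(dm$X); T <- ncol(dm$X)
  kmax <- min(params$nev, L, T)
  if (kmax < params$nev && T <= 2) {
    warning("short series: nev clamped to ", kmax)
  }
  kmin <- min(params$neini, kmax)
  n_obs <- sum(dm$obs_mask)
  n_cv <- round(params$cv_fraction * n_obs)
  n_cv <- min(max(n_cv, 30L), 5000L)
  n_cv <- min(n_cv, floor(n_obs / 2))
  cv <- select_cv_points(dm, seed = params$seed, n_points = n_cv)
  cv_n <- sum(cv)

  cv_rmse <- rep(NA_real_, kmax)
  iters <- rep(NA_integer_, kmax)
  X0 <- NULL
  increases <- 0L
  best_rmse <- Inf
  last_rmse <- Inf
  ks_run <- integer(0)
  for (k in kmin:kmax) {
    fit <- reconstruct_fixed_k(dm, k, toliter = params$toliter,
                               nitemax = params$nitemax, cv_mask = cv,
                               X0 = X0, alpha = params$alpha,
                               numit = params$numit, times = dm$times)
    X0 <- fit$X
    iters[k] <- fit$n_iter
    err <- if (cv_n > 0) {
      sqrt(mean((fit$X[cv] - dm$X[cv])^2)) * dm$scale
    } else {
      NA_real_
    }
    cv_rmse[k] <- err
    ks_run <- c(ks_run, k)
    if (is.finite(err) && err > last_rmse) {
      increases <- increases + 1L
    } else {
      increases <- 0L
    }
    last_rmse <- err
    if (increases >= 2L) break
  }
  evaluated <- cv_rmse[ks_run]
  k_selected <- if (all(!is.finite(evaluated))) {
    kmin
  } else {
    ks_run[which.min(evaluated)]   # first minimum: smaller k wins ties
  }

  # final pass: withheld entries rejoin the observations
  final <- reconstruct_fixed_k(dm, k_selected, toliter = params$toliter,
                               nitemax = params$nitemax, cv_mask = NULL,
                               X0 = X0, alpha = params$alpha,
                               numit = params$numit, times = dm$times)
  Xout <- if (params$rec == 1L) final$model else final$X
  if (params$rec != 1L) {
    Xout[dm$obs_mask] <- dm$X[dm$obs_mask]   # keep observations verbatim
  }
  out <- list(series = matrix_to_series(dm, Xout),
              k_selected = k_selected,
              cv_rmse_by_k = stats::setNames(cv_rmse, seq_len(kmax)),
              iterations_by_k = stats::setNames(iters, seq_len(kmax)),
              converged = final$converged,
              excluded_rows = dm$excluded_rows,
              cv_n = cv_n)
  if (params$eof == 1L) out$modes <- final$svd
  structure(out, class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> k = %d, expected error = %.4g, converged = %s\n",
    x$k_selected, x$cv_rmse_by_k[x$k_selected],
    x$converged))
  invisible(x)
}
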