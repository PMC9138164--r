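#' Gridded scene
#'
#' A `scene` is one dated 2-D grid of a geophysical variable (for example
#' chlorophyll-a concentration in mg m^-3) together with a validity mask and
#' a land mask.  Row 1 is the northernmost row and column 1 the westernmost
#' column, the usual top-left raster convention.
#'
#' @param values numeric H x W matrix.  Entries outside `valid_mask` are
#'   ignored (and stored as `NA`).
#' @param valid_mask logical H x W matrix, `TRUE` where an observation is
#'   present.  If missing, derived as `is.finite(values)`.
#' @param land_mask logical H x W matrix, `TRUE` over land.  Land pixels are
#'   never observations and are never filled.  Defaults to all-`FALSE`.
#' @param timestamp a `Date` (or something coercible to one).
#' @param sensor_id character label of the originating sensor.
#' @param geo optional named list `(lat0, lon0, dlat, dlon)` giving the
#'   centre of pixel (1, 1) and the grid step; carried as metadata only.
#'
#' @return An object of class `scene`.
#' @export
scene <- function(values, valid_mask = NULL, land_mask = NULL,
                  timestamp = as.Date("2000-01-01"), sensor_id = "unknown",
                  geo = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  valid_mask <- as.matrix(valid_mask); storage.mode(valid_mask) <- "logical"
  land_mask  <- as.matrix(land_mask);  storage.mode(land_mask)  <- "logical"
  if (!identical(dim(values), dim(valid_mask)) ||
      !identical(dim(values), dim(land_mask))) {
    stop("values, valid_mask and land_mask must share one shape")
  }
  valid_mask[land_mask] <- FALSE        # land is never an observation
  values[!valid_mask] <- NA_real_
  if (any(!is.finite(values[valid_mask]))) {
    stop("values must be finite wherever valid_mask is TRUE")
  }
  structure(
    list(values = values, valid_mask = valid_mask, land_mask = land_mask,
         timestamp = as.Date(timestamp), sensor_id = as.character(sensor_id),
         geo = geo),
    class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$values)
  sea <- sum(!x$land_mask)
  cat(sprintf("<scene %s [%s]> %d x %d, %.1f%% of %d sea pixels valid\n",
              x$sensor_id, format(x$timestamp), d[1], d[2],
              100 * sum(x$valid_mask) / max(sea, 1), sea))
  invisible(x)
}

#' Fraction of sea pixels carrying data
#'
#' @param x a `scene`.
#' @return Fraction in `[0, 1]` of non-land pixels with a valid observation.
#' @export
scene_coverage <- function(x) {
  stopifnot(inherits(x, "scene"))
  sea <- !x$land_mask
  if (!any(sea)) return(NA_real_)
  sum(x$valid_mask & sea) / sum(sea)
}

#' Time-ordered stack of co-registered scenes
#'
#' All scenes must share one shape and one land mask, and their timestamps
#' must be strictly increasing.
#'
#' @param scenes list of [scene] objects.
#' @return An object of class `scene_series` with elements `scenes` (list)
#'   and `times` (`Date` vector).
#' @export
scene_series <- function(scenes) {
  if (length(scenes) < 1) stop("a scene_series needs at least one scene")
  if (!all(vapply(scenes, inherits, logical(1), "scene"))) {
    stop("all elements must be scene objects")
  }
  d0 <- dim(scenes[[1]]$values)
  lm0 <- scenes[[1]]$land_mask
  for (s in scenes) {
    if (!identical(dim(s$values), d0)) stop("scenes are not co-registered")
    if (!identical(s$land_mask, lm0)) stop("scenes disagree on the land mask")
  }
  times <- as.Date(vapply(scenes, function(s) as.character(s$timestamp),
                          character(1)))
  if (length(times) > 1 && any(diff(as.numeric(times)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  structure(list(scenes = scenes, times = times), class = "scene_series")
}

#' @export
length.scene_series <- function(x) length(x$scenes)

#' @export
print.scene_series <- function(x, ...) {
  d <- dim(x$scenes[[1]]$values)
  cat(sprintf("<scene_series> T=%d, %d x %d, %s .. %s\n",
              length(x$scenes), d[1], d[2],
              format(min(x$times)), format(max(x$times))))
  invisible(x)
}

#' @rdname scene_series
#' @param x object to test.
#' @export
is_scene_series <- function(x) inherits(x, "scene_series")

#' DINEOF parameter set
#'
#' Collects the tunable parameters of the DINEOF reconstruction.  Defaults
#' are the standard operational values: up to `nev = 20` EOF modes examined
#' starting from `neini = 1`, Lanczos controls `ncv = 35` and
#' `tol = 1e-8` (advisory hints for iterative SVD backends), at most
#' `nitemax = 300` stabilisation iterations per mode count with stopping
#' precision `toliter = 1e-3`, temporal-filter strength `alpha` (0 disables
#' the filter) applied for `numit` sweeps, and RNG `seed = 243435` for the
#' cross-validation draw.
#'
#' @param alpha filter strength, real >= 0.  0 disables temporal filtering.
#' @param numit number of filter iterations, integer >= 0.
#' @param nev maximum number of EOF modes examined.
#' @param neini minimum number of EOF modes examined (>= 1, <= `nev`).
#' @param ncv Krylov subspace size hint (> `nev`); advisory.
#' @param tol SVD convergence tolerance; advisory.
#' @param nitemax maximum iterations of the fill-SVD cycle per mode count.
#' @param toliter relative precision at which the cycle stops.
#' @param rec if 1, the rank-k reconstruction replaces every entry (full
#'   smoothing); if 0 (default), only missing entries are filled.
#' @param eof if 1, spatial and temporal modes are kept on the result.
#' @param norm if 1, anomalies are scaled to unit standard deviation before
#'   decomposition and rescaled afterwards.
#' @param seed RNG seed for the cross-validation subset.
#' @param cv_fraction fraction of observed entries withheld for
#'   cross-validated mode selection, in (0, 0.5).
#'
#' @return An object of class `dineof_params`.
#' @export
dineof_params <- function(alpha = 0, numit = 0, nev = 20L, neini = 1L,
                          ncv = 35L, tol = 1.0e-8, nitemax = 300L,
                          toliter = 1.0e-3, rec = 0L, eof = 0L, norm = 0L,
                          seed = 243435L, cv_fraction = 0.01) {
  p <- list(alpha = as.numeric(alpha), numit = as.integer(numit),
            nev = as.integer(nev), neini = as.integer(neini),
            ncv = as.integer(ncv), tol = as.numeric(tol),
            nitemax = as.integer(nitemax), toliter = as.numeric(toliter),
            rec = as.integer(rec), eof = as.integer(eof),
            norm = as.integer(norm), seed = as.integer(seed),
            cv_fraction = as.numeric(cv_fraction))
  if (p$alpha < 0) stop("alpha must be >= 0")
  if (p$numit < 0) stop("numit must be >= 0")
  if (p$neini < 1 || p$neini > p$nev) stop("need 1 <= neini <= nev")
  if (p$ncv <= p$nev) stop("ncv must exceed nev")
  if (p$tol <= 0 || p$toliter <= 0) stop("tol and toliter must be > 0")
  if (p$nitemax < 1) stop("nitemax must be >= 1")
  if (p$cv_fraction <= 0 || p$cv_fraction >= 0.5) {
    stop("cv_fraction must lie in (0, 0.5)")
  }
  structure(p, class = "dineof_params")
}

#' @export
print.dineof_params <- function(x, ...) {
  cat("<dineof_params>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
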