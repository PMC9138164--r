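#' Write a scene series to NetCDF
#'
#' One 3-D variable `value(x, y, time)` with a declared `_FillValue`, a byte
#' variable `land_mask(x, y)` (1 = land), and a `time` coordinate in days
#' since 1970-01-01.  Missing sea pixels are stored as the fill value.
#'
#' @param series a [scene_series].
#' @param path output file path.
#' @param varname name for the data variable.
#' @param fill_value numeric fill value declared on the variable.
#' @return `path`, invisibly.
#' @export
write_netcdf <- function(series, path, varname = "value",
                         fill_value = -999.0) {
  stopifnot(is_scene_series(series))
  d <- dim(series$scenes[[1]]$values)
  H <- d[1]; W <- d[2]
  dim_x <- ncdf4::ncdim_def("x", "pixel", seq_len(W))
  dim_y <- ncdf4::ncdim_def("y", "pixel", seq_len(H))
  dim_t <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(series$times), unlim = TRUE)
  var_v <- ncdf4::ncvar_def(varname, "", list(dim_x, dim_y, dim_t),
                            missval = fill_value, prec = "double")
  var_m <- ncdf4::ncvar_def("land_mask", "", list(dim_x, dim_y),
                            prec = "integer")
  nc <- ncdf4::nc_create(path, list(var_v, var_m))
  on.exit(ncdf4::nc_close(nc))
  arr <- array(fill_value, dim = c(W, H, length(series$scenes)))
  for (t in seq_along(series$scenes)) {
    s <- series$scenes[[t]]
    v <- s$values
    v[!s$valid_mask] <- fill_value
    arr[, , t] <- t(v)                 # (row, col) -> (x, y)
  }
  ncdf4::ncvar_put(nc, var_v, arr)
  ncdf4::ncvar_put(nc, var_m, t(series$scenes[[1]]$land_mask) * 1L)
  sid <- vapply(series$scenes, function(s) s$sensor_id, character(1))
  ncdf4::ncatt_put(nc, 0, "sensor_id", paste(sid, collapse = ","))
  invisible(path)
}

#' Read a scene series from NetCDF
#'
#' Accepts a 2-D or 3-D variable.  Cells at the variable's declared
#' `_FillValue`/`missing_value` (or non-finite, when no fill attribute is
#' declared) become missing.  A `land_mask` variable is honoured when
#' present; otherwise the land mask is all-`FALSE`.
#'
#' @param path NetCDF file path.
#' @param varname variable to read; by default the first variable that is
#'   not named `land_mask`.
#' @return A [scene_series].
#' @export
read_netcdf <- function(path, varname = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vnames <- names(nc$var)
  if (is.null(varname)) {
    varname <- setdiff(vnames, "land_mask")[1]
    if (is.na(varname)) stop("file has no data variable")
  }
  if (!varname %in% vnames) {
    stop("variable '", varname, "' not found in ", path)
  }
  arr <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  # ncvar_get already maps the declared fill value to NA
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3) stop("variable must be 2-D or 3-D")
  W <- dim(arr)[1]; H <- dim(arr)[2]; T <- dim(arr)[3]

  if ("time" %in% names(nc$dim)) {
    times <- as.Date(nc$dim$time$vals, origin = "1970-01-01")
  } else {
    times <- as.Date("2000-01-01") + seq_len(T) - 1
  }
  if (T > 1 && any(diff(as.numeric(times)) <= 0)) {
    stop("time axis is not strictly increasing")
  }
  land <- if ("land_mask" %in% vnames) {
    t(ncdf4::ncvar_get(nc, "land_mask", collapse_degen = FALSE)[, , drop = TRUE]) > 0
  } else {
    matrix(FALSE, H, W)
  }
  dim(land) <- c(H, W)
  sid <- ncdf4::ncatt_get(nc, 0, "sensor_id")
  sids <- if (sid$hasatt) strsplit(sid$value, ",")[[1]] else rep("unknown", T)
  if (length(sids) != T) sids <- rep(sids[1], T)

  scenes <- vector("list", T)
  for (t in seq_len(T)) {
    v <- t(arr[, , t])
    dim(v) <- c(H, W)
    scenes[[t]] <- scene(v, valid_mask = is.finite(v) & !land,
                         land_mask = land, timestamp = times[t],
                         sensor_id = sids[t])
  }
  scene_series(scenes)
}
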