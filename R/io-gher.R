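# GHER-dialect binary I/O.
#
# The dialect implemented here is record-framed in the Fortran unformatted
# sequential style: every record is preceded and followed by its byte count
# as a 4-byte little-endian integer.  Record 1 is the header of five 4-byte
# integers (imax = width, jmax = height, kmax = time steps, iprec = 4 for
# single precision, nbmots = words per data record).  Records 2..kmax+1 each
# hold one time step as imax*jmax IEEE-754 single-precision values, x
# varying fastest, row 1 (north) first.  Land and missing cells are encoded
# in-band as the exclusion value.

write_record <- function(con, raw_or_num, what) {
  if (what == "integer") {
    payload <- writeBin(as.integer(raw_or_num), raw(), size = 4L,
                        endian = "little")
  } else {
    payload <- writeBin(as.numeric(raw_or_num), raw(), size = 4L,
                        endian = "little")
  }
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4L, endian = "little")
}

read_record <- function(con, what, n) {
  len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(len) == 0) stop("unexpected end of GHER file")
  out <- readBin(con, what, n, size = 4L, endian = "little")
  len2 <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(len, len2)) stop("corrupt GHER record framing")
  out
}

#' Round a numeric vector or matrix to single precision
#'
#' Utility for predicting exactly what the single-precision GHER writer
#' will store.
#'
#' @param x numeric vector or matrix.
#' @return `x` with every value replaced by its nearest float32.
#' @export
as_float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               length(x), size = 4L)
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' Write a scene series as GHER-dialect binary plus time file
#'
#' Masked cells (land and missing alike) are encoded in-band as
#' `exclusion_value`.  The time file is plain text with one numeric day
#' offset per step, relative to the first timestamp; these offsets drive
#' the gap-aware temporal covariance filter.  Because land and missing
#' cells share one in-band code, pass `mask_path` to also write the land
#' mask (1 = land) as a companion GHER file when the distinction must
#' survive a round trip.
#'
#' @param series a [scene_series].
#' @param data_path output path for the value file.
#' @param time_path output path for the time file.
#' @param exclusion_value sentinel encoding masked cells; must not occur as
#'   a genuine observation.
#' @param mask_path optional output path for the land-mask file.
#' @return `data_path`, invisibly.
#' @export
write_gher <- function(series, data_path, time_path,
                       exclusion_value = 9999.0, mask_path = NULL) {
  stopifnot(is_scene_series(series))
  excl32 <- as_float32(exclusion_value)
  for (s in series$scenes) {
    if (any(as_float32(s$values[s$valid_mask]) == excl32)) {
      stop("exclusion_value ", exclusion_value,
           " occurs as a genuine data value; choose another sentinel")
    }
  }
  d <- dim(series$scenes[[1]]$values)
  H <- d[1]; W <- d[2]; T <- length(series$scenes)
  con <- file(data_path, "wb")
  on.exit(close(con))
  write_record(con, c(W, H, T, 4L, W * H), "integer")
  for (s in series$scenes) {
    v <- s$values
    v[!s$valid_mask] <- exclusion_value
    write_record(con, as.vector(t(v)), "numeric")   # x fastest
  }
  offs <- as.numeric(series$times - series$times[1])
  writeLines(format(offs, trim = TRUE, scientific = FALSE), time_path)
  if (!is.null(mask_path)) {
    mcon <- file(mask_path, "wb")
    on.exit(close(mcon), add = TRUE)
    write_record(mcon, c(W, H, 1L, 4L, W * H), "integer")
    write_record(mcon, as.vector(t(series$scenes[[1]]$land_mask * 1)),
                 "numeric")
  }
  invisible(data_path)
}

#' Read a GHER-dialect binary plus time file
#'
#' @param data_path value file written by [write_gher()].
#' @param time_path companion time file of day offsets.
#' @param exclusion_value sentinel marking masked cells.
#' @param mask_path optional companion land-mask file; without it all
#'   excluded cells are treated as missing sea.
#' @param origin calendar date of offset 0.
#' @param sensor_id label attached to every scene.
#' @return A [scene_series].
#' @export
read_gher <- function(data_path, time_path, exclusion_value = 9999.0,
                      mask_path = NULL, origin = as.Date("2000-01-01"),
                      sensor_id = "gher") {
  con <- file(data_path, "rb")
  on.exit(close(con))
  hdr <- read_record(con, "integer", 5L)
  W <- hdr[1]; H <- hdr[2]; T <- hdr[3]
  if (hdr[4] != 4L) stop("unsupported precision code: ", hdr[4])
  offs <- scan(time_path, what = numeric(), quiet = TRUE)
  if (length(offs) != T) stop("time file length does not match kmax")
  times <- origin + offs
  land <- matrix(FALSE, H, W)
  if (!is.null(mask_path)) {
    mcon <- file(mask_path, "rb")
    on.exit(close(mcon), add = TRUE)
    mh <- read_record(mcon, "integer", 5L)
    if (mh[1] != W || mh[2] != H) stop("mask file shape mismatch")
    land <- matrix(read_record(mcon, "numeric", W * H) > 0.5, H, W,
                   byrow = TRUE)
  }
  excl32 <- as_float32(exclusion_value)
  scenes <- vector("list", T)
  for (t in seq_len(T)) {
    v <- matrix(read_record(con, "numeric", W * H), H, W, byrow = TRUE)
    valid <- (v != excl32) & !land
    v[!valid] <- NA_real_
    scenes[[t]] <- scene(v, valid_mask = valid, land_mask = land,
                         timestamp = times[t], sensor_id = sensor_id)
  }
  scene_series(scenes)
}

#' Write a DINEOF init file
#'
#' Emits the line-oriented `key = value` parameter file consumed by the
#' reconstruction driver: the full [dineof_params] set plus input/output
#' paths.
#'
#' @param params a [dineof_params].
#' @param path output path for the init file.
#' @param paths named character vector/list of file paths (for example
#'   `data`, `mask`, `time`, `output`) to record alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_init_file <- function(params, path, paths = NULL) {
  stopifnot(inherits(params, "dineof_params"))
  fmt <- function(v) {
    if (is.numeric(v) && v == round(v) && abs(v) < 2^31) {
      format(as.integer(v))
    } else {
      format(v, scientific = TRUE)
    }
  }
  lines <- vapply(names(unclass(params)),
                  function(nm) sprintf("%s = %s", nm, fmt(params[[nm]])),
                  character(1))
  if (!is.null(paths)) {
    lines <- c(lines, sprintf("%s = '%s'", names(paths), unlist(paths)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a DINEOF init file back into a parameter set
#'
#' @param path init file written by [write_init_file()].
#' @return A list with elements `params` (a [dineof_params]) and `paths`
#'   (named character vector of any path entries).
#' @export
read_init_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  pnames <- names(unclass(dineof_params()))
  is_path <- grepl("^'.*'$", vals) | !(keys %in% pnames)
  paths <- gsub("^'|'$", "", vals[is_path])
  names(paths) <- keys[is_path]
  args <- as.list(as.numeric(vals[!is_path]))
  names(args) <- keys[!is_path]
  list(params = do.call(dineof_params, args), paths = paths)
}
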