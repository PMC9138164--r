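# Same-day multi-sensor merge: base selection, RMSE-priority donor
# ordering, pixel substitution, and IDW seam adjustment.

#' Pick the base image among same-day scenes
#'
#' The base image is the scene with the most valid sea pixels; ties go to
#' the lowest index.
#'
#' @param scenes list of co-registered [scene] objects for one day.
#' @return Integer index of the base scene.
#' @export
select_base <- function(scenes) {
  if (length(scenes) < 1) stop("need at least one scene")
  counts <- vapply(scenes, function(s) sum(s$valid_mask & !s$land_mask),
                   numeric(1))
  which.max(counts)           # which.max returns the first maximum
}

#' Rank donor scenes by RMSE against the base
#'
#' For each donor, RMSE is computed over the N pixels valid in both the
#' base and that donor: `sqrt(sum((base - donor)^2) / N)`.  Donors are
#' ordered by ascending RMSE, so the donor most consistent with the base
#' gets the highest substitution priority.  A donor sharing no valid pixel
#' with the base gets infinite RMSE and last priority.
#'
#' @param base the base [scene].
#' @param donors list of donor [scene] objects.
#' @return A `merge_plan`: list with `donor_order` (indices into `donors`,
#'   by priority) and `rmse_values` (per donor, unsorted).
#' @export
rank_donors <- function(base, donors) {
  stopifnot(inherits(base, "scene"))
  rmse_values <- vapply(donors, function(d) {
    both <- base$valid_mask & d$valid_mask
    if (!any(both)) return(Inf)
    sqrt(mean((base$values[both] - d$values[both])^2))
  }, numeric(1))
  structure(list(donor_order = order(rmse_values),
                 rmse_values = rmse_values),
            class = "merge_plan")
}

#' Merge donor scenes into the base
#'
#' Base pixels are kept verbatim.  Each missing sea pixel of the base takes
#' the value of the highest-priority donor that is valid there; a pixel
#' missing in every input stays missing.  A provenance map records, per
#' pixel, where its value came from: 0 = base, k > 0 = donor k, -1 =
#' unfilled sea, -2 = land.
#'
#' @param base the base [scene].
#' @param plan a `merge_plan` from [rank_donors()].
#' @param donors the donor list the plan was built from.
#' @return List with `scene` (merged [scene]) and `provenance` (integer
#'   matrix as above).
#' @export
merge_scenes <- function(base, plan, donors) {
  stopifnot(inherits(plan, "merge_plan"))
  d0 <- dim(base$values)
  for (d in donors) {
    if (!identical(dim(d$values), d0)) stop("donor shape mismatch")
  }
  values <- base$values
  valid <- base$valid_mask
  prov <- matrix(-1L, d0[1], d0[2])
  prov[base$land_mask] <- -2L
  prov[valid] <- 0L
  for (k in plan$donor_order) {
    d <- donors[[k]]
    take <- !valid & !base$land_mask & d$valid_mask
    values[take] <- d$values[take]
    valid[take] <- TRUE
    prov[take] <- k
  }
  merged <- scene(values, valid_mask = valid, land_mask = base$land_mask,
                  timestamp = base$timestamp,
                  sensor_id = paste0(base$sensor_id, "+merged"),
                  geo = base$geo)
  list(scene = merged, provenance = prov)
}

#' IDW seam adjustment of donor-sourced pixels
#'
#' Differences in acquisition time and conditions leave visible seams
#' between base and donor regions.  For every donor-sourced pixel the
#' nearest base-sourced valid pixel is located along each of the four axis
#' directions (-x, +x, -y, +y) within `max_radius` pixels; the adjusted
#' value blends the donor value v (weight 1) with those base values b_i
#' weighted by inverse distance: `(v + sum(b_i / d_i^power)) /
#' (1 + sum(1 / d_i^power))`.  A donor pixel with no base neighbour in
#' range is left unchanged, and base pixels are never modified, so the
#' adjustment pulls donor values toward the base field only near seams.
#'
#' @param merged merged [scene] from [merge_scenes()].
#' @param provenance its provenance matrix.
#' @param power IDW exponent (> 0, default 2: squared-distance weights).
#' @param max_radius search radius along each axis, in pixels.
#' @return The adjusted [scene].
#' @export
idw_adjust <- function(merged, provenance, power = 2, max_radius = 10L) {
  stopifnot(inherits(merged, "scene"))
  if (power <= 0) stop("power must be > 0")
  H <- nrow(merged$values); W <- ncol(merged$values)
  is_base <- provenance == 0L
  out <- merged$values
  idx <- which(provenance > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(merged)
  for (n in seq_len(nrow(idx))) {
    i <- idx[n, 1]; j <- idx[n, 2]
    wsum <- 1; vsum <- merged$values[i, j]
    for (dir in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      for (d in seq_len(max_radius)) {
        ii <- i + dir[1] * d; jj <- j + dir[2] * d
        if (ii < 1L || ii > H || jj < 1L || jj > W) break
        if (is_base[ii, jj]) {
          w <- 1 / d^power
          wsum <- wsum + w
          vsum <- vsum + w * merged$values[ii, jj]
          break
        }
      }
    }
    out[i, j] <- vsum / wsum
  }
  scene(out, valid_mask = merged$valid_mask, land_mask = merged$land_mask,
        timestamp = merged$timestamp, sensor_id = merged$sensor_id,
        geo = merged$geo)
}

#' Full same-day fusion of a list of sensor scenes
#'
#' Convenience wrapper: select the base, rank the remaining scenes as
#' donors, substitute, and IDW-adjust the seams.
#'
#' @param scenes list of co-registered same-day [scene] objects.
#' @param power,max_radius passed to [idw_adjust()].
#' @return List with `scene`, `provenance`, `base_index` and `plan`.
#' @export
fuse_day <- function(scenes, power = 2, max_radius = 10L) {
  b <- select_base(scenes)
  donors <- scenes[-b]
  plan <- rank_donors(scenes[[b]], donors)
  m <- merge_scenes(scenes[[b]], plan, donors)
  adj <- idw_adjust(m$scene, m$provenance, power, max_radius)
  list(scene = adj, provenance = m$provenance, base_index = b, plan = plan)
}
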