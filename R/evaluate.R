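# Evaluation harness: masked RMSE scoring, the cloud-coverage x tile-size
# experiment, and the alpha/numit/time-window hyper-parameter sweep.

#' RMSE between two scenes over an evaluation mask
#'
#' Root-mean-square difference over the pixels of `eval_mask` that carry a
#' valid reference value.  An empty evaluation set yields `NA`, never an
#' error.
#'
#' @param reference truth [scene].
#' @param estimate reconstructed [scene].
#' @param eval_mask logical matrix selecting the scored pixels; defaults
#'   to all pixels valid in both scenes.
#' @return A single numeric RMSE, or `NA` if no pixel qualifies.
#' @export
scene_rmse <- function(reference, estimate, eval_mask = NULL) {
  stopifnot(inherits(reference, "scene"), inherits(estimate, "scene"))
  if (is.null(eval_mask)) {
    eval_mask <- reference$valid_mask & estimate$valid_mask
  }
  ok <- eval_mask & reference$valid_mask & estimate$valid_mask
  if (!any(ok)) return(NA_real_)
  sqrt(mean((reference$values[ok] - estimate$values[ok])^2))
}

#' Run a tiled DINEOF fill over a series
#'
#' Splits the series by `plan`, fills each tile independently, and
#' reassembles.  Tiles with no usable data (all land, or no observed sea
#' entry) pass through unchanged.
#'
#' @param series a [scene_series].
#' @param plan a [plan_tiles()] result (or `NULL` for whole-image fill).
#' @param params a [dineof_params].
#' @return List with `series` (filled) and `tile_results` (per-tile
#'   [dineof_fill()] results, `NULL` where a tile was passed through).
#' @export
tiled_fill <- function(series, plan = NULL, params = dineof_params()) {
  if (is.null(plan)) {
    res <- dineof_fill(series, params)
    return(list(series = res$series, tile_results = list(res)))
  }
  subs <- split_series(series, plan)
  results <- vector("list", length(subs))
  filled <- vector("list", length(subs))
  for (n in seq_along(subs)) {
    sub <- subs[[n]]
    n_obs <- sum(vapply(sub$scenes, function(s) sum(s$valid_mask),
                        numeric(1)))
    if (n_obs == 0) {               # all-land or never-observed tile
      filled[[n]] <- sub
      next
    }
    p <- params
    Lsub <- sum(!sub$scenes[[1]]$land_mask)
    kcap <- max(1L, min(p$nev, Lsub, length(sub)))
    if (kcap < p$nev) {
      p$nev <- kcap
      p$neini <- min(p$neini, kcap)
      p$ncv <- max(p$ncv, p$nev + 1L)
    }
    res <- dineof_fill(sub, p)
    results[[n]] <- res
    # carry unfilled (never-observed) pixels through as missing
    filled[[n]] <- res$series
  }
  list(series = assemble_series(filled, plan), tile_results = results)
}

#' Cloud-coverage x tile-size experiment
#'
#' For every combination of cloud coverage, tile specification and seed:
#' corrupt the hole-free truth series with seeded correlated cloud masks
#' (an independent mask per time step), run the tiled fill, and score the
#' RMSE on the clouded pixels only (the only pixels whose truth was
#' hidden).  Cells whose tile exceeds `max_cells` pixels per tile series
#' are recorded as infeasible rather than run.
#'
#' @param truth_series hole-free [scene_series] (e.g. monthly composites).
#' @param coverages numeric vector of cloud fractions, e.g.
#'   `c(0.2, 0.3, 0.5)`.
#' @param tile_specs list of tile specifications: each either `NULL`
#'   (whole image) or a list with `J` and `K` (or `halvings`).
#' @param params a [dineof_params].
#' @param seeds integer vector of replicate seeds.
#' @param corr_length cloud blob scale in pixels.
#' @param max_cells per-tile memory budget in matrix cells (`L * T`);
#'   `Inf` disables the check.
#' @return A data frame with one row per (coverage, tile spec) cell:
#'   mean/sd RMSE, mean/sd elapsed seconds, replicate count, feasibility.
#' @export
cloud_experiment <- function(truth_series, coverages, tile_specs, params,
                             seeds = 1:10, corr_length = 6,
                             max_cells = Inf) {
  stopifnot(is_scene_series(truth_series))
  d <- dim(truth_series$scenes[[1]]$values)
  land <- truth_series$scenes[[1]]$land_mask
  rows <- list()
  for (cov in coverages) {
    for (si in seq_along(tile_specs)) {
      spec <- tile_specs[[si]]
      plan <- if (is.null(spec)) NULL else {
        do.call(plan_tiles, c(list(H = d[1], W = d[2]), spec))
      }
      label <- if (is.null(plan)) "whole" else {
        sprintf("%dx%d", plan$J, plan$K)
      }
      tile_cells <- if (is.null(plan)) {
        prod(d) * length(truth_series)
      } else {
        max(plan$tiles$height * plan$tiles$width) * length(truth_series)
      }
      if (tile_cells > max_cells) {
        rows[[length(rows) + 1L]] <- data.frame(
          coverage_pct = 100 * cov, tiles = label, feasible = FALSE,
          rmse_mean = NA_real_, rmse_sd = NA_real_,
          time_mean = NA_real_, time_sd = NA_real_, replicates = 0L)
        next
      }
      rmses <- numeric(0); times <- numeric(0)
      for (sd_i in seeds) {
        masks <- lapply(seq_along(truth_series$scenes), function(t) {
          gen_cloud_mask(d[1], d[2], cov, corr_length,
                         seed = sd_i * 1000L + t, land_mask = land)
        })
        corrupted <- scene_series(lapply(
          seq_along(truth_series$scenes), function(t) {
            s <- truth_series$scenes[[t]]
            valid <- s$valid_mask & !masks[[t]]
            v <- s$values
            v[!valid] <- NA_real_
            scene(v, valid_mask = valid, land_mask = land,
                  timestamp = s$timestamp, sensor_id = s$sensor_id)
          }))
        t0 <- proc.time()[["elapsed"]]
        fill <- tiled_fill(corrupted, plan, params)
        el <- proc.time()[["elapsed"]] - t0
        if (cov == 0) {
          r <- 0                       # nothing was hidden, nothing to score
        } else {
          errs2 <- numeric(0)
          for (t in seq_along(truth_series$scenes)) {
            sc <- masks[[t]] & truth_series$scenes[[t]]$valid_mask &
              fill$series$scenes[[t]]$valid_mask
            if (any(sc)) {
              errs2 <- c(errs2,
                         (fill$series$scenes[[t]]$values[sc] -
                            truth_series$scenes[[t]]$values[sc])^2)
            }
          }
          r <- if (length(errs2)) sqrt(mean(errs2)) else NA_real_
        }
        rmses <- c(rmses, r); times <- c(times, el)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        coverage_pct = 100 * cov, tiles = label, feasible = TRUE,
        rmse_mean = mean(rmses, na.rm = TRUE),
        rmse_sd = if (length(rmses) > 1) stats::sd(rmses, na.rm = TRUE)
                  else NA_real_,
        time_mean = mean(times),
        time_sd = if (length(times) > 1) stats::sd(times) else NA_real_,
        replicates = length(seeds))
    }
  }
  do.call(rbind, rows)
}

#' Hyper-parameter sweep over zones, filter settings and window length
#'
#' For each zone tile of `zone_plan` and each combination of `alpha`,
#' `numit` and time-window length, the series is truncated to its most
#' recent `time` steps, filled by DINEOF, and the cross-validated expected
#' error at the selected mode count is recorded — the per-zone error grid
#' used to pick the filter settings.
#'
#' @param series a [scene_series].
#' @param zone_plan a [plan_tiles()] result defining the zones (for
#'   example 2 x 3).
#' @param alphas numeric vector of filter strengths.
#' @param numits integer vector of filter iteration counts.
#' @param time_windows integer vector of window lengths in time steps.
#' @param params base [dineof_params]; `alpha`/`numit` are overridden per
#'   cell.
#' @return A data frame with columns `zone`, `alpha`, `numit`, `time`,
#'   `expected_error`, `k_selected`, `elapsed`.
#' @export
hyperparam_sweep <- function(series, zone_plan, alphas, numits,
                             time_windows, params = dineof_params()) {
  stopifnot(is_scene_series(series), inherits(zone_plan, "tile_plan"))
  zones <- split_series(series, zone_plan)
  rows <- list()
  for (z in seq_along(zones)) {
    for (tw in time_windows) {
      T <- length(zones[[z]])
      keep <- max(1L, T - tw + 1L):T
      sub <- scene_series(zones[[z]]$scenes[keep])
      for (a in alphas) {
        for (nit in numits) {
          p <- params
          p$alpha <- a; p$numit <- as.integer(nit)
          Lsub <- sum(!sub$scenes[[1]]$land_mask)
          kcap <- max(1L, min(p$nev, Lsub, length(sub)))
          p$nev <- kcap; p$neini <- min(p$neini, kcap)
          p$ncv <- max(p$ncv, p$nev + 1L)
          t0 <- proc.time()[["elapsed"]]
          res <- dineof_fill(sub, p)
          rows[[length(rows) + 1L]] <- data.frame(
            zone = z, alpha = a, numit = nit, time = tw,
            expected_error = unname(res$cv_rmse_by_k[res$k_selected]),
            k_selected = res$k_selected,
            elapsed = proc.time()[["elapsed"]] - t0)
        }
      }
    }
  }
  do.call(rbind, rows)
}
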