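# Pixel-size calibration: fit an ensemble of seed models into the target
# map relabelled at candidate pixel sizes and pick the size with the best
# mean stereochemical score; plus the per-axis radius-of-gyration
# anisotropy diagnostic.

#' Generate seed models from an unbiased simulation
#'
#' Runs the unbiased (no density term) Langevin dynamics of the restraint
#' potential and takes snapshots at evenly spaced times, mirroring the use
#' of starting models drawn from an unrestrained simulation. With seven
#' seeds this reproduces the published calibration ensemble.
#'
#' @param model an [atomic_model()].
#' @param topo the matching [build_topology()].
#' @param n_seeds number of seed models (>= 2; the reference protocol uses
#'   7).
#' @param config a [fit_config()]; supplies the seed, temperature, timestep
#'   and friction.
#' @param spacing time between snapshots, ps.
#' @return list of `n_seeds` atomic models.
#' @export
generate_seed_models <- function(model, topo, n_seeds = 7, config,
                                 spacing = 2) {
  stopifnot(inherits(model, "atomic_model"), inherits(topo, "topology"),
            inherits(config, "fit_config"))
  if (n_seeds < 2) stop("n_seeds must be >= 2")
  ra <- restraint_args(model, topo, k_rep = config$k_rep)
  dt <- config$timestep
  per <- max(1L, round(spacing / dt))
  noise_sd <- sqrt(2 * KB_KJ_MOL_K * config$temperature * dt / config$gamma)
  mob <- dt / config$gamma
  n <- n_atoms(model)
  seeds <- with_seed(config$seed, {
    x <- model$coords
    out <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      for (step in seq_len(per)) {
        f <- restraint_forces(x, ra)$forces
        x <- x + f * mob
        if (noise_sd > 0) x <- x + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
      }
      out[[s]] <- set_coords(model, x)
    }
    out
  })
  if (n_seeds >= 2) {
    rms <- vapply(seq_len(n_seeds - 1), function(s)
      rmsd(seeds[[s]], seeds[[s + 1]]), numeric(1))
    if (any(rms == 0))
      warning("degenerate dynamics: consecutive seed models are identical")
  }
  seeds
}

#' Schedule or run a pixel-size calibration scan
#'
#' For every combination of seed model and candidate pixel size the target
#' map is relabelled ([relabel_pixel_size()]), the spread width is
#' recomputed from the candidate pixel size, the seed is rigid-body aligned
#' and fitted ([run_fit()]), the best frame within the FSC-average plateau
#' is selected, and its stereochemical quality is recorded. The pixel size
#' with the lowest mean score over seeds is the calibration estimate.
#' A failing run is recorded as `NA` with a warning and excluded from that
#' pixel's mean.
#'
#' @param seeds list of seed [atomic_model()]s (>= 2), e.g. from
#'   [generate_seed_models()].
#' @param topo the seeds' common [build_topology()].
#' @param target target `density_map`.
#' @param pixel_grid candidate pixel sizes in Å (>= 2 values, or 1 for a
#'   degenerate scan). The reference protocol scans 0.80–0.86 in 0.01
#'   steps.
#' @param config a [fit_config()]; per-run seeds are derived
#'   deterministically from `config$seed`.
#' @param epsilon plateau tolerance passed to [select_best_frame()].
#' @param dry_run if `TRUE`, only the run schedule (a data.frame with one
#'   row per planned fitting run) is returned; nothing is fitted.
#' @return a `calibration_result`: `pixel_sizes`, `scores` (seed x pixel
#'   matrix), `mean_score`, `se_score` (sd/sqrt(n)), `n_runs`, and
#'   `selected_pixel` (the pixel size with minimal mean score).
#' @export
run_pixel_scan <- function(seeds, topo, target,
                           pixel_grid = seq(0.80, 0.86, by = 0.01), config,
                           epsilon = 0.01, dry_run = FALSE) {
  stopifnot(is.list(seeds), length(seeds) >= 1,
            inherits(target, "density_map"), inherits(config, "fit_config"))
  if (length(pixel_grid) < 1) stop("empty pixel grid")
  schedule <- expand.grid(seed_index = seq_along(seeds),
                          pixel_size = pixel_grid)
  schedule$run_seed <- config$seed + schedule$seed_index +
    1000L * match(schedule$pixel_size, pixel_grid)
  if (dry_run) return(schedule)
  if (length(seeds) < 2) stop("need >= 2 seed models")

  scores <- matrix(NA_real_, length(seeds), length(pixel_grid),
                   dimnames = list(NULL, sprintf("%.3g", pixel_grid)))
  for (pi in seq_along(pixel_grid)) {
    p <- pixel_grid[pi]
    tgt <- normalize_map(relabel_pixel_size(target, p))
    par <- spread_params(spread_width(p))
    for (si in seq_along(seeds)) {
      row <- schedule$seed_index == si & schedule$pixel_size == p
      cfg <- config
      cfg$seed <- as.integer(schedule$run_seed[row][1] %% .Machine$integer.max)
      scores[si, pi] <- tryCatch({
        ali <- rigid_body_align(seeds[[si]], tgt, par, global = FALSE)
        traj <- run_fit(ali$model, topo, tgt, cfg, par)
        sel <- select_best_frame(traj, epsilon)
        sel$quality_at_selection
      }, error = function(e) {
        warning("fitting run failed (seed ", si, ", pixel ", p, "): ",
                conditionMessage(e))
        NA_real_
      })
    }
  }
  nn <- colSums(!is.na(scores))
  mean_score <- colMeans(scores, na.rm = TRUE)
  se_score <- apply(scores, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  })
  structure(list(pixel_sizes = pixel_grid, scores = scores,
                 mean_score = unname(mean_score),
                 se_score = unname(se_score), n_runs = unname(nn),
                 selected_pixel = pixel_grid[which.min(mean_score)],
                 schedule = schedule),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d pixel sizes x %d seeds, selected %.3g A/pixel\n",
              length(x$pixel_sizes), nrow(x$scores), x$selected_pixel))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Plot mean quality score against candidate pixel size
#'
#' Mean selected-frame quality per pixel size with +-1 standard-error bars;
#' the selected pixel size is marked.
#'
#' @param x a `calibration_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.calibration_result <- function(x, ...) {
  se <- ifelse(is.na(x$se_score), 0, x$se_score)
  ylim <- range(x$mean_score - se, x$mean_score + se)
  graphics::plot(x$pixel_sizes, x$mean_score, type = "b", pch = 19,
                 xlab = "pixel size (A)", ylab = "mean quality score",
                 ylim = ylim, ...)
  graphics::arrows(x$pixel_sizes, x$mean_score - se, x$pixel_sizes,
                   x$mean_score + se, angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$selected_pixel, lty = 2)
  invisible(x)
}

#' Calibration table
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return data.frame with `pixel_size`, `n`, `mean_score`, `se_score`.
#' @export
as.data.frame.calibration_result <- function(x, ...) {
  data.frame(pixel_size = x$pixel_sizes, n = x$n_runs,
             mean_score = x$mean_score, se_score = x$se_score)
}

# right-handed orthonormal frame with the third axis along `normal`
axis_frame <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  # v = n x u, so u x v = n and (u, v, n) is right-handed
  rbind(u = u, v = v, n = n)
}

#' Radius-of-gyration anisotropy diagnostic
#'
#' For every trajectory frame, the radii of gyration about the membrane
#' normal and two perpendicular axes are divided by the same radii of the
#' reference model. Ratios converging above 1 indicate the map stretches
#' the model (the pixel size label is too large); below 1, compression. A
#' model uniformly scaled by `s` gives ratios exactly `s` on every axis.
#'
#' @param traj a [run_fit()] trajectory.
#' @param reference the reference [atomic_model()] (same atoms/order).
#' @param membrane_normal direction of the membrane normal (default z).
#' @return an object of class `rg_diagnostic`: `times` (ps), `ratios`
#'   (frames x 3 matrix, columns `perp1`, `perp2`, `normal`), `axes`
#'   (3 x 3, rows are the axis directions) and `reference_rg`.
#' @export
rg_diagnostic <- function(traj, reference, membrane_normal = c(0, 0, 1)) {
  stopifnot(inherits(traj, "fit_trajectory"),
            inherits(reference, "atomic_model"))
  if (n_atoms(reference) != n_atoms(traj$model))
    stop("reference and trajectory atom counts differ")
  ax <- axis_frame(as.numeric(membrane_normal))
  ref_rg <- apply(ax, 1, function(a) rg_about_axis(reference, a))
  if (any(ref_rg <= 0)) stop("reference radii of gyration must be > 0")
  ratios <- t(vapply(traj$frames, function(fr) {
    m <- set_coords(traj$model, fr$coords)
    apply(ax, 1, function(a) rg_about_axis(m, a)) / ref_rg
  }, numeric(3)))
  colnames(ratios) <- c("perp1", "perp2", "normal")
  structure(list(times = vapply(traj$frames, `[[`, numeric(1), "time"),
                 ratios = ratios, axes = ax, reference_rg = ref_rg),
            class = "rg_diagnostic")
}

#' @export
print.rg_diagnostic <- function(x, ...) {
  last <- x$ratios[nrow(x$ratios), ]
  cat(sprintf(
    "<rg_diagnostic> %d frames; final Rg ratios: perp %.4f / %.4f, normal %.4f\n",
    nrow(x$ratios), last[1], last[2], last[3]))
  invisible(x)
}
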