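# Frame selection: the best stereochemical frame within the FSC-average
# plateau of a fitting trajectory.

#' Detect the FSC-average plateau of a trajectory
#'
#' The plateau is the relative-tolerance superlevel set of the FSC-average
#' maximum: all frames `i` with
#' `fsc_avg_i >= (1 - epsilon) * max_j fsc_avg_j`. This deterministic
#' definition admits both contiguous late-trajectory plateaus and any other
#' frame that reaches within `epsilon` of the maximum.
#'
#' @param traj a [run_fit()] trajectory (>= 3 frames).
#' @param epsilon relative plateau tolerance (default 0.01).
#' @return integer vector of frame indices.
#' @export
detect_plateau <- function(traj, epsilon = 0.01) {
  fa <- vapply(traj$frames, `[[`, numeric(1), "fsc_avg")
  if (length(fa) < 3) stop("need at least 3 frames to detect a plateau")
  if (any(!is.finite(fa))) stop("trajectory frames lack finite fsc_avg")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (max(fa) == min(fa))
    warning("all frames share the same fsc_avg: degenerate plateau")
  thr <- (1 - epsilon) * max(fa)
  which(fa >= thr)
}

#' Select the best-quality frame within the FSC-average plateau
#'
#' Among the plateau frames ([detect_plateau()]), the frame with the lowest
#' quality score (lower = better) is chosen; ties are broken by the earliest
#' time.
#'
#' @param traj a [run_fit()] trajectory whose frames carry `fsc_avg` and
#'   `quality`.
#' @param epsilon relative plateau tolerance.
#' @return an object of class `selection_result`: `frame_index`,
#'   `plateau_indices`, `fsc_avg_max`, `quality_at_selection`, `epsilon`,
#'   `time` and the selected `model`.
#' @export
select_best_frame <- function(traj, epsilon = 0.01) {
  plateau <- detect_plateau(traj, epsilon)
  q <- vapply(traj$frames, `[[`, numeric(1), "quality")
  best <- plateau[which.min(q[plateau])]
  structure(list(frame_index = best, plateau_indices = plateau,
                 fsc_avg_max = max(vapply(traj$frames, `[[`, numeric(1),
                                          "fsc_avg")),
                 quality_at_selection = q[best], epsilon = epsilon,
                 time = traj$frames[[best]]$time,
                 model = frame_model(traj, best)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> frame %d (t = %.3g ps): quality %.3f, plateau of %d frames (eps = %g, max fsc_avg %.4f)\n",
    x$frame_index, x$time, x$quality_at_selection,
    length(x$plateau_indices), x$epsilon, x$fsc_avg_max))
  invisible(x)
}

#' Write a selection report as JSON
#' @param sel a [select_best_frame()] result.
#' @param path output path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(list(
    frame_index = sel$frame_index, time_ps = sel$time,
    fsc_avg_max = sel$fsc_avg_max,
    quality_at_selection = sel$quality_at_selection,
    epsilon = sel$epsilon,
    plateau_first = min(sel$plateau_indices),
    plateau_last = max(sel$plateau_indices),
    plateau_size = length(sel$plateau_indices)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
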