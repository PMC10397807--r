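# Map-similarity and model-quality metrics: global cross-correlation,
# Fourier shell correlation (FSC) and its thresholded average, a windowed
# half-map local-quality score, a bonded-geometry + clash stereochemical
# score, and per-axis radii of gyration.

#' Cross-correlation of two maps
#'
#' Pearson correlation of the voxel values; invariant to positive affine
#' rescaling of either map.
#'
#' @param a,b `density_map`s on identical grids.
#' @return correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("maps have different grid shapes")
  va <- as.vector(a$grid); vb <- as.vector(b$grid)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("constant map: correlation undefined")
  cor(va, vb)
}

# integer frequency index along one axis of an N-point DFT
fft_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

#' Fourier shell correlation between two maps
#'
#' The complex correlation of the two discrete Fourier transforms, averaged
#' within spherical shells of width `1/(N p)` (one shell per integer radius
#' in reciprocal-voxel units, out to Nyquist). Real input maps give real FSC
#' up to numerical noise; the real part is returned. Shells where either map
#' has (numerically) zero power — e.g. the DC shell of mean-zero maps — are
#' reported as `NA` and skipped by [fsc_average()].
#'
#' @param a,b `density_map`s on the same cubic grid with equal voxel size.
#' @return an object of class `fsc_curve`: a data.frame with `shell_freq`
#'   (1/Å), `fsc` and `n_voxels`, plus a `nyquist` attribute.
#' @export
fsc_curve <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  da <- dim(a$grid)
  if (!identical(da, dim(b$grid))) stop("maps have different grid shapes")
  if (length(unique(da)) != 1L)
    stop("FSC needs a cubic grid; pad the maps upstream")
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-9)
    stop("maps have different voxel sizes")
  n <- da[1]
  p <- a$voxel_size[1]
  fa <- fft(a$grid)
  fb <- fft(b$grid)
  ii <- fft_index(n)
  r2 <- outer(outer(ii^2, ii^2, "+"), ii^2, "+")
  shell <- as.vector(round(sqrt(r2)))
  keep <- shell <= n %/% 2
  shell <- shell[keep] + 1L  # 1-based bins
  num <- Re(as.vector(fa * Conj(fb)))[keep]
  pa <- as.vector(Mod(fa)^2)[keep]
  pb <- as.vector(Mod(fb)^2)[keep]
  nshell <- n %/% 2 + 1L
  shell_sum <- function(v) {
    out <- numeric(nshell)
    t <- rowsum(v, shell)
    out[as.integer(rownames(t))] <- t
    out
  }
  s_num <- shell_sum(num)
  s_pa <- shell_sum(pa)
  s_pb <- shell_sum(pb)
  s_n <- shell_sum(rep(1, length(num)))
  denom <- sqrt(s_pa * s_pb)
  scale_ref <- max(denom)
  fsc <- ifelse(denom > 1e-14 * scale_ref, s_num / denom, NA_real_)
  out <- data.frame(shell_freq = (seq_len(nshell) - 1) / (n * p),
                    fsc = fsc, n_voxels = as.integer(s_n))
  class(out) <- c("fsc_curve", "data.frame")
  attr(out, "nyquist") <- 1 / (2 * p)
  out
}

#' FSC average up to a resolution threshold
#'
#' Arithmetic mean of the FSC over all shells with spatial frequency at or
#' below `1/resolution_threshold`. Shells flagged `NA` (zero power) are
#' skipped.
#'
#' @param curve an [fsc_curve()].
#' @param resolution_threshold resolution threshold in Å; must be within the
#'   grid's Nyquist range (threshold >= 2 x pixel size).
#' @return mean FSC, unitless.
#' @export
fsc_average <- function(curve, resolution_threshold = 2.88) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (resolution_threshold <= 0) stop("resolution_threshold must be > 0")
  nyq <- attr(curve, "nyquist")
  if (!is.null(nyq) && 1 / resolution_threshold > nyq + 1e-12)
    stop("threshold ", resolution_threshold,
         " A is beyond Nyquist (", signif(1 / (2 * nyq), 4), " A)")
  sel <- curve$shell_freq <= 1 / resolution_threshold
  vals <- curve$fsc[sel]
  mean(vals[!is.na(vals)])
}

#' Write an FSC curve as tab-separated text
#' @param curve an [fsc_curve()].
#' @param path output path.
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# extract a window^3 sub-grid centred as close to `center` (voxel index,
# 1-based) as the grid edge allows; the window is shifted, never shrunk
window_slab <- function(grid, center, window) {
  d <- dim(grid)
  h <- (window - 1L) %/% 2L
  lo <- pmin(pmax(center - h, 1L), d - window + 1L)
  grid[lo[1]:(lo[1] + window - 1L), lo[2]:(lo[2] + window - 1L),
       lo[3]:(lo[3] + window - 1L), drop = FALSE]
}

#' Windowed local map-quality score from half-maps
#'
#' A simplified, windowed analog of half-map local quality measures: around
#' each probe point, a cubic window of `window` voxels is cut from the
#' model-generated map, the full map and the two half-maps, and the local
#' score is
#' `q = FSC_avg(model_window, full_window) - FSC_avg(half1_window, half2_window)`
#' (FSC averaged over all shells of the window). `q` near 0 means the model
#' explains the map about as well as the half-maps reproduce each other;
#' `q < -0.5` flags regions where the model correlates much worse than the
#' half-map reproducibility, and `q > +0.5` regions where it correlates
#' better than the data reproduce themselves (a warning sign of fitting
#' noise). This is the package's own windowed score with its own sign
#' semantics; it preserves the conventional +-0.5 interpretation bands and
#' window default of 15 voxels, but it is not the published FSC-Q algorithm
#' and is not expected to reproduce deposited FSC-Q values.
#'
#' @param model_map,full_map,half1,half2 `density_map`s on a common grid.
#' @param model optional [atomic_model()]; probe points are then the atoms'
#'   nearest voxels. Without a model, a regular lattice of window centres
#'   (stride = half a window) is probed.
#' @param window odd cubic window edge in voxels (>= 5; default 15).
#' @return an object of class `local_quality`: list with `q` (per probe),
#'   `centers` (voxel indices), `mean_q`, `frac_above` (+0.5),
#'   `frac_below` (-0.5) and `window`.
#' @export
local_quality <- function(model_map, full_map, half1, half2, window = 15,
                          model = NULL) {
  maps <- list(model_map, full_map, half1, half2)
  for (m in maps) stopifnot(inherits(m, "density_map"))
  d <- dim(full_map$grid)
  for (m in maps) if (!identical(dim(m$grid), d))
    stop("all maps must share a grid")
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L)
    stop("window must be odd and >= 5")
  if (any(window > d)) stop("window larger than the grid")
  if (!is.null(model)) {
    stopifnot(inherits(model, "atomic_model"))
    centers <- round((t(model$coords) - full_map$origin) /
                       full_map$voxel_size + 0.5)
    centers <- t(pmin(pmax(centers, 1), d))
  } else {
    h <- max(1L, window %/% 2L)
    gx <- seq(1L + h, d[1] - h, by = h)
    gy <- seq(1L + h, d[2] - h, by = h)
    gz <- seq(1L + h, d[3] - h, by = h)
    centers <- as.matrix(expand.grid(gx, gy, gz))
  }
  storage.mode(centers) <- "integer"
  p <- full_map$voxel_size[1]
  q <- vapply(seq_len(nrow(centers)), function(r) {
    ctr <- centers[r, ]
    wm <- density_map(window_slab(model_map$grid, ctr, window), p)
    wf <- density_map(window_slab(full_map$grid, ctr, window), p)
    w1 <- density_map(window_slab(half1$grid, ctr, window), p)
    w2 <- density_map(window_slab(half2$grid, ctr, window), p)
    m1 <- mean_fsc_all_shells(wm, wf)
    m2 <- mean_fsc_all_shells(w1, w2)
    m1 - m2
  }, numeric(1))
  structure(list(q = q, centers = centers, mean_q = mean(q),
                 frac_above = mean(q > 0.5), frac_below = mean(q < -0.5),
                 window = window),
            class = "local_quality")
}

# mean FSC over all shells of a (small) window; identical windows give 1
mean_fsc_all_shells <- function(a, b) {
  if (identical(a$grid, b$grid)) return(1)
  cv <- tryCatch(fsc_curve(a, b), error = function(e) NULL)
  if (is.null(cv)) return(NA_real_)
  v <- cv$fsc[!is.na(cv$fsc)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' @export
print.local_quality <- function(x, ...) {
  cat(sprintf(
    "<local_quality> %d probes, window %d: mean q = %.3f, q > +0.5: %.1f%%, q < -0.5: %.1f%%\n",
    length(x$q), x$window, x$mean_q, 100 * x$frac_above, 100 * x$frac_below))
  invisible(x)
}

#' Stereochemical quality score
#'
#' A bonded-geometry plus clash score standing in for knowledge-based model
#' quality potentials (lower is better): the weighted sum of the RMS bond
#' deviation from the topology's reference lengths (Å), the RMS angle
#' deviation (rad) and the steric clash count per 1000 atoms. A clash is a
#' non-excluded heavy-atom pair closer than the sum of the two repulsion
#' radii minus 0.4 Å, the conventional steric-overlap gap. A geometry at its
#' reference values with no clashes scores exactly 0.
#'
#' @param model an [atomic_model()].
#' @param topo a [build_topology()] result for the same atoms.
#' @param weights weights `(w_b, w_a, w_c)` for the three components; the
#'   defaults `(10 per Å, 5 per rad, 0.1)` put typical well-refined
#'   fixtures around 0.5–1.5.
#' @return an object of class `quality_score` with `total`, `bond_rms`,
#'   `angle_rms`, `clash_per_1000` and `weights`.
#' @export
stereo_score <- function(model, topo, weights = c(w_b = 10, w_a = 5, w_c = 0.1)) {
  stopifnot(inherits(model, "atomic_model"), inherits(topo, "topology"))
  if (topo$n_atoms != n_atoms(model))
    stop("topology does not match the model")
  if (nrow(topo$bonds) == 0 && nrow(topo$angles) == 0)
    warning("empty topology: all score components are 0")
  co <- model$coords
  bond_rms <- if (nrow(topo$bonds)) {
    d <- sqrt(rowSums((co[topo$bonds$i, , drop = FALSE] -
                         co[topo$bonds$j, , drop = FALSE])^2))
    sqrt(mean((d - topo$bonds$b0)^2))
  } else 0
  angle_rms <- if (nrow(topo$angles)) {
    th <- vapply(seq_len(nrow(topo$angles)), function(r)
      angle_between(co[topo$angles$i[r], ], co[topo$angles$j[r], ],
                    co[topo$angles$k[r], ]), numeric(1))
    sqrt(mean((th - topo$angles$theta0)^2))
  } else 0
  clash <- count_clashes(model, topo)
  cp1000 <- 1000 * clash / n_atoms(model)
  total <- weights[[1]] * bond_rms + weights[[2]] * angle_rms +
    weights[[3]] * cp1000
  structure(list(total = total, bond_rms = bond_rms, angle_rms = angle_rms,
                 clash_per_1000 = cp1000, weights = weights),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf(
    "<quality_score> total %.3f (bond RMS %.3f A, angle RMS %.3f rad, clashes/1000 %.2f)\n",
    x$total, x$bond_rms, x$angle_rms, x$clash_per_1000))
  invisible(x)
}

# non-excluded heavy-atom pairs closer than r_i + r_j - 0.4 A
count_clashes <- function(model, topo, gap = 0.4) {
  heavy <- which(model$is_heavy)
  if (length(heavy) < 2) return(0L)
  d <- as.matrix(stats::dist(model$coords[heavy, , drop = FALSE]))
  r <- topo$repulsion_radius[heavy]
  lim <- outer(r, r, "+") - gap
  hit <- which(upper.tri(d) & d < lim, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  pairs <- cbind(heavy[pmin(hit[, 1], hit[, 2])],
                 heavy[pmax(hit[, 1], hit[, 2])])
  if (nrow(topo$excluded_pairs)) {
    key <- paste(pairs[, 1], pairs[, 2])
    exkey <- paste(topo$excluded_pairs[, 1], topo$excluded_pairs[, 2])
    sum(!(key %in% exkey))
  } else nrow(pairs)
}

#' Score a model with an external GOAP executable
#'
#' Writes the selected chain to a temporary PDB and invokes an external
#' all-atom statistical-potential scorer (lower is better), parsing the last
#' numeric field of its output. This is an optional hook: when the
#' executable is absent a `denfit_optional_dependency` error is raised and
#' the built-in [stereo_score()] remains the default quality source.
#'
#' @param model_file path to a PDB file to score.
#' @param goap_executable path to the scorer executable.
#' @param chain chain to score (default "A").
#' @return numeric score (lower = better).
#' @export
external_goap <- function(model_file, goap_executable, chain = "A") {
  if (!file.exists(model_file)) stop("model file not found: ", model_file)
  if (is.null(goap_executable) || !nzchar(goap_executable) ||
      (!file.exists(goap_executable) && !nzchar(Sys.which(goap_executable))))
    stop(errorCondition(paste0(
      "optional dependency absent: external scorer '", goap_executable,
      "' not found; the built-in stereo score remains the default"),
      class = "denfit_optional_dependency"))
  model <- read_model(model_file)
  sel <- model$chain_id == chain
  if (!any(sel)) stop("no atoms in chain ", chain)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_model(subset_atoms(model, which(sel)), tmp)
  out <- system2(goap_executable, args = shQuote(tmp), stdout = TRUE,
                 stderr = FALSE)
  toks <- regmatches(out, gregexpr("-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", out))
  nums <- suppressWarnings(as.numeric(unlist(toks)))
  nums <- nums[is.finite(nums)]
  if (!length(nums)) stop("could not parse a score from the external scorer")
  nums[length(nums)]
}

#' Radius of gyration about an axis
#'
#' Mass-weighted RMS perpendicular distance of the atoms from the axis
#' through the center of mass:
#' `sqrt(sum(m_i d_i^2) / sum(m_i))`.
#'
#' @param model an [atomic_model()].
#' @param axis direction of the axis (any nonzero length-3 vector).
#' @return radius of gyration in Å.
#' @export
rg_about_axis <- function(model, axis) {
  stopifnot(inherits(model, "atomic_model"))
  axis <- as.numeric(axis)
  nn <- sqrt(sum(axis^2))
  if (!is.finite(nn) || nn == 0) stop("axis must be nonzero")
  u <- axis / nn
  if (sum(model$mass) <= 0) stop("zero total mass")
  x <- sweep(model$coords, 2, center_of_mass(model))
  along <- x %*% u
  d2 <- rowSums(x^2) - as.vector(along)^2
  d2[d2 < 0] <- 0
  sqrt(sum(model$mass * d2) / sum(model$mass))
}
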