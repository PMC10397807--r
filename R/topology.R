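# Structure-based restraint topology: bonds and angles are read off the
# input geometry (reference values = observed values), so the potential's
# minimum is the starting structure. This plays the role a full biomolecular
# force field would play in a simulation engine, at a fraction of the cost.

#' Build a structure-based restraint topology
#'
#' Bonds are all heavy-atom pairs closer than `bond_cutoff` in the input
#' geometry, with the observed distance as the reference length. Angles are
#' formed by every pair of bonds sharing an atom, with the observed angle as
#' reference. Bonded 1-2 and 1-3 pairs are excluded from steric repulsion;
#' every atom carries an element-derived repulsion radius.
#'
#' @param model an [atomic_model()].
#' @param bond_cutoff bond detection cutoff in Å. The default 1.9 Å covers
#'   covalent bonds up to C–S; coarse-grained bead models need a larger
#'   value (e.g. 1.15 x the bead spacing).
#' @param k_bond harmonic bond force constant, kJ/mol/Å².
#' @param k_angle harmonic angle force constant, kJ/mol/rad².
#' @param max_valence warn when an atom exceeds this many bonds.
#' @return an object of class `topology` with elements `bonds`
#'   (data.frame `i, j, b0, k_b`), `angles` (data.frame
#'   `i, j, k, theta0, k_theta`; `j` is the vertex), `excluded_pairs`
#'   (2-column matrix) and `repulsion_radius` (per atom, Å).
#' @export
build_topology <- function(model, bond_cutoff = 1.9, k_bond = 200,
                           k_angle = 50, max_valence = 6) {
  stopifnot(inherits(model, "atomic_model"))
  if (bond_cutoff <= 0) stop("bond_cutoff must be > 0")
  heavy <- which(model$is_heavy)
  bonds <- matrix(integer(0), 0, 2)
  b0 <- numeric(0)
  if (length(heavy) >= 2) {
    d <- as.matrix(stats::dist(model$coords[heavy, , drop = FALSE]))
    hit <- which(upper.tri(d) & d <= bond_cutoff & d > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      bonds <- cbind(heavy[hit[, 1]], heavy[hit[, 2]])
      b0 <- d[hit]
      ord <- order(bonds[, 1], bonds[, 2])
      bonds <- bonds[ord, , drop = FALSE]
      b0 <- b0[ord]
    }
  }
  valence <- tabulate(c(bonds), nbins = n_atoms(model))
  if (any(valence > max_valence))
    warning(sum(valence > max_valence), " atom(s) exceed max valence ",
            max_valence)

  # angles: for each vertex atom, all pairs of its bonded partners
  ang <- matrix(integer(0), 0, 3)
  if (nrow(bonds)) {
    partners <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
    ang_list <- lapply(names(partners), function(v) {
      p <- sort(unique(partners[[v]]))
      if (length(p) < 2) return(NULL)
      cmb <- utils::combn(p, 2)
      cbind(cmb[1, ], as.integer(v), cmb[2, ])
    })
    ang_list <- Filter(Negate(is.null), ang_list)
    if (length(ang_list)) {
      ang <- do.call(rbind, ang_list)
      ang <- ang[order(ang[, 2], ang[, 1], ang[, 3]), , drop = FALSE]
    }
  }
  theta0 <- if (nrow(ang)) vapply(seq_len(nrow(ang)), function(r) {
    angle_between(model$coords[ang[r, 1], ], model$coords[ang[r, 2], ],
                  model$coords[ang[r, 3], ])
  }, numeric(1)) else numeric(0)

  excl <- rbind(bonds, if (nrow(ang)) cbind(ang[, 1], ang[, 3]))
  if (is.null(excl)) excl <- matrix(integer(0), 0, 2)
  if (nrow(excl)) {
    excl <- t(apply(excl, 1, sort))
    excl <- unique(excl)
  }
  structure(list(
    bonds = data.frame(i = bonds[, 1], j = bonds[, 2], b0 = b0,
                       k_b = rep_len(k_bond, nrow(bonds))),
    angles = data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3],
                        theta0 = theta0,
                        k_theta = rep_len(k_angle, nrow(ang))),
    excluded_pairs = excl,
    repulsion_radius = element_lookup(ELEMENT_RADIUS, model$element, 1.7,
                                      "radius"),
    n_atoms = n_atoms(model)),
    class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d bonds, %d angles, %d excluded pairs, %d atoms\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$excluded_pairs),
              x$n_atoms))
  invisible(x)
}

# interior angle at vertex b (radians)
angle_between <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cs)))
}

# 0-based arguments for the C++ kernels, assembled once per topology/model.
restraint_args <- function(model, topo, k_rep = 100,
                           pos_ref = NULL, pos_idx = NULL, k_pos = 0) {
  list(bonds = cbind(as.integer(topo$bonds$i) - 1L,
                     as.integer(topo$bonds$j) - 1L),
       b0 = as.numeric(topo$bonds$b0), kb = as.numeric(topo$bonds$k_b),
       angles = cbind(as.integer(topo$angles$i) - 1L,
                      as.integer(topo$angles$j) - 1L,
                      as.integer(topo$angles$k) - 1L),
       th0 = as.numeric(topo$angles$theta0),
       kth = as.numeric(topo$angles$k_theta),
       rep_idx = which(model$is_heavy) - 1L,
       radii = as.numeric(topo$repulsion_radius),
       excl = matrix(as.integer(topo$excluded_pairs) - 1L,
                     nrow = nrow(topo$excluded_pairs)),
       k_rep = k_rep,
       pos_ref = pos_ref, pos_idx = if (is.null(pos_idx)) NULL else
         as.integer(pos_idx) - 1L,
       k_pos = k_pos)
}

# Restraint energy/forces via the compiled kernel.
restraint_forces <- function(coords, ra) {
  cpp_restraint_forces(coords, ra$bonds, ra$b0, ra$kb, ra$angles, ra$th0,
                       ra$kth, ra$rep_idx, ra$radii, ra$excl, ra$k_rep,
                       ra$pos_ref, ra$pos_idx, ra$k_pos)
}
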