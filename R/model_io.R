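# Atomic models: an ordered set of atoms with coordinates, element, mass,
# Gaussian spread amplitude and residue/chain bookkeeping. Atom order is
# significant and preserved through read/write round trips.

# Atomic masses (amu) and atomic numbers for the elements that occur in
# protein/nucleic models and common ligands/ions. Unknown elements fall back
# to carbon with a warning.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
                  MG = 24.305, CA = 40.078, MN = 54.938, "NA" = 22.99,
                  K = 39.098, CL = 35.45, CU = 63.546, F = 18.998,
                  BR = 79.904, I = 126.904)
ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34, FE = 26,
               ZN = 30, MG = 12, CA = 20, MN = 25, "NA" = 11, K = 19, CL = 17,
               CU = 29, F = 9, BR = 35, I = 53)
# Steric repulsion radii (Å), van der Waals-like, used for clash detection
# and the soft-core repulsion term.
ELEMENT_RADIUS <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
                    SE = 1.9, FE = 1.4, ZN = 1.39, MG = 1.73, CA = 1.9,
                    MN = 1.4, "NA" = 2.27, K = 2.75, CL = 1.75, CU = 1.4,
                    F = 1.47, BR = 1.85, I = 1.98)

element_lookup <- function(table, elements, default, what) {
  key <- toupper(elements)
  out <- unname(table[key])
  if (anyNA(out)) {
    bad <- unique(elements[is.na(out)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using default ", what, " ", default)
    out[is.na(out)] <- default
  }
  out
}

#' Construct an atomic model
#'
#' @param coords n x 3 numeric matrix of Å coordinates.
#' @param element character vector of element symbols.
#' @param mass atomic masses (amu); derived from `element` if `NULL`.
#' @param amplitude unitless Gaussian spread weights; defaults to the atomic
#'   number of each element (so heavier atoms scatter more).
#' @param atom_name PDB atom names.
#' @param res_id integer residue numbers.
#' @param res_name residue names.
#' @param chain_id chain identifiers.
#' @param is_heavy logical heavy-atom (non-hydrogen) flags; derived from
#'   `element` if `NULL`.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(coords, element, mass = NULL, amplitude = NULL,
                         atom_name = NULL, res_id = NULL, res_name = NULL,
                         chain_id = NULL, is_heavy = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("empty model")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  element <- rep_len(as.character(element), n)
  if (is.null(mass))
    mass <- element_lookup(ELEMENT_MASS, element, 12.011, "mass")
  if (is.null(amplitude))
    amplitude <- element_lookup(ELEMENT_Z, element, 6, "amplitude")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be > 0")
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    stop("amplitudes must be > 0")
  if (is.null(is_heavy)) is_heavy <- toupper(element) != "H"
  structure(list(
    coords = coords,
    element = element,
    mass = rep_len(as.numeric(mass), n),
    amplitude = rep_len(as.numeric(amplitude), n),
    atom_name = rep_len(if (is.null(atom_name)) "CA" else as.character(atom_name), n),
    res_id = rep_len(if (is.null(res_id)) seq_len(n) else as.integer(res_id), n),
    res_name = rep_len(if (is.null(res_name)) "GLY" else as.character(res_name), n),
    chain_id = rep_len(if (is.null(chain_id)) "A" else as.character(chain_id), n),
    is_heavy = rep_len(as.logical(is_heavy), n)),
    class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chains, %d heavy\n",
              n_atoms(x), length(unique(x$chain_id)), sum(x$is_heavy)))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an `atomic_model`.
#' @export
n_atoms <- function(model) nrow(model$coords)

# Replace coordinates, keeping all other atom attributes.
set_coords <- function(model, coords) {
  stopifnot(identical(dim(coords), dim(model$coords)))
  model$coords <- coords
  model
}

# Subset atoms, preserving order.
subset_atoms <- function(model, idx) {
  m <- model
  m$coords <- model$coords[idx, , drop = FALSE]
  for (f in c("element", "mass", "amplitude", "atom_name", "res_id",
              "res_name", "chain_id", "is_heavy"))
    m[[f]] <- model[[f]][idx]
  m
}

#' Mass-weighted center of mass
#' @param model an `atomic_model`.
#' @return length-3 Å vector.
#' @export
center_of_mass <- function(model) {
  colSums(model$coords * model$mass) / sum(model$mass)
}

#' Root-mean-square deviation between two models
#'
#' Plain coordinate RMSD without superposition (atoms must correspond).
#' @param a,b `atomic_model`s with equal atom counts.
#' @export
rmsd <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) stop("atom counts differ")
  sqrt(mean(rowSums((a$coords - b$coords)^2)))
}

#' Read an atomic model from a PDB file
#'
#' Atoms are returned in file order with element-derived masses and default
#' spread amplitudes (atomic numbers). Non-hydrogen atoms are flagged heavy.
#' Elements missing from the internal tables draw a warning and carbon
#' defaults.
#'
#' @param path path to a PDB file (ATOM and HETATM records).
#' @return an [atomic_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in ", path)
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele)) || all(!nzchar(trimws(ele))))
    ele <- suppressWarnings(bio3d::atom2ele(pdb))
  ele <- trimws(ele)
  ele[!nzchar(ele)] <- substr(trimws(at$elety[!nzchar(ele)]), 1, 1)
  ch <- at$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  atomic_model(coords = cbind(at$x, at$y, at$z), element = ele,
               atom_name = trimws(at$elety), res_id = at$resno,
               res_name = trimws(at$resid), chain_id = ch)
}

#' Write an atomic model to a PDB file
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$coords)),
                   type = rep("ATOM", n_atoms(model)),
                   resno = model$res_id, resid = model$res_name,
                   chain = model$chain_id, elety = model$atom_name,
                   elesy = model$element)
  invisible(path)
}
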