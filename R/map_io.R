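# Density maps: a 3D scalar grid with voxel spacing (Angstrom per voxel) and
# the Angstrom offset of the corner of voxel (0,0,0). Internal storage is an
# R array with x varying fastest, i.e. grid[ix, iy, iz].

#' Construct a density map
#'
#' A density map is a 3D scalar grid together with its voxel size (Å per
#' voxel along each axis) and the Å offset of the corner of voxel
#' `(0, 0, 0)`. The physical extent along axis `i` is always
#' `dim(grid)[i] * voxel_size[i]` and is never stored separately. Voxel
#' values are samples at voxel centres, `origin + (index - 0.5) * voxel_size`
#' in 1-based indexing.
#'
#' @param grid numeric 3D array, at least 2 voxels along every axis.
#' @param voxel_size positive voxel spacing in Å; length 1 (isotropic) or 3.
#' @param origin Å offset of the corner of the first voxel (length 3).
#' @param label free-text map label.
#' @return an object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0), label = "") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  if (any(dim(grid) < 2L))
    stop("grid must have at least 2 voxels along every axis")
  if (!is.numeric(grid))
    stop("grid must be numeric")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be positive (length 1 or 3)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), label = as.character(label)[1]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.4g x %.4g x %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  extent %.4g x %.4g x %.4g A, origin (%.3g, %.3g, %.3g) A\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g%s\n",
              min(x$grid), mean(x$grid), max(x$grid),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Physical extent of a density map
#' @param m a `density_map`.
#' @return length-3 vector of Å extents, `dim * voxel_size`.
#' @export
map_extent <- function(m) dim(m$grid) * m$voxel_size

# Voxel centre coordinates (Å) along one axis, 1-based.
voxel_centers <- function(m, axis) {
  m$origin[axis] + (seq_len(dim(m$grid)[axis]) - 0.5) * m$voxel_size[axis]
}

read_raw_slice <- function(raw, offset, what, n, size) {
  readBin(raw[(offset + 1):(offset + n * size)], what = what, n = n,
          size = size, endian = "little")
}

#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte MRC2014 header and the data block (modes 0, 1, 2 and
#' 6 are supported). Axis-order permutations recorded in the `MAPC/MAPR/MAPS`
#' header words are normalised on read so that the returned grid always
#' stores x fastest. The origin is taken from the MRC2014 `ORIGIN` words
#' when set, otherwise from the CCP4 `NXSTART/NYSTART/NZSTART` offsets.
#' Little-endian files only (the format used by all modern cryo-EM software).
#'
#' @param path path to an MRC/CCP4 volume.
#' @return a [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("malformed MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  nxyz <- read_raw_slice(raw, 0, "integer", 3, 4)
  mode <- read_raw_slice(raw, 12, "integer", 1, 4)
  nstart <- read_raw_slice(raw, 16, "integer", 3, 4)
  mxyz <- read_raw_slice(raw, 28, "integer", 3, 4)
  cella <- read_raw_slice(raw, 40, "numeric", 3, 4)
  mapcrs <- read_raw_slice(raw, 64, "integer", 3, 4)
  org <- read_raw_slice(raw, 196, "numeric", 3, 4)
  if (any(nxyz < 1) || any(mxyz < 1) || any(cella <= 0))
    stop("malformed MRC header (non-positive dimensions or cell): ", path)
  nvox <- prod(as.double(nxyz))
  esize <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L,
                  stop("unsupported MRC mode ", mode, " in ", path))
  if (sz < 1024 + nvox * esize)
    stop("truncated MRC file (data block shorter than header promises): ",
         path)
  data_raw <- raw[(1025):(1024 + nvox * esize)]
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(data_raw, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(data_raw, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(data_raw, "numeric", n = nvox, size = 4,
                  endian = "little"),
    "6" = as.numeric(readBin(data_raw, "integer", n = nvox, size = 2,
                             signed = FALSE, endian = "little")))
  arr <- array(vals, dim = nxyz)
  axes <- mapcrs
  if (!all(sort(axes) == 1:3)) axes <- 1:3  # tolerate blank headers
  if (!all(axes == 1:3)) arr <- aperm(arr, match(1:3, axes))
  voxel <- cella / mxyz
  if (max(voxel) - min(voxel) > 1e-6 * max(voxel))
    warning("anisotropic voxel size in ", path, ": ",
            paste(signif(voxel, 6), collapse = " x "))
  origin <- if (any(abs(org) > 0)) as.numeric(org)
            else as.numeric(nstart[match(1:3, if (all(sort(mapcrs) == 1:3)) mapcrs else 1:3)] * voxel)
  density_map(arr, voxel, origin, label = basename(path))
}

#' Write a density map as MRC
#'
#' Writes a standard little-endian MRC2014 file, mode 2 (32-bit float), axis
#' order x-fastest, with the origin stored in the `ORIGIN` header words.
#'
#' @param m a [density_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(m, path) {
  stopifnot(inherits(m, "density_map"))
  if (any(!is.finite(m$grid)))
    stop("grid contains non-finite values; refusing to write")
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(m$grid)
  writeBin(as.integer(d), con, size = 4, endian = "little")          # NX NY NZ
  writeBin(2L, con, size = 4, endian = "little")                     # MODE
  writeBin(integer(3), con, size = 4, endian = "little")             # NSTART
  writeBin(as.integer(d), con, size = 4, endian = "little")          # MX MY MZ
  writeBin(as.numeric(d * m$voxel_size), con, size = 4, endian = "little")
  writeBin(rep(90, 3), con, size = 4, endian = "little")             # CELLB
  writeBin(1:3, con, size = 4, endian = "little")                    # MAPC/R/S
  writeBin(as.numeric(c(min(m$grid), max(m$grid), mean(m$grid))), con,
           size = 4, endian = "little")                              # DMIN..
  writeBin(c(1L, 0L), con, size = 4, endian = "little")              # ISPG, NSYMBT
  writeBin(raw(100), con)                                            # EXTRA
  writeBin(as.numeric(m$origin), con, size = 4, endian = "little")   # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                   # MACHST
  writeBin(sd(as.vector(m$grid)), con, size = 4, endian = "little")  # RMS
  writeBin(1L, con, size = 4, endian = "little")                     # NLABL
  lab <- substr(sprintf("%-80s", m$label), 1, 80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeBin(raw(720), con)
  writeBin(as.numeric(m$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Relabel the pixel size of a map
#'
#' Sets the voxel size header field without touching any voxel value: the
#' grid is NOT resampled, so the physical extent (and every physical length
#' of the map, including the origin offset) scales by `new_p / old_p`. This
#' mirrors the pixel-size calibration procedure, where the same
#' reconstruction is reinterpreted at candidate voxel sizes.
#'
#' @param m a [density_map()].
#' @param new_p new pixel size in Å (scalar, applied to all axes).
#' @return the relabelled `density_map`.
#' @export
relabel_pixel_size <- function(m, new_p) {
  stopifnot(inherits(m, "density_map"))
  if (!is.numeric(new_p) || length(new_p) != 1L || !is.finite(new_p) ||
      new_p <= 0)
    stop("new pixel size must be a positive number")
  ratio <- new_p / m$voxel_size
  m$origin <- m$origin * ratio
  m$voxel_size <- rep(new_p, 3L)
  m
}

#' Normalize a map to zero mean and unit standard deviation
#'
#' Statistics are computed over all voxels by default; an optional logical
#' mask restricts them to a region (the whole grid is still transformed).
#' The population standard deviation (divisor `N`) is used so that
#' normalization is exactly idempotent.
#'
#' @param m a [density_map()].
#' @param mask optional logical array of the grid's shape.
#' @return normalized `density_map`.
#' @export
normalize_map <- function(m, mask = NULL) {
  stopifnot(inherits(m, "density_map"))
  v <- if (is.null(mask)) as.vector(m$grid) else {
    if (!identical(dim(mask), dim(m$grid)))
      stop("mask shape must match the grid")
    as.vector(m$grid[mask])
  }
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (!is.finite(sdev) || sdev <= 0)
    stop("constant map: normalization undefined")
  m$grid <- (m$grid - mu) / sdev
  m
}

# TRUE if the map is already normalized to mean 0, sd 1.
is_normalized_map <- function(m, tol = 1e-6) {
  v <- as.vector(m$grid)
  abs(mean(v)) < tol && abs(sqrt(mean((v - mean(v))^2)) - 1) < tol
}
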