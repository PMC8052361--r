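# Stride-2 lattice labeling. The lattice is anchored at even (0-based) map
# grid indices: lattice point (i,j,k) sits at map index (2i,2j,2k), physical
# coordinate origin + 2*(i,j,k) for the canonical 1-Angstrom grid. A point is
# included iff some heavy atom lies within 3.0 A (boundary inclusive); its
# primary label is the class of the nearest heavy atom and its label set is
# the set of classes of all atoms within the radius.

LABEL_RADIUS <- 3.0

lattice_dims <- function(map_dims) as.integer(floor((map_dims - 1) / 2) + 1)

#' Label the stride-2 lattice of a map from a structure
#'
#' @param map A [density_map] on the canonical 1-Angstrom grid, aligned with
#'   the structure coordinates.
#' @param structure A `toy_complex` (or [read_structure()] result).
#' @param radius Labeling radius in Angstrom (default 3.0, boundary
#'   inclusive).
#' @return An object of class `labeled_grid` with fields `dims` (lattice
#'   dims), `origin`, `stride`, `included` (logical 3-D array),
#'   `primary` (integer 3-D array indexing [class_labels()], 0 where
#'   excluded), `label_set` (4-D logical array, last dim = class), and
#'   `nearest` (nearest heavy-atom distance, `Inf` where excluded).
#' @export
label_grid <- function(map, structure, radius = LABEL_RADIUS) {
  stopifnot_density_map(map)
  if (!isTRUE(all.equal(map$spacing, c(1, 1, 1))))
    stop("label_grid requires the canonical 1-Angstrom grid; resample first")
  xyz <- atom_coords(structure)
  if (nrow(xyz) == 0L) stop("empty structure: no atoms to label from")
  cls <- match(atom_class(structure), class_labels())

  ld <- lattice_dims(dim(map$values))
  nlat <- prod(ld)
  best_d2 <- rep(Inf, nlat)
  best_cls <- integer(nlat)
  lset <- matrix(FALSE, nlat, 4L)
  org <- map$origin
  r2max <- radius^2

  for (i in seq_len(nrow(xyz))) {
    a <- xyz[i, ]
    lo <- ceiling((a - radius - org) / 2)
    hi <- floor((a + radius - org) / 2)
    lo <- pmax(lo, 0); hi <- pmin(hi, ld - 1)
    if (any(hi < lo)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- org[1] + 2 * ix; cy <- org[2] + 2 * iy; cz <- org[3] + 2 * iz
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    d2 <- rep((cx - a[1])^2, times = ny * nz) +
      rep(rep((cy - a[2])^2, each = nx), times = nz) +
      rep((cz - a[3])^2, each = nx * ny)
    sel <- d2 <= r2max
    if (!any(sel)) next
    li <- (rep(ix, times = ny * nz) +
             rep(rep(iy, each = nx), times = nz) * ld[1] +
             rep(iz, each = nx * ny) * ld[1] * ld[2]) + 1L
    li <- li[sel]; d2 <- d2[sel]
    lset[li + (cls[i] - 1L) * nlat] <- TRUE
    upd <- d2 < best_d2[li]
    if (any(upd)) {
      best_d2[li[upd]] <- d2[upd]
      best_cls[li[upd]] <- cls[i]
    }
  }
  out <- list(
    dims = ld,
    map_dims = dim(map$values),
    origin = org,
    stride = 2L,
    included = array(best_cls > 0L, dim = ld),
    primary = array(best_cls, dim = ld),
    label_set = array(lset, dim = c(ld, 4L)),
    nearest = array(sqrt(best_d2), dim = ld))
  class(out) <- "labeled_grid"
  out
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat(sprintf("<labeled_grid> %d x %d x %d stride-%d lattice, %d included points\n",
              x$dims[1], x$dims[2], x$dims[3], x$stride, sum(x$included)))
  if (any(x$included)) {
    tab <- table(factor(class_labels()[x$primary[x$included]],
                        levels = class_labels()))
    cat("  primary labels:", paste(sprintf("%s=%d", names(tab), tab),
                                   collapse = " "), "\n")
  }
  invisible(x)
}

#' Inclusion lattice for a map without a structure
#'
#' Prediction-time surrogate for atom-based inclusion: a stride-2 point is
#' included iff its normalized density exceeds `threshold` (default 0, i.e.
#' above the contour for experimental maps, above the minimum for simulated
#' maps).
#'
#' @param map Normalized [density_map] at 1-Angstrom spacing.
#' @param threshold Normalized density threshold (default 0, exclusive).
#' @return A `labeled_grid`-shaped object with only `included` populated.
#' @export
density_inclusion_grid <- function(map, threshold = 0) {
  stopifnot_density_map(map)
  if (!isTRUE(map$normalized)) stop("map must be normalized")
  d <- dim(map$values)
  ld <- lattice_dims(d)
  idx <- lapply(1:3, function(k) seq(1L, d[k], by = 2L))
  inc <- map$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] > threshold
  structure(list(dims = ld, map_dims = d, origin = map$origin, stride = 2L,
                 included = array(inc, dim = ld),
                 primary = NULL, label_set = NULL, nearest = NULL),
            class = "labeled_grid")
}

#' Extract training/inference voxels from a map
#'
#' One sample per included stride-2 lattice point: an 11x11x11 window of
#' normalized densities centered on the point, zero-padded where the window
#' reaches outside the map. Sample order is deterministic: lattice index
#' column-major (x fastest).
#'
#' @param map Normalized [density_map] at 1-Angstrom spacing.
#' @param grid A `labeled_grid` (from [label_grid()] or
#'   [density_inclusion_grid()]).
#' @param window Window side in grid points (odd; default 11).
#' @return An object of class `voxel_samples`: list with `X` (window-values
#'   matrix, `window^3 x n`, channel layout matching the network input),
#'   `centers` (n x 3, 0-based lattice indices), `coords` (n x 3 Angstrom),
#'   `primary` (factor, or NULL), `label_set` (n x 4 logical, or NULL).
#' @export
extract_voxels <- function(map, grid, window = 11L) {
  stopifnot_density_map(map)
  if (!isTRUE(map$normalized)) stop("map must be normalized before voxel extraction")
  if (!isTRUE(all.equal(map$spacing, c(1, 1, 1))))
    stop("extract_voxels requires the canonical 1-Angstrom grid")
  if (window %% 2L != 1L) stop("window must be odd")
  if (!identical(as.integer(grid$map_dims), as.integer(dim(map$values))))
    stop("grid does not match map dimensions")
  pad <- (window - 1L) %/% 2L
  d <- dim(map$values)
  pd <- d + 2L * pad
  pvol <- array(0, dim = pd)
  pvol[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <-
    map$values

  inc_lin <- which(grid$included)           # column-major: x fastest
  n <- length(inc_lin)
  ld <- grid$dims
  ci <- arrayInd(inc_lin, ld) - 1L          # 0-based lattice indices
  # corner of each window in the padded volume (1-based linear index)
  corner <- (2L * ci[, 1] + 1L) +
    (2L * ci[, 2]) * pd[1] +
    (2L * ci[, 3]) * pd[1] * pd[2]
  off <- as.vector(outer(outer(0:(window - 1), (0:(window - 1)) * pd[1], "+"),
                         (0:(window - 1)) * pd[1] * pd[2], "+"))
  X <- matrix(pvol[outer(off, corner, "+")], nrow = window^3, ncol = n)

  primary <- NULL; lset <- NULL
  if (!is.null(grid$primary)) {
    primary <- factor(class_labels()[grid$primary[inc_lin]], levels = class_labels())
    ls4 <- matrix(grid$label_set, nrow = prod(ld), ncol = 4L)
    lset <- ls4[inc_lin, , drop = FALSE]
    colnames(lset) <- class_labels()
  }
  structure(list(X = X, centers = ci,
                 coords = sweep(2 * ci, 2, grid$origin, "+"),
                 primary = primary, label_set = lset,
                 window = as.integer(window), stride = 2L,
                 lattice_dims = ld, inc_lin = inc_lin),
            class = "voxel_samples")
}

#' @export
print.voxel_samples <- function(x, ...) {
  cat(sprintf("<voxel_samples> %d windows of %d^3 grid values\n",
              ncol(x$X), x$window))
  invisible(x)
}
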