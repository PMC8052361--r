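#' Canonical structural class labels
#'
#' The four structural classes assigned to map grid points, in the canonical
#' order used for every probability vector in the package: alpha-helix,
#' beta-strand, other/coil, and nucleic acid (DNA/RNA).
#'
#' @return Character vector `c("HELIX", "STRAND", "OTHER", "NUCLEIC")`.
#' @export
class_labels <- function() c("HELIX", "STRAND", "OTHER", "NUCLEIC")

#' Protein structural classes
#'
#' The subset of [class_labels()] describing protein secondary structure.
#'
#' @return Character vector `c("HELIX", "STRAND", "OTHER")`.
#' @export
protein_classes <- function() c("HELIX", "STRAND", "OTHER")

as_class_factor <- function(x) {
  factor(as.character(x), levels = class_labels())
}

#' Construct a density map
#'
#' A `density_map` is a 3-D scalar grid with a physical anchoring: grid point
#' `i` (0-based index along each axis) sits at `origin + i * spacing`
#' Angstrom. This is the container for both experimental-style CCP4/MRC
#' volumes and simulated maps.
#'
#' @param values Numeric 3-D array of densities, dims `(nx, ny, nz)`.
#' @param origin Numeric length-3, position of grid point (0,0,0) in Angstrom.
#' @param spacing Numeric length-3 (or scalar), grid step in Angstrom per axis.
#' @param resolution Optional nominal resolution in Angstrom.
#' @param contour_level Optional author-recommended contour level, in raw
#'   density units; required to normalize experimental maps.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                        resolution = NULL, contour_level = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(dim(values) < 1L)) stop("map dims must all be >= 1")
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  structure(
    list(values = values, origin = origin, spacing = spacing,
         resolution = resolution, contour_level = contour_level,
         normalized = FALSE),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  origin  : %.3f %.3f %.3f A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  spacing : %.3f %.3f %.3f A\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$resolution))
    cat(sprintf("  resolution   : %.2f A\n", x$resolution))
  if (!is.null(x$contour_level))
    cat(sprintf("  contour level: %g\n", x$contour_level))
  cat(sprintf("  density : [%g, %g]%s\n", min(x$values), max(x$values),
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Physical coordinates of map grid points along one axis
#'
#' @param map A `density_map`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of grid-point coordinates in Angstrom.
#' @keywords internal
map_axis_coords <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 1) * map$spacing[axis]
}

stopifnot_density_map <- function(x, arg = "map") {
  if (!inherits(x, "density_map")) stop(sprintf("`%s` must be a density_map", arg))
  invisible(x)
}
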