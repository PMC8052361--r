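#' Resample a density map to the canonical 1.0-Angstrom grid
#'
#' Trilinearly interpolates the map onto a unit-spaced lattice anchored at the
#' input origin rounded to integer Angstrom, covering the input bounding box.
#' Target points falling outside the input box get density 0 (solvent
#' padding). The operation is idempotent: a map already on an integer-anchored
#' 1-Angstrom grid is returned unchanged.
#'
#' @param map A [density_map]; every dimension must be at least 2.
#' @return A [density_map] with `spacing == c(1, 1, 1)`.
#' @export
resample_to_unit_grid <- function(map) {
  stopifnot_density_map(map)
  d <- dim(map$values)
  if (any(d < 2L)) stop("degenerate map: every dimension must be >= 2 to interpolate")
  new_origin <- round(map$origin)
  if (all(map$spacing == 1) && all(map$origin == new_origin)) return(map)

  hi <- map$origin + (d - 1) * map$spacing
  nd <- pmax(2L, as.integer(floor(hi - new_origin)) + 1L)

  # fractional source indices (0-based) of every target grid point, per axis
  src <- lapply(1:3, function(ax) {
    (new_origin[ax] + 0:(nd[ax] - 1) - map$origin[ax]) / map$spacing[ax]
  })
  gx <- rep(src[[1]], times = nd[2] * nd[3])
  gy <- rep(rep(src[[2]], each = nd[1]), times = nd[3])
  gz <- rep(src[[3]], each = nd[1] * nd[2])

  inside <- gx >= 0 & gx <= d[1] - 1 & gy >= 0 & gy <= d[2] - 1 & gz >= 0 & gz <= d[3] - 1
  out <- numeric(nd[1] * nd[2] * nd[3])
  if (any(inside)) {
    gx <- gx[inside]; gy <- gy[inside]; gz <- gz[inside]
    x0 <- pmin(floor(gx), d[1] - 2); fx <- gx - x0
    y0 <- pmin(floor(gy), d[2] - 2); fy <- gy - y0
    z0 <- pmin(floor(gz), d[3] - 2); fz <- gz - z0
    v <- map$values
    corner <- function(dx, dy, dz) {
      v[cbind(x0 + dx + 1, y0 + dy + 1, z0 + dz + 1)]
    }
    acc <- corner(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      corner(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      corner(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      corner(1, 1, 0) * fx * fy * (1 - fz) +
      corner(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      corner(1, 0, 1) * fx * (1 - fy) * fz +
      corner(0, 1, 1) * (1 - fx) * fy * fz +
      corner(1, 1, 1) * fx * fy * fz
    out[inside] <- acc
  }
  res <- density_map(array(out, dim = nd), origin = new_origin, spacing = c(1, 1, 1),
                     resolution = map$resolution, contour_level = map$contour_level)
  res$normalized <- map$normalized
  res
}

#' Normalize map densities to [0, 1]
#'
#' Simulated maps get plain min-max normalization,
#' `v' = (v - min) / (max - min)`. Experimental maps first clamp negative
#' densities to zero, then use the author-recommended contour level as the
#' minimum: `v' = clip((v - c) / (max - c), 0, 1)`, so density at (or below)
#' the contour maps to 0.
#'
#' @param map A [density_map].
#' @param mode `"simulated"` or `"experimental"`.
#' @return A [density_map] with values in `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_map <- function(map, mode = c("simulated", "experimental")) {
  stopifnot_density_map(map)
  mode <- match.arg(mode)
  v <- map$values
  if (mode == "simulated") {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("flat map: max density equals min, cannot normalize")
    out <- (v - lo) / (hi - lo)
  } else {
    if (is.null(map$contour_level))
      stop("experimental-mode normalization requires `contour_level`")
    v[v < 0] <- 0
    cl <- map$contour_level
    hi <- max(v)
    if (hi <= cl) stop("flat map: max density does not exceed the contour level")
    out <- pmin(pmax((v - cl) / (hi - cl), 0), 1)
    dim(out) <- dim(v)
  }
  res <- map
  res$values <- out
  res$normalized <- TRUE
  res
}

#' Pearson cross-correlation of two density maps
#'
#' Correlation over all co-located grid values; the two maps must share
#' dimensions and spacing (resample first if they do not).
#'
#' @param a,b [density_map]s on the same grid.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b) {
  stopifnot_density_map(a, "a"); stopifnot_density_map(b, "b")
  if (!identical(dim(a$values), dim(b$values)))
    stop("shape mismatch: maps must share dimensions")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("shape mismatch: maps must share spacing")
  va <- as.numeric(a$values); vb <- as.numeric(b$values)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(va, vb)
}
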