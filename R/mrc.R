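# CCP4/MRC 2014 volume I/O. Mode-2 (float32) maps only; the 1024-byte header
# is parsed word-by-word. Axis permutation (MAPC/MAPR/MAPS) is normalized to
# (x, y, z) on read; files are written canonically (MAPC=1, MAPR=2, MAPS=3).
# Values are float32 on disk, doubles in memory.

#' Read a CCP4/MRC density map
#'
#' Reads a mode-2 (32-bit float) CCP4/MRC 2014 volume. Whatever axis
#' permutation the header declares, the returned grid is re-ordered to the
#' package's fixed (x, y, z) convention. The physical origin is taken from the
#' ORIGIN header record when set, otherwise from NXSTART/NYSTART/NZSTART times
#' the grid spacing.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A [density_map].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop(sprintf("truncated MRC header (file %s has %d bytes, need 1024)", path, sz))
  con <- file(path, "rb"); on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)

  parse_hdr <- function(endian) {
    ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = endian)
    flts <- readBin(hdr_raw, "numeric", n = 256L, size = 4L, endian = endian)
    list(ints = ints, flts = flts)
  }
  endian <- "little"
  h <- parse_hdr(endian)
  mode <- h$ints[4]
  if (!(mode %in% 0:6)) { # wrong byte order? retry swapped
    endian <- "big"
    h <- parse_hdr(endian)
    mode <- h$ints[4]
  }
  if (!(mode %in% 0:6)) stop("unreadable MRC header: MODE field not recognized")
  map_tag <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    warning("MRC 'MAP ' tag missing; attempting to read anyway")
  if (mode != 2L)
    stop(sprintf("non-volumetric or unsupported MRC mode %d (only mode 2 float maps are supported)", mode))

  n_crs <- h$ints[1:3]
  if (any(n_crs < 1) || any(n_crs > 1e5)) stop("unreadable MRC header: implausible dimensions")
  nstart_crs <- h$ints[5:7]
  m_xyz <- h$ints[8:10]
  cella <- h$flts[11:13]
  axes <- h$ints[17:19]                      # crystallographic axis per c/r/s dim
  if (!setequal(axes, 1:3)) stop("unreadable MRC header: MAPC/MAPR/MAPS not a permutation of 1:3")
  origin_rec <- h$flts[50:52]

  nvox <- prod(n_crs)
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = endian)
  if (length(vals) < nvox)
    stop(sprintf("truncated MRC data: expected %d voxels, read %d", nvox, length(vals)))
  a <- array(vals, dim = n_crs)              # column (fastest) = c, then r, s
  perm <- match(1:3, axes)                   # data dim holding x, y, z
  a <- aperm(a, perm)
  nstart_xyz <- nstart_crs[perm]

  m_xyz[m_xyz <= 0] <- dim(a)[m_xyz <= 0]
  spacing <- ifelse(cella > 0, cella / m_xyz, 1)
  origin <- if (any(origin_rec != 0)) origin_rec else nstart_xyz * spacing
  density_map(a, origin = origin, spacing = spacing)
}

#' Write a density map as CCP4/MRC
#'
#' Writes a mode-2 (32-bit float, little-endian) MRC 2014 file with canonical
#' axis order (MAPC=1, MAPR=2, MAPS=3), the cell set to `dims * spacing`, and
#' the physical origin stored in the ORIGIN record.
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot_density_map(map)
  d <- dim(map$values)
  vals <- as.numeric(map$values)
  con <- file(path, "wb"); on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d)                                   # NX NY NZ
  wi(2L)                                  # MODE 2 = float32
  wi(c(0L, 0L, 0L))                       # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * map$spacing)                     # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(1:3)                                 # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals))) # DMIN DMAX DMEAN
  wi(1L)                                  # ISPG
  wi(0L)                                  # NSYMBT
  wi(c(0L, 0L))                           # EXTRA words 25-26
  writeBin(charToRaw("MRCO"), con)        # EXTTYP
  wi(20141L)                              # NVERSION
  wi(rep(0L, 21L))                        # EXTRA words 29-49
  wf(map$origin)                          # ORIGIN x y z
  writeBin(charToRaw("MAP "), con)        # MAP tag
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vals))                     # RMS
  wi(1L)                                  # NLABL
  lab <- sprintf("%-80s", "em2struct volume")
  writeBin(charToRaw(lab), con)
  writeBin(raw(80L * 9L), con)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}
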