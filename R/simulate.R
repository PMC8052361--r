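# Gaussian-kernel map simulation from atomic coordinates, in the style of the
# standard map-simulation utilities. The kernel width follows the FWHM
# convention sigma = 0.4247 * resolution, truncated at a spherical radius of
# 3 sigma; atom weights are uniform (class contrast at 6-10 A comes from
# geometry and packing, not element scattering factors).

#' Simulate a density map from a toy complex
#'
#' Places an isotropic Gaussian kernel `exp(-|p - atom|^2 / (2 sigma^2))` at
#' every heavy atom, with `sigma = 0.4247 * resolution` (the stated resolution
#' is treated as the kernel FWHM) and spherical truncation at `3 sigma`. The
#' map bounding box is the atom bounding box padded by `3 sigma`; the origin
#' is snapped to integer Angstrom so that stride-2 lattices are anchored
#' deterministically.
#'
#' @param complex A [build_toy_complex()] result (or any object with an
#'   `atoms` data frame carrying `x`, `y`, `z`).
#' @param resolution Nominal resolution in Angstrom (> 0).
#' @param spacing Grid spacing in Angstrom (default 1.0).
#' @param noise_sd Standard deviation of optional additive Gaussian noise, in
#'   raw density units (default 0, i.e. no noise).
#' @return A [density_map] with the `resolution` field set.
#' @export
simulate_map <- function(complex, resolution, spacing = 1.0, noise_sd = 0) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (spacing <= 0) stop("spacing must be > 0")
  xyz <- atom_coords(complex)
  if (nrow(xyz) == 0L) stop("empty complex: no atoms to simulate")
  sigma <- 0.4247 * resolution
  cut <- 3 * sigma

  origin <- floor(apply(xyz, 2, min) - cut)
  hi <- apply(xyz, 2, max) + cut
  nd <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  vol <- array(0, dim = nd)

  ax <- lapply(1:3, function(k) origin[k] + (0:(nd[k] - 1)) * spacing)
  inv2s2 <- 1 / (2 * sigma^2)
  cut2 <- cut^2
  for (i in seq_len(nrow(xyz))) {
    a <- xyz[i, ]
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - a[k]) <= cut)
    })
    if (any(lengths(rng) == 0L)) next
    d2x <- (ax[[1]][rng[[1]]] - a[1])^2
    d2y <- (ax[[2]][rng[[2]]] - a[2])^2
    d2z <- (ax[[3]][rng[[3]]] - a[3])^2
    r2 <- outer(outer(d2x, d2y, "+"), d2z, "+")
    kern <- exp(-r2 * inv2s2)
    kern[r2 > cut2] <- 0
    vol[rng[[1]], rng[[2]], rng[[3]]] <- vol[rng[[1]], rng[[2]], rng[[3]]] + kern
  }
  if (noise_sd > 0) vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim = nd)
  density_map(vol, origin = origin, spacing = rep(spacing, 3),
              resolution = resolution)
}

#' Write a toy complex as a minimal PDB file plus a label sidecar
#'
#' @param complex A `toy_complex`.
#' @param pdb_path Output PDB path (ATOM records only).
#' @param label_path Output TSV path (`chain_id`, `residue_index`, `label`).
#' @return `pdb_path`, invisibly.
#' @export
write_structure <- function(complex, pdb_path, label_path = NULL) {
  at <- complex$atoms
  elety <- if (!is.null(at$name)) at$name else {
    # fall back: element + occurrence index within the residue
    key <- paste(at$chain_id, at$residue_index)
    paste0(at$element, stats::ave(seq_len(nrow(at)), key, at$element,
                                  FUN = seq_along))
  }
  n <- nrow(at)
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue_index,
                   chain = at$chain_id,
                   resid = at$residue_name,
                   elety = elety,
                   elesy = at$element,
                   o = rep(1, n), b = rep(0, n))
  if (!is.null(label_path)) {
    utils::write.table(complex$labels, label_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(pdb_path)
}

#' Read a structure and its per-residue class labels
#'
#' Reads a PDB file (heavy atoms; any hydrogens are dropped) and a label
#' sidecar TSV as written by [write_structure()] or derived from a STRIDE
#' report via [stride_labels()].
#'
#' @param pdb_path PDB file path.
#' @param labels Either a label TSV path or a data frame with `chain_id`,
#'   `residue_index`, `label`.
#' @return A `toy_complex`-compatible object.
#' @export
read_structure <- function(pdb_path, labels) {
  pdb <- bio3d::read.pdb(pdb_path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  keep <- toupper(trimws(elem)) != "H"
  a <- a[keep, ]; elem <- elem[keep]
  if (is.character(labels)) {
    labels <- utils::read.table(labels, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = c("character", "integer", "character"))
  }
  lab_key <- paste(labels$chain_id, labels$residue_index)
  key <- paste(a$chain, a$resno)
  lab <- labels$label[match(key, lab_key)]
  if (anyNA(lab)) stop("PDB contains residues with no label entry")
  atoms <- data.frame(
    element = trimws(elem),
    name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z,
    chain_id = a$chain, residue_index = a$resno,
    residue_name = a$resid,
    is_nucleic = lab == "NUCLEIC",
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, labels = labels, segment_kinds = NULL),
            class = "toy_complex")
}

default_fixture_spec <- function() {
  # one segment of each kind per complex: guarantees 4-class coverage per map
  function() list(
    list(kind = "helix", length = sample(8:12, 1)),
    list(kind = "strand", length = sample(5:8, 1)),
    list(kind = "coil", length = sample(6:9, 1)),
    list(kind = "nucleic", length = sample(5:8, 1)))
}

#' Generate a fixture set of simulated maps with ground truth
#'
#' Writes `n` (map, structure, label) triples plus a manifest. Each complex
#' contains one helix, one strand, one coil and one nucleic segment of
#' randomized lengths, so all four classes are represented in every map.
#'
#' @param n Number of complexes.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces the set byte-for-byte.
#' @param resolution_mode `"uniform"` (drawn uniformly from
#'   `resolution_range`) or `"fixed"`.
#' @param resolution Fixed resolution in Angstrom, for `"fixed"` mode.
#' @param resolution_range Range for `"uniform"` mode (default `c(6, 10)`).
#' @param spec_fn Optional zero-argument function returning a segment spec
#'   list for one complex; defaults to the 4-segment layout above.
#' @return The manifest as a data frame (invisibly also written to
#'   `manifest.tsv` and `manifest.json` in `out_dir`).
#' @export
make_fixture_set <- function(n, out_dir, seed = 1L,
                             resolution_mode = c("fixed", "uniform"),
                             resolution = 6.0,
                             resolution_range = c(6, 10),
                             spec_fn = NULL) {
  resolution_mode <- match.arg(resolution_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory %s", out_dir))
  if (is.null(spec_fn)) spec_fn <- default_fixture_spec()
  set.seed(as.integer(seed))
  res <- switch(resolution_mode,
                fixed = rep(resolution, n),
                uniform = stats::runif(n, resolution_range[1], resolution_range[2]))
  specs <- lapply(seq_len(n), function(i) spec_fn())
  seeds <- sample.int(2^30, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("fx%03d", i)
    cx <- build_toy_complex(specs[[i]], seed = seeds[i])
    m <- simulate_map(cx, resolution = res[i])
    map_f <- file.path(out_dir, paste0(id, ".mrc"))
    pdb_f <- file.path(out_dir, paste0(id, ".pdb"))
    lab_f <- file.path(out_dir, paste0(id, "_labels.tsv"))
    write_map(m, map_f)
    write_structure(cx, pdb_f, lab_f)
    rows[[i]] <- data.frame(id = id, map = basename(map_f),
                            structure = basename(pdb_f),
                            labels = basename(lab_f),
                            resolution = res[i],
                            complex_seed = seeds[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = as.integer(seed),
                            resolution_mode = resolution_mode,
                            entries = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load one fixture entry (map + labeled structure)
#'
#' @param manifest Manifest data frame from [make_fixture_set()].
#' @param i Row index.
#' @param dir The fixture directory.
#' @return List with `map` (normalized [density_map]) and `complex`.
#' @export
load_fixture <- function(manifest, i, dir) {
  m <- read_map(file.path(dir, manifest$map[i]))
  m$resolution <- manifest$resolution[i]
  cx <- read_structure(file.path(dir, manifest$structure[i]),
                       file.path(dir, manifest$labels[i]))
  list(map = normalize_map(resample_to_unit_grid(m), "simulated"), complex = cx)
}
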