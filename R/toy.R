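# Toy protein / nucleic-acid complexes with known per-residue class labels.
# These stand in for PDB entries: residues carry only heavy pseudo-atoms
# (4 backbone + 1 side-chain atom per amino acid, ~20 atoms per nucleotide),
# which is all the labeling rules ever look at. No hydrogens are modeled.

DEG <- pi / 180

random_rotation <- function() {
  # uniform-ish rotation via QR of a Gaussian matrix, det forced to +1
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# returns list(atoms = matrix n x 3, element, residue_index) in local coords
segment_helix <- function(len) {
  i <- 0:(len - 1)
  th <- i * 100 * DEG
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  at <- function(t) cbind(2.3 * cos(t * 100 * DEG), 2.3 * sin(t * 100 * DEG), 1.5 * t)
  n_ <- at(i - 0.35)
  c_ <- at(i + 0.35)
  u <- cbind(cos(th + 35 * DEG), sin(th + 35 * DEG), 0)
  o_ <- c_ + 1.23 * u
  cb <- ca + 1.53 * cbind(cos(th), sin(th), 0)
  list(coords = rbind(n_, ca, c_, o_, cb),
       element = rep(c("N", "C", "C", "O", "C"), each = len),
       name = rep(c("N", "CA", "C", "O", "CB"), each = len),
       residue_index = rep(i + 1L, times = 5L),
       atoms_per_residue = 5L)
}

segment_strand <- function(len) {
  i <- 0:(len - 1)
  zig <- 0.95 * (-1)^i
  ca <- cbind(zig, 0, 3.3 * i)
  n_ <- ca + cbind(-0.4 * (-1)^i, 0.4, -1.2)
  c_ <- ca + cbind(-0.4 * (-1)^i, -0.4, 1.2)
  o_ <- c_ + cbind(rep(0, len), -1.23, 0)
  cb <- ca + cbind(1.3 * (-1)^i, 0.9, 0)
  list(coords = rbind(n_, ca, c_, o_, cb),
       element = rep(c("N", "C", "C", "O", "C"), each = len),
       name = rep(c("N", "CA", "C", "O", "CB"), each = len),
       residue_index = rep(i + 1L, times = 5L),
       atoms_per_residue = 5L)
}

segment_coil <- function(len) {
  # self-avoiding random walk of CA positions, 3.8 A steps
  ca <- matrix(0, len, 3)
  dir <- c(1, 0, 0)
  if (len > 1) {
    for (k in 2:len) {
      placed <- FALSE
      for (try in 1:200) {
        prop <- stats::rnorm(3)
        prop <- prop / sqrt(sum(prop^2))
        cand_dir <- 0.6 * dir + prop          # mild persistence
        cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
        cand <- ca[k - 1, ] + 3.8 * cand_dir
        ok <- TRUE
        if (k > 2) {
          dd <- sqrt(rowSums((ca[1:(k - 2), , drop = FALSE] -
                                matrix(cand, k - 2, 3, byrow = TRUE))^2))
          ok <- all(dd >= 3.2)
        }
        if (ok) { ca[k, ] <- cand; dir <- cand_dir; placed <- TRUE; break }
      }
      if (!placed) stop("coil self-avoiding walk failed after bounded retries")
    }
  }
  # local frame perpendiculars for the remaining backbone pseudo-atoms
  perp <- function(v) {
    w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- cross3(v, w); p / sqrt(sum(p^2))
  }
  n_ <- ca; c_ <- ca; o_ <- ca; cb <- ca
  for (k in seq_len(len)) {
    v <- if (k < len) ca[min(k + 1, len), ] - ca[k, ] else ca[k, ] - ca[max(k - 1, 1), ]
    if (all(v == 0)) v <- c(1, 0, 0)
    v <- v / sqrt(sum(v^2))
    p1 <- perp(v); p2 <- cross3(v, p1)
    n_[k, ] <- ca[k, ] - 1.0 * v + 1.0 * p1
    c_[k, ] <- ca[k, ] + 1.0 * v + 1.0 * p1
    o_[k, ] <- c_[k, ] + 1.23 * p2
    cb[k, ] <- ca[k, ] + 1.53 * p2 * (-1)
  }
  i <- seq_len(len)
  list(coords = rbind(n_, ca, c_, o_, cb),
       element = rep(c("N", "C", "C", "O", "C"), each = len),
       name = rep(c("N", "CA", "C", "O", "CB"), each = len),
       residue_index = rep(i, times = 5L),
       atoms_per_residue = 5L)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

segment_nucleic <- function(len) {
  # single helical strand: rise 3.4 A/nt, twist 36 deg, backbone radius 9 A,
  # ~20 heavy atoms per nucleotide (phosphate + sugar ring + base blob)
  coords <- NULL; element <- character(0); resi <- integer(0)
  for (k in 0:(len - 1)) {
    th <- k * 36 * DEG
    u <- c(cos(th), sin(th), 0)              # radial (outward)
    t_ <- c(-sin(th), cos(th), 0)            # tangent
    z <- c(0, 0, 1)
    base_z <- 3.4 * k
    pos <- function(r, dt, dz) r * u + dt * t_ + (base_z + dz) * z
    pts <- rbind(
      pos(9.0, 0.0, 0.0),                    # P
      pos(9.6, 1.2, 0.6), pos(9.6, -1.2, 0.6), # O1P, O2P
      pos(8.2, 0.8, 1.2),                    # O5'
      pos(7.6, 0.4, 1.8),                    # C5'
      pos(7.2, -0.6, 1.4),                   # C4'
      pos(7.4, -1.6, 0.8),                   # O4'
      pos(6.4, -0.4, 0.4),                   # C3'
      pos(6.6, 0.6, -0.4),                   # O3'
      pos(5.8, -1.2, 1.2),                   # C2'
      pos(6.2, -2.0, 1.8),                   # C1'
      # base blob: 9 atoms in a planar-ish disc reaching toward the axis
      pos(5.0, -1.6, 1.8), pos(4.2, -0.8, 1.8), pos(3.4, -1.2, 1.8),
      pos(2.6, -0.6, 1.8), pos(2.8, 0.6, 1.8), pos(3.6, 1.0, 1.8),
      pos(4.4, 0.4, 1.8), pos(2.0, 1.2, 1.8), pos(1.4, 0.2, 1.8))
    coords <- rbind(coords, pts)
    element <- c(element, c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C",
                            "C", "C", "N", "C", "N", "C", "C", "O", "N"))
    resi <- c(resi, rep(k + 1L, 20L))
  }
  nm <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'",
          "C1'", "C4", "C5", "N7", "C8", "N9", "C6", "C2", "O6", "N1")
  list(coords = coords, element = element, name = rep(nm, times = len),
       residue_index = resi, atoms_per_residue = 20L)
}

segment_kind_label <- c(helix = "HELIX", strand = "STRAND",
                        coil = "OTHER", nucleic = "NUCLEIC")

#' Build a toy protein/nucleic complex with known labels
#'
#' Assembles idealised structural segments -- alpha-helices (rise 1.5
#' A/residue, 100-degree twist, C-alpha radius 2.3 A), extended zigzag
#' beta-strands (~3.3 A rise), self-avoiding random-walk coils (3.8 A steps)
#' and single-stranded helical nucleic chains (3.4 A rise, ~20 heavy atoms per
#' nucleotide) -- into one complex with non-overlapping placement. Each
#' segment becomes its own chain; every residue carries a ground-truth class
#' label derived from the segment kind.
#'
#' @param spec A list of segment descriptors; each a list with `kind` (one of
#'   `"helix"`, `"strand"`, `"coil"`, `"nucleic"`) and `length` (residues or
#'   nucleotides, >= 1).
#' @param seed Integer seed; the same `spec` and `seed` give identical
#'   coordinates.
#' @param min_sep Minimum inter-segment heavy-atom distance in Angstrom
#'   (default 5).
#' @return An object of class `toy_complex`: a list with `atoms` (data frame:
#'   `element`, `x`, `y`, `z`, `chain_id`, `residue_index`, `residue_name`,
#'   `is_nucleic`) and `labels` (data frame: `chain_id`, `residue_index`,
#'   `label`).
#' @export
build_toy_complex <- function(spec, seed = 1L, min_sep = 5) {
  if (length(spec) < 1L) stop("`spec` must describe at least one segment")
  kinds <- vapply(spec, function(s) s$kind, character(1))
  lens <- vapply(spec, function(s) as.integer(s$length), integer(1))
  if (!all(kinds %in% names(segment_kind_label)))
    stop("unknown segment kind; use helix/strand/coil/nucleic")
  if (any(lens < 1L)) stop("segment lengths must be >= 1")
  set.seed(as.integer(seed))

  built <- lapply(seq_along(spec), function(j) {
    switch(kinds[j],
           helix = segment_helix(lens[j]),
           strand = segment_strand(lens[j]),
           coil = segment_coil(lens[j]),
           nucleic = segment_nucleic(lens[j]))
  })

  placed <- list()
  box <- 12 + 9 * length(spec)^(1 / 3)     # cube side, grown on failure
  for (j in seq_along(built)) {
    seg <- built[[j]]
    ctr <- colMeans(seg$coords)
    local <- sweep(seg$coords, 2, ctr)
    ok <- FALSE
    for (try in 1:300) {
      rot <- random_rotation()
      shift <- stats::runif(3, -box / 2, box / 2)
      cand <- local %*% t(rot) + matrix(shift, nrow(local), 3, byrow = TRUE)
      clash <- FALSE
      for (p in placed) {
        dmin <- min_pair_distance(cand, p)
        if (dmin < min_sep) { clash <- TRUE; break }
      }
      if (!clash) { placed[[j]] <- cand; ok <- TRUE; break }
      if (try %% 50 == 0) box <- box * 1.15
    }
    if (!ok) stop("unsatisfiable segment placement after bounded retries")
  }

  chain_ids <- LETTERS[seq_along(spec)]
  atoms <- do.call(rbind, lapply(seq_along(spec), function(j) {
    seg <- built[[j]]
    data.frame(
      element = seg$element,
      name = seg$name,
      x = placed[[j]][, 1], y = placed[[j]][, 2], z = placed[[j]][, 3],
      chain_id = chain_ids[j],
      residue_index = seg$residue_index,
      residue_name = if (kinds[j] == "nucleic") "ADE" else "ALA",
      is_nucleic = kinds[j] == "nucleic",
      stringsAsFactors = FALSE)
  }))
  labels <- do.call(rbind, lapply(seq_along(spec), function(j) {
    data.frame(chain_id = chain_ids[j],
               residue_index = seq_len(lens[j]),
               label = segment_kind_label[[kinds[j]]],
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL; rownames(labels) <- NULL
  structure(list(atoms = atoms, labels = labels, segment_kinds = kinds),
            class = "toy_complex")
}

min_pair_distance <- function(a, b) {
  # min over all pairs; chunked to bound memory
  best <- Inf
  step <- 2000L
  for (s in seq(1, nrow(a), by = step)) {
    ia <- s:min(s + step - 1, nrow(a))
    d2 <- outer(rowSums(a[ia, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ia, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy_complex> %d atoms, %d residues, %d chains (%s)\n",
              nrow(x$atoms), nrow(x$labels),
              length(unique(x$atoms$chain_id)),
              paste(x$segment_kinds, collapse = ", ")))
  invisible(x)
}

atom_coords <- function(cx) as.matrix(cx$atoms[, c("x", "y", "z")])

# per-atom class label (character), via the residue label table
atom_class <- function(cx) {
  key <- paste(cx$atoms$chain_id, cx$atoms$residue_index)
  lab <- cx$labels$label[match(key, paste(cx$labels$chain_id, cx$labels$residue_index))]
  if (anyNA(lab)) stop("atom with no residue label")
  lab
}
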