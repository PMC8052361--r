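test_that("STRIDE codes map to the four classes", {
  expect_identical(stride_to_class("G", FALSE), "HELIX")
  expect_identical(stride_to_class("H", FALSE), "HELIX")
  expect_identical(stride_to_class("I", FALSE), "HELIX")
  expect_identical(stride_to_class("E", FALSE), "STRAND")
  expect_identical(stride_to_class("B", FALSE), "STRAND")
  expect_identical(stride_to_class("b", FALSE), "STRAND")
  expect_identical(stride_to_class(c("T", "C", " "), FALSE),
                   rep("OTHER", 3))
  # nucleic atoms are NUCLEIC regardless of any code
  expect_identical(stride_to_class(c("H", "E", "T"), TRUE),
                   rep("NUCLEIC", 3))
  # unknown codes fall through to OTHER with a message, never an error
  expect_message(out <- stride_to_class("Z", FALSE), "unknown")
  expect_identical(out, "OTHER")
})

test_that("STRIDE reports parse into per-residue labels", {
  rpt <- c(
    "REM  --------------- Secondary structure summary ---------------",
    "ASG  ALA A    1    1    H    AlphaHelix    -57.16    -47.51     92.3",
    "ASG  GLY A    2    2    E    Strand        -60.00    140.00     10.1",
    "ASG  SER B    7    3    C    Coil           80.00     10.00     55.0")
  p <- withr::local_tempfile()
  writeLines(rpt, p)
  tab <- read_stride(p)
  expect_identical(tab$label, c("HELIX", "STRAND", "OTHER"))
  expect_identical(tab$chain_id, c("A", "A", "B"))
  expect_identical(tab$residue_index, c(1L, 2L, 7L))
  tab2 <- read_stride(p, nucleic_chains = "B")
  expect_identical(tab2$label[3], "NUCLEIC")
  expect_error(read_stride(withr::local_tempfile()), "not found")
})

test_that("the 3-Angstrom labeling rule is boundary-inclusive and nearest-wins", {
  m <- synthetic_norm_map(c(11, 11, 11))
  place <- function(coords, classes) {
    n <- length(classes)
    atoms <- data.frame(element = "C", name = "X1",
                        x = sapply(coords, `[`, 1),
                        y = sapply(coords, `[`, 2),
                        z = sapply(coords, `[`, 3),
                        chain_id = "A", residue_index = seq_len(n),
                        residue_name = "ALA", is_nucleic = classes == "NUCLEIC",
                        stringsAsFactors = FALSE)
    labels <- data.frame(chain_id = "A", residue_index = seq_len(n),
                         label = classes, stringsAsFactors = FALSE)
    structure(list(atoms = atoms, labels = labels), class = "toy_complex")
  }
  # helix atom at 2.9 A from lattice point (4,4,4): included, {HELIX}
  lg <- label_grid(m, place(list(c(4 + 2.9, 4, 4)), "HELIX"))
  expect_true(lg$included[3, 3, 3])
  expect_identical(class_labels()[lg$primary[3, 3, 3]], "HELIX")
  expect_identical(which(lg$label_set[3, 3, 3, ]), 1L)

  # nearest atom at 3.1 A: excluded
  lg2 <- label_grid(m, place(list(c(4, 4, 4 + 3.1)), "HELIX"))
  expect_false(lg2$included[3, 3, 3])

  # exactly 3.0 A: the boundary is inclusive
  lg3 <- label_grid(m, place(list(c(4 + 3.0, 4, 4)), "HELIX"))
  expect_true(lg3$included[3, 3, 3])

  # helix at 1.0 A and nucleic at 2.5 A: both in the set, primary = nearest
  lg4 <- label_grid(m, place(list(c(4 + 1.0, 4, 4), c(4, 4 + 2.5, 4)),
                             c("HELIX", "NUCLEIC")))
  expect_identical(sort(class_labels()[which(lg4$label_set[3, 3, 3, ])]),
                   c("HELIX", "NUCLEIC"))
  expect_identical(class_labels()[lg4$primary[3, 3, 3]], "HELIX")

  empty <- structure(list(atoms = data.frame(x = numeric(0), y = numeric(0),
                                             z = numeric(0)),
                          labels = data.frame()), class = "toy_complex")
  expect_error(label_grid(m, empty), "empty")
})

test_that("label_grid matches the all-pairs brute force on random structures", {
  for (s in 1:3) {
    m <- synthetic_norm_map(c(17, 15, 16), origin = c(-3, 2, 5), seed = s)
    cx <- random_structure(25, box = 14, seed = s + 100)
    cx$atoms$x <- cx$atoms$x - 3; cx$atoms$y <- cx$atoms$y + 2
    cx$atoms$z <- cx$atoms$z + 5
    lg <- label_grid(m, cx)
    bf <- brute_label_grid(m, cx)
    expect_identical(lg$included, bf$included)
    expect_identical(lg$primary, bf$primary)
    expect_identical(lg$label_set, bf$label_set)
  }
})

test_that("voxel extraction enumerates the stride-2 lattice with zero padding", {
  # fully included 21^3 map: 11^3 = 1331 stride-2 centers
  m <- synthetic_norm_map(c(21, 21, 21))
  grid <- density_inclusion_grid(m, threshold = -1)   # everything included
  expect_identical(sum(grid$included), 1331L)
  vox <- extract_voxels(m, grid)
  expect_identical(ncol(vox$X), 1331L)
  expect_true(all(vox$X >= 0 & vox$X <= 1))

  # center at lattice index (1,1,1) (map point (2,2,2)): window rows that fall
  # outside the map are zero-padded
  m2 <- synthetic_norm_map(c(9, 9, 9), seed = 4)
  m2$values[] <- pmax(m2$values, 0.05)       # strictly positive map
  g2 <- density_inclusion_grid(m2)
  v2 <- extract_voxels(m2, g2)
  first <- which(v2$centers[, 1] == 1 & v2$centers[, 2] == 1 & v2$centers[, 3] == 1)
  w <- array(v2$X[, first], c(11, 11, 11))
  expect_true(all(w[1:3, , ] == 0))          # map x-index range covered: -3..7
  expect_equal(w[4:11, 4:11, 4:11], m2$values[1:8, 1:8, 1:8])

  # window values match a brute-force gather for random centers
  cx <- random_structure(20, box = 12, seed = 6)
  m3 <- synthetic_norm_map(c(15, 15, 15), seed = 7)
  lg3 <- label_grid(m3, cx)
  v3 <- extract_voxels(m3, lg3)
  expect_identical(ncol(v3$X), sum(lg3$included))
  pad <- array(0, dim(m3$values) + 10)
  pad[6:20, 6:20, 6:20] <- m3$values
  for (q in sample(ncol(v3$X), min(5, ncol(v3$X)))) {
    ci <- v3$centers[q, ] * 2 + 1            # corner in padded coords
    expect_identical(array(v3$X[, q], c(11, 11, 11)),
                     pad[ci[1]:(ci[1] + 10), ci[2]:(ci[2] + 10),
                         ci[3]:(ci[3] + 10)])
  }
  # labels carried through in deterministic x-fastest order
  expect_identical(as.integer(v3$primary), lg3$primary[which(lg3$included)])
})

test_that("balanced batches hit their quotas exactly, with replacement if needed", {
  cx <- tiny_complex(seed = 13)
  m <- normalize_map(simulate_map(cx, 6), "simulated")
  lg <- label_grid(m, cx)
  vox <- extract_voxels(m, lg)

  b <- balanced_batches(vox, task = "multiclass", n_batches = 3, seed = 1)
  for (idx in b) {
    expect_length(idx, 256L)
    expect_true(all(table(vox$primary[idx]) == 64L))
  }
  for (cl in class_labels()) {
    bb <- balanced_batches(vox, task = "binary", positive_class = cl,
                           n_batches = 2, seed = 2)
    for (idx in bb) {
      pos <- vox$label_set[idx, cl]
      expect_identical(sum(pos), 128L)
      expect_identical(sum(!pos), 128L)
    }
  }

  # a stratum smaller than its quota is sampled with replacement
  small <- list(primary = factor(c(rep("HELIX", 100), rep("STRAND", 100),
                                   rep("OTHER", 10), rep("NUCLEIC", 100)),
                                 levels = class_labels()),
                label_set = NULL)
  small$label_set <- matrix(FALSE, 310, 4, dimnames = list(NULL, class_labels()))
  small$label_set[cbind(1:310, as.integer(small$primary))] <- TRUE
  bs <- balanced_batches(small, task = "multiclass", n_batches = 1, seed = 3)
  expect_identical(sum(small$primary[bs[[1]]] == "OTHER"), 64L)

  # empty stratum errors, naming the class
  none <- list(primary = factor(rep(c("HELIX", "STRAND", "OTHER"), 40),
                                levels = class_labels()))
  none$label_set <- matrix(FALSE, 120, 4, dimnames = list(NULL, class_labels()))
  none$label_set[cbind(1:120, as.integer(none$primary))] <- TRUE
  expect_error(balanced_batches(none, task = "multiclass"), "NUCLEIC")
  expect_error(balanced_batches(none, task = "binary",
                                positive_class = "NUCLEIC"), "NUCLEIC")

  # seeded draws are reproducible
  expect_identical(balanced_batches(vox, "multiclass", n_batches = 2, seed = 9),
                   balanced_batches(vox, "multiclass", n_batches = 2, seed = 9))
})
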