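# Shared fixture builders for the test suite. Everything is generated in code
# under fixed seeds; nothing is read from disk except files the tests write.

four_segment_spec <- function() list(
  list(kind = "helix", length = 10),
  list(kind = "strand", length = 6),
  list(kind = "coil", length = 7),
  list(kind = "nucleic", length = 6))

tiny_complex <- function(seed = 7) build_toy_complex(four_segment_spec(), seed = seed)

# a normalized 1-Angstrom map marked as such, for geometry-only tests
synthetic_norm_map <- function(dims, origin = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  m <- density_map(array(runif(prod(dims)), dim = dims), origin = origin)
  m$normalized <- TRUE
  m
}

# a pseudo-structure of unlabeled-geometry random atoms (each its own residue)
random_structure <- function(n_atoms, box = 20, seed = 1) {
  set.seed(seed)
  cls <- sample(class_labels(), n_atoms, replace = TRUE)
  atoms <- data.frame(
    element = sample(c("C", "N", "O"), n_atoms, replace = TRUE),
    name = "X1",
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    chain_id = "A", residue_index = seq_len(n_atoms),
    residue_name = "ALA", is_nucleic = cls == "NUCLEIC",
    stringsAsFactors = FALSE)
  labels <- data.frame(chain_id = "A", residue_index = seq_len(n_atoms),
                       label = cls, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, labels = labels, segment_kinds = NULL),
            class = "toy_complex")
}

# untrained (random-init) phase-1 classifier bundle, for inference-contract
# tests that do not depend on accuracy
untrained_classifiers <- function(width = 1 / 32, seed = 3) {
  clf <- list(binary = list(), multiclass = NULL)
  for (i in seq_along(class_labels())) {
    cfg <- phase1_config(width = width, head = "binary")
    clf$binary[[class_labels()[i]]] <- build_phase1(cfg, seed = seed + i)
  }
  clf$multiclass <- build_phase1(phase1_config(width = width, head = "multiclass"),
                                 seed = seed + 5)
  class(clf) <- "phase1_classifiers"
  clf
}

# construct an assignment_grid + labeled_grid pair directly (no models), for
# metric oracle tests
random_eval_pair <- function(seed, max_dims = c(9, 9, 9)) {
  set.seed(seed)
  ld <- sapply(max_dims, function(d) sample(4:d, 1))
  nlat <- prod(ld)
  included <- array(runif(nlat) < 0.6, dim = ld)
  n <- sum(included)
  if (n == 0) { included[1] <- TRUE; n <- 1 }
  lset <- matrix(FALSE, nlat, 4)
  inc_lin <- which(included)
  for (p in inc_lin) {
    k <- sample(1:2, 1, prob = c(0.8, 0.2))
    lset[p, sample(1:4, k)] <- TRUE
  }
  primary <- integer(nlat)
  primary[inc_lin] <- apply(lset[inc_lin, , drop = FALSE], 1, function(r)
    sample(rep(which(r), 2), 1))
  truth <- structure(list(
    dims = ld, map_dims = 2L * ld - 1L, origin = c(0, 0, 0), stride = 2L,
    included = included, primary = array(primary, dim = ld),
    label_set = array(lset, dim = c(ld, 4L)),
    nearest = array(ifelse(included, 1, Inf), dim = ld)),
    class = "labeled_grid")

  probs <- matrix(stats::rexp(4 * n), n, 4)
  probs <- probs / rowSums(probs)
  labels <- factor(class_labels()[max.col(probs, ties.method = "first")],
                   levels = class_labels())
  ci <- arrayInd(inc_lin, ld) - 1L
  assign <- structure(list(
    dims = ld, origin = c(0, 0, 0), stride = 2L, map_dims = 2L * ld - 1L,
    included = included, inc_lin = inc_lin, probs = probs, labels = labels,
    source = rep("phase2", n), coords = 2 * ci,
    channels = NULL), class = "assignment_grid")
  list(assign = assign, truth = truth)
}
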