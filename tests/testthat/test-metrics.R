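test_that("voxel metrics follow the multi-label precision/recall/F1 definitions", {
  pr <- random_eval_pair(1)
  # perfect assignment on single-label truth: every score is 1
  prim <- pr$truth$primary[pr$truth$included]
  ls1 <- matrix(FALSE, prod(pr$truth$dims), 4)
  ls1[cbind(which(pr$truth$included), prim)] <- TRUE
  pr$truth$label_set <- array(ls1, c(pr$truth$dims, 4))
  perfect <- pr$assign
  perfect$labels <- factor(class_labels()[prim], levels = class_labels())
  vm <- voxel_metrics(perfect, pr$truth)
  present <- vm$per_class$support > 0 & vm$per_class$n_predicted > 0
  expect_true(all(vm$per_class$precision[present] == 1))
  expect_true(all(vm$per_class$recall[vm$per_class$support > 0] == 1))
  expect_equal(vm$overall$accuracy, 1)
  expect_equal(vm$overall$f1, 1)

  # precision 0.5, recall 1 gives F1 = 2/3 (harmonic mean)
  truth <- random_eval_pair(2)$truth
  nlat <- prod(truth$dims)
  truth$included[] <- FALSE; truth$included[1:4] <- TRUE
  truth$label_set <- array(FALSE, c(truth$dims, 4))
  ls <- matrix(FALSE, nlat, 4)
  ls[1:2, 1] <- TRUE; ls[3:4, 2] <- TRUE     # 2 HELIX, 2 STRAND points
  truth$label_set <- array(ls, c(truth$dims, 4))
  truth$primary <- array(0L, truth$dims)
  truth$primary[1:2] <- 1L; truth$primary[3:4] <- 2L
  a <- list(dims = truth$dims, origin = truth$origin, stride = 2L,
            map_dims = truth$map_dims, included = truth$included,
            inc_lin = which(truth$included),
            probs = diag(4)[c(1, 1, 1, 1), ],
            labels = factor(rep("HELIX", 4), levels = class_labels()),
            source = rep("phase2", 4), coords = matrix(0, 4, 3))
  class(a) <- "assignment_grid"
  vm2 <- voxel_metrics(a, truth)
  hel <- vm2$per_class[vm2$per_class$class == "HELIX", ]
  expect_equal(hel$precision, 0.5)
  expect_equal(hel$recall, 1.0)
  expect_equal(hel$f1, 2 / 3)

  # a prediction matching any label in the set counts as correct
  ls[3, 1] <- TRUE                           # point 3 now {HELIX, STRAND}
  truth$label_set <- array(ls, c(truth$dims, 4))
  vm3 <- voxel_metrics(a, truth)
  expect_equal(vm3$overall$accuracy, 3 / 4)

  bad <- a; bad$included <- !truth$included
  expect_error(voxel_metrics(bad, truth), "mismatch|differ")
})

test_that("voxel metrics agree exactly with brute force on random pairs", {
  for (s in 1:10) {
    pr <- random_eval_pair(s + 20)
    vm <- voxel_metrics(pr$assign, pr$truth)
    bf <- brute_voxel_metrics(pr$assign, pr$truth)
    expect_equal(vm$per_class$precision, bf$per$precision, tolerance = 1e-12)
    expect_equal(vm$per_class$recall, bf$per$recall, tolerance = 1e-12)
    expect_equal(vm$per_class$f1, bf$per$f1, tolerance = 1e-12)
    expect_equal(vm$overall$f1, bf$f1, tolerance = 1e-12)
    expect_equal(vm$overall$accuracy, bf$accuracy, tolerance = 1e-12)
  }
})

test_that("residue assignment takes the majority vote with probability tie-breaks", {
  # lattice with 3 assigned points around one residue
  ld <- c(5L, 5L, 5L)
  included <- array(FALSE, ld)
  included[2, 2, 2] <- included[3, 2, 2] <- included[2, 3, 2] <- TRUE
  inc_lin <- which(included)
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1),
                 c(0.6, 0.2, 0.1, 0.1),
                 c(0.1, 0.6, 0.2, 0.1))
  labels <- factor(c("HELIX", "HELIX", "STRAND"), levels = class_labels())
  a <- list(dims = ld, origin = c(0, 0, 0), stride = 2L, map_dims = 2L * ld - 1L,
            included = included, inc_lin = inc_lin, probs = probs,
            labels = labels, source = rep("phase2", 3),
            coords = (arrayInd(inc_lin, ld) - 1L) * 2)
  class(a) <- "assignment_grid"

  # one residue with an atom at (3.5, 2.8, 2.2): within 3 A of all three points
  res <- structure(list(
    atoms = data.frame(element = "C", name = "CA", x = 3.5, y = 2.8, z = 2.2,
                       chain_id = "A", residue_index = 1L, residue_name = "ALA",
                       is_nucleic = FALSE, stringsAsFactors = FALSE),
    labels = data.frame(chain_id = "A", residue_index = 1L, label = "HELIX",
                        stringsAsFactors = FALSE)), class = "toy_complex")
  ra <- residue_assignment(a, res)
  expect_identical(ra$pred, "HELIX")          # majority 2 of 3
  expect_identical(ra$n_points, 3L)

  # 1-1 tie between HELIX and STRAND: higher mean probability wins
  a2 <- a
  a2$included[2, 3, 2] <- FALSE
  a2$inc_lin <- which(a2$included)
  a2$probs <- rbind(c(0.55, 0.40, 0.03, 0.02),
                    c(0.30, 0.65, 0.03, 0.02))
  a2$labels <- factor(c("HELIX", "STRAND"), levels = class_labels())
  a2$source <- rep("phase2", 2)
  ra2 <- residue_assignment(a2, res)
  expect_identical(ra2$pred, "STRAND")        # mean p_strand 0.525 > p_helix 0.425

  # residue far from every assigned point is unassigned
  res_far <- res
  res_far$atoms$x <- 100
  ra3 <- residue_assignment(a, res_far)
  expect_true(is.na(ra3$pred))
  expect_identical(ra3$n_points, 0L)
})

test_that("Q scores aggregate per-class fractions as weighted averages", {
  truth <- rep(c("HELIX", "STRAND"), each = 4)
  pred <- c(rep("HELIX", 4), "STRAND", "STRAND", "HELIX", "HELIX")
  q <- q_scores(truth = truth, pred = pred)
  expect_equal(unname(q$per_class["HELIX"]), 1.0)
  expect_equal(unname(q$per_class["STRAND"]), 0.5)
  expect_equal(q$Q4, 0.75)                   # equal class sizes
  expect_equal(q$Q3, 0.75)
  expect_equal(q$Q2, 1.0)                    # all protein under the collapse

  # all correct
  qq <- q_scores(truth = truth, pred = truth)
  expect_equal(qq$Q4, 1); expect_equal(qq$Q3, 1); expect_equal(qq$Q2, 1)

  # Q3 is not-applicable (never 0) without protein residues
  qn <- q_scores(truth = rep("NUCLEIC", 5), pred = rep("NUCLEIC", 5))
  expect_true(is.na(qn$Q3))
  expect_equal(qn$Q4, 1)

  # NA predictions are excluded but counted
  q2 <- q_scores(truth = c("HELIX", "HELIX"), pred = c("HELIX", NA))
  expect_equal(q2$Q4, 1)
  expect_identical(q2$n_unassigned, 1L)

  expect_error(q_scores(truth = truth, pred = pred[-1]), "length")
})

test_that("the Q2 collapse can flip a four-class NUCLEIC call to PROTEIN", {
  pv <- protein_vs_nucleic(c(0.2, 0.2, 0.2, 0.4))
  expect_identical(pv$label, "PROTEIN")
  expect_equal(pv$p_protein, 0.6)
  expect_identical(protein_vs_nucleic(c(0.1, 0.1, 0.1, 0.7))$label, "NUCLEIC")
  # exact tie goes to protein
  expect_identical(protein_vs_nucleic(c(0.25, 0.15, 0.10, 0.50))$label, "PROTEIN")
  expect_error(protein_vs_nucleic(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")

  # through q_scores: argmax label NUCLEIC, probability-sum says PROTEIN
  q <- q_scores(truth = "HELIX", pred = "NUCLEIC",
                probs = matrix(c(0.2, 0.2, 0.2, 0.4), 1))
  expect_equal(q$Q2, 1.0)                    # collapse fixed the call
  expect_equal(q$Q4, 0.0)
})

test_that("cyclic label permutation on balanced truth zeroes recall and Q4", {
  truth <- rep(class_labels(), each = 10)
  perm <- c(class_labels()[-1], class_labels()[1])
  pred <- perm[match(truth, class_labels())]
  q <- q_scores(truth = truth, pred = pred)
  expect_true(all(q$per_class == 0))
  expect_equal(q$Q4, 0)
})

test_that("correcting one wrong residue never decreases any Q score", {
  set.seed(12)
  truth <- sample(class_labels(), 60, replace = TRUE)
  pred <- sample(class_labels(), 60, replace = TRUE)
  base <- q_scores(truth = truth, pred = pred)
  wrong <- which(pred != truth)
  for (w in wrong[seq_len(min(10, length(wrong)))]) {
    fixed <- pred; fixed[w] <- truth[w]
    q <- q_scores(truth = truth, pred = fixed)
    expect_gte(q$Q4, base$Q4)
    if (!is.na(base$Q3) && !is.na(q$Q3)) expect_gte(q$Q3, base$Q3)
    ok <- !is.na(q$per_class) & !is.na(base$per_class)
    expect_true(all(q$per_class[ok] >= base$per_class[ok]))
  }
})

test_that("segment enumeration honors length thresholds and the 50% rule", {
  mk <- function(truth, pred, chain = "A", start = 1L) {
    data.frame(chain_id = chain,
               residue_index = seq(start, length.out = length(truth)),
               truth = truth, pred = pred, stringsAsFactors = FALSE)
  }
  # helix run of 6 with exactly 3 correct: 50% >= 50% counts as correct
  r <- mk(rep("HELIX", 6), c("HELIX", "HELIX", "HELIX", "OTHER", "OTHER", "OTHER"))
  sa <- segment_accuracy(r)
  expect_identical(sa$n_helix_segments, 1L)
  expect_equal(sa$helix, 1.0)

  # helix run of 5 is not a segment
  r2 <- mk(rep("HELIX", 5), rep("HELIX", 5))
  sa2 <- segment_accuracy(r2)
  expect_identical(sa2$n_helix_segments, 0L)
  expect_true(is.na(sa2$helix))

  # strand run of 3, all correct
  r3 <- mk(rep("STRAND", 3), rep("STRAND", 3))
  expect_equal(segment_accuracy(r3)$strand, 1.0)

  # 2 of 6 correct fails the 50% rule
  r4 <- mk(rep("HELIX", 6), c("HELIX", "HELIX", rep("STRAND", 4)))
  expect_equal(segment_accuracy(r4)$helix, 0.0)

  # a residue-numbering gap breaks a run
  r5 <- rbind(mk(rep("STRAND", 2), rep("STRAND", 2), start = 1L),
              mk(rep("STRAND", 2), rep("STRAND", 2), start = 10L))
  expect_identical(segment_accuracy(r5)$n_strand_segments, 0L)

  # segments are disjoint and single-class; residues conserved
  set.seed(30)
  truth <- sample(class_labels(), 80, replace = TRUE, prob = c(.4, .3, .2, .1))
  r6 <- mk(truth, sample(class_labels(), 80, replace = TRUE))
  segs <- segment_accuracy(r6)$segments
  if (nrow(segs) > 0) {
    spans <- unlist(lapply(seq_len(nrow(segs)), function(i)
      segs$start[i]:segs$end[i]))
    expect_identical(anyDuplicated(spans), 0L)
    for (i in seq_len(nrow(segs)))
      expect_true(all(truth[segs$start[i]:segs$end[i]] == segs$class[i]))
  }
})
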