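#' Run the desk-scale end-to-end training study
#'
#' Generates a fixture set of simulated maps from toy complexes, splits it
#' cluster-atomically into phase-1 / phase-2 / test pools, trains the five
#' phase-1 classifiers and the phase-2 refiner, and evaluates on the held-out
#' test maps. This is the package's self-contained, reproducible analog of the
#' full training campaign, sized to run on one CPU in minutes: by default 40
#' maps at 6 Angstrom (20 phase-1, 10 phase-2, 10 test), a width-1/16 phase-1
#' network, 5 epochs of 8 balanced optimizer steps.
#'
#' @param seed Integer root seed for every source of randomness.
#' @param n_maps Number of simulated maps.
#' @param resolution Simulated map resolution in Angstrom.
#' @param fractions Pool fractions (phase1, phase2, test).
#' @param width Phase-1 channel-width multiplier.
#' @param epochs Training epochs.
#' @param steps_per_epoch Balanced optimizer steps per epoch.
#' @param dir Working directory for the fixture files (default a tempdir).
#' @param verbose Print progress.
#' @return List with `split`, `classifiers`, `refiner`, test-set summaries:
#'   `voxel_accuracy`, `nucleic_recall`, per-map `q4_phase1`, `q4_phase2`,
#'   `frac_q4_improved`, `overall_f1` (per-map voxel F1, phase 2),
#'   `mean_q3`, `reports` (per-map `evaluation_report`s), and `n_test_voxels`.
#' @export
run_desk_study <- function(seed = 1L, n_maps = 40L, resolution = 6,
                           fractions = c(0.5, 0.25, 0.25), width = 1 / 16,
                           epochs = 5L, steps_per_epoch = 8L,
                           dir = file.path(tempdir(), "em2struct_study"),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(seed)

  say("simulating %d maps at %.1f A ...", n_maps, resolution)
  man <- make_fixture_set(n_maps, dir, seed = (seed + 1013L) %% .Machine$integer.max,
                          resolution_mode = "fixed", resolution = resolution)
  fx <- lapply(seq_len(nrow(man)), function(i) {
    f <- load_fixture(man, i, dir)
    lg <- label_grid(f$map, f$complex)
    list(map = f$map, complex = f$complex, grid = lg,
         vox = extract_voxels(f$map, lg))
  })
  names(fx) <- man$id

  split <- make_split(man$id, fractions = fractions, seed = seed)
  say("split: phase1 %d+%d, phase2 %d+%d, test %d",
      length(split$phase1_train), length(split$phase1_val),
      length(split$phase2_train), length(split$phase2_val),
      length(split$test))

  cfg <- train_config(epochs = epochs, steps_per_epoch = steps_per_epoch,
                      seed = seed)
  net <- phase1_config(width = width)
  tr <- pool_samples(lapply(fx[split$phase1_train], `[[`, "vox"))
  va <- pool_samples(lapply(fx[split$phase1_val], `[[`, "vox"))
  say("training phase 1 (5 classifiers, %d train voxels) ...", ncol(tr$X))
  clf <- train_phase1(tr, va, config = cfg, net = net)

  say("training phase 2 on %d maps ...",
      length(split$phase2_train) + length(split$phase2_val))
  pool <- lapply(fx[c(split$phase2_train, split$phase2_val)],
                 function(f) list(map = f$map, grid = f$grid))
  p2 <- train_phase2(pool, clf, config = cfg,
                     phase1_ids = c(split$phase1_train, split$phase1_val))

  say("evaluating on %d held-out maps ...", length(split$test))
  test_sam <- pool_samples(lapply(fx[split$test], `[[`, "vox"))
  p <- phase1_predict(clf$multiclass, test_sam$X)
  pred <- max.col(t(p), ties.method = "first")
  voxel_accuracy <- mean(test_sam$label_set[cbind(seq_len(ncol(test_sam$X)), pred)])
  nuc <- as.integer(test_sam$primary) == 4L
  nucleic_recall <- mean(pred[nuc] == 4L)

  q1 <- q2v <- f1v <- q3v <- numeric(0)
  reports <- list()
  for (id in split$test) {
    f <- fx[[id]]
    a1 <- detect(f$map, clf, refiner = NULL, include = f$grid)
    a2 <- detect(f$map, clf, refiner = p2$model, include = f$grid)
    r1 <- q_scores(residue_assignment(a1, f$complex))
    rep2 <- evaluate_map(a2, f$grid, f$complex)
    q1 <- c(q1, r1$Q4)
    q2v <- c(q2v, rep2$q$Q4)
    q3v <- c(q3v, rep2$q$Q3)
    f1v <- c(f1v, rep2$voxel$overall$f1)
    reports[[id]] <- rep2
  }

  list(split = split, classifiers = clf, refiner = p2$model,
       train_logs = clf$logs, phase2_log = p2$log,
       voxel_accuracy = voxel_accuracy, nucleic_recall = nucleic_recall,
       q4_phase1 = q1, q4_phase2 = q2v,
       frac_q4_improved = mean(q2v >= q1),
       overall_f1 = f1v, mean_q3 = mean(q3v, na.rm = TRUE),
       reports = reports, n_test_voxels = ncol(test_sam$X),
       n_test_maps = length(split$test))
}
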