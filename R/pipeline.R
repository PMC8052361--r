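# Training and whole-map inference. Phase 1 trains five classifiers (four
# binary, one four-class) on balanced batches from the phase-1 map pool;
# phase 2 trains on a disjoint pool using the frozen phase-1 outputs; detect()
# scans a map at stride 2 and lets phase 2 overwrite the phase-1 assignment
# at every point it covers.

#' Training configuration
#'
#' Defaults follow the published schedule: Adam at learning rate 0.002, L2
#' regularization 1e-5, batch size 256, 30 epochs. An "epoch" is
#' `ceil(n_train / batch_size)` balanced optimizer steps unless
#' `steps_per_epoch` is set (balanced resampling has no natural epoch
#' boundary).
#'
#' @param learning_rate Adam learning rate.
#' @param l2_weight L2 regularization coefficient (applied as weight decay).
#' @param epochs Training epochs (>= 1).
#' @param batch_size Total batch size.
#' @param steps_per_epoch Optional fixed number of optimizer steps per epoch.
#' @param seed Root seed; all sampling and initialization derive from it.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.002, l2_weight = 1e-5,
                         epochs = 30L, batch_size = 256L,
                         steps_per_epoch = NULL, seed = 1L) {
  if (learning_rate <= 0 || l2_weight < 0) stop("rates must be positive")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, l2_weight = l2_weight,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 steps_per_epoch = steps_per_epoch, seed = as.integer(seed)),
            class = "train_config")
}

#' Cluster-respecting split of maps into phase-1 / phase-2 / test pools
#'
#' Assigns whole clusters (never individual maps) to the three pools at the
#' requested fractions, then splits the phase-1 and phase-2 pools 80/20 into
#' train/validation by map. No cluster ever spans two pools, so there is no
#' redundancy between testing and training.
#'
#' @param ids Character or integer vector of map identifiers.
#' @param clusters List of integer vectors (indices into `ids`), e.g. from
#'   [cluster_complete_linkage()]; defaults to all-singleton clusters. Every
#'   id must belong to exactly one cluster.
#' @param fractions Length-3 pool fractions (phase1, phase2, test).
#' @param val_fraction Within-pool validation fraction (default 0.2).
#' @param seed Integer seed.
#' @return A `split_plan`: list of id vectors `phase1_train`, `phase1_val`,
#'   `phase2_train`, `phase2_val`, `test`.
#' @export
make_split <- function(ids, clusters = NULL, fractions = c(0.8, 0.1, 0.1),
                       val_fraction = 0.2, seed = 1L) {
  n <- length(ids)
  if (is.null(clusters)) clusters <- as.list(seq_len(n))
  memb <- unlist(clusters)
  if (!setequal(memb, seq_len(n)) || length(memb) != n)
    stop("every map must belong to exactly one cluster")
  if (length(clusters) < 3L)
    stop("fewer clusters than pools: need at least 3 clusters")
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  fractions <- fractions / sum(fractions)
  set.seed(as.integer(seed))

  # largest-remainder target pool sizes
  raw <- n * fractions
  target <- floor(raw)
  rem <- n - sum(target)
  if (rem > 0) {
    ord <- order(raw - target, decreasing = TRUE)
    target[ord[seq_len(rem)]] <- target[ord[seq_len(rem)]] + 1
  }

  pools <- list(integer(0), integer(0), integer(0))
  deficit <- target
  for (cl in clusters[sample.int(length(clusters))]) {
    p <- which.max(deficit)
    pools[[p]] <- c(pools[[p]], cl)
    deficit[p] <- deficit[p] - length(cl)
  }

  split80 <- function(members) {
    m <- length(members)
    n_val <- max(1L, round(val_fraction * m))
    if (m < 2L) return(list(train = members, val = integer(0)))
    val <- sample(members, n_val)
    list(train = setdiff(members, val), val = val)
  }
  s1 <- split80(pools[[1]])
  s2 <- split80(pools[[2]])
  plan <- list(phase1_train = ids[s1$train], phase1_val = ids[s1$val],
               phase2_train = ids[s2$train], phase2_val = ids[s2$val],
               test = ids[pools[[3]]])
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> phase1 %d+%d (train+val), phase2 %d+%d, test %d\n",
              length(x$phase1_train), length(x$phase1_val),
              length(x$phase2_train), length(x$phase2_val), length(x$test)))
  invisible(x)
}

# concatenate voxel_samples objects (labels required)
pool_samples <- function(sample_list) {
  sample_list <- Filter(Negate(is.null), sample_list)
  if (length(sample_list) == 0L) stop("no samples to pool")
  structure(list(
    X = do.call(cbind, lapply(sample_list, `[[`, "X")),
    primary = factor(unlist(lapply(sample_list, function(s) as.character(s$primary))),
                     levels = class_labels()),
    label_set = do.call(rbind, lapply(sample_list, `[[`, "label_set")),
    window = sample_list[[1]]$window),
    class = "voxel_samples")
}

# one-hot targets in canonical class order
one_hot <- function(labels) {
  Y <- matrix(0, 4L, length(labels))
  Y[cbind(as.integer(labels), seq_along(labels))] <- 1
  Y
}

train_one_classifier <- function(model, train, val, task, positive_class, config) {
  binary <- task == "binary"
  n_train <- ncol(train$X)
  steps <- if (!is.null(config$steps_per_epoch)) config$steps_per_epoch
           else ceiling(n_train / config$batch_size)
  opt <- adam_new(model$layers, lr = config$learning_rate,
                  weight_decay = config$l2_weight)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  best <- list(acc = -Inf, state = NULL)

  val_acc <- function() {
    if (binary) {
      p <- phase1_predict(model, val$X)
      truth <- val$label_set[, positive_class]
      mean((p >= 0.5) == truth)
    } else {
      p <- phase1_predict(model, val$X)
      pred <- max.col(t(p), ties.method = "first")
      mean(val$label_set[cbind(seq_len(ncol(val$X)), pred)])
    }
  }

  for (ep in seq_len(config$epochs)) {
    batches <- balanced_batches(train,
                                task = if (binary) "binary" else "multiclass",
                                positive_class = positive_class,
                                n_batches = steps,
                                batch_size = config$batch_size)
    ep_loss <- 0
    for (idx in batches) {
      Xb <- train$X[, idx, drop = FALSE]
      Z <- net_forward(model$layers, Xb, training = TRUE)
      N <- length(idx)
      if (binary) {
        y <- as.numeric(train$label_set[idx, positive_class])
        p <- sigmoid(as.numeric(Z))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
        dZ <- matrix((p - y) / N, 1L, N)
      } else {
        Y <- one_hot(train$primary[idx])
        P <- softmax_cols(Z)
        loss <- -mean(log(pmax(colSums(P * Y), 1e-12)))
        dZ <- (P - Y) / N
      }
      net_backward(model$layers, dZ)
      adam_step(opt)
      ep_loss <- ep_loss + loss / length(batches)
    }
    net_calibrate_bn(model$layers, train$X,
                     batches[seq_len(min(4L, length(batches)))])
    acc <- val_acc()
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                 val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, state = net_state(model$layers))
  }
  if (!is.null(best$state)) net_restore(model$layers, best$state)
  list(model = model, log = log, best_val_accuracy = best$acc)
}

#' Train the five phase-1 classifiers
#'
#' Trains four binary classifiers (one per structural class; 128 positive +
#' 128 negative windows per batch) and one four-class classifier (64 windows
#' per class per batch) with cross-entropy loss, Adam, and L2 regularization.
#' After each epoch the validation voxel accuracy is logged; the returned
#' classifiers carry the best-validation-epoch weights.
#'
#' @param train_samples,val_samples Pooled `voxel_samples` (see
#'   [extract_voxels()]) for the phase-1 train/validation maps.
#' @param config A [train_config()].
#' @param net A [phase1_config()] whose `head` field is ignored (set per
#'   classifier).
#' @return A `phase1_classifiers` object: list with `binary` (named list of
#'   four models), `multiclass`, and `logs`.
#' @export
train_phase1 <- function(train_samples, val_samples, config = train_config(),
                         net = phase1_config()) {
  present <- table(factor(train_samples$primary, levels = class_labels()))
  if (any(present == 0L))
    stop(sprintf("class absent from training data: %s",
                 paste(names(present)[present == 0L], collapse = ", ")))
  set.seed(config$seed)
  seeds <- sample.int(2^30, 5L)
  logs <- list()

  binary <- list()
  for (i in seq_along(class_labels())) {
    cl <- class_labels()[i]
    cfg <- net; cfg$head <- "binary"
    m <- build_phase1(cfg, seed = seeds[i])
    set.seed(seeds[i] + 1L)
    r <- train_one_classifier(m, train_samples, val_samples,
                              task = "binary", positive_class = cl,
                              config = config)
    binary[[cl]] <- r$model
    logs[[paste0("binary_", cl)]] <- r$log
  }
  cfg <- net; cfg$head <- "multiclass"
  m <- build_phase1(cfg, seed = seeds[5])
  set.seed(seeds[5] + 1L)
  r <- train_one_classifier(m, train_samples, val_samples,
                            task = "multiclass", positive_class = NULL,
                            config = config)
  logs$multiclass <- r$log
  structure(list(binary = binary, multiclass = r$model, logs = logs),
            class = "phase1_classifiers")
}

#' Scan a map with the phase-1 classifiers
#'
#' Evaluates all five classifiers on the 11^3 window of every included
#' stride-2 point and stores the 8 probability channels in canonical order:
#' binary HELIX, STRAND, OTHER, NUCLEIC, then the four multiclass softmax
#' probabilities.
#'
#' @param map Normalized [density_map] at 1-Angstrom spacing.
#' @param classifiers A `phase1_classifiers` object.
#' @param include A `labeled_grid` defining the included points; default
#'   [density_inclusion_grid()] (normalized density > 0).
#' @return A `probability_grid`: lattice geometry, `included`, and `channels`
#'   (`n_lattice x 8` matrix, zero rows where excluded).
#' @export
scan_phase1 <- function(map, classifiers, include = NULL) {
  if (is.null(include)) include <- density_inclusion_grid(map)
  vox <- extract_voxels(map, include, window = classifiers$multiclass$config$window)
  n <- ncol(vox$X)
  ch <- matrix(0, prod(include$dims), 8L)
  if (n > 0) {
    for (i in seq_along(class_labels())) {
      ch[vox$inc_lin, i] <- phase1_predict(classifiers$binary[[class_labels()[i]]],
                                           vox$X)
    }
    ch[vox$inc_lin, 5:8] <- t(phase1_predict(classifiers$multiclass, vox$X))
  }
  structure(list(dims = include$dims, origin = include$origin, stride = 2L,
                 map_dims = include$map_dims,
                 included = include$included, channels = ch,
                 inc_lin = vox$inc_lin),
            class = "probability_grid")
}

# 7^3 x 8 neighborhoods around every included lattice point (zero-filled
# outside the lattice and at excluded points); rows channel-fastest to match
# the phase-2 convolution layout.
phase2_neighborhoods <- function(pgrid, radius = 3L) {
  ld <- pgrid$dims
  side <- 2L * radius + 1L
  pld <- ld + 2L * radius
  A8 <- array(0, dim = c(8L, pld))
  ch <- t(pgrid$channels)                       # 8 x n_lattice
  dim(ch) <- c(8L, ld)
  A8[, (radius + 1):(radius + ld[1]), (radius + 1):(radius + ld[2]),
     (radius + 1):(radius + ld[3])] <- ch
  inc_lin <- which(pgrid$included)
  ci <- arrayInd(inc_lin, ld) - 1L
  # corner (0-based lattice index of the window corner) in padded coords = ci
  corner <- 1L + 8L * (ci[, 1] + ci[, 2] * pld[1] + ci[, 3] * pld[1] * pld[2])
  sp <- spatial_grid(c(side, side, side))
  off <- 8L * (sp[, 1] + sp[, 2] * pld[1] + sp[, 3] * pld[1] * pld[2])
  off <- as.vector(outer(0:7, off, "+"))
  X <- matrix(A8[outer(off, corner, "+")], nrow = 8L * side^3,
              ncol = length(inc_lin))
  list(X = X, inc_lin = inc_lin)
}

#' Train the phase-2 refinement network
#'
#' Builds 7^3 x 8 neighborhoods of phase-1 probabilities around every included
#' point of the phase-2 pool maps (missing neighbors zero-filled), with the
#' center's primary label as target, and trains with cross-entropy. The
#' phase-2 pool must be disjoint from the maps used to train phase 1.
#'
#' @param pool Named list (one entry per phase-2 pool map) of lists with
#'   `map` (normalized [density_map]) and `grid` (its [label_grid()]).
#' @param classifiers Trained `phase1_classifiers`.
#' @param config A [train_config()].
#' @param net A [phase2_config()].
#' @param phase1_ids Ids of maps used in phase-1 training/validation; overlap
#'   with `names(pool)` is an error.
#' @param val_fraction Fraction of pool maps held out for validation.
#' @return List with `model` (a `phase2_model`) and `log`.
#' @export
train_phase2 <- function(pool, classifiers, config = train_config(),
                         net = phase2_config(), phase1_ids = NULL,
                         val_fraction = 0.2) {
  if (!is.null(phase1_ids) && length(intersect(names(pool), phase1_ids)) > 0)
    stop("phase-2 pool overlaps phase-1 maps: pools must be disjoint")
  set.seed(config$seed)

  per_map <- lapply(pool, function(entry) {
    pg <- scan_phase1(entry$map, classifiers, include = entry$grid)
    nb <- phase2_neighborhoods(pg)
    prim <- entry$grid$primary[nb$inc_lin]
    list(X = nb$X, y = prim)
  })
  n_maps <- length(per_map)
  n_val <- max(1L, round(val_fraction * n_maps))
  if (n_maps < 2L) stop("phase-2 pool needs at least 2 maps")
  val_ix <- sample.int(n_maps, n_val)
  bindx <- function(ix) list(
    X = do.call(cbind, lapply(per_map[ix], `[[`, "X")),
    y = unlist(lapply(per_map[ix], `[[`, "y")))
  tr <- bindx(setdiff(seq_len(n_maps), val_ix))
  va <- bindx(val_ix)

  model <- build_phase2(net, seed = config$seed)
  opt <- adam_new(model$layers, lr = config$learning_rate,
                  weight_decay = config$l2_weight)
  n_train <- ncol(tr$X)
  steps <- if (!is.null(config$steps_per_epoch)) config$steps_per_epoch
           else ceiling(n_train / config$batch_size)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  best <- list(acc = -Inf, state = NULL)
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    for (s in seq_len(steps)) {
      idx <- sample.int(n_train, min(config$batch_size, n_train))
      Z <- net_forward(model$layers, tr$X[, idx, drop = FALSE], training = TRUE)
      Y <- matrix(0, 4L, length(idx))
      Y[cbind(tr$y[idx], seq_along(idx))] <- 1
      P <- softmax_cols(Z)
      ep_loss <- ep_loss + -mean(log(pmax(colSums(P * Y), 1e-12))) / steps
      net_backward(model$layers, (P - Y) / length(idx))
      adam_step(opt)
    }
    net_calibrate_bn(model$layers, tr$X,
                     lapply(seq_len(min(4L, steps)), function(s)
                       sample.int(n_train, min(config$batch_size, n_train))))
    pv <- phase2_predict(model, va$X)
    acc <- mean(max.col(t(pv), ties.method = "first") == va$y)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                 val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, state = net_state(model$layers))
  }
  if (!is.null(best$state)) net_restore(model$layers, best$state)
  list(model = model, log = log, best_val_accuracy = best$acc)
}

#' Detect structural classes across a whole map
#'
#' Runs the phase-1 scan, then the phase-2 refiner at every included stride-2
#' point; phase 2 overwrites the phase-1 result wherever it runs (everywhere,
#' except points whose entire 7^3 neighborhood carries no phase-1 output,
#' which keep the phase-1 multiclass argmax). Argmax ties break by canonical
#' class order.
#'
#' @param map Normalized [density_map] at 1-Angstrom spacing.
#' @param classifiers Trained `phase1_classifiers`.
#' @param refiner Trained `phase2_model` (or NULL for phase-1-only output).
#' @param include Optional inclusion `labeled_grid`; default density rule.
#' @return An `assignment_grid`: lattice geometry, `included`, `probs`
#'   (`n_included x 4`), `labels` (factor), `source` (`"phase1"`/`"phase2"`),
#'   `coords` (n x 3 Angstrom), plus the phase-1 `channels`.
#' @export
detect <- function(map, classifiers, refiner = NULL, include = NULL) {
  pg <- scan_phase1(map, classifiers, include = include)
  inc_lin <- pg$inc_lin
  n <- length(inc_lin)
  p1_probs <- pg$channels[inc_lin, 5:8, drop = FALSE]
  if (!is.null(refiner) && n > 0) {
    nb <- phase2_neighborhoods(pg)
    stopifnot(identical(nb$inc_lin, inc_lin))
    covered <- colSums(abs(nb$X)) > 0
    probs <- p1_probs
    src <- rep("phase1", n)
    if (any(covered)) {
      probs[covered, ] <- t(phase2_predict(refiner, nb$X[, covered, drop = FALSE]))
      src[covered] <- "phase2"
    }
  } else {
    probs <- p1_probs
    src <- rep("phase1", n)
  }
  labels <- factor(class_labels()[max.col(probs, ties.method = "first")],
                   levels = class_labels())
  ci <- arrayInd(inc_lin, pg$dims) - 1L
  structure(list(dims = pg$dims, origin = pg$origin, stride = 2L,
                 map_dims = pg$map_dims,
                 included = pg$included, inc_lin = inc_lin,
                 probs = probs, labels = labels, source = src,
                 coords = sweep(2 * ci, 2, pg$origin, "+"),
                 channels = pg$channels),
            class = "assignment_grid")
}

#' @export
print.assignment_grid <- function(x, ...) {
  cat(sprintf("<assignment_grid> %d assigned points on a %s stride-2 lattice\n",
              length(x$inc_lin), paste(x$dims, collapse = "x")))
  print(table(x$labels))
  invisible(x)
}

#' Collapse four-class probabilities to protein vs nucleic
#'
#' The protein probability is the sum of the three secondary-structure class
#' probabilities; the label is `PROTEIN` when it is at least the nucleic
#' probability (ties go to protein). Note a point labeled NUCLEIC by 4-class
#' argmax can collapse to PROTEIN (e.g. probabilities 0.2/0.2/0.2/0.4).
#'
#' @param probs Numeric vector of 4 probabilities (canonical order), or an
#'   `n x 4` matrix; each row must sum to 1 (tolerance 1e-6).
#' @return Data frame with `label` (`"PROTEIN"`/`"NUCLEIC"`), `p_protein`,
#'   `p_nucleic`.
#' @export
protein_vs_nucleic <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 4L) stop("probs must have 4 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probabilities must sum to 1")
  p_prot <- rowSums(probs[, 1:3, drop = FALSE])
  p_nuc <- probs[, 4]
  data.frame(label = ifelse(p_prot >= p_nuc, "PROTEIN", "NUCLEIC"),
             p_protein = p_prot, p_nucleic = p_nuc,
             stringsAsFactors = FALSE)
}

#' Write detection results
#'
#' `write_detect_tsv` writes one row per assigned grid point: x, y, z
#' (Angstrom), the four class probabilities, the label and the source phase.
#' `write_detect_pdb` writes a pseudo-atom PDB for visualization: one HETATM
#' per point, residue name encoding the class (ALA = helix, VAL = strand,
#' GLY = other, ADE = nucleic), B-factor = the maximum probability.
#'
#' @param assign An `assignment_grid` from [detect()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detect_tsv <- function(assign, path) {
  df <- data.frame(x = assign$coords[, 1], y = assign$coords[, 2],
                   z = assign$coords[, 3],
                   p_helix = assign$probs[, 1], p_strand = assign$probs[, 2],
                   p_other = assign$probs[, 3], p_nucleic = assign$probs[, 4],
                   label = as.character(assign$labels),
                   source = assign$source)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detect_tsv
#' @export
write_detect_pdb <- function(assign, path) {
  resname <- c(HELIX = "ALA", STRAND = "VAL", OTHER = "GLY", NUCLEIC = "ADE")
  n <- length(assign$inc_lin)
  lines <- sprintf(
    "HETATM%5d  C   %3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(n) %% 100000,
    resname[as.character(assign$labels)],
    seq_len(n) %% 10000,
    assign$coords[, 1], assign$coords[, 2], assign$coords[, 3],
    apply(assign$probs, 1, max))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
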