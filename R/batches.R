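#' Balanced batch index sampling
#'
#' Batch composition follows the training scheme: binary tasks draw 128
#' positive and 128 negative windows per batch (positives are samples whose
#' label set contains the target class); the four-class task draws 64 windows
#' per class (by primary label), giving batches of 256 in both cases. Strata
#' smaller than their quota are sampled with replacement.
#'
#' @param samples A `voxel_samples` object (with labels), or a list with
#'   `primary` and `label_set`.
#' @param task `"multiclass"` or `"binary"`.
#' @param positive_class For binary tasks, the target class label.
#' @param n_batches Number of batches to draw.
#' @param batch_size Total batch size (default 256).
#' @param seed Optional integer seed (seeds the draw reproducibly).
#' @return List of length `n_batches`; each element is an integer vector of
#'   sample indices of length `batch_size`.
#' @export
balanced_batches <- function(samples, task = c("multiclass", "binary"),
                             positive_class = NULL, n_batches = 1L,
                             batch_size = 256L, seed = NULL) {
  task <- match.arg(task)
  if (is.null(samples$primary)) stop("samples carry no labels")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(samples$primary)

  if (task == "binary") {
    if (is.null(positive_class) || !(positive_class %in% class_labels()))
      stop("binary task needs `positive_class` from class_labels()")
    pos <- which(samples$label_set[, positive_class])
    neg <- setdiff(seq_len(n), pos)
    if (length(pos) == 0L)
      stop(sprintf("no positive samples for class %s", positive_class))
    if (length(neg) == 0L)
      stop(sprintf("no negative samples for class %s", positive_class))
    strata <- list(pos, neg)
    quota <- rep(batch_size %/% 2L, 2L)
  } else {
    strata <- lapply(class_labels(), function(cl) which(samples$primary == cl))
    empty <- lengths(strata) == 0L
    if (any(empty))
      stop(sprintf("no samples with primary label %s",
                   paste(class_labels()[empty], collapse = ", ")))
    quota <- rep(batch_size %/% 4L, 4L)
  }

  lapply(seq_len(n_batches), function(b) {
    unlist(lapply(seq_along(strata), function(s) {
      st <- strata[[s]]
      sample(st, quota[s], replace = length(st) < quota[s])
    }), use.names = FALSE)
  })
}

#' Cluster maps by complete linkage on sequence identity
#'
#' Agglomerates items on the distance `1 - identity`: starting from
#' singletons, repeatedly merges the pair of clusters with the smallest
#' complete-linkage distance (the maximum pairwise distance between members)
#' while that distance is at most `1 - threshold`. With the default threshold
#' of 0.35, items sharing >= 35% identity (directly or through a chain of
#' complete-linkage merges) end up in one cluster. Ties in the merge order are
#' broken deterministically by the lexicographically smallest cluster pair
#' (clusters ordered by their smallest member index).
#'
#' @param identity Symmetric matrix of pairwise sequence identities in
#'   `[0, 1]` with unit diagonal.
#' @param threshold Identity threshold (default 0.35).
#' @return List of integer vectors, each a cluster of item indices (sorted);
#'   clusters ordered by smallest member.
#' @export
cluster_complete_linkage <- function(identity, threshold = 0.35) {
  identity <- as.matrix(identity)
  n <- nrow(identity)
  if (n != ncol(identity)) stop("identity matrix must be square")
  if (n == 0L) return(list())
  if (max(abs(identity - t(identity))) > 1e-12)
    stop("identity matrix must be symmetric")
  if (any(abs(diag(identity) - 1) > 1e-12))
    stop("identity matrix must have unit diagonal")
  dmax <- 1 - threshold

  clusters <- as.list(seq_len(n))
  d <- 1 - identity
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL; best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        cl_d <- max(d[clusters[[i]], clusters[[j]]])
        if (cl_d < best_d - 1e-15) { best_d <- cl_d; best <- c(i, j) }
      }
    }
    if (best_d > dmax) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    # keep clusters ordered by smallest member for deterministic tie-breaks
    clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  }
  clusters[order(vapply(clusters, min, integer(1)))]
}
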