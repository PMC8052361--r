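# Independent brute-force oracles: plain nested loops, no code shared with
# the implementation they check.

brute_label_grid <- function(map, cx, radius = 3.0) {
  d <- dim(map$values); org <- map$origin
  ld <- as.integer(floor((d - 1) / 2) + 1)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")])
  key <- paste(cx$atoms$chain_id, cx$atoms$residue_index)
  lab <- cx$labels$label[match(key, paste(cx$labels$chain_id,
                                          cx$labels$residue_index))]
  cls <- match(lab, class_labels())
  included <- array(FALSE, ld); primary <- array(0L, ld)
  lset <- array(FALSE, c(ld, 4))
  for (i in 0:(ld[1] - 1)) for (j in 0:(ld[2] - 1)) for (k in 0:(ld[3] - 1)) {
    p <- org + 2 * c(i, j, k)
    dd <- sqrt(colSums((t(xyz) - p)^2))
    w <- which(dd <= radius)
    if (length(w) > 0) {
      included[i + 1, j + 1, k + 1] <- TRUE
      primary[i + 1, j + 1, k + 1] <- cls[w[which.min(dd[w])]]
      for (c_ in unique(cls[w])) lset[i + 1, j + 1, k + 1, c_] <- TRUE
    }
  }
  list(included = included, primary = primary, label_set = lset)
}

brute_voxel_metrics <- function(assign, truth) {
  inc <- which(truth$included)
  nlat <- prod(truth$dims)
  lset <- matrix(truth$label_set, nlat, 4)
  pred <- as.integer(assign$labels)
  per <- data.frame(class = class_labels(), tp = 0, n_predicted = 0,
                    support = 0, precision = 0, recall = NA_real_, f1 = 0)
  n_correct <- 0
  for (q in seq_along(inc)) {
    if (lset[inc[q], pred[q]]) n_correct <- n_correct + 1
  }
  for (c_ in 1:4) {
    tp <- 0; npred <- 0; supp <- 0
    for (q in seq_along(inc)) {
      if (pred[q] == c_) {
        npred <- npred + 1
        if (lset[inc[q], c_]) tp <- tp + 1
      }
      if (lset[inc[q], c_]) supp <- supp + 1
    }
    prec <- if (npred > 0) tp / npred else 0
    rec <- if (supp > 0) tp / supp else NA_real_
    f1 <- if (!is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[c_, c("tp", "n_predicted", "support", "precision", "recall", "f1")] <-
      list(tp, npred, supp, prec, rec, f1)
  }
  w <- per$support
  wa <- function(x) { ok <- !is.na(x) & w > 0; sum(x[ok] * w[ok]) / sum(w[ok]) }
  list(per = per, precision = wa(per$precision), recall = wa(per$recall),
       f1 = wa(per$f1), accuracy = n_correct / length(inc))
}

brute_q_scores <- function(truth, pred, probs = NULL) {
  keep <- !is.na(pred)
  truth <- truth[keep]; pred <- pred[keep]
  if (!is.null(probs)) probs <- probs[keep, , drop = FALSE]
  per <- setNames(rep(NA_real_, 4), class_labels())
  for (cl in class_labels()) {
    denom <- 0; num <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl) {
        denom <- denom + 1
        if (pred[i] == cl) num <- num + 1
      }
    }
    if (denom > 0) per[cl] <- num / denom
  }
  q4 <- 0; n <- length(truth)
  for (i in seq_len(n)) if (pred[i] == truth[i]) q4 <- q4 + 1
  q4 <- if (n > 0) q4 / n else NA_real_
  prot_n <- 0; prot_ok <- 0
  for (i in seq_len(n)) {
    if (truth[i] %in% c("HELIX", "STRAND", "OTHER")) {
      prot_n <- prot_n + 1
      if (pred[i] == truth[i]) prot_ok <- prot_ok + 1
    }
  }
  q3 <- if (prot_n > 0) prot_ok / prot_n else NA_real_
  q2_ok <- 0
  for (i in seq_len(n)) {
    t2 <- if (truth[i] == "NUCLEIC") "NUCLEIC" else "PROTEIN"
    p2 <- if (!is.null(probs)) {
      if (probs[i, 1] + probs[i, 2] + probs[i, 3] >= probs[i, 4])
        "PROTEIN" else "NUCLEIC"
    } else if (pred[i] == "NUCLEIC") "NUCLEIC" else "PROTEIN"
    if (t2 == p2) q2_ok <- q2_ok + 1
  }
  q2 <- if (n > 0) q2_ok / n else NA_real_
  list(per_class = per, Q4 = q4, Q3 = q3, Q2 = q2)
}

brute_segment_accuracy <- function(chain_id, residue_index, truth, pred) {
  o <- order(chain_id, residue_index)
  chain_id <- chain_id[o]; residue_index <- residue_index[o]
  truth <- truth[o]; pred <- pred[o]
  n <- length(truth)
  counts <- c(HELIX = 0, STRAND = 0); correct <- c(HELIX = 0, STRAND = 0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && chain_id[j + 1] == chain_id[i] &&
           residue_index[j + 1] == residue_index[j] + 1 &&
           truth[j + 1] == truth[i]) j <- j + 1
    cl <- truth[i]; len <- j - i + 1
    min_len <- if (cl == "HELIX") 6 else if (cl == "STRAND") 3 else Inf
    if (len >= min_len) {
      counts[cl] <- counts[cl] + 1
      hits <- 0
      for (q in i:j) if (!is.na(pred[q]) && pred[q] == cl) hits <- hits + 1
      if (hits / len >= 0.5) correct[cl] <- correct[cl] + 1
    }
    i <- j + 1
  }
  list(helix = if (counts["HELIX"] > 0) unname(correct["HELIX"] / counts["HELIX"]) else NA_real_,
       strand = if (counts["STRAND"] > 0) unname(correct["STRAND"] / counts["STRAND"]) else NA_real_,
       n_helix = unname(counts["HELIX"]), n_strand = unname(counts["STRAND"]))
}

# Independent oracle: Lance-Williams complete-linkage agglomeration on a
# shrinking distance matrix (the implementation recomputes max-over-members
# from scratch instead), with the same documented lexicographic tie-break.
lw_complete_oracle <- function(identity, threshold = 0.35) {
  n <- nrow(identity)
  D <- 1 - identity
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    # order candidate pairs by (min member of i, min member of j)
    key <- vapply(idx, function(i) min(members[[i]]), integer(1))
    idx <- idx[order(key)]
    best <- NULL; best_d <- Inf
    for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
      dv <- D[idx[a], idx[b]]
      if (dv < best_d - 1e-15) { best_d <- dv; best <- c(idx[a], idx[b]) }
    }
    if (best_d > 1 - threshold) break
    i <- best[1]; j <- best[2]
    # Lance-Williams update for complete linkage: d(k, ij) = max(d(k,i), d(k,j))
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- max(D[k, i], D[k, j])
    }
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    active[j] <- FALSE
  }
  out <- members[active]
  out[order(vapply(out, min, integer(1)))]
}

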