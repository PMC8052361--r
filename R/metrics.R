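# Three-level evaluation: multi-label voxel precision/recall/F1, majority-vote
# residue/nucleotide Q-scores (Q4/Q3/Q2), and segment-level accuracy. Every
# ratio is reported together with its numerator and denominator.

#' Voxel-level precision, recall and F1 against a labeled grid
#'
#' A prediction at a grid point is correct iff it belongs to the point's label
#' set (a voxel may legitimately carry several classes within the 3-Angstrom
#' radius). Per class `c`: precision = correct predictions of `c` / all
#' predictions of `c`; recall = correct predictions of `c` / all points whose
#' label set contains `c`; F1 = their harmonic mean (0 when precision + recall
#' is 0). Overall values are averages over classes weighted by true class
#' counts; `accuracy` is the plain fraction of points whose prediction is in
#' their label set.
#'
#' @param assign An `assignment_grid` from [detect()].
#' @param truth The matching [label_grid()].
#' @return List with `per_class` (data frame), `overall` (precision, recall,
#'   f1, accuracy), and `n_points`.
#' @export
voxel_metrics <- function(assign, truth) {
  if (!identical(as.integer(assign$dims), as.integer(truth$dims)))
    stop("lattice mismatch between assignment and truth")
  if (!identical(which(assign$included), which(truth$included)))
    stop("included-point sets differ between assignment and truth")
  inc <- assign$inc_lin
  n <- length(inc)
  pred <- as.integer(assign$labels)
  lset <- matrix(truth$label_set, nrow = prod(truth$dims), ncol = 4L)[inc, , drop = FALSE]
  correct <- lset[cbind(seq_len(n), pred)]

  per <- lapply(1:4, function(c) {
    n_pred <- sum(pred == c)
    tp <- sum(pred == c & lset[, c])
    support <- sum(lset[, c])
    precision <- if (n_pred > 0) tp / n_pred else 0
    recall <- if (support > 0) tp / support else NA_real_
    f1 <- if (!is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(class = class_labels()[c], tp = tp, n_predicted = n_pred,
               support = support, precision = precision, recall = recall,
               f1 = f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- per$support
  wavg <- function(x) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  list(per_class = per,
       overall = list(precision = wavg(per$precision),
                      recall = wavg(per$recall),
                      f1 = wavg(per$f1),
                      accuracy = mean(correct)),
       n_points = n)
}

#' Majority-vote residue/nucleotide assignment
#'
#' For each residue or nucleotide, collects the assigned grid points within
#' `radius` (3.0 Angstrom) of any of its heavy atoms; the predicted class is
#' the majority vote over those points, ties broken by the highest mean class
#' probability; residues with no collected point are unassigned (`NA`) and
#' excluded from Q-scores (their count is reported).
#'
#' @param assign An `assignment_grid` from [detect()].
#' @param structure The structure aligned to the map.
#' @param radius Collection radius in Angstrom (default 3.0).
#' @return Data frame, one row per residue: `chain_id`, `residue_index`,
#'   `truth`, `pred` (NA when unassigned), `n_points`, and the mean class
#'   probabilities `p_helix`..`p_nucleic`.
#' @export
residue_assignment <- function(assign, structure, radius = LABEL_RADIUS) {
  xyz <- atom_coords(structure)
  if (nrow(xyz) == 0L) stop("empty structure")
  at_res <- paste(structure$atoms$chain_id, structure$atoms$residue_index)
  res_tab <- structure$labels
  res_key <- paste(res_tab$chain_id, res_tab$residue_index)

  ld <- assign$dims
  org <- assign$origin
  nlat <- prod(ld)
  lin_of_point <- match(seq_len(nlat), assign$inc_lin)  # lattice -> assigned row

  pts_by_res <- vector("list", nrow(res_tab))
  names(pts_by_res) <- res_key
  r2max <- radius^2
  for (i in seq_len(nrow(xyz))) {
    a <- xyz[i, ]
    lo <- pmax(ceiling((a - radius - org) / 2), 0)
    hi <- pmin(floor((a + radius - org) / 2), ld - 1)
    if (any(hi < lo)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    nx <- length(ix); ny <- length(iy); nz <- length(iz)
    d2 <- rep((org[1] + 2 * ix - a[1])^2, times = ny * nz) +
      rep(rep((org[2] + 2 * iy - a[2])^2, each = nx), times = nz) +
      rep((org[3] + 2 * iz - a[3])^2, each = nx * ny)
    li <- (rep(ix, times = ny * nz) +
             rep(rep(iy, each = nx), times = nz) * ld[1] +
             rep(iz, each = nx * ny) * ld[1] * ld[2]) + 1L
    li <- li[d2 <= r2max]
    rows <- lin_of_point[li]
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) next
    k <- at_res[i]
    pts_by_res[[k]] <- c(pts_by_res[[k]], rows)
  }

  out <- res_tab
  out$truth <- res_tab$label
  out$label <- NULL
  out$pred <- NA_character_
  out$n_points <- 0L
  pm <- matrix(NA_real_, nrow(res_tab), 4L)
  for (r in seq_len(nrow(res_tab))) {
    rows <- unique(pts_by_res[[res_key[r]]])
    if (length(rows) == 0L) next
    out$n_points[r] <- length(rows)
    votes <- tabulate(as.integer(assign$labels[rows]), nbins = 4L)
    meanp <- colMeans(assign$probs[rows, , drop = FALSE])
    pm[r, ] <- meanp
    top <- which(votes == max(votes))
    out$pred[r] <- class_labels()[
      if (length(top) == 1L) top else top[which.max(meanp[top])]]
  }
  out$p_helix <- pm[, 1]; out$p_strand <- pm[, 2]
  out$p_other <- pm[, 3]; out$p_nucleic <- pm[, 4]
  out
}

#' Residue-level Q-scores
#'
#' Per-class fraction of residues/nucleotides whose class is correctly
#' assigned. `Q4` is the class-size-weighted average over the four classes
#' (equal to the plain fraction correct); `Q3` restricts to residues whose
#' true class is a protein class; `Q2` is the fraction correct after
#' collapsing truth and prediction to protein vs nucleic (prediction collapsed
#' through [protein_vs_nucleic()] on the mean probabilities when available).
#' Unassigned residues (NA predictions) are excluded from all denominators and
#' counted in `n_unassigned`. Scores whose denominator is empty are `NA`
#' (not-applicable), never 0.
#'
#' @param residues Data frame from [residue_assignment()], or two vectors via
#'   `truth`/`pred` arguments.
#' @param truth,pred Optional label vectors (used when `residues` is NULL).
#' @param probs Optional `n x 4` matrix of mean class probabilities for the
#'   Q2 collapse.
#' @return List with `per_class` fractions, `Q4`, `Q3`, `Q2`, counts.
#' @export
q_scores <- function(residues = NULL, truth = NULL, pred = NULL, probs = NULL) {
  if (!is.null(residues)) {
    truth <- residues$truth
    pred <- residues$pred
    pc <- c("p_helix", "p_strand", "p_other", "p_nucleic")
    if (is.null(probs) && all(pc %in% names(residues)))
      probs <- as.matrix(residues[, pc])
  }
  if (length(truth) != length(pred)) stop("length mismatch between truth and prediction")
  assigned <- !is.na(pred)
  n_unassigned <- sum(!assigned)
  t_ <- factor(truth[assigned], levels = class_labels())
  p_ <- factor(pred[assigned], levels = class_labels())
  if (!is.null(probs)) probs <- probs[assigned, , drop = FALSE]

  per_class <- vapply(class_labels(), function(cl) {
    sel <- t_ == cl
    if (!any(sel)) return(NA_real_)
    mean(p_[sel] == cl)
  }, numeric(1))
  q4 <- if (length(t_) > 0) mean(p_ == t_) else NA_real_
  prot <- t_ %in% protein_classes()
  q3 <- if (any(prot)) mean(p_[prot] == t_[prot]) else NA_real_

  collapse <- function(x) ifelse(x == "NUCLEIC", "NUCLEIC", "PROTEIN")
  t2 <- collapse(as.character(t_))
  p2 <- if (!is.null(probs) && !anyNA(probs)) {
    protein_vs_nucleic(probs)$label
  } else collapse(as.character(p_))
  q2 <- if (length(t2) > 0) mean(p2 == t2) else NA_real_

  list(per_class = per_class, Q4 = q4, Q3 = q3, Q2 = q2,
       n_assigned = length(t_), n_unassigned = n_unassigned)
}

#' Segment-level accuracy for helices and strands
#'
#' A segment is a maximal run of consecutive residues (same chain, contiguous
#' residue numbering) sharing one true secondary-structure class, with minimum
#' length 6 for helices and 3 for strands. A segment is correctly assigned
#' iff at least 50% of its residues are predicted with the segment's class.
#'
#' @param residues Data frame with `chain_id`, `residue_index`, `truth`,
#'   `pred` (e.g. from [residue_assignment()]).
#' @return List with per-class accuracy (`helix`, `strand`; NA when no
#'   segment exists), counts, and the enumerated `segments` data frame.
#' @export
segment_accuracy <- function(residues) {
  df <- residues[order(residues$chain_id, residues$residue_index), ]
  min_len <- c(HELIX = 6L, STRAND = 3L)
  segs <- list()
  for (ch in unique(df$chain_id)) {
    d <- df[df$chain_id == ch, ]
    if (nrow(d) == 0L) next
    # run breaks on class change or residue-number gap
    new_run <- c(TRUE, d$truth[-1] != d$truth[-nrow(d)] |
                   diff(d$residue_index) != 1L)
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      rows <- which(run_id == r)
      cl <- d$truth[rows[1]]
      if (!cl %in% names(min_len)) next
      if (length(rows) < min_len[[cl]]) next
      frac <- mean(!is.na(d$pred[rows]) & d$pred[rows] == cl)
      segs[[length(segs) + 1L]] <- data.frame(
        chain_id = ch, start = d$residue_index[rows[1]],
        end = d$residue_index[rows[length(rows)]], class = cl,
        length = length(rows), frac_correct = frac,
        correct = frac >= 0.5, stringsAsFactors = FALSE)
    }
  }
  segs <- if (length(segs) > 0) do.call(rbind, segs) else
    data.frame(chain_id = character(0), start = integer(0), end = integer(0),
               class = character(0), length = integer(0),
               frac_correct = numeric(0), correct = logical(0))
  acc <- function(cl) {
    s <- segs[segs$class == cl, ]
    if (nrow(s) == 0L) NA_real_ else mean(s$correct)
  }
  list(helix = acc("HELIX"), strand = acc("STRAND"),
       n_helix_segments = sum(segs$class == "HELIX"),
       n_strand_segments = sum(segs$class == "STRAND"),
       segments = segs)
}

#' Full evaluation of a map assignment
#'
#' Bundles voxel metrics, residue assignment, Q-scores and segment accuracy
#' into one report.
#'
#' @param assign An `assignment_grid`.
#' @param truth The matching [label_grid()].
#' @param structure The structure with per-residue labels.
#' @return An `evaluation_report` list.
#' @export
evaluate_map <- function(assign, truth, structure) {
  vm <- voxel_metrics(assign, truth)
  res <- residue_assignment(assign, structure)
  qs <- q_scores(res)
  sa <- segment_accuracy(res)
  rep_ <- list(voxel = vm, residues = res, q = qs, segment = sa)
  class(rep_) <- "evaluation_report"
  rep_
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Voxel level (multi-label):\n")
  print(x$voxel$per_class, row.names = FALSE, digits = 3)
  ov <- x$voxel$overall
  cat(sprintf("  overall: precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f  (n=%d)\n",
              ov$precision, ov$recall, ov$f1, ov$accuracy, x$voxel$n_points))
  cat("Residue/nucleotide level:\n")
  pcs <- paste(sprintf("%s %.3f", names(x$q$per_class), x$q$per_class),
               collapse = "  ")
  cat(" ", pcs, "\n")
  cat(sprintf("  Q4 %.3f  Q3 %s  Q2 %s  (assigned %d, unassigned %d)\n",
              x$q$Q4,
              ifelse(is.na(x$q$Q3), "NA", sprintf("%.3f", x$q$Q3)),
              ifelse(is.na(x$q$Q2), "NA", sprintf("%.3f", x$q$Q2)),
              x$q$n_assigned, x$q$n_unassigned))
  cat(sprintf("Segment level: helix %s (n=%d)  strand %s (n=%d)\n",
              ifelse(is.na(x$segment$helix), "NA", sprintf("%.3f", x$segment$helix)),
              x$segment$n_helix_segments,
              ifelse(is.na(x$segment$strand), "NA", sprintf("%.3f", x$segment$strand)),
              x$segment$n_strand_segments))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    voxel = list(per_class = report$voxel$per_class,
                 overall = report$voxel$overall,
                 n_points = report$voxel$n_points),
    q_scores = list(per_class = as.list(report$q$per_class),
                    Q4 = report$q$Q4, Q3 = report$q$Q3, Q2 = report$q$Q2,
                    n_assigned = report$q$n_assigned,
                    n_unassigned = report$q$n_unassigned),
    segment = list(helix = report$segment$helix,
                   strand = report$segment$strand,
                   n_helix_segments = report$segment$n_helix_segments,
                   n_strand_segments = report$segment$n_strand_segments))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
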