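#' Confusion matrix container
#'
#' A labeled non-negative integer count grid: rows are true classes, columns
#' detected/predicted classes.
#'
#' @param counts numeric matrix (or something coercible).
#' @param labels row/column labels (used for both when `col_labels` is
#'   NULL).
#' @param col_labels optional distinct column labels.
#' @return Matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts),
                             col_labels = NULL) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion matrix counts must be non-negative integers")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(m)) stop("label/dimension mismatch")
    rownames(m) <- labels
    colnames(m) <- col_labels %||% labels
  }
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Match detections against annotations
#'
#' Greedy one-to-one matching: detections are visited in descending score
#' order, each claiming the still-unmatched annotation of highest IoU
#' provided that IoU reaches `iou_threshold`. Leftover detections are false
#' positives, leftover annotations false negatives. (False positive/negative
#' rates are advisory on real scans, where annotation is incomplete and
#' unmatched detections are often genuine nodes.)
#'
#' @param detections detection data.frame (needs `score`).
#' @param annotations annotation box data.frame.
#' @param iou_threshold minimum IoU for a match.
#' @return List with `matches` (data.frame `detection`, `annotation`,
#'   `iou`), `false_positives` (detection row indices) and
#'   `false_negatives` (annotation row indices).
#' @export
match_detections <- function(detections, annotations, iou_threshold = 0.5) {
  nd <- nrow(detections); na <- nrow(annotations)
  matches <- data.frame(detection = integer(0), annotation = integer(0),
                        iou = numeric(0))
  if (nd > 0L && na > 0L) {
    m <- iou_matrix(detections, annotations)
    ord <- order(-detections$score, detections$x_min, detections$y_min)
    taken <- logical(na)
    for (i in ord) {
      cand <- which(!taken & m[i, ] >= iou_threshold)
      if (length(cand) > 0L) {
        j <- cand[which.max(m[i, cand])]
        taken[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(detection = i, annotation = j,
                                    iou = m[i, j]))
      }
    }
  }
  list(matches = matches,
       false_positives = setdiff(seq_len(nd), matches$detection),
       false_negatives = setdiff(seq_len(na), matches$annotation))
}

#' Node-type confusion over a test set
#'
#' Counts (true type, detected type) over matched detection/annotation pairs
#' only. The true type of an annotation is the proxy label of its image's
#' taxon; in two-type mode hybrid images have no defined truth and are
#' rejected.
#'
#' @param pairs data.frame with columns `true_type` and `detected_type`
#'   (one row per matched pair), e.g. from [evaluate_detector()].
#' @param type_set active node types.
#' @return [confusion_matrix()] with `type_set` rows and columns.
#' @export
node_confusion <- function(pairs, type_set = c("H", "L")) {
  bad <- setdiff(unique(c(pairs$true_type, pairs$detected_type)), type_set)
  if (length(bad) > 0L) {
    stop("node type(s) ", paste(bad, collapse = ", "),
         " outside the active type set {",
         paste(type_set, collapse = ", "),
         "}; hybrid images have no true node type in two-type mode")
  }
  counts <- table(factor(pairs$true_type, levels = type_set),
                  factor(pairs$detected_type, levels = type_set))
  confusion_matrix(unclass(as.matrix(counts)), labels = type_set)
}

#' Cross-type accuracy of a node confusion matrix
#'
#' Fraction of matched nodes whose detected type equals the true type:
#' trace over total.
#'
#' @param m square [confusion_matrix()].
#' @return Named list with `accuracy` (raw fraction) and `percent` (rounded
#'   to the nearest percent, half away from zero).
#' @export
cross_type_accuracy <- function(m) {
  if (nrow(m) != ncol(m)) stop("cross-type accuracy needs a square matrix")
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(m)) / total
  list(accuracy = acc, percent = as.integer(round_half_up(100 * acc)))
}

#' Pairwise confusion rate between two node types
#'
#' Restricted to entries whose true AND detected types are both in
#' `{type_a, type_b}`, the fraction with true != detected — e.g. how often
#' H and F nodes are mistaken for one another.
#'
#' @param m [confusion_matrix()].
#' @param type_a,type_b the two types.
#' @return List with `errors`, `total`, `rate`.
#' @export
pairwise_confusion_rate <- function(m, type_a, type_b) {
  pair <- c(type_a, type_b)
  if (!all(pair %in% rownames(m)) || !all(pair %in% colnames(m))) {
    stop("types must be present in both axes")
  }
  sub <- m[pair, pair]
  errors <- sum(sub) - sum(diag(sub))
  list(errors = errors, total = sum(sub),
       rate = if (sum(sub) > 0) errors / sum(sub) else 0)
}

#' Error count within one confusion-matrix margin
#'
#' Off-diagonal count and total along one row or column — e.g. "nodes in
#' *E. laevigatum* images are classified incorrectly only six times out of
#' 96" is the L column's off-diagonal count over its sum.
#'
#' @param m [confusion_matrix()].
#' @param label row/column label.
#' @param margin `"column"` or `"row"`.
#' @return List with `errors`, `total`, `rate`.
#' @export
label_error_count <- function(m, label, margin = c("column", "row")) {
  margin <- match.arg(margin)
  v <- if (margin == "column") m[, label] else m[label, ]
  correct <- unname(v[label])
  list(errors = sum(v) - correct, total = sum(v),
       rate = if (sum(v) > 0) (sum(v) - correct) / sum(v) else 0)
}

#' Taxon confusion matrix and image-level accuracy
#'
#' @param true_labels,predicted_labels equal-length taxon vectors.
#' @return [confusion_matrix()] over the three taxa (rows true, columns
#'   predicted).
#' @export
taxon_confusion <- function(true_labels, predicted_labels) {
  true_labels <- check_taxon(true_labels)
  predicted_labels <- check_taxon(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  counts <- table(factor(true_labels, levels = TAXA),
                  factor(predicted_labels, levels = TAXA))
  confusion_matrix(unclass(as.matrix(counts)), labels = TAXA)
}

#' @rdname taxon_confusion
#' @param m square [confusion_matrix()].
#' @return `image_accuracy`: list with `accuracy`, `percent`, `correct`,
#'   `total`.
#' @export
image_accuracy <- function(m) {
  a <- cross_type_accuracy(m)
  c(a, list(correct = sum(diag(m)), total = sum(m)))
}

#' Evaluate a detector on annotated images
#'
#' Runs [detect()] on each image, matches against its node annotations,
#' and assembles the matched-pair table plus FP/FN counts.
#'
#' @param model trained `node_detector`.
#' @param images list of [annotated_image()] with pixel data and taxa.
#' @param iou_threshold match threshold.
#' @param score_threshold,overlap_threshold passed to [detect()].
#' @return List with `pairs` (image_id, true_type, detected_type, iou,
#'   score), `n_false_positives`, `n_false_negatives`, `n_detections`,
#'   `n_annotations`.
#' @export
evaluate_detector <- function(model, images, iou_threshold = 0.5,
                              score_threshold = 0.3,
                              overlap_threshold = 0.5) {
  pairs <- list(); fp <- 0L; fn <- 0L; ndet <- 0L; nann <- 0L
  for (img in images) {
    det <- detect(model, img$image, score_threshold, overlap_threshold)
    gt <- node_ground_truth(img)
    res <- match_detections(det, gt, iou_threshold)
    ndet <- ndet + nrow(det); nann <- nann + nrow(gt)
    fp <- fp + length(res$false_positives)
    fn <- fn + length(res$false_negatives)
    if (nrow(res$matches) > 0L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        image_id = img$image_id,
        true_type = gt$node_type[res$matches$annotation],
        detected_type = det$node_type[res$matches$detection],
        iou = res$matches$iou,
        score = det$score[res$matches$detection])
    }
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(image_id = character(0), true_type = character(0),
               detected_type = character(0), iou = numeric(0),
               score = numeric(0))
  list(pairs = pairs, n_false_positives = fp, n_false_negatives = fn,
       n_detections = ndet, n_annotations = nann)
}

#' Render a confusion matrix with its derived metrics
#'
#' Formats a node or taxon confusion matrix as a compact report:
#' the count grid plus the derived percentages (cross-type accuracy for node
#' tables, classification accuracy for taxon tables, and the H/F pairwise
#' confusion when an F row is present).
#'
#' @param m [confusion_matrix()] (or a plain labeled matrix of counts).
#' @param kind `"node"` or `"taxon"`.
#' @return Character vector of report lines (also printed invisibly
#'   friendly via `cat`).
#' @export
render_confusion <- function(m, kind = c("node", "taxon")) {
  kind <- match.arg(kind)
  m <- confusion_matrix(as.matrix(m), labels = rownames(m),
                        col_labels = colnames(m))
  lines <- utils::capture.output(print(unclass(m)))
  a <- cross_type_accuracy(m)
  if (kind == "node") {
    lines <- c(lines, sprintf("%d of %d matched nodes correct: %d%% cross-type accuracy",
                              sum(diag(m)), sum(m), a$percent))
    if (all(c("H", "F") %in% rownames(m))) {
      hf <- pairwise_confusion_rate(m, "H", "F")
      lines <- c(lines, sprintf("H/F confused %d of %d times (%.1f%%)",
                                hf$errors, hf$total, 100 * hf$rate))
    }
  } else {
    lines <- c(lines, sprintf("%d of %d images correct: %d%% classification accuracy",
                              sum(diag(m)), sum(m), a$percent))
  }
  lines
}
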