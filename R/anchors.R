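#' Anchor grid specification
#'
#' The detector superimposes a grid of regular sample points on the image;
#' the grid pitch equals the size of the smallest object expected (30 px for
#' stem nodes). At every grid point one candidate box is placed per
#' (size, aspect-ratio) pair — six sizes and six ratios by default, for 36
#' boxes per grid point.
#'
#' @param pitch grid spacing in pixels.
#' @param sizes box scales (square-root-area side lengths); default a
#'   geometric progression from `pitch` to `4 * pitch`.
#' @param aspect_ratios width/height ratios; nodes on pressed stems are
#'   about as wide as tall, so the default spans 1/3 to 2.
#' @return List of class `anchor_spec`.
#' @export
anchor_spec <- function(pitch = 30,
                        sizes = round(pitch * 4^(seq(0, 1, length.out = 6))),
                        aspect_ratios = c(1 / 3, 1 / 2, 2 / 3, 1, 3 / 2, 2)) {
  stopifnot(pitch > 0, length(sizes) >= 1, length(aspect_ratios) >= 1,
            all(sizes > 0), all(aspect_ratios > 0))
  structure(list(pitch = as.numeric(pitch), sizes = as.numeric(sizes),
                 aspect_ratios = as.numeric(aspect_ratios)),
            class = "anchor_spec")
}

#' Build the anchor grid for an image
#'
#' Grid points sit at `pitch/2 + k * pitch` in both directions (so a
#' `90 x 90` image at pitch 30 has `3 x 3` points). Each point carries
#' `length(sizes) * length(aspect_ratios)` anchors centered on it; a size
#' `s` and ratio `r` give a box of width `s * sqrt(r)` and height
#' `s / sqrt(r)`, clipped to the image bounds.
#'
#' @param image_size `c(height, width)` in pixels (a scalar means square).
#' @param spec [anchor_spec()].
#' @return Box data.frame with one row per anchor (columns `x_min`...`y_max`
#'   plus `cx`, `cy`, `size`, `ratio`).
#' @export
build_anchor_grid <- function(image_size, spec = anchor_spec()) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  h <- image_size[1]; w <- image_size[2]
  p <- spec$pitch
  if (h < p || w < p) {
    stop("image (", h, "x", w, ") smaller than the grid pitch (", p, ")")
  }
  gx <- p / 2 + p * (seq_len(floor(w / p)) - 1)
  gy <- p / 2 + p * (seq_len(floor(h / p)) - 1)
  combos <- expand.grid(ratio = spec$aspect_ratios, size = spec$sizes,
                        cx = gx, cy = gy, KEEP.OUT.ATTRS = FALSE)
  bw <- combos$size * sqrt(combos$ratio)
  bh <- combos$size / sqrt(combos$ratio)
  out <- data.frame(x_min = combos$cx - bw / 2, y_min = combos$cy - bh / 2,
                    x_max = combos$cx + bw / 2, y_max = combos$cy + bh / 2,
                    cx = combos$cx, cy = combos$cy,
                    size = combos$size, ratio = combos$ratio)
  clip_boxes(out, w, h, drop_empty = FALSE)
}

#' Greedy overlap suppression (non-maximum suppression)
#'
#' A detection is not output if its score, although above threshold, is lower
#' than that of an overlapping detection already kept: detections are visited
#' in descending score order and kept only if their IoU with every
#' already-kept detection is at most `overlap_threshold`. Ties in score are
#' broken by smaller `(x_min, y_min)`, so the result does not depend on input
#' order.
#'
#' @param detections data.frame with box columns and `score` (extra columns
#'   such as `node_type` carried through).
#' @param overlap_threshold IoU above which the lower-scoring box is
#'   suppressed.
#' @return The kept detections, sorted by descending score.
#' @export
suppress_overlaps <- function(detections, overlap_threshold = 0.5) {
  n <- nrow(detections)
  if (n == 0L) return(detections)
  stopifnot(all(detections$score >= 0 & detections$score <= 1))
  ord <- order(-detections$score, detections$x_min, detections$y_min,
               detections$x_max, detections$y_max)
  d <- detections[ord, , drop = FALSE]
  x1 <- d$x_min; y1 <- d$y_min; x2 <- d$x_max; y2 <- d$y_max
  area <- (x2 - x1) * (y2 - y1)
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept) > 0L) {
      iw <- pmax(0, pmin(x2[kept], x2[i]) - pmax(x1[kept], x1[i]))
      ih <- pmax(0, pmin(y2[kept], y2[i]) - pmax(y1[kept], y1[i]))
      inter <- iw * ih
      if (any(inter / (area[kept] + area[i] - inter) > overlap_threshold)) {
        next
      }
    }
    kept <- c(kept, i)
  }
  out <- d[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SSD-style box offset encoding: center deltas scaled by anchor size, log
# size ratios.
encode_offsets <- function(anchors, gt) {
  aw <- anchors$x_max - anchors$x_min; ah <- anchors$y_max - anchors$y_min
  acx <- (anchors$x_min + anchors$x_max) / 2
  acy <- (anchors$y_min + anchors$y_max) / 2
  gw <- gt$x_max - gt$x_min; gh <- gt$y_max - gt$y_min
  gcx <- (gt$x_min + gt$x_max) / 2; gcy <- (gt$y_min + gt$y_max) / 2
  cbind(dx = (gcx - acx) / aw, dy = (gcy - acy) / ah,
        dw = log(gw / aw), dh = log(gh / ah))
}

decode_offsets <- function(anchors, offsets) {
  aw <- anchors$x_max - anchors$x_min; ah <- anchors$y_max - anchors$y_min
  acx <- (anchors$x_min + anchors$x_max) / 2
  acy <- (anchors$y_min + anchors$y_max) / 2
  cx <- acx + offsets[, 1] * aw
  cy <- acy + offsets[, 2] * ah
  w <- aw * exp(offsets[, 3]); h <- ah * exp(offsets[, 4])
  data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
             x_max = cx + w / 2, y_max = cy + h / 2)
}

#' Assign training targets to anchors
#'
#' Standard multibox assignment: every ground-truth box claims its best-IoU
#' anchor, and additionally every anchor whose IoU with some ground truth is
#' at least `match_threshold` is assigned to its best-overlapping ground
#' truth. All remaining anchors are background. Positive anchors carry
#' center/size offset regression targets.
#'
#' @param anchors anchor box data.frame from [build_anchor_grid()].
#' @param ground_truth box data.frame with a `node_type` column (the proxy
#'   label inherited from the image taxon).
#' @param match_threshold IoU threshold for positive assignment.
#' @return List with `label` (character; `"background"` or a node type),
#'   `gt_index` (NA for background) and `offsets` (matrix, NA rows for
#'   background).
#' @export
assign_training_targets <- function(anchors, ground_truth,
                                    match_threshold = 0.5) {
  n <- nrow(anchors)
  label <- rep("background", n)
  gt_index <- rep(NA_integer_, n)
  offsets <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, c("dx", "dy", "dw", "dh")))
  if (nrow(ground_truth) > 0L) {
    m <- iou_matrix(anchors, ground_truth)
    best_gt <- max.col(m, ties.method = "first")
    best_iou <- m[cbind(seq_len(n), best_gt)]
    pos <- best_iou >= match_threshold
    # force-match each ground truth to its single best anchor; when two
    # ground truths claim the same anchor, the higher-IoU one wins. A
    # ground truth overlapping no anchor at all stays unmatched.
    force_iou <- apply(m, 2, max)
    for (g in order(force_iou)) {
      if (force_iou[g] <= 0) next
      a <- which.max(m[, g])
      pos[a] <- TRUE
      best_gt[a] <- g
    }
    gt_index[pos] <- best_gt[pos]
    label[pos] <- ground_truth$node_type[best_gt[pos]]
    offsets[pos, ] <- encode_offsets(anchors[pos, , drop = FALSE],
                                     ground_truth[best_gt[pos], , drop = FALSE])
  }
  list(label = label, gt_index = gt_index, offsets = offsets)
}
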