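#' Display quantization of a confidence score
#'
#' Multiplies a score in `[0, 1]` by ten and rounds to the nearest integer
#' (half away from zero), giving a legible 0 (no confidence) to 10 (full
#' confidence) scale, e.g. 0.73 displays as 7. Quantization is display-only:
#' every downstream computation consumes the raw scores.
#'
#' @param score numeric vector in `[0, 1]`.
#' @return Integer vector in `0..10`.
#' @export
quantize_score <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  as.integer(round_half_up(score * 10))
}

#' Mean score of the top-k detections of one node type
#'
#' Filters the detections to `type`, sorts by descending score, and averages
#' the first `min(k, available)` scores. With no detections of the type the
#' statistic is 0 with `n = 0` — "no evidence of that type" — unless
#' `pad_to_k` is set, in which case the missing scores count as zeros in a
#' fixed-length-k average.
#'
#' @param detections data.frame with `node_type` and `score`.
#' @param type node type to aggregate.
#' @param k number of top scores to average.
#' @param pad_to_k treat absent detections as zero scores.
#' @return List with `mean` and `n` (number of real detections used).
#' @export
top_k_mean <- function(detections, type, k = 10L, pad_to_k = FALSE) {
  stopifnot(k >= 1)
  s <- detections$score[detections$node_type == type]
  s <- sort(s, decreasing = TRUE)
  n <- min(length(s), k)
  if (pad_to_k) {
    return(list(mean = sum(s[seq_len(n)]) / k, n = n))
  }
  if (n == 0L) return(list(mean = 0, n = 0L))
  list(mean = mean(s[seq_len(n)]), n = n)
}

top_k_sd <- function(detections, type, k = 10L) {
  s <- sort(detections$score[detections$node_type == type], decreasing = TRUE)
  n <- min(length(s), k)
  if (n < 2L) return(0)
  stats::sd(s[seq_len(n)])
}

#' Per-image detection statistics
#'
#' The per-image feature vector handed to the taxon classifier: the average
#' score of the 10 top-scoring detections of each node type (`a_H`, `a_L`,
#' and `a_F` in three-type mode). Alternative statistics — the ratio of the
#' two averages, or their standard deviations — are kept behind `variant`
#' for ablation; the averages are the default as they work best.
#'
#' @param detections detection data.frame for one image.
#' @param type_set active node types, `c("H","L")` or `c("H","L","F")`.
#' @param k top-k depth.
#' @param variant `"means"`, `"ratio"` or `"stds"`.
#' @param pad_to_k see [top_k_mean()].
#' @return One-row data.frame. For `"means"`: `a_H`, `a_L` (optionally
#'   `a_F`) and counts `n_H`, `n_L` (`n_F`). For `"ratio"`: `ratio`
#'   (`a_H / a_L`) and `ratio_defined` (FALSE with `a_L == 0`, ratio NA).
#'   For `"stds"`: `s_H`, `s_L` (`s_F`).
#' @export
image_features <- function(detections, type_set = c("H", "L"), k = 10L,
                           variant = c("means", "ratio", "stds"),
                           pad_to_k = FALSE) {
  variant <- match.arg(variant)
  stats_ <- lapply(type_set, function(tp) {
    top_k_mean(detections, tp, k, pad_to_k)
  })
  means <- vapply(stats_, `[[`, 0, "mean")
  ns <- vapply(stats_, function(x) as.integer(x$n), 0L)
  if (variant == "means") {
    out <- as.data.frame(c(as.list(means), as.list(ns)))
    names(out) <- c(paste0("a_", type_set), paste0("n_", type_set))
    return(out)
  }
  if (variant == "ratio") {
    a_H <- means[type_set == "H"]; a_L <- means[type_set == "L"]
    if (a_L == 0) {
      return(data.frame(ratio = NA_real_, ratio_defined = FALSE))
    }
    return(data.frame(ratio = a_H / a_L, ratio_defined = TRUE))
  }
  sds <- vapply(type_set, function(tp) top_k_sd(detections, tp, k), 0)
  out <- as.data.frame(as.list(sds))
  names(out) <- paste0("s_", type_set)
  out
}

#' Feature table for a set of images
#'
#' Runs [detect()] on each image and assembles the classifier's input table.
#'
#' @param model trained `node_detector`.
#' @param images list of [annotated_image()] with pixel data.
#' @param score_threshold,overlap_threshold passed to [detect()].
#' @param k top-k depth.
#' @return data.frame with `image_id`, the per-type averages and counts, and
#'   `taxon` where known.
#' @export
feature_table <- function(model, images, score_threshold = 0.3,
                          overlap_threshold = 0.5, k = 10L) {
  rows <- lapply(images, function(img) {
    det <- detect(model, img$image, score_threshold, overlap_threshold)
    cbind(data.frame(image_id = img$image_id),
          image_features(det, model$type_set, k),
          data.frame(taxon = if (is.na(img$taxon)) NA_character_ else
            img$taxon))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
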