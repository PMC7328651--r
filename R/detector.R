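#' Detector training configuration
#'
#' @param batch_size images per mini-batch gradient step.
#' @param learning_rate fixed step size for mini-batch gradient descent.
#' @param max_iterations hard cap on gradient steps.
#' @param patience consecutive validation checks without improvement before
#'   training stops (the best-validation checkpoint is returned).
#' @param check_interval iterations between validation evaluations.
#' @param neg_ratio hard-negative to positive anchor ratio in the loss.
#' @param pos_weight classification-loss weight of positive anchors
#'   relative to background (balances the residual class skew after
#'   mining).
#' @param match_threshold IoU for positive anchor assignment.
#' @param augment_reuse number of gradient steps an augmented variant of a
#'   training image serves before a fresh rotation/crop is drawn.
#' @return List of class `training_config`.
#' @export
training_config <- function(batch_size = 8L, learning_rate = 1e-4,
                            max_iterations = 2000L, patience = 5L,
                            check_interval = 25L, neg_ratio = 3,
                            pos_weight = 3, match_threshold = 0.5,
                            augment_reuse = 4L) {
  stopifnot(batch_size > 0, learning_rate > 0, max_iterations >= 0,
            patience > 0, check_interval > 0, neg_ratio > 0,
            match_threshold > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 check_interval = as.integer(check_interval),
                 neg_ratio = neg_ratio, pos_weight = pos_weight,
                 match_threshold = match_threshold,
                 augment_reuse = as.integer(augment_reuse)),
            class = "training_config")
}

# Integral image (summed-area table) per channel: S[i+1, j+1, ch] = sum of
# image[1:i, 1:j, ch].
integral_image <- function(image) {
  cpp_integral(image)
}

#' Mean-pooled grid features for a set of boxes
#'
#' Each box is divided into a `grid[1] x grid[2]` grid of cells; the raw
#' feature vector is the per-cell, per-channel mean pixel value, computed in
#' O(1) per cell from the image's summed-area table. When a `normalization`
#' (per-feature center and scale, estimated from the training images) is
#' supplied, features are standardized — the input-normalization step that
#' keeps fixed-rate gradient descent well conditioned.
#'
#' @param image `h x w x 3` array in `[0, 1]`, or a precomputed
#'   [integral_image()] array (then supply `image_dim`).
#' @param boxes box data.frame.
#' @param grid `c(rows, cols)` pooling grid.
#' @param normalization NULL for raw cell means, or a list with numeric
#'   vectors `center` and `scale` of length `3 * prod(grid)`.
#' @param image_dim `c(h, w)`; supply it when `image` is an integral image.
#' @return `nrow(boxes) x (3 * prod(grid) + 1)` matrix; last column is a
#'   constant intercept.
#' @export
anchor_features <- function(image, boxes, grid = c(6, 4),
                            normalization = NULL, image_dim = NULL) {
  S <- if (is.null(image_dim)) integral_image(image) else image
  n <- nrow(boxes)
  d <- 3L * prod(grid)
  if (n == 0L) return(matrix(0, 0L, d + 1L))
  b <- as.matrix(boxes[c("x_min", "y_min", "x_max", "y_max")])
  F_ <- cpp_pool_features(S, b, grid[1], grid[2], c(0, 0, 0), 1)
  if (!is.null(normalization)) {
    F_[, seq_len(d)] <- sweep(sweep(F_[, seq_len(d), drop = FALSE], 2,
                                    normalization$center, `-`),
                              2, normalization$scale, `*`)
  }
  F_
}

# Per-feature standardization estimated from sampled anchors of the
# training images. `target_scale` sets the typical per-row feature
# magnitude, chosen so that one gradient step at the fixed learning rate
# moves a logit by order one.
estimate_normalization <- function(images, spec, grid, target_scale,
                                   n_sample = 400L) {
  F_all <- do.call(rbind, lapply(images, function(img) {
    anchors <- build_anchor_grid(dim(img$image)[1:2], spec)
    take <- sample.int(nrow(anchors), min(n_sample, nrow(anchors)))
    anchor_features(img$image, anchors[take, , drop = FALSE], grid)
  }))
  d <- ncol(F_all) - 1L
  center <- colMeans(F_all[, seq_len(d), drop = FALSE])
  sds <- pmax(apply(F_all[, seq_len(d), drop = FALSE], 2, stats::sd), 1e-3)
  list(center = center, scale = target_scale / sds)
}

taxon_node_type <- function(taxon) {
  c(hyemale = "H", laevigatum = "L", ferrissii = "F")[[taxon]]
}

node_ground_truth <- function(annotated) {
  ann <- annotated$annotations
  ann <- ann[ann$category == "normal_stem_node", , drop = FALSE]
  if (is.na(annotated$taxon)) {
    stop("image ", annotated$image_id,
         " has no taxon label; cannot proxy-label its nodes")
  }
  ann$node_type <- taxon_node_type(annotated$taxon)
  ann
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

smooth_l1 <- function(r) ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5)
smooth_l1_grad <- function(r) pmin(pmax(r, -1), 1)

# Per-shape linear heads, the multibox convention: each of the S anchor
# shapes (size x ratio combination) owns its own classifier and offset
# regressor. W: d x K x S array; V: d x 4 x S array.
shape_logits <- function(F_all, shape_idx, W) {
  Z <- matrix(0, nrow(F_all), dim(W)[2])
  for (s in unique(shape_idx)) {
    r <- which(shape_idx == s)
    Z[r, ] <- F_all[r, , drop = FALSE] %*% W[, , s]
  }
  Z
}

shape_offsets <- function(F_all, shape_idx, V) {
  O <- matrix(0, nrow(F_all), 4)
  for (s in unique(shape_idx)) {
    r <- which(shape_idx == s)
    O[r, ] <- F_all[r, , drop = FALSE] %*% V[, , s]
  }
  O
}

# classification + localization loss and gradients for one set of sampled
# anchors. cls: one-hot targets over c(background, type_set); pos rows also
# carry offset targets.
multibox_step <- function(F_all, shape_idx, y_idx, pos_rows, off_target,
                          W, V, n_pos, pos_weight = 1) {
  P <- softmax_rows(shape_logits(F_all, shape_idx, W))
  Y <- matrix(0, nrow(P), ncol(P))
  Y[cbind(seq_len(nrow(P)), y_idx)] <- 1
  wts <- ifelse(y_idx == 1L, 1, pos_weight)
  loss_cls <- -sum(wts * log(pmax(P[Y == 1], 1e-12))) / n_pos
  gW <- array(0, dim(W))
  E <- (P - Y) * wts
  for (s in unique(shape_idx)) {
    r <- which(shape_idx == s)
    gW[, , s] <- crossprod(F_all[r, , drop = FALSE],
                           E[r, , drop = FALSE]) / n_pos
  }
  loss_loc <- 0
  gV <- array(0, dim(V))
  if (length(pos_rows) > 0L) {
    ps <- shape_idx[pos_rows]
    Fp <- F_all[pos_rows, , drop = FALSE]
    R <- shape_offsets(Fp, ps, V) - off_target
    loss_loc <- sum(smooth_l1(R)) / n_pos
    G <- smooth_l1_grad(R)
    for (s in unique(ps)) {
      r <- which(ps == s)
      gV[, , s] <- crossprod(Fp[r, , drop = FALSE],
                             G[r, , drop = FALSE]) / n_pos
    }
  }
  list(loss = loss_cls + loss_loc, gW = gW, gV = gV)
}

# Precompute the reusable parts of one augmented variant's training rows:
# features and labels of positive anchors plus a random background
# candidate pool.
prepare_training_rows <- function(annotated, anchors, classes, grid,
                                  normalization, n_shapes, config,
                                  neg_pool = 1500L) {
  S <- integral_image(annotated$image)
  gt <- node_ground_truth(annotated)
  tgt <- assign_training_targets(anchors, gt, config$match_threshold)
  pos_idx <- which(tgt$label != "background")
  bg_idx <- which(tgt$label == "background")
  cand <- if (length(bg_idx) > neg_pool) sample(bg_idx, neg_pool) else bg_idx
  dim_ <- dim(annotated$image)[1:2]
  list(F_pos = anchor_features(S, anchors[pos_idx, , drop = FALSE], grid,
                               normalization, image_dim = dim_),
       F_cand = anchor_features(S, anchors[cand, , drop = FALSE], grid,
                                normalization, image_dim = dim_),
       pos_shape = (pos_idx - 1L) %% n_shapes + 1L,
       cand_shape = (cand - 1L) %% n_shapes + 1L,
       y_pos = match(tgt$label[pos_idx], classes),
       off_target = tgt$offsets[pos_idx, , drop = FALSE],
       n_pos = length(pos_idx))
}

# Mine hard negatives against the current weights and assemble the rows
# fed to multibox_step.
mine_training_rows <- function(prep, W, config) {
  n_neg <- max(config$neg_ratio, ceiling(config$neg_ratio * prep$n_pos))
  p_bg <- softmax_rows(shape_logits(prep$F_cand, prep$cand_shape, W))[, 1]
  hard <- order(p_bg)[seq_len(min(n_neg, nrow(prep$F_cand)))]
  list(F_all = rbind(prep$F_pos, prep$F_cand[hard, , drop = FALSE]),
       shape_idx = c(prep$pos_shape, prep$cand_shape[hard]),
       y_idx = c(prep$y_pos, rep(1L, length(hard))),
       pos_rows = seq_len(prep$n_pos),
       off_target = prep$off_target,
       n_pos = prep$n_pos)
}

#' Train the anchor-grid node detector
#'
#' A single-stage detector in the multibox mould: every anchor box receives
#' a class score over \{background\} + node types and four box-offset
#' regressions, both linear in mean-pooled grid features of the anchor's
#' pixels. Node labels are proxies inherited from the image taxon (every
#' node in an *E. hyemale* image is an H node, etc.). Training minimizes
#' softmax cross-entropy (with hard-negative mining at `neg_ratio`:1) plus
#' smooth-L1 offset loss, normalized by the positive-anchor count, by
#' mini-batch gradient descent at a fixed learning rate. The validation
#' loss is evaluated every `check_interval` iterations; training stops at
#' `max_iterations` or once the validation loss has failed to improve for
#' `patience` consecutive checks, and the best-validation checkpoint is
#' returned.
#'
#' @param train list of [annotated_image()] with pixel data and taxon
#'   labels.
#' @param val validation images (same form); drives early stopping.
#' @param config [training_config()].
#' @param seed integer; fixed seed gives an identical loss trajectory.
#' @param spec [anchor_spec()].
#' @param aug [augmentation_config()] applied to each training image
#'   (rotate + crop), or NULL to train on whole images.
#' @param type_set node types to learn (`c("H","L")` or `c("H","L","F")`);
#'   inferred from the taxa present when NULL.
#' @param feature_grid pooling grid for [anchor_features()].
#' @param feature_scale target per-feature magnitude after input
#'   standardization (see [anchor_features()]).
#' @param bg_prior initial background probability encoded in the bias.
#' @return A `node_detector` model object.
#' @export
train_detector <- function(train, val, config = training_config(), seed = 1L,
                           spec = anchor_spec(), aug = augmentation_config(),
                           type_set = NULL, feature_grid = c(6, 4),
                           feature_scale = 8, bg_prior = 0.9) {
  if (length(train) == 0L) stop("empty training set")
  if (length(val) == 0L) stop("empty validation set")
  taxa <- vapply(train, function(x) x$taxon, "")
  if (is.null(type_set)) {
    type_set <- intersect(c("H", "L", "F"),
                          unique(vapply(taxa, taxon_node_type, "")))
  }
  if ("F" %in% vapply(unique(taxa), taxon_node_type, "") &&
      !"F" %in% type_set) {
    stop("hybrid (ferrissii) images in the training set but type_set has ",
         "no F class; drop them or enable three-type mode")
  }
  classes <- c("background", type_set)
  d <- 3L * prod(feature_grid) + 1L
  n_shapes <- length(spec$sizes) * length(spec$aspect_ratios)
  W <- array(0, c(d, length(classes), n_shapes))
  # prior initialization: start with p(background) = bg_prior at every
  # anchor, so early iterations refine rather than rediscover the vast
  # background majority
  W[d, 1, ] <- log(bg_prior / (1 - bg_prior) * length(type_set))
  V <- array(0, c(d, 4, n_shapes))
  with_seed(seed, {
    normalization <- estimate_normalization(
      train[seq_len(min(8L, length(train)))], spec, feature_grid,
      feature_scale)
    # validation rows are fixed once: whole images, positives plus a seeded
    # random negative sample
    val_rows <- lapply(val, function(img) {
      anchors <- build_anchor_grid(c(img$height %||% dim(img$image)[1],
                                     img$width %||% dim(img$image)[2]), spec)
      S <- integral_image(img$image)
      gt <- node_ground_truth(img)
      tgt <- assign_training_targets(anchors, gt, config$match_threshold)
      pos_idx <- which(tgt$label != "background")
      bg_idx <- which(tgt$label == "background")
      neg <- if (length(bg_idx) > 500L) sample(bg_idx, 500L) else bg_idx
      keep <- c(pos_idx, neg)
      F_all <- anchor_features(S, anchors[keep, , drop = FALSE], feature_grid,
                               normalization,
                               image_dim = dim(img$image)[1:2])
      list(F_all = F_all,
           shape_idx = (keep - 1L) %% n_shapes + 1L,
           y_idx = match(c(tgt$label[pos_idx], rep("background", length(neg))),
                         classes),
           pos_rows = seq_along(pos_idx),
           off_target = tgt$offsets[pos_idx, , drop = FALSE],
           n_pos = max(1L, length(pos_idx)))
    })
    val_loss <- function(W, V) {
      mean(vapply(val_rows, function(r) {
        multibox_step(r$F_all, r$shape_idx, r$y_idx, r$pos_rows,
                      r$off_target, W, V, r$n_pos, config$pos_weight)$loss
      }, 0))
    }
    crop_anchors <- if (!is.null(aug)) {
      build_anchor_grid(rep(aug$crop_size, 2), spec)
    }
    fills <- lapply(train, function(img) {
      c(mean(img$image[, , 1]), mean(img$image[, , 2]),
        mean(img$image[, , 3]))
    })
    fresh_rows <- function(b) {
      img <- train[[b]]
      if (!is.null(aug)) {
        img <- augment(img, aug, fill = fills[[b]])
        anchors <- crop_anchors
      } else {
        anchors <- build_anchor_grid(dim(img$image)[1:2], spec)
      }
      prepare_training_rows(img, anchors, classes, feature_grid,
                            normalization, n_shapes, config)
    }
    cache <- vector("list", length(train))
    cache_uses <- integer(length(train))
    best <- list(W = W, V = V, loss = val_loss(W, V), iter = 0L)
    bad_checks <- 0L
    history <- data.frame(iteration = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    it <- 0L
    while (it < config$max_iterations) {
      it <- it + 1L
      batch <- sample(seq_along(train), config$batch_size,
                      replace = length(train) < config$batch_size)
      gW <- array(0, dim(W)); gV <- array(0, dim(V))
      loss_acc <- 0
      for (b in batch) {
        if (is.null(cache[[b]]) || cache_uses[b] >= config$augment_reuse) {
          cache[[b]] <- fresh_rows(b)
          cache_uses[b] <- 0L
        }
        cache_uses[b] <- cache_uses[b] + 1L
        rows <- mine_training_rows(cache[[b]], W, config)
        if (rows$n_pos == 0L && length(rows$y_idx) == 0L) next
        st <- multibox_step(rows$F_all, rows$shape_idx, rows$y_idx,
                            rows$pos_rows, rows$off_target, W, V,
                            max(1L, rows$n_pos), config$pos_weight)
        gW <- gW + st$gW / config$batch_size
        gV <- gV + st$gV / config$batch_size
        loss_acc <- loss_acc + st$loss / config$batch_size
      }
      if (!all(is.finite(gW)) || !all(is.finite(gV))) {
        stop("detector training diverged (non-finite gradient) at iteration ",
             it, "; train loss ", signif(loss_acc, 4))
      }
      W <- W - config$learning_rate * gW
      V <- V - config$learning_rate * gV
      if (it %% config$check_interval == 0L) {
        vl <- val_loss(W, V)
        history <- rbind(history, data.frame(iteration = it,
                                             train_loss = loss_acc,
                                             val_loss = vl))
        if (vl < best$loss - 1e-6) {
          best <- list(W = W, V = V, loss = vl, iter = it)
          bad_checks <- 0L
        } else {
          bad_checks <- bad_checks + 1L
          if (bad_checks >= config$patience) break
        }
      }
    }
    structure(list(anchor_spec = spec, type_set = type_set,
                   classes = classes, feature_grid = feature_grid,
                   W = best$W, V = best$V,
                   input_normalization = normalization,
                   feature_scale = feature_scale, bg_prior = bg_prior,
                   trained = TRUE, best_iteration = best$iter,
                   best_val_loss = best$loss, history = history,
                   config = unclass(config), seed = as.integer(seed)),
              class = "node_detector")
  })
}

#' @export
print.node_detector <- function(x, ...) {
  cat("<node_detector> types {", paste(x$type_set, collapse = ", "),
      "}, pitch ", x$anchor_spec$pitch, " px, ",
      length(x$anchor_spec$sizes) * length(x$anchor_spec$aspect_ratios),
      " anchors/grid point; best val loss ", signif(x$best_val_loss, 4),
      " @ iteration ", x$best_iteration, "\n", sep = "")
  invisible(x)
}

#' Run the detector on an image
#'
#' Scores every anchor of the grid, takes the per-anchor best node type and
#' its softmax probability as the detection score, drops anchors whose best
#' type score is below `score_threshold` (or whose best class is
#' background), refines the surviving boxes with the regressed offsets, and
#' applies [suppress_overlaps()].
#'
#' @param model trained `node_detector`.
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param score_threshold minimum type score.
#' @param overlap_threshold IoU for suppression.
#' @return Detection data.frame: box columns, `node_type`, `score`,
#'   descending by score.
#' @export
detect <- function(model, image, score_threshold = 0.3,
                   overlap_threshold = 0.5) {
  if (!inherits(model, "node_detector") || !isTRUE(model$trained)) {
    stop("detect() needs a trained node_detector")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  anchors <- build_anchor_grid(c(h, w), model$anchor_spec)
  F_all <- anchor_features(image, anchors, model$feature_grid,
                           model$input_normalization)
  n_shapes <- dim(model$W)[3]
  shape_idx <- (seq_len(nrow(anchors)) - 1L) %% n_shapes + 1L
  P <- softmax_rows(shape_logits(F_all, shape_idx, model$W))
  type_probs <- P[, -1, drop = FALSE]
  best_type <- max.col(type_probs, ties.method = "first")
  best_score <- type_probs[cbind(seq_len(nrow(P)), best_type)]
  keep <- best_score >= score_threshold
  if (!any(keep)) {
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      node_type = character(0), score = numeric(0)))
  }
  off <- shape_offsets(F_all[keep, , drop = FALSE], shape_idx[keep],
                       model$V)
  boxes <- decode_offsets(anchors[keep, , drop = FALSE], off)
  boxes <- clip_boxes(cbind(boxes,
                            node_type = model$type_set[best_type[keep]],
                            score = best_score[keep]),
                      w, h)
  suppress_overlaps(boxes, overlap_threshold)
}

#' Save / load a detector model
#'
#' The checkpoint is a single JSON file holding the anchor specification,
#' type set, input normalization and weight matrices; reloading reproduces
#' inference bit-for-bit.
#'
#' @param model `node_detector`.
#' @param path JSON path.
#' @return `path` / the reloaded model.
#' @export
save_detector <- function(model, path) {
  obj <- model
  # %.17g strings round-trip doubles exactly through JSON
  obj$anchor_spec <- lapply(unclass(model$anchor_spec),
                            function(x) sprintf("%.17g", x))
  obj$W <- sprintf("%.17g", as.vector(model$W))
  obj$V <- sprintf("%.17g", as.vector(model$V))
  obj$input_normalization <- lapply(model$input_normalization,
                                    function(x) sprintf("%.17g", x))
  obj$dims <- dim(model$W)
  obj$history <- NULL
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- array(as.numeric(obj$W), obj$dims)
  obj$V <- array(as.numeric(obj$V), c(obj$dims[1], 4, obj$dims[3]))
  obj$input_normalization <- lapply(obj$input_normalization, as.numeric)
  obj$dims <- NULL
  obj$anchor_spec <- structure(lapply(obj$anchor_spec, as.numeric),
                               class = "anchor_spec")
  structure(obj, class = "node_detector")
}
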