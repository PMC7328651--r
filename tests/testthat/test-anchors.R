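# Brute-force suppression oracle, deliberately written with plain loops.
nms_oracle <- function(det, thr) {
  ord <- order(-det$score, det$x_min, det$y_min, det$x_max, det$y_max)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (iou_oracle(as.numeric(det[i, 1:4]), as.numeric(det[j, 1:4])) > thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  det[kept, , drop = FALSE]
}

test_that("iou matches hand-computed overlaps", {
  b <- bounding_box(0, 0, 2, 2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, bounding_box(5, 5, 7, 7)), 0)
  expect_equal(iou(b, bounding_box(1, 0, 3, 2)), 1 / 3)
  # touching boxes share no area under the half-open convention
  expect_equal(iou(b, bounding_box(2, 0, 4, 2)), 0)
})

test_that("iou_matrix agrees with elementwise iou on random boxes", {
  set.seed(11)
  a <- random_boxes(15)
  b <- random_boxes(12)
  m <- iou_matrix(a, b)
  for (i in sample(15, 5)) {
    for (j in sample(12, 5)) {
      expect_equal(m[i, j], iou_oracle(as.numeric(a[i, 1:4]),
                                       as.numeric(b[j, 1:4])))
    }
  }
})

test_that("anchor grid has pitch-spaced points and 36 boxes per point", {
  spec <- anchor_spec(pitch = 30)
  expect_length(spec$sizes, 6L)
  expect_length(spec$aspect_ratios, 6L)
  g <- build_anchor_grid(c(90, 90), spec)
  expect_equal(nrow(g), 9L * 36L)
  expect_setequal(unique(g$cx), c(15, 45, 75))
  expect_setequal(unique(g$cy), c(15, 45, 75))
  g1 <- build_anchor_grid(c(90, 90), anchor_spec(30, sizes = 20,
                                                 aspect_ratios = 1))
  expect_equal(nrow(g1), 9L)
  # all anchors clipped inside the frame
  big <- build_anchor_grid(c(120, 150), spec)
  expect_true(all(big$x_min >= 0 & big$y_min >= 0 &
                    big$x_max <= 150 & big$y_max <= 120))
  expect_equal(nrow(big), 4L * 5L * 36L)
  expect_error(build_anchor_grid(c(20, 90), spec), "pitch")
})

test_that("overlap suppression keeps the higher-scoring of two overlaps", {
  det <- data.frame(x_min = c(0, 2), y_min = c(0, 0),
                    x_max = c(10, 12), y_max = c(10, 10),
                    score = c(0.7, 0.9))
  out <- suppress_overlaps(det, 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 0.9)
  # disjoint boxes all survive
  det2 <- data.frame(x_min = c(0, 20, 40), y_min = 0,
                     x_max = c(10, 30, 50), y_max = 10,
                     score = c(0.5, 0.9, 0.1))
  expect_equal(suppress_overlaps(det2, 0.5)$score, c(0.9, 0.5, 0.1))
})

test_that("overlap suppression matches the brute-force oracle", {
  set.seed(21)
  for (rep in 1:40) {
    det <- random_detections(sample(5:50, 1), max_coord = 60, max_side = 30)
    thr <- runif(1, 0.2, 0.7)
    got <- suppress_overlaps(det, thr)
    want <- nms_oracle(det, thr)
    expect_equal(got[c("x_min", "y_min", "x_max", "y_max", "score")],
                 want[c("x_min", "y_min", "x_max", "y_max", "score")],
                 ignore_attr = TRUE)
  }
})

test_that("overlap suppression is invariant to input permutation", {
  set.seed(22)
  det <- random_detections(30, max_coord = 50, max_side = 25)
  det$score <- round(det$score, 1)   # force score ties
  base <- suppress_overlaps(det, 0.4)
  for (rep in 1:10) {
    perm <- det[sample(nrow(det)), , drop = FALSE]
    expect_equal(suppress_overlaps(perm, 0.4), base, ignore_attr = TRUE)
  }
})

test_that("training-target assignment handles the degenerate cases", {
  an <- build_anchor_grid(c(90, 90), anchor_spec(30))
  none <- assign_training_targets(an, data.frame(x_min = numeric(0),
                                                 y_min = numeric(0),
                                                 x_max = numeric(0),
                                                 y_max = numeric(0),
                                                 node_type = character(0)))
  expect_true(all(none$label == "background"))
  # a ground truth equal to an anchor matches it with zero offsets
  gt <- an[100, c("x_min", "y_min", "x_max", "y_max")]
  gt$node_type <- "H"
  tg <- assign_training_targets(an, gt)
  expect_equal(tg$label[100], "H")
  expect_equal(unname(tg$offsets[100, ]), rep(0, 4))
})

test_that("best-IoU anchor matching agrees with brute-force argmax", {
  set.seed(23)
  for (rep in 1:20) {
    anchors <- random_boxes(25, max_coord = 80, max_side = 35)
    gt <- random_boxes(sample(1:5, 1), max_coord = 80, max_side = 35)
    gt$node_type <- sample(c("H", "L"), nrow(gt), replace = TRUE)
    tg <- assign_training_targets(anchors, gt, match_threshold = 0.5)
    m <- matrix(0, nrow(anchors), nrow(gt))
    for (i in seq_len(nrow(anchors))) {
      for (j in seq_len(nrow(gt))) {
        m[i, j] <- iou_oracle(as.numeric(anchors[i, 1:4]),
                              as.numeric(gt[j, 1:4]))
      }
    }
    best_anchor <- vapply(seq_len(nrow(gt)), function(j) which.max(m[, j]),
                          1L)
    overlapping <- which(apply(m, 2, max) > 0)
    for (j in overlapping) {
      a <- best_anchor[j]
      claimants <- intersect(which(best_anchor == a), overlapping)
      winner <- claimants[which.max(m[a, claimants])]
      # each overlapping ground truth's best anchor is positive; a
      # contested anchor goes to the highest-IoU claimant
      expect_false(tg$label[a] == "background")
      expect_equal(tg$label[a], gt$node_type[winner])
    }
    for (i in seq_len(nrow(anchors))) {
      if (max(m[i, ]) >= 0.5) expect_false(tg$label[i] == "background")
      if (max(m[i, ]) < 0.5 && !(i %in% vapply(seq_len(nrow(gt)),
                                               function(j) which.max(m[, j]),
                                               1L))) {
        expect_equal(tg$label[i], "background")
      }
    }
  }
})

test_that("offset encoding and decoding are mutually inverse", {
  set.seed(24)
  anchors <- random_boxes(30)
  gt <- random_boxes(30)
  off <- equinode:::encode_offsets(anchors, gt)
  back <- equinode:::decode_offsets(anchors, off)
  expect_equal(back$x_min, gt$x_min)
  expect_equal(back$y_max, gt$y_max)
})
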