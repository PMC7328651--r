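# Literal count grids of the reported two-type and three-type node
# experiments and the two image-classification experiments; the derived
# numbers (totals, accuracies, pairwise confusion) are what the evaluation
# layer must reproduce.
node_2type <- matrix(c(145, 4, 2, 121), 2, 2, byrow = TRUE,
                     dimnames = list(c("H", "L"), c("H", "L")))
node_3type <- matrix(c(85, 5, 22, 0, 90, 0, 14, 1, 108), 3, 3, byrow = TRUE,
                     dimnames = list(c("H", "L", "F"), c("H", "L", "F")))
taxa_knn <- matrix(c(9, 0, 1, 0, 10, 0, 2, 0, 8), 3, 3, byrow = TRUE,
                   dimnames = list(TAXA, TAXA))
taxa_tree <- matrix(c(8, 1, 1, 0, 10, 0, 1, 0, 9), 3, 3, byrow = TRUE,
                    dimnames = list(TAXA, TAXA))

greedy_match_oracle <- function(det, ann, thr) {
  ord <- order(-det$score, det$x_min, det$y_min)
  taken <- rep(FALSE, nrow(ann))
  pairs <- NULL
  for (i in ord) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(ann))) {
      if (taken[j]) next
      v <- iou_oracle(as.numeric(det[i, 1:4]), as.numeric(ann[j, 1:4]))
      if (v >= thr && v > best) { best <- v; bj <- j }
    }
    if (bj > 0) {
      taken[bj] <- TRUE
      pairs <- rbind(pairs, c(i, bj))
    }
  }
  pairs
}

test_that("two-type node table yields 272 matched nodes and 98% accuracy", {
  m <- confusion_matrix(node_2type)
  expect_equal(sum(m), 272)
  a <- cross_type_accuracy(m)
  expect_equal(a$accuracy, 266 / 272)
  expect_equal(a$percent, 98L)
})

test_that("three-type node table yields 87%, 36/229 H-F, 6/96 L errors", {
  m <- confusion_matrix(node_3type)
  a <- cross_type_accuracy(m)
  expect_equal(a$accuracy, 283 / 325)
  expect_equal(a$percent, 87L)
  hf <- pairwise_confusion_rate(m, "H", "F")
  expect_equal(hf$errors, 36)
  expect_equal(hf$total, 229)
  expect_equal(round(hf$rate, 3), 0.157)
  lcol <- label_error_count(m, "L", "column")
  expect_equal(lcol$errors, 6)
  expect_equal(lcol$total, 96)
})

test_that("both classifier tables give 27/30 = 90% image accuracy", {
  for (tab in list(taxa_knn, taxa_tree)) {
    a <- image_accuracy(confusion_matrix(tab))
    expect_equal(a$correct, 27)
    expect_equal(a$total, 30)
    expect_equal(a$accuracy, 0.9)
    expect_equal(a$percent, 90L)
  }
})

test_that("accuracy metrics are invariant under label permutation", {
  m <- confusion_matrix(node_3type)
  perm <- c(3, 1, 2)
  mp <- confusion_matrix(node_3type[perm, perm])
  expect_equal(cross_type_accuracy(mp), cross_type_accuracy(m))
  expect_equal(pairwise_confusion_rate(mp, "H", "F"),
               pairwise_confusion_rate(m, "H", "F"))
})

test_that("degenerate confusion matrices are handled", {
  expect_equal(cross_type_accuracy(confusion_matrix(diag(5, 3),
                                                    c("H", "L", "F")))$accuracy,
               1.0)
  expect_error(cross_type_accuracy(confusion_matrix(matrix(0, 2, 2),
                                                    c("H", "L"))), "empty")
  expect_error(confusion_matrix(matrix(-1, 2, 2)), "non-negative")
  all_wrong <- taxon_confusion(c("hyemale", "laevigatum"),
                               c("laevigatum", "hyemale"))
  expect_equal(image_accuracy(all_wrong)$accuracy, 0)
  sym <- confusion_matrix(matrix(c(0, 4, 4, 0), 2), c("H", "F"))
  expect_equal(pairwise_confusion_rate(sym, "H", "F")$rate, 1.0)
})

test_that("detection matching: identity, pure-FP and conservation", {
  set.seed(51)
  ann <- random_boxes(8)
  det <- ann
  det$score <- runif(8)
  res <- match_detections(det, ann, 0.5)
  expect_equal(nrow(res$matches), 8L)
  expect_length(res$false_positives, 0L)
  expect_length(res$false_negatives, 0L)
  only <- match_detections(cbind(random_boxes(1), score = 0.9),
                           ann[0, ], 0.5)
  expect_equal(only$false_positives, 1L)
  mixed <- match_detections(cbind(random_boxes(10), score = runif(10)),
                            random_boxes(6), 0.3)
  expect_equal(nrow(mixed$matches) + length(mixed$false_positives), 10L)
  expect_equal(nrow(mixed$matches) + length(mixed$false_negatives), 6L)
  expect_equal(anyDuplicated(mixed$matches$annotation), 0L)
})

test_that("greedy matching agrees with the brute-force oracle", {
  set.seed(52)
  for (rep in 1:30) {
    det <- cbind(random_boxes(sample(3:12, 1), max_coord = 50,
                              max_side = 25),
                 score = round(runif(sample(3:12, 1) * 0 + 1), 3))
    det$score <- round(runif(nrow(det)), 3)
    ann <- random_boxes(sample(2:10, 1), max_coord = 50, max_side = 25)
    thr <- runif(1, 0.2, 0.6)
    got <- match_detections(det, ann, thr)
    want <- greedy_match_oracle(det, ann, thr)
    if (is.null(want)) {
      expect_equal(nrow(got$matches), 0L)
    } else {
      expect_equal(as.matrix(got$matches[c("detection", "annotation")]),
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("node_confusion counts matched pairs and rejects foreign types", {
  pairs <- data.frame(true_type = c("H", "H", "L", "L", "H"),
                      detected_type = c("H", "L", "L", "L", "H"))
  m <- node_confusion(pairs, c("H", "L"))
  expect_equal(sum(m), nrow(pairs))
  expect_equal(m["H", "L"], 1)
  expect_error(node_confusion(data.frame(true_type = "F",
                                         detected_type = "H"),
                              c("H", "L")),
               "hybrid")
})

test_that("rendered tables carry the headline percentages", {
  out <- render_reference_table(taxa_knn, "taxon")
  expect_true(any(grepl("90% classification accuracy", out)))
  out2 <- render_reference_table(node_2type, "node")
  expect_true(any(grepl("98% cross-type accuracy", out2)))
  out3 <- render_reference_table(node_3type, "node")
  expect_true(any(grepl("87% cross-type accuracy", out3)))
  expect_true(any(grepl("36 of 229", out3)))
  expect_error(render_reference_table(matrix(0, 2, 3), "node"), "square")
})
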