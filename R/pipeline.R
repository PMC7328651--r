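#' End-to-end pipeline configuration
#'
#' Bundles every stage's configuration with a global seed. Defaults follow
#' the reference protocol where one is stated (30 px anchor pitch, 6 sizes x
#' 6 aspect ratios, batch size 8, learning rate 1e-4, 500 px training crops,
#' 54/24/30 split of 108 images, top-10 score averages, 5 nearest
#' neighbors) and documented desk-scale choices elsewhere.
#'
#' @param mode `"two_type"` (H/L detector; the hybrid is recognized only at
#'   the image level) or `"three_type"` (adds F nodes for hybrid-image
#'   nodes).
#' @param n_per_taxon synthetic images per taxon.
#' @param n_train,n_val,n_test split sizes (must sum to `3 * n_per_taxon`).
#' @param synthetic [synthetic_params()].
#' @param anchors [anchor_spec()].
#' @param training [training_config()].
#' @param augmentation [augmentation_config()].
#' @param classifier_variant,classifier_k image classifier choice.
#' @param stat_k top-k depth for the score averages.
#' @param score_threshold,overlap_threshold,match_iou detection and
#'   evaluation thresholds.
#' @param seed global seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("two_type", "three_type"),
                            n_per_taxon = 36L,
                            n_train = NULL, n_val = NULL, n_test = NULL,
                            synthetic = synthetic_params(),
                            anchors = anchor_spec(),
                            training = training_config(),
                            augmentation = augmentation_config(),
                            classifier_variant = "knn",
                            classifier_k = 5L,
                            stat_k = 10L,
                            score_threshold = 0.3,
                            overlap_threshold = 0.5,
                            match_iou = 0.5,
                            seed = 1L) {
  mode <- match.arg(mode)
  n <- 3L * as.integer(n_per_taxon)
  # the reference design: half for training, 24/108 validation, 30/108 test
  n_train <- as.integer(n_train %||% round(n / 2))
  n_val <- as.integer(n_val %||% round(n * 24 / 108))
  n_test <- as.integer(n_test %||% (n - n_train - n_val))
  stopifnot(n_train + n_val + n_test == n)
  structure(list(mode = mode, n_per_taxon = as.integer(n_per_taxon),
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 synthetic = synthetic, anchors = anchors,
                 training = training, augmentation = augmentation,
                 classifier_variant = classifier_variant,
                 classifier_k = as.integer(classifier_k),
                 stat_k = as.integer(stat_k),
                 score_threshold = score_threshold,
                 overlap_threshold = overlap_threshold,
                 match_iou = match_iou, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(substr(tools::md5sum(tmp), 1, 12))
}

#' Run the full replication pipeline
#'
#' generate -> split -> train detector (with rotation/crop augmentation) ->
#' detect -> per-image statistics -> fit and apply the taxon classifier ->
#' evaluate. In `two_type` mode the detector trains only on *E. hyemale*
#' and *E. laevigatum* images (the hybrid enters at the classification
#' stage); in `three_type` mode hybrid images contribute F-labeled nodes.
#' Node-type evaluation covers the test images whose taxon defines a true
#' node type (parents only in two-type mode, all three in three-type mode).
#'
#' Deterministic: a fixed config (including its seed) reproduces the
#' dataset, the split, the training trajectory, and therefore every output
#' byte-for-byte.
#'
#' @param config [pipeline_config()].
#' @param dir optional output directory for the feature CSV, detection CSV,
#'   report JSON and text report.
#' @param dataset optionally, a precomputed `list(images, manifest)` to use
#'   instead of generating one.
#' @return List of class `pipeline_report`: split, detector, feature table,
#'   node and taxon confusion matrices with accuracies, config echo and
#'   hash.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = NULL,
                         dataset = NULL) {
  seed <- config$seed
  if (is.null(dataset)) {
    dataset <- generate_dataset(config$n_per_taxon, config$synthetic,
                                seed = seed)
  }
  images <- dataset$images
  manifest <- dataset$manifest
  ids <- manifest$image_id
  split <- split_dataset(ids, config$n_train, config$n_val, config$n_test,
                         seed = seed + 1L, taxa = manifest$taxon)
  by_id <- stats::setNames(images, ids)
  pick <- function(which_ids) by_id[which_ids]
  type_set <- if (config$mode == "two_type") c("H", "L") else c("H", "L", "F")
  parents_only <- function(imgs) {
    imgs[vapply(imgs, function(x) x$taxon != "ferrissii", TRUE)]
  }
  det_train <- pick(split$train); det_val <- pick(split$validation)
  if (config$mode == "two_type") {
    det_train <- parents_only(det_train)
    det_val <- parents_only(det_val)
  }
  detector <- train_detector(det_train, det_val, config$training,
                             seed = seed + 2L, spec = config$anchors,
                             aug = config$augmentation,
                             type_set = type_set)
  features <- feature_table(detector, images, config$score_threshold,
                            config$overlap_threshold, config$stat_k)
  split_of <- stats::setNames(rep(c("train", "validation", "test"),
                                  c(length(split$train),
                                    length(split$validation),
                                    length(split$test))),
                              c(split$train, split$validation, split$test))
  features$split <- unname(split_of[features$image_id])
  train_feats <- features[features$split == "train", , drop = FALSE]
  test_feats <- features[features$split == "test", , drop = FALSE]
  classifier <- fit_taxon_classifier(train_feats, train_feats$taxon,
                                     variant = config$classifier_variant,
                                     k = config$classifier_k,
                                     seed = seed + 3L)
  predicted <- predict_taxon(classifier, test_feats)
  t_conf <- taxon_confusion(test_feats$taxon, predicted)
  node_eval_imgs <- pick(split$test)
  if (config$mode == "two_type") node_eval_imgs <- parents_only(node_eval_imgs)
  node_eval <- evaluate_detector(detector, node_eval_imgs, config$match_iou,
                                 config$score_threshold,
                                 config$overlap_threshold)
  n_conf <- node_confusion(node_eval$pairs, type_set)
  report <- structure(list(
    mode = config$mode,
    config = config, config_hash = config_hash(config),
    split = split,
    detector = detector,
    classifier = classifier,
    features = features,
    predictions = data.frame(image_id = test_feats$image_id,
                             true_taxon = test_feats$taxon,
                             predicted_taxon = predicted),
    node_confusion = n_conf,
    cross_type = cross_type_accuracy(n_conf),
    node_eval = node_eval[c("n_false_positives", "n_false_negatives",
                            "n_detections", "n_annotations")],
    taxon_confusion = t_conf,
    image_accuracy = image_accuracy(t_conf)), class = "pipeline_report")
  if (!is.null(dir)) write_report(report, dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (", x$mode, ", config ", x$config_hash, ")\n\n",
      sep = "")
  cat("Node-type confusion (matched detections):\n")
  cat(render_confusion(x$node_confusion, "node"), sep = "\n")
  cat("\nTaxon confusion (test images):\n")
  cat(render_confusion(x$taxon_confusion, "taxon"), sep = "\n")
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- report$features
  f[sapply(f, is.numeric)] <- lapply(f[sapply(f, is.numeric)],
                                     function(x) format(x, digits = 12))
  utils::write.csv(f, file.path(dir, "features.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  save_detector(report$detector, file.path(dir, "detector.json"))
  jsonlite::write_json(list(
    mode = report$mode, config_hash = report$config_hash,
    seed = report$config$seed,
    node_confusion = unclass(report$node_confusion),
    node_labels = rownames(report$node_confusion),
    cross_type = report$cross_type,
    node_eval = report$node_eval,
    taxon_confusion = unclass(report$taxon_confusion),
    taxon_labels = rownames(report$taxon_confusion),
    image_accuracy = report$image_accuracy,
    thresholds = report$config[c("score_threshold", "overlap_threshold",
                                 "match_iou")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  writeLines(c(utils::capture.output(print(report))),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' Recompute a reference table's derived metrics from its literal counts
#'
#' Accepts the literal count grid of a reference experiment's table (node
#' confusion for the two- and three-type detection experiments; taxon
#' confusion for the 5-nn and decision-tree classifications) and recomputes
#' the derived numbers: totals, cross-type or classification accuracy, and
#' the H/F pairwise confusion where applicable.
#'
#' @param counts square count matrix, rows = true classes in order
#'   (H, L(, F) for node tables; hyemale, laevigatum, ferrissii for taxon
#'   tables). A data.frame or an unlabeled matrix is accepted.
#' @param kind `"node"` or `"taxon"`.
#' @return Character vector of formatted report lines (invisibly); printed.
#' @export
render_reference_table <- function(counts, kind = c("node", "taxon")) {
  kind <- match.arg(kind)
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m)) stop("count grid must be square")
  if (is.null(rownames(m))) {
    labels <- if (kind == "node") c("H", "L", "F")[seq_len(nrow(m))] else
      TAXA[seq_len(nrow(m))]
    rownames(m) <- colnames(m) <- labels
  }
  lines <- render_confusion(confusion_matrix(m), kind)
  cat(lines, sep = "\n")
  invisible(lines)
}
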