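#' Fit an image-level taxon classifier
#'
#' Three simple classifiers over the per-image detection statistics
#' (`a_H`, `a_L`, and `a_F` in three-type mode), predicting one of the
#' three taxa:
#' \itemize{
#'   \item `"logistic"` — multinomial logistic regression (straight-line
#'     class boundaries in the feature plane), with a small weight decay so
#'     separable small-sample fits converge;
#'   \item `"tree"` — a decision tree of axis-aligned threshold questions
#'     ("is `a_L` greater than t?"), Gini splits, shallow by default since
#'     training sets hold a few dozen images;
#'   \item `"knn"` — k-nearest-neighbor (default k = 5) memorizing the
#'     training pairs; a test image gets the majority taxon among the k
#'     closest training images in Euclidean distance.
#' }
#'
#' @param features data.frame of numeric feature columns (e.g. `a_H`,
#'   `a_L`); non-feature columns `image_id`, `taxon`, and counts `n_*` are
#'   ignored automatically.
#' @param labels taxon label per row.
#' @param variant `"knn"`, `"tree"` or `"logistic"`.
#' @param k neighbors for knn.
#' @param seed seed for the (stochastic) logistic fit initialization.
#' @param maxdepth,minbucket tree regularization.
#' @return A `taxon_classifier` model object.
#' @export
fit_taxon_classifier <- function(features, labels,
                                 variant = c("knn", "tree", "logistic"),
                                 k = 5L, seed = 1L,
                                 maxdepth = 3L, minbucket = 2L) {
  variant <- match.arg(variant)
  X <- classifier_matrix(features)
  labels <- check_taxon(labels)
  if (nrow(X) != length(labels)) {
    stop("features (", nrow(X), " rows) and labels (", length(labels),
         ") differ in length")
  }
  y <- factor(labels, levels = TAXA)
  if (variant != "knn" && length(unique(labels)) < 2L) {
    stop("logistic/tree fits need at least two classes in the training set")
  }
  fit <- switch(variant,
    knn = {
      if (k < 1L || k > nrow(X)) {
        stop("knn needs 1 <= k <= number of training points")
      }
      list(X = X, y = y, k = as.integer(k))
    },
    tree = {
      df <- data.frame(X, .taxon = y)
      rpart::rpart(.taxon ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(maxdepth = maxdepth,
                                                  minbucket = minbucket,
                                                  minsplit = 2L * minbucket,
                                                  cp = 0.001, xval = 0L))
    },
    logistic = {
      df <- data.frame(X, .taxon = droplevels(y))
      with_seed(seed, nnet::multinom(.taxon ~ ., data = df, decay = 1e-3,
                                     maxit = 500, trace = FALSE))
    })
  structure(list(variant = variant, fit = fit,
                 feature_names = colnames(X), seed = as.integer(seed)),
            class = "taxon_classifier")
}

# keep only numeric feature columns, in a stable order
classifier_matrix <- function(features, feature_names = NULL) {
  df <- as.data.frame(features)
  drop <- c("image_id", "taxon", grep("^n_", names(df), value = TRUE))
  df <- df[setdiff(names(df), drop)]
  df <- df[vapply(df, is.numeric, TRUE)]
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, names(df))
    if (length(missing) > 0L) {
      stop("features missing columns: ", paste(missing, collapse = ", "))
    }
    df <- df[feature_names]
  }
  as.matrix(df)
}

#' @export
print.taxon_classifier <- function(x, ...) {
  cat("<taxon_classifier> ", x$variant, " on (",
      paste(x$feature_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Predict taxa for new images
#'
#' Deterministic given the fitted model. knn votes among the k nearest
#' training points in Euclidean distance; a vote tie goes to the tied class
#' with the smallest mean neighbor distance, then to the fixed taxon order
#' (hyemale, laevigatum, ferrissii).
#'
#' @param model `taxon_classifier`.
#' @param features feature data.frame (same columns as at fit time).
#' @return Character vector of taxon labels.
#' @export
predict_taxon <- function(model, features) {
  X <- classifier_matrix(features, model$feature_names)
  switch(model$variant,
    knn = unname(apply(X, 1, function(q) knn_vote(model$fit, q))),
    tree = {
      df <- as.data.frame(X)
      as.character(predict(model$fit, df, type = "class"))
    },
    logistic = {
      df <- as.data.frame(X)
      as.character(predict(model$fit, df, type = "class"))
    })
}

knn_vote <- function(fit, q) {
  d <- sqrt(colSums((t(fit$X) - q)^2))
  ord <- order(d)               # stable: index order breaks distance ties
  nb <- ord[seq_len(fit$k)]
  votes <- table(fit$y[nb])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    mean_d <- vapply(top, function(cl) mean(d[nb][fit$y[nb] == cl]), 0)
    top <- top[mean_d == min(mean_d)]
    top <- top[order(match(top, TAXA))]
  }
  top[1]
}

#' Cross-validated comparison of classifier variants
#'
#' Stratified n-fold cross-validation over a grid of classifier variants and
#' hyperparameters, reporting mean held-out accuracy per configuration —
#' the model-selection protocol behind "decision trees and 5-nearest-neighbor
#' classifiers work best".
#'
#' @param features feature data.frame.
#' @param labels taxon labels.
#' @param variant_grid list of configs, each a list with `variant` and
#'   optional hyperparameters (e.g. `list(variant = "knn", k = 5)`).
#' @param n_folds folds (>= 2; must not exceed the smallest class count).
#' @param seed fold-assignment seed.
#' @return data.frame with one row per configuration: `variant`, `params`,
#'   `accuracy`.
#' @export
cross_validate <- function(features, labels,
                           variant_grid = list(
                             list(variant = "logistic"),
                             list(variant = "tree"),
                             list(variant = "knn", k = 1L),
                             list(variant = "knn", k = 3L),
                             list(variant = "knn", k = 5L),
                             list(variant = "knn", k = 7L)),
                           n_folds = 5L, seed = 1L) {
  labels <- check_taxon(labels)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > min(table(labels))) {
    stop("n_folds exceeds the smallest class count (",
         min(table(labels)), ")")
  }
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  rows <- lapply(variant_grid, function(cfg) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      model <- fit_taxon_classifier(features[tr, , drop = FALSE], labels[tr],
                                    variant = cfg$variant,
                                    k = cfg$k %||% 5L, seed = seed)
      pred <- predict_taxon(model, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    data.frame(variant = cfg$variant,
               params = if (!is.null(cfg$k)) paste0("k=", cfg$k) else "",
               accuracy = correct / n)
  })
  do.call(rbind, rows)
}

#' Save / load a taxon classifier
#'
#' knn and tree models serialize to JSON (the tree as its frame of
#' threshold questions is refit from stored training data on load for the
#' rpart variants; knn stores its memorized points directly).
#'
#' @param model `taxon_classifier` (knn only for JSON round-trip; tree and
#'   logistic are better persisted by refitting from the stored features).
#' @param path JSON path.
#' @export
save_classifier <- function(model, path) {
  if (model$variant != "knn") {
    stop("only knn classifiers serialize to JSON; refit tree/logistic from ",
         "the feature table")
  }
  obj <- list(variant = "knn", k = model$fit$k,
              feature_names = model$feature_names,
              X = as.vector(model$fit$X), n = nrow(model$fit$X),
              y = as.character(model$fit$y))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(obj$X, nrow = obj$n, ncol = length(obj$feature_names))
  colnames(X) <- obj$feature_names
  structure(list(variant = "knn",
                 fit = list(X = X, y = factor(obj$y, levels = TAXA),
                            k = as.integer(obj$k)),
                 feature_names = obj$feature_names, seed = NA_integer_),
            class = "taxon_classifier")
}
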