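# Three well-separated clusters in the (a_H, a_L) plane, one per taxon:
# parents sit on one high axis each, the hybrid carries both signals.
separable_features <- function(n_per = 10, sd = 0.02, seed = 1) {
  withr::local_seed(seed)
  centers <- list(hyemale = c(0.9, 0.1), laevigatum = c(0.1, 0.9),
                  ferrissii = c(0.6, 0.6))
  rows <- lapply(names(centers), function(tx) {
    data.frame(a_H = rnorm(n_per, centers[[tx]][1], sd),
               a_L = rnorm(n_per, centers[[tx]][2], sd),
               taxon = tx)
  })
  do.call(rbind, rows)
}

knn_oracle <- function(X, y, k, q, taxa_order = TAXA) {
  d <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) d[i] <- sqrt(sum((X[i, ] - q)^2))
  nb <- order(d)[seq_len(k)]
  counts <- table(factor(as.character(y[nb]), levels = taxa_order))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    md <- sapply(top, function(cl) mean(d[nb][as.character(y[nb]) == cl]))
    top <- top[md == min(md)]
  }
  top[1]
}

test_that("all three variants separate well-separated clusters", {
  f <- separable_features()
  for (v in c("knn", "tree", "logistic")) {
    m <- fit_taxon_classifier(f, f$taxon, variant = v)
    expect_equal(mean(predict_taxon(m, f) == f$taxon), 1.0,
                 info = v)
  }
})

test_that("knn predictions agree with a brute-force all-distances oracle", {
  withr::local_seed(41)
  for (rep in 1:25) {
    n <- sample(10:25, 1)
    X <- cbind(a_H = runif(n), a_L = runif(n))
    y <- sample(TAXA, n, replace = TRUE)
    k <- sample(c(1, 3, 5), 1)
    m <- fit_taxon_classifier(as.data.frame(X), y, "knn", k = k)
    queries <- as.data.frame(cbind(a_H = runif(4), a_L = runif(4)))
    got <- predict_taxon(m, queries)
    for (qi in 1:4) {
      expect_equal(got[qi], knn_oracle(X, y, k, as.numeric(queries[qi, ])))
    }
  }
})

test_that("knn with k=1 returns the label of an exactly matching point", {
  f <- separable_features(n_per = 5)
  m <- fit_taxon_classifier(f, f$taxon, "knn", k = 1)
  expect_equal(predict_taxon(m, f[7, , drop = FALSE]), f$taxon[7])
})

test_that("knn is consistent under a common positive rescaling", {
  f <- separable_features(n_per = 8, sd = 0.05, seed = 2)
  m1 <- fit_taxon_classifier(f, f$taxon, "knn", k = 5)
  f2 <- f
  f2[c("a_H", "a_L")] <- f2[c("a_H", "a_L")] * 3.7
  m2 <- fit_taxon_classifier(f2, f2$taxon, "knn", k = 5)
  withr::local_seed(42)
  probes <- data.frame(a_H = runif(20), a_L = runif(20))
  probes2 <- probes * 3.7
  expect_equal(predict_taxon(m1, probes), predict_taxon(m2, probes2))
})

test_that("knn votes of a single-class training set are that class", {
  X <- data.frame(a_H = runif(6), a_L = runif(6))
  m <- fit_taxon_classifier(X, rep("ferrissii", 6), "knn", k = 3)
  expect_equal(unique(predict_taxon(m, X)), "ferrissii")
})

test_that("tree predictions are threshold questions on the features", {
  # one split suffices: a_L > 0.5 separates laevigatum
  f <- data.frame(a_H = c(0.9, 0.85, 0.8, 0.1, 0.15, 0.2),
                  a_L = c(0.1, 0.15, 0.2, 0.9, 0.85, 0.8))
  y <- rep(c("hyemale", "laevigatum"), each = 3)
  m <- fit_taxon_classifier(f, y, "tree", minbucket = 1)
  expect_equal(predict_taxon(m, data.frame(a_H = 0.1, a_L = 0.9)),
               "laevigatum")
  expect_equal(predict_taxon(m, data.frame(a_H = 0.9, a_L = 0.1)),
               "hyemale")
  # piecewise-constant: perturbations that cross no split threshold
  # leave the label unchanged
  splits <- m$fit$splits
  eps <- 0.01
  base <- predict_taxon(m, data.frame(a_H = 0.9, a_L = 0.1))
  expect_equal(predict_taxon(m, data.frame(a_H = 0.9 + eps, a_L = 0.1 + eps)),
               base)
})

test_that("fit validates inputs", {
  f <- separable_features(n_per = 4)
  expect_error(fit_taxon_classifier(f[1:5, ], f$taxon, "knn"), "differ")
  expect_error(fit_taxon_classifier(f[1:4, ], f$taxon[1:4], "tree"),
               "two classes")
  expect_error(fit_taxon_classifier(f, f$taxon, "knn", k = 99), "k")
})

test_that("classifier fits are deterministic under a fixed seed", {
  f <- separable_features(n_per = 8, sd = 0.1, seed = 3)
  withr::local_seed(43)
  probes <- data.frame(a_H = runif(25), a_L = runif(25))
  for (v in c("knn", "tree", "logistic")) {
    m1 <- fit_taxon_classifier(f, f$taxon, v, seed = 9)
    m2 <- fit_taxon_classifier(f, f$taxon, v, seed = 9)
    expect_identical(predict_taxon(m1, probes), predict_taxon(m2, probes),
                     info = v)
  }
})

test_that("logistic decision regions are convex on a probe grid", {
  f <- separable_features(n_per = 10, sd = 0.05, seed = 4)
  m <- fit_taxon_classifier(f, f$taxon, "logistic")
  g <- expand.grid(a_H = seq(0, 1, by = 0.05), a_L = seq(0, 1, by = 0.05))
  lab <- predict_taxon(m, g)
  # midpoint of any two same-class probe points is in the same class
  withr::local_seed(44)
  for (rep in 1:40) {
    cl <- sample(unique(lab), 1)
    pts <- g[lab == cl, , drop = FALSE]
    if (nrow(pts) < 2) next
    two <- pts[sample(nrow(pts), 2), ]
    mid <- (two[1, ] + two[2, ]) / 2
    expect_equal(predict_taxon(m, mid), cl)
  }
})

test_that("cross_validate reports per-variant accuracies with fixed folds", {
  f <- separable_features(n_per = 10, sd = 0.03, seed = 5)
  grid <- list(list(variant = "knn", k = 1), list(variant = "knn", k = 5),
               list(variant = "tree"))
  cv1 <- cross_validate(f, f$taxon, grid, n_folds = 5, seed = 6)
  cv2 <- cross_validate(f, f$taxon, grid, n_folds = 5, seed = 6)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$accuracy == 1.0))
  expect_error(cross_validate(f, f$taxon, grid, n_folds = 12, seed = 1),
               "smallest class")
})

test_that("knn classifiers round-trip through JSON", {
  f <- separable_features(n_per = 6, sd = 0.05, seed = 7)
  m <- fit_taxon_classifier(f, f$taxon, "knn", k = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  withr::local_seed(45)
  probes <- data.frame(a_H = runif(20), a_L = runif(20))
  expect_identical(predict_taxon(m, probes), predict_taxon(m2, probes))
})
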