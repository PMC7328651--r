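#' @importFrom jsonlite fromJSON toJSON write_json read_json
NULL

#' Allowed structural annotation categories
#' @export
ANNOTATION_CATEGORIES <- c("strobilus", "normal_stem_node",
                           "normal_stem_internode", "injured_stem_node")

#' The three focal taxa
#'
#' Order is fixed (used for deterministic tie-breaking in classifiers).
#' @export
TAXA <- c("hyemale", "laevigatum", "ferrissii")

normalize_category <- function(x) gsub("[ -]+", "_", trimws(tolower(x)))

check_categories <- function(x) {
  x <- normalize_category(x)
  bad <- setdiff(unique(x), ANNOTATION_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown annotation category: ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(ANNOTATION_CATEGORIES, collapse = ", "))
  }
  x
}

check_taxon <- function(x) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), TAXA)
  if (length(bad) > 0L) {
    stop("unknown taxon: ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(TAXA, collapse = ", "))
  }
  x
}

#' Construct an annotated image
#'
#' @param image_id unique identifier (usually the file name).
#' @param annotations data.frame with box columns plus `category`.
#' @param image optional `height x width x 3` array in `[0, 1]`, or NULL when
#'   only annotations are carried.
#' @param taxon image-level taxon label (`"hyemale"`, `"laevigatum"`,
#'   `"ferrissii"`) or NA.
#' @param width,height image dimensions; inferred from `image` when present.
#'   Boxes extending past the frame are clipped with a warning.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, annotations, image = NULL, taxon = NA,
                            width = NULL, height = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  if (nrow(annotations) > 0L) {
    validate_boxes(annotations)
    annotations$category <- check_categories(annotations$category)
  } else if (is.null(annotations$category)) {
    annotations$category <- character(0)
  }
  if (!is.null(image)) {
    stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
    height <- dim(image)[1]
    width <- dim(image)[2]
  }
  if (!is.null(width) && !is.null(height) && nrow(annotations) > 0L) {
    clipped <- clip_boxes(annotations, width, height)
    if (nrow(clipped) < nrow(annotations) ||
        !isTRUE(all.equal(clipped[c("x_min", "y_min", "x_max", "y_max")],
                          annotations[c("x_min", "y_min", "x_max", "y_max")],
                          check.attributes = FALSE))) {
      warning("annotation boxes extended past image bounds in ", image_id,
              "; clipped")
    }
    annotations <- clipped
  }
  if (!is.na(taxon)) taxon <- check_taxon(taxon)
  structure(list(image_id = image_id, image = image,
                 annotations = annotations, taxon = taxon,
                 width = width, height = height),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat("<annotated_image> ", x$image_id,
      if (!is.na(x$taxon)) paste0(" [", x$taxon, "]") else "",
      ": ", nrow(x$annotations), " annotation(s)",
      if (!is.null(x$width)) paste0(", ", x$width, "x", x$height) else "",
      "\n", sep = "")
  invisible(x)
}

empty_annotations <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), category = character(0))
}

#' Read a VGG Image Annotator (VIA) v2 project file
#'
#' Parses rectangle regions from VIA v2 project JSON. VIA stores rectangles as
#' `(x, y, width, height)`; these are converted to half-open boxes
#' `(x, y, x + width, y + height)`. The structural category is read from
#' `region_attributes$category` (spaces are normalized to underscores).
#'
#' Pixel data are not loaded; only annotations, identifiers and (when present
#' in `file_attributes`) image dimensions travel through.
#'
#' @param path VIA v2 project JSON file.
#' @return List of [annotated_image()] objects (no pixel data).
#' @export
read_via <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed VIA JSON in ", path,
                                           ": ", conditionMessage(e)))
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  out <- vector("list", length(meta))
  for (i in seq_along(meta)) {
    entry <- meta[[i]]
    if (is.null(entry$filename)) {
      stop("malformed VIA JSON: entry ", sQuote(names(meta)[i]),
           " has no 'filename'")
    }
    regions <- entry$regions
    if (length(regions) > 0L) {
      rows <- lapply(regions, function(r) {
        sa <- r$shape_attributes
        if (is.null(sa$name) || sa$name != "rect") {
          stop("unsupported region shape ", sQuote(sa$name %||% "<missing>"),
               " in ", entry$filename, "; only 'rect' is supported")
        }
        for (k in c("x", "y", "width", "height")) {
          if (is.null(sa[[k]])) {
            stop("malformed VIA JSON: rectangle in ", entry$filename,
                 " missing shape_attributes$", k)
          }
        }
        cat_ <- r$region_attributes$category
        if (is.null(cat_)) {
          stop("region in ", entry$filename,
               " has no region_attributes$category")
        }
        data.frame(x_min = sa$x, y_min = sa$y,
                   x_max = sa$x + sa$width, y_max = sa$y + sa$height,
                   category = check_categories(cat_))
      })
      ann <- do.call(rbind, rows)
    } else {
      ann <- empty_annotations()
    }
    fa <- entry$file_attributes
    w <- if (!is.null(fa$width)) as.numeric(fa$width) else NULL
    h <- if (!is.null(fa$height)) as.numeric(fa$height) else NULL
    out[[i]] <- annotated_image(entry$filename, ann, width = w, height = h)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations as a VIA v2 project file
#'
#' Inverse of [read_via()]: box coordinates and categories round-trip
#' losslessly. Pixel data are not written (use [write_dataset()] for that).
#'
#' @param images list of [annotated_image()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_via <- function(images, path) {
  meta <- list()
  for (img in images) {
    ann <- img$annotations
    regions <- lapply(seq_len(nrow(ann)), function(i) {
      list(shape_attributes = list(name = "rect",
                                   x = ann$x_min[i], y = ann$y_min[i],
                                   width = ann$x_max[i] - ann$x_min[i],
                                   height = ann$y_max[i] - ann$y_min[i]),
           region_attributes = list(category = ann$category[i]))
    })
    fa <- list()
    if (!is.null(img$width)) fa <- list(width = img$width, height = img$height)
    key <- paste0(img$image_id, "-1")
    meta[[key]] <- list(filename = img$image_id, size = -1L,
                        regions = regions, file_attributes = fa)
  }
  doc <- list(`_via_settings` = list(project = list(name = "equinode")),
              `_via_img_metadata` = meta,
              `_via_attributes` = list(
                region = list(category = list(
                  type = "dropdown",
                  options = stats::setNames(as.list(ANNOTATION_CATEGORIES),
                                            ANNOTATION_CATEGORIES)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write the image-level manifest
#'
#' VIA has no slot for an image-level class, so taxon labels (and, once
#' assigned, the train/validation/test split) live in a sidecar CSV with
#' columns `image_id`, `taxon`, and optionally `split`.
#'
#' @param path CSV path.
#' @return data.frame with columns `image_id`, `taxon` (and `split` if
#'   present).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "taxon") %in% names(m))) {
    stop("manifest must have columns image_id, taxon")
  }
  m$taxon <- check_taxon(m$taxon)
  m
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic train/validation/test split
#'
#' Partitions image ids into disjoint train/validation/test sets of the
#' requested sizes. When per-image taxon labels are supplied the split is
#' stratified: each taxon contributes proportionally to each subset, with
#' remainders assigned in seeded order.
#'
#' @param image_ids character vector of unique ids.
#' @param n_train,n_val,n_test subset sizes; must sum to
#'   `length(image_ids)`.
#' @param seed integer seed; the same seed always yields the same split.
#' @param taxa optional taxon label per id (enables stratification).
#' @return List with elements `train`, `validation`, `test` (character
#'   vectors) and `seed`.
#' @export
split_dataset <- function(image_ids, n_train, n_val, n_test, seed,
                          taxa = NULL) {
  n <- length(image_ids)
  if (anyDuplicated(image_ids)) stop("image_ids must be unique")
  if (any(c(n_train, n_val, n_test) < 0)) stop("split counts must be >= 0")
  if (n_train + n_val + n_test != n) {
    stop("split counts (", n_train, " + ", n_val, " + ", n_test,
         ") must sum to the number of ids (", n, ")")
  }
  assign_one <- function(ids, k_train, k_val) {
    perm <- sample(ids)
    list(train = perm[seq_len(k_train)],
         validation = perm[k_train + seq_len(k_val)],
         test = perm[k_train + k_val + seq_len(length(ids) - k_train - k_val)])
  }
  out <- with_seed(seed, {
    if (is.null(taxa)) {
      assign_one(image_ids, n_train, n_val)
    } else {
      stopifnot(length(taxa) == n)
      taxa <- check_taxon(taxa)
      groups <- split(image_ids, taxa)
      # proportional integer allocation per stratum; remainders dealt in
      # seeded stratum order
      alloc <- function(total) {
        base <- floor(total * lengths(groups) / n)
        rem <- total - sum(base)
        if (rem > 0) {
          extra <- sample(names(groups), rem,
                          prob = lengths(groups) / n, replace = FALSE)
          base[extra] <- base[extra] + 1L
        }
        base
      }
      k_train <- alloc(n_train)
      k_val <- alloc(n_val)
      # clamp so each stratum's train+val never exceeds its size
      for (g in names(groups)) {
        over <- k_train[g] + k_val[g] - length(groups[[g]])
        if (over > 0) k_val[g] <- k_val[g] - over
      }
      parts <- lapply(names(groups), function(g) {
        assign_one(groups[[g]], k_train[g], k_val[g])
      })
      res <- list(train = unlist(lapply(parts, `[[`, "train")),
                  validation = unlist(lapply(parts, `[[`, "validation")),
                  test = unlist(lapply(parts, `[[`, "test")))
      # stratified rounding can leave subsets off-target by a remainder;
      # rebalance by moving seeded-random ids between subsets
      rebalance <- function(res, name, target) {
        while (length(res[[name]]) > target) {
          donor <- name
          recv <- names(res)[which(vapply(res, length, 1L) <
                                     c(n_train, n_val, n_test))][1]
          pick <- sample(res[[donor]], 1L)
          res[[donor]] <- setdiff(res[[donor]], pick)
          res[[recv]] <- c(res[[recv]], pick)
        }
        res
      }
      res <- rebalance(res, "train", n_train)
      res <- rebalance(res, "validation", n_val)
      res <- rebalance(res, "test", n_test)
      res
    }
  })
  out <- lapply(out, function(x) if (is.null(x)) character(0) else unname(x))
  stopifnot(length(out$train) == n_train, length(out$validation) == n_val,
            length(out$test) == n_test)
  c(out, list(seed = as.integer(seed)))
}
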