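#' Parameters for the synthetic specimen generator
#'
#' The generator emulates the morphological contrast the pipeline exploits on
#' pressed *Equisetum* stems: hyemale-type (H) nodes show a dark-light-dark
#' horizontal band triplet (dark stripe near the sheath base, ashy-white
#' middle, dark rim), laevigatum-type (L) nodes a green sheath with a single
#' narrow black rim. Hybrid (*E. xferrissii*) specimens carry a mixture, with
#' H-like nodes predominating toward the stem base and L-like nodes toward
#' the apex.
#'
#' @param image_size square image side in pixels.
#' @param stems_per_image integer range `c(min, max)` of stems per specimen.
#' @param nodes_per_stem integer range of nodes along each stem.
#' @param node_size node patch side in pixels; must be at least 30, the
#'   detector's smallest-object grid pitch.
#' @param stem_curvature range (radians) of the maximum tilt of the stem
#'   centerline from vertical.
#' @param hybrid_gradient `c(p_base, p_apex)`: probability that a hybrid node
#'   is H-type at the stem base / apex; `p_base >= p_apex`.
#' @param background_noise standard deviation of additive Gaussian pixel
#'   noise on the paper background (image values are in `[0, 1]`).
#' @param strobili render a strobilus at each stem apex (annotated as
#'   `strobilus`, never detected).
#' @param seed default seed used by [generate_dataset()] when none is given.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size = 700,
                             stems_per_image = c(2L, 4L),
                             nodes_per_stem = c(8L, 14L),
                             node_size = 36,
                             stem_curvature = c(0.02, 0.12),
                             hybrid_gradient = c(p_base = 0.9, p_apex = 0.1),
                             background_noise = 0.02,
                             strobili = FALSE,
                             seed = 1L) {
  stopifnot(length(hybrid_gradient) == 2L,
            all(hybrid_gradient >= 0), all(hybrid_gradient <= 1))
  if (hybrid_gradient[1] < hybrid_gradient[2]) {
    stop("hybrid_gradient: p_base must be >= p_apex (H predominates basally)")
  }
  if (node_size < 30) stop("node_size must be >= 30 (detector grid pitch)")
  if (image_size < 4 * node_size) {
    stop("image_size too small to fit one stem (need >= 4 * node_size)")
  }
  structure(list(image_size = as.integer(image_size),
                 stems_per_image = as.integer(stems_per_image),
                 nodes_per_stem = as.integer(nodes_per_stem),
                 node_size = as.integer(node_size),
                 stem_curvature = as.numeric(stem_curvature),
                 hybrid_gradient = stats::setNames(as.numeric(hybrid_gradient),
                                                   c("p_base", "p_apex")),
                 background_noise = as.numeric(background_noise),
                 strobili = isTRUE(strobili),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# sheath / stem palette, jittered per call
palette_synthetic <- list(
  paper = c(0.93, 0.91, 0.85),
  stem = c(0.42, 0.58, 0.35),
  h_field = c(0.82, 0.78, 0.68),   # ashy white-tan between the dark bands
  h_band = c(0.16, 0.13, 0.11),
  l_field = c(0.50, 0.66, 0.32),   # green sheath, lighter than the stem
  l_rim = c(0.08, 0.08, 0.08),
  strobilus = c(0.45, 0.32, 0.15)
)

fill_rows <- function(patch, rows, col) {
  for (ch in 1:3) patch[rows, , ch] <- col[ch]
  patch
}

#' Render a single node patch
#'
#' Draws the appearance of one nodal leaf sheath as a `size x size x 3` RGB
#' array in `[0, 1]`. H patches carry two interior dark bands (basal stripe
#' and rim) separated by a light field; L patches are a green field with one
#' narrow dark rim. Band widths and hues are jittered from the current RNG
#' stream, so rendering is deterministic under a fixed `.Random.seed`.
#'
#' @param type `"H"` or `"L"` (hybrid nodes are rendered as one of the two
#'   parental appearances; there is no separate hybrid look).
#' @param size patch side in pixels, at least 8.
#' @param noise_sd additive pixel noise standard deviation.
#' @return `size x size x 3` numeric array.
#' @export
render_node <- function(type = c("H", "L"), size, noise_sd = 0.02) {
  type <- match.arg(type)
  if (size < 8) stop("node patch size must be >= 8 px")
  size <- as.integer(size)
  pal <- palette_synthetic
  jit <- function(col, amt = 0.05) clamp01(col + stats::runif(3, -amt, amt))
  rows_at <- function(lo, hi) {
    r1 <- max(1L, as.integer(round(lo * size)))
    r2 <- min(size, as.integer(round(hi * size)))
    r1:r2
  }
  if (type == "H") {
    patch <- array(rep(jit(pal$h_field), each = size * size),
                   dim = c(size, size, 3))
    # rim band (toward the apex, i.e. top of the patch) and basal stripe,
    # both strictly interior
    rim_lo <- stats::runif(1, 0.08, 0.12)
    patch <- fill_rows(patch, rows_at(rim_lo, rim_lo + stats::runif(1, 0.10, 0.16)),
                       jit(pal$h_band))
    base_lo <- stats::runif(1, 0.60, 0.68)
    patch <- fill_rows(patch, rows_at(base_lo, base_lo + stats::runif(1, 0.12, 0.18)),
                       jit(pal$h_band))
  } else {
    patch <- array(rep(jit(pal$l_field), each = size * size),
                   dim = c(size, size, 3))
    rim_lo <- stats::runif(1, 0.06, 0.10)
    patch <- fill_rows(patch, rows_at(rim_lo, rim_lo + stats::runif(1, 0.04, 0.08)),
                       jit(pal$l_rim))
  }
  clamp01(patch + array(stats::rnorm(length(patch), 0, noise_sd), dim(patch)))
}

#' Node type along a hybrid stem
#'
#' The probability that a hybrid node looks hyemale-like falls linearly from
#' `p_base` at the stem base to `p_apex` at the apex.
#'
#' @param relative_position position along the stem in `[0, 1]`
#'   (0 = base, 1 = apex).
#' @param params [synthetic_params()].
#' @return `"H"` or `"L"`, drawn from the current RNG stream.
#' @export
hybrid_node_type <- function(relative_position, params = synthetic_params()) {
  if (any(relative_position < 0 | relative_position > 1)) {
    stop("relative_position must lie in [0, 1]")
  }
  g <- params$hybrid_gradient
  p <- g["p_base"] + (g["p_apex"] - g["p_base"]) * relative_position
  ifelse(stats::runif(length(relative_position)) < p, "H", "L")
}

#' Generate one synthetic pressed specimen
#'
#' Draws gently curved stems on a noisy paper-like background, places nodes
#' at regular intervals along each stem, and renders each node by taxon:
#' *E. hyemale* images carry only H-type nodes, *E. laevigatum* only L-type,
#' and *E. xferrissii* a basal-to-apical H-to-L gradient via
#' [hybrid_node_type()]. Ground-truth boxes (category `normal_stem_node`)
#' tightly enclose each node patch; the annotation table additionally
#' records each node's rendered type and relative stem position for
#' downstream analyses.
#'
#' @param taxon one of `"hyemale"`, `"laevigatum"`, `"ferrissii"`.
#' @param params [synthetic_params()].
#' @param seed integer; the same `(taxon, params, seed)` triple reproduces
#'   the image and annotations bit-for-bit.
#' @param image_id identifier for the result.
#' @return An [annotated_image()] with pixel data attached.
#' @export
generate_specimen <- function(taxon, params = synthetic_params(), seed,
                              image_id = paste0(taxon, "_", seed)) {
  taxon <- match.arg(taxon, TAXA)
  s <- params$image_size
  ns <- params$node_size
  with_seed(seed, {
    img <- array(rep(palette_synthetic$paper, each = s * s), dim = c(s, s, 3))
    img <- clamp01(img + array(stats::rnorm(s * s * 3, 0, params$background_noise),
                               dim = dim(img)))
    n_stems <- sample(params$stems_per_image[1]:params$stems_per_image[2], 1)
    margin <- max(ns, round(0.05 * s))
    y_bottom <- s - margin
    y_top <- margin
    stem_w <- max(6L, as.integer(round(0.55 * ns)))
    half_w <- ns %/% 2
    ann <- list()
    for (k in seq_len(n_stems)) {
      cx <- s * (k - 0.5) / n_stems + stats::runif(1, -0.06, 0.06) * s
      cx <- min(max(cx, half_w + 2), s - half_w - 2)
      theta <- stats::runif(1, params$stem_curvature[1], params$stem_curvature[2])
      len <- y_bottom - y_top
      period <- len * stats::runif(1, 1.2, 2.0)
      amp <- tan(theta) * period / (2 * pi)
      phase <- stats::runif(1, 0, 2 * pi)
      ys <- y_top:y_bottom
      xs <- cx + amp * sin(2 * pi * (y_bottom - ys) / period + phase)
      xs <- pmin(pmax(xs, half_w + 2), s - half_w - 2)
      shade <- stats::rnorm(length(ys), 0, 0.015)
      for (i in seq_along(ys)) {
        c1 <- as.integer(round(xs[i] - stem_w / 2)) + 1L
        c2 <- as.integer(round(xs[i] + stem_w / 2))
        col <- clamp01(palette_synthetic$stem + shade[i])
        for (ch in 1:3) img[ys[i], c1:c2, ch] <- col[ch]
      }
      n_nodes <- sample(params$nodes_per_stem[1]:params$nodes_per_stem[2], 1)
      # regular spacing with a small positional jitter, base (t = 0) at the
      # bottom of the sheet
      t_pos <- (seq_len(n_nodes) - 0.5) / n_nodes +
        stats::runif(n_nodes, -0.2, 0.2) / n_nodes
      t_pos <- pmin(pmax(t_pos, 0), 1)
      types <- switch(taxon,
                      hyemale = rep("H", n_nodes),
                      laevigatum = rep("L", n_nodes),
                      ferrissii = hybrid_node_type(t_pos, params))
      for (j in seq_len(n_nodes)) {
        cy <- y_bottom - t_pos[j] * len
        ci <- as.integer(round(xs[match(round(cy), ys)]))
        r1 <- as.integer(round(cy - ns / 2)); r1 <- max(1L, min(r1, s - ns))
        c1 <- ci - half_w; c1 <- max(1L, min(c1, s - ns))
        patch <- render_node(types[j], ns, noise_sd = params$background_noise)
        img[r1:(r1 + ns - 1L), c1:(c1 + ns - 1L), ] <- patch
        ann[[length(ann) + 1L]] <- data.frame(
          x_min = c1 - 1L, y_min = r1 - 1L,
          x_max = c1 - 1L + ns, y_max = r1 - 1L + ns,
          category = "normal_stem_node",
          rendered_type = types[j], relative_position = t_pos[j])
      }
      if (params$strobili) {
        sc <- as.integer(round(xs[1]))
        sh <- as.integer(round(1.6 * ns)); sw <- stem_w + 4L
        r1 <- max(1L, y_top - sh %/% 2); r2 <- min(s, r1 + sh - 1L)
        c1 <- max(1L, sc - sw %/% 2); c2 <- min(s, c1 + sw - 1L)
        for (ch in 1:3) img[r1:r2, c1:c2, ch] <- palette_synthetic$strobilus[ch]
        ann[[length(ann) + 1L]] <- data.frame(
          x_min = c1 - 1L, y_min = r1 - 1L, x_max = c2, y_max = r2,
          category = "strobilus", rendered_type = NA_character_,
          relative_position = NA_real_)
      }
    }
    ann <- if (length(ann) > 0) do.call(rbind, ann) else empty_annotations()
    annotated_image(image_id, ann, image = img, taxon = taxon)
  })
}

#' Generate a balanced synthetic dataset
#'
#' Emulates the balanced study design of 36 verified images per taxon:
#' produces `3 * n_per_taxon` specimens with ground-truth annotations and a
#' taxon manifest. With `dir` set, PNG images, a VIA v2 project JSON and the
#' manifest CSV are written via the annotation I/O layer.
#'
#' @param n_per_taxon images per taxon (>= 1).
#' @param params [synthetic_params()].
#' @param seed master seed; per-image seeds are drawn from it.
#' @param dir optional output directory.
#' @return List with `images` (list of [annotated_image()]) and `manifest`
#'   (data.frame `image_id`, `taxon`).
#' @export
generate_dataset <- function(n_per_taxon, params = synthetic_params(),
                             seed = params$seed, dir = NULL) {
  stopifnot(n_per_taxon >= 1)
  n <- 3L * as.integer(n_per_taxon)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  taxa <- rep(TAXA, each = n_per_taxon)
  ids <- sprintf("%s_%03d.png", taxa, rep(seq_len(n_per_taxon), times = 3))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- generate_specimen(taxa[i], params, sub_seeds[i],
                                     image_id = ids[i])
  }
  manifest <- data.frame(image_id = ids, taxon = taxa,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) write_dataset(images, manifest, dir)
  list(images = images, manifest = manifest)
}

#' Write a dataset to disk
#'
#' Writes one PNG per image plus `annotations.json` (VIA v2) and
#' `manifest.csv` into `dir`.
#'
#' @param images list of [annotated_image()] with pixel data.
#' @param manifest data.frame (`image_id`, `taxon`, optional `split`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(images, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in images) {
    if (is.null(img$image)) stop("image ", img$image_id, " has no pixel data")
    png::writePNG(img$image, file.path(dir, img$image_id))
  }
  write_via(images, file.path(dir, "annotations.json"))
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return Same shape as [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  images <- read_via(file.path(dir, "annotations.json"))
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  taxon_of <- stats::setNames(manifest$taxon, manifest$image_id)
  images <- lapply(images, function(img) {
    img$image <- png::readPNG(file.path(dir, img$image_id))
    img$height <- dim(img$image)[1]
    img$width <- dim(img$image)[2]
    if (img$image_id %in% names(taxon_of)) img$taxon <- taxon_of[[img$image_id]]
    img
  })
  list(images = images, manifest = manifest)
}
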