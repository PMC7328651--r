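#' Augmentation configuration
#'
#' Detector training augments each specimen by rotating it about its center
#' by a random angle and cropping a random fixed-size sub-image, with the
#' bounding boxes transformed consistently.
#'
#' @param crop_size side of the square crop in pixels (training protocol
#'   uses 500).
#' @param angle_range degrees, `c(min, max)`; default the full circle.
#' @param min_box_visibility minimum fraction of a box's area that must
#'   remain inside the crop for the box to be kept (then clipped).
#' @param seed optional seed used by [augment()] when given.
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_size = 500,
                                angle_range = c(0, 360),
                                min_box_visibility = 0.5,
                                seed = NULL) {
  stopifnot(crop_size > 0, min_box_visibility > 0, min_box_visibility <= 1)
  structure(list(crop_size = as.integer(crop_size),
                 angle_range = as.numeric(angle_range),
                 min_box_visibility = as.numeric(min_box_visibility),
                 seed = seed),
            class = "augmentation_config")
}

# Forward rotation of points about (cx, cy) by `angle` degrees in image
# coordinates (y down); positive angles appear counterclockwise on screen.
rotate_points <- function(x, y, angle, cx, cy) {
  th <- angle * pi / 180
  list(x = cx + cos(th) * (x - cx) + sin(th) * (y - cy),
       y = cy - sin(th) * (x - cx) + cos(th) * (y - cy))
}

#' Rotate an image and its boxes about the image center
#'
#' The image is rotated by `angle` degrees about its center on a same-size
#' canvas (bilinear resampling; pixels mapped from outside the source are
#' filled with `fill`, by default the mean image color). Each box becomes the
#' axis-aligned bounding rectangle of its four rotated corners, clipped to
#' the frame — the standard convention for axis-aligned detectors, which
#' grows boxes at angles off the multiples of 90 degrees.
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param boxes box data.frame (extra columns carried through).
#' @param angle degrees.
#' @param fill length-3 RGB fill color, or NULL for the image mean.
#' @return List with `image` and `boxes`.
#' @export
rotate_image_and_boxes <- function(image, boxes, angle, fill = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (angle %% 360 == 0) return(list(image = image, boxes = boxes))
  if (is.null(fill)) {
    fill <- c(mean(image[, , 1]), mean(image[, , 2]), mean(image[, , 3]))
  }
  cx <- w / 2; cy <- h / 2
  out <- cpp_rotate_bilinear(image, angle, fill)
  list(image = out, boxes = rotate_boxes(boxes, angle, cx, cy, w, h))
}

#' Rotate boxes about a point, returning axis-aligned hulls
#'
#' @param boxes box data.frame.
#' @param angle degrees.
#' @param cx,cy rotation center.
#' @param width,height frame to clip against (NULL to skip clipping).
#' @return Transformed box data.frame.
#' @export
rotate_boxes <- function(boxes, angle, cx, cy, width = NULL, height = NULL) {
  if (nrow(boxes) == 0L) return(boxes)
  corners_x <- cbind(boxes$x_min, boxes$x_max, boxes$x_min, boxes$x_max)
  corners_y <- cbind(boxes$y_min, boxes$y_min, boxes$y_max, boxes$y_max)
  r <- rotate_points(corners_x, corners_y, angle, cx, cy)
  out <- boxes
  out$x_min <- apply(r$x, 1, min); out$x_max <- apply(r$x, 1, max)
  out$y_min <- apply(r$y, 1, min); out$y_max <- apply(r$y, 1, max)
  if (!is.null(width)) out <- clip_boxes(out, width, height)
  out
}

reflect_pad <- function(image, target_h, target_w) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h >= target_h && w >= target_w) return(image)
  ridx <- seq_len(max(h, target_h))
  cidx <- seq_len(max(w, target_w))
  reflect <- function(i, n) {
    # indices reflected off both edges (period 2n - 2)
    j <- (i - 1) %% (2 * n - 2)
    ifelse(j < n, j + 1, 2 * n - j - 1)
  }
  if (h == 1) ridx <- rep(1L, length(ridx)) else ridx <- reflect(ridx, h)
  if (w == 1) cidx <- rep(1L, length(cidx)) else cidx <- reflect(cidx, w)
  image[ridx[seq_len(max(h, target_h))], cidx[seq_len(max(w, target_w))], ,
        drop = FALSE]
}

#' Random fixed-size crop with box bookkeeping
#'
#' Cuts a `crop_size x crop_size` window at a position drawn from the current
#' RNG stream, translates the boxes into crop coordinates, drops boxes whose
#' visible-area fraction falls below `min_box_visibility`, and clips the
#' survivors. Images smaller than the crop are reflection-padded first.
#'
#' @param image `height x width x 3` array.
#' @param boxes box data.frame.
#' @param config [augmentation_config()].
#' @return List with `image` (exactly `crop_size` square), `boxes`, and
#'   `origin` (the crop's top-left corner in source coordinates).
#' @export
random_crop <- function(image, boxes, config = augmentation_config()) {
  cs <- config$crop_size
  image <- reflect_pad(image, cs, cs)
  h <- dim(image)[1]; w <- dim(image)[2]
  ox <- if (w > cs) sample.int(w - cs + 1L, 1L) - 1L else 0L
  oy <- if (h > cs) sample.int(h - cs + 1L, 1L) - 1L else 0L
  out <- image[oy + seq_len(cs), ox + seq_len(cs), , drop = FALSE]
  list(image = out,
       boxes = crop_box_bookkeeping(boxes, ox, oy, cs,
                                    config$min_box_visibility),
       origin = c(x = ox, y = oy))
}

crop_box_bookkeeping <- function(boxes, ox, oy, cs, min_vis) {
  if (nrow(boxes) == 0L) return(boxes)
  b <- boxes
  b$x_min <- b$x_min - ox; b$x_max <- b$x_max - ox
  b$y_min <- b$y_min - oy; b$y_max <- b$y_max - oy
  full <- box_area(b)
  vis_w <- pmax(0, pmin(b$x_max, cs) - pmax(b$x_min, 0))
  vis_h <- pmax(0, pmin(b$y_max, cs) - pmax(b$y_min, 0))
  keep <- (vis_w * vis_h) / full >= min_vis
  clip_boxes(b[keep, , drop = FALSE], cs, cs)
}

#' Rotate-then-crop augmentation of an annotated image
#'
#' Composition of [rotate_image_and_boxes()] (random angle from
#' `angle_range`) and [random_crop()]. Randomness comes from the current RNG
#' stream, or from `config$seed`/`seed` when given.
#'
#' @param annotated [annotated_image()] with pixel data.
#' @param config [augmentation_config()].
#' @param seed optional seed for a reproducible single draw.
#' @param fill rotation border fill color; NULL for the mean image color.
#' @return A new [annotated_image()] of size `crop_size`.
#' @export
augment <- function(annotated, config = augmentation_config(), seed = NULL,
                    fill = NULL) {
  run <- function() {
    angle <- stats::runif(1, config$angle_range[1], config$angle_range[2])
    img <- annotated$image
    h <- dim(img)[1]; w <- dim(img)[2]
    cs <- config$crop_size
    if (h >= cs && w >= cs) {
      # fused path: sample only the crop's pixels from the rotated frame —
      # numerically identical to rotate-then-crop
      if (is.null(fill)) {
        fill <- c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
      }
      rboxes <- rotate_boxes(annotated$annotations, angle %% 360,
                             w / 2, h / 2, w, h)
      ox <- if (w > cs) sample.int(w - cs + 1L, 1L) - 1L else 0L
      oy <- if (h > cs) sample.int(h - cs + 1L, 1L) - 1L else 0L
      out <- if (angle %% 360 == 0) {
        img[oy + seq_len(cs), ox + seq_len(cs), , drop = FALSE]
      } else {
        cpp_rotate_crop(img, angle, fill, ox, oy, cs)
      }
      boxes <- crop_box_bookkeeping(rboxes, ox, oy, cs,
                                    config$min_box_visibility)
      return(annotated_image(annotated$image_id, boxes, image = out,
                             taxon = annotated$taxon))
    }
    rot <- rotate_image_and_boxes(annotated$image, annotated$annotations,
                                  angle, fill = fill)
    cr <- random_crop(rot$image, rot$boxes, config)
    annotated_image(annotated$image_id, cr$boxes, image = cr$image,
                    taxon = annotated$taxon)
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) run() else with_seed(seed, run())
}
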