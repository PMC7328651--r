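#' Bounding boxes
#'
#' Boxes are axis-aligned rectangles in pixel coordinates, 0-based and
#' half-open: a box covers `[x_min, x_max) x [y_min, y_max)` with the origin
#' at the top-left of the image. Coordinates are kept as doubles until
#' rasterization so that rotation and cropping stay lossless.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of equal length.
#' @return A data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(b)
  b
}

#' Validate box invariants
#'
#' Checks `x_min < x_max`, `y_min < y_max`, all coordinates finite and
#' non-negative.
#'
#' @param boxes a data.frame with box columns.
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes) {
  stopifnot(is.data.frame(boxes))
  need <- c("x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(boxes))
  if (length(missing_cols) > 0L) {
    stop("boxes missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(boxes) == 0L) return(invisible(boxes))
  m <- as.matrix(boxes[need])
  if (!all(is.finite(m))) stop("box coordinates must be finite")
  if (any(m < 0)) stop("box coordinates must be >= 0")
  if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
    stop("degenerate box: need x_min < x_max and y_min < y_max")
  }
  invisible(boxes)
}

box_area <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' Clip boxes to an image frame
#'
#' @param boxes box data.frame.
#' @param width,height frame dimensions in pixels.
#' @param drop_empty drop boxes that vanish entirely outside the frame.
#' @return Clipped box data.frame (other columns preserved).
#' @export
clip_boxes <- function(boxes, width, height, drop_empty = TRUE) {
  if (nrow(boxes) == 0L) return(boxes)
  b <- boxes
  b$x_min <- pmax(b$x_min, 0)
  b$y_min <- pmax(b$y_min, 0)
  b$x_max <- pmin(b$x_max, width)
  b$y_max <- pmin(b$y_max, height)
  if (drop_empty) b <- b[b$x_min < b$x_max & b$y_min < b$y_max, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Intersection-over-union of two boxes
#'
#' Vectorized elementwise over rows when `a` and `b` have matching lengths.
#'
#' @param a,b box data.frames (or single-row boxes).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' iou(bounding_box(0, 0, 2, 2), bounding_box(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  union <- box_area(a) + box_area(b) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Pairwise IoU matrix
#'
#' @param a,b box data.frames with `na` and `nb` rows.
#' @return `na x nb` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  cols <- c("x_min", "y_min", "x_max", "y_max")
  cpp_iou_matrix(as.matrix(a[cols]), as.matrix(b[cols]))
}

# Run expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (the display convention used for scores and
# percentages; base round() rounds half to even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
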