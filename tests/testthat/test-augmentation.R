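test_that("zero rotation is the identity", {
  p <- tiny_params()
  img <- generate_specimen("hyemale", p, 81)
  r <- rotate_image_and_boxes(img$image, img$annotations, 0)
  expect_identical(r$image, img$image)
  expect_identical(r$boxes, img$annotations)
})

test_that("90-degree rotation maps boxes by corner arithmetic", {
  im <- array(runif(100 * 100 * 3), dim = c(100, 100, 3))
  b <- bounding_box(10, 20, 40, 60)
  r <- rotate_boxes(b, 90, 50, 50, 100, 100)
  expect_equal(unlist(r[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 20, y_min = 60, x_max = 60, y_max = 90))
})

test_that("rotated boxes track the rotated pixel mask", {
  # oracle: rasterize the box as a mask, rotate the mask as an image, and
  # take the bounding rectangle of the surviving mask pixels
  for (angle in c(90, 180, 270, 37, 122.5)) {
    mask <- array(0, dim = c(120, 120, 3))
    mask[31:60, 21:50, ] <- 1   # box (20, 30, 50, 60)
    b <- bounding_box(20, 30, 50, 60)
    rot <- rotate_image_and_boxes(mask, b, angle, fill = c(0, 0, 0))
    on <- which(rot$image[, , 1] > 0.5, arr.ind = TRUE)
    mask_box <- c(min(on[, 2]) - 1, min(on[, 1]) - 1,
                  max(on[, 2]), max(on[, 1]))
    got <- as.numeric(rot$boxes[1, c("x_min", "y_min", "x_max", "y_max")])
    expect_true(all(abs(got - mask_box) <= 1.5),
                info = paste("angle", angle))
  }
})

test_that("rotating by a then -a never shrinks the axis-aligned hull", {
  set.seed(82)
  boxes <- random_boxes(10, max_coord = 80, max_side = 30)
  area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)
  for (angle in c(33, 61, 140)) {
    there <- rotate_boxes(boxes, angle, 60, 60)
    back <- rotate_boxes(there, -angle, 60, 60)
    expect_true(all(area(back) >= area(boxes) - 1e-9))
  }
  # at multiples of 90 degrees the hull is exact
  there <- rotate_boxes(boxes, 90, 60, 60)
  back <- rotate_boxes(there, -90, 60, 60)
  expect_equal(area(back), area(boxes))
})

test_that("a crop covering the whole image leaves boxes unchanged", {
  p <- tiny_params()
  img <- generate_specimen("laevigatum", p, 83)
  cfg <- augmentation_config(crop_size = p$image_size)
  cr <- withr::with_seed(84, random_crop(img$image, img$annotations, cfg))
  expect_identical(cr$image, img$image)
  expect_equal(cr$boxes, img$annotations)
})

test_that("crop keeps or drops boxes by visible-area fraction", {
  # 100 x 50 image, 50 px crop: the x origin is pinned at 0, only the y
  # origin is random. Box rows 40..60: visibility is 0.5 exactly when the
  # crop starts at row 0.
  im <- array(0.5, dim = c(100, 50, 3))
  b <- data.frame(x_min = 10, y_min = 40, x_max = 30, y_max = 60)
  crop_at_origin0 <- function(min_vis) {
    cfg <- augmentation_config(crop_size = 50, min_box_visibility = min_vis)
    for (s in 1:1000) {
      cr <- withr::with_seed(s, random_crop(im, b, cfg))
      if (cr$origin[["y"]] == 0) return(cr)
    }
    stop("no seed produced the origin-0 crop")
  }
  kept <- crop_at_origin0(0.5)
  expect_equal(nrow(kept$boxes), 1L)
  expect_equal(kept$boxes$y_max, 50)   # clipped to the crop
  dropped <- crop_at_origin0(0.6)
  expect_equal(nrow(dropped$boxes), 0L)
  # fully outside the crop window: always dropped
  far <- data.frame(x_min = 10, y_min = 70, x_max = 30, y_max = 90)
  cfg <- augmentation_config(crop_size = 50, min_box_visibility = 0.1)
  cr <- withr::with_seed(1, random_crop(im, far, cfg))
  expect_equal(nrow(cr$boxes), 0L)
})

test_that("crop visibility agrees with a pixel-mask counting oracle", {
  set.seed(85)
  im <- array(0.5, dim = c(80, 80, 3))
  for (rep in 1:20) {
    b <- random_boxes(1, max_coord = 45, max_side = 25)
    b[] <- round(b[])   # integer box so the pixel mask is exact
    b$x_max <- b$x_min + max(1, b$x_max - b$x_min)
    b$y_max <- b$y_min + max(1, b$y_max - b$y_min)
    cfg <- augmentation_config(crop_size = 40, min_box_visibility = 0.5)
    seed <- sample.int(1e6, 1)
    cr <- withr::with_seed(seed, random_crop(im, b, cfg))
    # oracle: count box pixels inside the crop window
    mask <- matrix(FALSE, 80, 80)
    mask[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- TRUE
    ox <- cr$origin["x"]; oy <- cr$origin["y"]
    visible <- sum(mask[oy + seq_len(40), ox + seq_len(40)])
    frac <- visible / sum(mask)
    expect_equal(nrow(cr$boxes) == 1L, frac >= 0.5,
                 info = paste("visible fraction", round(frac, 3)))
  }
})

test_that("small images are reflection-padded up to the crop size", {
  im <- array(runif(30 * 40 * 3), dim = c(30, 40, 3))
  cfg <- augmentation_config(crop_size = 64)
  cr <- withr::with_seed(86, random_crop(im, data.frame(x_min = 1, y_min = 1,
                                                        x_max = 5, y_max = 5),
                                         cfg))
  expect_equal(dim(cr$image), c(64, 64, 3))
  expect_identical(cr$image[1:30, 1:40, ], im[, , ])
})

test_that("augment composes rotation and crop deterministically", {
  p <- tiny_params()
  img <- generate_specimen("ferrissii", p, 87)
  cfg <- tiny_aug()
  a1 <- augment(img, cfg, seed = 88)
  a2 <- augment(img, cfg, seed = 88)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$annotations, a2$annotations)
  expect_equal(dim(a1$image), c(200, 200, 3))
  # every output box satisfies the invariants inside the crop frame
  origins <- replicate(40, {
    a <- augment(img, cfg)
    validate_boxes(a$annotations)
    expect_true(all(a$annotations$x_max <= 200 & a$annotations$y_max <= 200))
    paste(round(a$annotations$x_min[1], 2), round(a$annotations$y_min[1], 2))
  })
  expect_gt(length(unique(origins)), 1L)
})

test_that("augmented ground truth still covers its node pixels", {
  # node pixels are dark against the paper; inside each surviving box at
  # least some sheath signal must remain visible
  p <- tiny_params()
  img <- generate_specimen("hyemale", p, 89)
  cfg <- tiny_aug(min_box_visibility = 0.6)
  withr::local_seed(90)
  for (rep in 1:10) {
    a <- augment(img, cfg)
    ann <- a$annotations
    for (i in seq_len(nrow(ann))) {
      patch <- a$image[floor(ann$y_min[i] + 1):ceiling(ann$y_max[i]),
                       floor(ann$x_min[i] + 1):ceiling(ann$x_max[i]), ,
                       drop = FALSE]
      expect_lt(min(patch), 0.45)
    }
  }
})
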