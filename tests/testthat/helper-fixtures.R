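# Small-scale fixtures shared across test files. All synthetic data are
# generated in code at test time.

tiny_params <- function(...) {
  synthetic_params(image_size = 240, stems_per_image = c(1L, 2L),
                   nodes_per_stem = c(4L, 6L), node_size = 30, ...)
}

tiny_aug <- function(...) augmentation_config(crop_size = 200, ...)

# A deterministic set of pure-taxon specimens for detector tests.
tiny_parent_set <- function(n_each = 4L, params = tiny_params(),
                            seed0 = 100L) {
  c(lapply(seq_len(n_each), function(i) {
      generate_specimen("hyemale", params, seed0 + i, sprintf("h%02d", i))
    }),
    lapply(seq_len(n_each), function(i) {
      generate_specimen("laevigatum", params, seed0 + 50L + i,
                        sprintf("l%02d", i))
    }))
}

random_boxes <- function(n, max_coord = 100, max_side = 40) {
  x1 <- runif(n, 0, max_coord - 1)
  y1 <- runif(n, 0, max_coord - 1)
  data.frame(x_min = x1, y_min = y1,
             x_max = x1 + runif(n, 0.5, max_side),
             y_max = y1 + runif(n, 0.5, max_side))
}

random_detections <- function(n, types = c("H", "L"), ...) {
  b <- random_boxes(n, ...)
  b$node_type <- sample(types, n, replace = TRUE)
  b$score <- round(runif(n), 3)
  b
}

# Scalar IoU computed independently of the package's vectorized version;
# used by several brute-force oracles.
iou_oracle <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  areaa <- (a[3] - a[1]) * (a[4] - a[2])
  areab <- (b[3] - b[1]) * (b[4] - b[2])
  if (areaa + areab - inter <= 0) return(0)
  inter / (areaa + areab - inter)
}

# Minimal VIA v2 project JSON written from raw strings (independent of
# write_via) so read_via is exercised against an external dialect.
write_raw_via <- function(path, filename = "img1.png") {
  txt <- sprintf('{
  "_via_settings": {"ui": {}},
  "_via_img_metadata": {
    "%s12345": {
      "filename": "%s",
      "size": 12345,
      "regions": [
        {"shape_attributes": {"name": "rect", "x": 10, "y": 20,
                              "width": 30, "height": 40},
         "region_attributes": {"category": "normal stem node"}},
        {"shape_attributes": {"name": "rect", "x": 50, "y": 60,
                              "width": 20, "height": 25},
         "region_attributes": {"category": "strobilus"}},
        {"shape_attributes": {"name": "rect", "x": 5, "y": 5,
                              "width": 12, "height": 80},
         "region_attributes": {"category": "normal_stem_internode"}}
      ],
      "file_attributes": {}
    }
  },
  "_via_attributes": {}
}', filename, filename)
  writeLines(txt, path)
  path
}
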