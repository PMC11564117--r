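# Jaccard overlap between one predicted label and one truth label.
jaccard <- function(pred, truth) sum(pred & truth) / sum(pred | truth)

test_that("blank and constant images yield empty label maps without error", {
  blank <- generate_scene(scene_config(n_beads = 0, image_shape = c(64, 64)))
  lab <- segment_beads(blank$image)
  expect_equal(max(lab$labels), 0)
  expect_equal(nrow(fit_circular_rois(lab)), 0)
  expect_error(segment_beads(array(0, c(4, 4, 2))), "2D")
  expect_error(segment_beads(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("a single noiseless bead is recovered with high overlap", {
  sc <- single_bead_scene(radius = 20, interior_level = 5, center = c(64, 64))
  lab <- segment_beads(sc$image)
  expect_equal(max(lab$labels), 1)
  expect_gte(jaccard(lab$labels == 1, sc$truth_labels == 1), 0.9)
  rois <- fit_circular_rois(lab)
  expect_equal(rois$center_row, 64, tolerance = 0.5)
  expect_equal(rois$center_col, 64, tolerance = 0.5)
  expect_lt(abs(rois$radius - 20), 1)
})

test_that("touching beads are split by the watershed", {
  cfg <- scene_config(image_shape = c(128, 128), n_beads = 0,
                      background_level = 10)
  # centers 1.5 radii apart: overlapping disks
  beads <- list(bead_spec(c(64, 49), 20, 100, 2, 5),
                bead_spec(c(64, 79), 20, 100, 2, 5))
  sc <- generate_scene(cfg, beads)
  lab <- segment_beads(sc$image)
  expect_equal(max(lab$labels), 2)
  # each predicted label majority-overlaps exactly one truth disk
  for (k in 1:2) {
    ov <- vapply(1:2, function(j)
      sum(lab$labels == k & sc$truth_labels == j) / sum(lab$labels == k),
      numeric(1))
    expect_gt(max(ov), 0.5)
  }
})

test_that("detection is perfect on noiseless fields and robust at SNR 10", {
  sc <- generate_scene(scene_config(image_shape = c(512, 512), n_beads = 12,
                                    interior_level = 5, seed = 31))
  lab <- segment_beads(sc$image)
  rois <- fit_circular_rois(lab)
  tt <- beads_table(sc)
  match_truth <- function(rois, tt, tol = 5) {
    vapply(seq_len(nrow(rois)), function(k) {
      d <- sqrt((tt$center_row - rois$center_row[k])^2 +
                  (tt$center_col - rois$center_col[k])^2)
      which.min(d)[d[which.min(d)] < tol]
    }, integer(1))
  }
  hits <- match_truth(rois, tt)
  expect_equal(sort(unique(hits)), seq_len(nrow(tt)))  # recall 1
  expect_equal(length(hits), nrow(tt))                 # precision 1
  expect_lt(max(abs(rois$radius - tt$radius[hits])), 1)

  noisy <- generate_scene(scene_config(image_shape = c(512, 512), n_beads = 12,
                                       interior_level = 5,
                                       gaussian_noise_sd = 10, seed = 31))
  rois_n <- fit_circular_rois(segment_beads(noisy$image))
  hits_n <- match_truth(rois_n, tt)
  expect_gte(length(unique(hits_n)) / nrow(tt), 0.95)
})

test_that("segmentation is idempotent in effect", {
  sc <- generate_scene(scene_config(n_beads = 6, gaussian_noise_sd = 8,
                                    seed = 13))
  a <- segment_beads(sc$image)
  b <- segment_beads(sc$image)
  expect_identical(a$labels, b$labels)
})

test_that("circular ROI fit reproduces area-equivalent radius and centroid", {
  # build a label of exactly 1257 pixels: the 1257 grid points closest to a
  # center; sqrt(1257/pi) = 20.0005
  labels <- matrix(0L, 96, 96)
  px <- expand.grid(i = 1:96, j = 1:96)
  d <- sqrt((px$i - 48)^2 + (px$j - 48)^2)
  sel <- order(d)[1:1257]
  labels[cbind(px$i[sel], px$j[sel])] <- 1L
  lm <- structure(list(labels = labels, source_channel = "x"),
                  class = "label_map")
  roi <- fit_circular_rois(lm)
  expect_equal(roi$radius, sqrt(1257 / pi), tolerance = 1e-10)
  expect_equal(roi$radius, 20.00, tolerance = 0.01)
  expect_equal(roi$center_row, 48, tolerance = 0.5)
  expect_equal(roi$area_px, 1257)
  expect_false(roi$touches_edge)

  # tiny labels are dropped by the minimum-area filter
  labels2 <- matrix(0L, 96, 96); labels2[5, 5] <- 1L
  lm2 <- structure(list(labels = labels2, source_channel = "x"),
                   class = "label_map")
  expect_equal(nrow(fit_circular_rois(lm2, min_area_px = 50)), 0)
})

test_that("touches_edge flags circles crossing the image bounds", {
  # a square blob in the corner: centroid (10.5, 10.5), equal-area radius
  # 11.28 px, so the fitted circle crosses both near edges
  labels <- matrix(0L, 96, 96)
  labels[1:20, 1:20] <- 1L
  lm <- structure(list(labels = labels, source_channel = "x"),
                  class = "label_map")
  roi <- fit_circular_rois(lm)
  expect_true(roi$touches_edge)
  # the same blob in the middle does not
  labels_mid <- matrix(0L, 96, 96)
  labels_mid[39:58, 39:58] <- 1L
  lm_mid <- structure(list(labels = labels_mid, source_channel = "x"),
                      class = "label_map")
  expect_false(fit_circular_rois(lm_mid)$touches_edge)
})

test_that("exclusion mask is the union of dilated fitted circles", {
  one <- data.frame(label = 1L, center_row = 40, center_col = 40, radius = 10,
                    area_px = 314L, touches_edge = FALSE)
  m1 <- build_exclusion_mask(one, c(96, 96), margin = 2)
  px <- expand.grid(i = 1:96, j = 1:96)
  expect_equal(sum(m1), sum((px$i - 40)^2 + (px$j - 40)^2 <= 12^2))

  none <- one[0, ]
  expect_false(any(build_exclusion_mask(none, c(96, 96))))

  two <- rbind(one, data.frame(label = 2L, center_row = 40, center_col = 80,
                               radius = 8, area_px = 201L, touches_edge = FALSE))
  m2 <- build_exclusion_mask(two, c(96, 96), margin = 2)
  expect_equal(sum(m2), sum(m1) +
                 sum((px$i - 40)^2 + (px$j - 80)^2 <= 10^2))
})

test_that("a custom backend plugs in behind the segmentation seam", {
  sc <- single_bead_scene(interior_level = 5)
  oracle_backend <- function(image, params) sc$truth_labels
  lab <- segment_beads(sc$image, backend = oracle_backend,
                       source_channel = "GFP")
  expect_equal(max(lab$labels), 1)
  expect_identical(lab$source_channel, "GFP")
  expect_equal(sum(lab$labels == 1), sum(sc$truth_labels == 1))
})

test_that("max projection combines channels pixelwise", {
  a <- matrix(1:4, 2, 2); b <- matrix(c(4, 1, 1, 9), 2, 2)
  expect_equal(max_project(list(a, b)), matrix(c(4, 2, 3, 9), 2, 2))
})
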