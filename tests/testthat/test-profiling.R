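roi_for <- function(scene, label = 1L) {
  b <- scene$beads[[label]]
  list(label = label, center_row = b$center[1], center_col = b$center[2],
       radius = b$radius)
}

test_that("a flat image gives zero amplitude on every line", {
  img <- matrix(37, 128, 128)
  roi <- list(label = 1L, center_row = 64, center_col = 64, radius = 20)
  profs <- sample_radial_profiles(img, roi, NULL)
  expect_length(profs, 20)
  expect_true(all(vapply(profs, `[[`, numeric(1), "amplitude") == 0))
  expect_true(all(vapply(profs, `[[`, logical(1), "valid")))
})

test_that("line geometry follows the profile config", {
  img <- matrix(0, 128, 128)
  roi <- list(label = 1L, center_row = 64, center_col = 64, radius = 20)
  cfg <- profile_config(n_lines = 8, length_factor = 1.5, step_px = 0.5,
                        start_angle_rad = 0.3)
  profs <- sample_radial_profiles(img, roi, NULL, cfg)
  angles <- vapply(profs, `[[`, numeric(1), "angle_rad")
  expect_equal(angles, 0.3 + (0:7) * 2 * pi / 8)
  d <- profs[[1]]$distances
  expect_equal(d, seq(0, 30, by = 0.5))
  expect_equal(profs[[1]]$amplitude,
               max(profs[[1]]$intensities) - min(profs[[1]]$intensities))
  expect_error(
    sample_radial_profiles(img, list(label = 1, center_row = 64,
                                     center_col = 64, radius = 0.8), NULL),
    "degenerate ROI")
})

test_that("uniform ring amplitudes recover the rim height within 2%", {
  sc <- single_bead_scene(radius = 20, rim_amplitude = 100, interior_level = 0)
  profs <- sample_radial_profiles(sc$image, roi_for(sc), NULL)
  amps <- vapply(profs, `[[`, numeric(1), "amplitude")
  expect_true(all(abs(amps - 100) / 100 < 0.02))
})

test_that("amplitudes are invariant to offset and scale with gain", {
  sc <- single_bead_scene(radius = 18, rim_amplitude = 80)
  roi <- roi_for(sc)
  base <- vapply(sample_radial_profiles(sc$image, roi, NULL), `[[`,
                 numeric(1), "amplitude")
  shifted <- vapply(sample_radial_profiles(sc$image + 50, roi, NULL), `[[`,
                    numeric(1), "amplitude")
  gained <- vapply(sample_radial_profiles(sc$image * 3, roi, NULL), `[[`,
                   numeric(1), "amplitude")
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(gained, 3 * base, tolerance = 1e-12)
})

test_that("implementation agrees with a 10x-finer brute-force oracle", {
  sc <- single_bead_scene(radius = 16, rim_amplitude = 120, rim_sigma = 2,
                          interior_level = 5, background = 20)
  roi <- roi_for(sc)
  profs <- sample_radial_profiles(sc$image, roi, NULL)
  for (p in profs[c(1, 6, 11, 16)]) {
    oracle <- oracle_line_amplitude(sc$image, c(roi$center_row, roi$center_col),
                                    roi$radius, p$angle_rad, step = 0.05)
    expect_equal(p$amplitude, oracle, tolerance = 0.02)
  }
})

test_that("rotating the scene by 90 degrees preserves the amplitude multiset", {
  sc <- single_bead_scene(radius = 20, rim_amplitude = 100, rim_sigma = 2,
                          interior_level = 5, defect_fraction = 0.3,
                          defect_start = 0.7)
  roi <- roi_for(sc)
  amps <- sort(vapply(sample_radial_profiles(sc$image, roi, NULL), `[[`,
                      numeric(1), "amplitude"))
  rot <- t(sc$image)[, nrow(sc$image):1]  # 90-degree rotation
  ctr_rot <- list(label = 1L, center_row = roi$center_col,
                  center_col = nrow(sc$image) + 1 - roi$center_row,
                  radius = roi$radius)
  amps_rot <- sort(vapply(sample_radial_profiles(rot, ctr_rot, NULL), `[[`,
                          numeric(1), "amplitude"))
  expect_equal(amps_rot, amps, tolerance = 0.01)
})

test_that("lines truncate at neighbouring beads and at the image edge", {
  cfg <- scene_config(image_shape = c(128, 128), n_beads = 0,
                      background_level = 10)
  beads <- list(bead_spec(c(64, 55), 15, 100, 2, 0),
                bead_spec(c(64, 85), 15, 100, 2, 0))
  sc <- generate_scene(cfg, beads)
  rois <- data.frame(label = 1:2, center_row = 64, center_col = c(55, 85),
                     radius = 15, area_px = 707L, touches_edge = FALSE)
  mask <- build_exclusion_mask(rois, dim(sc$image), margin = 2)
  profs <- sample_radial_profiles(sc$image, rois[1, ], mask)
  towards <- which.min(abs(vapply(profs, `[[`, numeric(1), "angle_rad") - pi / 2))
  expect_true(profs[[towards]]$truncated)
  # the line leaves its own dilated circle (radius + margin = 17 px) and is
  # blocked at the first sample whose pixel lies beyond it (rasterization
  # keeps the d = 17.5 sample: it rounds onto the 17-px boundary pixel)
  last_d <- max(profs[[towards]]$distances)
  expect_lte(last_d, 17.5)
  # a bead never truncates itself: away-facing lines keep full length
  away <- which.min(abs(vapply(profs, `[[`, numeric(1), "angle_rad") - 3 * pi / 2))
  expect_false(profs[[away]]$truncated)

  # edge truncation: bead close to the border
  edge_sc <- single_bead_scene(radius = 20, center = c(64, 25))
  profs_e <- sample_radial_profiles(edge_sc$image, roi_for(edge_sc), NULL)
  expect_true(any(vapply(profs_e, `[[`, logical(1), "truncated")))
})

test_that("bead summaries follow the mean/sd conventions", {
  mk <- function(amps, valid = TRUE) lapply(amps, function(a)
    structure(list(bead_label = 1L, angle_rad = 0, distances = 0:4,
                   intensities = rep(0, 5), amplitude = a, truncated = FALSE,
                   valid = valid), class = "line_profile"))
  m <- summarize_bead(mk(rep(10, 20)))
  expect_equal(m$mean_amplitude, 10)
  expect_equal(m$sd_amplitude, 0)
  expect_equal(m$n_valid_lines, 20L)

  one <- summarize_bead(mk(7))
  expect_equal(one$mean_amplitude, 7)
  expect_equal(one$sd_amplitude, 0)  # n = 1 convention
  expect_true(one$low_n)

  half <- summarize_bead(mk(c(rep(0, 10), rep(20, 10))))
  expect_equal(half$mean_amplitude, 10)
  expect_equal(half$sd_amplitude, sqrt(20 * 100 / 19), tolerance = 1e-12)
  expect_equal(half$sd_amplitude, 10.2598, tolerance = 1e-4)

  none <- summarize_bead(mk(c(1, 2), valid = FALSE))
  expect_false(none$qc_pass)
  expect_identical(none$qc_reason, "no_valid_lines")
  expect_equal(none$n_valid_lines, 0L)
})

test_that("parameter recovery is monotone and accurate on noiseless beads", {
  amps <- c(20, 50, 100, 200)
  est <- vapply(amps, function(A) {
    sc <- single_bead_scene(radius = 20, rim_amplitude = A, interior_level = 0)
    summarize_bead(sample_radial_profiles(sc$image, roi_for(sc), NULL))$mean_amplitude
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_true(all(abs(est - amps) / amps < 0.05))
})
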