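# Shared fixtures. All scenes are generated in code; nothing is stored.

# Single centered bead on a quiet field; interior at background unless stated.
single_bead_scene <- function(radius = 20, rim_amplitude = 100, rim_sigma = 2,
                              interior_level = 0, background = 10,
                              gaussian_noise_sd = 0, poisson_scale = 0,
                              shape = c(128, 128), center = shape / 2,
                              defect_fraction = 0, defect_start = 0,
                              seed = 1L) {
  cfg <- scene_config(image_shape = shape, n_beads = 0,
                      background_level = background,
                      gaussian_noise_sd = gaussian_noise_sd,
                      poisson_scale = poisson_scale, seed = seed)
  b <- bead_spec(center, radius, rim_amplitude, rim_sigma, interior_level,
                 defect_fraction, defect_start)
  generate_scene(cfg, list(b))
}

# Independent analytic scene model: background + interior disk + Gaussian
# ring, evaluated at continuous (row, col). Written separately from the
# renderer on purpose; tests compare the two.
analytic_bead_value <- function(row, col, center, radius, rim_amplitude,
                                rim_sigma, interior_level, background) {
  d <- sqrt((row - center[1])^2 + (col - center[2])^2)
  ring <- rim_amplitude * exp(-(d - radius)^2 / (2 * rim_sigma^2))
  background + ifelse(d <= radius, interior_level, 0) + ring
}

# Independent bilinear lookup used by the brute-force profile oracle.
oracle_bilinear <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  mapply(function(ri, ci) {
    if (ri < 1 || ri > nr || ci < 1 || ci > nc) return(NA_real_)
    i0 <- min(floor(ri), nr - 1); j0 <- min(floor(ci), nc - 1)
    fi <- ri - i0; fj <- ci - j0
    image[i0, j0] * (1 - fi) * (1 - fj) + image[i0 + 1, j0] * fi * (1 - fj) +
      image[i0, j0 + 1] * (1 - fi) * fj + image[i0 + 1, j0 + 1] * fi * fj
  }, r, c)
}

# Brute-force line amplitude: resample the image along one radial line at a
# finer step and take max - min. Independent of sample_radial_profiles().
oracle_line_amplitude <- function(image, center, radius, angle,
                                  length_factor = 1.5, step = 0.05) {
  d <- seq(0, length_factor * radius, by = step)
  v <- oracle_bilinear(image, center[1] + d * cos(angle),
                       center[2] + d * sin(angle))
  v <- v[!is.na(v)]
  max(v) - min(v)
}

# Minimal two-condition manifest on disk built from synthetic scenes.
write_two_condition_experiment <- function(dir, amp_control = 100,
                                           amp_treat = 50, n_beads = 8,
                                           seed = 11L) {
  spec <- list(
    image_shape = c(256L, 256L), n_beads = n_beads, interior_level = 0,
    conditions = list(
      list(name = "control", rim_amplitude = amp_control, control = TRUE),
      list(name = "treatment", rim_amplitude = amp_treat)))
  simulate_experiment(spec, dir, seed = seed)
}
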