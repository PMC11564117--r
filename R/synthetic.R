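#' Specify a single synthetic bead
#'
#' A bead is rendered as a filled interior disk plus a bright ring whose
#' radial cross-section is Gaussian: at distance \eqn{d} from the center the
#' ring contributes \eqn{A \exp\{-(d-r)^2 / (2\sigma^2)\}}, peaking on the
#' circle of radius \eqn{r}. This emulates the rim of recruited fluorescent
#' prey seen on a confocal equatorial section of a coated bead. A contiguous
#' arc of the ring can be zeroed (`defect_fraction`) to model unevenly coated
#' beads.
#'
#' @param center numeric length-2, continuous (row, col) position in pixels.
#'   Pixel (i, j) has its center at coordinate (i, j), 1-based.
#' @param radius bead radius in pixels, at least 3.
#' @param rim_amplitude ring peak height in gray-value units above the local
#'   (background + interior) level; non-negative.
#' @param rim_sigma Gaussian cross-section width of the ring, pixels.
#' @param interior_level bead body fill above background, gray-value units.
#' @param defect_fraction fraction of the ring arc zeroed, in `[0, 1)`.
#' @param defect_start start angle of the defect arc, radians; `NA` means the
#'   generator draws it at random.
#' @return an object of class `bead_spec`.
#' @export
bead_spec <- function(center, radius, rim_amplitude,
                      rim_sigma = 2, interior_level = 5,
                      defect_fraction = 0, defect_start = NA_real_) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius) || radius < 3)
    stopf("bead radius must be >= 3 px (got %s)", format(radius))
  if (rim_sigma <= 0) stopf("rim_sigma must be > 0")
  if (rim_amplitude < 0) stopf("rim_amplitude must be >= 0")
  if (defect_fraction < 0 || defect_fraction >= 1)
    stopf("defect_fraction must be in [0, 1)")
  structure(list(center = as.numeric(center), radius = radius,
                 rim_amplitude = rim_amplitude, rim_sigma = rim_sigma,
                 interior_level = interior_level,
                 defect_fraction = defect_fraction,
                 defect_start = defect_start),
            class = "bead_spec")
}

#' Configure a synthetic bead scene
#'
#' Holds everything [generate_scene()] needs: image geometry, how many beads
#' to place and with what radii, the photometric parameters shared by the
#' sampled beads, and the noise model. Noise is applied detector-style:
#' Poisson shot noise first (on the noiseless signal, `poisson_scale` photons
#' per gray-value unit; 0 disables it), then additive Gaussian read noise.
#'
#' Defaults describe a realistic field at 20x magnification: a 256x256 tile,
#' beads of radius 20 +/- 3 px, background 100 gray values, rim amplitude 100.
#'
#' @param image_shape integer length-2 (height, width), each at least 64.
#' @param n_beads number of beads to place.
#' @param background_level flat background, gray-value units.
#' @param gaussian_noise_sd additive read-noise SD, gray-value units.
#' @param poisson_scale photons per gray-value unit; 0 disables shot noise.
#' @param min_separation minimum center-to-center distance, pixels; defaults
#'   to 2.2x the mean radius (mostly separated beads, occasional touching
#'   pairs when radii exceed the mean). Set below two radii to force touching.
#' @param radius_mean,radius_sd bead radius distribution, pixels (normal,
#'   truncated at 3 px).
#' @param rim_amplitude,rim_sigma,interior_level,defect_fraction photometric
#'   parameters applied to every sampled bead (see [bead_spec()]).
#' @param seed integer; scenes are bit-reproducible given the same config.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(256L, 256L), n_beads = 12,
                         background_level = 100, gaussian_noise_sd = 0,
                         poisson_scale = 0, min_separation = NULL,
                         radius_mean = 20, radius_sd = 3,
                         rim_amplitude = 100, rim_sigma = 2,
                         interior_level = 5, defect_fraction = 0,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2)
  if (any(image_shape < 64)) stopf("image_shape must be at least 64 x 64")
  if (!is_count(n_beads)) stopf("n_beads must be a non-negative integer")
  if (gaussian_noise_sd < 0 || poisson_scale < 0)
    stopf("noise parameters must be >= 0")
  if (is.null(min_separation)) min_separation <- 2.2 * radius_mean
  structure(list(image_shape = as.integer(image_shape),
                 n_beads = as.integer(n_beads),
                 background_level = background_level,
                 gaussian_noise_sd = gaussian_noise_sd,
                 poisson_scale = poisson_scale,
                 min_separation = min_separation,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 rim_amplitude = rim_amplitude, rim_sigma = rim_sigma,
                 interior_level = interior_level,
                 defect_fraction = defect_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Add one bead's interior disk and (possibly defective) ring to `image`,
# restricted to a bounding box. Returns the updated image.
render_bead <- function(image, bead) {
  nr <- nrow(image); nc <- ncol(image)
  pad <- ceiling(bead$radius + 4 * bead$rim_sigma + 1)
  i0 <- max(1L, floor(bead$center[1] - pad)); i1 <- min(nr, ceiling(bead$center[1] + pad))
  j0 <- max(1L, floor(bead$center[2] - pad)); j1 <- min(nc, ceiling(bead$center[2] + pad))
  if (i0 > i1 || j0 > j1) return(image)
  ii <- i0:i1; jj <- j0:j1
  di <- ii - bead$center[1]; dj <- jj - bead$center[2]
  d <- sqrt(outer(di^2, dj^2, `+`))
  ring <- bead$rim_amplitude * exp(-(d - bead$radius)^2 / (2 * bead$rim_sigma^2))
  if (bead$defect_fraction > 0) {
    theta <- outer(di, dj, function(a, b) atan2(b, a)) %% (2 * pi)
    start <- if (is.na(bead$defect_start)) 0 else bead$defect_start %% (2 * pi)
    width <- 2 * pi * bead$defect_fraction
    rel <- (theta - start) %% (2 * pi)
    ring[rel < width] <- 0
  }
  interior <- ifelse(d <= bead$radius, bead$interior_level, 0)
  image[ii, jj] <- image[ii, jj] + interior + ring
  image
}

# Rejection-sample bead centers honouring min_separation; bounded retries.
place_beads <- function(config) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  beads <- vector("list", config$n_beads)
  centers <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(config$n_beads)) {
    radius <- max(3, rnorm(1, config$radius_mean, config$radius_sd))
    margin <- radius + 2
    placed <- FALSE
    for (try in seq_len(200L)) {
      cand <- c(runif(1, 1 + margin, nr - margin),
                runif(1, 1 + margin, nc - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2)) >=
              config$min_separation)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("could not place bead %d with min_separation = %s after 200 tries",
            k, format(config$min_separation))
    centers <- rbind(centers, cand)
    defect_start <- if (config$defect_fraction > 0) runif(1, 0, 2 * pi) else NA_real_
    beads[[k]] <- bead_spec(cand, radius, config$rim_amplitude,
                            config$rim_sigma, config$interior_level,
                            config$defect_fraction, defect_start)
  }
  beads
}

#' Render a synthetic bead scene with ground truth
#'
#' Renders `background + sum over beads (interior disk + Gaussian ring)`,
#' then applies Poisson resampling (if enabled) and additive Gaussian noise.
#' Bead placement, radii, defect-arc angles and noise all derive from
#' `config$seed`; identical configs render bit-identical scenes. A label
#' image marks each bead's true disk for downstream parameter-recovery tests.
#'
#' @param config a [scene_config()].
#' @param bead_overrides optional list of [bead_spec()] used verbatim instead
#'   of sampling bead geometry (noise still follows the config).
#' @return an object of class `synthetic_scene`: `config`, `beads` (list of
#'   `bead_spec`), `image` (numeric matrix), `truth_labels` (integer matrix,
#'   0 background, k marks bead k's disk).
#' @examples
#' sc <- generate_scene(scene_config(n_beads = 3, seed = 7))
#' range(sc$image)
#' @export
generate_scene <- function(config, bead_overrides = NULL) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  with_seed(config$seed, {
    beads <- if (!is.null(bead_overrides)) {
      stopifnot(all(vapply(bead_overrides, inherits, logical(1), "bead_spec")))
      for (b in bead_overrides)
        if (b$center[1] < 1 || b$center[1] > nr || b$center[2] < 1 || b$center[2] > nc)
          stopf("bead override center (%s, %s) outside image",
                format(b$center[1]), format(b$center[2]))
      bead_overrides
    } else place_beads(config)
    img <- matrix(config$background_level, nr, nc)
    for (b in beads) img <- render_bead(img, b)

    labels <- matrix(0L, nr, nc)
    if (length(beads) > 0) {
      # nearest-center assignment where true disks overlap
      best <- matrix(Inf, nr, nc)
      for (k in seq_along(beads)) {
        b <- beads[[k]]
        pad <- ceiling(b$radius) + 1L
        i0 <- max(1L, floor(b$center[1] - pad)); i1 <- min(nr, ceiling(b$center[1] + pad))
        j0 <- max(1L, floor(b$center[2] - pad)); j1 <- min(nc, ceiling(b$center[2] + pad))
        ii <- i0:i1; jj <- j0:j1
        d <- sqrt(outer((ii - b$center[1])^2, (jj - b$center[2])^2, `+`))
        sel <- d <= b$radius & d < best[ii, jj]
        lab <- labels[ii, jj]; bst <- best[ii, jj]
        lab[sel] <- k; bst[sel] <- d[sel]
        labels[ii, jj] <- lab; best[ii, jj] <- bst
      }
    }

    if (config$poisson_scale > 0)
      img[] <- rpois(length(img), pmax(img, 0) * config$poisson_scale) /
        config$poisson_scale
    if (config$gaussian_noise_sd > 0)
      img[] <- img + rnorm(length(img), 0, config$gaussian_noise_sd)

    structure(list(config = config, beads = beads, image = img,
                   truth_labels = labels),
              class = "synthetic_scene")
  })
}

#' Ground-truth bead table of a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @return data frame with one row per bead: id, center, radius and
#'   photometric parameters.
#' @export
beads_table <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  do.call(rbind, lapply(seq_along(scene$beads), function(k) {
    b <- scene$beads[[k]]
    data.frame(bead = k, center_row = b$center[1], center_col = b$center[2],
               radius = b$radius, rim_amplitude = b$rim_amplitude,
               rim_sigma = b$rim_sigma, interior_level = b$interior_level,
               defect_fraction = b$defect_fraction)
  }))
}

#' Simulate a competitor dose series
#'
#' Generates one scene per dose with the shared geometry distribution of
#' `base` and a rim amplitude following a hyperbolic competition curve
#' `max_amplitude / (1 + dose / ic50)`. This mirrors the design of a
#' competitor titration (e.g. 0.1-10 uM) in which increasing competitor
#' displaces the fluorescent prey from the bead surface. The hyperbolic form
#' is a demonstration surrogate, not a fitted binding model.
#'
#' @param base a [scene_config()]; scene k uses `base$seed + k`.
#' @param doses positive concentrations (any consistent unit).
#' @param max_amplitude rim amplitude at dose 0, gray-value units.
#' @param ic50 dose at which amplitude halves, same unit as `doses`.
#' @return list with one element per dose: `list(dose =, scene =)`.
#' @export
generate_dose_series <- function(base, doses, max_amplitude, ic50) {
  stopifnot(inherits(base, "scene_config"))
  if (length(doses) == 0) stopf("dose list must not be empty")
  if (any(doses <= 0)) stopf("doses must be > 0")
  if (ic50 <= 0) stopf("ic50 must be > 0")
  lapply(seq_along(doses), function(k) {
    cfg <- base
    cfg$rim_amplitude <- max_amplitude / (1 + doses[k] / ic50)
    cfg$seed <- base$seed + k
    class(cfg) <- "scene_config"
    list(dose = doses[k], scene = generate_scene(cfg))
  })
}

#' Write a scene to disk (TIFF + ground-truth sidecars)
#'
#' Writes `<name>.tif` (image, 16-bit), `<name>_labels.tif` (truth labels,
#' 16-bit), `<name>_truth.csv` (bead table) and `<name>_config.yaml`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, paste0(name, ".tif")),
             labels = file.path(dir, paste0(name, "_labels.tif")),
             truth = file.path(dir, paste0(name, "_truth.csv")),
             config = file.path(dir, paste0(name, "_config.yaml")))
  write_tiff(scene$image, paths[["image"]])
  write_tiff(scene$truth_labels, paths[["labels"]])
  tab <- beads_table(scene)
  if (is.null(tab)) tab <- data.frame(bead = integer(0))
  write.csv(tab, paths[["truth"]], row.names = FALSE)
  yaml::write_yaml(unclass(scene$config), paths[["config"]])
  invisible(paths)
}
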