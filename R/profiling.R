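#' Radial line-profile parameters
#'
#' @param n_lines number of evenly spaced radial lines per bead (default 20,
#'   the assay's standard setting).
#' @param length_factor line length as a multiple of the fitted radius; lines
#'   start at the bead center and extend beyond the rim into inter-bead
#'   space.
#' @param step_px sampling step along a line, pixels (bilinear
#'   interpolation).
#' @param min_valid_samples a line with fewer retained samples is discarded.
#' @param start_angle_rad angle of line 0.
#' @return an object of class `profile_config`.
#' @export
profile_config <- function(n_lines = 20L, length_factor = 1.5, step_px = 0.5,
                           min_valid_samples = 5L, start_angle_rad = 0) {
  if (n_lines < 3) stopf("n_lines must be >= 3")
  if (length_factor <= 1) stopf("length_factor must be > 1")
  if (step_px <= 0) stopf("step_px must be > 0")
  structure(list(n_lines = as.integer(n_lines), length_factor = length_factor,
                 step_px = step_px,
                 min_valid_samples = as.integer(min_valid_samples),
                 start_angle_rad = start_angle_rad),
            class = "profile_config")
}

#' Sample radial line profiles across one bead
#'
#' Draws `n_lines` lines at angles `start_angle + k * 2 * pi / n_lines` from
#' the bead center, sampling the image by bilinear interpolation at distances
#' `0, step_px, ..., length_factor * radius`. A line is truncated at the
#' first sample that leaves the image or enters the exclusion mask outside
#' the bead's own (margin-dilated) circle — so a line never runs into an
#' adjacent bead, and a bead never truncates itself. Each retained line is
#' scored by its amplitude, `max(intensities) - min(intensities)`: the rim
#' peak against the darkest point along the line.
#'
#' @param image 2D numeric matrix.
#' @param roi one-row `bead_rois` slice (or any list with `label`,
#'   `center_row`, `center_col`, `radius`).
#' @param exclusion_mask logical matrix from [build_exclusion_mask()], or
#'   `NULL` for no truncation.
#' @param config a [profile_config()].
#' @param margin the mask dilation margin used when the mask was built.
#' @return list of `line_profile` objects: `bead_label`, `angle_rad`,
#'   `distances`, `intensities`, `amplitude`, `truncated`, `valid`.
#' @export
sample_radial_profiles <- function(image, roi, exclusion_mask = NULL,
                                   config = profile_config(), margin = 2) {
  stopifnot(inherits(config, "profile_config"))
  if (!is.null(exclusion_mask))
    stopifnot(all(dim(exclusion_mask) == dim(image)))
  radius <- roi$radius
  if (radius < 2 * config$step_px)
    stopf("degenerate ROI: radius %.2f px is below 2 * step_px = %.2f px",
          radius, 2 * config$step_px)
  ctr <- c(roi$center_row, roi$center_col)
  dists <- seq(0, config$length_factor * radius, by = config$step_px)
  own_r2 <- (radius + margin)^2
  nr <- nrow(image); nc <- ncol(image)
  lapply(seq_len(config$n_lines) - 1L, function(k) {
    angle <- config$start_angle_rad + k * 2 * pi / config$n_lines
    rr <- ctr[1] + dists * cos(angle)
    cc <- ctr[2] + dists * sin(angle)
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    blocked <- !inside
    if (!is.null(exclusion_mask)) {
      ri <- pmin(pmax(round(rr), 1), nr)
      ci <- pmin(pmax(round(cc), 1), nc)
      in_mask <- exclusion_mask[cbind(ri, ci)]
      # own-bead test on the same rasterized pixel the mask was looked up at,
      # so a bead's own dilated circle never blocks its lines at the boundary
      own <- (ri - ctr[1])^2 + (ci - ctr[2])^2 <= own_r2
      blocked <- blocked | (in_mask & !own)
    }
    n_keep <- if (any(blocked)) which(blocked)[1] - 1L else length(dists)
    truncated <- n_keep < length(dists)
    d <- dists[seq_len(n_keep)]
    v <- if (n_keep > 0) bilinear_sample(image, rr[seq_len(n_keep)],
                                         cc[seq_len(n_keep)]) else numeric(0)
    valid <- n_keep >= config$min_valid_samples
    structure(list(bead_label = roi$label, angle_rad = angle, distances = d,
                   intensities = v,
                   amplitude = if (n_keep > 0) max(v) - min(v) else NA_real_,
                   truncated = truncated, valid = valid),
              class = "line_profile")
  })
}

#' Summarize a bead from its line profiles
#'
#' Per-bead score: arithmetic mean and sample standard deviation (ddof = 1)
#' of the amplitudes of the valid lines. A bead with a single valid line
#' gets `sd = 0` and a `low_n` flag; a bead with no valid line is marked
#' unmeasurable (`qc_pass = FALSE`, reason `"no_valid_lines"`). QC against
#' the SD rule is applied later by [qc_filter()].
#'
#' @param profiles list of `line_profile` from [sample_radial_profiles()].
#' @return an object of class `bead_measurement`.
#' @export
summarize_bead <- function(profiles) {
  stopifnot(length(profiles) > 0)
  label <- profiles[[1]]$bead_label
  amps <- vapply(profiles[vapply(profiles, `[[`, logical(1), "valid")],
                 `[[`, numeric(1), "amplitude")
  if (length(amps) == 0) {
    return(structure(list(bead_label = label, line_amplitudes = numeric(0),
                          mean_amplitude = NA_real_, sd_amplitude = NA_real_,
                          n_valid_lines = 0L, low_n = TRUE,
                          qc_pass = FALSE, qc_reason = "no_valid_lines"),
                     class = "bead_measurement"))
  }
  structure(list(bead_label = label, line_amplitudes = amps,
                 mean_amplitude = mean(amps),
                 sd_amplitude = if (length(amps) > 1) sd(amps) else 0,
                 n_valid_lines = length(amps), low_n = length(amps) < 3,
                 qc_pass = NA, qc_reason = NA_character_),
            class = "bead_measurement")
}

#' Measure every bead in an image
#'
#' Convenience wrapper: profiles and summarizes each non-edge ROI.
#'
#' @param image 2D numeric matrix (the measurement channel).
#' @param rois `bead_rois` data frame.
#' @param exclusion_mask from [build_exclusion_mask()] (or `NULL`).
#' @param config a [profile_config()].
#' @param margin mask dilation margin, pixels.
#' @param exclude_edge drop beads whose fitted circle touches the image edge.
#' @return list with `measurements` (list of `bead_measurement`) and
#'   `n_edge_excluded`.
#' @export
measure_beads <- function(image, rois, exclusion_mask = NULL,
                          config = profile_config(), margin = 2,
                          exclude_edge = TRUE) {
  use <- if (exclude_edge) !rois$touches_edge else rep(TRUE, nrow(rois))
  meas <- lapply(which(use), function(k) {
    profs <- sample_radial_profiles(image, rois[k, ], exclusion_mask,
                                    config, margin)
    summarize_bead(profs)
  })
  list(measurements = meas, n_edge_excluded = sum(!use))
}

#' Tabulate bead measurements
#'
#' @param measurements list of `bead_measurement`.
#' @return data frame with one row per bead.
#' @export
measurements_table <- function(measurements) {
  if (length(measurements) == 0)
    return(data.frame(bead_label = integer(0), mean_amplitude = numeric(0),
                      sd_amplitude = numeric(0), n_valid_lines = integer(0),
                      qc_pass = logical(0), qc_reason = character(0)))
  do.call(rbind, lapply(measurements, function(m)
    data.frame(bead_label = m$bead_label, mean_amplitude = m$mean_amplitude,
               sd_amplitude = m$sd_amplitude, n_valid_lines = m$n_valid_lines,
               qc_pass = m$qc_pass, qc_reason = m$qc_reason)))
}
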