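#' Segmentation parameters
#'
#' Controls the default classical segmentation backend: global Otsu
#' threshold, hole filling (bead interiors are dimmer than rims), Euclidean
#' distance transform, and peak-seeded watershed to split touching beads.
#'
#' @param min_area_px smallest object kept, pixels; default `ceiling(pi * 5^2)`
#'   rejects noise specks smaller than a 5-px-radius disk.
#' @param peak_min_distance minimum distance between watershed seed peaks,
#'   pixels; about half the smallest expected bead radius.
#' @param threshold fixed gray-value threshold, or `NULL` for Otsu.
#' @param fill_holes fill enclosed background (dim bead interiors).
#' @param refine_circles clip each segmented object to the circle whose
#'   radius is the peak of its radial mean-intensity profile. Any level-set
#'   threshold places the object boundary on the ring's outer Gaussian
#'   skirt, a few pixels beyond the true bead radius; the rim peak itself
#'   marks the bead surface, so snapping to it recovers the bead disk.
#'   Refinement is skipped for objects without a rim-like profile.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(min_area_px = ceiling(pi * 25), peak_min_distance = 10L,
                       threshold = NULL, fill_holes = TRUE,
                       refine_circles = TRUE) {
  stopifnot(min_area_px >= 1, peak_min_distance >= 1)
  structure(list(min_area_px = as.integer(min_area_px),
                 peak_min_distance = as.integer(peak_min_distance),
                 threshold = threshold, fill_holes = isTRUE(fill_holes),
                 refine_circles = isTRUE(refine_circles)),
            class = "seg_params")
}

# Otsu's threshold on a 256-bin histogram; NULL for constant images.
otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(NULL)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(image, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment beads in a grayscale image
#'
#' Default backend: threshold (Otsu unless fixed), fill holes, Euclidean
#' distance transform, seed at distance-transform peaks (greedy non-maximum
#' suppression at `peak_min_distance`), marker watershed to split touching
#' beads, then drop objects under `min_area_px` and compact labels to
#' `1..K`. The whole chain is deterministic for fixed inputs.
#'
#' Alternative segmenters (e.g. a learned model run externally) plug in via
#' `backend`, a `function(image, params)` returning an integer label matrix
#' of the same shape; the rest of the pipeline only consumes the label map.
#'
#' @param image 2D numeric matrix of finite gray values.
#' @param params a [seg_params()].
#' @param backend optional replacement segmentation function.
#' @param source_channel channel name recorded in the result.
#' @return an object of class `label_map`: `labels` (integer matrix, 0 =
#'   background, `1..K` beads), `source_channel`.
#' @export
segment_beads <- function(image, params = seg_params(), backend = NULL,
                          source_channel = "unknown") {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a 2D numeric matrix")
  if (!all(is.finite(image))) stopf("image must contain only finite values")
  stopifnot(inherits(params, "seg_params"))

  if (!is.null(backend)) {
    labels <- backend(image, params)
    stopifnot(is.matrix(labels), all(dim(labels) == dim(image)))
    storage.mode(labels) <- "integer"
    labels <- compact_labels(labels, params$min_area_px)
    return(structure(list(labels = labels, source_channel = source_channel),
                     class = "label_map"))
  }
  labels <- {
    thr <- if (is.null(params$threshold)) otsu_threshold(image) else params$threshold
    if (is.null(thr)) {
      matrix(0L, nrow(image), ncol(image))
    } else {
      mask <- image > thr
      if (params$fill_holes) mask <- cpp_fill_holes(mask)
      if (!any(mask)) {
        matrix(0L, nrow(image), ncol(image))
      } else {
        edt <- cpp_edt(mask)
        seeds <- find_seeds(edt, params$peak_min_distance)
        if (nrow(seeds) == 0) {
          cpp_label(mask)
        } else {
          markers <- matrix(0L, nrow(image), ncol(image))
          markers[seeds] <- seq_len(nrow(seeds))
          cpp_watershed(edt, markers, mask)
        }
      }
    }
  }
  if (params$refine_circles && max(labels) > 0L)
    labels <- refine_to_circles(labels, image)
  labels <- compact_labels(labels, params$min_area_px)
  structure(list(labels = labels, source_channel = source_channel),
            class = "label_map")
}

# Snap each label to the circle at its rim-intensity peak. The radial mean
# profile (1-px bins from the object centroid) of a rim bead peaks at the
# bead radius; pixels of the label beyond that circle are the threshold's
# Gaussian-skirt overshoot and are dropped. Objects whose profile is not
# rim-like (peak too central or barely above the interior level) keep their
# original pixel set.
refine_to_circles <- function(labels, image) {
  out <- labels
  for (k in seq_len(max(labels))) {
    px <- which(labels == k, arr.ind = TRUE)
    if (nrow(px) == 0) next
    ctr <- colMeans(px)
    d <- sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
    dmax <- max(d)
    if (dmax < 3) next
    bin <- floor(d) + 1L
    vals <- image[px]
    mean_prof <- vapply(split(vals, bin), mean, numeric(1))
    centers <- as.numeric(names(mean_prof)) - 0.5
    peak <- which.max(mean_prof)
    inner <- mean_prof[centers < 0.5 * dmax]
    if (length(inner) == 0 || centers[peak] < 0.6 * dmax ||
        mean_prof[peak] <= 1.05 * mean(inner)) next
    r_hat <- centers[peak]
    drop <- d > r_hat
    if (any(drop)) out[px[drop, , drop = FALSE]] <- 0L
  }
  out
}

# Distance-transform peaks with greedy non-maximum suppression.
find_seeds <- function(edt, min_distance) {
  mx <- cpp_maxfilter(edt, min_distance)
  cand <- which(edt > 1 & edt == mx, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cand)
  ord <- order(-edt[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    sel <- cand[keep, , drop = FALSE]
    d2 <- (sel[, 1] - cand[k, 1])^2 + (sel[, 2] - cand[k, 2])^2
    if (all(d2 >= min_distance^2)) keep[k] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

# Drop labels under min_area and renumber contiguously in raster order.
compact_labels <- function(labels, min_area_px) {
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_area_px)
  remap <- integer(max(labels))
  # stable ordering: labels keep their relative order after compaction
  remap[keep] <- seq_along(keep)
  out <- labels
  nz <- labels > 0L
  out[nz] <- remap[labels[nz]]
  out
}

#' Combine measurement channels for segmentation
#'
#' Per-pixel maximum across channels; the default segmentation input when
#' no single channel is designated, so that a bead bright in any channel is
#' detected.
#'
#' @param channels named list of same-shaped matrices.
#' @return one matrix.
#' @export
max_project <- function(channels) {
  stopifnot(length(channels) >= 1)
  out <- channels[[1]]
  for (ch in channels[-1]) out <- pmax(out, ch)
  out
}

#' Fit one circular ROI per segmented bead
#'
#' For each label: center = unweighted centroid of its pixels; radius =
#' `sqrt(area / pi)` (the circle of equal area); `touches_edge` flags circles
#' extending past the image bounds. Labels smaller than `min_area_px` are
#' dropped.
#'
#' @param labelmap a `label_map` from [segment_beads()].
#' @param min_area_px minimum pixel area retained.
#' @return data frame of class `bead_rois`: `label`, `center_row`,
#'   `center_col`, `radius`, `area_px`, `touches_edge`.
#' @export
fit_circular_rois <- function(labelmap, min_area_px = ceiling(pi * 25)) {
  stopifnot(inherits(labelmap, "label_map"))
  labels <- labelmap$labels
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area_px) return(NULL)
    ctr <- colMeans(px)
    radius <- sqrt(area / pi)
    edge <- ctr[1] - radius < 0.5 || ctr[1] + radius > nr + 0.5 ||
      ctr[2] - radius < 0.5 || ctr[2] + radius > nc + 0.5
    data.frame(label = k, center_row = ctr[1], center_col = ctr[2],
               radius = radius, area_px = area, touches_edge = edge)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), center_row = numeric(0),
                      center_col = numeric(0), radius = numeric(0),
                      area_px = integer(0), touches_edge = logical(0))
  attr(out, "image_shape") <- c(nr, nc)
  class(out) <- c("bead_rois", class(out))
  out
}

#' Build the combined bead exclusion mask
#'
#' Union of all fitted circles, each dilated by `margin` pixels. Radial line
#' profiles are truncated when they enter this mask outside their own bead,
#' so profiles never protrude into adjacent beads.
#'
#' @param rois a `bead_rois` data frame.
#' @param image_shape integer (height, width).
#' @param margin dilation of each circle, pixels.
#' @return logical matrix, `TRUE` inside any dilated bead circle.
#' @export
build_exclusion_mask <- function(rois, image_shape, margin = 2) {
  nr <- image_shape[1]; nc <- image_shape[2]
  mask <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(rois))) {
    r <- rois$radius[k] + margin
    i0 <- max(1L, floor(rois$center_row[k] - r))
    i1 <- min(nr, ceiling(rois$center_row[k] + r))
    j0 <- max(1L, floor(rois$center_col[k] - r))
    j1 <- min(nc, ceiling(rois$center_col[k] + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - rois$center_row[k])^2, (jj - rois$center_col[k])^2, `+`)
    mask[ii, jj] <- mask[ii, jj] | (d2 <= r^2)
  }
  mask
}
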