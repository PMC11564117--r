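#' Assemble a pipeline run configuration
#'
#' The manifest names the experiment: one entry per condition with its image
#' files, its measurement channel, and a `control: true` flag on exactly one
#' condition. All analysis parameters live here so that a run is a pure
#' function of its config.
#'
#' @param manifest path to a manifest YAML (see Details), or an equivalent
#'   named list. YAML layout:
#'   ```yaml
#'   channels: [GFP, mCherry]
#'   conditions:
#'     - name: control
#'       control: true
#'       channel: GFP
#'       images: [ctrl_1.tif]
#'     - name: treatment
#'       channel: GFP
#'       images: [treat_1.tif]
#'   ```
#'   Relative image paths resolve against the manifest's directory.
#' @param output_dir where result tables are written.
#' @param seg segmentation parameters, [seg_params()].
#' @param profile profiling parameters, [profile_config()].
#' @param qc_ratio SD/mean exclusion threshold (default 0.5).
#' @param mask_margin exclusion-mask dilation, pixels.
#' @param exclude_edge drop beads touching the image edge.
#' @param seg_channel channel used for segmentation; `"max"` (default) takes
#'   the per-pixel maximum over all channels.
#' @param seed integer recorded in the run record; the quantification path is
#'   deterministic, the seed covers any stochastic extension.
#' @return an object of class `run_config`.
#' @export
run_config <- function(manifest, output_dir, seg = seg_params(),
                       profile = profile_config(), qc_ratio = 0.5,
                       mask_margin = 2, exclude_edge = TRUE,
                       seg_channel = "max", seed = 1L) {
  if (qc_ratio <= 0 || qc_ratio > 1) stopf("qc_ratio must be in (0, 1]")
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stopf("manifest '%s' does not exist", manifest)
    base <- dirname(normalizePath(manifest))
    manifest <- yaml::read_yaml(manifest)
    manifest$conditions <- lapply(manifest$conditions, function(cd) {
      cd$images <- vapply(cd$images, function(p)
        if (file.exists(p)) p else file.path(base, p), character(1))
      cd
    })
  }
  stopifnot(is.list(manifest), !is.null(manifest$conditions))
  ctrl <- vapply(manifest$conditions, function(cd) isTRUE(cd$control), logical(1))
  if (sum(ctrl) != 1)
    stopf("manifest must flag exactly one condition with control: true")
  structure(list(manifest = manifest,
                 control = manifest$conditions[[which(ctrl)]]$name,
                 output_dir = output_dir, seg = seg, profile = profile,
                 qc_ratio = qc_ratio, mask_margin = mask_margin,
                 exclude_edge = exclude_edge, seg_channel = seg_channel,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Quantify one image: segment, fit ROIs, mask, profile, summarize.
quantify_image <- function(path, channels, measure_channel, config) {
  imgs <- read_multichannel_image(path, channels)
  if (!measure_channel %in% channels)
    stopf("channel '%s' not among channels of '%s'", measure_channel, path)
  seg_img <- if (identical(config$seg_channel, "max")) max_project(imgs)
  else imgs[[config$seg_channel]]
  lab <- segment_beads(seg_img, config$seg,
                       source_channel = config$seg_channel)
  rois <- fit_circular_rois(lab, config$seg$min_area_px)
  mask <- build_exclusion_mask(rois, dim(seg_img), config$mask_margin)
  mb <- measure_beads(imgs[[measure_channel]], rois, mask, config$profile,
                      config$mask_margin, config$exclude_edge)
  list(labelmap = lab, rois = rois, measurements = mb$measurements,
       n_edge_excluded = mb$n_edge_excluded)
}

#' Run the full quantification pipeline
#'
#' For every image of every condition: segment the bead field, fit circular
#' ROIs, build the combined exclusion mask, draw radial line profiles, and
#' summarize each bead. Then apply the SD-based QC rule, normalize all bead
#' means to the control condition's average, and compare each condition to
#' the control with one-way ANOVA + Dunnett. Writes `beads.csv` (per bead),
#' `conditions.csv` (per condition), `stats.csv` (per comparison), per-image
#' label TIFFs, and `run_record.yaml`.
#'
#' Conditions with no QC-passing beads are reported with zero counts and
#' dropped from the statistics with a warning.
#'
#' @param config a [run_config()].
#' @param write_outputs write result files to `config$output_dir`.
#' @return list: `beads` (data frame), `conditions` (data frame), `stats`
#'   (`stats_report` or `NULL`), `record` (run record list).
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  channels <- unlist(config$manifest$channels)
  if (is.null(channels)) stopf("manifest must name the image channels")

  bead_rows <- list()
  counts <- list()
  labelmaps <- list()
  for (cd in config$manifest$conditions) {
    ch <- if (!is.null(cd$channel)) cd$channel else channels[1]
    found <- edge <- 0L
    meas_all <- list()
    for (r in seq_along(cd$images)) {
      path <- cd$images[[r]]
      q <- tryCatch(quantify_image(path, channels, ch, config),
                    error = function(e) stopf(
                      "stage 'quantify' failed on '%s' (condition '%s'): %s",
                      path, cd$name, conditionMessage(e)))
      found <- found + nrow(q$rois)
      edge <- edge + q$n_edge_excluded
      labelmaps[[paste0(cd$name, "_", r)]] <- q$labelmap
      for (m in q$measurements) {
        m$replicate <- r
        meas_all[[length(meas_all) + 1]] <- m
      }
    }
    qc <- qc_filter(meas_all, config$qc_ratio)
    unmeasurable <- sum(vapply(qc$excluded, function(m)
      identical(m$qc_reason, "no_valid_lines"), logical(1)))
    counts[[cd$name]] <- c(found = found, edge_excluded = edge,
                           unmeasurable = unmeasurable,
                           qc_excluded = length(qc$excluded) - unmeasurable,
                           passed = length(qc$passed))
    for (m in c(qc$passed, qc$excluded))
      bead_rows[[length(bead_rows) + 1]] <- data.frame(
        condition = cd$name, replicate = m$replicate, bead_label = m$bead_label,
        mean_amplitude = m$mean_amplitude, sd_amplitude = m$sd_amplitude,
        n_valid_lines = m$n_valid_lines, qc_pass = m$qc_pass,
        qc_reason = m$qc_reason)
  }
  beads <- if (length(bead_rows)) do.call(rbind, bead_rows) else
    data.frame(condition = character(0), replicate = integer(0),
               bead_label = integer(0), mean_amplitude = numeric(0),
               sd_amplitude = numeric(0), n_valid_lines = integer(0),
               qc_pass = logical(0), qc_reason = character(0))

  cond_names <- vapply(config$manifest$conditions, `[[`, character(1), "name")
  raw_means <- lapply(cond_names, function(nm)
    beads$mean_amplitude[beads$condition == nm & beads$qc_pass])
  names(raw_means) <- cond_names
  if (length(raw_means[[config$control]]) == 0)
    stopf("stage 'normalize' failed: control condition '%s' has no QC-passing beads",
          config$control)
  normalized <- normalize_to_control(raw_means, config$control)
  beads$normalized <- NA_real_
  for (nm in cond_names)
    beads$normalized[beads$condition == nm & beads$qc_pass] <- normalized[[nm]]

  empty <- names(normalized)[vapply(normalized, length, integer(1)) < 2]
  if (length(empty) > 0)
    warning(sprintf("condition(s) with fewer than 2 QC-passing beads excluded from statistics: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  usable <- normalized[!names(normalized) %in% empty]
  stats <- if (length(usable) >= 2 && config$control %in% names(usable))
    anova_dunnett(usable, config$control) else NULL

  conditions <- do.call(rbind, lapply(cond_names, function(nm) {
    v <- normalized[[nm]]
    data.frame(condition = nm, n_beads_pass = length(v),
               n_beads_excluded = unname(counts[[nm]]["qc_excluded"] +
                                         counts[[nm]]["unmeasurable"]),
               mean_normalized = if (length(v)) mean(v) else NA_real_,
               sd_normalized = if (length(v) > 1) sd(v) else NA_real_)
  }))

  record <- list(
    package_version = as.character(packageVersion("beadrim")),
    control = config$control, qc_ratio = config$qc_ratio,
    seed = config$seed,
    n_images = sum(vapply(config$manifest$conditions,
                          function(cd) length(cd$images), integer(1))),
    counts = lapply(counts, as.list),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (write_outputs) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(beads, file.path(config$output_dir, "beads.csv"),
              row.names = FALSE)
    write.csv(conditions, file.path(config$output_dir, "conditions.csv"),
              row.names = FALSE)
    if (!is.null(stats))
      write.csv(cbind(test = stats$test_name, F = stats$statistic,
                      df1 = stats$df[["df1"]], df2 = stats$df[["df2"]],
                      stats$comparisons),
                file.path(config$output_dir, "stats.csv"), row.names = FALSE)
    for (nm in names(labelmaps))
      write_tiff(labelmaps[[nm]]$labels,
                 file.path(config$output_dir, paste0("labels_", nm, ".tif")))
    yaml::write_yaml(record, file.path(config$output_dir, "run_record.yaml"))
  }
  list(beads = beads, conditions = conditions, stats = stats, record = record)
}

#' Simulate a multi-condition experiment to disk
#'
#' Thin wrapper over the synthetic generator: renders one or more scenes per
#' condition, writes them as TIFF + ground-truth sidecars, and emits a
#' manifest YAML ready for [run_pipeline()]. `spec` is a list with
#' `conditions` (each: `name`, `rim_amplitude`, optional `control`,
#' `n_images`) and optional scene parameters passed to [scene_config()].
#'
#' @param spec experiment description (list or path to a YAML file).
#' @param out_dir output directory.
#' @param seed base seed; image j of condition i uses a distinct derived seed.
#' @return path to the written manifest YAML.
#' @export
simulate_experiment <- function(spec, out_dir, seed = 1L) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  stopifnot(!is.null(spec$conditions))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scene_args <- spec[setdiff(names(spec), c("conditions", "channels"))]
  manifest <- list(channels = list("GFP"), conditions = list())
  for (i in seq_along(spec$conditions)) {
    cd <- spec$conditions[[i]]
    n_img <- if (!is.null(cd$n_images)) cd$n_images else 1L
    images <- character(n_img)
    for (j in seq_len(n_img)) {
      args <- scene_args
      args$rim_amplitude <- cd$rim_amplitude
      args$seed <- seed + 1000L * i + j
      scene <- generate_scene(do.call(scene_config, args))
      stem <- sprintf("%s_%d", cd$name, j)
      write_scene(scene, out_dir, stem)
      images[j] <- paste0(stem, ".tif")
    }
    manifest$conditions[[i]] <- list(name = cd$name,
                                     control = isTRUE(cd$control),
                                     channel = "GFP",
                                     images = as.list(images))
  }
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}
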