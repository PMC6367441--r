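#' Pipeline run configuration
#'
#' Collects the analysis parameters of the whole pipeline. All defaults
#' equal the standard protocol constants: saccade threshold multiplier
#' 6, minimum amplitude 0.5 dva, minimum saccade duration 6 samples,
#' minimum fixation duration 50 ms, KDE bandwidth grid 0.5–2.0 dva in
#' 0.1 steps on a 128 x 128 grid, 79-px spectrum patches, and
#' 1200/31.1 px per degree.
#'
#' @param ... Named overrides; unknown names are an error. Synthetic-run
#'   scale is controlled by `participants`, `sessions`,
#'   `images_per_block`, `n_images`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    px_per_deg = default_px_per_deg(),
    image_size_px = c(1200, 960),
    L_max = 100, gamma = 2.2,
    lambda = 6, min_amplitude = 0.5, min_samples = 6, min_fix_duration = 50,
    velocity_window = 5, merge_gap_ms = 12,
    bw_grid = seq(0.5, 2.0, by = 0.1), density_grid = c(128, 128),
    patch_size = 79,
    participants = 10, sessions = 8, images_per_block = 25, n_images = 25,
    background_slope = 1, orientation_bias = 0.2,
    scanpath = scanpath_params(),
    seed = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop_config("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$lambda <= 0) stop_config("lambda must be positive")
  if (cfg$min_amplitude < 0) stop_config("min_amplitude must be non-negative")
  if (cfg$min_samples < 1) stop_config("min_samples must be at least 1")
  if (cfg$patch_size %% 2 != 1) stop_config("patch_size must be odd")
  if (any(cfg$bw_grid <= 0)) stop_config("bandwidths must be positive")
  if (cfg$px_per_deg <= 0) stop_config("px_per_deg must be positive")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] entries.
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scanpath)) y$scanpath <- do.call(scanpath_params, y$scanpath)
  do.call(run_config, y)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

write_stage_csv <- function(d, path, hash) {
  readr::write_lines(paste0("# config_hash: ", hash), path)
  readr::write_csv(d, path, append = TRUE, col_names = TRUE)
}

#' Write / read a gridded map as plain text with a JSON sidecar
#'
#' The map matrix is stored as a headerless CSV of cell values and its
#' extent, bandwidth and source in `<path>.json`.
#'
#' @param map A [density_map()].
#' @param path Output path for the grid values.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.table(map$values, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  jsonlite::write_json(list(extent = map$extent, bandwidth = map$bandwidth,
                            source = map$source, grid = map$grid),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  density_map(v, extent = list(xlim = meta$extent$xlim, ylim = meta$extent$ylim),
              bandwidth = meta$bandwidth, source = meta$source)
}

#' Write a gray-level image as 8-bit PNG
#'
#' @param gray Matrix of gray levels in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(gray, path) {
  png::writePNG(pmin(pmax(gray, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates a synthetic experiment (backgrounds, design, scanpaths, raw
#' gaze traces), then runs the analysis stages in order — event detection,
#' scanpath statistics, fixation-density estimation, patch spectra — and
#' writes tidy CSV tables (each stamped with the configuration hash) plus
#' a `manifest.json` to `out_dir`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing.
#' @return List with the design, event tables, analysis tables, density
#'   results and spectrum summary, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  validate_config(cfg)
  hash <- config_hash(cfg)
  ppd <- cfg$px_per_deg
  extent <- image_extent(cfg$image_size_px, ppd)

  # --- synth stage -----------------------------------------------------
  design <- gen_design(participants = cfg$participants, sessions = cfg$sessions,
                       images_per_block = cfg$images_per_block,
                       seed = cfg$seed)
  design <- design[design$image_id <= cfg$n_images, , drop = FALSE]
  images <- lapply(seq_len(cfg$n_images), function(i)
    gen_background(cfg$image_size_px[1], cfg$image_size_px[2],
                   slope = cfg$background_slope,
                   orientation_bias = cfg$orientation_bias,
                   seed = cfg$seed * 131 + i))
  names(images) <- as.character(seq_len(cfg$n_images))
  positions <- dplyr::bind_rows(lapply(seq_len(cfg$n_images), function(i)
    dplyr::mutate(sample_target_positions(cfg$image_size_px,
                                          seed = cfg$seed * 977 + i),
                  image_id = i)))
  truth <- gen_cohort_events(design, params = cfg$scanpath,
                             positions = positions, px_per_deg = ppd,
                             extent = extent, seed = cfg$seed)
  design <- truth$design

  # --- detect stage ----------------------------------------------------
  fixl <- list(); sacl <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    sp <- list(fixations = truth$fixations[truth$fixations$trial_id == tr$trial_id, ],
               saccades = truth$saccades[truth$saccades$trial_id == tr$trial_id, ])
    trace <- render_trace(sp, noise_sd = cfg$scanpath$noise_sd,
                          subject_id = tr$subject_id, trial_id = tr$trial_id,
                          seed = (cfg$seed * 6007 + i) %% .Machine$integer.max)
    ev <- detect_events(trace, lambda = cfg$lambda,
                        min_samples = cfg$min_samples,
                        min_amplitude = cfg$min_amplitude,
                        window = cfg$velocity_window,
                        merge_gap_ms = cfg$merge_gap_ms,
                        min_fix_duration = cfg$min_fix_duration)
    fixl[[i]] <- ev$fixations; sacl[[i]] <- ev$saccades
  }
  fixations <- dplyr::bind_rows(fixl)
  saccades <- dplyr::bind_rows(sacl)

  # --- scanpath stage --------------------------------------------------
  trial_stats <- summarize_trials(fixations, saccades, design)
  aggregates <- dplyr::bind_rows(lapply(
    c("amplitude", "duration", "search_time", "detection"),
    function(v) dplyr::mutate(aggregate_by_condition(trial_stats, v),
                              variable = v)))
  timecourse <- timecourse_by_index(fixations, saccades, design)
  pairs <- saccade_pairs(saccades, fixations)

  # --- density stage ---------------------------------------------------
  fix_img <- dplyr::inner_join(
    fixations,
    design[, c("subject_id", "trial_id", "image_id")],
    by = c("subject_id", "trial_id"))
  density_tbl <- list(); maps <- list()
  for (img in sort(unique(fix_img$image_id))) {
    d <- fix_img[fix_img$image_id == img, ]
    if (length(unique(d$subject_id)) < 2) next
    bw <- select_bandwidth_loso(d, extent = extent, candidates = cfg$bw_grid,
                                grid = cfg$density_grid)
    m <- kde_density(d, bandwidth = as.numeric(bw), extent = extent,
                     grid = cfg$density_grid)
    maps[[as.character(img)]] <- m
    density_tbl[[as.character(img)]] <- tibble::tibble(
      image_id = img, bandwidth = as.numeric(bw), n_fixations = nrow(d),
      loglik_vs_uniform = loglik_vs_uniform(d, m))
  }
  density_tbl <- dplyr::bind_rows(density_tbl)
  if (length(maps) > 0 && nrow(pairs) > 0) {
    pair_img <- dplyr::left_join(
      pairs, design[, c("subject_id", "trial_id", "image_id")],
      by = c("subject_id", "trial_id"))
    pairs$density_value <- NA_real_
    for (img in names(maps)) {
      sel <- which(pair_img$image_id == as.integer(img))
      if (length(sel) > 0) {
        pts <- tibble::tibble(x = pairs$end_x[sel], y = pairs$end_y[sel])
        inside <- pts$x >= extent$xlim[1] & pts$x <= extent$xlim[2] &
          pts$y >= extent$ylim[1] & pts$y <= extent$ylim[2]
        pairs$density_value[sel[inside]] <-
          lookup_map_values(maps[[img]], pts[inside, ])
      }
    }
  }
  direction_bins <- bin_by_direction_change(pairs)
  direction_bins_windowed <- bin_by_direction_change(pairs,
                                                     amplitude_window = c(3, 8))

  # --- spectra stage ---------------------------------------------------
  lum <- lapply(images, function(im) gray_to_luminance(im, cfg$gamma, cfg$L_max)$values)
  fix_px <- dplyr::mutate(fix_img, x_px = .data$x * ppd, y_px = .data$y * ppd)
  fixated <- NULL; control <- NULL; spec_sum <- NULL
  sets <- lapply(sort(unique(fix_px$image_id)), function(img)
    extract_fixation_patches(lum[[img]], fix_px[fix_px$image_id == img, ],
                             size = cfg$patch_size))
  n_tot <- sum(vapply(sets, function(s) dim(s$patches)[3], 0))
  if (n_tot > 0 && length(lum) >= 2) {
    fixated <- structure(list(
      patches = {
        a <- array(0, dim = c(cfg$patch_size, cfg$patch_size, n_tot)); k <- 0
        for (s in sets) {
          n <- dim(s$patches)[3]
          if (n > 0) a[, , k + seq_len(n)] <- s$patches
          k <- k + n
        }
        a
      },
      meta = dplyr::bind_rows(lapply(sets, `[[`, "meta")),
      n_dropped = sum(vapply(sets, `[[`, 0, "n_dropped")),
      size = cfg$patch_size, origin = "fixated"), class = "patch_set")
    control <- control_patches(lum, fix_px, size = cfg$patch_size)
    groups <- sf_class_of(
      design$target_kind[match(fixated$meta$trial_id, design$trial_id)],
      known = design$target_known[match(fixated$meta$trial_id, design$trial_id)])
    spec_sum <- spectrum_summary(fixated, control, groups = groups)
  }

  result <- list(config = cfg, config_hash = hash, design = design,
                 fixations = fixations, saccades = saccades,
                 trial_stats = trial_stats, aggregates = aggregates,
                 timecourse = timecourse, pairs = pairs,
                 direction_bins = direction_bins,
                 direction_bins_windowed = direction_bins_windowed,
                 density = density_tbl, density_maps = maps,
                 spectra = spec_sum)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(design = design, fixations = fixations, saccades = saccades,
                   trial_stats = trial_stats, aggregates = aggregates,
                   timecourse = timecourse, direction_bins = direction_bins,
                   direction_bins_windowed = direction_bins_windowed,
                   density = density_tbl)
    for (nm in names(tables)) {
      write_stage_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")), hash)
    }
    for (nm in names(maps)) {
      write_map(maps[[nm]], file.path(out_dir, paste0("density_map_", nm, ".csv")))
    }
    if (!is.null(spec_sum)) {
      spectra_tbl <- tibble::tibble(
        n_fixated = spec_sum$n_fixated, n_control = spec_sum$n_control,
        sd_over_mean = spec_sum$sd_over_mean,
        mean_ratio_vs_control = mean(spec_sum$ratio_vs_control))
      write_stage_csv(spectra_tbl, file.path(out_dir, "spectra_summary.csv"), hash)
    }
    jsonlite::write_json(
      list(config_hash = hash,
           files = list.files(out_dir),
           stages = c("synth", "detect", "scanpath", "density", "spectra")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(result)
}
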