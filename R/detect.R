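#' Construct a gaze trace
#'
#' A per-trial time series of gaze samples in degrees of visual angle,
#' uniformly sampled (1000 Hz by default). Time must be strictly
#' increasing with a uniform step; traces with gaps should be split into
#' separate trials before detection.
#'
#' @param t Sample times in ms.
#' @param x,y Gaze position in dva.
#' @param subject_id,trial_id Identifiers carried through detection.
#' @return A tibble with class `gaze_trace`.
#' @export
gaze_trace <- function(t, x, y, subject_id = NA_character_, trial_id = NA_character_) {
  stopifnot(length(t) == length(x), length(x) == length(y), length(t) >= 2)
  dt <- diff(t)
  if (any(dt <= 0)) stop_config("gaze trace time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt, 1))
    stop_config("gaze trace must be uniformly sampled; split trials at gaps")
  out <- tibble::tibble(subject_id = subject_id, trial_id = trial_id,
                        t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("gaze_trace", class(out))
  out
}

#' Read a gaze-sample CSV and convert pixels to degrees
#'
#' Expects columns `subject_id`, `trial_id`, `t_ms`, `x_px`, `y_px`.
#'
#' @param path CSV file path.
#' @param px_per_deg Pixels per degree used for the conversion.
#' @return Tibble of samples with `x`, `y` in dva, one row per sample.
#' @export
read_gaze_csv <- function(path, px_per_deg = default_px_per_deg()) {
  d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("subject_id", "trial_id", "t_ms", "x_px", "y_px")
  if (!all(need %in% names(d)))
    stop_config("gaze CSV must have columns ", paste(need, collapse = ", "))
  dplyr::mutate(d, t = .data$t_ms, x = .data$x_px / px_per_deg,
                y = .data$y_px / px_per_deg)
}

# centred moving-window difference estimate of one velocity component.
# For half-window m the interior estimate is
#   v_k = sum_{j=1..m} (z_{k+j} - z_{k-j}) / (dt * m * (m + 1)),
# the least-squares slope of a symmetric window; edges use the largest
# symmetric window that fits (truncated), and the first/last sample get 0.
moving_slope <- function(z, dt, m) {
  n <- length(z)
  cs <- cumsum(z)
  k <- seq_len(n)
  mk <- pmin(m, k - 1L, n - k)
  v <- numeric(n)
  for (mm in sort(unique(mk[mk > 0]))) {
    sel <- which(mk == mm)
    upper <- cs[sel + mm] - cs[sel]
    below <- numeric(length(sel))
    pos <- sel - mm - 1L
    below[pos >= 1] <- cs[pos[pos >= 1]]
    lower <- cs[sel - 1] - below
    v[sel] <- (upper - lower) / (dt * mm * (mm + 1))
  }
  v
}

#' Per-sample gaze velocity
#'
#' Centred moving-window differentiator (default 5-sample window), which
#' both estimates and smooths the velocity; window edges are handled by
#' truncated symmetric windows.
#'
#' @param trace A [gaze_trace()].
#' @param window Odd window length in samples.
#' @return Tibble with `vx`, `vy` and `speed` (dva/s), one row per sample.
#' @export
compute_velocity <- function(trace, window = 5) {
  stopifnot(window %% 2 == 1, window >= 3)
  if (nrow(trace) <= window)
    stop_config("trace shorter than the velocity window: trial too short")
  dt <- (trace$t[2] - trace$t[1]) / 1000  # s
  m <- (window - 1) / 2
  vx <- moving_slope(trace$x, dt, m)
  vy <- moving_slope(trace$y, dt, m)
  tibble::tibble(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

# median-based standard deviation: sqrt(median(v^2) - median(v)^2)
median_sd <- function(v) {
  s2 <- median(v^2) - median(v)^2
  if (s2 < 0) s2 <- 0
  sqrt(s2)
}

#' Velocity threshold from a median-based standard deviation
#'
#' `threshold = center + lambda * sqrt(median(v^2) - median(v)^2)`, with
#' the centre taken as the median of the per-trial velocity distribution
#' (a robust reading of "average velocity", consistent with the
#' median-based spread); the arithmetic mean is available as an option.
#'
#' @param v Numeric vector of velocities (one component, or magnitudes).
#' @param lambda Multiplier (default 6).
#' @param center `"median"` (default) or `"mean"`.
#' @return Scalar threshold.
#' @export
velocity_threshold <- function(v, lambda = 6, center = c("median", "mean")) {
  center <- match.arg(center)
  s <- median_sd(v)
  if (!is.finite(s) || s <= 0)
    stop_config("zero median-based velocity dispersion (constant trace); no threshold defined")
  ctr <- if (center == "median") median(v) else mean(v)
  ctr + lambda * s
}

# merge supra-threshold runs separated by fewer than gap_samples samples
merge_runs <- function(supra, gap_samples) {
  r <- rle(supra)
  if (gap_samples > 0 && length(r$lengths) > 2) {
    inner <- which(!r$values)
    inner <- inner[inner > 1 & inner < length(r$values)]
    r$values[inner[r$lengths[inner] < gap_samples]] <- TRUE
    r <- rle(inverse.rle(r))
  }
  r
}

#' Detect saccades with the velocity-threshold algorithm
#'
#' Marks a sample as saccadic when its velocity exceeds a per-trial
#' threshold of `lambda` median-based standard deviations above the
#' trial's median velocity. With the default elliptic criterion the two
#' components are thresholded jointly:
#' `((vx - mx) / (lambda sx))^2 + ((vy - my) / (lambda sy))^2 > 1`;
#' a pure speed-magnitude criterion is available. Supra-threshold runs
#' separated by less than `merge_gap_ms` are merged, runs of at least
#' `min_samples` samples become candidate saccades, and candidates with
#' amplitude below `min_amplitude` are discarded.
#'
#' @param trace A [gaze_trace()].
#' @param lambda Threshold multiplier (default 6).
#' @param min_samples Minimum saccade duration in samples (default 6).
#' @param min_amplitude Minimum amplitude in dva (default 0.5).
#' @param window Velocity window in samples.
#' @param merge_gap_ms Sub-threshold gaps shorter than this are merged.
#' @param criterion `"elliptic"` (per-component, default) or
#'   `"magnitude"`.
#' @return Tibble of saccade events: onset/offset time, start/end
#'   position, `amplitude` (dva), `direction` (degrees in \[0, 360)),
#'   `peak_velocity` (dva/s), `sac_index` within the trial.
#' @export
detect_saccades <- function(trace, lambda = 6, min_samples = 6,
                            min_amplitude = 0.5, window = 5,
                            merge_gap_ms = 12,
                            criterion = c("elliptic", "magnitude")) {
  criterion <- match.arg(criterion)
  if (lambda <= 0) stop_config("lambda must be positive")
  vel <- compute_velocity(trace, window = window)
  if (criterion == "elliptic") {
    sx <- median_sd(vel$vx); sy <- median_sd(vel$vy)
    if (sx <= 0 || sy <= 0)
      stop_config("zero median-based velocity dispersion (constant trace); no threshold defined")
    rx <- (vel$vx - median(vel$vx)) / (lambda * sx)
    ry <- (vel$vy - median(vel$vy)) / (lambda * sy)
    supra <- rx^2 + ry^2 > 1
  } else {
    thr <- velocity_threshold(vel$speed, lambda = lambda)
    supra <- vel$speed > thr
  }
  dt_ms <- trace$t[2] - trace$t[1]
  r <- merge_runs(supra, ceiling(merge_gap_ms / dt_ms))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_samples
  n <- nrow(trace)
  prev_end <- 0L
  events <- lapply(which(keep), function(i) {
    a <- starts[i]; b <- ends[i]
    # refine boundaries: walk outward down the velocity slope to the
    # nearest local speed minimum, capturing the sub-threshold tails of
    # the saccade without crossing into the previous event
    while (a > prev_end + 1L && vel$speed[a - 1] < vel$speed[a]) a <- a - 1L
    while (b < n && vel$speed[b + 1] < vel$speed[b]) b <- b + 1L
    # endpoint positions averaged over a few settled fixation samples
    # strictly outside the event, suppressing sample noise
    s_hi <- max(prev_end + 1L, a - 2L); s_lo <- max(prev_end + 1L, a - 6L)
    e_lo <- min(n, b + 2L); e_hi <- min(n, b + 6L)
    prev_end <<- b
    sx <- mean(trace$x[s_lo:s_hi]); sy <- mean(trace$y[s_lo:s_hi])
    ex <- mean(trace$x[e_lo:e_hi]); ey <- mean(trace$y[e_lo:e_hi])
    amp <- sqrt((ex - sx)^2 + (ey - sy)^2)
    if (amp < min_amplitude) return(NULL)
    tibble::tibble(
      subject_id = trace$subject_id[1], trial_id = trace$trial_id[1],
      onset_t = trace$t[a], offset_t = trace$t[b],
      duration = trace$t[b] - trace$t[a],
      start_x = sx, start_y = sy, end_x = ex, end_y = ey,
      amplitude = amp,
      direction = (atan2(ey - sy, ex - sx) * 180 / pi) %% 360,
      peak_velocity = max(vel$speed[a:b])
    )
  })
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0) {
    out <- tibble::tibble(subject_id = character(), trial_id = character(),
                          onset_t = numeric(), offset_t = numeric(),
                          duration = numeric(), start_x = numeric(),
                          start_y = numeric(), end_x = numeric(),
                          end_y = numeric(), amplitude = numeric(),
                          direction = numeric(), peak_velocity = numeric())
  }
  out$sac_index <- seq_len(nrow(out))
  out
}

#' Derive fixations from the epochs between saccades
#'
#' Each epoch between two subsequent saccades is a fixation, as are the
#' leading and trailing epochs of the trial; with no saccades the whole
#' trial is one fixation. The centroid is the mean sample position inside
#' the epoch. The first fixation of the trial is flagged (`is_first`) so
#' analyses can exclude the experimentally enforced initial fixation.
#'
#' @param trace A [gaze_trace()].
#' @param saccades Saccade table from [detect_saccades()] (ordered,
#'   non-overlapping).
#' @return Tibble of fixations: `start_t`, `end_t`, `duration` (ms),
#'   centroid `x`, `y` (dva), `ordinal_index`, `is_first`.
#' @export
extract_fixations <- function(trace, saccades) {
  bounds_lo <- c(trace$t[1], saccades$offset_t)
  bounds_hi <- c(saccades$onset_t, trace$t[nrow(trace)])
  keep <- bounds_hi > bounds_lo
  bounds_lo <- bounds_lo[keep]; bounds_hi <- bounds_hi[keep]
  out <- lapply(seq_along(bounds_lo), function(i) {
    sel <- trace$t >= bounds_lo[i] & trace$t <= bounds_hi[i]
    tibble::tibble(
      subject_id = trace$subject_id[1], trial_id = trace$trial_id[1],
      start_t = bounds_lo[i], end_t = bounds_hi[i],
      duration = bounds_hi[i] - bounds_lo[i],
      x = mean(trace$x[sel]), y = mean(trace$y[sel])
    )
  })
  out <- dplyr::bind_rows(out)
  out$ordinal_index <- seq_len(nrow(out))
  out$is_first <- out$ordinal_index == 1L
  out
}

#' Remove short fixations
#'
#' Fixations shorter than `min_duration` ms (default 50) are removed;
#' these are largely glissades. Ordinal indices are recomputed; the
#' `is_first` flag of the original first fixation is preserved if it
#' survives.
#'
#' @param fixations Fixation table from [extract_fixations()].
#' @param min_duration Minimum duration in ms.
#' @return Filtered fixation table.
#' @export
filter_fixations <- function(fixations, min_duration = 50) {
  out <- fixations[fixations$duration >= min_duration, , drop = FALSE]
  if (nrow(out) > 0) {
    out <- dplyr::group_by(out, .data$subject_id, .data$trial_id)
    out <- dplyr::mutate(out, ordinal_index = dplyr::row_number())
    out <- dplyr::ungroup(out)
  }
  out
}

#' Run the full detection chain on one trace
#'
#' Convenience wrapper: [detect_saccades()], [extract_fixations()],
#' [filter_fixations()].
#'
#' @inheritParams detect_saccades
#' @param min_fix_duration Minimum fixation duration in ms (default 50).
#' @return List with `saccades` and `fixations` tibbles.
#' @export
detect_events <- function(trace, lambda = 6, min_samples = 6,
                          min_amplitude = 0.5, window = 5,
                          merge_gap_ms = 12, min_fix_duration = 50,
                          criterion = c("elliptic", "magnitude")) {
  sac <- detect_saccades(trace, lambda = lambda, min_samples = min_samples,
                         min_amplitude = min_amplitude, window = window,
                         merge_gap_ms = merge_gap_ms,
                         criterion = match.arg(criterion))
  fix <- filter_fixations(extract_fixations(trace, sac),
                          min_duration = min_fix_duration)
  list(saccades = sac, fixations = fix)
}
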