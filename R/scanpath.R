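#' Change in saccadic direction
#'
#' Absolute angular difference between the direction vectors of two
#' successive saccades, folded to \[0, 180\] degrees: 0 means direction
#' maintained ("saccadic momentum"), 180 a full reversal ("return
#' saccade"). Only the magnitude of the turn is retained, so left and
#' right turns are equivalent and the measure is invariant under global
#' rotation of the scanpath.
#'
#' @param dir1,dir2 Directions of the earlier and later saccade in
#'   degrees (vectorized).
#' @return Angle change in degrees within \[0, 180\].
#' @export
direction_change <- function(dir1, dir2) {
  fold_angle(dir2 - dir1)
}

#' Per-trial summary statistics
#'
#' Joins detected events with the experiment design and reduces each
#' trial to its mean saccade amplitude, mean fixation duration, fixation
#' and saccade counts, plus design-level variables (`session`,
#' `target_kind`, `sf_class`, `present`, and `detected` / `search_time`
#' when the design carries them).
#'
#' @param fixations,saccades Event tables from [detect_events()] or the
#'   synthetic generator (must carry `subject_id`, `trial_id`).
#' @param design Trial table with `subject_id`, `trial_id`, `session`,
#'   `target_kind`, `sf_class`, `present` and optionally `detected`,
#'   `search_time`.
#' @param exclude_first Drop the flagged first fixation from the duration
#'   summary (default `FALSE`).
#' @return Tibble with one row per trial.
#' @export
summarize_trials <- function(fixations, saccades, design, exclude_first = FALSE) {
  fx <- fixations
  if (exclude_first && "is_first" %in% names(fx)) fx <- fx[!fx$is_first, , drop = FALSE]
  fsum <- fx |>
    dplyr::group_by(.data$subject_id, .data$trial_id) |>
    dplyr::summarise(mean_duration = mean(.data$duration),
                     n_fixations = dplyr::n(), .groups = "drop")
  ssum <- saccades |>
    dplyr::group_by(.data$subject_id, .data$trial_id) |>
    dplyr::summarise(mean_amplitude = mean(.data$amplitude),
                     n_saccades = dplyr::n(), .groups = "drop")
  design |>
    dplyr::left_join(fsum, by = c("subject_id", "trial_id")) |>
    dplyr::left_join(ssum, by = c("subject_id", "trial_id"))
}

#' Aggregate a scanpath variable by condition and session
#'
#' Produces the mean +/- SEM of a trial-level variable per grouping
#' condition (spatial-frequency class by default, or target kind) and
#' session. By default trials are first averaged within subject and the
#' SEM is taken over subjects (the error-bar convention used throughout
#' the analyses); pooled aggregation over trials is available.
#'
#' For `variable = "detection"` the value is the hit rate among
#' target-present trials; use `variable = "false_alarm"` for the
#' detected proportion among target-absent trials.
#'
#' @param trial_stats Per-trial table from [summarize_trials()].
#' @param variable One of `"amplitude"`, `"duration"`, `"search_time"`,
#'   `"detection"`, `"false_alarm"`.
#' @param by Grouping column (default `"sf_class"`; `"target_kind"` for
#'   per-target bars).
#' @param by_session Include `session` in the grouping keys.
#' @param per_subject_first Average within subject before computing the
#'   mean and SEM over subjects.
#' @return Tidy tibble with grouping keys, `mean`, `sem` and `n` (number
#'   of subjects or trials); empty groups keep a row with `n = 0` and
#'   `NA` mean.
#' @export
aggregate_by_condition <- function(trial_stats,
                                   variable = c("amplitude", "duration",
                                                "search_time", "detection",
                                                "false_alarm"),
                                   by = "sf_class", by_session = TRUE,
                                   per_subject_first = TRUE) {
  variable <- match.arg(variable)
  d <- trial_stats
  col <- switch(variable,
    amplitude = "mean_amplitude", duration = "mean_duration",
    search_time = "search_time", detection = "detected",
    false_alarm = "detected")
  if (!col %in% names(d))
    stop_config("trial_stats lacks column '", col, "' needed for variable '", variable, "'")
  if (variable == "detection") d <- d[d$present, , drop = FALSE]
  if (variable == "false_alarm") d <- d[!d$present, , drop = FALSE]
  d$.value <- as.numeric(d[[col]])
  keys <- c(by, if (by_session) "session")
  d[[by]] <- factor(d[[by]])
  if (per_subject_first) {
    d <- d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "subject_id"))), .drop = FALSE) |>
      dplyr::summarise(.value = mean(.data$.value, na.rm = TRUE), .groups = "drop")
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .drop = FALSE) |>
    dplyr::summarise(
      n = sum(is.finite(.data$.value)),
      mean = ifelse(.data$n > 0, mean(.data$.value[is.finite(.data$.value)]), NA_real_),
      sem = sem(.data$.value),
      .groups = "drop") |>
    dplyr::relocate(dplyr::all_of(c(keys, "mean", "sem", "n")))
}

#' Time-course of fixation durations and saccade amplitudes by ordinal index
#'
#' Mean fixation duration and saccade amplitude as a function of their
#' ordinal position within the trial, per spatial-frequency class; used
#' to expose the coarse-to-fine trend (durations grow, amplitudes shrink
#' as the trial unfolds). The experimentally enforced first fixation can
#' be excluded, since it is shaped by the design and the central fixation
#' bias rather than by search.
#'
#' @param fixations,saccades Event tables with `ordinal_index` /
#'   `sac_index`.
#' @param design Trial table providing `sf_class` per trial.
#' @param max_index Largest ordinal index reported; indices beyond the
#'   longest trial yield rows with `n = 0`.
#' @param exclude_first Drop the flagged first fixation.
#' @param per_subject_first Average within subject before the SEM over
#'   subjects.
#' @return Tidy tibble: `measure` (`"fixation_duration"` or
#'   `"saccade_amplitude"`), `index`, `sf_class`, `mean`, `sem`, `n`.
#' @export
timecourse_by_index <- function(fixations, saccades, design, max_index = 15,
                                exclude_first = TRUE, per_subject_first = TRUE) {
  key <- design[, c("subject_id", "trial_id", "sf_class")]
  fx <- fixations
  if (exclude_first && "is_first" %in% names(fx)) fx <- fx[!fx$is_first, , drop = FALSE]
  fx <- fx |>
    dplyr::inner_join(key, by = c("subject_id", "trial_id")) |>
    dplyr::transmute(measure = "fixation_duration", index = .data$ordinal_index,
                     sf_class = .data$sf_class, subject_id = .data$subject_id,
                     value = .data$duration)
  sc <- saccades |>
    dplyr::inner_join(key, by = c("subject_id", "trial_id")) |>
    dplyr::transmute(measure = "saccade_amplitude", index = .data$sac_index,
                     sf_class = .data$sf_class, subject_id = .data$subject_id,
                     value = .data$amplitude)
  d <- dplyr::bind_rows(fx, sc) |> dplyr::filter(.data$index <= max_index)
  if (per_subject_first) {
    d <- d |>
      dplyr::group_by(.data$measure, .data$index, .data$sf_class, .data$subject_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  out <- d |>
    dplyr::group_by(.data$measure, .data$index, .data$sf_class) |>
    dplyr::summarise(mean = mean(.data$value), sem = sem(.data$value),
                     n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(measure = c("fixation_duration", "saccade_amplitude"),
                             index = seq_len(max_index),
                             sf_class = sort(unique(design$sf_class)))
  grid |>
    dplyr::left_join(out, by = c("measure", "index", "sf_class")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Build successive-saccade pairs
#'
#' Pairs each saccade with its predecessor within the same trial and
#' records the change in direction, the amplitude of the later saccade,
#' and (when fixations are supplied) the duration of the intervening
#' fixation — the fixation lying between the two saccades. The endpoint
#' of the later saccade (`end_x`, `end_y`) supports map lookups at
#' saccadic landing points.
#'
#' @param saccades Saccade table (ordered within trial by `sac_index`).
#' @param fixations Optional fixation table used for intervening
#'   durations; pairs whose intervening fixation was filtered out get
#'   `NA`.
#' @return Tibble with one row per saccade pair.
#' @export
saccade_pairs <- function(saccades, fixations = NULL) {
  d <- saccades |>
    dplyr::arrange(.data$subject_id, .data$trial_id, .data$onset_t) |>
    dplyr::group_by(.data$subject_id, .data$trial_id) |>
    dplyr::mutate(prev_direction = dplyr::lag(.data$direction),
                  prev_amplitude = dplyr::lag(.data$amplitude),
                  prev_offset_t = dplyr::lag(.data$offset_t)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_direction)) |>
    dplyr::mutate(angle_change = direction_change(.data$prev_direction, .data$direction),
                  next_amplitude = .data$amplitude)
  d$intervening_duration <- NA_real_
  if (!is.null(fixations) && nrow(d) > 0) {
    for (i in seq_len(nrow(d))) {
      sel <- fixations$subject_id == d$subject_id[i] &
        fixations$trial_id == d$trial_id[i] &
        fixations$start_t >= d$prev_offset_t[i] - 1e-9 &
        fixations$end_t <= d$onset_t[i] + 1e-9
      if (sum(sel) == 1) d$intervening_duration[i] <- fixations$duration[sel]
    }
  }
  d[, c("subject_id", "trial_id", "angle_change", "next_amplitude",
        "prev_amplitude", "intervening_duration", "end_x", "end_y",
        "onset_t", "prev_offset_t")]
}

#' Bin saccade pairs by change in direction
#'
#' Averages successive-saccade amplitude, intervening fixation duration
#' and any endpoint-value columns (`density_value`, `saliency_value`,
#' added beforehand via [lookup_map_values()]) within angular bins of the
#' change in saccade direction. An optional amplitude window restricts
#' the analysis to successive saccades within a given dva interval (used
#' to remove small corrective and rare large saccades when scoring
#' endpoint density).
#'
#' @param pairs Table from [saccade_pairs()], optionally with value
#'   columns attached.
#' @param n_bins Number of equal-width bins over \[0, 180\] (default 9,
#'   i.e. 20-degree bins).
#' @param amplitude_window Optional `c(lo, hi)` in dva applied to
#'   `next_amplitude`.
#' @return Tibble with bin edges and midpoint, `n` per bin (empty bins
#'   kept with `n = 0`), and a `mean_*` column for each available
#'   measure. Bin counts over all bins sum to the number of contributing
#'   pairs.
#' @export
bin_by_direction_change <- function(pairs, n_bins = 9, amplitude_window = NULL) {
  if (!is.null(amplitude_window)) {
    stopifnot(length(amplitude_window) == 2)
    pairs <- pairs[pairs$next_amplitude >= amplitude_window[1] &
                     pairs$next_amplitude <= amplitude_window[2], , drop = FALSE]
  }
  edges <- seq(0, 180, length.out = n_bins + 1)
  bin_of <- cut(pairs$angle_change, edges, include.lowest = TRUE, labels = FALSE)
  vals <- intersect(c("next_amplitude", "intervening_duration",
                      "density_value", "saliency_value"), names(pairs))
  out <- tibble::tibble(bin = seq_len(n_bins),
                        angle_lo = edges[-length(edges)],
                        angle_hi = edges[-1],
                        angle_mid = (edges[-1] + edges[-length(edges)]) / 2,
                        n = as.integer(tabulate(bin_of, nbins = n_bins)))
  for (v in vals) {
    m <- rep(NA_real_, n_bins)
    ok <- !is.na(bin_of) & !is.na(pairs[[v]])
    if (any(ok)) {
      agg <- tapply(pairs[[v]][ok], bin_of[ok], mean)
      m[as.integer(names(agg))] <- as.numeric(agg)
    }
    out[[paste0("mean_", sub("^(next_|intervening_)", "", v))]] <- m
  }
  out
}
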