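#' Generate a 1/f-spectrum background image
#'
#' Random-phase noise whose amplitude spectrum follows `f^(-slope)`
#' radially, emulating the spectral statistics of natural scenes, with an
#' optional amplitude boost for near-horizontal and near-vertical
#' structure. The result is affinely rescaled to gray levels \[0, 255\]
#' (continuous; rounding happens when writing 8-bit PNG).
#'
#' @param width,height Image size in pixels.
#' @param slope Radial spectral exponent (>= 0; 0 gives white noise, 1
#'   the natural-scene-like decline).
#' @param orientation_bias Amplitude modulation in \[0, 1): spectra are
#'   multiplied by `1 + bias * cos(4 theta)`, peaking on the horizontal
#'   and vertical frequency axes.
#' @param seed Optional integer seed; the image is deterministic given
#'   it.
#' @return Numeric matrix (rows = y) of gray levels in \[0, 255\].
#' @export
gen_background <- function(width = 1200, height = 960, slope = 1,
                           orientation_bias = 0, seed = NULL) {
  stopifnot(slope >= 0, orientation_bias >= 0, orientation_bias < 1)
  with_seed(seed, {
    W <- matrix(stats::rnorm(height * width), height, width)
    Fw <- stats::fft(W)
    fx <- fft_freqs(width)
    fy <- fft_freqs(height)
    FX <- matrix(fx, height, width, byrow = TRUE)
    FY <- matrix(fy, height, width, byrow = FALSE)
    r <- sqrt(FX^2 + FY^2)
    amp <- r
    amp[r > 0] <- r[r > 0]^(-slope)
    amp[r == 0] <- 0  # zero DC; mean set by the final rescale
    if (orientation_bias > 0) {
      theta <- atan2(FY, FX)
      amp <- amp * (1 + orientation_bias * cos(4 * theta))
    }
    phase <- Fw / ifelse(Mod(Fw) > 0, Mod(Fw), 1)
    img <- Re(stats::fft(phase * amp, inverse = TRUE)) / length(W)
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1]) * 255
    img
  })
}

#' Default scanpath-generator parameters
#'
#' Ground-truth parameters of the synthetic searcher. The two
#' spatial-frequency classes differ in mean saccade amplitude (low-SF
#' 5.5 dva vs high-SF 4.5 dva) and mean fixation duration (low-SF 260 ms
#' vs high-SF 220 ms), reproducing the direction of the empirical
#' effects; saccade directions mix a direction-maintaining forward mode
#' with a return-biased selective mode; durations grow and amplitudes
#' shrink over the trial (coarse-to-fine drift).
#'
#' @param ... Named overrides of the defaults.
#' @return A `scanpath_params` list.
#' @export
scanpath_params <- function(...) {
  p <- list(
    low  = list(amp_mean = 5.5, amp_sd = 2.0, dur_mean = 260, dur_sd = 60),
    high = list(amp_mean = 4.5, amp_sd = 2.0, dur_mean = 220, dur_sd = 60),
    p_forward = 0.45,     # probability of a direction-maintaining saccade
    p_return = 0.35,      # probability of a reversal, given not forward
    jitter_deg = 15,      # direction jitter SD within a mode
    dur_factor_forward = 0.8,  # preceding-fixation duration scale, forward mode
    dur_factor_return = 1.3,   # preceding-fixation duration scale, return mode
    amp_factor_forward = 0.85, # amplitude scale for forward-mode saccades
    amp_factor_return = 1.2,   # amplitude scale for return saccades
    cf_dur = 8,           # fixation-duration increase per ordinal index (ms)
    cf_amp = 0.15,        # amplitude decrease per ordinal index (dva)
    amp_range = c(1, 12), # truncation bounds for amplitudes (dva)
    dur_min = 80,         # fixation-duration floor (ms)
    first_fix_ms = 125,   # enforced minimum for the first fixation (ms)
    trial_cap = 10000,    # maximum trial duration (ms)
    noise_sd = 0.05,      # position noise SD when rendering traces (dva)
    capture_radius = 1.5, # fixation-to-target distance that ends the trial (dva)
    p_false_alarm = 0.034 # per-trial false-alarm probability on absent trials
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop_config("unknown scanpath parameter: ", nm)
    p[[nm]] <- ov[[nm]]
  }
  stopifnot(p$p_forward >= 0, p$p_forward <= 1, p$jitter_deg >= 0,
            p$low$amp_sd > 0, p$high$dur_sd > 0)
  structure(p, class = "scanpath_params")
}

#' Generate the full experiment design
#'
#' Enumerates the session/block/trial structure: each participant runs
#' `sessions` sessions of 6 blocks (one block per target, order
#' randomized per session) of 25 images; per block between 3 and 7
#' trials are target-absent (about 20%); target positions are drawn
#' uniformly among the 8 grid positions per present trial; and in one
#' designated session the target is drawn at random per trial and its
#' identity is unknown in advance (`sf_class = "unknown"`).
#'
#' @param participants,sessions,images_per_block Design counts (defaults
#'   10, 8, 25; with 6 blocks this yields 12,000 trials).
#' @param absent_range Inclusive range of target-absent trials per
#'   25-image block (scaled proportionally for other block sizes).
#' @param unknown_session Session whose trials have unknown target
#'   identity (`NA` for none).
#' @param n_positions Number of possible target positions.
#' @param seed Optional integer seed.
#' @return Tibble with one row per trial: `subject_id`, `session`,
#'   `block`, `trial_id`, `image_id`, `target_kind`, `target_known`,
#'   `sf_class`, `present`, `position_index`.
#' @export
gen_design <- function(participants = 10, sessions = 8, images_per_block = 25,
                       absent_range = c(3, 7), unknown_session = 7,
                       n_positions = 8, seed = NULL) {
  kinds <- target_kinds()
  with_seed(seed, {
    rows <- vector("list", participants * sessions * length(kinds))
    k <- 0L
    for (s in seq_len(participants)) {
      sid <- sprintf("s%02d", s)
      for (ses in seq_len(sessions)) {
        block_targets <- sample(kinds)
        for (b in seq_along(block_targets)) {
          n_img <- images_per_block
          # absent_range is defined per 25-image block; scale it for
          # smaller blocks, keeping the ~20% absent fraction
          lo <- min(n_img - 1L, max(0L, round(absent_range[1] * n_img / 25)))
          hi <- min(n_img - 1L, max(lo, round(absent_range[2] * n_img / 25)))
          n_abs <- if (hi > lo) sample(lo:hi, 1) else lo
          absent <- if (n_abs > 0) sample(n_img, n_abs) else integer(0)
          known <- is.na(unknown_session) || ses != unknown_session
          kind <- if (known) rep(block_targets[b], n_img) else sample(kinds, n_img, replace = TRUE)
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            subject_id = sid, session = ses, block = b,
            image_id = seq_len(n_img),
            target_kind = kind,
            target_known = known,
            sf_class = sf_class_of(kind, known = known),
            present = !(seq_len(n_img) %in% absent),
            position_index = ifelse(seq_len(n_img) %in% absent, NA_integer_,
                                    sample(n_positions, n_img, replace = TRUE))
          )
        }
      }
    }
    d <- dplyr::bind_rows(rows)
    d$trial_id <- sprintf("%s_t%05d", d$subject_id,
                          stats::ave(seq_len(nrow(d)), d$subject_id, FUN = seq_along))
    dplyr::relocate(d, dplyr::all_of(c("subject_id", "trial_id")))
  })
}

# draw from N(mean, sd) truncated to [lo, hi] by rejection
rtrunc_norm <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

# saccade duration (ms) from the amplitude main sequence
saccade_duration_ms <- function(amplitude) round(21 + 2.2 * amplitude)

#' Generate one synthetic scanpath with known ground truth
#'
#' Alternates fixations and saccades until the trial cap. Fixation
#' durations and saccade amplitudes are drawn from the class-specific
#' distributions with a coarse-to-fine drift over ordinal index. Each
#' saccade either maintains the previous direction (forward mode, with
#' jitter) with probability `p_forward`, or switches: reversals
#' (+180 degrees) with probability `p_return`, otherwise a uniformly
#' random new direction — emulating the bimodal intersaccadic-angle
#' distribution. Forward-mode saccades use short preceding fixations and
#' smaller amplitudes (a less selective default scan); endpoints are kept
#' inside the image extent. When a target position is given, a fixation
#' landing within the capture radius ends the trial as a detection.
#'
#' @param sf `"low"`, `"high"` or `"unknown"` (parameters averaged).
#' @param params A [scanpath_params()].
#' @param target_xy Optional target position `c(x, y)` in dva.
#' @param extent Image extent in dva.
#' @param present Whether a target is present (for false-alarm draws).
#' @param seed Optional integer seed.
#' @return List with `fixations` (tibble: index, x, y, duration,
#'   start_t, is_first), `saccades` (tibble: index, start/end position,
#'   amplitude, direction, duration, onset_t, forward_mode), `detected`,
#'   `search_time` (ms).
#' @export
gen_scanpath <- function(sf = c("low", "high", "unknown"),
                         params = scanpath_params(), target_xy = NULL,
                         extent = image_extent(), present = !is.null(target_xy),
                         seed = NULL) {
  sf <- match.arg(sf)
  cls <- if (sf == "unknown") {
    list(amp_mean = (params$low$amp_mean + params$high$amp_mean) / 2,
         amp_sd = params$low$amp_sd,
         dur_mean = (params$low$dur_mean + params$high$dur_mean) / 2,
         dur_sd = params$low$dur_sd)
  } else params[[sf]]
  with_seed(seed, {
    margin <- 0.5
    xr <- extent$xlim + c(margin, -margin)
    yr <- extent$ylim + c(margin, -margin)
    pos <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    t_now <- 0
    fix <- list(); sac <- list()
    detected <- FALSE
    i <- 1L
    dir_prev <- NULL
    repeat {
      # mode of the *upcoming* saccade drives the preceding fixation:
      # forward (default-scan) saccades follow short fixations and are
      # small; return saccades follow long fixations and are large
      mode <- if (is.null(dir_prev)) "random"
        else if (stats::runif(1) < params$p_forward) "forward"
        else if (stats::runif(1) < params$p_return) "return"
        else "random"
      dur_fac <- switch(mode, forward = params$dur_factor_forward,
                        return = params$dur_factor_return, 1)
      amp_fac <- switch(mode, forward = params$amp_factor_forward,
                        return = params$amp_factor_return, 1)
      dur <- max(params$dur_min,
                 stats::rnorm(1, cls$dur_mean * dur_fac + params$cf_dur * (i - 1),
                              cls$dur_sd))
      if (i == 1L) dur <- max(dur, params$first_fix_ms)
      dur <- round(dur)
      fix[[i]] <- tibble::tibble(index = i, x = pos[1], y = pos[2],
                                 duration = dur, start_t = t_now,
                                 end_t = t_now + dur, is_first = i == 1L)
      t_now <- t_now + dur
      if (detected || t_now >= params$trial_cap) break
      # choose the next saccade
      amp <- rtrunc_norm(cls$amp_mean * amp_fac - params$cf_amp * (i - 1),
                         cls$amp_sd, params$amp_range[1], params$amp_range[2])
      new_pos <- NULL
      for (try in 1:20) {
        dir <- if (mode == "forward" && try <= 10) {
          dir_prev + stats::rnorm(1, 0, params$jitter_deg)
        } else if (mode == "return" && try <= 10) {
          dir_prev + 180 + stats::rnorm(1, 0, params$jitter_deg)
        } else {
          stats::runif(1, 0, 360)
        }
        cand <- pos + amp * c(cos(dir * pi / 180), sin(dir * pi / 180))
        if (cand[1] >= xr[1] && cand[1] <= xr[2] &&
            cand[2] >= yr[1] && cand[2] <= yr[2]) { new_pos <- cand; break }
      }
      if (is.null(new_pos)) {  # aim at the image centre as a fallback
        ctr <- c(mean(xr), mean(yr))
        dir <- atan2(ctr[2] - pos[2], ctr[1] - pos[1]) * 180 / pi
        new_pos <- pos + amp * c(cos(dir * pi / 180), sin(dir * pi / 180))
        new_pos <- pmin(pmax(new_pos, c(xr[1], yr[1])), c(xr[2], yr[2]))
      }
      sdur <- saccade_duration_ms(amp)
      sac[[i]] <- tibble::tibble(
        index = i, start_x = pos[1], start_y = pos[2],
        end_x = new_pos[1], end_y = new_pos[2],
        amplitude = sqrt(sum((new_pos - pos)^2)),
        direction = (atan2(new_pos[2] - pos[2], new_pos[1] - pos[1]) * 180 / pi) %% 360,
        duration = sdur, onset_t = t_now, offset_t = t_now + sdur,
        mode = mode)
      dir_prev <- sac[[i]]$direction
      t_now <- t_now + sdur
      pos <- new_pos
      i <- i + 1L
      if (!is.null(target_xy) && present &&
          sqrt(sum((pos - target_xy)^2)) <= params$capture_radius) {
        detected <- TRUE  # one more fixation on the target, then stop
      }
    }
    if (!present && stats::runif(1) < params$p_false_alarm) detected <- TRUE
    list(fixations = dplyr::bind_rows(fix), saccades = dplyr::bind_rows(sac),
         detected = detected, search_time = t_now)
  })
}

#' Render a scanpath into a raw gaze trace
#'
#' Samples fixations as stationary positions and saccades as
#' minimum-jerk position ramps at the given sampling rate, adding
#' isotropic Gaussian position noise — the inverse of event detection,
#' enabling round-trip recovery tests. Every saccade must span at least
#' 6 samples and 0.5 dva so the round trip is well-posed.
#'
#' @param scanpath Result of [gen_scanpath()].
#' @param rate Sampling rate in Hz (default 1000).
#' @param noise_sd Position noise SD in dva.
#' @param subject_id,trial_id Identifiers stamped on the trace.
#' @param seed Optional integer seed.
#' @return A [gaze_trace()].
#' @export
render_trace <- function(scanpath, rate = 1000, noise_sd = 0.05,
                         subject_id = "s01", trial_id = "t1", seed = NULL) {
  stopifnot(rate > 0)
  dt_ms <- 1000 / rate
  fx <- scanpath$fixations; sc <- scanpath$saccades
  if (nrow(sc) > 0) {
    bad <- sc$amplitude < 0.5 | sc$duration < 6 * dt_ms
    if (any(bad))
      stop_config(sum(bad), " saccade(s) below the detectability floor ",
                  "(>= 0.5 dva and >= 6 samples); adjust generator parameters")
  }
  xs <- list(); ys <- list()
  for (i in seq_len(nrow(fx))) {
    n <- max(1, round(fx$duration[i] / dt_ms))
    xs[[length(xs) + 1]] <- rep(fx$x[i], n)
    ys[[length(ys) + 1]] <- rep(fx$y[i], n)
    if (i <= nrow(sc)) {
      ns <- max(1, round(sc$duration[i] / dt_ms))
      tau <- seq_len(ns) / (ns + 1)
      s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5  # minimum-jerk profile
      xs[[length(xs) + 1]] <- sc$start_x[i] + s * (sc$end_x[i] - sc$start_x[i])
      ys[[length(ys) + 1]] <- sc$start_y[i] + s * (sc$end_y[i] - sc$start_y[i])
    }
  }
  x <- unlist(xs); y <- unlist(ys)
  with_seed(seed, {
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, noise_sd)
      y <- y + stats::rnorm(length(y), 0, noise_sd)
    }
    gaze_trace(t = (seq_along(x) - 1) * dt_ms, x = x, y = y,
               subject_id = subject_id, trial_id = trial_id)
  })
}

#' Generate ground-truth events for a whole design
#'
#' Runs [gen_scanpath()] for each trial of a design, using per-image
#' target positions (dva), and returns pooled fixation and saccade
#' tables in the same shape that detection produces, plus the design
#' augmented with `detected` and `search_time`.
#'
#' @param design Trial table from [gen_design()].
#' @param params A [scanpath_params()].
#' @param positions Optional tibble of target positions per
#'   `(image_id, position_index)` with `x_px`, `y_px` columns.
#' @param px_per_deg Pixels per degree (to convert positions).
#' @param extent Image extent in dva.
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @return List with `fixations`, `saccades` (pooled tibbles) and
#'   `design` (with outcome columns).
#' @export
gen_cohort_events <- function(design, params = scanpath_params(),
                              positions = NULL,
                              px_per_deg = default_px_per_deg(),
                              extent = image_extent(), seed = 1) {
  fixl <- vector("list", nrow(design))
  sacl <- vector("list", nrow(design))
  detected <- logical(nrow(design))
  search_time <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    target_xy <- NULL
    if (isTRUE(tr$present) && !is.null(positions) && !is.na(tr$position_index)) {
      p <- positions[positions$image_id == tr$image_id &
                       positions$position_index == tr$position_index, ]
      if (nrow(p) == 1) target_xy <- c(p$x_px, p$y_px) / px_per_deg
    }
    sp <- gen_scanpath(sf = tr$sf_class, params = params, target_xy = target_xy,
                       extent = extent, present = isTRUE(tr$present),
                       seed = (seed * 7919 + i) %% .Machine$integer.max)
    detected[i] <- sp$detected
    search_time[i] <- sp$search_time
    fixl[[i]] <- dplyr::mutate(sp$fixations, subject_id = tr$subject_id,
                               trial_id = tr$trial_id,
                               ordinal_index = .data$index)
    sacl[[i]] <- dplyr::mutate(sp$saccades, subject_id = tr$subject_id,
                               trial_id = tr$trial_id, sac_index = .data$index)
  }
  design$detected <- detected
  design$search_time <- search_time
  list(fixations = dplyr::bind_rows(fixl), saccades = dplyr::bind_rows(sacl),
       design = design)
}
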