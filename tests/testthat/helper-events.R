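# shared fixtures and independent oracles, all built in code

# piecewise trace builder: alternating fixations (ms at a position) and
# linear ramps between them, 1000 Hz, optional isotropic position noise
make_ramp_trace <- function(segments, noise_sd = 0, seed = 1) {
  xs <- c(); ys <- c()
  pos <- segments[[1]]$pos
  for (seg in segments) {
    n <- seg$ms
    if (seg$type == "fix") {
      xs <- c(xs, rep(seg$pos[1], n)); ys <- c(ys, rep(seg$pos[2], n))
      pos <- seg$pos
    } else {
      tau <- seq_len(n) / (n + 1)
      xs <- c(xs, pos[1] + tau * (seg$pos[1] - pos[1]))
      ys <- c(ys, pos[2] + tau * (seg$pos[2] - pos[2]))
      pos <- seg$pos
    }
  }
  set.seed(seed)
  gaze_trace(t = seq_along(xs) - 1,
             x = xs + rnorm(length(xs), 0, noise_sd),
             y = ys + rnorm(length(ys), 0, noise_sd),
             subject_id = "s01", trial_id = "t1")
}

# a scanpath object with uniform amplitudes / durations drawn directly,
# independent of gen_scanpath (amplitudes 1-15 dva, fixations 100-600 ms)
make_random_scanpath <- function(n_sac = 6, seed = 1,
                                 amp_range = c(1, 15),
                                 dur_range = c(100, 600)) {
  set.seed(seed)
  pos <- c(0, 0)
  t_now <- 0
  fix <- list(); sac <- list()
  for (i in seq_len(n_sac + 1)) {
    dur <- round(runif(1, dur_range[1], dur_range[2]))
    fix[[i]] <- tibble::tibble(index = i, x = pos[1], y = pos[2],
                               duration = dur, start_t = t_now,
                               end_t = t_now + dur, is_first = i == 1)
    t_now <- t_now + dur
    if (i > n_sac) break
    amp <- runif(1, amp_range[1], amp_range[2])
    th <- runif(1, 0, 2 * pi)
    new_pos <- pos + amp * c(cos(th), sin(th))
    sdur <- round(21 + 2.2 * amp)
    sac[[i]] <- tibble::tibble(index = i, start_x = pos[1], start_y = pos[2],
                               end_x = new_pos[1], end_y = new_pos[2],
                               amplitude = amp,
                               direction = (th * 180 / pi) %% 360,
                               duration = sdur, onset_t = t_now,
                               offset_t = t_now + sdur, mode = "random")
    t_now <- t_now + sdur
    pos <- new_pos
  }
  list(fixations = dplyr::bind_rows(fix), saccades = dplyr::bind_rows(sac),
       detected = FALSE, search_time = t_now)
}

# greedy matching of detected to true saccades by onset time
match_events <- function(true_sac, det_sac, tol_ms = 20) {
  used <- rep(FALSE, nrow(det_sac))
  amp_true <- c(); amp_det <- c(); n_matched <- 0L
  for (i in seq_len(nrow(true_sac))) {
    d <- abs(det_sac$onset_t - true_sac$onset_t[i])
    j <- which(!used & d < tol_ms)
    if (length(j)) {
      j <- j[which.min(d[j])]
      used[j] <- TRUE
      n_matched <- n_matched + 1L
      amp_true <- c(amp_true, true_sac$amplitude[i])
      amp_det <- c(amp_det, det_sac$amplitude[j])
    }
  }
  list(n_true = nrow(true_sac), n_matched = n_matched,
       n_extra = sum(!used), amp_true = amp_true, amp_det = amp_det)
}

# brute-force saccade detector: explicit per-sample loops implementing
# the same velocity, threshold, merge, run-length and boundary rules
brute_force_detect <- function(trace, lambda = 6, min_samples = 6,
                               min_amplitude = 0.5, window = 5,
                               merge_gap_ms = 12) {
  n <- nrow(trace)
  dt <- (trace$t[2] - trace$t[1]) / 1000
  m <- (window - 1) / 2
  vx <- numeric(n); vy <- numeric(n)
  for (k in seq_len(n)) {
    mm <- min(m, k - 1, n - k)
    if (mm < 1) next
    sx <- 0; sy <- 0
    for (j in seq_len(mm)) {
      sx <- sx + trace$x[k + j] - trace$x[k - j]
      sy <- sy + trace$y[k + j] - trace$y[k - j]
    }
    vx[k] <- sx / (dt * mm * (mm + 1))
    vy[k] <- sy / (dt * mm * (mm + 1))
  }
  msd <- function(v) sqrt(median(v^2) - median(v)^2)
  ex <- lambda * msd(vx); ey <- lambda * msd(vy)
  supra <- ((vx - median(vx)) / ex)^2 + ((vy - median(vy)) / ey)^2 > 1
  # merge short sub-threshold gaps
  gap <- ceiling(merge_gap_ms / (dt * 1000))
  i <- 1
  while (i <= n) {
    if (!supra[i]) {
      j <- i
      while (j <= n && !supra[j]) j <- j + 1
      if (i > 1 && j <= n && (j - i) < gap) supra[i:(j - 1)] <- TRUE
      i <- j
    } else i <- i + 1
  }
  speed <- sqrt(vx^2 + vy^2)
  out <- list(); prev_end <- 0
  i <- 1
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j <= n && supra[j]) j <- j + 1
      a <- i; b <- j - 1
      if (b - a + 1 >= min_samples) {
        while (a > prev_end + 1 && speed[a - 1] < speed[a]) a <- a - 1
        while (b < n && speed[b + 1] < speed[b]) b <- b + 1
        s_hi <- max(prev_end + 1, a - 2); s_lo <- max(prev_end + 1, a - 6)
        e_lo <- min(n, b + 2); e_hi <- min(n, b + 6)
        prev_end <- b
        p1 <- c(mean(trace$x[s_lo:s_hi]), mean(trace$y[s_lo:s_hi]))
        p2 <- c(mean(trace$x[e_lo:e_hi]), mean(trace$y[e_lo:e_hi]))
        amp <- sqrt(sum((p2 - p1)^2))
        if (amp >= min_amplitude)
          out[[length(out) + 1]] <- c(onset = trace$t[a], offset = trace$t[b],
                                      amplitude = amp)
      }
      i <- j
    } else i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), offset = numeric(), amplitude = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# brute-force KDE: per-cell double loop over grid cells and fixations
brute_kde <- function(x, y, bandwidth, extent, grid = c(128, 128)) {
  nx <- grid[2]; ny <- grid[1]
  cw <- diff(extent$xlim) / nx; ch <- diff(extent$ylim) / ny
  gx <- extent$xlim[1] + (seq_len(nx) - 0.5) * cw
  gy <- extent$ylim[1] + (seq_len(ny) - 0.5) * ch
  M <- matrix(0, ny, nx)
  for (r in seq_len(ny)) {
    for (cc in seq_len(nx)) {
      s <- 0
      for (k in seq_along(x)) {
        s <- s + dnorm(gx[cc], x[k], bandwidth) * dnorm(gy[r], y[k], bandwidth)
      }
      M[r, cc] <- s
    }
  }
  M / sum(M)
}

# closed-form mean of N(mu, sd) truncated (by rejection) to [lo, hi]
trunc_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# closed-form mean of max(lo, X) for X ~ N(mu, sd) (left-censoring)
cens_mean <- function(mu, sd, lo) {
  a <- (lo - mu) / sd
  lo * pnorm(a) + mu * (1 - pnorm(a)) + sd * dnorm(a)
}

# tiny design for cohort-level tests
small_design <- function(subjects = 4, trials_per_class = 6, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(subjects)),
                   sf_class = c("low", "high"),
                   rep = seq_len(trials_per_class),
                   stringsAsFactors = FALSE)
  tibble::tibble(
    subject_id = d$subject_id,
    trial_id = sprintf("%s_%s_%02d", d$subject_id, d$sf_class, d$rep),
    session = 1L, block = 1L,
    image_id = sample(4, nrow(d), replace = TRUE),
    target_kind = ifelse(d$sf_class == "low", "gaussian_blob", "gabor_vertical"),
    target_known = TRUE, sf_class = d$sf_class,
    present = FALSE, position_index = NA_integer_
  )
}
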