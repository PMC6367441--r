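test_that("direction change folds to [0, 180] with the expected symmetries", {
  expect_equal(direction_change(0, 0), 0)
  expect_equal(direction_change(0, 180), 180)
  expect_equal(direction_change(0, 90), 90)
  expect_equal(direction_change(350, 10), 20)  # wraps across 0
  set.seed(9)
  d1 <- runif(200, 0, 360); d2 <- runif(200, 0, 360); rot <- runif(1, 0, 360)
  # left/right turns equivalent; invariant under global rotation
  expect_equal(direction_change(d1, d2), direction_change(d2, d1))
  expect_equal(direction_change(d1 + rot, d2 + rot), direction_change(d1, d2))
  expect_true(all(direction_change(d1, d2) >= 0 & direction_change(d1, d2) <= 180))
})

make_stats <- function(amp, subject = "s01", sf = "low", session = 1) {
  tibble::tibble(subject_id = subject, trial_id = paste0("t", seq_along(amp)),
                 session = session, sf_class = sf, target_kind = "gaussian_blob",
                 present = TRUE, mean_amplitude = amp, mean_duration = 200,
                 search_time = 1000, detected = TRUE)
}

test_that("condition aggregation pools means and flags degenerate groups", {
  st <- make_stats(c(4, 6))
  out <- aggregate_by_condition(st, "amplitude", per_subject_first = FALSE)
  expect_equal(out$mean, 5)
  expect_equal(out$n, 2)
  # a single value yields an undefined SEM, flagged as NA with n = 1
  one <- aggregate_by_condition(make_stats(4.2), "amplitude",
                                per_subject_first = FALSE)
  expect_equal(one$n, 1)
  expect_true(is.na(one$sem))
})

test_that("synthetic cohort recovers the low/high amplitude and duration gap", {
  design <- small_design(subjects = 5, trials_per_class = 8)
  pars <- scanpath_params(trial_cap = 4000,
                          dur_factor_forward = 1, dur_factor_return = 1,
                          amp_factor_forward = 1, amp_factor_return = 1,
                          cf_amp = 0, cf_dur = 0)
  ev <- gen_cohort_events(design, params = pars, seed = 21)
  st <- summarize_trials(ev$fixations, ev$saccades, ev$design)
  agg <- aggregate_by_condition(st, "amplitude")
  lo <- agg$mean[agg$sf_class == "low"]; hi <- agg$mean[agg$sf_class == "high"]
  se <- sqrt(sum(agg$sem^2))
  # oracle: the gap between the truncated-normal means of the two classes
  gap <- trunc_mean(5.5, 2, 1, 12) - trunc_mean(4.5, 2, 1, 12)
  expect_lt(abs((lo - hi) - gap), 2 * se)
  agg_d <- aggregate_by_condition(st, "duration")
  expect_gt(agg_d$mean[agg_d$sf_class == "low"],
            agg_d$mean[agg_d$sf_class == "high"])
})

test_that("amplitude-gap sign is recovered in nearly all replicate cohorts", {
  hits <- 0
  for (r in 1:100) {
    design <- small_design(subjects = 4, trials_per_class = 6, seed = r)
    ev <- gen_cohort_events(design, params = scanpath_params(trial_cap = 2500),
                            seed = 5000 + r)
    st <- summarize_trials(ev$fixations, ev$saccades, ev$design)
    agg <- aggregate_by_condition(st, "amplitude")
    if (agg$mean[agg$sf_class == "low"] > agg$mean[agg$sf_class == "high"])
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("ordinal time-course recovers a planted coarse-to-fine slope", {
  design <- small_design(subjects = 6, trials_per_class = 10)
  pars <- scanpath_params(cf_dur = 10, cf_amp = 0)
  pars$low$dur_sd <- 40; pars$high$dur_sd <- 40
  ev <- gen_cohort_events(design, params = pars, seed = 31)
  tc <- timecourse_by_index(ev$fixations, ev$saccades, ev$design,
                            max_index = 12, exclude_first = TRUE)
  d <- tc[tc$measure == "fixation_duration" & tc$index >= 2 &
            tc$index <= 9 & tc$n > 5, ]
  fit <- lm(mean ~ index, data = d)
  expect_equal(coef(fit)[["index"]], 10, tolerance = 0.2)
})

test_that("time-course handles identical trials and out-of-range indices", {
  fx <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:3), function(s)
    tibble::tibble(subject_id = s, trial_id = paste0(s, "_t1"),
                   start_t = c(0, 200, 500), end_t = c(200, 500, 800),
                   duration = c(200, 300, 300), x = 1, y = 1,
                   ordinal_index = 1:3, is_first = c(TRUE, FALSE, FALSE))))
  sc <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:3), function(s)
    tibble::tibble(subject_id = s, trial_id = paste0(s, "_t1"),
                   onset_t = c(195, 495), offset_t = c(200, 500),
                   amplitude = c(5, 3), direction = 0, duration = 5,
                   sac_index = 1:2)))
  design <- tibble::tibble(subject_id = sprintf("s%02d", 1:3),
                           trial_id = paste0(subject_id, "_t1"),
                           sf_class = "low")
  tc <- timecourse_by_index(fx, sc, design, max_index = 6)
  dur <- tc[tc$measure == "fixation_duration", ]
  expect_equal(dur$sem[dur$n == 3], c(0, 0))  # identical across subjects
  expect_equal(sum(dur$n == 0), 4)            # indices 1 (excluded), 4:6
  amp <- tc[tc$measure == "saccade_amplitude", ]
  expect_equal(amp$mean[amp$index == 1 & amp$n > 0], 5)
})

test_that("direction-change bins expose the two-mode structure", {
  design <- small_design(subjects = 5, trials_per_class = 10)
  ev <- gen_cohort_events(design, params = scanpath_params(trial_cap = 5000),
                          seed = 41)
  pairs <- saccade_pairs(ev$saccades, ev$fixations)
  bins <- bin_by_direction_change(pairs)
  expect_equal(nrow(bins), 9)
  expect_equal(sum(bins$n), nrow(pairs))
  # forward mode: short intervening fixations; return mode: long ones
  expect_gt(bins$mean_duration[9], bins$mean_duration[1])
  # the angle distribution is bimodal: ends heavier than the middle
  expect_gt(bins$n[1], bins$n[5])
  expect_gt(bins$n[9], bins$n[5])
})

test_that("a memoryless random walker yields a flat angle-change histogram", {
  set.seed(55)
  n <- 4000
  sac <- tibble::tibble(subject_id = "s01", trial_id = "t1",
                        onset_t = seq(0, by = 300, length.out = n),
                        offset_t = seq(40, by = 300, length.out = n),
                        amplitude = runif(n, 1, 10),
                        direction = runif(n, 0, 360),
                        end_x = 0, end_y = 0,
                        duration = 40, sac_index = seq_len(n))
  bins <- bin_by_direction_change(saccade_pairs(sac))
  expect_true(all(abs(bins$n - (n - 1) / 9) / ((n - 1) / 9) < 0.25))
})

test_that("the amplitude window restricts the endpoint analysis", {
  pairs <- tibble::tibble(subject_id = "s", trial_id = "t",
                          angle_change = c(10, 90, 170),
                          next_amplitude = c(2, 5, 7),
                          prev_amplitude = 4,
                          intervening_duration = c(150, 200, 300),
                          end_x = 1, end_y = 1, onset_t = 1, prev_offset_t = 0)
  full <- bin_by_direction_change(pairs)
  expect_equal(sum(full$n), 3)
  win <- bin_by_direction_change(pairs, amplitude_window = c(3, 8))
  expect_equal(sum(win$n), 2)  # the 2-dva successive saccade is excluded
  expect_true(all(win$n[win$angle_lo == 0] == 0))
})

test_that("detection and false-alarm rates aggregate over the right trials", {
  st <- tibble::tibble(
    subject_id = rep(c("s01", "s02"), each = 4),
    trial_id = paste0("t", 1:8), session = 1, sf_class = "low",
    target_kind = "gaussian_blob",
    present = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    detected = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    mean_amplitude = 5, mean_duration = 200, search_time = 1000)
  hit <- aggregate_by_condition(st, "detection", per_subject_first = FALSE)
  expect_equal(hit$mean, 3 / 5)
  fa <- aggregate_by_condition(st, "false_alarm", per_subject_first = FALSE)
  expect_equal(fa$mean, 1 / 3)
})
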