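fit_radial_slope <- function(img, f_range = c(0.02, 0.3)) {
  A <- amplitude_spectrum(img, px_per_deg = 1)  # cycles per pixel
  rs <- radial_spectrum(A, n_bins = 60)
  rs <- rs[rs$f >= f_range[1] & rs$f <= f_range[2] & rs$amplitude > 0, ]
  coef(lm(log(rs$amplitude) ~ log(rs$f)))[[2]]
}

test_that("background spectra follow the requested power law", {
  flat <- gen_background(256, 256, slope = 0, seed = 1)
  expect_lt(abs(fit_radial_slope(flat)), 0.1)
  pink <- gen_background(256, 256, slope = 1, seed = 1)
  expect_equal(fit_radial_slope(pink), -1, tolerance = 0.1)
  expect_identical(gen_background(128, 128, seed = 9),
                   gen_background(128, 128, seed = 9))
  img <- gen_background(128, 160, seed = 2)
  expect_equal(dim(img), c(160, 128))  # rows = y, cols = x
  expect_true(min(img) >= 0 && max(img) <= 255)
})

test_that("an orientation bias boosts horizontal/vertical structure", {
  img <- gen_background(256, 256, slope = 1, orientation_bias = 0.5, seed = 3)
  A <- amplitude_spectrum(img, px_per_deg = 1)
  f <- fft_freqs(256, 1, shifted = TRUE)
  R <- sqrt(outer(f^2, f^2, `+`))
  theta <- atan2(outer(f, 0 * f, `+`), outer(0 * f, f, `+`))  # row=fy, col=fx
  band <- R > 0.05 & R < 0.3
  axis_cells <- band & (abs(cos(2 * theta)) > 0.9)   # near 0/90/180/270 deg
  diag_cells <- band & (abs(cos(2 * theta)) < 0.3)
  expect_gt(mean(A[axis_cells]), 1.3 * mean(A[diag_cells]))
})

test_that("the default design enumerates the full experiment", {
  d <- gen_design(seed = 2)
  expect_equal(nrow(d), 12000)  # 10 x 8 x 6 x 25
  # per block, between 3 and 7 target-absent trials
  n_abs <- tapply(!d$present,
                  paste(d$subject_id, d$session, d$block), sum)
  expect_true(all(n_abs >= 3 & n_abs <= 7))
  expect_true(mean(!d$present) >= 0.12 && mean(!d$present) <= 0.28)
  # positions uniform among 8; absent trials have none
  expect_true(all(is.na(d$position_index[!d$present])))
  expect_true(all(d$position_index[d$present] %in% 1:8))
  # mean appearances per (target, image, position) combination ~ 8
  pres <- d[d$present, ]
  counts <- table(pres$target_kind, pres$image_id, pres$position_index)
  expect_equal(mean(counts), 8, tolerance = 0.03)
  # session 7 targets are drawn per trial and unknown in advance
  s7 <- d[d$session == 7, ]
  expect_true(all(s7$sf_class == "unknown"))
  expect_gt(length(unique(paste(s7$block, s7$target_kind))), 6)
  expect_true(all(d$sf_class[d$session != 7] %in% c("low", "high")))
  # reproducible and scalable
  expect_identical(d, gen_design(seed = 2))
  expect_equal(nrow(gen_design(participants = 3, sessions = 2, seed = 1)),
               3 * 2 * 6 * 25)
})

test_that("forced forward mode maintains direction exactly", {
  big <- list(xlim = c(-1e5, 1e5), ylim = c(-1e5, 1e5))
  sp <- gen_scanpath("low", scanpath_params(p_forward = 1, jitter_deg = 0,
                                            trial_cap = 4000),
                     extent = big, seed = 6)
  ch <- direction_change(head(sp$saccades$direction, -1),
                         tail(sp$saccades$direction, -1))
  expect_equal(ch, rep(0, length(ch)), tolerance = 1e-9)
})

test_that("generated event statistics match the parameterized amounts", {
  pars <- scanpath_params(trial_cap = 3000,
                          dur_factor_forward = 1, dur_factor_return = 1,
                          amp_factor_forward = 1, amp_factor_return = 1,
                          cf_amp = 0, cf_dur = 0)
  amps <- list(low = c(), high = c())
  durs <- list(low = c(), high = c())
  for (s in 1:200) {
    cls <- if (s %% 2) "low" else "high"
    sp <- gen_scanpath(cls, pars, seed = 3000 + s)
    amps[[cls]] <- c(amps[[cls]], sp$saccades$amplitude)
    durs[[cls]] <- c(durs[[cls]], sp$fixations$duration[!sp$fixations$is_first])
  }
  for (cls in c("low", "high")) {
    # oracle: closed-form mean of the truncated sampling distributions
    amp_expected <- trunc_mean(pars[[cls]]$amp_mean, pars[[cls]]$amp_sd,
                               pars$amp_range[1], pars$amp_range[2])
    dur_expected <- cens_mean(pars[[cls]]$dur_mean, pars[[cls]]$dur_sd,
                              pars$dur_min)
    expect_lt(abs(mean(amps[[cls]]) - amp_expected),
              3 * sd(amps[[cls]]) / sqrt(length(amps[[cls]])))
    expect_lt(abs(mean(durs[[cls]]) - dur_expected),
              3 * sd(durs[[cls]]) / sqrt(length(durs[[cls]])) + 1)
  }
  expect_gt(mean(amps$low), mean(amps$high))
  expect_gt(mean(durs$low), mean(durs$high))
})

test_that("rendered traces invert generation faithfully", {
  # hand-built scanpath: 300 ms + 20 ms saccade of 5 dva + 300 ms
  sp <- list(fixations = tibble::tibble(index = 1:2, x = c(5, 10), y = c(5, 5),
                                        duration = c(300, 300),
                                        start_t = c(0, 320),
                                        end_t = c(300, 620),
                                        is_first = c(TRUE, FALSE)),
             saccades = tibble::tibble(index = 1, start_x = 5, start_y = 5,
                                       end_x = 10, end_y = 5, amplitude = 5,
                                       direction = 0, duration = 20,
                                       onset_t = 300, offset_t = 320,
                                       mode = "random"))
  tr <- render_trace(sp, noise_sd = 0.02, seed = 8)
  expect_equal(nrow(tr), 620)
  det <- detect_saccades(tr)
  expect_equal(nrow(det), 1)
  expect_equal(det$amplitude, 5, tolerance = 0.05)

  # zero noise keeps fixation samples constant
  tr0 <- render_trace(sp, noise_sd = 0)
  expect_equal(unique(tr0$x[1:300]), 5)
  expect_identical(render_trace(sp, seed = 4), render_trace(sp, seed = 4))

  # events below the detectability floor are rejected
  bad <- sp
  bad$saccades$amplitude <- 0.3
  expect_error(render_trace(bad), "floor")
})

test_that("full round trip recovers events and classes across a cohort", {
  n_true <- 0; n_matched <- 0; n_extra <- 0; amp_err <- c()
  for (s in 1:30) {
    sp <- gen_scanpath(if (s %% 2) "low" else "high",
                       scanpath_params(trial_cap = 4000), seed = 9000 + s)
    tr <- render_trace(sp, seed = 9500 + s)
    det <- detect_saccades(tr)
    m <- match_events(sp$saccades, det)
    n_true <- n_true + m$n_true; n_matched <- n_matched + m$n_matched
    n_extra <- n_extra + m$n_extra
    amp_err <- c(amp_err, abs(m$amp_det - m$amp_true))
  }
  expect_gte(n_matched / n_true, 0.95)
  expect_lte(n_extra / n_true, 0.05)
  expect_lt(max(amp_err), 0.2)
})
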