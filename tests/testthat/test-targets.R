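test_that("all six targets render normalized with the stated structure", {
  imgs <- lapply(target_kinds(), function(k) make_target(target_spec(k)))
  names(imgs) <- target_kinds()

  for (k in target_kinds()) {
    expect_identical(max(abs(imgs[[k]]$values)), 1, label = k)
    expect_true(nrow(imgs[[k]]$values) %% 2 == 1, label = k)
  }
  # blob peaks at its centre pixel
  blob <- imgs$gaussian_blob$values
  ctr <- (nrow(blob) + 1) / 2
  expect_equal(blob[ctr, ctr], 1)
  # all stimuli but the blob are near zero mean
  for (k in setdiff(target_kinds(), "gaussian_blob")) {
    expect_lt(abs(mean(imgs[[k]]$values)), 1e-2, label = k)
  }
  # negative hat is the elementwise negation of the positive hat
  expect_equal(imgs$mexican_hat_neg$values, -imgs$mexican_hat_pos$values)
  # horizontal gabor is the transpose of the vertical one
  expect_equal(imgs$gabor_horizontal$values, t(imgs$gabor_vertical$values))
  # cross is the half-contrast sum of the two gabors (already unit peak)
  expect_equal(imgs$gabor_cross$values,
               (imgs$gabor_vertical$values + imgs$gabor_horizontal$values) / 2,
               tolerance = 1e-12)
})

test_that("mexican hat peaks positively at the centre (closed-form oracle)", {
  # oracle: difference of two unit-integral 2-D Gaussians on a fine grid
  d <- seq(-2, 2, by = 0.005)
  g <- function(r2, s) exp(-r2 / (2 * s^2)) / (2 * pi * s^2)
  r2 <- outer(d^2, d^2, `+`)
  dog <- g(r2, 0.2) - g(r2, 0.4)
  expect_equal(which(dog == max(dog), arr.ind = TRUE)[1, ],
               c(row = (length(d) + 1) / 2, col = (length(d) + 1) / 2))
  expect_gt(max(dog), 0)
  # the rendered target shares both properties
  hat <- make_target(target_spec("mexican_hat_pos"))$values
  ctr <- (nrow(hat) + 1) / 2
  expect_equal(hat[ctr, ctr], 1)  # centre is the global maximum
})

test_that("target spectra match their closed forms", {
  blob <- make_target(target_spec("gaussian_blob"))
  # spatial sigma 0.4 dva -> frequency sigma 1 / (2 pi 0.4) = 0.3979 cyc/deg
  expect_equal(spectrum_gaussian_sigma(blob), 1 / (2 * pi * 0.4),
               tolerance = 0.01)
  gv <- make_target(target_spec("gabor_vertical"))
  pk <- spectrum_peak(gv)
  expect_equal(abs(pk$fx), 8, tolerance = 0.01)
  expect_equal(pk$fy, 0, tolerance = 0.05)
  # the two hats have identical amplitude spectra to machine precision
  hp <- amplitude_spectrum(make_target(target_spec("mexican_hat_pos"))$values)
  hn <- amplitude_spectrum(make_target(target_spec("mexican_hat_neg"))$values)
  expect_equal(hp, hn, tolerance = 1e-12)
})

test_that("normalize_amplitude rescales to unit amplitude and rejects zeros", {
  expect_equal(normalize_amplitude(matrix(0.5, 3, 3)), matrix(1, 3, 3))
  expect_equal(normalize_amplitude(c(-2, 1)), c(-1, 0.5))
  expect_error(normalize_amplitude(matrix(0, 2, 2)), "degenerate")
})

test_that("target_spec validates its inputs", {
  expect_error(target_spec("gaussian_blob", alpha = 0), "alpha")
  expect_error(target_spec("gaussian_blob", alpha = 0.6), "alpha")
  expect_error(target_spec("pyramid"), "arg")
  expect_error(target_spec("gaussian_blob", support_px = 10), "odd")
  expect_error(target_spec("gaussian_blob", support_px = 11), "3 sigma")
})

test_that("embed_target implements the luminance equation", {
  L <- 100
  one_px <- structure(list(
    values = {
      m <- matrix(0, 5, 5); m[3, 3] <- 1; m
    },
    spec = list(alpha = 0.15)  # minimal stand-in spec for a hand-built patch
  ), class = "target_image")

  bg0 <- luminance_image(matrix(0, 20, 20), L_max = L)
  out <- embed_target(bg0, one_px, position = c(10, 10), alpha = 0.15)
  expect_equal(out$values[10, 10], 0.30 * L)
  expect_equal(out$values[1, 1], 0.15 * L)
  expect_equal(sum(out$values != 0.15 * L), 1)

  # alpha = 0 collapses to the background
  bg <- luminance_image(matrix(runif(400, 0, L), 20, 20), L_max = L)
  expect_equal(embed_target(bg, one_px, c(10, 10), alpha = 0)$values, bg$values)

  # saturation case: background at L_max, target at +1 covering the image
  allpos <- structure(list(values = matrix(1, 19, 19), spec = one_px$spec),
                      class = "target_image")
  bgmax <- luminance_image(matrix(L, 19, 19), L_max = L)
  out <- embed_target(bgmax, allpos, c(10, 10), alpha = 0.25)
  expect_equal(out$values, matrix(L, 19, 19))

  expect_error(embed_target(bg0, one_px, c(2, 2), alpha = 0.15), "bounds")
  expect_error(embed_target(bg0, one_px, c(10, 10), alpha = 0.7), "alpha")
})

test_that("embedding preserves the displayable range on random inputs", {
  set.seed(42)
  L <- 100
  for (i in 1:1000) {
    alpha <- runif(1, .Machine$double.eps, 0.5)
    bg <- luminance_image(matrix(runif(64, 0, L), 8, 8), L_max = L)
    tv <- matrix(runif(9, -1, 1), 3, 3)
    tgt <- structure(list(values = tv / max(abs(tv)),
                          spec = list(alpha = alpha)),
                     class = "target_image")
    out <- embed_target(bg, tgt, c(4, 4), alpha = alpha)
    expect_true(min(out$values) >= 0 && max(out$values) <= L)
  }
})

test_that("gray/luminance conversion is a gamma power law with exact round trip", {
  expect_equal(gray_to_luminance(0), 0)
  expect_equal(gray_to_luminance(255, gamma = 2.2, L_max = 100), 100)
  expect_equal(gray_to_luminance(128, gamma = 2, L_max = 100), 25.21,
               tolerance = 1e-3)
  g <- matrix(0:255, 16, 16)
  lum <- gray_to_luminance(g, gamma = 2.2, L_max = 100)
  back <- luminance_to_gray(lum)
  expect_equal(as.vector(back), as.vector(g))
  expect_equal(attr(back, "n_clipped"), 0L)
  # out-of-range inverse inputs are clipped and counted
  expect_warning(out <- luminance_to_gray(matrix(c(-5, 50, 120), 1, 3),
                                          gamma = 2.2, L_max = 100),
                 "clipped")
  expect_equal(attr(out, "n_clipped"), 2)
  expect_equal(as.vector(out)[c(1, 3)], c(0L, 255L))
})

test_that("target positions: one per rectangle, inside the margin, reproducible", {
  p <- sample_target_positions(c(1200, 960), seed = 7)
  expect_equal(nrow(p), 8)
  expect_setequal(p$position_index, 1:8)
  expect_true(all(p$x_px >= 100 & p$x_px <= 1100))
  expect_true(all(p$y_px >= 100 & p$y_px <= 860))
  # one position in each 300 x 480 rectangle
  expect_setequal(paste(p$row, p$col), paste(rep(1:2, each = 4), rep(1:4, 2)))
  expect_true(all(p$x_px > (p$col - 1) * 300 & p$x_px <= p$col * 300))
  expect_true(all(p$y_px > (p$row - 1) * 480 & p$y_px <= p$row * 480))
  expect_identical(p, sample_target_positions(c(1200, 960), seed = 7))
  expect_error(sample_target_positions(c(300, 300), margin_px = 200), "feasible")
})
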