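#' Supported search-target kinds
#'
#' Six low-level targets differing in orientation and spatial-frequency
#' content: an isotropic Gaussian blob, a positive and a negative Mexican
#' hat (difference of Gaussians), a vertical and a horizontal Gabor, and a
#' Gabor cross (the mean of the two Gabors). Blob and hats are the
#' low-spatial-frequency group; the Gabors and the cross the
#' high-spatial-frequency group.
#'
#' @return Character vector of the six target kinds.
#' @export
target_kinds <- function() {
  c("gaussian_blob", "mexican_hat_pos", "mexican_hat_neg",
    "gabor_vertical", "gabor_horizontal", "gabor_cross")
}

#' Map target kinds to their spatial-frequency class
#'
#' @param kind Character vector of target kinds.
#' @param known Logical (recycled); `FALSE` marks trials where the target
#'   identity was not known in advance, whose class is `"unknown"`.
#' @return Character vector with values `"low"`, `"high"` or `"unknown"`.
#' @export
sf_class_of <- function(kind, known = TRUE) {
  low <- c("gaussian_blob", "mexican_hat_pos", "mexican_hat_neg")
  high <- c("gabor_vertical", "gabor_horizontal", "gabor_cross")
  cls <- ifelse(kind %in% low, "low", ifelse(kind %in% high, "high", NA_character_))
  if (anyNA(cls)) stop_config("unknown target kind: ", paste(unique(kind[is.na(cls)]), collapse = ", "))
  known <- rep_len(known, length(cls))
  cls[!known] <- "unknown"
  cls
}

#' Parametric description of a search target
#'
#' Fixed geometry per kind: the blob has a spatial standard deviation of
#' 0.4 dva; the Mexican hats are differences of unit-integral Gaussians
#' with standard deviations 0.2 and 0.4 dva; the Gabors have a carrier of
#' 8 cyc/dva and an elliptic Gaussian envelope with standard deviations
#' 0.06 dva (across the bars) and 0.32 dva (along the bars).
#'
#' @param kind One of [target_kinds()].
#' @param alpha Target contrast as a fraction of the maximum displayable
#'   luminance; must lie in (0, 0.5] so that embedding preserves the
#'   displayable range. In practice this contrast is calibrated per
#'   target in a pilot so detection sits near threshold; 0.15 is a
#'   package default, not a calibrated value.
#' @param px_per_deg Pixels per degree of visual angle.
#' @param support_px Odd side length of the rendered patch in pixels;
#'   `NULL` chooses the smallest odd size covering +/- 4 standard
#'   deviations of the widest Gaussian component (truncation error below
#'   1e-3 of the peak).
#' @return A `target_spec` object (list).
#' @export
target_spec <- function(kind, alpha = 0.15, px_per_deg = default_px_per_deg(),
                        support_px = NULL) {
  kind <- match.arg(kind, target_kinds())
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 0.5)
    stop_config("alpha must lie in (0, 0.5]")
  if (!is.numeric(px_per_deg) || px_per_deg <= 0)
    stop_config("px_per_deg must be positive")
  geom <- switch(kind,
    gaussian_blob   = list(sigma = 0.4),
    mexican_hat_pos = list(sigma = c(0.2, 0.4)),
    mexican_hat_neg = list(sigma = c(0.2, 0.4)),
    gabor_vertical  = ,
    gabor_horizontal = ,
    gabor_cross     = list(sigma = c(0.06, 0.32), carrier_freq = 8)
  )
  sigma_max <- max(geom$sigma)
  if (is.null(support_px)) {
    support_px <- odd_ceiling(2 * 4 * sigma_max * px_per_deg + 1)
  }
  support_px <- as.integer(support_px)
  if (support_px %% 2 == 0) stop_config("support_px must be odd")
  half_deg <- (support_px - 1) / 2 / px_per_deg
  if (half_deg < 3 * sigma_max)
    stop_config("support_px too small: patch must contain +/- 3 sigma of the widest component")
  structure(
    c(list(kind = kind, alpha = alpha, px_per_deg = px_per_deg,
           support_px = support_px), geom),
    class = "target_spec"
  )
}

# coordinate grids (dva) for a rendered patch; centre pixel at (0, 0)
patch_grid <- function(support_px, px_per_deg) {
  d <- (seq_len(support_px) - (support_px + 1) / 2) / px_per_deg
  list(x = matrix(d, support_px, support_px, byrow = TRUE),
       y = matrix(d, support_px, support_px, byrow = FALSE))
}

# unit-integral isotropic 2-D Gaussian evaluated at (x, y) dva
gauss2_unit <- function(x, y, sigma) {
  exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Rescale an array to unit amplitude
#'
#' Divides by the maximum absolute value so that `max(abs(out)) == 1`.
#'
#' @param values Numeric array, not identically zero.
#' @return Array of the same shape with unit amplitude.
#' @export
normalize_amplitude <- function(values) {
  m <- max(abs(values))
  if (!is.finite(m) || m == 0) stop_config("cannot normalize an all-zero (degenerate) target")
  values / m
}

#' Render a search target
#'
#' Evaluates the closed-form stimulus of `spec` on a pixel grid centred on
#' the patch centre and normalizes it to unit amplitude. The negative
#' Mexican hat is the elementwise negation of the positive one; the Gabor
#' cross is the mean of the vertical and the horizontal Gabor (each at
#' half contrast) before renormalization.
#'
#' @param spec A [target_spec()].
#' @return A `target_image`: list with `values` (square matrix in
#'   \[-1, 1\], rows = y, cols = x) and `spec`.
#' @export
make_target <- function(spec) {
  stopifnot(inherits(spec, "target_spec"))
  g <- patch_grid(spec$support_px, spec$px_per_deg)
  gabor <- function(xa, ya) {  # carrier along xa, envelope sigmas (across, along)
    cos(2 * pi * spec$carrier_freq * xa) *
      exp(-(xa^2 / (2 * spec$sigma[1]^2) + ya^2 / (2 * spec$sigma[2]^2)))
  }
  values <- switch(spec$kind,
    gaussian_blob = exp(-(g$x^2 + g$y^2) / (2 * spec$sigma^2)),
    mexican_hat_pos = gauss2_unit(g$x, g$y, spec$sigma[1]) -
      gauss2_unit(g$x, g$y, spec$sigma[2]),
    mexican_hat_neg = -(gauss2_unit(g$x, g$y, spec$sigma[1]) -
      gauss2_unit(g$x, g$y, spec$sigma[2])),
    gabor_vertical = gabor(g$x, g$y),
    gabor_horizontal = gabor(g$y, g$x),
    gabor_cross = (gabor(g$x, g$y) + gabor(g$y, g$x)) / 2
  )
  structure(list(values = normalize_amplitude(values), spec = spec),
            class = "target_image")
}

#' Construct a luminance image
#'
#' @param values Matrix of luminances in cd/m^2, all within \[0, L_max\].
#' @param L_max Maximum displayable luminance (cd/m^2).
#' @param gamma Exponent of the power function used for the gray-level
#'   conversion of this image.
#' @return A `luminance_image` object.
#' @export
luminance_image <- function(values, L_max = 100, gamma = 2.2) {
  stopifnot(is.matrix(values), L_max > 0, gamma > 0)
  if (min(values) < 0 || max(values) > L_max)
    stop_config("luminance values must lie in [0, L_max]")
  structure(list(values = values, L_max = L_max, gamma = gamma),
            class = "luminance_image")
}

#' Convert 8-bit gray levels to luminance
#'
#' Uses the monitor power function `L = L_max * (gray / 255) ^ gamma`.
#'
#' @param gray Numeric array of gray levels in \[0, 255\].
#' @param gamma Power-function exponent (> 0).
#' @param L_max Maximum luminance in cd/m^2.
#' @return A [luminance_image()] when `gray` is a matrix, otherwise a
#'   numeric array of luminances.
#' @export
gray_to_luminance <- function(gray, gamma = 2.2, L_max = 100) {
  stopifnot(gamma > 0, L_max > 0)
  if (min(gray) < 0 || max(gray) > 255) stop_config("gray levels must lie in [0, 255]")
  lum <- L_max * (gray / 255)^gamma
  if (is.matrix(gray)) luminance_image(lum, L_max = L_max, gamma = gamma) else lum
}

#' Convert luminance back to 8-bit gray levels
#'
#' Inverts the fitted power function and rounds to integer gray levels.
#' Input values outside \[0, L_max\] are clipped; the number of clipped
#' pixels is returned in the `n_clipped` attribute.
#'
#' @param lum A [luminance_image()] or numeric array of luminances.
#' @param gamma,L_max Conversion parameters; taken from the
#'   `luminance_image` when one is supplied.
#' @return Integer array of gray levels in \[0, 255\] with attribute
#'   `n_clipped`.
#' @export
luminance_to_gray <- function(lum, gamma = 2.2, L_max = 100) {
  if (inherits(lum, "luminance_image")) {
    gamma <- lum$gamma; L_max <- lum$L_max; lum <- lum$values
  }
  n_clip <- sum(lum < 0 | lum > L_max)
  if (n_clip > 0) warning(n_clip, " luminance value(s) outside [0, L_max] clipped")
  lum <- pmin(pmax(lum, 0), L_max)
  gray <- round(255 * (lum / L_max)^(1 / gamma))
  storage.mode(gray) <- "integer"
  attr(gray, "n_clipped") <- n_clip
  gray
}

#' Embed a target into a background luminance image
#'
#' Rescales the background to the range \[alpha, 1 - alpha\] * L_max and
#' adds the target with luminance amplitude alpha * L_max:
#' `I_fin = alpha * L_max + (1 - 2 alpha) * I_L + alpha * L_max * T`,
#' with the target zero-padded outside its footprint. For alpha in
#' \[0, 0.5\] the result never leaves the displayable range \[0, L_max\];
#' alpha = 0 is the degenerate case returning the rescaled-free
#' background unchanged.
#'
#' @param background A [luminance_image()].
#' @param target A [make_target()] result (values in \[-1, 1\]).
#' @param position Centre of the target footprint as `c(x, y)` in 1-based
#'   pixel coordinates (x = column, y = row).
#' @param alpha Contrast fraction in \[0, 0.5\]; defaults to the value in
#'   the target's spec.
#' @return A `luminance_image` of the composed stimulus.
#' @export
embed_target <- function(background, target, position, alpha = NULL) {
  stopifnot(inherits(background, "luminance_image"), inherits(target, "target_image"))
  alpha <- alpha %||% target$spec$alpha
  if (alpha < 0 || alpha > 0.5) stop_config("alpha must lie in [0, 0.5]")
  Tv <- target$values
  half <- (nrow(Tv) - 1) / 2
  cx <- round(position[1]); cy <- round(position[2])
  nr <- nrow(background$values); nc <- ncol(background$values)
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc)
    stop_config("target footprint exceeds image bounds at position (",
                cx, ", ", cy, ")")
  L <- background$L_max
  out <- alpha * L + (1 - 2 * alpha) * background$values
  out[rows, cols] <- out[rows, cols] + alpha * L * Tv
  luminance_image(out, L_max = L, gamma = background$gamma)
}

#' Sample one target position per grid rectangle
#'
#' Lays a grid of `n_cols` x `n_rows` rectangles over the image and draws
#' one uniformly random integer pixel position per rectangle, constrained
#' to lie at least `margin_px` from every image border so the target is
#' never cut off.
#'
#' @param image_size_px Image size `c(width, height)` in pixels.
#' @param n_cols,n_rows Grid dimensions (default 4 x 2, eight positions).
#' @param margin_px Minimum distance from every image border in pixels.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Tibble with `position_index`, grid `col`/`row`, and `x_px`,
#'   `y_px` (1-based pixel coordinates).
#' @export
sample_target_positions <- function(image_size_px = c(1200, 960), n_cols = 4,
                                    n_rows = 2, margin_px = 100, seed = NULL) {
  w <- image_size_px[1]; h <- image_size_px[2]
  xb <- round(seq(0, w, length.out = n_cols + 1))
  yb <- round(seq(0, h, length.out = n_rows + 1))
  with_seed(seed, {
    out <- vector("list", n_cols * n_rows)
    k <- 0L
    for (r in seq_len(n_rows)) {
      for (cc in seq_len(n_cols)) {
        lo_x <- max(xb[cc] + 1, margin_px); hi_x <- min(xb[cc + 1], w - margin_px)
        lo_y <- max(yb[r] + 1, margin_px); hi_y <- min(yb[r + 1], h - margin_px)
        if (lo_x > hi_x || lo_y > hi_y)
          stop_config("no feasible position in rectangle (", r, ", ", cc,
                      "): margin too large for the image")
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          position_index = k, col = cc, row = r,
          x_px = sample(lo_x:hi_x, 1L), y_px = sample(lo_y:hi_y, 1L)
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
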