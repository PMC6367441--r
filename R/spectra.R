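#' Amplitude spectrum of an image patch
#'
#' Magnitude of the 2-D discrete Fourier transform (unnormalized
#' convention), with the zero-frequency bin moved to the matrix centre.
#' Frequency axes in cyc/deg are attached as attributes `fx` (columns)
#' and `fy` (rows) when `px_per_deg` is given.
#'
#' @param patch Numeric matrix (typically a luminance patch).
#' @param px_per_deg Pixels per degree; `NULL` omits the frequency axes.
#' @return Non-negative matrix of the same size as `patch`.
#' @export
amplitude_spectrum <- function(patch, px_per_deg = NULL) {
  stopifnot(is.matrix(patch))
  A <- fftshift2(Mod(stats::fft(patch)))
  if (!is.null(px_per_deg)) {
    attr(A, "fx") <- fft_freqs(ncol(patch), px_per_deg, shifted = TRUE)
    attr(A, "fy") <- fft_freqs(nrow(patch), px_per_deg, shifted = TRUE)
  }
  A
}

# zero-pad a patch into the centre of a pad x pad matrix
zero_pad <- function(values, pad) {
  stopifnot(pad >= max(dim(values)))
  P <- matrix(0, pad, pad)
  ro <- floor((pad - nrow(values)) / 2)
  co <- floor((pad - ncol(values)) / 2)
  P[ro + seq_len(nrow(values)), co + seq_len(ncol(values))] <- values
  P
}

#' Radially averaged amplitude spectrum
#'
#' Averages a (zero-frequency-centred) amplitude spectrum within annular
#' frequency bins.
#'
#' @param amplitude Matrix from [amplitude_spectrum()] with frequency-axis
#'   attributes, or any matrix together with explicit `fx`, `fy`.
#' @param fx,fy Frequency axes (cyc/deg) for columns and rows.
#' @param n_bins Number of radial bins up to the Nyquist frequency of the
#'   shorter axis.
#' @return Tibble with bin centre `f` (cyc/deg), mean `amplitude`, and `n`
#'   cells per bin.
#' @export
radial_spectrum <- function(amplitude, fx = attr(amplitude, "fx"),
                            fy = attr(amplitude, "fy"), n_bins = 50) {
  stopifnot(!is.null(fx), !is.null(fy))
  R <- sqrt(outer(fy^2, fx^2, `+`))
  fmax <- min(max(abs(fx)), max(abs(fy)))
  edges <- seq(0, fmax, length.out = n_bins + 1)
  bin <- cut(R, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  agg <- tapply(amplitude[keep], bin[keep], mean)
  cnt <- tapply(amplitude[keep], bin[keep], length)
  idx <- as.integer(names(agg))
  tibble::tibble(f = (edges[idx] + edges[idx + 1]) / 2,
                 amplitude = as.numeric(agg), n = as.integer(cnt))
}

#' Estimate the Gaussian width of a target's amplitude spectrum
#'
#' For targets whose amplitude spectrum is Gaussian in frequency (the
#' Gaussian blob), fits `log A = a - f^2 / (2 sigma_f^2)` by least squares
#' over a frequency band where the spectrum is well above numerical noise
#' and returns `sigma_f` (cyc/deg). The patch is zero-padded to `pad`
#' pixels per side for fine frequency resolution.
#'
#' @param target A `target_image` (or plain matrix plus `px_per_deg`).
#' @param px_per_deg Pixels per degree; taken from the spec if a
#'   `target_image` is given.
#' @param pad Padded side length in pixels.
#' @param f_range Frequency band (cyc/deg) used for the fit.
#' @return Estimated `sigma_f` in cyc/deg.
#' @export
spectrum_gaussian_sigma <- function(target, px_per_deg = NULL, pad = 512,
                                    f_range = c(0.05, 1.0)) {
  if (inherits(target, "target_image")) {
    px_per_deg <- target$spec$px_per_deg
    target <- target$values
  }
  stopifnot(!is.null(px_per_deg))
  A <- Mod(stats::fft(zero_pad(target, pad)))
  f <- fft_freqs(pad, px_per_deg)
  R2 <- outer(f^2, f^2, `+`)
  keep <- R2 >= f_range[1]^2 & R2 <= f_range[2]^2 & A > 1e-8 * max(A)
  fit <- stats::lm(log(A[keep]) ~ R2[keep])
  slope <- coef(fit)[[2]]
  if (slope >= 0) stop_config("spectrum is not decaying over the fitted band")
  sqrt(-1 / (2 * slope))
}

#' Locate the non-DC peak of a target's amplitude spectrum
#'
#' @inheritParams spectrum_gaussian_sigma
#' @return List with `fx`, `fy` (cyc/deg) of the maximum away from zero
#'   frequency and its magnitude `f`.
#' @export
spectrum_peak <- function(target, px_per_deg = NULL, pad = 512) {
  if (inherits(target, "target_image")) {
    px_per_deg <- target$spec$px_per_deg
    target <- target$values
  }
  stopifnot(!is.null(px_per_deg))
  A <- Mod(stats::fft(zero_pad(target, pad)))
  A[1, 1] <- 0  # exclude DC
  i <- which.max(A)
  r <- (i - 1) %% pad + 1
  cc <- (i - 1) %/% pad + 1
  f <- fft_freqs(pad, px_per_deg)
  list(fx = f[cc], fy = f[r], f = sqrt(f[cc]^2 + f[r]^2))
}

#' Extract fixed-size patches around fixated pixels
#'
#' Cuts `size` x `size` pixel patches centred on each fixated pixel
#' (coordinates rounded to the nearest pixel). Fixations whose patch does
#' not lie entirely inside the image are dropped and counted.
#'
#' @param image Numeric matrix (rows = y, cols = x), typically in
#'   luminance units.
#' @param fixations Data frame with `x_px`, `y_px` columns (1-based pixel
#'   coordinates); other columns are carried into the metadata.
#' @param size Odd patch side length in pixels (default 79, about 2.05
#'   dva at the default pixel scale).
#' @param origin Label stored with the set (`"fixated"` or `"control"`).
#' @return A `patch_set`: list with `patches` (size x size x n array),
#'   `meta` (tibble of retained fixations), `n_dropped`, `size`, `origin`.
#' @export
extract_fixation_patches <- function(image, fixations, size = 79,
                                     origin = "fixated") {
  stopifnot(is.matrix(image), size %% 2 == 1)
  half <- (size - 1) / 2
  cx <- round(fixations$x_px); cy <- round(fixations$y_px)
  ok <- cx - half >= 1 & cx + half <= ncol(image) &
    cy - half >= 1 & cy + half <= nrow(image)
  idx <- which(ok)
  patches <- array(0, dim = c(size, size, length(idx)))
  for (k in seq_along(idx)) {
    i <- idx[k]
    patches[, , k] <- image[(cy[i] - half):(cy[i] + half),
                            (cx[i] - half):(cx[i] + half)]
  }
  structure(list(patches = patches,
                 meta = tibble::as_tibble(fixations[idx, , drop = FALSE]),
                 n_dropped = sum(!ok), size = size, origin = origin),
            class = "patch_set")
}

#' Extract control patches by cyclically shifting the image index
#'
#' Control patches are taken at the measured fixation coordinates but
#' from the *next* image in cyclic order: fixations on image 1 cut
#' patches from image 2, and so on; fixations on the last image cut
#' patches from the first. This preserves fixation-location statistics
#' while decoupling patch content from gaze.
#'
#' @param images Ordered list of image matrices (>= 2, equal sizes
#'   recommended).
#' @param fixations Data frame with `image_id` (index into `images` or a
#'   name), `x_px`, `y_px`.
#' @param size Odd patch side length in pixels.
#' @return A `patch_set` with `origin = "control"`; its metadata carries
#'   `source_image` (the image the patch came from). Per-image drop counts
#'   are in attribute-free column bookkeeping: `n_dropped` totals them.
#' @export
control_patches <- function(images, fixations, size = 79) {
  if (length(images) < 2)
    stop_config("control patches need at least 2 images (cyclic index shift)")
  ids <- names(images) %||% as.character(seq_along(images))
  names(images) <- ids
  pos <- match(as.character(fixations$image_id), ids)
  if (anyNA(pos)) stop_config("fixation image_id not found among images")
  sets <- lapply(seq_along(images), function(i) {
    fx <- fixations[pos == i, , drop = FALSE]
    if (nrow(fx) == 0) return(NULL)
    j <- if (i == length(images)) 1L else i + 1L
    ps <- extract_fixation_patches(images[[j]], fx, size = size, origin = "control")
    ps$meta$source_image <- ids[j]
    ps
  })
  sets <- Filter(Negate(is.null), sets)
  patches <- array(0, dim = c(size, size, sum(vapply(sets, function(s) dim(s$patches)[3], 0))))
  k <- 0L
  for (s in sets) {
    n <- dim(s$patches)[3]
    if (n > 0) patches[, , k + seq_len(n)] <- s$patches
    k <- k + n
  }
  structure(list(patches = patches,
                 meta = dplyr::bind_rows(lapply(sets, `[[`, "meta")),
                 n_dropped = sum(vapply(sets, `[[`, 0, "n_dropped")),
                 size = size, origin = "control"),
            class = "patch_set")
}

# amplitude spectra of all patches in a set: size x size x n array
patch_spectra <- function(patch_set) {
  n <- dim(patch_set$patches)[3]
  out <- array(0, dim = dim(patch_set$patches))
  for (k in seq_len(n)) out[, , k] <- fftshift2(Mod(stats::fft(patch_set$patches[, , k])))
  out
}

array_mean <- function(a) apply(a, c(1, 2), mean)

#' Summarize amplitude spectra of fixated versus control patches
#'
#' Computes per-patch amplitude spectra, averages them within groups, and
#' forms ratio maps: fixated mean over control mean, and (when a grouping
#' vector is given) each group's mean over the grand mean across groups.
#' Patch-to-patch variability is quantified as SD/M per frequency, with a
#' scalar summary (mean over frequencies).
#'
#' @param fixated,control `patch_set` objects from
#'   [extract_fixation_patches()] / [control_patches()].
#' @param groups Optional factor/character vector (one per fixated patch,
#'   e.g. target kind) for per-condition ratios.
#' @return A `spectrum_summary` list: `mean_fixated`, `mean_control`,
#'   `ratio_vs_control`, `group_means` and `ratio_vs_grand` (lists by
#'   group), `sd_over_mean_map`, `sd_over_mean`, and patch counts.
#' @export
spectrum_summary <- function(fixated, control = NULL, groups = NULL) {
  if (dim(fixated$patches)[3] == 0) stop_config("empty fixated patch set")
  sf <- patch_spectra(fixated)
  mean_fix <- array_mean(sf)
  mean_ctrl <- NULL
  ratio_ctrl <- NULL
  if (!is.null(control)) {
    if (dim(control$patches)[3] == 0) stop_config("empty control patch set")
    mean_ctrl <- array_mean(patch_spectra(control))
    ratio_ctrl <- mean_fix / mean_ctrl
  }
  group_means <- ratio_grand <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    stopifnot(length(groups) == dim(sf)[3])
    gl <- sort(unique(groups))
    group_means <- lapply(gl, function(g) array_mean(sf[, , groups == g, drop = FALSE]))
    names(group_means) <- gl
    grand <- Reduce(`+`, group_means) / length(group_means)
    ratio_grand <- lapply(group_means, function(m) m / grand)
  }
  sdm_map <- apply(sf, c(1, 2), stats::sd) / mean_fix
  structure(list(mean_fixated = mean_fix, mean_control = mean_ctrl,
                 ratio_vs_control = ratio_ctrl, group_means = group_means,
                 ratio_vs_grand = ratio_grand, sd_over_mean_map = sdm_map,
                 sd_over_mean = mean(sdm_map),
                 n_fixated = dim(sf)[3],
                 n_control = if (is.null(control)) 0L else dim(control$patches)[3]),
            class = "spectrum_summary")
}
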