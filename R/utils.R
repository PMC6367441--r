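# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# ambient .Random.seed is restored afterwards. `seed = NULL` leaves the
# ambient stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# smallest odd integer >= n
odd_ceiling <- function(n) {
  n <- ceiling(n)
  if (n %% 2 == 0) n + 1L else as.integer(n)
}

#' DFT frequency axis in cycles per degree
#'
#' Frequencies of an n-point discrete Fourier transform for samples taken
#' at `px_per_deg` pixels per degree, in the native unshifted DFT order,
#' or ascending (zero-frequency centred) with `shifted = TRUE`.
#'
#' @param n Number of samples.
#' @param px_per_deg Sampling rate in pixels per degree (1 gives cycles
#'   per pixel).
#' @param shifted Return the axis in ascending order.
#' @return Numeric vector of length `n` in cyc/deg.
#' @export
fft_freqs <- function(n, px_per_deg = 1, shifted = FALSE) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f <- f * px_per_deg
  if (shifted) f[order(f)] else f
}

# move the zero-frequency bin of a 2-D DFT to the matrix centre: for n
# samples the DC bin lands at index floor(n / 2) + 1, matching the
# ascending axis of fft_freqs(shifted = TRUE)
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- nr - floor(nr / 2); sc <- nc - floor(nc / 2)
  m[c((sr + 1):nr, seq_len(sr)), c((sc + 1):nc, seq_len(sc))]
}

# fold an absolute angular difference (degrees) into [0, 180]
fold_angle <- function(a) {
  a <- abs(a) %% 360
  pmin(a, 360 - a)
}

# standard error of the mean; NA for n < 2
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stop_config <- function(...) stop(..., call. = FALSE)
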