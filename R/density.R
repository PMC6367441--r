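#' Construct a gridded density map
#'
#' A probability map over the image extent on a regular grid (128 x 128
#' by default): cell values are probability *mass* and sum to 1. Rows
#' index y, columns x; cells are half-open, a point on a boundary belongs
#' to the cell on its upper-index side (the last cells include their
#' outer edge).
#'
#' @param values Non-negative matrix; normalized to unit mass.
#' @param extent List with `xlim`, `ylim` in dva (see [image_extent()]).
#' @param bandwidth Kernel bandwidth in dva (for KDE maps).
#' @param source `"empirical_kde"`, `"external_map"` or `"uniform"`.
#' @return A `density_map` object.
#' @export
density_map <- function(values, extent, bandwidth = NA_real_,
                        source = "external_map") {
  stopifnot(is.matrix(values))
  if (min(values) < 0) stop_config("density values must be non-negative")
  s <- sum(values)
  if (!is.finite(s) || s <= 0) stop_config("density map has no mass")
  structure(list(values = values / s, extent = extent, bandwidth = bandwidth,
                 source = source, grid = dim(values)),
            class = "density_map")
}

#' Uniform density map
#'
#' @inheritParams density_map
#' @param grid Grid size `c(ny, nx)`.
#' @return A uniform `density_map`.
#' @export
uniform_map <- function(extent, grid = c(128, 128)) {
  density_map(matrix(1, grid[1], grid[2]), extent, source = "uniform")
}

# cell-centre coordinates of a grid over an extent
grid_centers <- function(extent, grid) {
  nx <- grid[2]; ny <- grid[1]
  cw <- diff(extent$xlim) / nx
  ch <- diff(extent$ylim) / ny
  list(x = extent$xlim[1] + (seq_len(nx) - 0.5) * cw,
       y = extent$ylim[1] + (seq_len(ny) - 0.5) * ch)
}

# unnormalized Gaussian kernel sums evaluated at grid cell centres
kernel_sum_grid <- function(x, y, bandwidth, extent, grid) {
  ctr <- grid_centers(extent, grid)
  Wx <- outer(x, ctr$x, function(a, b) stats::dnorm(b, a, bandwidth))  # n x nx
  Wy <- outer(y, ctr$y, function(a, b) stats::dnorm(b, a, bandwidth))  # n x ny
  t(Wy) %*% Wx                                                        # ny x nx
}

#' Kernel density estimate of a fixation map
#'
#' Sums isotropic Gaussian kernels centred on the fixation positions,
#' evaluates them at the cell centres of the grid, and renormalizes to
#' unit mass over the image window (which also serves as the edge
#' correction: mass falling outside the image is redistributed by the
#' normalization).
#'
#' @param fixations Data frame with `x`, `y` in dva (or two numeric
#'   vectors via `y`).
#' @param bandwidth Kernel standard deviation in dva (> 0).
#' @param extent Image extent, see [image_extent()].
#' @param grid Grid size `c(ny, nx)`; default 128 x 128.
#' @return A `density_map` with `source = "empirical_kde"`.
#' @export
kde_density <- function(fixations, bandwidth, extent = image_extent(),
                        grid = c(128, 128)) {
  stopifnot(bandwidth > 0)
  x <- fixations$x; y <- fixations$y
  if (length(x) < 1) stop_config("kde_density needs at least one fixation")
  M <- kernel_sum_grid(x, y, bandwidth, extent, grid)
  density_map(M, extent, bandwidth = bandwidth, source = "empirical_kde")
}

# floor cell mass at eps and renormalize, so log never returns -Inf
floor_map <- function(p, eps = 1e-12) {
  p <- pmax(p, eps)
  p / sum(p)
}

# grid cell index of each point (list of row, col); errors if outside extent
point_cells <- function(map, x, y) {
  nx <- map$grid[2]; ny <- map$grid[1]
  cw <- diff(map$extent$xlim) / nx
  ch <- diff(map$extent$ylim) / ny
  tol <- 1e-9
  if (any(x < map$extent$xlim[1] - tol | x > map$extent$xlim[2] + tol |
          y < map$extent$ylim[1] - tol | y > map$extent$ylim[2] + tol))
    stop_config("point outside the map extent")
  col <- pmin(pmax(floor((x - map$extent$xlim[1]) / cw) + 1, 1), nx)
  row <- pmin(pmax(floor((y - map$extent$ylim[1]) / ch) + 1, 1), ny)
  list(row = row, col = col)
}

#' Look up map values at points
#'
#' Nearest-cell lookup of a gridded map at the given positions. The map
#' is either a [density_map()] (probability mass per cell) or a plain
#' matrix — e.g. an externally computed saliency map — whose raw values
#' are returned untouched, together with an explicit `extent`. Cells are
#' half-open: a point exactly on a cell boundary belongs to the
#' higher-index cell, except on the outer image edge, which belongs to
#' the last cell; the rule is deterministic.
#'
#' @param map A [density_map()] or a numeric matrix (rows = y).
#' @param points Data frame with `x`, `y` in dva.
#' @param extent Required when `map` is a plain matrix.
#' @return Numeric vector of cell values at the points.
#' @export
lookup_map_values <- function(map, points, extent = NULL) {
  if (is.matrix(map)) {
    if (is.null(extent)) stop_config("a plain-matrix map needs an explicit extent")
    map <- structure(list(values = map, extent = extent, grid = dim(map)),
                     class = "value_map")
  }
  idx <- point_cells(map, points$x, points$y)
  map$values[cbind(idx$row, idx$col)]
}

#' Mean log-likelihood of points relative to a uniform map
#'
#' Average over points of `log p(cell) - log p_uniform`, where
#' `p_uniform = 1 / n_cells`. Positive values indicate the map predicts
#' the points better than chance, negative values worse. Cell masses are
#' floored at `eps` and renormalized before taking logs so that a point
#' in a zero-mass cell never yields `-Inf`.
#'
#' @param points Data frame with `x`, `y` in dva; when `per = "trial"` a
#'   `trial_id` column is required.
#' @param map A [density_map()].
#' @param base `"nat"` (natural log, default) or `"bits"`.
#' @param per `"fixation"` averages over all points; `"trial"` averages
#'   within trial first, then over trials.
#' @param eps Mass floor per cell.
#' @return Scalar mean log-likelihood difference.
#' @export
loglik_vs_uniform <- function(points, map, base = c("nat", "bits"),
                              per = c("fixation", "trial"), eps = 1e-12) {
  base <- match.arg(base); per <- match.arg(per)
  p <- floor_map(map$values, eps)
  fm <- density_map(p, map$extent, map$bandwidth, map$source)
  v <- lookup_map_values(fm, points)
  ll <- log(v) - log(1 / prod(map$grid))
  if (per == "trial") {
    ll <- tapply(ll, points$trial_id, mean)
  }
  out <- mean(ll)
  if (base == "bits") out <- out / log(2)
  out
}

#' Leave-one-subject-out bandwidth selection
#'
#' For each candidate bandwidth, each subject's fixations are scored by
#' their log-likelihood under a kernel density estimate fitted to all
#' *other* subjects' fixations; the bandwidth maximizing the summed
#' held-out log-likelihood across subjects is returned (ties broken
#' toward the larger bandwidth). The default candidate grid runs from
#' 0.5 to 2.0 dva in steps of 0.1 dva and the selection is typically run
#' per image.
#'
#' @param fixations Data frame with `subject_id`, `x`, `y` (dva).
#' @param extent Image extent.
#' @param candidates Candidate bandwidths in dva.
#' @param grid Grid size `c(ny, nx)`.
#' @param eps Mass floor per cell for the likelihood evaluation.
#' @return Selected bandwidth (scalar) with attribute `profile`, a
#'   tibble of candidate bandwidths and summed held-out log-likelihoods.
#' @export
select_bandwidth_loso <- function(fixations, extent = image_extent(),
                                  candidates = seq(0.5, 2.0, by = 0.1),
                                  grid = c(128, 128), eps = 1e-12) {
  per_subj <- split(fixations, fixations$subject_id)
  usable <- names(per_subj)[vapply(per_subj, nrow, 0L) > 0]
  if (length(usable) < length(per_subj))
    warning("skipping ", length(per_subj) - length(usable),
            " subject(s) with zero fixations")
  per_subj <- per_subj[usable]
  if (length(usable) < 2)
    stop_config("LOSO bandwidth selection needs at least 2 subjects with fixations")
  ll <- vapply(candidates, function(h) {
    grids <- lapply(per_subj[usable], function(d)
      kernel_sum_grid(d$x, d$y, h, extent, grid))
    total <- Reduce(`+`, grids)
    sum(vapply(usable, function(s) {
      others <- total - grids[[s]]
      p <- floor_map(others / sum(others), eps)
      m <- density_map(p, extent, bandwidth = h, source = "empirical_kde")
      sum(log(lookup_map_values(m, per_subj[[s]])))
    }, 0))
  }, 0)
  best <- max(which(ll == max(ll)))  # ties -> larger bandwidth
  structure(candidates[best],
            profile = tibble::tibble(bandwidth = candidates, loglik = ll))
}
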