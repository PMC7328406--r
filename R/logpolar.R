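#' Log-polar histogram lattice specification
#'
#' Defines the (theta, ln r) lattice on which trajectory densities are built.
#' Working in log-polar coordinates about the nest equalizes visit density
#' across radii: a plain spatial histogram has effectively larger bins far
#' from the nest and tiny, densely revisited bins near it, whereas after the
#' `(x, y) -> (theta, ln r)` transform comparable exploration effort covers
#' comparable lattice area.
#'
#' Theta nodes are placed at integer multiples of `theta_step`. The truncated
#' range covers `[-K, K] * theta_step` with `K = floor(pi / theta_step)`; the
#' padded range used for histogramming and blurring doubles it to
#' `[-2K, 2K] * theta_step`, covering a full extra period on each side so the
#' blur sees periodic data (see [periodic_pad()]). ln-r nodes run from
#' `lnr_min` to `lnr_max` in steps of `lnr_step`, endpoints included. With
#' the defaults (`theta_step` 0.01, ln r in 4.3..6.5 by 0.0025 — the arena's
#' radial extent in log-millimetres) the padded lattice is 1257 x 881 nodes
#' and the truncated one 629 x 881.
#'
#' @param theta_step Angular node spacing (radians).
#' @param lnr_min,lnr_max Radial range in ln-mm; points outside the open
#'   interval are dropped by [cartesian_to_logpolar()].
#' @param lnr_step Radial node spacing (ln-mm).
#' @param sigma Gaussian blur width in lattice cells, isotropic on the
#'   lattice. Under the log-radial metric a lattice sigma of 30 (default)
#'   corresponds to a physical blur growing from roughly 6 mm near the nest
#'   to 40 mm at the arena edge.
#' @return A `logpolar_spec` list with node vectors and counts.
#' @export
logpolar_spec <- function(theta_step = 0.01, lnr_min = 4.3, lnr_max = 6.5,
                          lnr_step = 0.0025, sigma = 30) {
  stopifnot(theta_step > 0, lnr_step > 0, lnr_max > lnr_min, sigma >= 0)
  k_half <- as.integer(floor(pi / theta_step + 1e-9))
  n_lnr <- round((lnr_max - lnr_min) / lnr_step) + 1L
  structure(list(
    theta_step = theta_step, lnr_min = lnr_min, lnr_max = lnr_max,
    lnr_step = lnr_step, sigma = sigma, k_half = k_half,
    n_theta_trunc = 2L * k_half + 1L,
    n_theta_pad = 4L * k_half + 1L,
    n_lnr = as.integer(n_lnr),
    theta_nodes_trunc = seq(-k_half, k_half) * theta_step,
    theta_nodes_pad = seq(-2L * k_half, 2L * k_half) * theta_step,
    lnr_nodes = lnr_min + (seq_len(n_lnr) - 1L) * lnr_step
  ), class = "logpolar_spec")
}

#' @export
print.logpolar_spec <- function(x, ...) {
  cat(sprintf(
    "<logpolar_spec> padded %d x %d (truncated %d x %d), sigma = %g cells\n",
    x$n_theta_pad, x$n_lnr, x$n_theta_trunc, x$n_lnr, x$sigma))
  invisible(x)
}

#' Cartesian to log-polar transform
#'
#' Maps planar points to `(theta, lnr)` about `center`, with
#' `theta = atan2(y - cy, x - cx)` in `(-pi, pi]` and `lnr` the natural log
#' of the Euclidean radius in mm. Points whose `lnr` falls outside the open
#' interval `(lnr_min, lnr_max)` — including zero-radius points, whose log is
#' undefined — are dropped and counted.
#'
#' @param points Data.frame with `x_mm`, `y_mm` columns, or a 2-column
#'   matrix.
#' @param center Numeric `c(x, y)` of the nest (mm).
#' @param lnr_min,lnr_max Radial limits in ln-mm.
#' @return Data.frame with columns `theta`, `lnr` and attribute `n_dropped`.
#' @export
cartesian_to_logpolar <- function(points, center = c(0, 0), lnr_min = 4.3,
                                  lnr_max = 6.5) {
  if (is.matrix(points)) points <- data.frame(x_mm = points[, 1],
                                              y_mm = points[, 2])
  dx <- points$x_mm - center[1]
  dy <- points$y_mm - center[2]
  r <- sqrt(dx^2 + dy^2)
  keep <- r > 0
  lnr <- rep(NA_real_, length(r))
  lnr[keep] <- log(r[keep])
  keep <- keep & !is.na(lnr) & lnr > lnr_min & lnr < lnr_max
  out <- data.frame(theta = atan2(dy[keep], dx[keep]), lnr = lnr[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Duplicate points across the periodic angular boundary
#'
#' Copies every point once across the theta boundary — points with
#' `theta <= 0` reappear at `theta + 2*pi` and points with `theta > 0` at
#' `theta - 2*pi` — extending the data onto the padded `[-2pi, 2pi]` range.
#' Blurring the padded histogram and truncating back then behaves as if theta
#' were genuinely periodic, preventing ringing at the `+-pi` seam.
#'
#' @param points Data.frame with `theta`, `lnr` (theta in `(-pi, pi]`).
#' @return Data.frame with `2 * nrow(points)` rows: originals then copies.
#' @export
periodic_pad <- function(points) {
  shifted <- points
  shifted$theta <- ifelse(points$theta <= 0, points$theta + 2 * pi,
                          points$theta - 2 * pi)
  rbind(points, shifted)
}

#' Gaussian blur with mass-conserving (reflect) boundaries
#'
#' Separable 2D convolution with an isotropic Gaussian of standard deviation
#' `sigma` cells, kernel truncated at `truncate * sigma`, boundaries handled
#' by mirror reflection so the total mass of the field is conserved exactly
#' and a uniform field is a fixed point.
#'
#' @param mat Numeric matrix.
#' @param sigma Standard deviation in cells; 0 returns `mat` unchanged.
#' @param truncate Kernel support radius in sigmas.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(mat, sigma, truncate = 4) {
  if (sigma == 0) return(mat)
  radius <- floor(truncate * sigma + 0.5)
  offs <- -radius:radius
  g <- exp(-offs^2 / (2 * sigma^2))
  g <- g / sum(g)
  k_row <- reflect_kernel_matrix(nrow(mat), g, radius)
  k_col <- reflect_kernel_matrix(ncol(mat), g, radius)
  k_row %*% mat %*% t(k_col)
}

# Band matrix K with K[i, fold(i + off)] += g[off], fold = mirror reflection
# about the array edges (half-sample symmetric, repeated until in range).
reflect_kernel_matrix <- function(n, g, radius) {
  k <- matrix(0, n, n)
  for (off in -radius:radius) {
    w <- g[off + radius + 1L]
    j <- seq_len(n) + off
    repeat {
      below <- j < 1L
      above <- j > n
      if (!any(below) && !any(above)) break
      j[below] <- 1L - j[below]
      j[above] <- 2L * n + 1L - j[above]
    }
    idx <- cbind(seq_len(n), j)
    k[idx] <- k[idx] + w
  }
  k
}

#' Bin log-polar points onto the padded lattice
#'
#' Nearest-node binning of (already padded) points onto the
#' `n_theta_pad x n_lnr` lattice; points falling off the lattice are ignored.
#'
#' @param points Data.frame with `theta`, `lnr`.
#' @param spec A [logpolar_spec()].
#' @return Integer count matrix (theta rows, lnr columns).
#' @export
bin_logpolar <- function(points, spec) {
  ti <- as.integer(round(points$theta / spec$theta_step)) + 2L * spec$k_half + 1L
  li <- as.integer(round((points$lnr - spec$lnr_min) / spec$lnr_step)) + 1L
  ok <- ti >= 1L & ti <= spec$n_theta_pad & li >= 1L & li <= spec$n_lnr
  counts <- integer(spec$n_theta_pad * spec$n_lnr)
  idx <- (li[ok] - 1L) * spec$n_theta_pad + ti[ok]
  tab <- tabulate(idx, nbins = length(counts))
  matrix(tab, spec$n_theta_pad, spec$n_lnr)
}

# Blur a padded count matrix, truncate theta back to [-pi, pi], normalize.
finish_density <- function(counts, spec) {
  blurred <- gaussian_blur(counts, spec$sigma)
  central <- (spec$k_half + 1L):(3L * spec$k_half + 1L)
  grid_distribution(blurred[central, , drop = FALSE])
}

#' Blurred density estimate from padded log-polar points
#'
#' Histograms the (padded) points on the padded lattice by nearest node,
#' convolves with the spec's isotropic Gaussian, truncates the angular range
#' back to `[-pi, pi]`, and normalizes to total mass one. Deterministic in
#' its inputs.
#'
#' @param points Data.frame with `theta`, `lnr`, already passed through
#'   [periodic_pad()].
#' @param spec A [logpolar_spec()].
#' @return A [grid_distribution()] of size `n_theta_trunc x n_lnr`.
#' @export
build_density <- function(points, spec) {
  if (nrow(points) == 0) {
    stop("cannot build a density from zero points", call. = FALSE)
  }
  finish_density(bin_logpolar(points, spec), spec)
}

#' Empirical target distribution from pooled trajectories
#'
#' The full trajectory-to-target pipeline: drop points inside the central
#' mask ([remove_mask_region()]), transform to log-polar about the nest
#' ([cartesian_to_logpolar()]), duplicate across the periodic angular
#' boundary ([periodic_pad()]), then histogram, blur and normalize
#' ([build_density()]). Pooling every walker's exploration into one
#' distribution gives the empirical estimate of where walkers "want" to
#' spend time — the reference target against which partial exploration is
#' scored.
#'
#' @param trajs A trajectory table (see [as_trajectories()]).
#' @param spec A [logpolar_spec()].
#' @param center Nest position `c(x, y)` in mm.
#' @param mask_half_width_mm Central mask half-width (mm); `NULL` skips mask
#'   removal.
#' @return A [grid_distribution()] of size `n_theta_trunc x n_lnr`.
#' @export
build_target <- function(trajs, spec = logpolar_spec(), center = c(0, 0),
                         mask_half_width_mm = 75) {
  if (nrow(trajs) == 0) stop("no trajectories supplied", call. = FALSE)
  if (!is.null(mask_half_width_mm)) {
    trajs <- remove_mask_region(trajs, mask_half_width_mm)
  }
  lp <- cartesian_to_logpolar(trajs, center = center,
                              lnr_min = spec$lnr_min, lnr_max = spec$lnr_max)
  build_density(periodic_pad(lp), spec)
}
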