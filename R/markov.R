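#' Memoryless "Markov ant" trajectories by movement resampling
#'
#' Builds null-model walkers that move like the pooled real walkers but
#' remember nothing: a trajectory is the concatenation of 1-second movement
#' segments (runs of `segment_s / dt_s` consecutive displacement vectors)
#' drawn uniformly at random from the pooled displacement vector of all
#' source trajectories. A candidate segment that would carry the walker
#' outside the arena is rejected and redrawn, so the walk stays within
#' bounds while preserving the source movement statistics. Having neither an
#' internal memory nor externalized markers, these walkers benchmark
#' exploration without any self-avoidance.
#'
#' @param pool A trajectory table supplying the movement segments.
#' @param duration_s Length of the generated trajectory (s).
#' @param segment_s Segment length (s); must be a multiple of `dt_s`.
#' @param arena_mm Arena side (mm), centred on the origin.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param start `c(x, y)` start position in mm.
#' @param ant_id,colony,treatment,order Labels attached to the output.
#' @param dt_s Time step (s).
#' @param max_retries Redraws allowed per segment before giving up.
#' @return A trajectory table with `duration_s / dt_s + 1` rows.
#' @export
markov_ant_resample <- function(pool, duration_s = 2700, segment_s = 1,
                                arena_mm = 900, seed = NULL,
                                start = c(0, 0), ant_id = "markov-1",
                                colony = "markov", treatment = "MK",
                                order = 1L, dt_s = 0.1, max_retries = 1000) {
  segs <- movement_segments(pool, segment_s = segment_s, dt_s = dt_s)
  with_local_seed(seed, markov_ant_impl(segs, duration_s, segment_s,
                                        arena_mm, start, ant_id, colony,
                                        treatment, order, dt_s, max_retries))
}

# Pooled displacement segments: list of dx and dy matrices, one row per
# segment of `segment_s / dt_s` consecutive displacements from a single ant.
movement_segments <- function(pool, segment_s = 1, dt_s = 0.1) {
  if (nrow(pool) == 0) stop("empty trajectory pool", call. = FALSE)
  len <- round(segment_s / dt_s)
  if (abs(len * dt_s - segment_s) > 1e-9 || len < 1) {
    stop("`segment_s` must be a positive multiple of `dt_s`", call. = FALSE)
  }
  dx_rows <- list(); dy_rows <- list()
  for (id in unique(pool$ant_id)) {
    sub <- pool[pool$ant_id == id, , drop = FALSE]
    if (nrow(sub) < len + 1) next
    dx <- diff(sub$x_mm); dy <- diff(sub$y_mm)
    n_seg <- length(dx) %/% len
    if (n_seg < 1) next
    keep <- seq_len(n_seg * len)
    dx_rows[[id]] <- matrix(dx[keep], nrow = n_seg, byrow = TRUE)
    dy_rows[[id]] <- matrix(dy[keep], nrow = n_seg, byrow = TRUE)
  }
  if (!length(dx_rows)) {
    stop("pool contains no trajectory long enough for a full segment",
         call. = FALSE)
  }
  list(dx = do.call(rbind, dx_rows), dy = do.call(rbind, dy_rows), len = len)
}

markov_ant_impl <- function(segs, duration_s, segment_s, arena_mm, start,
                            ant_id, colony, treatment, order, dt_s,
                            max_retries) {
  n_seg_draws <- round(duration_s / segment_s)
  half <- arena_mm / 2
  n_pts <- n_seg_draws * segs$len + 1L
  x <- numeric(n_pts); y <- numeric(n_pts)
  x[1] <- start[1]; y[1] <- start[2]
  pos <- 1L
  n_pool <- nrow(segs$dx)
  for (s in seq_len(n_seg_draws)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      i <- sample.int(n_pool, 1L)
      cx <- x[pos] + cumsum(segs$dx[i, ])
      cy <- y[pos] + cumsum(segs$dy[i, ])
      if (all(abs(cx) <= half) && all(abs(cy) <= half)) {
        idx <- pos + seq_len(segs$len)
        x[idx] <- cx; y[idx] <- cy
        pos <- pos + segs$len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "no admissible segment from (%.1f, %.1f) after %d retries",
        x[pos], y[pos], max_retries), call. = FALSE)
    }
  }
  as_trajectories(data.frame(
    ant_id = ant_id, colony = colony, treatment = treatment,
    order = as.integer(order), t_s = (seq_len(n_pts) - 1L) * dt_s,
    x_mm = x, y_mm = y), arena_mm = arena_mm, dt_s = dt_s)
}

#' Colonies of Markov ants
#'
#' Convenience wrapper generating `n_colonies` colonies of
#' `ants_per_colony` independent [markov_ant_resample()] walkers, labelled
#' with colony and release order.
#'
#' @inheritParams markov_ant_resample
#' @param n_colonies,ants_per_colony Cohort dimensions.
#' @return A trajectory table.
#' @export
simulate_markov_colonies <- function(pool, n_colonies = 100,
                                     ants_per_colony = 6,
                                     duration_s = 2700, segment_s = 1,
                                     arena_mm = 900, seed = NULL,
                                     dt_s = 0.1) {
  segs <- movement_segments(pool, segment_s = segment_s, dt_s = dt_s)
  with_local_seed(seed, {
    out <- vector("list", n_colonies * ants_per_colony)
    k <- 0L
    for (ci in seq_len(n_colonies)) {
      for (ai in seq_len(ants_per_colony)) {
        k <- k + 1L
        out[[k]] <- markov_ant_impl(
          segs, duration_s, segment_s, arena_mm, start = c(0, 0),
          ant_id = sprintf("mk%03d-a%d", ci, ai),
          colony = sprintf("mk%03d", ci), treatment = "MK",
          order = ai, dt_s = dt_s, max_retries = 1000)
      }
    }
    as_trajectories(do.call(rbind, out), arena_mm = arena_mm, dt_s = dt_s)
  })
}
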