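#' Configuration of a synthetic exploration cohort
#'
#' Describes a cohort of simulated central-place explorers released one after
#' another into a square arena, with optional stigmergic avoidance coupling
#' between successive walkers. Each walker performs a correlated random walk
#' from the arena centre: its heading persists with concentration
#' `turning_kappa` (turn noise is wrapped-normal with standard deviation
#' `1/sqrt(turning_kappa)` per step), step lengths come from a truncated
#' normal speed model, walls reflect, and a weak pull draws the walker toward
#' the colony's preferred direction — an environmental angular preference
#' (the heterogeneity real cohorts display) drawn once per colony from
#' `quadrant_bias` and shared by its walkers, with a small per-walker jitter. Every walker
#' deposits a footprint field along its path (spread `deposit_sigma_mm`);
#' later walkers feel the accumulated field of their predecessors and are
#' steered down its gradient with weight `avoidance_strength`.
#'
#' `clean_between_ants = TRUE` emulates the cleaned-arena treatment: the
#' shared field is wiped before each new walker, so only information from
#' nest-mates is removed — each walker still lays and reacts to its own
#' marks while walking, exactly as cleaning between releases would leave
#' intact. Cohorts are labelled `"C"` when cleaned and `"NC"` otherwise.
#' Setting `avoidance_strength = 0` removes the coupling altogether.
#'
#' @param n_colonies Number of replicate colonies.
#' @param ants_per_colony Walkers released per colony.
#' @param duration_s Tracked duration per walker (s).
#' @param dt_s Time step (s).
#' @param arena_mm Arena side (mm), centred on the nest.
#' @param speed_mean,speed_sd Speed model (mm/s); draws are truncated at 0.
#' @param turning_kappa Heading-persistence concentration (1/rad^2).
#' @param quadrant_bias Nonnegative weights over quadrants 1-4
#'   (counter-clockwise from +x,+y); each colony's preferred direction is
#'   drawn from the quadrant chosen with these weights.
#' @param bias_pull Strength of the per-step pull toward the preferred
#'   direction (rad per step at full misalignment).
#' @param avoidance_strength Nonnegative weight of the repulsion away from
#'   the deposited field's gradient; 0 disables avoidance.
#' @param deposit_sigma_mm Footprint spread applied to each walker's
#'   deposits when they join the shared field.
#' @param field_cell_mm Resolution of the deposit field lattice (mm).
#' @param clean_between_ants Wipe the shared field before each new walker.
#' @param seed Integer seed.
#' @param colony_pref_seed Optional integer: when set, colony preferred
#'   directions are drawn from their own stream seeded by
#'   `colony_pref_seed + colony index`. Give two cohorts the same value to
#'   model the same colonies (same environmental preference) observed under
#'   two treatments, the paired design the treatment contrast assumes.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_colonies = 3, ants_per_colony = 6,
                          duration_s = 2700, dt_s = 0.1, arena_mm = 900,
                          speed_mean = 7, speed_sd = 4, turning_kappa = 30,
                          quadrant_bias = c(1, 2, 1, 0.5), bias_pull = 0.05,
                          avoidance_strength = 2, deposit_sigma_mm = 60,
                          field_cell_mm = 20, clean_between_ants = FALSE,
                          seed = NULL, colony_pref_seed = NULL) {
  stopifnot(n_colonies >= 1, ants_per_colony >= 1, duration_s > 0, dt_s > 0,
            arena_mm > 0, speed_mean > 0, speed_sd >= 0, turning_kappa > 0,
            bias_pull >= 0, avoidance_strength >= 0, deposit_sigma_mm >= 0,
            field_cell_mm > 0)
  if (length(quadrant_bias) != 4 || any(quadrant_bias < 0) ||
      sum(quadrant_bias) <= 0) {
    stop("`quadrant_bias` must be 4 nonnegative weights with positive sum",
         call. = FALSE)
  }
  structure(list(
    n_colonies = as.integer(n_colonies),
    ants_per_colony = as.integer(ants_per_colony),
    duration_s = duration_s, dt_s = dt_s, arena_mm = arena_mm,
    speed_mean = speed_mean, speed_sd = speed_sd,
    turning_kappa = turning_kappa, quadrant_bias = quadrant_bias,
    bias_pull = bias_pull, avoidance_strength = avoidance_strength,
    deposit_sigma_mm = deposit_sigma_mm, field_cell_mm = field_cell_mm,
    clean_between_ants = isTRUE(clean_between_ants), seed = seed,
    colony_pref_seed = colony_pref_seed),
    class = "cohort_config")
}

#' Simulate a cohort of exploring walkers
#'
#' Runs the generative model described in [cohort_config()] and returns a
#' validated trajectory table: `duration_s / dt_s + 1` points per walker,
#' all inside the arena, labelled with colony, release order, and treatment
#' (`"C"` if the shared field is cleaned between walkers, else `"NC"`).
#' Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A trajectory table (see [as_trajectories()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_steps <- round(cfg$duration_s / cfg$dt_s)
  half <- cfg$arena_mm / 2
  nf <- max(3L, ceiling(cfg$arena_mm / cfg$field_cell_mm))
  cell <- cfg$arena_mm / nf
  treatment <- if (cfg$clean_between_ants) "C" else "NC"
  quad_centers <- c(pi / 4, 3 * pi / 4, -3 * pi / 4, -pi / 4)
  qb <- cfg$quadrant_bias / sum(cfg$quadrant_bias)
  sd_turn <- 1 / sqrt(cfg$turning_kappa)
  sigma_cells <- cfg$deposit_sigma_mm / cell
  out <- vector("list", cfg$n_colonies * cfg$ants_per_colony)
  k <- 0L
  for (ci in seq_len(cfg$n_colonies)) {
    shared <- matrix(0, nf, nf)
    draw_pref <- function() {
      quad <- sample.int(4L, 1L, prob = qb)
      quad_centers[quad] + stats::runif(1, -pi / 4, pi / 4)
    }
    colony_pref <- if (is.null(cfg$colony_pref_seed)) draw_pref() else
      with_local_seed(cfg$colony_pref_seed + ci, draw_pref())
    for (ai in seq_len(cfg$ants_per_colony)) {
      if (cfg$clean_between_ants) shared[] <- 0
      walk <- simulate_walk(cfg, n_steps, half, shared, nf, cell,
                            colony_pref, sd_turn)
      shared <- shared + gaussian_blur(walk$deposits, sigma_cells)
      k <- k + 1L
      out[[k]] <- data.frame(
        ant_id = sprintf("%s-col%d-a%d", treatment, ci, ai),
        colony = sprintf("col%d", ci), treatment = treatment,
        order = ai, t_s = (0:n_steps) * cfg$dt_s,
        x_mm = walk$x, y_mm = walk$y)
    }
  }
  as_trajectories(do.call(rbind, out), arena_mm = cfg$arena_mm,
                  dt_s = cfg$dt_s)
}

# One walker: correlated random walk with quadrant pull, wall reflection,
# gradient repulsion from `shared`, and nearest-cell deposits along the path.
simulate_walk <- function(cfg, n_steps, half, shared, nf, cell, colony_pref,
                          sd_turn) {
  pref <- colony_pref + stats::runif(1, -pi / 8, pi / 8)
  heading <- stats::runif(1, -pi, pi)
  turns <- stats::rnorm(n_steps, 0, sd_turn)
  steps_mm <- pmax(0, stats::rnorm(n_steps, cfg$speed_mean,
                                   cfg$speed_sd)) * cfg$dt_s
  avoid <- cfg$avoidance_strength
  pull <- cfg$bias_pull
  x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
  deposits <- matrix(0, nf, nf)
  own <- shared   # walker feels predecessors' field plus its own raw marks
  cx <- 0; cy <- 0
  for (t in seq_len(n_steps)) {
    heading <- heading + turns[t] + pull * sin(pref - heading)
    if (avoid > 0) {
      ix <- floor((cx + half) / cell) + 1L
      iy <- floor((cy + half) / cell) + 1L
      ix <- min(max(ix, 1L), nf); iy <- min(max(iy, 1L), nf)
      ixm <- max(ix - 1L, 1L); ixp <- min(ix + 1L, nf)
      iym <- max(iy - 1L, 1L); iyp <- min(iy + 1L, nf)
      gx <- (own[ixp, iy] - own[ixm, iy]) / ((ixp - ixm) * cell)
      gy <- (own[ix, iyp] - own[ix, iym]) / ((iyp - iym) * cell)
      gmag <- sqrt(gx^2 + gy^2)
      if (gmag > 0) {
        w <- min(1, gmag * cell / (own[ix, iy] + 1))
        heading <- heading + avoid * w * sin(atan2(-gy, -gx) - heading)
      }
    }
    nx <- cx + steps_mm[t] * cos(heading)
    ny <- cy + steps_mm[t] * sin(heading)
    if (abs(nx) > half) {
      nx <- sign(nx) * 2 * half - nx
      heading <- pi - heading
    }
    if (abs(ny) > half) {
      ny <- sign(ny) * 2 * half - ny
      heading <- -heading
    }
    cx <- min(max(nx, -half), half)
    cy <- min(max(ny, -half), half)
    x[t + 1L] <- cx; y[t + 1L] <- cy
    ix <- min(max(floor((cx + half) / cell) + 1L, 1L), nf)
    iy <- min(max(floor((cy + half) / cell) + 1L, 1L), nf)
    deposits[ix, iy] <- deposits[ix, iy] + 1
    own[ix, iy] <- own[ix, iy] + 1
  }
  list(x = x, y = y, deposits = deposits)
}
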