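# Shared fixtures, all generated in code.

# Straight-line trajectory from the centre outward at fixed speed.
straight_trajectory <- function(ant_id = "a1", colony = "col1",
                                treatment = "NC", order = 1L,
                                heading = 0, speed_mm_s = 50,
                                duration_s = 8, dt_s = 0.1) {
  t_s <- seq(0, duration_s, by = dt_s)
  r <- speed_mm_s * t_s
  data.frame(ant_id = ant_id, colony = colony, treatment = treatment,
             order = order, t_s = t_s,
             x_mm = r * cos(heading), y_mm = r * sin(heading))
}

# Small labelled cohort: n_colonies x orders straight walkers fanning out.
fan_cohort <- function(n_colonies = 3, orders = 1:6, treatment = "NC",
                       duration_s = 8) {
  speed <- min(50, 420 / duration_s)
  rows <- list()
  for (ci in seq_len(n_colonies)) {
    for (k in orders) {
      rows[[length(rows) + 1L]] <- straight_trajectory(
        ant_id = sprintf("%s-c%d-a%d", treatment, ci, k),
        colony = sprintf("col%d", ci), treatment = treatment, order = k,
        heading = 2 * pi * (ci * length(orders) + k) / 17,
        speed_mm_s = speed, duration_s = duration_s)
    }
  }
  as_trajectories(do.call(rbind, rows))
}

# Coarse log-polar lattice keeping pipeline tests fast.
coarse_spec <- function(sigma = 3) {
  logpolar_spec(theta_step = 0.1, lnr_step = 0.025, sigma = sigma)
}

# Independent single-step transition oracle: enumerates the nine proposals
# and integrates the accept/reject rule analytically, straight from the
# ratio formulas (no package sampler code).
oracle_transition_matrix <- function(p_mat, m_mat, variant) {
  nr <- nrow(p_mat); nc <- ncol(p_mat); ncell <- nr * nc
  wrap <- function(i, n) ((i - 1) %% n) + 1
  tm <- matrix(0, ncell, ncell)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    i <- (cc - 1) * nr + r
    pc <- p_mat[r, cc]
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- wrap(r + dr, nr); c2 <- wrap(cc + dc, nc)
      j <- (c2 - 1) * nr + r2
      pp <- p_mat[r2, c2]
      ratio <- if (pc == 0) {
        if (pp == 0) 1 else Inf
      } else if (variant == "plain_mh") {
        pp / pc
      } else if (pp == 0) {
        0
      } else {
        (pp^2 / pc^2) * (m_mat[r, cc] / m_mat[r2, c2])
      }
      acc <- min(1, ratio)
      tm[i, j] <- tm[i, j] + acc / 9
      tm[i, i] <- tm[i, i] + (1 - acc) / 9
    }
  }
  tm
}

# Minimal chain_trace carrying given visit counts.
fake_trace <- function(visits) {
  structure(list(states = matrix(integer(), 0, 2), visits = visits,
                 ce_curve = data.frame(step = numeric(),
                                       ce_nats = numeric()),
                 n_rows = nrow(visits), n_cols = ncol(visits)),
            class = "chain_trace")
}
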