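#' Moore-neighbourhood proposal on a periodic lattice
#'
#' Adds an independent uniform draw from \{-1, 0, +1\} to each coordinate of
#' `state` and wraps the result periodically, so the candidate is one of the
#' nine cells of the Moore neighbourhood (the current cell included), each
#' with probability 1/9. Consumes exactly two RNG draws.
#'
#' @param state Integer vector `c(row, col)`, 1-based.
#' @param n_rows,n_cols Lattice dimensions.
#' @return Integer vector `c(row, col)` of the proposed cell.
#' @export
propose_move <- function(state, n_rows, n_cols) {
  dr <- sample.int(3L, 1L) - 2L
  dc <- sample.int(3L, 1L) - 2L
  wrap_state(state[1] + dr, state[2] + dc, n_rows, n_cols)
}

wrap_state <- function(r, c, n_rows, n_cols) {
  c(((r - 1L) %% n_rows) + 1L, ((c - 1L) %% n_cols) + 1L)
}

match_variant <- function(variant) {
  match.arg(variant, c("plain_mh", "trail"))
}

#' Metropolis-Hastings acceptance ratio, plain and trail variants
#'
#' For the plain variant the ratio is the classic `P(proposed)/P(current)`.
#' The trail variant multiplies it by
#' `[P(proposed)/M(proposed)] / [P(current)/M(current)]`, so the chain targets
#' `P^2 / M` (renormalized): the squared term sharpens the pull towards
#' high-probability regions — a cell of mass 0.2 becomes four times as
#' attractive as one of mass 0.1 rather than twice — while the accumulated
#' memory `M` repels the walker from ground already covered. As `M` converges
#' to `P` the objective falls back to `P` itself.
#'
#' Because `M` enters only through `M(current)/M(proposed)`, the ratio is
#' exactly invariant under global rescaling of the memory: raw counts and the
#' per-step renormalized field give bit-identical decisions.
#'
#' Zero-mass target cells (possible in sparse random targets) are handled as:
#' `P(proposed) = 0` with `P(current) > 0` gives ratio 0 (never accept);
#' `P(current) = 0` (possible only at initialization) gives `Inf` for a
#' positive proposal — any escape is accepted — and 1 when both are zero, so
#' the walker diffuses freely on null support.
#'
#' @param p Target [grid_distribution()].
#' @param m [memory_model()] (ignored by the plain variant; may be `NULL`
#'   then).
#' @param current,proposed Integer `c(row, col)` states, 1-based.
#' @param variant `"plain_mh"` or `"trail"`.
#' @return Nonnegative acceptance ratio (possibly `Inf`).
#' @examples
#' p <- grid_distribution(matrix(c(0.2, 0.1, 0.35, 0.35), 2, 2))
#' m <- memory_model(2, 2)
#' acceptance_ratio(p, m, c(1, 2), c(1, 1), "trail")  # (0.2/0.1)^2 = 4
#' @export
acceptance_ratio <- function(p, m, current, proposed,
                             variant = c("plain_mh", "trail")) {
  variant <- match_variant(variant)
  stopifnot_grid(p)
  pc <- p[current[1], current[2]]
  pp <- p[proposed[1], proposed[2]]
  if (pc == 0) return(if (pp == 0) 1 else Inf)
  if (variant == "plain_mh") return(pp / pc)
  stopifnot(inherits(m, "memory_model"))
  if (pp == 0) return(0)
  mc <- m$counts[current[1], current[2]]
  mp <- m$counts[proposed[1], proposed[2]]
  # (pp/pc) * (pp/mp)/(pc/mc), grouped so a global rescaling of M cancels
  # not just mathematically but bit-for-bit
  (pp / pc)^2 * (mc / mp)
}

#' One sampler step: propose, accept or reject, deposit
#'
#' Reference single-step implementation of the sampler's transition kernel:
#' proposes a Moore-neighbourhood move, accepts when the acceptance ratio
#' exceeds 1 and otherwise when it exceeds a fresh uniform draw, then — after
#' the decision, whatever it was — applies one decay step to the memory (when
#' `decay_lambda > 0`) and deposits one marker at the post-decision cell.
#' Rejections therefore still deepen the memory where the walker sits, just
#' as a stationary ant keeps marking the ground beneath it.
#'
#' [run_chain()] executes the same kernel in a fused loop; this function is
#' the transparent one-step form used for inspection and testing.
#'
#' @inheritParams acceptance_ratio
#' @param state Integer `c(row, col)` current state.
#' @return List with `state` (the post-decision state), `m` (updated memory),
#'   and `accepted` (logical).
#' @export
mh_step <- function(p, m, state, variant = c("plain_mh", "trail")) {
  variant <- match_variant(variant)
  proposed <- propose_move(state, nrow(p), ncol(p))
  ratio <- acceptance_ratio(p, m, state, proposed, variant)
  accepted <- ratio > 1 || ratio > stats::runif(1)
  if (accepted) state <- proposed
  if (m$decay_lambda > 0) {
    m$counts <- m$alpha + (m$counts - m$alpha) * exp(-m$decay_lambda)
  }
  m$counts[state[1], state[2]] <- m$counts[state[1], state[2]] + 1
  list(state = state, m = m, accepted = accepted)
}

#' Configuration of a sampler run
#'
#' @param variant `"plain_mh"` (targets `P`) or `"trail"` (targets `P^2/M`).
#' @param n_steps Number of steps to run.
#' @param alpha Positive Dirichlet prior pseudo-count per memory cell.
#' @param decay_lambda Nonnegative per-step memory decay constant.
#' @param cleaning_times Integer step indices (within `1..n_steps`) at which
#'   the memory's deposits are reset to the pure prior, emulating the removal
#'   of accumulated markers after each of a sequence of walkers; applied after
#'   the step completes. Deposits keep accumulating between resets.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param start `"uniform-random"` (default) or an integer `c(row, col)`.
#' @param ce_snapshot_interval Record a cross-entropy snapshot every this many
#'   steps (plus one at the final step); `NULL` disables snapshots.
#' @param ce_estimate What the snapshot compares against the target:
#'   `"visits"` (default) uses the smoothed empirical visit distribution of
#'   the sample so far; `"memory"` uses the normalized memory field.
#' @param ce_smoothing_alpha Pseudo-count added to every cell of the visit
#'   histogram before normalizing, guaranteeing the positivity that
#'   [cross_entropy()] demands. Ignored for `ce_estimate = "memory"`.
#' @return A `chain_config` list.
#' @export
chain_config <- function(variant = c("plain_mh", "trail"), n_steps,
                         alpha = 1, decay_lambda = 0,
                         cleaning_times = integer(), seed = NULL,
                         start = "uniform-random",
                         ce_snapshot_interval = 1000L,
                         ce_estimate = c("visits", "memory"),
                         ce_smoothing_alpha = 1) {
  variant <- match_variant(variant)
  ce_estimate <- match.arg(ce_estimate)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 0 ||
      n_steps != round(n_steps)) {
    stop("`n_steps` must be a nonnegative integer", call. = FALSE)
  }
  cleaning_times <- as.integer(sort(cleaning_times))
  if (length(cleaning_times) &&
      (min(cleaning_times) < 1 || max(cleaning_times) > n_steps)) {
    stop("`cleaning_times` must lie within 1..n_steps", call. = FALSE)
  }
  if (!is.null(ce_snapshot_interval) &&
      (!is.numeric(ce_snapshot_interval) || ce_snapshot_interval < 1)) {
    stop("`ce_snapshot_interval` must be a positive integer or NULL",
         call. = FALSE)
  }
  structure(list(variant = variant, n_steps = as.integer(n_steps),
                 alpha = alpha, decay_lambda = decay_lambda,
                 cleaning_times = cleaning_times, seed = seed, start = start,
                 ce_snapshot_interval = ce_snapshot_interval,
                 ce_estimate = ce_estimate,
                 ce_smoothing_alpha = ce_smoothing_alpha),
            class = "chain_config")
}

#' Run a sampler chain
#'
#' Executes `n_steps` of the configured kernel ([mh_step()] semantics) against
#' the target `p`, recording every visited state, periodic cross-entropy
#' snapshots, and the final memory field. Fully reproducible given
#' `config$seed`: per step the proposal consumes two draws and the acceptance
#' one, taken from pre-generated blocks in fixed order.
#'
#' @param p Target [grid_distribution()].
#' @param config A [chain_config()].
#' @return A `chain_trace`: list with `states` (an `n_steps` x 2 integer
#'   matrix of visited row/col), `ce_curve` (data.frame `step`, `ce_nats`),
#'   `visits` (visit-count matrix), `final_memory` ([memory_model()]),
#'   `start`, `n_rows`, `n_cols`, and the `config`.
#' @export
run_chain <- function(p, config) {
  stopifnot_grid(p)
  stopifnot(inherits(config, "chain_config"))
  with_local_seed(config$seed, run_chain_impl(p, config))
}

run_chain_impl <- function(p, config) {
  nr <- nrow(p); nc <- ncol(p); ncell <- nr * nc
  n <- config$n_steps
  trail <- config$variant == "trail"
  alpha <- config$alpha
  lambda <- config$decay_lambda
  decay_f <- exp(-lambda)
  pv <- as.numeric(p)
  psup <- pv > 0
  pv_sup <- pv[psup]

  if (identical(config$start, "uniform-random")) {
    start <- c(sample.int(nr, 1L), sample.int(nc, 1L))
  } else {
    start <- as.integer(config$start)
    stopifnot(length(start) == 2, start >= 1, start[1] <= nr, start[2] <= nc)
  }

  mv <- rep(alpha, ncell)
  visits <- integer(ncell)
  rows_out <- integer(n); cols_out <- integer(n)

  snap_int <- config$ce_snapshot_interval
  snap_steps <- if (!is.null(snap_int) && n > 0) {
    if (snap_int <= n) unique(c(seq.int(snap_int, n, by = snap_int), n))
    else n
  } else integer()
  ce_steps <- numeric(length(snap_steps)); ce_vals <- numeric(length(snap_steps))
  snap_i <- 1L
  a <- config$ce_smoothing_alpha
  use_visits <- config$ce_estimate == "visits"

  cleans <- config$cleaning_times
  clean_i <- 1L
  n_clean <- length(cleans)

  if (n > 0) {
    drs <- sample.int(3L, n, replace = TRUE) - 2L
    dcs <- sample.int(3L, n, replace = TRUE) - 2L
    us <- stats::runif(n)
    sr <- start[1]; sc <- start[2]
    pc <- pv[(sc - 1L) * nr + sr]
    for (t in seq_len(n)) {
      rp <- sr + drs[t]
      if (rp < 1L) rp <- nr else if (rp > nr) rp <- 1L
      cp <- sc + dcs[t]
      if (cp < 1L) cp <- nc else if (cp > nc) cp <- 1L
      ip <- (cp - 1L) * nr + rp
      pp <- pv[ip]
      if (pc == 0) {
        ratio <- if (pp == 0) 1 else Inf
      } else if (trail) {
        if (pp == 0) {
          ratio <- 0
        } else {
          ic <- (sc - 1L) * nr + sr
          ratio <- (pp / pc)^2 * (mv[ic] / mv[ip])
        }
      } else {
        ratio <- pp / pc
      }
      if (ratio > 1 || ratio > us[t]) {
        sr <- rp; sc <- cp; pc <- pp
      }
      ic <- (sc - 1L) * nr + sr
      if (lambda > 0) mv <- alpha + (mv - alpha) * decay_f
      mv[ic] <- mv[ic] + 1
      visits[ic] <- visits[ic] + 1L
      rows_out[t] <- sr; cols_out[t] <- sc
      if (clean_i <= n_clean && t == cleans[clean_i]) {
        mv[] <- alpha
        clean_i <- clean_i + 1L
      }
      if (snap_i <= length(snap_steps) && t == snap_steps[snap_i]) {
        est <- if (use_visits) (visits[psup] + a) / (t + a * ncell) else
          mv[psup] / sum(mv)
        ce_steps[snap_i] <- t
        ce_vals[snap_i] <- -sum(pv_sup * log(est))
        snap_i <- snap_i + 1L
      }
    }
  }

  structure(list(
    states = cbind(row = rows_out, col = cols_out),
    ce_curve = data.frame(step = ce_steps, ce_nats = ce_vals),
    visits = matrix(visits, nr, nc),
    final_memory = memory_model(nr, nc, alpha = alpha,
                                decay_lambda = lambda,
                                counts = matrix(pmax(mv, alpha), nr, nc)),
    start = start, n_rows = nr, n_cols = nc, config = config
  ), class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("<chain_trace> %s, %d steps on %d x %d lattice\n",
              x$config$variant, nrow(x$states), x$n_rows, x$n_cols))
  if (nrow(x$ce_curve)) {
    cat(sprintf("  final CE: %.4f nats at step %d\n",
                x$ce_curve$ce_nats[nrow(x$ce_curve)],
                as.integer(x$ce_curve$step[nrow(x$ce_curve)])))
  }
  invisible(x)
}

#' Empirical visit distribution of a chain trace
#'
#' Normalizes the chain's visit counts, optionally after adding
#' `smoothing_alpha` pseudo-counts to every cell so the result is strictly
#' positive and usable as a [cross_entropy()] estimate.
#'
#' @param trace A `chain_trace` from [run_chain()].
#' @param smoothing_alpha Nonnegative pseudo-count per cell.
#' @return A [grid_distribution()].
#' @export
visit_distribution <- function(trace, smoothing_alpha = 0) {
  stopifnot(inherits(trace, "chain_trace"))
  if (smoothing_alpha < 0) {
    stop("`smoothing_alpha` must be nonnegative", call. = FALSE)
  }
  v <- trace$visits + smoothing_alpha
  if (sum(v) == 0) {
    stop("no visits and no smoothing: distribution undefined", call. = FALSE)
  }
  grid_distribution(v)
}

#' Exact single-step transition matrix of the sampler
#'
#' Enumerates the nine equiprobable proposals from every lattice cell and
#' integrates the accept/reject rule analytically (acceptance probability
#' `min(1, ratio)`), with the memory held fixed. Row `i` gives the
#' probability of moving from cell `i` (column-major index) to each cell in
#' one step. Used to verify the sampler against linear-algebra predictions —
#' e.g. its stationary distribution is the normalized `P^2/M` for the trail
#' variant with frozen memory.
#'
#' @inheritParams acceptance_ratio
#' @return A dense `(n_rows*n_cols)` square stochastic matrix.
#' @export
transition_matrix <- function(p, m, variant = c("plain_mh", "trail")) {
  variant <- match_variant(variant)
  nr <- nrow(p); nc <- ncol(p); ncell <- nr * nc
  tm <- matrix(0, ncell, ncell)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      i <- (cc - 1L) * nr + r
      for (dr in -1:1) {
        for (dc in -1:1) {
          to <- wrap_state(r + dr, cc + dc, nr, nc)
          j <- (to[2] - 1L) * nr + to[1]
          ratio <- acceptance_ratio(p, m, c(r, cc), to, variant)
          acc <- min(1, ratio)
          tm[i, j] <- tm[i, j] + acc / 9
          tm[i, i] <- tm[i, i] + (1 - acc) / 9
        }
      }
    }
  }
  tm
}
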