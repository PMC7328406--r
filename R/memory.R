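#' Externalized memory of visited states
#'
#' The self-avoiding sampler's memory `M` is a field of positive per-cell
#' weights: a Dirichlet prior of `alpha` pseudo-counts in every cell plus one
#' deposit for every step the walker has spent there — the lattice analogue of
#' a repellent chemical marker laid at every visited location. Normalizing the
#' weights gives the walker's running model of the target, which converges to
#' the target itself as exploration proceeds.
#'
#' Weights are stored unnormalized. The sampler's acceptance ratio only ever
#' uses `M` through the quotient `M(current)/M(proposed)`, which is invariant
#' under global rescaling, so keeping raw counts is exactly equivalent to
#' renormalizing the field to a probability distribution at every step while
#' costing O(1) per deposit.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param alpha Positive prior pseudo-count per cell.
#' @param decay_lambda Nonnegative per-step decay constant: each step the
#'   deposit excess above the prior is multiplied by `exp(-decay_lambda)`,
#'   modelling markers that fade with time. The prior floor never decays, so
#'   the field stays strictly positive.
#' @param counts Optional initial weight matrix (defaults to the pure prior);
#'   must be at least `alpha` everywhere.
#' @return An object of class `memory_model` with elements `counts`, `alpha`,
#'   `decay_lambda`.
#' @examples
#' m <- memory_model(2, 2, alpha = 1)
#' sum(m$counts)  # 4: the pure Dirichlet prior
#' @export
memory_model <- function(n_rows, n_cols, alpha = 1, decay_lambda = 0,
                         counts = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(decay_lambda) || length(decay_lambda) != 1 ||
      is.na(decay_lambda) || decay_lambda < 0) {
    stop("`decay_lambda` must be nonnegative", call. = FALSE)
  }
  if (is.null(counts)) {
    counts <- matrix(alpha, n_rows, n_cols)
  } else {
    if (!is.matrix(counts) || nrow(counts) != n_rows ||
        ncol(counts) != n_cols) {
      stop("`counts` must be an n_rows x n_cols matrix", call. = FALSE)
    }
    if (any(counts < alpha)) {
      stop("memory weights must be at least `alpha` everywhere",
           call. = FALSE)
    }
  }
  structure(list(counts = counts, alpha = alpha,
                 decay_lambda = decay_lambda),
            class = "memory_model")
}

#' @export
print.memory_model <- function(x, ...) {
  cat(sprintf(
    "<memory_model> %d x %d cells, alpha = %g, decay_lambda = %g, %g deposits\n",
    nrow(x$counts), ncol(x$counts), x$alpha, x$decay_lambda,
    sum(x$counts) - x$alpha * length(x$counts)))
  invisible(x)
}

#' Reset a memory to its pure prior
#'
#' The "cleaning" operation: removes every accumulated deposit, leaving
#' `alpha` in each cell — the in-silico counterpart of wiping an arena of
#' chemical marks between successive walkers.
#'
#' @param m A [memory_model()].
#' @return The reset `memory_model`.
#' @export
reset_memory <- function(m) {
  stopifnot(inherits(m, "memory_model"))
  m$counts[] <- m$alpha
  m
}

#' Normalized view of a memory field
#'
#' @param m A [memory_model()].
#' @return A [grid_distribution()] of the memory weights divided by their sum.
#' @export
memory_distribution <- function(m) {
  stopifnot(inherits(m, "memory_model"))
  grid_distribution(m$counts)
}
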