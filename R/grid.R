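#' Discrete probability distributions on a 2D lattice
#'
#' A `grid_distribution` is a nonnegative matrix of probability mass per cell
#' that sums to one. It serves three roles throughout the package: the target
#' distribution a sampler tries to draw from, the (normalized view of the)
#' sampler's externalized memory, and empirical density estimates built from
#' visit counts or trajectories.
#'
#' @param values Numeric matrix of nonnegative cell masses. It is normalized
#'   to total mass one unless `normalize = FALSE`, in which case it must
#'   already sum to one within `1e-9`.
#' @param normalize Divide `values` by their sum (default `TRUE`).
#' @return An object of class `grid_distribution`: the probability matrix with
#'   attributes preserved.
#' @examples
#' p <- grid_distribution(matrix(1, 2, 2))
#' sum(p)        # 1
#' entropy(p)    # log(4)
#' @seealso [sparse_gamma_target()], [entropy()], [cross_entropy()]
#' @export
grid_distribution <- function(values, normalize = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("grid values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("grid values must be nonnegative", call. = FALSE)
  }
  total <- sum(values)
  if (normalize) {
    if (total <= 0) stop("total mass must be positive", call. = FALSE)
    values <- values / total
  } else if (abs(total - 1) > 1e-9) {
    stop("grid mass must sum to 1 within 1e-9 (or set normalize = TRUE)",
         call. = FALSE)
  }
  structure(values, class = c("grid_distribution", "matrix", "array"))
}

#' @export
print.grid_distribution <- function(x, ...) {
  cat(sprintf("<grid_distribution> %d x %d cells, entropy %.4f nats\n",
              nrow(x), ncol(x), entropy(x)))
  invisible(x)
}

is_grid_distribution <- function(x) inherits(x, "grid_distribution")

stopifnot_grid <- function(p, arg = "p") {
  if (!is_grid_distribution(p)) {
    stop(sprintf("`%s` must be a grid_distribution", arg), call. = FALSE)
  }
  invisible(p)
}

#' Sparse random target distribution from i.i.d. gamma draws
#'
#' Generates a target on an `n_rows` x `n_cols` lattice by drawing every cell
#' independently from a gamma distribution with shape `shape_k` and scale 1,
#' then normalizing. Jointly the normalized cells are Dirichlet(`shape_k`)
#' distributed: small shapes (e.g. 0.1) give mostly low-probability cells with
#' a few high-probability ones — the kind of sparse landscape a central-place
#' forager confronts, where most surrounding space holds nothing of value.
#'
#' @param n_rows,n_cols Positive lattice dimensions.
#' @param shape_k Positive gamma shape parameter; the scale is fixed at 1.
#' @param seed Integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @return A [grid_distribution()].
#' @examples
#' p <- sparse_gamma_target(50, 50, shape_k = 0.1, seed = 1)
#' entropy(p) < log(50 * 50)   # sparse, so well below uniform entropy
#' @export
sparse_gamma_target <- function(n_rows, n_cols, shape_k, seed = NULL) {
  if (!is.numeric(n_rows) || length(n_rows) != 1 || n_rows < 1 ||
      n_rows != round(n_rows) ||
      !is.numeric(n_cols) || length(n_cols) != 1 || n_cols < 1 ||
      n_cols != round(n_cols)) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(shape_k) || length(shape_k) != 1 || !is.finite(shape_k) ||
      shape_k <= 0) {
    stop("`shape_k` must be a positive number", call. = FALSE)
  }
  draws <- with_local_seed(seed, stats::rgamma(n_rows * n_cols, shape = shape_k,
                                               scale = 1))
  # underflowed draws at tiny shapes stay as true zeros; samplers must cope
  grid_distribution(matrix(draws, nrow = n_rows, ncol = n_cols))
}

#' Shannon entropy of a grid distribution (nats)
#'
#' Computes `-sum(p * log(p))` with the convention `0 * log(0) = 0`. This is
#' the floor every cross-entropy curve converges to: an estimate equal to the
#' reference on its support attains it exactly.
#'
#' @param p A [grid_distribution()].
#' @return Entropy in nats.
#' @export
entropy <- function(p) {
  stopifnot_grid(p)
  v <- p[p > 0]
  -sum(v * log(v))
}

#' Cross-entropy between two grid distributions (nats)
#'
#' Computes `-sum(reference * log(estimate))`, the package's convergence
#' measure: it is bounded below by `entropy(reference)` (Gibbs' inequality)
#' with equality iff the estimate matches the reference on its support, so a
#' falling cross-entropy means the estimate is approaching the reference.
#'
#' Cells where the estimate is zero but the reference is positive are refused
#' rather than imputed: callers are expected to smooth their estimates first
#' (see e.g. the `smoothing_alpha` of [visit_distribution()]).
#'
#' @param reference,estimate [grid_distribution()]s of identical dimensions.
#' @return Cross-entropy in nats.
#' @export
cross_entropy <- function(reference, estimate) {
  stopifnot_grid(reference, "reference")
  stopifnot_grid(estimate, "estimate")
  if (!identical(dim(reference), dim(estimate))) {
    stop("`reference` and `estimate` must have identical dimensions",
         call. = FALSE)
  }
  sup <- reference > 0
  if (any(estimate[sup] == 0)) {
    stop("estimate has zero mass on the reference support; smooth it first",
         call. = FALSE)
  }
  -sum(reference[sup] * log(estimate[sup]))
}

#' Kullback-Leibler divergence KL(reference || estimate) in nats
#'
#' Convenience wrapper: `cross_entropy(reference, estimate) -
#' entropy(reference)`.
#'
#' @inheritParams cross_entropy
#' @return Nonnegative divergence in nats.
#' @export
kl_divergence <- function(reference, estimate) {
  cross_entropy(reference, estimate) - entropy(reference)
}

#' Read and write grid distributions as plain text
#'
#' The grid file format is a whitespace-separated matrix preceded by
#' `#`-prefixed header lines. The header always carries the dimensions
#' (`# dims: <n_rows> <n_cols>`) and any provenance key-value pairs supplied
#' at write time (for instance the seed and shape of a random target, or the
#' manifest of trajectories behind an empirical one). Values are written with
#' full double precision so a write/read cycle round-trips exactly.
#'
#' @param p A [grid_distribution()].
#' @param path File path.
#' @param provenance Named character vector (or coercible) of extra header
#'   fields.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns the
#'   [grid_distribution()] with a `provenance` attribute holding the header
#'   fields.
#' @export
write_grid <- function(p, path, provenance = character()) {
  stopifnot_grid(p)
  hdr <- c(sprintf("# dims: %d %d", nrow(p), ncol(p)))
  if (length(provenance)) {
    keys <- names(provenance)
    if (is.null(keys) || any(keys == "")) {
      stop("`provenance` must be a named vector", call. = FALSE)
    }
    hdr <- c(hdr, sprintf("# %s: %s", keys, as.character(provenance)))
  }
  rows <- apply(unclass(p), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- regmatches(hdr, regexec("^([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else "", "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else "", "")
  dims <- as.integer(strsplit(trimws(vals[keys == "dims"][1]), "\\s+")[[1]])
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  values <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                  as.numeric))
  if (!is.na(dims[1]) && (nrow(values) != dims[1] || ncol(values) != dims[2])) {
    stop(sprintf("grid file dims header says %d x %d but body is %d x %d",
                 dims[1], dims[2], nrow(values), ncol(values)), call. = FALSE)
  }
  p <- grid_distribution(values, normalize = FALSE)
  attr(p, "provenance") <- stats::setNames(vals[keys != "dims"],
                                           keys[keys != "dims"])
  p
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
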