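#' Cumulative cross-entropy convergence curves by walker order
#'
#' For each treatment and colony, pools the trajectories of walkers
#' `1..k` (for `k = 1 .. max order), rebuilds the blurred log-polar density
#' of the pooled points, and scores it against `final_target` by
#' cross-entropy. A falling curve means successive walkers are filling in the
#' parts of the target their predecessors missed; the floor is the entropy of
#' the final target. Colony curves are then averaged within treatment and the
#' standard error of the mean across colonies reported.
#'
#' Because a partial density can be exactly zero where the target is positive
#' (the blur kernel has finite support), each density is mixed with a uniform
#' distribution before scoring: `(1 - smoothing) * density + smoothing *
#' uniform`. The default mixing weight is small enough to leave the identity
#' case (curve built from the same pooling as the target) within a fraction
#' of a millinat of the entropy floor.
#'
#' @param trajs A trajectory table with `treatment`, `colony`, `order`
#'   labels; every colony must carry each order `1..max(order)` for its
#'   treatment.
#' @param final_target [grid_distribution()] on the spec's truncated lattice.
#' @param spec A [logpolar_spec()].
#' @param center Nest position (mm).
#' @param mask_half_width_mm Central mask half-width (mm); `NULL` to skip.
#' @param smoothing Uniform mixing weight in `[0, 1)`.
#' @return A `ce_curve_set`: list with `by_colony` (data.frame `treatment`,
#'   `colony`, `order`, `ce_nats`), `summary` (data.frame `treatment`,
#'   `order`, `mean_ce`, `se_ce`, `n_colonies`), and `target_entropy`.
#' @export
cumulative_ce_curves <- function(trajs, final_target, spec = logpolar_spec(),
                                 center = c(0, 0), mask_half_width_mm = 75,
                                 smoothing = 1e-6) {
  stopifnot_grid(final_target, "final_target")
  stopifnot(smoothing >= 0, smoothing < 1)
  if (!is.null(mask_half_width_mm)) {
    trajs <- remove_mask_region(trajs, mask_half_width_mm)
  }
  ncell <- length(final_target)
  unif <- 1 / ncell
  rows <- list()
  for (tr in sort(unique(trajs$treatment))) {
    sub_t <- trajs[trajs$treatment == tr, , drop = FALSE]
    orders <- sort(unique(sub_t$order))
    max_order <- max(orders)
    for (col_id in sort(unique(sub_t$colony))) {
      sub <- sub_t[sub_t$colony == col_id, , drop = FALSE]
      have <- sort(unique(sub$order))
      gap <- setdiff(seq_len(max_order), have)
      if (length(gap)) {
        stop(sprintf("treatment %s, colony %s is missing order(s) %s", tr,
                     col_id, paste(gap, collapse = ", ")), call. = FALSE)
      }
      cum_counts <- NULL
      for (k in seq_len(max_order)) {
        pts <- sub[sub$order == k, , drop = FALSE]
        lp <- cartesian_to_logpolar(pts, center = center,
                                    lnr_min = spec$lnr_min,
                                    lnr_max = spec$lnr_max)
        counts_k <- bin_logpolar(periodic_pad(lp), spec)
        cum_counts <- if (is.null(cum_counts)) counts_k else
          cum_counts + counts_k
        dens <- finish_density(cum_counts, spec)
        est <- grid_distribution(
          (1 - smoothing) * unclass(dens) + smoothing * unif,
          normalize = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, colony = col_id, order = k,
          ce_nats = cross_entropy(final_target, est))
      }
    }
  }
  by_colony <- do.call(rbind, rows)
  agg <- stats::aggregate(ce_nats ~ treatment + order, by_colony,
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  summary_df <- data.frame(treatment = agg$treatment, order = agg$order,
                           mean_ce = agg$ce_nats[, "mean"],
                           se_ce = agg$ce_nats[, "se"],
                           n_colonies = agg$ce_nats[, "n"])
  summary_df <- summary_df[order(summary_df$treatment, summary_df$order), ]
  rownames(summary_df) <- NULL
  structure(list(by_colony = by_colony, summary = summary_df,
                 target_entropy = entropy(final_target)),
            class = "ce_curve_set")
}

#' @export
print.ce_curve_set <- function(x, ...) {
  cat("<ce_curve_set>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("entropy floor of target: %.4f nats\n", x$target_entropy))
  invisible(x)
}

#' Paired treatment samples from a curve set
#'
#' Extracts aligned (colony, order) cross-entropy values for two treatments,
#' restricted to `orders` — the shape [permutation_test()] consumes. The
#' first-released walker is conventionally excluded from testing (orders 2
#' and up) because both treatments are equivalent until a predecessor has
#' marked the arena.
#'
#' @param curves A `ce_curve_set` from [cumulative_ce_curves()].
#' @param treatment_a,treatment_b Treatment labels.
#' @param orders Integer vector of orders to keep.
#' @return List with `values_a`, `values_b`, and `labels` (data.frame
#'   `colony`, `order`).
#' @export
paired_treatment_samples <- function(curves, treatment_a = "NC",
                                     treatment_b = "C", orders = 2:6) {
  stopifnot(inherits(curves, "ce_curve_set"))
  bc <- curves$by_colony
  a <- bc[bc$treatment == treatment_a & bc$order %in% orders, ]
  b <- bc[bc$treatment == treatment_b & bc$order %in% orders, ]
  a <- a[order(a$colony, a$order), ]
  b <- b[order(b$colony, b$order), ]
  if (nrow(a) == 0 || nrow(a) != nrow(b) ||
      !all(a$order == b$order) || !all(a$colony == b$colony)) {
    stop("treatments are not aligned on the same (colony, order) cells",
         call. = FALSE)
  }
  list(values_a = a$ce_nats, values_b = b$ce_nats,
       labels = data.frame(colony = a$colony, order = a$order))
}
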