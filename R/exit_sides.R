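#' First exit side of each trajectory from a centred square
#'
#' For every walker, finds the first segment of its path that crosses the
#' boundary of the square of half-width `square_half_width_mm` centred on the
#' nest, locates the crossing by linear interpolation along the segment, and
#' records which side (`right` x = +w, `left` x = -w, `top` y = +w, `bottom`
#' y = -w) was hit first. When a single segment would cross two sides, the
#' side reached at the smaller interpolation parameter wins (ties broken in
#' the order right, left, top, bottom). Walkers that never leave the square
#' are not assigned a side; they are tallied separately rather than silently
#' dropped.
#'
#' @param trajs A trajectory table.
#' @param square_half_width_mm Half-width of the virtual square (mm).
#' @return List with `counts` (named integer vector over the four sides),
#'   `n_non_exiting`, and `by_ant` (data.frame `ant_id`, `colony`,
#'   `treatment`, `order`, `side` with `NA` for non-exiting walkers).
#' @export
exit_sides <- function(trajs, square_half_width_mm) {
  w <- square_half_width_mm
  sides <- c("right", "left", "top", "bottom")
  ants <- unique(trajs$ant_id)
  side_of <- character(length(ants))
  meta <- vector("list", length(ants))
  for (k in seq_along(ants)) {
    sub <- trajs[trajs$ant_id == ants[k], , drop = FALSE]
    meta[[k]] <- sub[1, c("ant_id", "colony", "treatment", "order")]
    side_of[k] <- first_exit_side(sub$x_mm, sub$y_mm, w)
  }
  counts <- vapply(sides, function(s) sum(side_of == s), integer(1))
  by_ant <- do.call(rbind, meta)
  by_ant$side <- ifelse(side_of == "none", NA_character_, side_of)
  rownames(by_ant) <- NULL
  list(counts = counts, n_non_exiting = sum(side_of == "none"),
       by_ant = by_ant)
}

first_exit_side <- function(x, y, w) {
  inside <- pmax(abs(x), abs(y)) < w
  if (!inside[1]) return(point_side(x[1], y[1]))
  n <- length(x)
  if (n < 2) return("none")
  cross <- which(inside[-n] & !inside[-1])
  if (!length(cross)) return("none")
  i <- cross[1]
  segment_exit_side(x[i], y[i], x[i + 1], y[i + 1], w)
}

# Side whose boundary the segment (x1,y1) -> (x2,y2) reaches first, the start
# lying strictly inside the square.
segment_exit_side <- function(x1, y1, x2, y2, w) {
  t_side <- c(
    right  = if (x2 > x1)  (w - x1) / (x2 - x1) else Inf,
    left   = if (x2 < x1) (-w - x1) / (x2 - x1) else Inf,
    top    = if (y2 > y1)  (w - y1) / (y2 - y1) else Inf,
    bottom = if (y2 < y1) (-w - y1) / (y2 - y1) else Inf)
  t_side[t_side < 0 | t_side > 1] <- Inf
  names(t_side)[which.min(t_side)]
}

# Classification for a walker already outside the square at its first point.
point_side <- function(x, y) {
  if (abs(x) >= abs(y)) {
    if (x >= 0) "right" else "left"
  } else {
    if (y >= 0) "top" else "bottom"
  }
}
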