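#' Trajectory tables
#'
#' Trajectories are kept in a long data.frame with one row per tracked
#' position and columns `ant_id`, `colony`, `treatment`, `order`, `t_s`,
#' `x_mm`, `y_mm`. Coordinates are arena-centred millimetres (origin at the
#' nest, y increasing upward) sampled on a fixed time step (0.1 s by
#' default); `order` is the 1-based release rank of the walker within its
#' colony, and `treatment` a free label — by convention `"NC"` (markers left
#' to accumulate between walkers) or `"C"` (arena cleaned between walkers).
#'
#' `as_trajectories()` validates a data.frame against these invariants:
#' required columns present, timestamps strictly increasing per ant with
#' constant spacing `dt_s`, and positions within the centred square arena of
#' side `arena_mm`.
#'
#' @param df A data.frame with the columns above.
#' @param arena_mm Arena side length (mm).
#' @param dt_s Required time spacing (s).
#' @return `df` with class `trajectories` prepended, and `arena_mm`, `dt_s`
#'   attributes.
#' @export
as_trajectories <- function(df, arena_mm = 900, dt_s = 0.1) {
  required <- c("ant_id", "colony", "treatment", "order", "t_s", "x_mm",
                "y_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing trajectory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$order <- as.integer(df$order)
  if (any(is.na(df$order)) || any(df$order < 1)) {
    stop("`order` must be a positive integer", call. = FALSE)
  }
  half <- arena_mm / 2
  if (any(abs(df$x_mm) > half + 1e-9) || any(abs(df$y_mm) > half + 1e-9)) {
    stop(sprintf("positions outside the %g x %g mm arena", arena_mm,
                 arena_mm), call. = FALSE)
  }
  for (id in unique(df$ant_id)) {
    t_s <- df$t_s[df$ant_id == id]
    if (length(t_s) > 1) {
      dt <- diff(t_s)
      if (any(dt <= 0) || any(abs(dt - dt_s) > 1e-6)) {
        stop(sprintf("ant %s: timestamps must increase by exactly %g s", id,
                     dt_s), call. = FALSE)
      }
    }
  }
  structure(df, class = unique(c("trajectories", class(df))),
            arena_mm = arena_mm, dt_s = dt_s)
}

#' Read and write trajectory CSV files
#'
#' The dialect is a plain CSV with header
#' `ant_id,colony,treatment,order,t_s,x_mm,y_mm`. The reader validates
#' spacing and arena bounds via [as_trajectories()]; the writer emits the
#' same dialect.
#'
#' @param path File path.
#' @inheritParams as_trajectories
#' @return `read_trajectory_csv()` returns a validated trajectory table;
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path, arena_mm = 900, dt_s = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ant_id = "character",
                                       colony = "character",
                                       treatment = "character"))
  as_trajectories(df, arena_mm = arena_mm, dt_s = dt_s)
}

#' @rdname read_trajectory_csv
#' @param trajs A trajectory table.
#' @export
write_trajectory_csv <- function(trajs, path) {
  cols <- c("ant_id", "colony", "treatment", "order", "t_s", "x_mm", "y_mm")
  utils::write.csv(as.data.frame(trajs)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Remove the central masked region from trajectories
#'
#' Drops every point lying strictly inside the centred square mask of
#' half-width `half_width_mm` (a 15 x 15 cm mask by default), where walkers
#' mill around their entrance and follow the mask edge rather than explore;
#' points exactly on the mask boundary are kept. Row order is preserved and
#' an empty result is allowed.
#'
#' @param trajs A trajectory table (or any data.frame with `x_mm`, `y_mm`).
#' @param half_width_mm Mask half-width (mm).
#' @return The filtered table.
#' @export
remove_mask_region <- function(trajs, half_width_mm = 75) {
  keep <- pmax(abs(trajs$x_mm), abs(trajs$y_mm)) >= half_width_mm
  trajs[keep, , drop = FALSE]
}

#' Total tracked duration of a trajectory table
#'
#' Sums `(n_points - 1) * dt` over ants.
#'
#' @param trajs A trajectory table.
#' @param dt_s Time step (s); defaults to the table's `dt_s` attribute.
#' @return Total duration in seconds.
#' @export
total_duration_s <- function(trajs, dt_s = NULL) {
  if (is.null(dt_s)) dt_s <- attr(trajs, "dt_s") %||% 0.1
  n_per <- table(trajs$ant_id)
  sum(pmax(n_per - 1, 0)) * dt_s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
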