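# Single-cell motility metrics from trajectories: per-interval speeds,
# reversal counts per observation window, and the inclusion filter keeping
# only cells that moved through the entire recording.

validate_tracks <- function(tracks) {
  need <- c("cell", "time_s", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    abort(sprintf("`tracks` needs columns %s.", paste(need, collapse = ", ")))
  }
  invisible(tracks)
}

#' Per-interval speeds of tracked cells
#'
#' The Euclidean displacement between consecutive frames divided by the frame
#' interval, reported in micrometres per minute. Standard recordings use a
#' 20-second interval (pili-driven motility) or a 30-second interval
#' (gliding).
#'
#' @param tracks Tibble with columns `cell`, `time_s`, `x_um`, `y_um`.
#' @param interval Expected frame interval in seconds; frame times must match
#'   it (validation error otherwise).
#' @return Tibble with one row per interval: `cell`, `time_s` (interval
#'   start), `step_um`, `speed_um_min`.
#' @export
interval_speeds <- function(tracks, interval = 30) {
  validate_tracks(tracks)
  tracks <- dplyr::arrange(tracks, .data$cell, .data$time_s)
  out <- dplyr::reframe(
    dplyr::group_by(tracks, .data$cell),
    {
      ts <- .data$time_s
      dt <- diff(ts)
      if (length(dt) == 0L) abort("Each track needs at least 2 points.")
      if (any(abs(dt - interval) > 1e-6)) {
        abort(sprintf(
          "Track %s frame interval does not match %g s.", .data$cell[1], interval))
      }
      step <- sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)
      t_start <- ts[-length(ts)]
      tibble(time_s = t_start, step_um = step,
             speed_um_min = step / interval * 60)
    })
  dplyr::ungroup(out)
}

# Reversal count of a single track given its step vectors (rows = intervals).
# A reversal is scored when the direction of a significant step (length >=
# min_step) turns by at least `angle_threshold` degrees from the current
# heading AND the next significant step confirms the new direction (so the
# new direction persists for >= 2 intervals). The heading then flips; an
# unconfirmed turn is treated as jitter.
count_reversals_steps <- function(dx, dy, angle_threshold, min_step) {
  norms <- sqrt(dx^2 + dy^2)
  sig <- which(norms >= min_step)
  if (length(sig) == 0L) return(list(n = 0L, moving = FALSE))
  # small tolerance so an exactly antiparallel step (dot = -1) passes a
  # 180-degree threshold despite floating-point rounding
  cos_thr <- cos(angle_threshold * pi / 180) + 1e-9
  ref <- c(dx[sig[1]], dy[sig[1]]) / norms[sig[1]]
  n_rev <- 0L
  j <- 2L
  while (j <= length(sig)) {
    k <- sig[j]
    v <- c(dx[k], dy[k]) / norms[k]
    turned <- sum(ref * v) <= cos_thr
    if (turned) {
      if (j < length(sig)) {
        k2 <- sig[j + 1L]
        v2 <- c(dx[k2], dy[k2]) / norms[k2]
        if (sum(ref * v2) <= cos_thr) {
          n_rev <- n_rev + 1L
          ref <- v
        }
        # unconfirmed turn: jitter, heading unchanged
      }
    } else {
      ref <- v
    }
    j <- j + 1L
  }
  list(n = n_rev, moving = TRUE)
}

#' Count direction reversals per track
#'
#' Operationalizes a reversal as a turn of the net displacement direction by
#' at least `angle_threshold` (default 120 degrees) sustained for at least two
#' intervals, considering only steps of length `min_step` or more. The
#' defaults tolerate positional noise while still catching true 180-degree
#' flips; with `angle_threshold = 180` and `min_step = 0` the count on
#' noise-free tracks equals the number of programmed flips exactly.
#'
#' @param tracks Tibble with columns `cell`, `time_s`, `x_um`, `y_um`.
#' @param angle_threshold Minimum turn angle in degrees (default 120).
#' @param min_step Minimum displacement (um) for a step to define direction
#'   (default 0.03, half a typical 0.06 um pixel).
#' @return Tibble with `cell`, `n_reversals`, `moving` (`FALSE` when every
#'   step fell below `min_step`).
#' @export
count_reversals <- function(tracks, angle_threshold = 120, min_step = 0.03) {
  validate_tracks(tracks)
  assert_scalar_number(angle_threshold, "angle_threshold", min = 0, max = 180)
  assert_scalar_number(min_step, "min_step", min = 0)
  tracks <- dplyr::arrange(tracks, .data$cell, .data$time_s)
  out <- dplyr::reframe(
    dplyr::group_by(tracks, .data$cell),
    {
      res <- count_reversals_steps(diff(.data$x_um), diff(.data$y_um),
                                   angle_threshold, min_step)
      n_rev <- res$n
      is_moving <- res$moving
      tibble(n_reversals = n_rev, moving = is_moving)
    })
  dplyr::ungroup(out)
}

#' Keep only cells that moved for the entire recording
#'
#' A cell is retained if every single interval displacement is at least
#' `min_step` — the frame-local reading of "moved for the entire recording
#' period". Cells that pause for even one frame are excluded.
#'
#' @param tracks Tibble with columns `cell`, `time_s`, `x_um`, `y_um`.
#' @param min_step Minimum per-interval displacement in micrometres.
#' @return The subset of `tracks` for the retained cells.
#' @export
filter_moving <- function(tracks, min_step = 0.03) {
  validate_tracks(tracks)
  if (nrow(tracks) == 0L) return(tracks)
  tracks <- dplyr::arrange(tracks, .data$cell, .data$time_s)
  keep <- dplyr::summarise(
    dplyr::group_by(tracks, .data$cell),
    ok = all(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) >= min_step),
    .groups = "drop")
  dplyr::semi_join(tracks, dplyr::filter(keep, .data$ok), by = "cell")
}

#' Per-cell motility summary
#'
#' One row per cell: mean per-interval speed, raw reversal count, the count
#' normalized to the observation window (reversals scaled by
#' `window / track duration`), and whether the cell moved throughout.
#' Typically applied after [filter_moving()].
#'
#' @param tracks Tibble with columns `cell`, `time_s`, `x_um`, `y_um`.
#' @param interval Frame interval in seconds.
#' @param window Observation window in minutes for reversal normalization
#'   (default 15).
#' @param angle_threshold,min_step Passed to [count_reversals()].
#' @return A tibble of class `rodpol_motility`: `cell`, `mean_speed_um_min`,
#'   `n_reversals`, `reversals_per_window`, `moved_throughout`.
#' @export
summarize_motility <- function(tracks, interval = 30, window = 15,
                               angle_threshold = 120, min_step = 0.03) {
  speeds <- interval_speeds(tracks, interval = interval)
  revs <- count_reversals(tracks, angle_threshold = angle_threshold,
                          min_step = min_step)
  per_cell <- dplyr::summarise(
    dplyr::group_by(speeds, .data$cell),
    mean_speed_um_min = mean(.data$speed_um_min),
    duration_min = (dplyr::n() * interval) / 60,
    moved_throughout = all(.data$step_um >= min_step),
    .groups = "drop")
  out <- dplyr::left_join(per_cell, revs, by = "cell")
  out <- dplyr::mutate(
    out,
    reversals_per_window = .data$n_reversals * window / .data$duration_min)
  out <- dplyr::select(out, "cell", "mean_speed_um_min", "n_reversals",
                       "reversals_per_window", "moved_throughout")
  class(out) <- c("rodpol_motility", class(out))
  out
}

#' Strain-level motility statistics
#'
#' Mean and SD of per-cell mean speed and window-normalized reversal count,
#' across cells (per replicate) and across replicate means.
#'
#' @param per_cell A `rodpol_motility` tibble from [summarize_motility()].
#' @param replicate Replicate labels, one per cell (default: one replicate).
#' @return Tibble with one row per replicate plus a pooled row (mean and SD
#'   of the replicate means).
#' @export
aggregate_motility <- function(per_cell, replicate = NULL) {
  if (is.null(replicate)) replicate <- rep("1", nrow(per_cell))
  if (length(replicate) != nrow(per_cell)) {
    abort("`replicate` must give one label per cell.")
  }
  df <- dplyr::mutate(as_tibble(per_cell), replicate = as.character(replicate))
  per_rep <- dplyr::summarise(
    dplyr::group_by(df, .data$replicate),
    n_cells = dplyr::n(),
    mean_speed = mean(.data$mean_speed_um_min),
    sd_speed = sd(.data$mean_speed_um_min),
    mean_reversals = mean(.data$reversals_per_window),
    sd_reversals = sd(.data$reversals_per_window),
    .groups = "drop")
  pooled <- tibble(
    replicate = "pooled",
    n_cells = sum(per_rep$n_cells),
    mean_speed = mean(per_rep$mean_speed),
    sd_speed = sd(per_rep$mean_speed),
    mean_reversals = mean(per_rep$mean_reversals),
    sd_reversals = sd(per_rep$mean_reversals))
  dplyr::bind_rows(per_rep, pooled)
}
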