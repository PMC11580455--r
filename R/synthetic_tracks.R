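# Synthetic single-cell trajectories: constant-speed runs along a straight
# line, direction flipped by 180 degrees at programmed reversal times, plus
# optional Gaussian positional noise. Ground-truth reversal counts are stored
# regardless of noise.

#' Specify synthetic motility trajectories
#'
#' Defaults mirror a standard single-cell motility assay: cells observed for
#' 15 min at 30-second intervals (20-second intervals are the usual
#' alternative for pili-driven motility assays).
#'
#' @param n_tracks Number of trajectories.
#' @param speed Run speed in micrometres per minute.
#' @param frame_interval Time between frames, in seconds.
#' @param duration Recording duration, in minutes.
#' @param reversal_times `NULL` (no reversals), a numeric vector applied to
#'   every track, or a list of `n_tracks` numeric vectors — times in minutes,
#'   strictly increasing, inside `(0, duration)`.
#' @param positional_noise_sd Gaussian noise SD added independently to each
#'   coordinate, in micrometres.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `track_spec`.
#' @export
track_spec <- function(n_tracks = 1L,
                       speed = 2,
                       frame_interval = 30,
                       duration = 15,
                       reversal_times = NULL,
                       positional_noise_sd = 0,
                       seed = NULL) {
  assert_scalar_number(n_tracks, "n_tracks", min = 1)
  assert_scalar_number(speed, "speed", min = 0)
  assert_scalar_number(frame_interval, "frame_interval", min = 1e-9)
  assert_scalar_number(duration, "duration", min = 1e-9)
  assert_scalar_number(positional_noise_sd, "positional_noise_sd", min = 0)
  if (is.numeric(reversal_times)) {
    reversal_times <- rep(list(reversal_times), n_tracks)
  }
  if (!is.null(reversal_times)) {
    if (length(reversal_times) != n_tracks) {
      abort("`reversal_times` must have one entry per track.")
    }
    for (rt in reversal_times) {
      if (length(rt) > 0 &&
          (any(diff(rt) <= 0) || any(rt <= 0) || any(rt >= duration))) {
        abort("Reversal times must be strictly increasing and inside (0, duration).")
      }
    }
  }
  structure(list(n_tracks = as.integer(n_tracks), speed = speed,
                 frame_interval = frame_interval, duration = duration,
                 reversal_times = reversal_times,
                 positional_noise_sd = positional_noise_sd, seed = seed),
            class = "track_spec")
}

#' Draw well-separated reversal times on the frame grid
#'
#' Helper for building [track_spec()]s: draws `n` reversal times as multiples
#' of the frame interval, at least `edge_gap` intervals from both ends of the
#' recording and at least `min_gap` intervals apart — the spacing at which a
#' reversal is unambiguous to a detector requiring two intervals of
#' persistence. (Cells of gliding bacteria typically reverse no more than a
#' few times per 15 min, so well-separated reversals are the realistic case.)
#'
#' @param n Number of reversals.
#' @param duration Recording duration in minutes.
#' @param frame_interval Frame interval in seconds.
#' @param min_gap Minimum separation in intervals (default 3).
#' @param edge_gap Minimum distance from the start/end in intervals (default 2).
#' @return Numeric vector of times in minutes.
#' @export
draw_reversal_times <- function(n, duration = 15, frame_interval = 30,
                                min_gap = 3L, edge_gap = 2L) {
  if (n == 0) return(numeric())
  n_frames <- floor(duration * 60 / frame_interval)
  candidates <- seq(edge_gap, n_frames - edge_gap)
  if (length(candidates) < n * min_gap) {
    abort("Recording too short for the requested number of reversals.")
  }
  repeat {
    picks <- sort(sample(candidates, n))
    if (n == 1 || all(diff(picks) >= min_gap)) break
  }
  picks * frame_interval / 60
}

#' Generate synthetic trajectories with ground truth
#'
#' Each track starts at a random position with a random heading and moves at
#' constant speed; at each programmed reversal time the direction flips by
#' 180 degrees (before noise). Positions are sampled at the frame times by
#' exact integration of the signed progress, so reversal times need not fall
#' on the frame grid.
#'
#' @param spec A [track_spec()].
#' @return A list of class `rodpol_tracks`: `tracks`, a tibble with columns
#'   `cell`, `time_s`, `x_um`, `y_um` (one row per cell per frame), and
#'   `truth`, a tibble with `cell`, `speed_true` (um/min) and
#'   `n_reversals_true`.
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dt <- spec$frame_interval
  n_frames <- floor(spec$duration * 60 / dt)
  times <- (0:n_frames) * dt
  v_um_s <- spec$speed / 60
  tracks <- vector("list", spec$n_tracks)
  truth <- vector("list", spec$n_tracks)
  for (i in seq_len(spec$n_tracks)) {
    rev_s <- if (is.null(spec$reversal_times)) numeric() else
      spec$reversal_times[[i]] * 60
    # signed progress p(t): piecewise linear, slope alternating +1/-1 across
    # the reversal breakpoints
    brk <- c(0, rev_s)
    sign_seg <- (-1)^(seq_along(brk) - 1)
    p_brk <- c(0, cumsum(sign_seg[-length(brk)] * diff(brk)))
    seg <- findInterval(times, brk)
    p <- p_brk[seg] + sign_seg[seg] * (times - brk[seg])
    heading <- runif(1, 0, 2 * pi)
    u <- c(cos(heading), sin(heading))
    start <- runif(2, 0, 50)
    x <- start[1] + u[1] * v_um_s * p
    y <- start[2] + u[2] * v_um_s * p
    if (spec$positional_noise_sd > 0) {
      x <- x + rnorm(length(x), 0, spec$positional_noise_sd)
      y <- y + rnorm(length(y), 0, spec$positional_noise_sd)
    }
    tracks[[i]] <- tibble(cell = i, time_s = times, x_um = x, y_um = y)
    truth[[i]] <- tibble(cell = i, speed_true = spec$speed,
                         n_reversals_true = length(rev_s))
  }
  structure(list(tracks = dplyr::bind_rows(tracks),
                 truth = dplyr::bind_rows(truth),
                 spec = spec),
            class = "rodpol_tracks")
}

#' Write synthetic tracks to disk
#'
#' Writes `tracks.csv` (cell, time_s, x_um, y_um), `track_truth.csv`, and a
#' `manifest.yaml` under `dir`.
#'
#' @param tr A `rodpol_tracks` from [generate_tracks()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tracks <- function(tr, dir) {
  stopifnot(inherits(tr, "rodpol_tracks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tr$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(tr$truth, file.path(dir, "track_truth.csv"),
                   row.names = FALSE)
  sp <- tr$spec
  yaml::write_yaml(list(
    kind = "synthetic_tracks",
    package_version = as.character(utils::packageVersion("rodpol")),
    n_tracks = sp$n_tracks, speed_um_min = sp$speed,
    frame_interval_s = sp$frame_interval, duration_min = sp$duration,
    positional_noise_sd_um = sp$positional_noise_sd, seed = sp$seed,
    files = c("tracks.csv", "track_truth.csv")
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
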