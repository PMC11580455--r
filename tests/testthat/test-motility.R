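straight_track <- function(speed = 2, interval = 30, duration = 15,
                           dir = c(1, 0), cell = 1L) {
  times <- seq(0, duration * 60, by = interval)
  d <- dir / sqrt(sum(dir^2))
  tibble::tibble(cell = cell, time_s = times,
                 x_um = d[1] * speed / 60 * times,
                 y_um = d[2] * speed / 60 * times)
}

test_that("interval speeds convert displacement to um/min", {
  tr <- straight_track(speed = 2, interval = 30)
  sp <- interval_speeds(tr, interval = 30)
  expect_equal(nrow(sp), nrow(tr) - 1L)  # one speed per interval
  expect_equal(sp$speed_um_min, rep(2, 30))
  # stationary track
  still <- dplyr::mutate(tr, x_um = 0, y_um = 0)
  expect_equal(interval_speeds(still, interval = 30)$speed_um_min, rep(0, 30))
  # 1 um per 30 s is 2 um/min
  expect_equal(interval_speeds(straight_track(speed = 2), 30)$step_um[1], 1)
  expect_error(interval_speeds(tr, interval = 20), "interval")
})

test_that("generator speed is recovered exactly on noise-free tracks", {
  tr <- generate_tracks(track_spec(n_tracks = 3, speed = 3.7,
                                   reversal_times = c(5, 10), seed = 4))
  sp <- interval_speeds(tr$tracks, interval = 30)
  expect_equal(mean(sp$speed_um_min), 3.7, tolerance = 1e-9)
})

test_that("reversals are counted at sustained direction flips", {
  tr <- straight_track()
  expect_equal(count_reversals(tr)$n_reversals, 0L)

  one_flip <- generate_tracks(track_spec(reversal_times = 7.5, seed = 1))
  expect_equal(count_reversals(one_flip$tracks)$n_reversals, 1L)

  # all steps below min_step: zero reversals, flagged non-moving
  still <- dplyr::mutate(tr, x_um = x_um * 1e-4, y_um = y_um * 1e-4)
  res <- count_reversals(still, min_step = 0.03)
  expect_equal(res$n_reversals, 0L)
  expect_false(res$moving)
})

test_that("programmed reversal counts are recovered from noisy tracks", {
  set.seed(61)
  n_tracks <- 100L
  rev_times <- replicate(n_tracks,
                         draw_reversal_times(sample(0:4, 1), 15, 30),
                         simplify = FALSE)
  spec <- track_spec(n_tracks = n_tracks, speed = 2, frame_interval = 30,
                     duration = 15, reversal_times = rev_times,
                     positional_noise_sd = 0.1, seed = 62)  # 10% of the 1 um step
  tr <- generate_tracks(spec)
  got <- count_reversals(tr$tracks)
  hits <- got$n_reversals == tr$truth$n_reversals_true
  expect_gte(mean(hits), 0.95)
})

test_that("noise-free counting is exact with threshold 180 and no min step", {
  set.seed(63)
  rev_times <- replicate(20, draw_reversal_times(sample(0:3, 1), 15, 30),
                         simplify = FALSE)
  tr <- generate_tracks(track_spec(n_tracks = 20, reversal_times = rev_times,
                                   seed = 64))
  got <- count_reversals(tr$tracks, angle_threshold = 180, min_step = 0)
  expect_equal(got$n_reversals, tr$truth$n_reversals_true)
})

test_that("speeds and reversal counts are invariant to rigid motions and time reversal", {
  tr <- generate_tracks(track_spec(n_tracks = 5, reversal_times = c(4, 9),
                                   seed = 65))$tracks
  th <- 0.7
  moved <- dplyr::mutate(tr,
                         x2 = 10 + cos(th) * x_um - sin(th) * y_um,
                         y2 = -3 + sin(th) * x_um + cos(th) * y_um,
                         x_um = x2, y_um = y2, x2 = NULL, y2 = NULL)
  expect_equal(interval_speeds(moved, 30)$speed_um_min,
               interval_speeds(tr, 30)$speed_um_min)
  expect_equal(count_reversals(moved)$n_reversals,
               count_reversals(tr)$n_reversals)
  reversed <- dplyr::arrange(
    dplyr::mutate(tr, time_s = max(time_s) - time_s), cell, time_s)
  expect_equal(count_reversals(reversed)$n_reversals,
               count_reversals(tr)$n_reversals)
})

test_that("only cells moving through the whole recording are kept", {
  moving <- straight_track(cell = 1L)
  pausing <- straight_track(cell = 2L)
  pausing$x_um[16] <- pausing$x_um[15]  # one stationary frame
  pausing$y_um[16] <- pausing$y_um[15]
  both <- dplyr::bind_rows(moving, pausing)
  kept <- filter_moving(both, min_step = 0.03)
  expect_equal(unique(kept$cell), 1L)
  expect_equal(nrow(filter_moving(both[0, ], 0.03)), 0L)
})

test_that("motility summaries normalize reversals to the observation window", {
  tr <- generate_tracks(track_spec(n_tracks = 1, duration = 7.5,
                                   reversal_times = c(3, 5), seed = 7))
  s <- summarize_motility(tr$tracks, interval = 30, window = 15)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_reversals, 2L)
  expect_equal(s$reversals_per_window, 4)  # 2 in 7.5 min scaled to 15 min
  expect_equal(s$mean_speed_um_min, 2, tolerance = 1e-9)
  expect_true(s$moved_throughout)
})

test_that("cohort means match generator truth across replicates", {
  set.seed(71)
  specs <- lapply(1:3, function(r) {
    track_spec(n_tracks = 20, speed = 2.5,
               reversal_times = replicate(20, draw_reversal_times(2, 15, 30),
                                          simplify = FALSE),
               positional_noise_sd = 0.05, seed = 700 + r)
  })
  trs <- lapply(specs, generate_tracks)
  per_cell <- dplyr::bind_rows(lapply(seq_along(trs), function(r) {
    dplyr::mutate(summarize_motility(trs[[r]]$tracks), replicate = r)
  }))
  agg <- aggregate_motility(per_cell, replicate = per_cell$replicate)
  pooled <- agg[agg$replicate == "pooled", ]
  expect_lt(abs(pooled$mean_speed - 2.5), 0.2)
  expect_lt(abs(pooled$mean_reversals - 2), 0.2)
})
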