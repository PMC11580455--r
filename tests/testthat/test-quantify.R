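test_that("background estimation returns the non-cell median", {
  mask <- matrix(0L, 100, 100)
  mask[40:60, 40:60] <- 1L
  img <- matrix(100, 100, 100)
  img[mask == 1L] <- 900
  expect_equal(estimate_background(img, mask), 100)

  # noisy background: median of ~10^4 pixels is within +-0.5 of truth
  set.seed(21)
  img2 <- matrix(100 + rnorm(1e4, 0, 5), 100, 100)
  expect_lt(abs(estimate_background(img2, mask) - 100), 0.5)

  expect_error(estimate_background(img, matrix(1L, 100, 100)), "background")
})

test_that("cytoplasmic stats use mid-cell pixels with the population SD", {
  px <- tibble::tibble(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                       cap = c("A", "mid", "mid", "B"))
  img <- matrix(c(500, 190, 210, 500), 2, 2)
  s <- cytoplasmic_stats(px, img, background = 100)
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 10)  # divisor n over {90, 110}
  s2 <- cytoplasmic_stats(px, img, background = 100, sd_type = "sample")
  expect_equal(s2$sd, sqrt(200 / 1))
  # uniform cell: mean = intensity - background, SD = 0
  img3 <- matrix(200, 2, 2)
  s3 <- cytoplasmic_stats(px, img3, background = 100)
  expect_equal(list(s3$mean, s3$sd), list(100, 0))
})

test_that("cytoplasmic mean recovers the generator's diffuse level", {
  f <- make_single_cell(pole1 = 0.3, pole2 = 0.1, noise = TRUE, seed = 6)
  truth_level <- 0.6 * 5e4 / f$scene$truth$n_pixels
  s <- cytoplasmic_stats(f$cells$pixels[[1]], f$scene$image, background = 100)
  expect_lt(abs(s$mean - truth_level) / truth_level, 0.02)
})

test_that("cluster detection enforces both the 2 SD and 3 pixel rules", {
  f <- make_single_cell(pole1 = 0, pole2 = 0)
  px <- f$cells$pixels[[1]]
  img <- f$scene$noise_free

  # uniform cell, no spot: nothing detected even though SD = 0
  cyto <- cytoplasmic_stats(px, img, background = 100)
  expect_equal(cyto$sd, 0)
  cl <- detect_polar_clusters(px, img, 100, cyto)
  expect_equal(nrow(cl), 0L)

  # a 2-pixel spot 10x above threshold is rejected: size < 3
  capA <- px[px$cap == "A", ]
  r0 <- round(mean(capA$row))                      # axis row of this horizontal cell
  c0 <- round(mean(capA$col[capA$row == r0]))      # central cap-A column
  img2 <- img
  img2[r0, c0] <- img2[r0, c0] + 10000
  img2[r0, c0 + 1] <- img2[r0, c0 + 1] + 10000
  cl2 <- detect_polar_clusters(px, img2, 100, cyto)
  expect_equal(nrow(cl2), 0L)

  # one more pixel makes it a cluster
  img3 <- img2
  img3[r0, c0 - 1] <- img3[r0, c0 - 1] + 10000
  cl3 <- detect_polar_clusters(px, img3, 100, cyto)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$n_pixels, 3L)
  expect_equal(cl3$cap, "A")
})

test_that("detected cluster pixel sets match the brute-force oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  n_checked <- 0L
  for (i in 1:50) {
    p1 <- runif(1, 0, 0.6)
    p2 <- runif(1, 0, min(p1, 1 - p1))
    f <- make_single_cell(pole1 = p1, pole2 = p2, noise = TRUE,
                          seed = 3000 + i, length_um = 3.3,
                          shape = c(24, 64))
    px <- f$cells$pixels[[1]]
    cyto <- cytoplasmic_stats(px, f$scene$image, background = 100)
    got <- cluster_keys(detect_polar_clusters(px, f$scene$image, 100, cyto))
    want <- oracle_clusters(px, f$scene$image, 100, cyto)
    expect_identical(got, want)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 50L)
})

test_that("pole 1 is the brighter pole, ties go to cap A", {
  cl <- tibble::tibble(cap = c("A", "B"), n_pixels = c(4L, 4L),
                       integrated = c(300, 100), mean = c(75, 25),
                       pixels = list(NULL, NULL))
  expect_equal(assign_poles(cl)[c("pole1", "pole2", "pole1_cap")],
               list(pole1 = 300, pole2 = 100, pole1_cap = "A"))
  cl_b <- cl[2, ]
  expect_equal(assign_poles(cl_b)[c("pole1", "pole2", "pole1_cap")],
               list(pole1 = 100, pole2 = 0, pole1_cap = "B"))
  cl_tie <- tibble::tibble(cap = c("A", "B"), n_pixels = c(4L, 4L),
                           integrated = c(200, 200), mean = c(50, 50),
                           pixels = list(NULL, NULL))
  expect_equal(assign_poles(cl_tie)$pole1_cap, "A")
})

test_that("asymmetry index follows the printed formula", {
  expect_equal(asymmetry_index(100, 0), 1)
  expect_equal(asymmetry_index(50, 50), 0)
  expect_equal(asymmetry_index(75, 25), 0.5)
  expect_true(is.na(asymmetry_index(0, 0)))
  expect_error(asymmetry_index(10, 20), "pole1 >= pole2")
  # monotonicity: fixed pole1, increasing pole2 strictly decreases omega
  p2 <- seq(0, 80, by = 5)
  expect_true(all(diff(asymmetry_index(rep(80, length(p2)), p2)) < 0))
})

test_that("localization bins match the printed inequalities at the boundaries", {
  expect_equal(as.character(classify_localization(0.95)), "unipolar")
  expect_equal(as.character(classify_localization(0.9)), "bipolar_asymmetric")
  expect_equal(as.character(classify_localization(0.2)), "bipolar_asymmetric")
  expect_equal(as.character(classify_localization(0.19)), "bipolar_symmetric")
  expect_equal(as.character(classify_localization(NA_real_)), "diffuse")
  expect_error(classify_localization(1.2), "\\[0, 1\\]")
  expect_error(classify_localization(-0.1), "\\[0, 1\\]")
})

test_that("quantify_cells produces consistent percentages and categories", {
  # diffuse-only cell
  f <- make_single_cell(pole1 = 0, pole2 = 0)
  q <- quantify_cells(f$scene$image, f$scene$mask)
  expect_equal(q$pole1_pct, 0)
  expect_equal(q$cytoplasmic_pct, 100)
  expect_equal(as.character(q$category), "diffuse")

  # strong bipolar asymmetric cell: omega and category follow the arithmetic
  f2 <- make_single_cell(pole1 = 0.4, pole2 = 0.1)
  q2 <- quantify_cells(f2$scene$image, f2$scene$mask,
                       subtract_cytoplasm = TRUE)
  expect_equal(q2$cytoplasmic_pct, 100 - q2$pole1_pct - q2$pole2_pct)
  expect_equal(q2$omega, (q2$pole1 - q2$pole2) / (q2$pole1 + q2$pole2))
  expect_equal(as.character(q2$category), "bipolar_asymmetric")
  expect_equal(q2$pole1_pct, 40, tolerance = 0.05)
  expect_equal(q2$pole2_pct, 10, tolerance = 0.15)
})

test_that("unipolar percentage recovery stays within 5 points under noise", {
  scene <- generate_scene(
    scene_spec(n_cells = 60, image_shape = c(900, 900), seed = 55),
    localization_spec(pole1_fraction = 0.4, pole2_fraction = 0))
  q <- quantify_cells(scene$image, scene$mask, subtract_cytoplasm = TRUE)
  expect_gt(nrow(q), 50)
  expect_lt(abs(mean(q$pole1_pct) - 40), 5)
})

test_that("percentages always sum to 100 and every cell gets one category", {
  scene <- generate_scene(
    scene_spec(n_cells = 40, image_shape = c(800, 800), seed = 12),
    localization_spec(pole1_fraction = 0.35, pole2_fraction = 0.15))
  q <- quantify_cells(scene$image, scene$mask)
  expect_equal(q$pole1_pct + q$pole2_pct + q$cytoplasmic_pct,
               rep(100, nrow(q)), tolerance = 1e-6)
  expect_false(any(is.na(q$category)))
  expect_equal(sum(table(q$category)), nrow(q))
})

test_that("results are invariant to rescaling background-subtracted intensities", {
  scene <- generate_scene(
    scene_spec(n_cells = 15, image_shape = c(600, 600), seed = 9),
    localization_spec(pole1_fraction = 0.4, pole2_fraction = 0.1))
  q1 <- quantify_cells(scene$image, scene$mask, background = 100)
  img2 <- (scene$image - 100) * 7.3 + 100
  q2 <- quantify_cells(img2, scene$mask, background = 100)
  expect_equal(q2$omega, q1$omega, tolerance = 1e-9)
  expect_equal(q2$pole1_pct, q1$pole1_pct, tolerance = 1e-9)
  expect_equal(q2$cytoplasmic_pct, q1$cytoplasmic_pct, tolerance = 1e-9)
  expect_identical(as.character(q2$category), as.character(q1$category))
})
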