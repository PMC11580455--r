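test_that("extract_cells returns one region per label and handles edge cases", {
  mask <- matrix(0L, 20, 20)
  mask[3:7, 3:12] <- 1L
  mask[12:16, 5:15] <- 5L
  cells <- extract_cells(mask)
  expect_equal(cells$label, c(1L, 5L))
  expect_equal(cells$n_pixels, c(50L, 55L))

  # a label split into two 8-connected islands is rejected with a diagnostic
  mask2 <- mask
  mask2[12:16, 5:15] <- 0L
  mask2[12, 18] <- 1L
  expect_warning(cells2 <- extract_cells(mask2), "components")
  expect_equal(nrow(cells2), 0L)

  # border-touching cells are excluded by default, kept on request
  mask3 <- matrix(0L, 20, 20)
  mask3[1:5, 3:12] <- 2L
  expect_equal(nrow(extract_cells(mask3)), 0L)
  expect_equal(nrow(extract_cells(mask3, exclude_border = FALSE)), 1L)
})

test_that("axis of a horizontal rectangle is horizontal with ~40 px length", {
  mask <- matrix(0L, 15, 50)
  mask[6:10, 5:44] <- 1L
  cells <- compute_axis(extract_cells(mask))
  expect_equal(nrow(cells), 1L)
  # skeleton-length oracle: a 5 x 40 rectangle has a 40 px long midline
  expect_lt(abs(cells$axis_length - 40) / 40, 0.1)
  angle <- atan2(cells$tip_b_row - cells$tip_a_row,
                 cells$tip_b_col - cells$tip_a_col) * 180 / pi
  expect_lt(abs(angle) %% 180, 5)
  expect_equal(sort(c(cells$tip_a_col, cells$tip_b_col)), c(5, 44))
})

test_that("axis tips of synthetic spherocylinders match generator truth within 2 px", {
  scene <- generate_scene(
    scene_spec(n_cells = 12, image_shape = c(600, 600), seed = 42),
    localization_spec(pole1_fraction = 0.3, pole2_fraction = 0.1))
  cells <- compute_axis(extract_cells(scene$mask))
  g <- dplyr::left_join(geometry_table(cells), scene$truth, by = "label")
  d <- function(r1, c1, r2, c2) sqrt((r1 - r2)^2 + (c1 - c2)^2)
  direct <- pmax(d(g$tip_a_row.x, g$tip_a_col.x, g$tip_a_row.y, g$tip_a_col.y),
                 d(g$tip_b_row.x, g$tip_b_col.x, g$tip_b_row.y, g$tip_b_col.y))
  swapped <- pmax(d(g$tip_a_row.x, g$tip_a_col.x, g$tip_b_row.y, g$tip_b_col.y),
                  d(g$tip_b_row.x, g$tip_b_col.x, g$tip_a_row.y, g$tip_a_col.y))
  expect_true(all(pmin(direct, swapped) <= 2))
})

test_that("round or tiny blobs are excluded as geometrically degenerate", {
  mask <- matrix(0L, 20, 20)
  mask[5:14, 5:14] <- 1L  # square blob
  expect_warning(cells <- compute_axis(extract_cells(mask)), "degenerate")
  expect_equal(nrow(cells), 0L)
  mask2 <- matrix(0L, 10, 10)
  mask2[4:5, 4:6] <- 1L   # 6 pixels: too small
  expect_warning(cells2 <- compute_axis(extract_cells(mask2)), "degenerate")
  expect_equal(nrow(cells2), 0L)
})

test_that("polar caps partition the cell by arc coordinate", {
  mask <- matrix(0L, 15, 70)
  mask[6:10, 5:65] <- 1L  # axis length ~60 px
  cells <- compute_axis(extract_cells(mask))
  L <- cells$axis_length

  capped <- define_polar_caps(cells, cap_extent = 1 / 6)
  px <- capped$pixels[[1]]
  expect_true(all(px$cap %in% c("A", "B", "mid")))        # exactly one region each
  expect_true(all(px$arc[px$cap == "A"] <= L / 6 + 1e-9))
  expect_true(all(px$arc[px$cap == "B"] >= 5 * L / 6 - 1e-9))
  expect_true(all(px$arc[px$cap == "mid"] > L / 6 & px$arc[px$cap == "mid"] < 5 * L / 6))
  # symmetric cell: cap pixel counts match within 10%
  nA <- sum(px$cap == "A"); nB <- sum(px$cap == "B")
  expect_lt(abs(nA - nB) / max(nA, nB), 0.1)

  # cap_extent 0 means no polar pixels at all
  empty <- define_polar_caps(cells, cap_extent = 0)
  expect_true(all(empty$pixels[[1]]$cap == "mid"))
  expect_error(define_polar_caps(cells, cap_extent = 0.5), "overlap")
})

test_that("relabeling permutes but does not change per-cell geometry", {
  scene <- generate_scene(
    scene_spec(n_cells = 6, image_shape = c(400, 400), seed = 3),
    localization_spec())
  relabel <- c(9L, 2L, 11L, 4L, 30L, 6L)
  mask2 <- scene$mask
  mask2[scene$mask > 0] <- relabel[scene$mask[scene$mask > 0]]
  g1 <- geometry_table(compute_axis(extract_cells(scene$mask)))
  g2 <- geometry_table(compute_axis(extract_cells(mask2)))
  g2_matched <- g2[match(relabel[g1$label], g2$label), ]
  expect_equal(g1$axis_length, g2_matched$axis_length)
  expect_equal(g1$tip_a_row, g2_matched$tip_a_row)
  expect_equal(g1$tip_b_col, g2_matched$tip_b_col)
})

test_that("rotating a scene by 90 degrees rotates caps correspondingly", {
  scene <- generate_scene(
    scene_spec(n_cells = 4, image_shape = c(300, 300), seed = 8),
    localization_spec())
  nr <- nrow(scene$mask)
  caps1 <- define_polar_caps(compute_axis(extract_cells(scene$mask)))
  caps2 <- define_polar_caps(compute_axis(extract_cells(rot90cw(scene$mask))))
  for (i in seq_len(nrow(caps1))) {
    px1 <- caps1$pixels[[i]]
    px2 <- caps2$pixels[[which(caps2$label == caps1$label[i])]]
    # map original coordinates into the rotated frame
    key1 <- paste(px1$col, nr - px1$row + 1, sep = ",")
    key2 <- paste(px2$row, px2$col, sep = ",")
    # polar pixels map to polar pixels (cap identity A/B may swap); allow a
    # couple of boundary pixels to flip, since arc binning tie-breaks are not
    # exactly equivariant on a raster
    polar1 <- key1[px1$cap != "mid"]
    polar2 <- key2[px2$cap != "mid"]
    sym_diff <- length(union(polar1, polar2)) - length(intersect(polar1, polar2))
    expect_lte(sym_diff, 2)
  }
})
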