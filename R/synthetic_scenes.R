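# Ground-truthed synthetic scenes: spherocylindrical rod cells rasterized
# into a labeled mask plus a fluorescence rendering (diffuse cytoplasmic
# signal, zero/one/two polar Gaussian clusters, camera background, optional
# Poisson shot noise and Gaussian read noise). The truth table records the
# exact noise-free pole fractions and the localization category they imply,
# computed with the same asymmetry-index binning the pipeline applies.

#' Specify a synthetic scene of rod cells
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param image_shape Image size as `c(rows, cols)` in pixels.
#' @param pixel_size Pixel edge in micrometres (default 0.06, typical of a
#'   100x objective on an sCMOS camera).
#' @param cell_length_range Tip-to-tip cell length range in micrometres.
#' @param cell_width Cell width (diameter) in micrometres.
#' @param orientation Cell orientation in radians, or `"random"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param margin Minimum gap in pixels between a cell and the image border.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(n_cells,
                       image_shape = c(512L, 512L),
                       pixel_size = 0.06,
                       cell_length_range = c(5, 7),
                       cell_width = 0.5,
                       orientation = "random",
                       seed = NULL,
                       margin = 2L) {
  assert_scalar_number(n_cells, "n_cells", min = 0)
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    abort("`image_shape` must be c(rows, cols), each >= 8.")
  }
  assert_scalar_number(pixel_size, "pixel_size", min = 1e-6)
  if (length(cell_length_range) != 2L || any(cell_length_range <= 0) ||
      cell_length_range[1] > cell_length_range[2]) {
    abort("`cell_length_range` must be positive and non-decreasing.")
  }
  assert_scalar_number(cell_width, "cell_width", min = 1e-6)
  if (cell_width >= cell_length_range[1]) {
    abort("`cell_width` must be smaller than the minimum cell length.")
  }
  if (!identical(orientation, "random")) {
    assert_scalar_number(orientation, "orientation")
  }
  structure(list(n_cells = as.integer(n_cells),
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 cell_length_range = cell_length_range,
                 cell_width = cell_width,
                 orientation = orientation,
                 seed = seed,
                 margin = as.integer(margin)),
            class = "scene_spec")
}

#' Specify per-cell fluorescence allocation
#'
#' Total cellular fluorescence is split into a fraction at each pole
#' (rendered as Gaussian spots centred on the polar cap centres of the
#' medial axis) and a diffuse cytoplasmic remainder spread uniformly over the
#' cell pixels. By convention `pole1_fraction >= pole2_fraction`.
#'
#' @param total_intensity Integrated cell fluorescence above background, in
#'   camera counts.
#' @param pole1_fraction,pole2_fraction Fractions of `total_intensity` in the
#'   brighter and dimmer polar cluster; their sum must be <= 1.
#' @param cluster_sigma Gaussian spot standard deviation in pixels (default
#'   1.8 px, about a 250 nm FWHM point-spread function at 0.06 um/px).
#' @param background_level Uniform camera background in counts.
#' @param read_noise_sd Gaussian read noise SD in counts (0 disables).
#' @param shot_noise Apply Poisson shot noise to expected counts?
#' @return A list of class `localization_spec`.
#' @export
localization_spec <- function(total_intensity = 5e4,
                              pole1_fraction = 0,
                              pole2_fraction = 0,
                              cluster_sigma = 1.8,
                              background_level = 100,
                              read_noise_sd = 2,
                              shot_noise = TRUE) {
  assert_scalar_number(total_intensity, "total_intensity", min = 0)
  assert_scalar_number(pole1_fraction, "pole1_fraction", min = 0, max = 1)
  assert_scalar_number(pole2_fraction, "pole2_fraction", min = 0, max = 1)
  if (pole1_fraction + pole2_fraction > 1 + 1e-12) {
    abort("pole1_fraction + pole2_fraction must be <= 1.")
  }
  if (pole2_fraction > pole1_fraction) {
    abort("By convention pole1_fraction >= pole2_fraction.")
  }
  assert_scalar_number(cluster_sigma, "cluster_sigma", min = 1e-6)
  assert_scalar_number(background_level, "background_level", min = 0)
  assert_scalar_number(read_noise_sd, "read_noise_sd", min = 0)
  structure(list(total_intensity = total_intensity,
                 pole1_fraction = pole1_fraction,
                 pole2_fraction = pole2_fraction,
                 cluster_sigma = cluster_sigma,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "localization_spec")
}

# Pixels of a spherocylinder: centre `ctr` (row, col), unit axis `u`,
# tip-to-tip length `len_px`, width `w_px`. A pixel belongs to the cell if
# its centre lies within w/2 of the central segment.
rasterize_spherocylinder <- function(ctr, u, len_px, w_px, nr, nc) {
  half_seg <- (len_px - w_px) / 2
  a <- ctr - half_seg * u
  b <- ctr + half_seg * u
  rad <- w_px / 2
  r0 <- max(1L, floor(min(a[1], b[1]) - rad - 1))
  r1 <- min(nr, ceiling(max(a[1], b[1]) + rad + 1))
  c0 <- max(1L, floor(min(a[2], b[2]) - rad - 1))
  c1 <- min(nc, ceiling(max(a[2], b[2]) + rad + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  # distance from pixel centres to segment ab
  abv <- b - a
  ab2 <- sum(abv^2)
  t <- if (ab2 > 0) {
    pmin(pmax(((rr - a[1]) * abv[1] + (cc - a[2]) * abv[2]) / ab2, 0), 1)
  } else rep(0, length(rr))
  d2 <- (rr - (a[1] + t * abv[1]))^2 + (cc - (a[2] + t * abv[2]))^2
  keep <- d2 <= rad^2
  list(row = rr[keep], col = cc[keep], seg_a = a, seg_b = b)
}

#' Generate a synthetic rod-cell scene with ground truth
#'
#' Places non-overlapping (and non-touching) spherocylindrical cells by
#' rejection sampling, renders a fluorescence image and returns the exact
#' noise-free truth per cell. Each polar spot is renormalized over the cell's
#' pixels so its integrated in-cell intensity equals exactly
#' `pole_fraction * total_intensity`; the diffuse remainder is spread
#' uniformly. Which geometric end receives pole 1 is randomized per cell.
#'
#' @param spec A [scene_spec()].
#' @param loc A single [localization_spec()] applied to every cell, or a list
#'   of `n_cells` of them. Background and noise settings are scene-level and
#'   taken from the first element.
#' @param max_tries Placement attempts allowed per cell before the scene is
#'   declared too crowded; the error then reports how many cells were placed.
#' @return A list of class `rodpol_scene` with elements `mask` (integer label
#'   matrix), `image` (noisy counts), `noise_free` (expected counts, no
#'   noise), `truth` (tibble: label, pole fractions, true omega and category,
#'   spot centres, tip positions) and `spec`.
#' @export
generate_scene <- function(spec, loc, max_tries = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (inherits(loc, "localization_spec")) {
    loc <- rep(list(loc), spec$n_cells)
  }
  if (spec$n_cells > 0 && length(loc) != spec$n_cells) {
    abort("`loc` must be one localization_spec or a list of length n_cells.")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nr <- spec$image_shape[1]
  nc <- spec$image_shape[2]
  bg <- if (spec$n_cells > 0) loc[[1]]$background_level else 100
  read_sd <- if (spec$n_cells > 0) loc[[1]]$read_noise_sd else 0
  shot <- if (spec$n_cells > 0) loc[[1]]$shot_noise else FALSE

  mask <- matrix(0L, nr, nc)
  expected <- matrix(bg, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  truth <- vector("list", spec$n_cells)
  w_px <- spec$cell_width / spec$pixel_size
  margin <- spec$margin

  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      len_um <- runif(1, spec$cell_length_range[1], spec$cell_length_range[2])
      len_px <- len_um / spec$pixel_size
      theta <- if (identical(spec$orientation, "random")) {
        runif(1, 0, pi)
      } else spec$orientation
      u <- c(cos(theta), sin(theta))
      # orientation-aware half-extents so elongated cells fit thin images
      hr <- abs(u[1]) * (len_px - w_px) / 2 + w_px / 2 + 1
      hc <- abs(u[2]) * (len_px - w_px) / 2 + w_px / 2 + 1
      if (margin + hr >= nr - margin - hr || margin + hc >= nc - margin - hc) next
      ctr <- c(runif(1, margin + hr, nr - margin - hr),
               runif(1, margin + hc, nc - margin - hc))
      sc <- rasterize_spherocylinder(ctr, u, len_px, w_px, nr, nc)
      if (is.null(sc) || length(sc$row) < 9L) next
      if (any(sc$row <= margin | sc$row > nr - margin |
              sc$col <= margin | sc$col > nc - margin)) next
      # forbid touching: candidate pixels and their 8-neighbours must be free
      free <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (any(occupied[cbind(sc$row + dr, sc$col + dc)])) {
            free <- FALSE
            break
          }
        }
        if (!free) break
      }
      if (!free) next

      idx <- cbind(sc$row, sc$col)
      mask[idx] <- i
      occupied[idx] <- TRUE
      l <- loc[[i]]
      n_px <- length(sc$row)
      diffuse <- (1 - l$pole1_fraction - l$pole2_fraction) *
        l$total_intensity / n_px
      expected[idx] <- expected[idx] + diffuse
      # pole 1 goes to a random end; spot centres sit at the centres of the
      # two hemispherical caps on the medial axis
      ends <- if (runif(1) < 0.5) list(sc$seg_a, sc$seg_b) else
        list(sc$seg_b, sc$seg_a)
      fr <- c(l$pole1_fraction, l$pole2_fraction)
      centres <- matrix(NA_real_, 2, 2)
      for (k in 1:2) {
        if (fr[k] <= 0) next
        ck <- ends[[k]]
        centres[k, ] <- ck
        g <- exp(-((sc$row - ck[1])^2 + (sc$col - ck[2])^2) /
                   (2 * l$cluster_sigma^2))
        expected[idx] <- expected[idx] + g * (fr[k] * l$total_intensity / sum(g))
      }
      omega_true <- if (sum(fr) > 0) asymmetry_index(fr[1], fr[2]) else NA_real_
      axis_dir <- (sc$seg_b - sc$seg_a) / sqrt(sum((sc$seg_b - sc$seg_a)^2))
      truth[[i]] <- tibble(
        label = i,
        n_pixels = n_px,
        total_intensity = l$total_intensity,
        pole1_fraction = fr[1],
        pole2_fraction = fr[2],
        omega_true = omega_true,
        category_true = as.character(classify_localization(omega_true)),
        pole1_row = centres[1, 1], pole1_col = centres[1, 2],
        pole2_row = centres[2, 1], pole2_col = centres[2, 2],
        tip_a_row = sc$seg_a[1] - axis_dir[1] * w_px / 2,
        tip_a_col = sc$seg_a[2] - axis_dir[2] * w_px / 2,
        tip_b_row = sc$seg_b[1] + axis_dir[1] * w_px / 2,
        tip_b_col = sc$seg_b[2] + axis_dir[2] * w_px / 2,
        length_um = len_um,
        orientation = theta
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "Could not place cell %d of %d after %d attempts (%d cells placed); use a larger image or fewer cells.",
        i, spec$n_cells, max_tries, i - 1L),
        class = "rodpol_placement_error")
    }
  }

  image <- expected
  if (shot) image <- matrix(rpois(length(expected), expected), nr, nc)
  if (read_sd > 0) image <- image + rnorm(length(image), 0, read_sd)

  structure(list(
    mask = mask,
    image = image,
    noise_free = expected,
    truth = if (spec$n_cells > 0) dplyr::bind_rows(truth) else tibble(
      label = integer(), n_pixels = integer(), total_intensity = double(),
      pole1_fraction = double(), pole2_fraction = double(),
      omega_true = double(), category_true = character(),
      pole1_row = double(), pole1_col = double(),
      pole2_row = double(), pole2_col = double(),
      tip_a_row = double(), tip_a_col = double(),
      tip_b_row = double(), tip_b_col = double(),
      length_um = double(), orientation = double()),
    spec = spec
  ), class = "rodpol_scene")
}

#' Write a synthetic scene to disk
#'
#' Writes `mask.tif` and `fluorescence.tif` (16-bit TIFF), `truth.csv`, and a
#' `manifest.yaml` echoing the scene parameters, under `dir`.
#'
#' @param scene A `rodpol_scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "rodpol_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_mask(scene$mask, file.path(dir, "mask.tif"))
  write_fluorescence_image(scene$image, file.path(dir, "fluorescence.tif"))
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- scene$spec
  manifest <- list(
    kind = "synthetic_scene",
    package_version = as.character(utils::packageVersion("rodpol")),
    n_cells = sp$n_cells,
    image_shape = sp$image_shape,
    pixel_size_um = sp$pixel_size,
    cell_length_range_um = sp$cell_length_range,
    cell_width_um = sp$cell_width,
    seed = sp$seed,
    files = c("mask.tif", "fluorescence.tif", "truth.csv")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
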