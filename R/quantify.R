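# Polar fluorescence quantification. Per cell: background-subtracted totals,
# cytoplasmic statistics from the mid-cell region, polar cluster detection
# (component mean >= cytoplasmic mean + k SD, >= min_size pixels), pole
# assignment (pole 1 = brighter pole), the asymmetry index
# omega = (pole1 - pole2)/(pole1 + pole2), and four-way localization
# classification.

#' Estimate the camera background level
#'
#' The median intensity of all non-cell pixels — robust to the bright cell
#' tails that would bias a mean.
#'
#' @param image Numeric intensity matrix.
#' @param mask Integer label matrix of the same dimension (0 = background).
#' @return Background level, a single number.
#' @export
estimate_background <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) {
    abort("`image` and `mask` must have identical dimensions.")
  }
  bg <- image[mask == 0]
  if (length(bg) == 0L) {
    abort("Mask covers the entire image: no background pixels to estimate from.")
  }
  median(bg)
}

#' Cytoplasmic mean and SD of one cell
#'
#' Computed over the mid-cell pixels (the cell minus both polar caps) of the
#' background-subtracted image. Using mid-cell pixels breaks the circularity
#' of defining cytoplasm as "whatever is not in a cluster": it is a single
#' deterministic pass, and unbiased as long as clusters are polar.
#'
#' @param px Pixel tibble of one cell with columns `row`, `col`, `cap`
#'   (from [define_polar_caps()]).
#' @param image Numeric intensity matrix.
#' @param background Background level to subtract.
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1).
#' @return List with `mean`, `sd`, `n`; `NULL` if the mid-cell region is empty.
#' @export
cytoplasmic_stats <- function(px, image, background = 0,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  mid <- px[px$cap == "mid", , drop = FALSE]
  if (nrow(mid) == 0L) return(NULL)
  vals <- image[cbind(mid$row, mid$col)] - background
  m <- mean(vals)
  n <- length(vals)
  s <- if (n > 1L) {
    sqrt(sum((vals - m)^2) / if (sd_type == "population") n else n - 1L)
  } else 0
  list(mean = m, sd = s, n = n)
}

#' Detect polar fluorescent clusters in one cell
#'
#' Within each polar cap, pixels strictly brighter than
#' `cytoplasmic mean + k_sd * SD` seed candidate clusters; 8-connected
#' components of seeds are kept if they span at least `min_size` pixels and
#' their average fluorescence is at least the same threshold. The kept
#' components of a cap together form that cap's cluster set.
#'
#' @param px Pixel tibble with `row`, `col`, `cap`.
#' @param image Numeric intensity matrix.
#' @param background Background level to subtract.
#' @param cyto List with `mean` and `sd` from [cytoplasmic_stats()].
#' @param k_sd Threshold in cytoplasmic SD units (default 2).
#' @param min_size Minimum cluster size in pixels (default 3).
#' @return Tibble with one row per kept component: `cap`, `n_pixels`,
#'   `integrated` (background-subtracted sum), `mean`, and a `pixels`
#'   list-column.
#' @export
detect_polar_clusters <- function(px, image, background, cyto,
                                  k_sd = 2, min_size = 3L) {
  threshold <- cyto$mean + k_sd * cyto$sd
  out <- list()
  for (cap in c("A", "B")) {
    cp <- px[px$cap == cap, , drop = FALSE]
    if (nrow(cp) == 0L) next
    vals <- image[cbind(cp$row, cp$col)] - background
    seeds <- vals > threshold
    if (!any(seeds)) next
    r0 <- min(cp$row); c0 <- min(cp$col)
    sub <- matrix(FALSE, max(cp$row) - r0 + 1L, max(cp$col) - c0 + 1L)
    sub[cbind(cp$row[seeds] - r0 + 1L, cp$col[seeds] - c0 + 1L)] <- TRUE
    comp <- label_components(sub)
    comp_id <- comp[cbind(cp$row - r0 + 1L, cp$col - c0 + 1L)]
    for (k in seq_len(max(comp))) {
      in_k <- comp_id == k
      if (sum(in_k) < min_size) next
      if (mean(vals[in_k]) < threshold) next
      out[[length(out) + 1L]] <- tibble(
        cap = cap,
        n_pixels = sum(in_k),
        integrated = sum(vals[in_k]),
        mean = mean(vals[in_k]),
        pixels = list(tibble(row = cp$row[in_k], col = cp$col[in_k]))
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(cap = character(), n_pixels = integer(),
                  integrated = double(), mean = double(), pixels = list()))
  }
  dplyr::bind_rows(out)
}

#' Assign pole 1 and pole 2 from detected clusters
#'
#' Cluster fluorescence is summed per cap; the cap with the higher total is
#' pole 1 ("the pole with the highest fluorescence"). An exact tie is broken
#' deterministically in favour of cap A (the lower-arc-coordinate pole).
#'
#' @param clusters Tibble from [detect_polar_clusters()].
#' @return List with `pole1`, `pole2` (fluorescence totals, >= 0) and
#'   `pole1_cap` (`"A"`, `"B"`, or `NA` when no clusters were found).
#' @export
assign_poles <- function(clusters) {
  tot_a <- sum(clusters$integrated[clusters$cap == "A"])
  tot_b <- sum(clusters$integrated[clusters$cap == "B"])
  if (nrow(clusters) == 0L) {
    return(list(pole1 = 0, pole2 = 0, pole1_cap = NA_character_))
  }
  if (tot_b > tot_a) {
    list(pole1 = tot_b, pole2 = tot_a, pole1_cap = "B")
  } else {
    list(pole1 = tot_a, pole2 = tot_b, pole1_cap = "A")
  }
}

#' Asymmetry index of polar fluorescence
#'
#' `omega = (pole1 - pole2) / (pole1 + pole2)`, where pole 1 carries the
#' higher fluorescence. 1 means fully unipolar, 0 perfectly symmetric
#' bipolar. Undefined (NA) when both poles are zero — such a cell is diffuse.
#' Vectorized.
#'
#' @param pole1,pole2 Polar fluorescence totals with `pole1 >= pole2 >= 0`.
#' @return omega in `[0, 1]`, or `NA` where both inputs are zero.
#' @export
asymmetry_index <- function(pole1, pole2) {
  if (any(pole2 < 0) || any(pole1 < pole2)) {
    abort("Require pole1 >= pole2 >= 0 (pole 1 is the brighter pole).")
  }
  ifelse(pole1 + pole2 > 0, (pole1 - pole2) / (pole1 + pole2), NA_real_)
}

#' Classify localization from the asymmetry index
#'
#' Bins: unipolar (`omega > 0.9`), bipolar asymmetric (`0.2 <= omega <= 0.9`),
#' bipolar symmetric (`omega < 0.2`); the boundary values 0.9 and 0.2 fall in
#' the bipolar-asymmetric bin. `NA` (no polar cluster detected) is diffuse.
#' Vectorized.
#'
#' @param omega Numeric vector in `[0, 1]`, `NA` allowed.
#' @param bins Bin boundaries `c(unipolar, symmetric)` (defaults 0.9 and 0.2).
#' @return Factor with levels unipolar, bipolar_asymmetric, bipolar_symmetric,
#'   diffuse.
#' @export
classify_localization <- function(omega, bins = c(0.9, 0.2)) {
  ok <- is.na(omega) | (omega >= 0 & omega <= 1)
  if (!all(ok)) abort("`omega` values must lie in [0, 1].")
  if (length(bins) != 2L || bins[1] <= bins[2]) {
    abort("`bins` must be c(unipolar, symmetric) with unipolar > symmetric.")
  }
  out <- dplyr::case_when(
    is.na(omega) ~ "diffuse",
    omega > bins[1] ~ "unipolar",
    omega >= bins[2] ~ "bipolar_asymmetric",
    TRUE ~ "bipolar_symmetric"
  )
  factor(out, levels = LOCALIZATION_LEVELS)
}

#' Quantify polar fluorescence for every cell in an image
#'
#' The full per-cell pipeline: background estimation (median of non-cell
#' pixels, unless supplied), geometry ([extract_cells()], [compute_axis()],
#' [define_polar_caps()]), cytoplasmic statistics, cluster detection, pole
#' assignment, omega, and classification. Total cell fluorescence is the
#' background-subtracted sum over all cell pixels; pole percentages are
#' cluster fluorescence as a percentage of that total, and the cytoplasmic
#' percentage is the remainder, so the three always sum to 100.
#'
#' @param image Numeric intensity matrix.
#' @param mask Integer label matrix, or a prepared cell tibble from
#'   [define_polar_caps()].
#' @param background Background level; `NULL` (default) estimates it with
#'   [estimate_background()] (requires `mask` to be a matrix).
#' @param cap_extent Polar cap extent as a fraction of axis length.
#' @param k_sd,min_size Cluster detection thresholds (defaults 2 and 3).
#' @param bins omega bin boundaries, see [classify_localization()].
#' @param subtract_cytoplasm If `TRUE`, subtract the local cytoplasmic mean
#'   from cluster pixels before integrating pole fluorescence; the default
#'   (`FALSE`) integrates raw background-subtracted polar totals.
#' @param sd_type SD convention for [cytoplasmic_stats()].
#' @param exclude_border Passed to [extract_cells()].
#' @return A tibble of class `rodpol_quant`, one row per quantified cell:
#'   `label`, `n_pixels`, `total`, `pole1`, `pole2`, `pole1_pct`, `pole2_pct`,
#'   `cytoplasmic_pct`, `omega`, `category`, `n_clusters`, `pole1_cap`.
#'   Cells with non-positive total or an empty mid-cell region are dropped
#'   with a warning.
#' @export
quantify_cells <- function(image, mask, background = NULL,
                           cap_extent = 1 / 6, k_sd = 2, min_size = 3L,
                           bins = c(0.9, 0.2), subtract_cytoplasm = FALSE,
                           sd_type = c("population", "sample"),
                           exclude_border = TRUE) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(mask)) {
    if (is.null(background)) background <- estimate_background(image, mask)
    cells <- extract_cells(mask, exclude_border = exclude_border)
    cells <- compute_axis(cells)
    cells <- define_polar_caps(cells, cap_extent = cap_extent)
  } else {
    cells <- mask
    if (is.null(background)) {
      abort("Supply `background` when `mask` is a prepared cell tibble.")
    }
  }
  rows <- vector("list", nrow(cells))
  dropped <- character()
  for (i in seq_len(nrow(cells))) {
    px <- cells$pixels[[i]]
    lb <- cells$label[i]
    total <- sum(image[cbind(px$row, px$col)] - background)
    if (total <= 0) {
      dropped <- c(dropped, sprintf("label %d (non-positive total)", lb))
      next
    }
    cyto <- cytoplasmic_stats(px, image, background, sd_type = sd_type)
    if (is.null(cyto)) {
      dropped <- c(dropped, sprintf("label %d (empty mid-cell)", lb))
      next
    }
    clusters <- detect_polar_clusters(px, image, background, cyto,
                                      k_sd = k_sd, min_size = min_size)
    if (isTRUE(subtract_cytoplasm) && nrow(clusters) > 0L) {
      clusters$integrated <- pmax(
        clusters$integrated - clusters$n_pixels * cyto$mean, 0)
    }
    poles <- assign_poles(clusters)
    omega <- asymmetry_index(poles$pole1, poles$pole2)
    rows[[i]] <- tibble(
      label = lb,
      n_pixels = nrow(px),
      total = total,
      pole1 = poles$pole1,
      pole2 = poles$pole2,
      pole1_pct = 100 * poles$pole1 / total,
      pole2_pct = 100 * poles$pole2 / total,
      cytoplasmic_pct = 100 - 100 * poles$pole1 / total -
        100 * poles$pole2 / total,
      omega = omega,
      category = classify_localization(omega, bins = bins),
      n_clusters = nrow(clusters),
      pole1_cap = poles$pole1_cap
    )
  }
  if (length(dropped) > 0L) {
    warn(paste0("Excluded cells: ", paste(dropped, collapse = "; "), "."))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(label = integer(), n_pixels = integer(), total = double(),
                  pole1 = double(), pole2 = double(), pole1_pct = double(),
                  pole2_pct = double(), cytoplasmic_pct = double(),
                  omega = double(),
                  category = factor(character(), levels = LOCALIZATION_LEVELS),
                  n_clusters = integer(), pole1_cap = character())
  }
  class(out) <- c("rodpol_quant", class(out))
  out
}
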