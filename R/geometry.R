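# Per-cell geometry: pixel sets, medial axis, pole tips, along-axis (arc)
# coordinates and polar caps. Coordinates are 1-based (row, col) with the
# origin at the top-left pixel, matching R's matrix indexing.

#' Extract cell regions from a labeled mask
#'
#' Splits a labeled mask into one region per nonzero label. Each label must
#' form a single 8-connected component; labels violating this are rejected
#' with a warning. Cells touching the image border are excluded by default
#' because their truncated fluorescence would bias downstream asymmetry
#' measurements.
#'
#' @param mask Integer matrix of labels (0 = background).
#' @param exclude_border Drop cells touching the image border (default `TRUE`).
#' @return A tibble with one row per cell: `label`, `n_pixels`, `on_border`,
#'   and a list-column `pixels` of tibbles with columns `row`, `col`.
#' @export
extract_cells <- function(mask, exclude_border = TRUE) {
  if (!is.matrix(mask) || any(mask != round(mask))) {
    abort("`mask` must be an integer-valued matrix.")
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- sort(unique(mask[mask > 0]))
  rows <- lapply(labels, function(lb) {
    idx <- which(mask == lb)
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    # per-label connectivity check on the bounding-box submask
    sub <- matrix(FALSE, diff(range(r)) + 1L, diff(range(cc)) + 1L)
    sub[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
    comp <- label_components(sub)
    if (max(comp) > 1L) {
      warn(sprintf("Label %d splits into %d 8-connected components; rejected.",
                   lb, max(comp)))
      return(NULL)
    }
    tibble(
      label = as.integer(lb),
      n_pixels = length(idx),
      on_border = any(r == 1L | r == nr | cc == 1L | cc == nc),
      pixels = list(tibble(row = r, col = cc))
    )
  })
  cells <- dplyr::bind_rows(rows)
  if (nrow(cells) == 0L) {
    return(tibble(label = integer(), n_pixels = integer(),
                  on_border = logical(), pixels = list()))
  }
  if (exclude_border && any(cells$on_border)) {
    cells <- dplyr::filter(cells, !.data$on_border)
  }
  cells
}

# Medial axis of one cell from its pixel tibble. Returns NULL (with a reason
# attribute) if the region is too small or too round for a rod-cell axis.
cell_axis <- function(px) {
  n <- nrow(px)
  if (n < 9L) return(structure(list(), reason = "fewer than 9 pixels"))
  P <- cbind(px$row, px$col)
  ctr <- colMeans(P)
  X <- sweep(P, 2L, ctr)
  eg <- eigen(crossprod(X) / n, symmetric = TRUE)
  e1 <- eg$vectors[, 1L]
  # deterministic sign: first nonzero component positive
  if (e1[1] < 0 || (e1[1] == 0 && e1[2] < 0)) e1 <- -e1
  e2 <- c(-e1[2], e1[1])
  t1 <- drop(X %*% e1)
  t2 <- drop(X %*% e2)
  len_extent <- diff(range(t1)) + 1
  wid_extent <- diff(range(t2)) + 1
  if (len_extent < 2 * wid_extent) {
    return(structure(list(), reason = sprintf(
      "too round for an axis (extent %.1f x %.1f px)", len_extent, wid_extent)))
  }
  # pole tips: within the extreme half-pixel slice along the major axis, the
  # pixel closest to the axis (avoids jumping to a corner pixel of the slice)
  iA <- which(t1 <= min(t1) + 0.5); iA <- iA[which.min(abs(t2[iA]))]
  iB <- which(t1 >= max(t1) - 0.5); iB <- iB[which.min(abs(t2[iB]))]
  # backbone: centroids of ~1.5 px slices along the major axis (tracks mild
  # curvature), capped by the tips
  nb <- max(3L, ceiling(diff(range(t1)) / 1.5))
  cuts <- seq(min(t1), max(t1), length.out = nb + 1L)
  bin <- pmin(findInterval(t1, cuts, rightmost.closed = TRUE), nb)
  br <- tapply(P[, 1L], bin, mean)
  bc <- tapply(P[, 2L], bin, mean)
  poly <- rbind(P[iA, ], cbind(br, bc), P[iB, ])
  # drop near-duplicate consecutive vertices
  keep <- c(TRUE, rowSums((poly[-1L, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2) > 1e-9)
  poly <- poly[keep, , drop = FALSE]
  seg <- sqrt(rowSums((poly[-1L, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
  arc_vertex <- c(0, cumsum(seg))
  axis_length <- arc_vertex[length(arc_vertex)]
  # per-pixel arc coordinate: arc of the nearest backbone vertex
  d2 <- outer(P[, 1L], poly[, 1L], "-")^2 + outer(P[, 2L], poly[, 2L], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  arc <- arc_vertex[nearest]
  list(
    medial_axis = tibble(row = poly[, 1L], col = poly[, 2L], arc = arc_vertex),
    tip_a = P[iA, ],
    tip_b = P[iB, ],
    axis_length = axis_length,
    width = wid_extent,
    arc = arc
  )
}

#' Compute medial axis, pole tips and arc coordinates for each cell
#'
#' Fits a backbone to every cell region: the major principal axis of the
#' pixel set, refined by slice centroids so mildly curved cells are followed.
#' The pole tips are the two extreme pixels along the backbone; every cell
#' pixel receives an arc coordinate, its distance along the axis from tip A
#' (in pixels). Cells too small (< 9 pixels) or too round (axis extent less
#' than twice the width) are excluded with a warning, since a polar coordinate
#' system is meaningless for them.
#'
#' @param cells Tibble from [extract_cells()].
#' @return The input tibble with added columns `axis_length`, `width`,
#'   `tip_a_row`, `tip_a_col`, `tip_b_row`, `tip_b_col`, list-column
#'   `medial_axis`, and an `arc` column inside each `pixels` tibble.
#' @export
compute_axis <- function(cells) {
  res <- purrr::map(cells$pixels, cell_axis)
  ok <- vapply(res, function(x) length(x) > 0L, logical(1))
  if (any(!ok)) {
    bad <- cells$label[!ok]
    reasons <- vapply(res[!ok], function(x) attr(x, "reason"), character(1))
    warn(paste0("Excluded cells with degenerate geometry: ",
                paste(sprintf("label %d (%s)", bad, reasons), collapse = "; ")))
  }
  cells <- cells[ok, , drop = FALSE]
  res <- res[ok]
  if (nrow(cells) == 0L) {
    out <- dplyr::mutate(cells, axis_length = double(), width = double(),
                         tip_a_row = double(), tip_a_col = double(),
                         tip_b_row = double(), tip_b_col = double(),
                         medial_axis = list())
    return(out)
  }
  cells$pixels <- purrr::map2(cells$pixels, res,
                              function(px, g) dplyr::mutate(px, arc = g$arc))
  dplyr::mutate(
    cells,
    axis_length = vapply(res, `[[`, double(1), "axis_length"),
    width = vapply(res, `[[`, double(1), "width"),
    tip_a_row = vapply(res, function(g) g$tip_a[1], double(1)),
    tip_a_col = vapply(res, function(g) g$tip_a[2], double(1)),
    tip_b_row = vapply(res, function(g) g$tip_b[1], double(1)),
    tip_b_col = vapply(res, function(g) g$tip_b[2], double(1)),
    medial_axis = purrr::map(res, "medial_axis")
  )
}

#' Partition each cell into polar caps and mid-cell
#'
#' Cap A holds the pixels with arc coordinate at most `cap_extent * L` from
#' tip A, cap B those within the same fraction of tip B (`L` = axis length);
#' everything else is mid-cell. The mid-cell region defines the cytoplasmic
#' reference used by cluster detection. The default extent of 1/6 of the axis
#' length approximates the hemispherical pole caps of a rod roughly six times
#' longer than wide; it is a free parameter because published pipelines rarely
#' state where "polar" ends.
#'
#' @param cells Tibble from [compute_axis()].
#' @param cap_extent Fraction of the axis length per cap, in `[0, 0.5)`.
#'   `0` yields empty caps.
#' @return `cells` with a `cap` column (`"A"`, `"B"` or `"mid"`) added to each
#'   `pixels` tibble.
#' @export
define_polar_caps <- function(cells, cap_extent = 1 / 6) {
  assert_scalar_number(cap_extent, "cap_extent", min = 0)
  if (cap_extent >= 0.5) {
    abort("`cap_extent` must be < 0.5: caps would overlap.")
  }
  cells$pixels <- purrr::map2(cells$pixels, cells$axis_length, function(px, L) {
    if (is.null(px$arc)) abort("Run `compute_axis()` before defining caps.")
    cap <- rep("mid", nrow(px))
    if (cap_extent > 0) {
      cap[px$arc <= cap_extent * L] <- "A"
      cap[px$arc >= (1 - cap_extent) * L] <- "B"
    }
    dplyr::mutate(px, cap = cap)
  })
  cells
}

#' Export per-cell geometry as a flat table
#'
#' @param cells Tibble from [compute_axis()].
#' @return Tibble with one row per cell: label, pixel count, axis length and
#'   width (px), and tip coordinates — suitable for writing to CSV.
#' @export
geometry_table <- function(cells) {
  dplyr::select(cells, "label", "n_pixels", "axis_length", "width",
                "tip_a_row", "tip_a_col", "tip_b_row", "tip_b_col")
}
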