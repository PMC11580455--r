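# Raster I/O: labeled segmentation masks and single-channel fluorescence
# images as 16-bit TIFF (or 8/16-bit PNG for masks). All rasters are R
# matrices indexed (row, col), 1-based, origin top-left.

#' Read a labeled cell-segmentation mask
#'
#' Reads an integer-labeled raster (0 = background, positive integers = cell
#' labels, e.g. as exported from a segmentation tool) from TIFF or PNG.
#' Labels are preserved exactly; a raster whose values are not integers is
#' rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer matrix of labels (rows x cols).
#' @seealso [write_labeled_mask()], [extract_cells()]
#' @export
read_labeled_mask <- function(path) {
  raster <- read_raster(path)
  if (max(abs(raster - round(raster))) > 1e-6) {
    abort(sprintf("'%s' is not an integer-labeled mask.", path))
  }
  mask <- matrix(as.integer(round(raster)), nrow(raster), ncol(raster))
  if (all(mask == 0L)) {
    warn(sprintf("Mask '%s' contains no cells (all background).", path))
  }
  mask
}

#' Write a labeled mask to TIFF or PNG
#'
#' @param mask Integer matrix of labels.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#'   TIFF is written as 16-bit; PNG as 8-bit when all labels fit, else 16-bit.
#' @return `path`, invisibly.
#' @export
write_labeled_mask <- function(mask, path) {
  if (any(mask < 0) || any(mask != round(mask))) {
    abort("`mask` must contain non-negative integers.")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535) abort("Labels exceed 16-bit range.")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(mask) <= 255) {
      png::writePNG(mask / 255, path)
    } else if (max(mask) <= 65535) {
      png::writePNG(mask / 65535, path)
    } else {
      abort("Labels exceed 16-bit range.")
    }
  } else {
    abort(sprintf("Unsupported mask format '%s' (use tif/tiff/png).", ext))
  }
  invisible(path)
}

#' Read a single-channel fluorescence image
#'
#' @param path Path to a 16-bit (or 8-bit) grayscale TIFF or PNG.
#' @return Numeric matrix of intensities in camera counts.
#' @export
read_fluorescence_image <- function(path) {
  read_raster(path)
}

#' Write a fluorescence image as 16-bit TIFF
#'
#' Intensities are clipped to `[0, 65535]` and rounded to integer counts.
#'
#' @param image Numeric matrix.
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_fluorescence_image <- function(image, path) {
  counts <- pmin(pmax(round(image), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# Read TIFF (native integer counts) or PNG (rescaled by its bit depth) into a
# plain numeric matrix; multi-channel rasters are accepted only if all
# channels are identical.
read_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raster <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    raster <- png::readPNG(path, info = TRUE)
    info <- attr(raster, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    raster <- raster * (2^depth - 1)
  } else {
    abort(sprintf("Unsupported raster format '%s' (use tif/tiff/png).", ext))
  }
  if (length(dim(raster)) == 3L) {
    ch <- lapply(seq_len(dim(raster)[3]), function(k) raster[, , k])
    same <- all(vapply(ch[-1], function(m) identical(m, ch[[1]]), logical(1)))
    if (!same) abort(sprintf("'%s' is multi-channel; expected grayscale.", path))
    raster <- ch[[1]]
  }
  storage.mode(raster) <- "double"
  raster
}
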