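# Internal helpers shared across modules.

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be a single number, not NULL.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)))
  }
  invisible(x)
}

#' Label 8-connected components of a logical matrix
#'
#' Breadth-first labelling of the `TRUE` pixels of a logical matrix into
#' 8-connected components. Used for splitting threshold-exceeding pixels into
#' candidate clusters and for validating that each mask label forms a single
#' connected region. Intended for small regions (single cells or polar caps).
#'
#' @param fg Logical matrix; `TRUE` marks foreground pixels.
#' @return Integer matrix of the same dimension: 0 for background, components
#'   numbered 1, 2, ... in order of first (column-major) encounter.
#' @examples
#' m <- matrix(FALSE, 4, 4)
#' m[1, 1] <- m[2, 2] <- TRUE  # diagonal touch: one component
#' m[4, 4] <- TRUE             # isolated: second component
#' label_components(m)
#' @export
label_components <- function(fg) {
  if (!is.logical(fg) || !is.matrix(fg)) {
    abort("`fg` must be a logical matrix.")
  }
  nr <- nrow(fg)
  nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  current <- 0L
  # offsets of the 8-neighbourhood in (row, col)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nb_r <- r + dr
      nb_c <- cc + dc
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- current
        queue <- c(queue, nb)
      }
    }
  }
  lab
}
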