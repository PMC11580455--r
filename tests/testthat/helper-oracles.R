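# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: connected components come
# from igraph, the t-test from the textbook pooled-variance formula, and the
# omega binning from a direct transcription of the printed inequalities.

# Direct re-implementation of the asymmetry index and its bins.
oracle_omega <- function(p1, p2) (p1 - p2) / (p1 + p2)

oracle_category <- function(p1, p2) {
  if (p1 + p2 == 0) return("diffuse")
  w <- oracle_omega(p1, p2)
  if (w > 0.9) "unipolar"
  else if (w >= 0.2) "bipolar_asymmetric"
  else "bipolar_symmetric"
}

# Brute-force polar cluster detection: enumerate 8-connected components of
# above-threshold cap pixels with igraph, then apply the size and
# component-mean rules independently. Returns a list of sorted pixel-key
# vectors ("row,col"), one per kept cluster, sorted for set comparison.
oracle_clusters <- function(px, image, background, cyto, k_sd = 2, min_size = 3) {
  threshold <- cyto$mean + k_sd * cyto$sd
  found <- list()
  for (cap in c("A", "B")) {
    cp <- px[px$cap == cap, , drop = FALSE]
    if (nrow(cp) == 0) next
    vals <- image[cbind(cp$row, cp$col)] - background
    sel <- which(vals > threshold)
    if (length(sel) == 0) next
    pts <- cp[sel, , drop = FALSE]
    n <- length(sel)
    adj <- which(
      abs(outer(pts$row, pts$row, "-")) <= 1 &
        abs(outer(pts$col, pts$col, "-")) <= 1 &
        !diag(TRUE, n), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(adj, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      in_k <- comp == k
      if (sum(in_k) < min_size) next
      if (mean(vals[sel][in_k]) < threshold) next
      found[[length(found) + 1]] <-
        sort(paste(pts$row[in_k], pts$col[in_k], sep = ","))
    }
  }
  found[order(vapply(found, `[`, character(1), 1))]
}

# Textbook pooled-variance two-sample t statistic and two-tailed p-value.
oracle_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(statistic = t, p.value = p)
}

# Sorted pixel-key sets of the package's detected clusters, for comparison
# with oracle_clusters().
cluster_keys <- function(clusters) {
  found <- lapply(clusters$pixels, function(p)
    sort(paste(p$row, p$col, sep = ",")))
  found[order(vapply(found, `[`, character(1), 1))]
}

# One horizontal rod cell in a small image with chosen pole fractions;
# returns the scene plus prepared cell tibble (caps defined).
make_single_cell <- function(pole1 = 0, pole2 = 0, noise = FALSE, seed = 1,
                             length_um = 5.5, shape = c(40, 120)) {
  spec <- scene_spec(n_cells = 1, image_shape = shape,
                     cell_length_range = c(length_um, length_um),
                     orientation = pi / 2, seed = seed)
  loc <- localization_spec(pole1_fraction = pole1, pole2_fraction = pole2,
                           shot_noise = noise,
                           read_noise_sd = if (noise) 2 else 0)
  scene <- generate_scene(spec, loc)
  cells <- define_polar_caps(compute_axis(extract_cells(scene$mask)))
  list(scene = scene, cells = cells)
}

# Rotate a matrix 90 degrees clockwise; (r, c) maps to (c, nr - r + 1).
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
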