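# Shared fixture builders and comparison utilities.

# Renumber labels by row-major first appearance so labelings can be
# compared up to id permutation.
canonical_labels <- function(labels) {
  rm_order <- as.vector(t(labels))
  seen <- unique(rm_order[rm_order != 0])
  out <- labels
  out[labels != 0] <- match(labels[labels != 0], seen)
  out
}

# The patch partition as a set of sorted cell-index sets (order-free).
partition_sets <- function(labels) {
  ids <- sort(unique(labels[labels != 0]))
  sets <- lapply(ids, function(i) sort(which(labels == i)))
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# Two single-cell patches of one class, closest centers offset by
# (2 rows, 1 col): ENN = 100 * sqrt(5).
two_patch_fixture <- function(res = c(100, 100)) {
  blocks_landscape(c(5, 5), list(
    list(class_val = 1, row0 = 1, col0 = 1, height = 1, width = 1),
    list(class_val = 1, row0 = 3, col0 = 2, height = 1, width = 1)
  ), res = res)
}

# Striped landscape with m equally-sized class bands (for the maximum
# Shannon diversity check).
striped_landscape <- function(m, band = 5, res = c(100, 100)) {
  cells <- matrix(rep(seq_len(m), each = band * m * band),
                  nrow = m * band, byrow = FALSE)
  landscape(cells, res = res)
}

random_fixture <- function(seed, side = 30, probs = c(0.4, 0.35, 0.25)) {
  random_mosaic(c(side, side), probs, seed = seed)
}

# Georeferenced 2-class mosaic for buffer/zonal drivers.
geo_fixture <- function(seed = 7, side = 60) {
  g <- random_mosaic(c(side, side), c(0.3, 0.7), seed = seed)
  landscape(g$cells, res = c(100, 100), xmin = 0, ymin = 0,
            crs = "EPSG:32632")
}
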