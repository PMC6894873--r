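# Patch segmentation, geometry, adjacency and nearest-neighbour distances,
# all cached per landscape. The cache lives in an environment inside the
# landscape object, so repeated metric computations on the same grid never
# re-segment; `cache_info()` exposes the computation counters.

bump_counter <- function(grid, name) {
  cnt <- grid$cache$counters
  cnt[[name]] <- cnt[[name]] + 1L
  grid$cache$counters <- cnt
  invisible(NULL)
}

check_connectivity <- function(connectivity) {
  if (length(connectivity) != 1L || !connectivity %in% c(4, 8)) {
    stop_validation("`connectivity` must be 4 or 8")
  }
  as.integer(connectivity)
}

cached_labeling <- function(grid, connectivity) {
  key <- paste0("labeling_", connectivity)
  if (is.null(grid$cache[[key]])) {
    bump_counter(grid, "segmentations")
    res <- label_patches_cpp(grid$cells, grid$nodata, connectivity)
    lab <- list(labels = res$labels,
                patch_class = as.integer(res$patch_class),
                n_patches = length(res$patch_class),
                connectivity = connectivity)
    class(lab) <- "patch_labeling"
    grid$cache[[key]] <- lab
  }
  grid$cache[[key]]
}

cached_geometry <- function(grid, connectivity) {
  key <- paste0("geometry_", connectivity)
  if (is.null(grid$cache[[key]])) {
    lab <- cached_labeling(grid, connectivity)
    st <- patch_stats_cpp(lab$labels, lab$n_patches)
    ca <- cell_area_m2(grid)
    grid$cache[[key]] <- tibble::tibble(
      patch_id = seq_len(lab$n_patches),
      class_val = lab$patch_class,
      n_cells = as.integer(st$n_cells),
      n_sides = as.integer(st$sides_w) + as.integer(st$sides_h),
      area_m2 = as.numeric(st$n_cells) * ca,
      area_ha = as.numeric(st$n_cells) * ca / 1e4,
      perimeter = st$sides_w * grid$cell_width + st$sides_h * grid$cell_height
    )
  }
  grid$cache[[key]]
}

cached_adjacency <- function(grid) {
  if (is.null(grid$cache$adjacency)) {
    bump_counter(grid, "adjacency_builds")
    cls <- landscape_classes(grid)
    codes <- c(cls, grid$nodata)
    idx <- matrix(match(grid$cells, codes), nrow = nrow(grid$cells))
    raw <- adjacency_cpp(idx, length(codes))
    nm <- c(as.character(cls), "nodata")
    dimnames(raw$e_horiz) <- list(nm, nm)
    dimnames(raw$e_vert) <- list(nm, nm)
    adj <- list(classes = cls, nodata = grid$nodata,
                e_horiz = raw$e_horiz, e_vert = raw$e_vert,
                border_w = setNames(raw$border_w, nm),
                border_h = setNames(raw$border_h, nm),
                cell_width = grid$cell_width, cell_height = grid$cell_height)
    class(adj) <- "adjacency_table"
    grid$cache$adjacency <- adj
  }
  grid$cache$adjacency
}

cached_enn <- function(grid, connectivity) {
  key <- paste0("enn_", connectivity)
  if (is.null(grid$cache[[key]])) {
    bump_counter(grid, "enn_builds")
    lab <- cached_labeling(grid, connectivity)
    grid$cache[[key]] <- as.numeric(
      patch_enn_cpp(lab$labels, lab$patch_class,
                    grid$cell_width, grid$cell_height))
  }
  grid$cache[[key]]
}

#' Segment a landscape into patches
#'
#' Labels every maximal connected set of same-class cells under the chosen
#' neighbourhood rule. Patch ids are assigned in row-major first-contact
#' order; nodata cells are never labeled (label 0). Results are cached in
#' the landscape.
#'
#' @param grid a [landscape].
#' @param connectivity 8 (default, queen: sides and corners join a patch)
#'   or 4 (rook: sides only).
#' @return a `patch_labeling`: list with `labels` (integer matrix, 0 =
#'   nodata), `patch_class` (class code per patch id), `n_patches`, and
#'   `connectivity`.
#' @export
segment_patches <- function(grid, connectivity = 8) {
  check_landscape(grid)
  connectivity <- check_connectivity(connectivity)
  cached_labeling(grid, connectivity)
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf("<patch_labeling> %d patches, connectivity %d\n",
              x$n_patches, x$connectivity))
  invisible(x)
}

#' Patch geometry table
#'
#' One row per patch with its class, cell count, area and perimeter.
#' Perimeter sums every exposed cell side: a side is exposed when the rook
#' neighbour is a different class, nodata, or off the raster (borders and
#' nodata-facing sides always count). Horizontal sides contribute the cell
#' width, vertical sides the cell height.
#'
#' @inheritParams segment_patches
#' @return tibble with columns `patch_id`, `class_val`, `n_cells`,
#'   `n_sides` (exposed side count), `area_m2`, `area_ha`, `perimeter`
#'   (meters).
#' @export
patch_geometry <- function(grid, connectivity = 8) {
  check_landscape(grid)
  connectivity <- check_connectivity(connectivity)
  cached_geometry(grid, connectivity)
}

#' Class adjacency table
#'
#' Counts every interior shared cell side exactly once per unordered cell
#' pair (rook rule, independent of the patch connectivity), between every
#' pair of class codes with nodata kept as an extra pseudo-class. Counts
#' are split by the direction of the shared side so they convert to meters
#' for rectangular cells; raster-border sides are recorded separately per
#' class.
#'
#' @param grid a [landscape].
#' @return an `adjacency_table`: symmetric count matrices `e_horiz`
#'   (horizontally adjacent pairs, shared side length = cell height) and
#'   `e_vert` (vertically adjacent pairs, shared side length = cell width),
#'   border side tallies `border_w`/`border_h`, and the class codes.
#' @export
adjacency_table <- function(grid) {
  check_landscape(grid)
  cached_adjacency(grid)
}

#' @export
print.adjacency_table <- function(x, ...) {
  cat("<adjacency_table> shared cell-side counts (nodata as pseudo-class)\n")
  print(adjacency_counts(x))
  invisible(x)
}

#' Total adjacency counts as a matrix
#'
#' @param adj an [adjacency_table()].
#' @param include_nodata keep the nodata pseudo-class row/column?
#' @return symmetric matrix of shared-side counts (`e_horiz + e_vert`);
#'   each unordered cell pair is counted once, mirrored across the
#'   diagonal.
#' @export
adjacency_counts <- function(adj, include_nodata = TRUE) {
  if (!inherits(adj, "adjacency_table")) {
    stop_validation("expected an `adjacency_table`")
  }
  e <- adj$e_horiz + adj$e_vert
  if (!include_nodata) {
    keep <- seq_along(adj$classes)
    e <- e[keep, keep, drop = FALSE]
  }
  e
}

# Edge bookkeeping shared by the metric formulas. All lengths in meters,
# all side counts as plain counts. "boundary" sides are data-nodata plus
# raster-border sides.
edge_lengths <- function(adj) {
  ndat <- length(adj$classes)
  nd_i <- ndat + 1L
  len <- adj$e_horiz * adj$cell_height + adj$e_vert * adj$cell_width
  cnt <- adj$e_horiz + adj$e_vert
  border_len <- adj$border_w * adj$cell_width + adj$border_h * adj$cell_height
  border_cnt <- adj$border_w + adj$border_h
  dat <- seq_len(ndat)
  list(
    classes = adj$classes,
    inter_len = len[dat, dat, drop = FALSE],
    inter_cnt = cnt[dat, dat, drop = FALSE],
    nodata_len = len[dat, nd_i],
    nodata_cnt = cnt[dat, nd_i],
    border_len = border_len[dat],
    border_cnt = border_cnt[dat]
  )
}

# Total edge in meters; class scope when class_val given, else landscape.
total_edge_m <- function(adj, class_val = NULL, count_boundary = FALSE) {
  el <- edge_lengths(adj)
  if (!is.null(class_val)) {
    i <- match(class_val, el$classes)
    if (is.na(i)) stop_validation("unknown class: ", class_val)
    te <- sum(el$inter_len[i, -i])
    if (length(el$classes) == 1L) te <- 0
    if (count_boundary) te <- te + el$nodata_len[i] + el$border_len[i]
  } else {
    inter <- el$inter_len
    diag(inter) <- 0
    te <- sum(inter) / 2
    if (count_boundary) te <- te + sum(el$nodata_len) + sum(el$border_len)
  }
  te
}

# Boundary-inclusive side counts feeding the landscape shape index:
# every inter-class, nodata-facing and raster-border side once.
total_edge_sides <- function(adj, class_val = NULL) {
  el <- edge_lengths(adj)
  if (!is.null(class_val)) {
    i <- match(class_val, el$classes)
    if (is.na(i)) stop_validation("unknown class: ", class_val)
    s <- sum(el$inter_cnt[i, -i]) + el$nodata_cnt[i] + el$border_cnt[i]
    if (length(el$classes) == 1L) {
      s <- el$nodata_cnt[i] + el$border_cnt[i]
    }
  } else {
    inter <- el$inter_cnt
    diag(inter) <- 0
    s <- sum(inter) / 2 + sum(el$nodata_cnt) + sum(el$border_cnt)
  }
  as.numeric(s)
}

#' Euclidean nearest-neighbour distance per patch
#'
#' For each patch, the minimum cell-center to cell-center distance to any
#' other patch of the same class, in meters. Classes with a single patch
#' have no neighbour: their distance is NaN (undefined, never zero).
#' Computed over patch boundary cells, which attains the same minimum as
#' the all-pairs brute force.
#'
#' @inheritParams segment_patches
#' @return numeric vector, one distance per patch id.
#' @export
nearest_neighbor_distances <- function(grid, connectivity = 8) {
  check_landscape(grid)
  connectivity <- check_connectivity(connectivity)
  cached_enn(grid, connectivity)
}

#' Minimum perimeter of a maximally compact raster patch
#'
#' Side count of the most compact (squarest) patch of `n` cells, the
#' reference perimeter in the shape index and landscape shape index. With
#' `a = floor(sqrt(n))`: `4a` when `n = a^2`, `4a + 2` when
#' `n <= a(a+1)`, else `4a + 4`.
#'
#' @param n integer vector of cell counts (>= 1).
#' @return integer vector of side counts.
#' @examples
#' min_perimeter_cells(c(9, 2, 115)) # 12, 6, 44
#' @export
min_perimeter_cells <- function(n) {
  if (!length(n) || anyNA(n) || !all(is_whole(n)) || any(n < 1)) {
    stop_validation("`n` must be integer cell counts >= 1")
  }
  n <- round(n)
  a <- floor(sqrt(n))
  # floating-point guard: sqrt(a^2) can land just below a
  a <- ifelse((a + 1)^2 <= n, a + 1, a)
  ifelse(n == a^2, 4 * a, ifelse(n <= a * (a + 1), 4 * a + 2, 4 * a + 4))
}

#' Cache instrumentation for a landscape
#'
#' Reports how many times the expensive intermediates were computed for
#' this grid. Each stays at most 1 per connectivity however many metric
#' tables are built; nearest-neighbour distances are only ever computed
#' when an `euclidean_nearest_neighbor` family metric is requested.
#'
#' @param grid a [landscape].
#' @return list with counters `segmentations`, `adjacency_builds`,
#'   `enn_builds`.
#' @export
cache_info <- function(grid) {
  check_landscape(grid)
  grid$cache$counters
}
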