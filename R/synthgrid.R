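# Deterministic synthetic landscapes with closed-form ground truth, and
# small brute-force reference implementations (flood fill, exhaustive side
# enumeration, all-pairs distances). The oracles are intentionally naive
# and independent of the compiled segmentation/adjacency/ENN code so that
# any landscape can be audited at small scale.

#' Paint rectangular blocks onto a nodata canvas
#'
#' Builds a landscape from rectangles with known cell counts, areas and
#' perimeters (an isolated `h x w` block has `h*w` cells and perimeter
#' `2(h+w)` sides). Overlapping blocks resolve later-wins.
#'
#' @param canvas `c(rows, cols)` canvas size.
#' @param blocks list of block specs, each a list or named vector with
#'   `class_val`, `row0`, `col0` (1-based top-left cell), `height`,
#'   `width`.
#' @param res cell size(s) in meters, as in [landscape()].
#' @param nodata nodata code for the canvas.
#' @return a [landscape].
#' @examples
#' blocks_landscape(c(5, 5), list(list(class_val = 1, row0 = 2, col0 = 2,
#'                                     height = 2, width = 3)), res = 100)
#' @export
blocks_landscape <- function(canvas, blocks, res = c(100, 100), nodata = 0L) {
  if (length(canvas) != 2L || any(!is_whole(canvas)) || any(canvas < 1)) {
    stop_validation("`canvas` must be two positive integers (rows, cols)")
  }
  cells <- matrix(as.integer(nodata), nrow = canvas[1], ncol = canvas[2])
  for (b in blocks) {
    b <- as.list(b)
    need <- c("class_val", "row0", "col0", "height", "width")
    if (!all(need %in% names(b))) {
      stop_validation("each block needs fields: ", paste(need, collapse = ", "))
    }
    r1 <- b$row0 + b$height - 1
    c1 <- b$col0 + b$width - 1
    if (b$row0 < 1 || b$col0 < 1 || r1 > canvas[1] || c1 > canvas[2]) {
      stop_validation("block extends outside the canvas")
    }
    cells[b$row0:r1, b$col0:c1] <- as.integer(b$class_val)
  }
  landscape(cells, res = res, nodata = nodata)
}

#' Random categorical mosaic
#'
#' Draws each cell i.i.d. from a categorical distribution over the class
#' codes (plus nodata with probability `nodata_prob`), using R's default
#' Mersenne-Twister generator so a fixed seed reproduces the grid
#' bit-exactly on any platform.
#'
#' @param canvas `c(rows, cols)` canvas size.
#' @param class_probs probabilities per class; together with `nodata_prob`
#'   they must sum to 1. Class codes default to `1..m` or can be given as
#'   the vector's names.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param res cell size(s) in meters.
#' @param nodata_prob probability of a nodata cell.
#' @param nodata nodata code.
#' @return a [landscape].
#' @export
random_mosaic <- function(canvas, class_probs, seed = NULL, res = c(100, 100),
                          nodata_prob = 0, nodata = 0L) {
  if (length(canvas) != 2L || any(!is_whole(canvas)) || any(canvas < 1)) {
    stop_validation("`canvas` must be two positive integers (rows, cols)")
  }
  probs <- c(class_probs, nodata_prob)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop_validation("`class_probs` plus `nodata_prob` must sum to 1")
  }
  codes <- if (!is.null(names(class_probs))) {
    as.integer(names(class_probs))
  } else {
    seq_along(class_probs)
  }
  if (any(codes == nodata)) {
    stop_validation("class codes must differ from the nodata code")
  }
  draw <- function() {
    matrix(sample(c(codes, as.integer(nodata)), prod(canvas), replace = TRUE,
                  prob = probs),
           nrow = canvas[1], ncol = canvas[2])
  }
  cells <- if (is.null(seed)) {
    draw()
  } else if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(as.integer(seed), draw())
  } else {
    set.seed(as.integer(seed))
    draw()
  }
  landscape(cells, res = res, nodata = nodata)
}

#' Reference polyomino landscape for the worked patch metrics
#'
#' Three free-form polyominoes of one class at 100 m resolution whose
#' (cell count, exposed side count) pairs are (115, 106), (13, 26) and
#' (2, 6) — a compact 8x10 core with a 35-cell tail, a 2x2 block with a
#' 9-cell tail, and a domino. Running the patch-metrics table on this grid
#' reproduces the worked perimeter-area ratio, shape index and fractal
#' dimension values end-to-end (92.173913 / 2.409091 / 1.129654 etc.).
#'
#' @return a [landscape] with three patches of class 1, patch ids in the
#'   order above.
#' @export
reference_patches_landscape <- function() {
  blocks <- list(
    # patch 1: 8x10 rectangle + straight 35-cell tail -> n = 115, 106 sides
    list(class_val = 1, row0 = 2, col0 = 2, height = 1, width = 45),
    list(class_val = 1, row0 = 2, col0 = 2, height = 8, width = 10),
    # patch 2: 2x2 block + straight 9-cell tail -> n = 13, 26 sides
    list(class_val = 1, row0 = 12, col0 = 2, height = 2, width = 2),
    list(class_val = 1, row0 = 12, col0 = 4, height = 1, width = 9),
    # patch 3: domino -> n = 2, 6 sides
    list(class_val = 1, row0 = 16, col0 = 2, height = 1, width = 2)
  )
  blocks_landscape(c(18, 48), blocks, res = c(100, 100))
}

#' Brute-force patch segmentation oracle
#'
#' Plain R stack-based flood fill, the contractual ground truth for
#' [segment_patches()] on small grids (quadratic-ish, keep below ~1e4
#' cells).
#'
#' @inheritParams segment_patches
#' @return a `patch_labeling`, as [segment_patches()].
#' @export
oracle_segment <- function(grid, connectivity = 8) {
  check_landscape(grid)
  connectivity <- check_connectivity(connectivity)
  cells <- grid$cells
  nr <- nrow(cells)
  nc <- ncol(cells)
  labels <- matrix(0L, nr, nc)
  offsets <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  patch_class <- integer(0)
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (co in seq_len(nc)) {
      v <- cells[r, co]
      if (v == grid$nodata || labels[r, co] != 0L) next
      nxt <- nxt + 1L
      patch_class <- c(patch_class, v)
      stack <- list(c(r, co))
      labels[r, co] <- nxt
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offsets))) {
          r2 <- cur[1] + offsets[k, 1]
          c2 <- cur[2] + offsets[k, 2]
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (labels[r2, c2] == 0L && cells[r2, c2] == v) {
            labels[r2, c2] <- nxt
            stack[[length(stack) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  out <- list(labels = labels, patch_class = patch_class,
              n_patches = nxt, connectivity = connectivity)
  class(out) <- "patch_labeling"
  out
}

#' Exhaustive adjacency enumeration oracle
#'
#' Enumerates every interior horizontally or vertically shared cell side
#' once and tallies it by the unordered pair of class codes (nodata as
#' pseudo-class), independently of the compiled adjacency pass.
#'
#' @param grid a [landscape].
#' @return symmetric count matrix with the data classes first and a final
#'   `nodata` row/column, as [adjacency_counts()].
#' @export
oracle_adjacency <- function(grid) {
  check_landscape(grid)
  cells <- grid$cells
  cls <- landscape_classes(grid)
  codes <- c(cls, grid$nodata)
  m <- length(codes)
  e <- matrix(0, m, m, dimnames = list(c(as.character(cls), "nodata"),
                                       c(as.character(cls), "nodata")))
  tally <- function(a, b) {
    ia <- match(a, codes)
    ib <- match(b, codes)
    for (k in seq_along(ia)) {
      e[ia[k], ib[k]] <<- e[ia[k], ib[k]] + 1
      if (ia[k] != ib[k]) e[ib[k], ia[k]] <<- e[ib[k], ia[k]] + 1
    }
  }
  if (ncol(cells) > 1) {
    tally(as.vector(cells[, -ncol(cells)]), as.vector(cells[, -1]))
  }
  if (nrow(cells) > 1) {
    tally(as.vector(cells[-nrow(cells), ]), as.vector(cells[-1, ]))
  }
  e
}

#' All-pairs nearest-neighbour distance oracle
#'
#' For every patch, the minimum cell-center distance to any other patch of
#' the same class, computed by exhaustive comparison over all cells of the
#' class (no boundary-cell shortcut, no spatial index).
#'
#' @param labeling a `patch_labeling` for `grid`.
#' @param grid the [landscape] the labeling came from.
#' @return numeric vector of distances per patch id (NaN for single-patch
#'   classes).
#' @export
oracle_enn <- function(labeling, grid) {
  check_landscape(grid)
  labels <- labeling$labels
  nr <- nrow(labels)
  rows <- matrix(seq_len(nr), nr, ncol(labels))
  cols <- matrix(rep(seq_len(ncol(labels)), each = nr), nr)
  enn <- rep(NaN, labeling$n_patches)
  for (cv in unique(labeling$patch_class)) {
    ids <- which(labeling$patch_class == cv)
    if (length(ids) < 2) next
    sel <- labels %in% ids
    x <- cols[sel] * grid$cell_width
    y <- rows[sel] * grid$cell_height
    lab <- labels[sel]
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    same <- outer(lab, lab, "==")
    d2[same] <- Inf
    for (id in ids) {
      enn[id] <- sqrt(min(d2[lab == id, , drop = FALSE]))
    }
  }
  enn
}
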