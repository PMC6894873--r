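# Multi-landscape drivers. Each analysis is a list of landscapes plus an
# index table (one row per landscape: its date, buffer distance, ring
# label or attribute value). The class- and landscape-level builders
# evaluate each landscape with the single-landscape engine and stack the
# rows under the analysis' index scheme.

as_landscape <- function(x) {
  if (inherits(x, "landscape")) x else read_landscape(x)
}

new_multi_analysis <- function(landscapes, index, subclass, plot_x,
                               group_col = NULL) {
  stopifnot(nrow(index) == length(landscapes))
  structure(
    list(landscapes = landscapes, index = index, plot_x = plot_x,
         group_col = group_col),
    class = c(subclass, "multi_landscape_analysis")
  )
}

#' @export
print.multi_landscape_analysis <- function(x, ...) {
  cat(sprintf("<%s> %d landscapes, indexed by %s\n", class(x)[1],
              length(x$landscapes), paste(names(x$index), collapse = ", ")))
  invisible(x)
}

check_same_frame <- function(landscapes) {
  ref <- landscapes[[1]]
  for (l in landscapes[-1]) {
    if (!identical(dim(l$cells), dim(ref$cells))) {
      stop_validation("all snapshots must share the same raster shape")
    }
    if (!isTRUE(all.equal(c(l$cell_width, l$cell_height),
                          c(ref$cell_width, ref$cell_height)))) {
      stop_validation("all snapshots must share the same cell resolution")
    }
  }
  invisible(landscapes)
}

#' Spatiotemporal analysis of a landscape time series
#'
#' Wraps a temporally-ordered sequence of snapshots of the same region.
#' Class-level tables are indexed by `(class_val, dates)` and
#' landscape-level tables by `dates`; no patch-level table is offered
#' because patches carry no identity across snapshots.
#'
#' @param snapshots list of [landscape]s or raster paths, in temporal
#'   order, all with the same shape and resolution.
#' @param dates optional ordered labels (numbers, date strings or
#'   timestamps), one per snapshot; defaults to `0..n-1`. Used only as
#'   ordered labels.
#' @return a `spatiotemporal_analysis` handle for the
#'   `compute_*_metrics_df` and [plot_metric()] functions.
#' @export
spatiotemporal_analysis <- function(snapshots, dates = NULL) {
  if (!length(snapshots)) stop_validation("at least one snapshot is required")
  landscapes <- lapply(snapshots, as_landscape)
  check_same_frame(landscapes)
  dates <- dates %||% (seq_along(landscapes) - 1)
  if (length(dates) != length(landscapes)) {
    stop_validation("`dates` must have one entry per snapshot")
  }
  new_multi_analysis(landscapes, tibble::tibble(dates = dates),
                     "spatiotemporal_analysis", plot_x = "dates")
}

#' Generic zonal analysis
#'
#' Decomposes a landscape into zones given as boolean masks; each zone
#' becomes an independent landscape where out-of-mask cells are nodata, so
#' zone borders count as landscape boundary (excluded from edge metrics
#' unless `count_boundary`). Zones may overlap. Tables are indexed by
#' `attribute`.
#'
#' @param grid a [landscape] or raster path.
#' @param masks list of logical matrices congruent with the grid.
#' @param attribute_values optional labels, one per mask; defaults to
#'   `0..n-1`.
#' @return a `zonal_analysis` handle.
#' @export
zonal_analysis <- function(grid, masks, attribute_values = NULL) {
  grid <- as_landscape(grid)
  if (!length(masks)) stop_validation("at least one mask is required")
  landscapes <- lapply(masks, function(m) mask_landscape(grid, m))
  attribute_values <- attribute_values %||% (seq_along(masks) - 1)
  if (length(attribute_values) != length(masks)) {
    stop_validation("`attribute_values` must have one entry per mask")
  }
  new_multi_analysis(landscapes,
                     tibble::tibble(attribute = attribute_values),
                     "zonal_analysis", plot_x = "attribute")
}

mask_landscape <- function(grid, mask) {
  if (!is.matrix(mask) || !identical(dim(mask), dim(grid$cells))) {
    stop_validation("each mask must be a logical matrix congruent with the grid")
  }
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (anyNA(mask)) stop_validation("masks must not contain NA")
  cells <- grid$cells
  cells[!mask] <- grid$nodata
  landscape(cells, res = c(grid$cell_width, grid$cell_height),
            nodata = grid$nodata,
            xmin = if (grid$georeferenced) grid$xmin else NULL,
            ymin = if (grid$georeferenced) grid$ymin else NULL,
            crs = grid$crs)
}

## ---- buffer geometry ------------------------------------------------------

parse_geometry <- function(base_geometry) {
  if (is.numeric(base_geometry) && length(base_geometry) == 2L) {
    return(list(type = "point", xy = as.numeric(base_geometry)))
  }
  if (is.matrix(base_geometry) && ncol(base_geometry) == 2L &&
      nrow(base_geometry) >= 3L) {
    return(list(type = "polygon", coords = base_geometry))
  }
  if (is.character(base_geometry) && length(base_geometry) == 1L) {
    wkt <- trimws(base_geometry)
    if (grepl("^POINT", wkt, ignore.case = TRUE)) {
      nums <- as.numeric(strsplit(trimws(gsub("^POINT\\s*\\(|\\)$", "",
                                              wkt, ignore.case = TRUE)),
                                  "\\s+")[[1]])
      if (length(nums) == 2 && !anyNA(nums)) {
        return(list(type = "point", xy = nums))
      }
    }
    if (grepl("^POLYGON", wkt, ignore.case = TRUE)) {
      body <- gsub("^POLYGON\\s*\\(\\(|\\)\\)$", "", wkt, ignore.case = TRUE)
      ring <- strsplit(strsplit(body, "\\)\\s*,")[[1]][1], ",")[[1]]
      coords <- t(vapply(ring, function(s) {
        as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:2])
      }, numeric(2)))
      if (!anyNA(coords) && nrow(coords) >= 3) {
        return(list(type = "polygon", coords = unname(coords)))
      }
    }
    stop_validation("cannot parse geometry WKT: ", base_geometry)
  }
  stop_validation("`base_geometry` must be a point c(x, y), a 2-column ",
                  "polygon coordinate matrix, or POINT/POLYGON WKT")
}

normalize_crs <- function(crs) {
  tolower(gsub("\\s+", "", as.character(crs)))
}

check_geometry_crs <- function(grid, geometry_crs) {
  if (is.null(geometry_crs) || is.null(grid$crs)) return(invisible(NULL))
  if (!identical(normalize_crs(geometry_crs), normalize_crs(grid$crs))) {
    stop_validation("geometry CRS differs from the raster CRS; ",
                    "reprojection is not supported — supply the geometry ",
                    "in the raster's CRS")
  }
  invisible(NULL)
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  if (isTRUE(all.equal(coords[1, ], coords[n, ]))) {
    coords <- coords[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from query points to a polygon boundary (vectorized
# point-to-segment), zero for interior points.
polygon_distance <- function(px, py, coords) {
  n <- nrow(coords)
  if (!isTRUE(all.equal(coords[1, ], coords[n, ]))) {
    coords <- rbind(coords, coords[1, ])
    n <- n + 1L
  }
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    x1 <- coords[i, 1]; y1 <- coords[i, 2]
    x2 <- coords[i + 1, 1]; y2 <- coords[i + 1, 2]
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / len2))
    d2 <- pmin(d2, (px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2)
  }
  d <- sqrt(d2)
  d[points_in_polygon(px, py, coords)] <- 0
  d
}

#' Buffer zone masks around a feature of interest
#'
#' Rasterizes buffers of increasing distance around a point or polygon
#' into boolean cell masks: a cell belongs to a buffer when its center
#' lies within the buffer distance of the geometry (cell-center rule,
#' which makes consecutive rings an exact partition of the outermost
#' buffer). With `rings = TRUE` the masks are the annuli between
#' consecutive distances, labeled `"0-d1"`, `"d1-d2"`, ...
#'
#' @param grid a georeferenced [landscape].
#' @param base_geometry point `c(x, y)`, polygon coordinate matrix, or
#'   POINT/POLYGON WKT, in the raster's CRS.
#' @param distances strictly ascending buffer distances in meters; 0 is
#'   allowed first for polygons (the polygon itself).
#' @param geometry_crs optional CRS label of the geometry; must match the
#'   raster's CRS (no reprojection).
#' @param rings return ring masks instead of nested buffers.
#' @return list of zones, each `list(mask = <logical matrix>, label)`.
#' @export
buffer_masks <- function(grid, base_geometry, distances, geometry_crs = NULL,
                         rings = FALSE) {
  check_landscape(grid)
  if (!grid$georeferenced) {
    stop_validation("buffer analysis requires a georeferenced landscape")
  }
  geom <- parse_geometry(base_geometry)
  check_geometry_crs(grid, geometry_crs)
  distances <- as.numeric(distances)
  if (!length(distances) || is.unsorted(distances, strictly = TRUE)) {
    stop_validation("`distances` must be strictly ascending")
  }
  if (any(distances < 0)) stop_validation("`distances` must be nonnegative")
  if (distances[1] == 0 && (geom$type != "polygon" || rings)) {
    stop_validation("a zero distance is only meaningful for a polygon ",
                    "geometry without rings")
  }
  ctr <- cell_centers(grid)
  nr <- nrow(grid$cells)
  nc <- ncol(grid$cells)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = nc)
  d <- if (geom$type == "point") {
    sqrt((px - geom$xy[1])^2 + (py - geom$xy[2])^2)
  } else {
    polygon_distance(px, py, geom$coords)
  }
  buffers <- lapply(distances, function(dd) matrix(d <= dd, nrow = nr))
  if (rings) {
    zones <- vector("list", length(distances))
    prev <- matrix(FALSE, nr, nc)
    lab0 <- 0
    for (k in seq_along(distances)) {
      zones[[k]] <- list(mask = buffers[[k]] & !prev,
                         label = paste0(format(lab0, scientific = FALSE,
                                               trim = TRUE), "-",
                                        format(distances[k],
                                               scientific = FALSE,
                                               trim = TRUE)))
      prev <- buffers[[k]]
      lab0 <- distances[k]
    }
  } else {
    zones <- mapply(function(m, dd) list(mask = m, label = dd),
                    buffers, distances, SIMPLIFY = FALSE)
  }
  if (any(!vapply(zones, function(z) any(z$mask), logical(1)))) {
    warn_landmosaic(paste0("one or more buffer zones contain no cells ",
                           "(is the geometry outside the raster extent?)"),
                    class = "landmosaic_empty_mask")
  }
  zones
}

#' Buffer analysis around a feature of interest
#'
#' [zonal_analysis()] over [buffer_masks()]: metrics are computed for the
#' landscape clipped to each buffer (or ring) around the geometry. Tables
#' are indexed by `buffer_dist` (numeric distances, or `"start-end"` ring
#' strings).
#'
#' @inheritParams buffer_masks
#' @return a `buffer_analysis` handle (also a `zonal_analysis`).
#' @export
buffer_analysis <- function(grid, base_geometry, distances,
                            geometry_crs = NULL, rings = FALSE) {
  grid <- as_landscape(grid)
  zones <- buffer_masks(grid, base_geometry, distances, geometry_crs, rings)
  labels <- lapply(zones, `[[`, "label")
  labels <- if (rings) vapply(labels, as.character, character(1)) else
    vapply(labels, as.numeric, numeric(1))
  landscapes <- lapply(zones, function(z) mask_landscape(grid, z$mask))
  new_multi_analysis(landscapes, tibble::tibble(buffer_dist = labels),
                     c("buffer_analysis", "zonal_analysis"),
                     plot_x = "buffer_dist")
}

#' Spatiotemporal buffer analysis
#'
#' Combines a snapshot time series with buffer (or ring) zones: every
#' snapshot is clipped to every zone. Class-level tables are indexed by
#' `(buffer_dist, class_val, dates)` and landscape-level tables by
#' `(buffer_dist, dates)`.
#'
#' @inheritParams spatiotemporal_analysis
#' @inheritParams buffer_masks
#' @param snapshots list of [landscape]s or raster paths, in temporal
#'   order.
#' @return a `spatiotemporal_buffer_analysis` handle.
#' @export
spatiotemporal_buffer_analysis <- function(snapshots, base_geometry,
                                           distances, geometry_crs = NULL,
                                           dates = NULL, rings = FALSE) {
  if (!length(snapshots)) stop_validation("at least one snapshot is required")
  landscapes <- lapply(snapshots, as_landscape)
  check_same_frame(landscapes)
  dates <- dates %||% (seq_along(landscapes) - 1)
  if (length(dates) != length(landscapes)) {
    stop_validation("`dates` must have one entry per snapshot")
  }
  zones <- buffer_masks(landscapes[[1]], base_geometry, distances,
                        geometry_crs, rings)
  labels <- lapply(zones, `[[`, "label")
  labels <- if (rings) vapply(labels, as.character, character(1)) else
    vapply(labels, as.numeric, numeric(1))
  grids <- list()
  idx_dist <- c()
  idx_date <- c()
  for (k in seq_along(zones)) {
    for (t in seq_along(landscapes)) {
      grids[[length(grids) + 1L]] <- mask_landscape(landscapes[[t]],
                                                    zones[[k]]$mask)
      idx_dist <- c(idx_dist, labels[k])
      idx_date <- c(idx_date, dates[t])
    }
  }
  new_multi_analysis(grids,
                     tibble::tibble(buffer_dist = idx_dist, dates = idx_date),
                     "spatiotemporal_buffer_analysis",
                     plot_x = "dates", group_col = "buffer_dist")
}

## ---- metric tables over analyses ------------------------------------------

union_classes <- function(x) {
  sort(unique(unlist(lapply(x$landscapes, landscape_classes))))
}

# class_val goes first except for the spatiotemporal buffer scheme, where
# the buffer distance leads.
class_index_cols <- function(x) {
  if (inherits(x, "spatiotemporal_buffer_analysis")) {
    c("buffer_dist", "class_val", "dates")
  } else {
    c("class_val", names(x$index))
  }
}

#' @rdname compute_patch_metrics_df
#' @export
compute_patch_metrics_df.multi_landscape_analysis <- function(x, ...) {
  stop_validation("patch-level tables are not offered for multi-landscape ",
                  "analyses: patches carry no identity across zones or dates")
}

#' @rdname compute_class_metrics_df
#' @export
compute_class_metrics_df.multi_landscape_analysis <- function(
    x, metrics = NULL, classes = NULL, metrics_kws = list(),
    connectivity = 8, ...) {
  connectivity <- check_connectivity(connectivity)
  avail <- union_classes(x)
  if (!is.null(classes)) {
    bad <- setdiff(classes, avail)
    if (length(bad)) {
      stop_validation("class(es) not present in any landscape: ",
                      paste(bad, collapse = ", "))
    }
  }
  classes <- classes %||% avail
  rows <- lapply(seq_along(x$landscapes), function(i) {
    df <- class_metrics_table(x$landscapes[[i]], metrics, classes,
                              metrics_kws, connectivity)
    dplyr::bind_cols(x$index[rep(i, nrow(df)), , drop = FALSE], df)
  })
  out <- dplyr::bind_rows(rows)
  cols <- class_index_cols(x)
  out <- out[, c(cols, setdiff(names(out), cols))]
  ord <- lapply(cols, function(cn) {
    ref <- if (cn == "class_val") sort(unique(out[[cn]])) else
      unique(x$index[[cn]])
    match(out[[cn]], ref)
  })
  out[do.call(order, ord), ]
}

#' @rdname compute_landscape_metrics_df
#' @export
compute_landscape_metrics_df.multi_landscape_analysis <- function(
    x, metrics = NULL, metrics_kws = list(), connectivity = 8, ...) {
  connectivity <- check_connectivity(connectivity)
  rows <- lapply(seq_along(x$landscapes), function(i) {
    df <- landscape_metrics_row(x$landscapes[[i]], metrics, metrics_kws,
                                connectivity)
    dplyr::bind_cols(x$index[i, , drop = FALSE], df)
  })
  dplyr::bind_rows(rows)
}

## ---- plotting --------------------------------------------------------------

#' Plot the evolution of a metric across an analysis
#'
#' Draws the metric as a line-with-markers series over the analysis'
#' ordinate: dates for a spatiotemporal analysis, buffer distances or ring
#' labels for a buffer analysis, attribute values for a zonal analysis. A
#' spatiotemporal buffer analysis draws one series per buffer distance.
#' With `class_val` the metric is evaluated at the class level, otherwise
#' at the landscape level.
#'
#' @param x an analysis handle.
#' @param metric a metric label from [list_metrics()].
#' @param class_val optional class code for a class-level series.
#' @param gg optional existing ggplot to overlay the series onto.
#' @param plot_kws named list forwarded to the line layer (e.g.
#'   `list(colour = "red", linetype = 2)`).
#' @param ... passed between methods.
#' @return a ggplot object.
#' @export
plot_metric <- function(x, metric, class_val = NULL, gg = NULL,
                        plot_kws = list(), ...) {
  UseMethod("plot_metric")
}

#' @rdname plot_metric
#' @export
plot_metric.multi_landscape_analysis <- function(x, metric, class_val = NULL,
                                                 gg = NULL, plot_kws = list(),
                                                 ...) {
  if (length(metric) != 1L || !metric %in% unique(list_metrics()$metric)) {
    stop_validation("unknown metric: ", metric)
  }
  if (!is.null(class_val)) {
    if (!metric %in% class_metric_labels()) {
      stop_validation("'", metric, "' cannot be computed at the class level")
    }
    df <- compute_class_metrics_df(x, metrics = metric, classes = class_val)
  } else {
    if (!metric %in% landscape_metric_labels()) {
      stop_validation("'", metric, "' cannot be computed at the landscape level")
    }
    df <- compute_landscape_metrics_df(x, metrics = metric)
  }
  xcol <- x$plot_x
  if (is.character(df[[xcol]])) {
    df[[xcol]] <- factor(df[[xcol]], levels = unique(x$index[[xcol]]))
  }
  grp <- x$group_col
  aes <- if (!is.null(grp)) {
    ggplot2::aes(x = .data[[xcol]], y = .data[[metric]],
                 colour = factor(.data[[grp]]),
                 group = factor(.data[[grp]]))
  } else {
    ggplot2::aes(x = .data[[xcol]], y = .data[[metric]], group = 1)
  }
  line <- do.call(ggplot2::geom_line, plot_kws)
  pts <- ggplot2::geom_point()
  if (is.null(gg)) {
    gg <- ggplot2::ggplot(df, aes) + line + pts +
      ggplot2::labs(x = xcol, y = metric,
                    colour = if (!is.null(grp)) grp else NULL)
  } else {
    gg <- gg + ggplot2::geom_line(data = df, mapping = aes) +
      ggplot2::geom_point(data = df, mapping = aes)
  }
  gg
}

#' @importFrom ggplot2 .data
NULL
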