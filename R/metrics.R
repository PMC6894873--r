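# Metric registry and formulas. Defaults follow FRAGSTATS v4 semantics:
# percentages rather than fractions, areas in hectares, and landscape
# boundaries (nodata-facing and raster-border sides) excluded from edge
# totals unless `count_boundary` is set.

metric_bases <- c("area", "perimeter", "perimeter_area_ratio", "shape_index",
                  "fractal_dimension", "euclidean_nearest_neighbor")
stat_suffixes <- c("mn", "am", "md", "ra", "sd", "cv")

class_aggregates <- c("total_area", "proportion_of_landscape",
                      "number_of_patches", "patch_density",
                      "largest_patch_index", "total_edge", "edge_density",
                      "landscape_shape_index")
landscape_aggregates <- c("total_area", "number_of_patches", "patch_density",
                          "largest_patch_index", "total_edge", "edge_density",
                          "landscape_shape_index", "shannon_diversity_index",
                          "contagion")

dist_stat_labels <- function() {
  as.vector(t(outer(metric_bases, stat_suffixes, paste, sep = "_")))
}

class_metric_labels <- function() c(class_aggregates, dist_stat_labels())
landscape_metric_labels <- function() {
  c(landscape_aggregates, dist_stat_labels())
}

# Keyword schema (allowed options and defaults) per metric label.
# Distribution statistics inherit the schema of their base patch metric.
metric_kwargs_schema <- function(label) {
  base <- sub("_(mn|am|md|ra|sd|cv)$", "", label)
  switch(base,
    area = ,
    total_area = ,
    perimeter_area_ratio = list(hectares = TRUE),
    proportion_of_landscape = ,
    largest_patch_index = ,
    contagion = list(percent = TRUE),
    patch_density = list(percent = TRUE, hectares = TRUE),
    total_edge = list(count_boundary = FALSE),
    edge_density = list(count_boundary = FALSE, hectares = TRUE),
    perimeter = ,
    shape_index = ,
    fractal_dimension = ,
    euclidean_nearest_neighbor = ,
    number_of_patches = ,
    landscape_shape_index = ,
    shannon_diversity_index = list()
  )
}

#' List the implemented landscape metrics
#'
#' The registry of metric labels and the analysis levels at which each is
#' available: the 6 patch metrics, their 6 distribution statistics
#' (suffixes `_mn`, `_am`, `_md`, `_ra`, `_sd`, `_cv`) at class and
#' landscape level, 8 class aggregates and 9 landscape aggregates — 95
#' label/level entries in total.
#'
#' @param level optional filter: `"patch"`, `"class"` or `"landscape"`.
#' @return tibble with columns `metric` and `level`.
#' @export
list_metrics <- function(level = NULL) {
  reg <- dplyr::bind_rows(
    tibble::tibble(metric = metric_bases, level = "patch"),
    tibble::tibble(metric = class_metric_labels(), level = "class"),
    tibble::tibble(metric = landscape_metric_labels(), level = "landscape")
  )
  if (!is.null(level)) {
    if (!all(level %in% c("patch", "class", "landscape"))) {
      stop_validation("`level` must be patch, class or landscape")
    }
    reg <- reg[reg$level %in% level, ]
  }
  reg
}

## ---- pure metric formulas ------------------------------------------------

#' Shape index of a raster patch
#'
#' Exposed side count relative to the minimum perimeter of a maximally
#' compact patch of the same cell count ([min_perimeter_cells()]); 1 for a
#' square-ish patch, growing with boundary complexity. Defined in side
#' counts, hence only for square cells.
#'
#' @param n_cells cells in the patch.
#' @param perimeter_sides exposed cell-side count of the patch.
#' @return scalar >= 1.
#' @examples
#' shape_index(115, 106) # 2.409091
#' @export
shape_index <- function(n_cells, perimeter_sides) {
  perimeter_sides / min_perimeter_cells(n_cells)
}

#' Fractal dimension of a patch
#'
#' `2 ln(0.25 p) / ln(a)` with perimeter `p` in meters and area `a` in
#' square meters; near 1 for simple shapes, approaching 2 for highly
#' convoluted ones. A patch of exactly 1 square meter is the formula's
#' degenerate point and yields NaN.
#'
#' @param perimeter patch perimeter in meters.
#' @param area patch area in square meters.
#' @return scalar dimension estimate.
#' @examples
#' fractal_dimension(10600, 1150000) # 1.129654
#' @export
fractal_dimension <- function(perimeter, area) {
  out <- 2 * log(0.25 * perimeter) / log(area)
  out[area == 1] <- NaN
  out
}

#' Perimeter-area ratio of a patch
#'
#' @param perimeter perimeter in meters.
#' @param area patch area (hectares under the default conventions).
#' @return scalar meters per unit area.
#' @export
perimeter_area_ratio <- function(perimeter, area) {
  perimeter / area
}

#' Proportion of the landscape occupied by a class
#'
#' @param class_area,total_area areas in any common unit.
#' @param percent report a percentage (default) or a fraction.
#' @return scalar in (0, 100] (or (0, 1]).
#' @examples
#' proportion_of_landscape(24729, 321075) # 7.701939
#' @export
proportion_of_landscape <- function(class_area, total_area, percent = TRUE) {
  out <- class_area / total_area
  if (percent) out <- out * 100
  out
}

#' Patch density
#'
#' Number of patches per 100 hectares under the defaults.
#'
#' @param n_patches patch count in scope.
#' @param total_area total landscape area (hectares under the defaults).
#' @param percent multiply by 100 (patches per 100 area units, default).
#' @return scalar density.
#' @examples
#' patch_density(193, 321075) # 0.060111
#' @export
patch_density <- function(n_patches, total_area, percent = TRUE) {
  out <- n_patches / total_area
  if (percent) out <- out * 100
  out
}

#' Edge density
#'
#' @param total_edge total edge length in meters.
#' @param total_area total landscape area (hectares under the defaults).
#' @return meters of edge per unit area.
#' @examples
#' edge_density(1431600, 321075) # 4.458771
#' @export
edge_density <- function(total_edge, total_area) {
  total_edge / total_area
}

#' Largest patch index
#'
#' @param areas patch areas in scope.
#' @param total_area total landscape area in the same unit.
#' @param percent report a percentage (default).
#' @return share of the largest patch.
#' @export
largest_patch_index <- function(areas, total_area, percent = TRUE) {
  out <- max(areas) / total_area
  if (percent) out <- out * 100
  out
}

#' Landscape shape index
#'
#' Boundary-inclusive total edge side count relative to the minimum
#' perimeter of a maximally compact patch with the landscape's cell count;
#' 1 for a single compact patch filling the raster. Defined in side
#' counts, hence only for square cells.
#'
#' @param total_edge_sides boundary-inclusive edge side count (every
#'   inter-class, nodata-facing and raster-border side once).
#' @param n_cells data cell count in scope.
#' @return scalar >= 1.
#' @examples
#' landscape_shape_index(22038, 321075) # 9.716931
#' @export
landscape_shape_index <- function(total_edge_sides, n_cells) {
  total_edge_sides / min_perimeter_cells(n_cells)
}

#' Shannon diversity index of class proportions
#'
#' `-sum(p_i ln p_i)` in nats over the classes present; 0 for a single
#' class, `ln m` for `m` equally abundant classes.
#'
#' @param p class proportions summing to 1 (zeros allowed and dropped).
#' @return scalar in nats.
#' @export
shannon_diversity_index <- function(p) {
  if (!length(p) || anyNA(p) || any(p < 0)) {
    stop_validation("`p` must be nonnegative proportions")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop_validation("class proportions must sum to 1")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Contagion of a landscape mosaic
#'
#' Aggregation measure built from class proportions and cell-side
#' adjacency frequencies: `[1 + sum_{g,k} P_gk ln P_gk / (2 ln m)] * 100`
#' with `P_gk = p_g * e_gk / sum_k e_gk`, where `e_gk` are shared-side
#' counts between classes `g` and `k` (zero terms contribute zero).
#' Approaches 100 as one class dominates in large aggregates; 0 when every
#' pairing of equally abundant classes is equally frequent. Undefined
#' (NaN) for a single class.
#'
#' @param e symmetric matrix of shared-side counts between the data
#'   classes (nodata excluded), as in [adjacency_counts()].
#' @param p class proportions in the matching order.
#' @param percent report a percentage (default) or a fraction.
#' @return scalar contagion.
#' @export
contagion <- function(e, p, percent = TRUE) {
  m <- length(p)
  if (!is.matrix(e) || nrow(e) != m || ncol(e) != m) {
    stop_validation("`e` must be an m x m adjacency count matrix matching `p`")
  }
  if (m < 2) return(NaN)
  rs <- rowSums(e)
  P <- p * (e / ifelse(rs > 0, rs, 1))
  terms <- ifelse(P > 0, P * log(P), 0)
  out <- 1 + sum(terms) / (2 * log(m))
  if (percent) out <- out * 100
  out
}

#' Distribution statistic of per-patch metric values
#'
#' Aggregates patch-level values over a class or the whole landscape.
#' Undefined values (NaN, e.g. nearest-neighbour distances of single-patch
#' classes) are excluded, never zero-filled.
#'
#' @param values per-patch metric values.
#' @param weights per-patch areas (used by the area-weighted mean).
#' @param stat one of `"mn"` (mean), `"am"` (area-weighted mean), `"md"`
#'   (median), `"ra"` (range), `"sd"` (population standard deviation),
#'   `"cv"` (coefficient of variation, percent).
#' @return scalar; NaN when no value is defined.
#' @export
distribution_statistic <- function(values, weights = NULL, stat) {
  if (!stat %in% stat_suffixes) {
    stop_validation("`stat` must be one of ", paste(stat_suffixes, collapse = ", "))
  }
  keep <- !is.na(values)
  v <- values[keep]
  if (!length(v)) return(NaN)
  if (stat == "am") {
    if (is.null(weights)) stop_validation("`weights` required for stat 'am'")
    w <- weights[keep]
    return(sum(v * w) / sum(w))
  }
  switch(stat,
    mn = mean(v),
    md = median(v),
    ra = max(v) - min(v),
    sd = sqrt(mean((v - mean(v))^2)),
    cv = {
      s <- sqrt(mean((v - mean(v))^2))
      100 * s / mean(v)
    }
  )
}

## ---- request validation --------------------------------------------------

resolve_kwargs <- function(label, metrics_kws) {
  schema <- metric_kwargs_schema(label)
  user <- metrics_kws[[label]]
  if (is.null(user)) return(schema)
  bad <- setdiff(names(user), names(schema))
  if (length(bad)) {
    stop_validation(sprintf("metric '%s' does not accept keyword(s): %s",
                            label, paste(bad, collapse = ", ")))
  }
  modifyList(schema, user)
}

check_metrics_kws <- function(metrics_kws) {
  if (!is.list(metrics_kws)) {
    stop_validation("`metrics_kws` must be a named list of keyword lists")
  }
  all_labels <- unique(list_metrics()$metric)
  bad <- setdiff(names(metrics_kws), all_labels)
  if (length(bad)) {
    stop_validation("`metrics_kws` names unknown metric(s): ",
                    paste(bad, collapse = ", "))
  }
  for (label in names(metrics_kws)) resolve_kwargs(label, metrics_kws)
  invisible(metrics_kws)
}

needs_enn <- function(metrics) {
  any(startsWith(metrics, "euclidean_nearest_neighbor"))
}

warn_rectangular <- function(label) {
  warn_landmosaic(
    sprintf(paste0("'%s' is defined in cell-side counts and requires square",
                   " cells; returning NaN for rectangular cells"), label),
    "landmosaic_rectangular_cells")
}

warn_enn_undefined <- function() {
  warn_landmosaic(
    paste0("nearest-neighbour distance is undefined for single-patch classes;",
           " those patches are excluded from the distribution statistic"),
    "landmosaic_enn_undefined")
}

## ---- per-patch metric values ---------------------------------------------

patch_metric_values <- function(grid, label, kws, connectivity) {
  geom <- cached_geometry(grid, connectivity)
  switch(label,
    area = if (isTRUE(kws$hectares)) geom$area_ha else geom$area_m2,
    perimeter = geom$perimeter,
    perimeter_area_ratio =
      geom$perimeter / (if (isTRUE(kws$hectares)) geom$area_ha else geom$area_m2),
    shape_index = {
      if (!square_cells(grid)) {
        warn_rectangular("shape_index")
        rep(NaN, nrow(geom))
      } else if (nrow(geom) == 0L) {
        numeric(0)
      } else {
        shape_index(geom$n_cells, geom$n_sides)
      }
    },
    fractal_dimension = fractal_dimension(geom$perimeter, geom$area_m2),
    euclidean_nearest_neighbor = cached_enn(grid, connectivity),
    stop_validation("'", label, "' is not a patch-level metric")
  )
}

## ---- class / landscape metric engine -------------------------------------

# Everything the aggregate formulas need for one grid, computed lazily.
grid_summaries <- function(grid, connectivity, need_enn, need_adj) {
  geom <- cached_geometry(grid, connectivity)
  s <- list(
    geom = geom,
    A_m2 = sum(geom$area_m2),
    A_ha = sum(geom$area_ha),
    n_cells = sum(geom$n_cells),
    classes = landscape_classes(grid),
    square = square_cells(grid)
  )
  s$adj <- if (need_adj) cached_adjacency(grid) else NULL
  s$enn <- if (need_enn) cached_enn(grid, connectivity) else NULL
  s
}

aggregate_needs_adjacency <- function(metrics) {
  any(metrics %in% c("total_edge", "edge_density", "landscape_shape_index",
                     "contagion"))
}

# One class-level metric value; class_val assumed present unless the row is
# an absent-class placeholder handled by the caller.
class_metric_value <- function(grid, s, label, class_val, kws, connectivity) {
  sel <- s$geom$class_val == class_val
  g <- s$geom[sel, ]
  if (label %in% class_aggregates) {
    switch(label,
      total_area = if (isTRUE(kws$hectares)) sum(g$area_ha) else sum(g$area_m2),
      proportion_of_landscape =
        proportion_of_landscape(sum(g$area_m2), s$A_m2, percent = kws$percent),
      number_of_patches = nrow(g),
      patch_density = patch_density(
        nrow(g), if (isTRUE(kws$hectares)) s$A_ha else s$A_m2,
        percent = kws$percent),
      largest_patch_index =
        largest_patch_index(g$area_m2, s$A_m2, percent = kws$percent),
      total_edge = total_edge_m(s$adj, class_val,
                                count_boundary = kws$count_boundary),
      edge_density = edge_density(
        total_edge_m(s$adj, class_val, count_boundary = kws$count_boundary),
        if (isTRUE(kws$hectares)) s$A_ha else s$A_m2),
      landscape_shape_index = {
        if (!s$square) {
          warn_rectangular("landscape_shape_index")
          NaN
        } else {
          landscape_shape_index(total_edge_sides(s$adj, class_val),
                                sum(g$n_cells))
        }
      }
    )
  } else {
    base <- sub("_(mn|am|md|ra|sd|cv)$", "", label)
    stat <- sub(".*_", "", label)
    vals <- patch_metric_values(grid, base, kws, connectivity)[sel]
    if (base == "euclidean_nearest_neighbor" && any(is.na(vals)) &&
        !all(is.na(vals))) {
      warn_enn_undefined()
    }
    distribution_statistic(vals, weights = g$area_m2, stat = stat)
  }
}

landscape_metric_value <- function(grid, s, label, kws, connectivity) {
  if (label %in% landscape_aggregates) {
    switch(label,
      total_area = if (isTRUE(kws$hectares)) s$A_ha else s$A_m2,
      number_of_patches = nrow(s$geom),
      patch_density = {
        if (s$n_cells == 0) NaN else patch_density(
          nrow(s$geom), if (isTRUE(kws$hectares)) s$A_ha else s$A_m2,
          percent = kws$percent)
      },
      largest_patch_index = {
        if (nrow(s$geom) == 0L) NaN else
          largest_patch_index(s$geom$area_m2, s$A_m2, percent = kws$percent)
      },
      total_edge = total_edge_m(s$adj, count_boundary = kws$count_boundary),
      edge_density = {
        if (s$n_cells == 0) NaN else edge_density(
          total_edge_m(s$adj, count_boundary = kws$count_boundary),
          if (isTRUE(kws$hectares)) s$A_ha else s$A_m2)
      },
      landscape_shape_index = {
        if (!s$square) {
          warn_rectangular("landscape_shape_index")
          NaN
        } else if (s$n_cells == 0) {
          NaN
        } else {
          landscape_shape_index(total_edge_sides(s$adj), s$n_cells)
        }
      },
      shannon_diversity_index = {
        if (s$n_cells == 0) return(NaN)
        p <- vapply(s$classes, function(cv) {
          sum(s$geom$area_m2[s$geom$class_val == cv])
        }, numeric(1)) / s$A_m2
        shannon_diversity_index(p)
      },
      contagion = {
        if (s$n_cells == 0) return(NaN)
        p <- vapply(s$classes, function(cv) {
          sum(s$geom$area_m2[s$geom$class_val == cv])
        }, numeric(1)) / s$A_m2
        contagion(adjacency_counts(s$adj, include_nodata = FALSE), p,
                  percent = kws$percent)
      }
    )
  } else {
    base <- sub("_(mn|am|md|ra|sd|cv)$", "", label)
    stat <- sub(".*_", "", label)
    vals <- patch_metric_values(grid, base, kws, connectivity)
    if (base == "euclidean_nearest_neighbor" && any(is.na(vals)) &&
        !all(is.na(vals))) {
      warn_enn_undefined()
    }
    distribution_statistic(vals, weights = s$geom$area_m2, stat = stat)
  }
}

## ---- data-frame builders -------------------------------------------------

#' Patch-level metrics table
#'
#' One row per patch, with its class code and the requested patch metrics.
#' The default metric set is `area`, `perimeter`, `perimeter_area_ratio`,
#' `shape_index`, `fractal_dimension`, `euclidean_nearest_neighbor`;
#' nearest-neighbour distances are only computed when requested.
#'
#' @param x a [landscape].
#' @param metrics optional character vector of patch-level metric labels.
#' @param metrics_kws named list mapping metric labels to keyword lists,
#'   e.g. `list(area = list(hectares = FALSE))`.
#' @param connectivity patch neighbourhood rule, 8 (default) or 4.
#' @param ... passed between methods.
#' @return tibble with columns `patch_id`, `class_val`, then one column
#'   per metric.
#' @export
compute_patch_metrics_df <- function(x, ...) {
  UseMethod("compute_patch_metrics_df")
}

#' @rdname compute_patch_metrics_df
#' @export
compute_patch_metrics_df.landscape <- function(x, metrics = NULL,
                                               metrics_kws = list(),
                                               connectivity = 8, ...) {
  connectivity <- check_connectivity(connectivity)
  check_metrics_kws(metrics_kws)
  metrics <- metrics %||% metric_bases
  bad <- setdiff(metrics, metric_bases)
  if (length(bad)) {
    stop_validation("not (a) patch-level metric(s): ", paste(bad, collapse = ", "))
  }
  geom <- cached_geometry(x, connectivity)
  out <- tibble::tibble(patch_id = geom$patch_id, class_val = geom$class_val)
  for (label in metrics) {
    kws <- resolve_kwargs(label, metrics_kws)
    out[[label]] <- patch_metric_values(x, label, kws, connectivity)
  }
  out
}

#' Class-level metrics table
#'
#' One row per class with the requested class-level metrics: the 8 class
#' aggregates and the 36 distribution statistics of the patch metrics.
#' Labels only defined at the landscape level (Shannon diversity,
#' contagion) are silently dropped from requests, mirroring the behaviour
#' of the landscape builder with class-only labels.
#'
#' @inheritParams compute_patch_metrics_df
#' @param classes optional subset of class codes to report.
#' @return tibble with index column `class_val`, then one column per
#'   metric.
#' @export
compute_class_metrics_df <- function(x, ...) {
  UseMethod("compute_class_metrics_df")
}

#' @rdname compute_class_metrics_df
#' @export
compute_class_metrics_df.landscape <- function(x, metrics = NULL,
                                               classes = NULL,
                                               metrics_kws = list(),
                                               connectivity = 8, ...) {
  connectivity <- check_connectivity(connectivity)
  present <- landscape_classes(x)
  if (!is.null(classes)) {
    bad <- setdiff(classes, present)
    if (length(bad)) {
      stop_validation("class(es) not present in the landscape: ",
                      paste(bad, collapse = ", "))
    }
  }
  class_metrics_table(x, metrics, classes %||% present, metrics_kws,
                      connectivity)
}

# Shared with the multi-landscape drivers, which may legitimately ask for
# classes absent from an individual zone or snapshot.
class_metrics_table <- function(grid, metrics, classes, metrics_kws,
                                connectivity) {
  check_metrics_kws(metrics_kws)
  if (is.null(metrics)) {
    metrics <- class_metric_labels()
  } else {
    bad <- setdiff(metrics, unique(list_metrics()$metric))
    if (length(bad)) {
      stop_validation("unknown metric(s): ", paste(bad, collapse = ", "))
    }
    metrics <- intersect(metrics, class_metric_labels())
  }
  present <- landscape_classes(grid)
  s <- grid_summaries(grid, connectivity,
                      need_enn = needs_enn(metrics),
                      need_adj = aggregate_needs_adjacency(metrics))
  out <- tibble::tibble(class_val = as.integer(classes))
  for (label in metrics) {
    kws <- resolve_kwargs(label, metrics_kws)
    out[[label]] <- vapply(classes, function(cv) {
      if (cv %in% present) {
        as.numeric(class_metric_value(grid, s, label, cv, kws, connectivity))
      } else if (label %in% c("total_area", "number_of_patches",
                              "proportion_of_landscape")) {
        0
      } else {
        NaN
      }
    }, numeric(1))
  }
  out
}

#' Landscape-level metrics table
#'
#' A single row with the requested landscape-level metrics: the 9
#' landscape aggregates (including Shannon diversity and contagion) and
#' the 36 distribution statistics pooled over all patches regardless of
#' class. Class-only labels (`proportion_of_landscape`) are silently
#' dropped from requests.
#'
#' @inheritParams compute_patch_metrics_df
#' @return single-row tibble, one column per metric.
#' @export
compute_landscape_metrics_df <- function(x, ...) {
  UseMethod("compute_landscape_metrics_df")
}

#' @rdname compute_landscape_metrics_df
#' @export
compute_landscape_metrics_df.landscape <- function(x, metrics = NULL,
                                                   metrics_kws = list(),
                                                   connectivity = 8, ...) {
  connectivity <- check_connectivity(connectivity)
  landscape_metrics_row(x, metrics, metrics_kws, connectivity)
}

landscape_metrics_row <- function(grid, metrics, metrics_kws, connectivity) {
  check_metrics_kws(metrics_kws)
  if (is.null(metrics)) {
    metrics <- landscape_metric_labels()
  } else {
    bad <- setdiff(metrics, unique(list_metrics()$metric))
    if (length(bad)) {
      stop_validation("unknown metric(s): ", paste(bad, collapse = ", "))
    }
    metrics <- intersect(metrics, landscape_metric_labels())
  }
  s <- grid_summaries(grid, connectivity,
                      need_enn = needs_enn(metrics),
                      need_adj = aggregate_needs_adjacency(metrics))
  out <- tibble::tibble(.rows = 1L)
  for (label in metrics) {
    kws <- resolve_kwargs(label, metrics_kws)
    out[[label]] <- as.numeric(
      landscape_metric_value(grid, s, label, kws, connectivity))
  }
  out
}
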