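test_that("registry holds 95 label/level entries with valid structure", {
  reg <- list_metrics()
  expect_equal(nrow(reg), 95L)
  expect_equal(nrow(list_metrics("patch")), 6L)
  expect_equal(nrow(list_metrics("class")), 44L)
  expect_equal(nrow(list_metrics("landscape")), 45L)
  expect_false(any(duplicated(reg)))
  expect_true(all(grepl("^[a-z0-9_]+$", reg$metric)))
})

test_that("patch-level formulas reproduce the worked values", {
  expect_equal(shape_index(115, 106), 2.409091, tolerance = 5e-7)
  expect_equal(shape_index(13, 26), 1.625)
  expect_equal(shape_index(2, 6), 1)
  expect_equal(fractal_dimension(10600, 1150000), 1.129654, tolerance = 5e-7)
  expect_equal(fractal_dimension(600, 20000), 1.011893, tolerance = 5e-7)
  expect_equal(fractal_dimension(2600, 130000), 1.100096, tolerance = 5e-7)
  expect_equal(perimeter_area_ratio(10600, 115), 92.173913, tolerance = 5e-7)
  expect_equal(perimeter_area_ratio(2600, 13), 200)
  expect_equal(perimeter_area_ratio(400, 1), 400)
  # the 1-square-meter degenerate point of the fractal formula
  expect_true(is.nan(fractal_dimension(4, 1)))
})

test_that("aggregate formulas reproduce the worked values", {
  expect_equal(proportion_of_landscape(24729, 321075), 7.701939,
               tolerance = 5e-7)
  expect_equal(proportion_of_landscape(24729, 321075, percent = FALSE),
               0.077019, tolerance = 1e-5)
  expect_equal(proportion_of_landscape(5, 5), 100)
  expect_equal(patch_density(193, 321075), 0.060111, tolerance = 1e-5)
  expect_equal(patch_density(206, 321075), 0.064159, tolerance = 1e-5)
  expect_equal(patch_density(0, 10), 0)
  expect_equal(edge_density(1431600, 321075), 4.458771, tolerance = 5e-7)
  expect_equal(edge_density(0, 10), 0)
  expect_equal(landscape_shape_index(22038, 321075), 9.716931,
               tolerance = 5e-7)
  expect_equal(largest_patch_index(c(1, 3), 4), 75)
  expect_equal(largest_patch_index(10, 10), 100)
})

test_that("shannon diversity: zero, published proportions, maximum", {
  expect_equal(shannon_diversity_index(1), 0)
  p <- c(0.07701939, 0.92298061)
  expect_equal(shannon_diversity_index(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon_diversity_index(p), 0.271429, tolerance = 5e-6)
  expect_equal(shannon_diversity_index(rep(1 / 5, 5)), log(5))
  expect_error(shannon_diversity_index(c(0.5, 0.2)),
               class = "landmosaic_validation_error")
})

test_that("contagion matches direct formula evaluation and its limits", {
  # dominance in large aggregates -> high contagion
  g <- blocks_landscape(c(40, 40), list(
    list(class_val = 1, row0 = 1, col0 = 1, height = 40, width = 39),
    list(class_val = 2, row0 = 1, col0 = 40, height = 40, width = 1)))
  v <- compute_landscape_metrics_df(g, metrics = "contagion")$contagion
  expect_gt(v, 75)
  # equally-likely class pairings -> near zero
  r <- random_mosaic(c(60, 60), c(0.5, 0.5), seed = 5)
  v0 <- compute_landscape_metrics_df(r, metrics = "contagion")$contagion
  expect_lt(v0, 10)
  # single class -> undefined
  one <- landscape(matrix(1L, 4, 4), res = 100)
  expect_true(is.nan(
    compute_landscape_metrics_df(one, metrics = "contagion")$contagion))

  # re-evaluation oracle from the exhaustive adjacency enumeration
  g3 <- random_fixture(17, side = 30)
  e <- oracle_adjacency(g3)
  e <- e[-nrow(e), -ncol(e)]
  areas <- table(factor(g3$cells[g3$cells != 0],
                        levels = landscape_classes(g3)))
  p <- as.numeric(areas) / sum(areas)
  P <- p * (e / rowSums(e))
  expected <- (1 + sum(ifelse(P > 0, P * log(P), 0)) /
                 (2 * log(length(p)))) * 100
  got <- compute_landscape_metrics_df(g3, metrics = "contagion")$contagion
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("distribution statistics: means, weights, spread, degenerate", {
  expect_equal(distribution_statistic(c(1, 3), c(1, 1), "am"), 2)
  expect_equal(distribution_statistic(c(1, 3), c(1, 1), "mn"), 2)
  expect_equal(distribution_statistic(c(1, 3), c(0.1, 0.9), "am"), 2.8)
  expect_equal(distribution_statistic(rep(4, 3), stat = "sd"), 0)
  expect_equal(distribution_statistic(rep(4, 3), stat = "cv"), 0)
  expect_equal(distribution_statistic(rep(4, 3), stat = "ra"), 0)
  # population (not sample) standard deviation
  expect_equal(distribution_statistic(c(1, 3), stat = "sd"), 1)
  expect_equal(distribution_statistic(c(1, 2, 10), stat = "md"), 2)
  # NaNs are excluded, never zero-filled; all-NaN -> NaN
  expect_equal(distribution_statistic(c(NaN, 2, 4), stat = "mn"), 3)
  expect_true(is.nan(distribution_statistic(c(NaN, NaN), stat = "mn")))
})

test_that("patch table has the canonical header and honors subsetting", {
  g <- reference_patches_landscape()
  df <- compute_patch_metrics_df(g)
  expect_identical(names(df),
                   c("patch_id", "class_val", "area", "perimeter",
                     "perimeter_area_ratio", "shape_index",
                     "fractal_dimension", "euclidean_nearest_neighbor"))
  expect_equal(nrow(df), 3L)
  sub <- compute_patch_metrics_df(g, metrics = "area")
  expect_identical(names(sub), c("patch_id", "class_val", "area"))
  expect_identical(sub$area, df$area)
  expect_error(compute_patch_metrics_df(g, metrics = "total_area"),
               class = "landmosaic_validation_error")
})

test_that("class table: level dropping, class subsetting, kwargs", {
  g <- random_fixture(19, side = 25)
  df <- compute_class_metrics_df(g)
  expect_identical(names(df)[1], "class_val")
  expect_equal(nrow(df), 3L)
  expect_false("shannon_diversity_index" %in% names(df))
  expect_equal(ncol(df), 1 + 44)

  # landscape-only labels silently dropped from requests
  df2 <- compute_class_metrics_df(
    g, metrics = c("total_area", "shannon_diversity_index"))
  expect_identical(names(df2), c("class_val", "total_area"))

  # class subsetting keeps values identical
  df3 <- compute_class_metrics_df(g, classes = 2)
  expect_equal(nrow(df3), 1L)
  expect_equal(df3$total_area, df$total_area[df$class_val == 2])
  expect_error(compute_class_metrics_df(g, classes = 99),
               class = "landmosaic_validation_error")

  # fractional proportion via metrics_kws
  frac <- compute_class_metrics_df(
    g, metrics = "proportion_of_landscape",
    metrics_kws = list(proportion_of_landscape = list(percent = FALSE)))
  expect_equal(frac$proportion_of_landscape * 100,
               df$proportion_of_landscape, tolerance = 1e-12)

  expect_error(
    compute_class_metrics_df(g, metrics_kws = list(not_a_metric = list())),
    class = "landmosaic_validation_error")
  expect_error(
    compute_class_metrics_df(
      g, metrics_kws = list(total_edge = list(percent = TRUE))),
    class = "landmosaic_validation_error")
})

test_that("edge metrics: boundary handling and unit conversions", {
  g <- random_fixture(23, side = 30)
  led <- compute_landscape_metrics_df(g, metrics = "edge_density")
  led_b <- compute_landscape_metrics_df(
    g, metrics = "edge_density",
    metrics_kws = list(edge_density = list(count_boundary = TRUE)))
  led_bm <- compute_landscape_metrics_df(
    g, metrics = "edge_density",
    metrics_kws = list(edge_density = list(count_boundary = TRUE,
                                           hectares = FALSE)))
  expect_gt(led_b$edge_density, led$edge_density)
  # hectares/m2 forms differ by exactly 1e4
  expect_equal(led_b$edge_density / led_bm$edge_density, 1e4,
               tolerance = 1e-12)

  # class total edges sum to twice the landscape total without boundary
  cte <- compute_class_metrics_df(g, metrics = "total_edge")$total_edge
  lte <- compute_landscape_metrics_df(g, metrics = "total_edge")$total_edge
  expect_equal(sum(cte), 2 * lte)

  # 1x2 toy landscape: interior edge 100 m, boundary adds 600 m
  toy <- landscape(matrix(c(1, 2), 1), res = 100)
  expect_equal(
    compute_landscape_metrics_df(toy, metrics = "total_edge")$total_edge, 100)
  expect_equal(
    compute_landscape_metrics_df(
      toy, metrics = "total_edge",
      metrics_kws = list(total_edge = list(count_boundary = TRUE)))$total_edge,
    700)
})

test_that("landscape table aggregates are consistent with class tables", {
  g <- random_fixture(29, side = 25)
  cls <- compute_class_metrics_df(g)
  lnd <- compute_landscape_metrics_df(g)
  expect_equal(nrow(lnd), 1L)
  expect_true(all(c("total_area", "number_of_patches",
                    "shannon_diversity_index", "contagion") %in% names(lnd)))
  expect_false("proportion_of_landscape" %in% names(lnd))
  expect_equal(lnd$number_of_patches, sum(cls$number_of_patches))
  expect_equal(lnd$largest_patch_index, max(cls$largest_patch_index))
  expect_equal(sum(cls$proportion_of_landscape), 100, tolerance = 1e-9)

  one <- landscape(matrix(1L, 4, 4), res = 100)
  expect_equal(compute_landscape_metrics_df(
    one, metrics = "shannon_diversity_index")$shannon_diversity_index, 0)

  # landscape shape index of a full square raster is exactly 1
  expect_equal(compute_landscape_metrics_df(
    one, metrics = "landscape_shape_index")$landscape_shape_index, 1)
})

test_that("area-weighted statistics pool patches by area", {
  g <- reference_patches_landscape()
  geo <- patch_geometry(g)
  fd <- fractal_dimension(geo$perimeter, geo$area_m2)
  expected_am <- sum(fd * geo$area_m2) / sum(geo$area_m2)
  got <- compute_landscape_metrics_df(
    g, metrics = "fractal_dimension_am")$fractal_dimension_am
  expect_equal(got, expected_am, tolerance = 1e-12)

  cls <- compute_class_metrics_df(g, metrics = c("area_mn", "area_am",
                                                 "area_sd", "area_cv"))
  expect_equal(cls$area_mn, mean(geo$area_ha))
  expect_equal(cls$area_am, sum(geo$area_ha * geo$area_m2) / sum(geo$area_m2))
})

test_that("side-count metrics are undefined for rectangular cells", {
  g <- blocks_landscape(c(4, 4), list(
    list(class_val = 1, row0 = 1, col0 = 1, height = 2, width = 2)),
    res = c(50, 100))
  expect_warning(
    df <- compute_patch_metrics_df(g, metrics = "shape_index"),
    class = "landmosaic_rectangular_cells")
  expect_true(is.nan(df$shape_index))
  expect_warning(
    lsi <- compute_landscape_metrics_df(g, metrics = "landscape_shape_index"),
    class = "landmosaic_rectangular_cells")
  expect_true(is.nan(lsi$landscape_shape_index))
})

test_that("single-patch classes are excluded from ENN statistics with a warning", {
  g <- blocks_landscape(c(9, 9), list(
    list(class_val = 1, row0 = 1, col0 = 1, height = 1, width = 1),
    list(class_val = 1, row0 = 1, col0 = 5, height = 1, width = 1),
    list(class_val = 2, row0 = 5, col0 = 5, height = 2, width = 2)))
  expect_warning(
    df <- compute_landscape_metrics_df(
      g, metrics = "euclidean_nearest_neighbor_mn"),
    class = "landmosaic_enn_undefined")
  expect_equal(df$euclidean_nearest_neighbor_mn, 400)
  cls <- suppressWarnings(compute_class_metrics_df(
    g, metrics = "euclidean_nearest_neighbor_mn"))
  expect_true(is.nan(cls$euclidean_nearest_neighbor_mn[cls$class_val == 2]))
})

test_that("every registry label computes on a random mosaic and subsets match", {
  g <- random_mosaic(c(50, 50), c(0.4, 0.35, 0.25), seed = 41)
  cls <- compute_class_metrics_df(g)
  lnd <- compute_landscape_metrics_df(g)
  expect_equal(ncol(cls) - 1L, 44L)
  expect_equal(ncol(lnd), 45L)
  expect_true(all(vapply(cls[-1], is.numeric, logical(1))))

  # metric subsetting never changes values
  some <- c("edge_density", "patch_density", "area_am")
  sub <- compute_class_metrics_df(g, metrics = some)
  expect_identical(sub[some], cls[some])

  # an all-nodata landscape yields empty/NaN tables, not errors
  empty <- landscape(matrix(0L, 5, 5), res = 100)
  expect_equal(nrow(compute_class_metrics_df(empty)), 0L)
  lnd0 <- compute_landscape_metrics_df(empty)
  expect_equal(lnd0$number_of_patches, 0)
  expect_true(is.nan(lnd0$shannon_diversity_index))
})
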