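#' Construct a landscape from an integer class-code matrix
#'
#' A landscape is an immutable categorical raster: a 2-D lattice of integer
#' class codes together with the cell size in meters and the code that marks
#' cells with no data. All metrics in the package are computed from this
#' object. Treat it as read-only after construction: derived patch,
#' adjacency and nearest-neighbour results are cached inside it.
#'
#' @param cells integer matrix of class codes (row 1 is the top of the map).
#' @param res numeric of length 1 or 2: cell size in meters, `(x, y)` when
#'   two values are given. Rectangular (non-square) cells are supported;
#'   side-count based metrics (shape index families) are then undefined.
#' @param nodata integer code marking cells with no data. Defaults to 0.
#' @param xmin,ymin coordinates of the lower-left raster corner. Supplying
#'   both georeferences the grid (required for buffer analysis).
#' @param crs optional coordinate reference system identifier (EPSG code or
#'   PROJ/WKT string), kept as an opaque label.
#' @return an object of class `landscape`.
#' @examples
#' ls <- landscape(matrix(c(1, 1, 2, 2), 2), res = 100)
#' @export
landscape <- function(cells, res = c(1, 1), nodata = 0L,
                      xmin = NULL, ymin = NULL, crs = NULL) {
  if (!is.matrix(cells)) {
    stop_validation("`cells` must be a 2-D matrix of integer class codes")
  }
  if (!is.numeric(cells)) {
    stop_validation("`cells` must be numeric (integer class codes)")
  }
  if (anyNA(cells) || !all(is_whole(cells))) {
    stop_validation("class codes must be finite integers; use the nodata code, ",
                    "not NA or fractional values, for absent data")
  }
  res <- as.numeric(res)
  if (!length(res) %in% c(1L, 2L) || anyNA(res) || any(res <= 0)) {
    stop_validation("`res` must be one or two positive cell sizes in meters")
  }
  if (length(res) == 1L) res <- c(res, res)
  if (length(nodata) != 1L || !is_whole(as.numeric(nodata))) {
    stop_validation("`nodata` must be a single integer code")
  }
  georeferenced <- !is.null(xmin) && !is.null(ymin)
  storage.mode(cells) <- "integer"
  obj <- list(
    cells = cells,
    nodata = as.integer(nodata),
    cell_width = res[1],
    cell_height = res[2],
    xmin = if (georeferenced) as.numeric(xmin) else 0,
    ymin = if (georeferenced) as.numeric(ymin) else 0,
    georeferenced = georeferenced,
    crs = if (is.null(crs)) NULL else as.character(crs),
    cache = new.env(parent = emptyenv())
  )
  obj$cache$counters <- list(segmentations = 0L, adjacency_builds = 0L,
                             enn_builds = 0L)
  class(obj) <- "landscape"
  obj
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells at %g x %g m, nodata = %d\n",
              nrow(x$cells), ncol(x$cells), x$cell_width, x$cell_height,
              x$nodata))
  cls <- landscape_classes(x)
  cat(sprintf("  classes present: %s; data cells: %d\n",
              if (length(cls)) paste(cls, collapse = ", ") else "(none)",
              sum(x$cells != x$nodata)))
  if (x$georeferenced) {
    cat(sprintf("  origin (%g, %g)%s\n", x$xmin, x$ymin,
                if (is.null(x$crs)) "" else paste0(", crs: ", x$crs)))
  }
  invisible(x)
}

#' @export
dim.landscape <- function(x) dim(x$cells)

#' Class codes present in a landscape
#'
#' @param grid a [landscape].
#' @return sorted integer vector of data class codes (nodata excluded).
#' @export
landscape_classes <- function(grid) {
  check_landscape(grid)
  v <- unique(as.vector(grid$cells))
  sort(v[v != grid$nodata])
}

check_landscape <- function(grid) {
  if (!inherits(grid, "landscape")) {
    stop_validation("expected a `landscape` object")
  }
  invisible(grid)
}

square_cells <- function(grid) {
  isTRUE(all.equal(grid$cell_width, grid$cell_height))
}

cell_area_m2 <- function(grid) grid$cell_width * grid$cell_height

n_data_cells <- function(grid) sum(grid$cells != grid$nodata)

# Cell-center coordinates (row 1 = top row of the map).
cell_centers <- function(grid) {
  nr <- nrow(grid$cells)
  nc <- ncol(grid$cells)
  list(
    x = grid$xmin + (seq_len(nc) - 0.5) * grid$cell_width,
    y = grid$ymin + (nr - seq_len(nr) + 0.5) * grid$cell_height
  )
}

#' Read a landscape from an Esri ASCII grid file
#'
#' Reads a single-band integer raster in Esri ASCII Grid format (the
#' plain-text GDAL `AAIGrid` dialect: `ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize` (or `dx`+`dy`) header followed by row-major cell
#' values). Cell size, georeferencing and the nodata code are taken from
#' the header; when the file declares no `NODATA_value` and no override is
#' given, zero-valued cells are treated as no data. A sidecar `.prj` file,
#' when present, is read as the CRS label.
#'
#' @param path path to the raster file.
#' @param nodata optional integer overriding the file's nodata code.
#' @return a [landscape].
#' @export
read_landscape <- function(path, nodata = NULL) {
  if (length(path) != 1L || !is.character(path)) {
    stop_io("`path` must be a single file path")
  }
  if (!file.exists(path)) stop_io("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 0L
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s+(-?[0-9.eE+-]+)\\s*$", ln))[[1]]
    if (length(m) == 3 && tolower(m[2]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "dx", "dy", "nodata_value")) {
      header[[tolower(m[2])]] <- as.numeric(m[3])
      i <- i + 1L
    } else {
      break
    }
  }
  if (is.null(header$ncols) || is.null(header$nrows)) {
    stop_io("not an Esri ASCII grid (missing ncols/nrows header): ", path)
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  if (!is.null(header$cellsize)) {
    res <- c(header$cellsize, header$cellsize)
  } else if (!is.null(header$dx) && !is.null(header$dy)) {
    res <- c(header$dx, header$dy)
  } else {
    stop_io("raster header carries neither cellsize nor dx/dy: ", path)
  }
  vals <- suppressWarnings(
    as.numeric(scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
                    what = character(), quiet = TRUE))
  )
  if (anyNA(vals)) stop_io("raster body contains non-numeric tokens: ", path)
  if (length(vals) != nr * nc) {
    stop_io(sprintf("raster body has %d values, expected %d (%d x %d): %s",
                    length(vals), nr * nc, nr, nc, path))
  }
  if (!all(is_whole(vals))) {
    stop_validation("raster band is not integer-valued; class codes are ",
                    "categories and float rasters are rejected: ", path)
  }
  cells <- matrix(as.integer(round(vals)), nrow = nr, ncol = nc, byrow = TRUE)
  nodata_code <- if (!is.null(nodata)) {
    nodata
  } else if (!is.null(header$nodata_value)) {
    header$nodata_value
  } else {
    0L
  }
  prj <- sub("\\.[^.]*$", ".prj", path)
  crs <- if (file.exists(prj) && prj != path) {
    paste(readLines(prj, warn = FALSE), collapse = " ")
  } else {
    NULL
  }
  landscape(cells, res = res, nodata = nodata_code,
            xmin = header$xllcorner %||% 0, ymin = header$yllcorner %||% 0,
            crs = crs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a landscape to an Esri ASCII grid file
#'
#' Inverse of [read_landscape()]; round-trips cells, cell sizes, origin and
#' nodata code bit-exactly. A `.prj` sidecar is written when the landscape
#' carries a CRS label.
#'
#' @param grid a [landscape].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(grid, path) {
  check_landscape(grid)
  hdr <- c(
    sprintf("ncols %d", ncol(grid$cells)),
    sprintf("nrows %d", nrow(grid$cells)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    if (square_cells(grid)) {
      sprintf("cellsize %.10g", grid$cell_width)
    } else {
      c(sprintf("dx %.10g", grid$cell_width),
        sprintf("dy %.10g", grid$cell_height))
    },
    sprintf("NODATA_value %d", grid$nodata)
  )
  rows <- apply(grid$cells, 1, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write raster file: ", path)
  if (!is.null(grid$crs)) {
    writeLines(grid$crs, sub("\\.[^.]*$", ".prj", path))
  }
  invisible(path)
}

#' Write a metrics table to CSV
#'
#' Writes a tidy metrics table with its index columns first and metric
#' columns after, a header row, `.` as decimal separator and undefined
#' values (NaN/NA) as empty fields.
#'
#' @param table a data frame as returned by the `compute_*_metrics_df`
#'   functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table)) stop_validation("`table` must be a data frame")
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]][is.nan(out[[j]])] <- NA
  }
  ok <- tryCatch({
    suppressWarnings(
      write.table(out, file = path, sep = ",", na = "", row.names = FALSE,
                  col.names = TRUE, quote = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write table to: ", path)
  invisible(path)
}
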