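#' Gridded raster values with georeferencing
#'
#' A minimal single-layer raster: a numeric matrix of cell values plus the
#' geotransform needed to map between map coordinates and cells. Row 1 of the
#' matrix is the top (northernmost) row; `NA` marks nodata (e.g. ocean) cells.
#' Cells are square with side `cell_size` in map units; `xll`/`yll` give the
#' lower-left corner of the grid.
#'
#' Point-in-cell assignment uses half-open intervals `[edge, edge + cell_size)`
#' in both axes, so a point lying exactly on a shared edge belongs to exactly
#' one cell (the one to its east / south), and points on the extreme top or
#' right edge of the grid fall outside it.
#'
#' @param values numeric matrix (rows = height, cols = width); `NA` = nodata.
#' @param xll,yll map coordinates of the lower-left grid corner.
#' @param cell_size cell side length in map units (> 0).
#' @param crs_id opaque coordinate-system identifier string.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cell_size = 1,
                        crs_id = "local") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  if (any(is.nan(values))) {
    stop("raster values must not be NaN; use NA for nodata", call. = FALSE)
  }
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cell_size = as.numeric(cell_size), crs_id = as.character(crs_id)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xll, x$yll))
  cat(sprintf("  land cells: %d / %d; value range [%g, %g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

grid_width <- function(grid) ncol(grid$values)
grid_height <- function(grid) nrow(grid$values)
n_cells <- function(grid) length(grid$values)

#' Land (non-nodata) cell indices of a grid
#'
#' Cell indices are 1-based and scan row-major from the top-left cell:
#' `index = (row - 1) * width + col`.
#'
#' @param grid a `raster_grid`.
#' @return integer vector of cell indices.
#' @export
land_cells <- function(grid) {
  v <- t(grid$values)               # row-major order
  which(!is.na(as.vector(v)))
}

cell_to_rowcol <- function(grid, cells) {
  w <- grid_width(grid)
  row <- (cells - 1L) %/% w + 1L
  col <- (cells - 1L) %% w + 1L
  cbind(row = row, col = col)
}

rowcol_to_cell <- function(grid, row, col) {
  (row - 1L) * grid_width(grid) + col
}

#' Map coordinates of cell centers
#' @param grid a `raster_grid`.
#' @param cells integer cell indices (row-major from top-left).
#' @return two-column matrix of x, y center coordinates.
#' @export
cell_centers <- function(grid, cells) {
  rc <- cell_to_rowcol(grid, cells)
  cs <- grid$cell_size
  h <- grid_height(grid)
  x <- grid$xll + (rc[, "col"] - 0.5) * cs
  y <- grid$yll + (h - rc[, "row"] + 0.5) * cs
  cbind(x = x, y = y)
}

#' Locate points in grid cells (half-open cell intervals)
#' @param grid a `raster_grid`.
#' @param x,y point coordinates in map units.
#' @return integer cell indices; `NA` for points outside the grid extent.
#' @export
point_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$xll) / cs) + 1
  row <- grid_height(grid) - floor((y - grid$yll) / cs)
  inside <- !is.na(x) & !is.na(y) &
    col >= 1 & col <= grid_width(grid) &
    row >= 1 & row <= grid_height(grid)
  out <- rep(NA_integer_, length(x))
  out[inside] <- rowcol_to_cell(grid, as.integer(row[inside]),
                                as.integer(col[inside]))
  out
}

#' Extract cell values by cell index
#' @param grid a `raster_grid`.
#' @param cells integer cell indices.
#' @return numeric vector of values (`NA` at nodata cells).
#' @export
cell_values <- function(grid, cells) {
  rc <- cell_to_rowcol(grid, cells)
  grid$values[cbind(rc[, "row"], rc[, "col"])]
}

#' Build a grid from per-cell values
#'
#' Inverse of [cell_values()]: places `values` at `cells` and `NA` elsewhere,
#' inheriting geometry from `template`.
#' @param template a `raster_grid` providing geometry.
#' @param cells integer cell indices.
#' @param values numeric values, one per cell index.
#' @return a `raster_grid`.
#' @export
grid_from_cells <- function(template, cells, values) {
  stopifnot(length(cells) == length(values))
  m <- matrix(NA_real_, grid_height(template), grid_width(template))
  rc <- cell_to_rowcol(template, cells)
  m[cbind(rc[, "row"], rc[, "col"])] <- values
  raster_grid(m, template$xll, template$yll, template$cell_size,
              template$crs_id)
}

same_geometry <- function(a, b, tol = 1e-9) {
  grid_width(a) == grid_width(b) && grid_height(a) == grid_height(b) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cell_size - b$cell_size) < tol && a$crs_id == b$crs_id
}

#' A named, co-registered set of climate layers
#'
#' All layers must share width, height, origin, cell size, CRS and nodata
#' mask; this is enforced at construction.
#'
#' @param layers named list of `raster_grid` objects (bioclim-like variables).
#' @param scenario_label,period_label free-text labels (e.g. a climate-model
#'   name and a time-period tag).
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(layers, scenario_label = "baseline",
                          period_label = "baseline") {
  if (length(layers) < 1L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop("`layers` must be a non-empty named list", call. = FALSE)
  }
  ref <- layers[[1L]]
  for (nm in names(layers)) {
    g <- layers[[nm]]
    if (!inherits(g, "raster_grid")) {
      stop(sprintf("layer '%s' is not a raster_grid", nm), call. = FALSE)
    }
    if (!same_geometry(ref, g)) {
      stop(sprintf("layer '%s' is not co-registered with layer '%s'",
                   nm, names(layers)[1L]), call. = FALSE)
    }
    if (!identical(is.na(ref$values), is.na(g$values))) {
      stop(sprintf("layer '%s' has a different nodata mask than layer '%s'",
                   nm, names(layers)[1L]), call. = FALSE)
    }
  }
  structure(
    list(layers = layers, scenario_label = as.character(scenario_label),
         period_label = as.character(period_label)),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  ref <- x$layers[[1L]]
  cat(sprintf("<climate_stack> '%s' / '%s': %d layers (%s), %d x %d cells\n",
              x$scenario_label, x$period_label, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              grid_height(ref), grid_width(ref)))
  invisible(x)
}

#' Reference grid of a stack (its first layer)
#' @param stack a `climate_stack`.
#' @return a `raster_grid` sharing the stack's geometry and land mask.
#' @export
stack_ref_grid <- function(stack) stack$layers[[1L]]

#' Per-cell variable values of a stack
#' @param stack a `climate_stack`.
#' @param cells integer cell indices.
#' @param variables layer names to extract (default all).
#' @return numeric matrix, cells x variables.
#' @export
stack_values <- function(stack, cells, variables = names(stack$layers)) {
  variables <- as.vector(variables)   # drop stray attributes
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) {
    stop(sprintf("stack is missing variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- vapply(variables, function(v) cell_values(stack$layers[[v]], cells),
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, variables))
  out
}
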