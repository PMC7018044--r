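#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by row-major values,
#' first row = northernmost. Cells equal to the nodata sentinel become `NA`.
#' Only square cells are supported; a `dx`/`dy` style header is refused.
#'
#' @param path path to an `.asc` file.
#' @param crs_id CRS identifier to attach (ASCII grids carry none).
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path, crs_id = "local") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      if (length(parts) != 2L) {
        stop(sprintf("malformed header line in %s: '%s'", path, lines[i]),
             call. = FALSE)
      }
      hdr[[key]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else if (key %in% c("dx", "dy")) {
      stop("grids with distinct x/y cell sizes are not supported",
           call. = FALSE)
    } else {
      break
    }
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]]) || is.na(hdr[[k]])) {
      stop(sprintf("missing or invalid '%s' header in %s", k, path),
           call. = FALSE)
    }
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  # llcenter variants reference the center of the lower-left cell
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- hdr$nodata_value %||% -9999
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1L]]))
  if (length(vals) != nc * nr) {
    stop(sprintf("expected %d values in %s, found %d", nc * nr, path,
                 length(vals)), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop(sprintf("non-numeric cell value in %s", path), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, xll = xll, yll = yll, cell_size = cs, crs_id = crs_id)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 6 significant digits (human-diffable fixtures);
#' `NA` cells are written as the nodata sentinel.
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @param nodata numeric nodata sentinel to write for `NA` cells.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 6) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  if (any(is.infinite(m))) {
    stop("cannot write infinite cell values to an ASCII grid", call. = FALSE)
  }
  if (any(!is.na(m) & m == nodata)) {
    stop("a data cell equals the nodata sentinel; choose another sentinel",
         call. = FALSE)
  }
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  fmt <- function(v) {
    v[is.na(v)] <- nodata
    formatC(v, digits = digits, format = "g")
  }
  rows <- apply(m, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a set of co-registered ASCII grids as a climate stack
#'
#' @param paths named character vector: layer name -> file path.
#' @param scenario_label,period_label labels for the stack.
#' @param crs_id CRS identifier shared by all layers.
#' @return a [climate_stack()]; co-registration (including identical nodata
#'   masks) is enforced and misaligned layers raise an error.
#' @export
read_stack <- function(paths, scenario_label = "baseline",
                       period_label = "baseline", crs_id = "local") {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("`paths` must be a named vector (layer name -> path)", call. = FALSE)
  }
  layers <- lapply(paths, read_ascii_grid, crs_id = crs_id)
  climate_stack(layers, scenario_label, period_label)
}

#' Write every layer of a stack as ASCII grids
#' @param stack a [climate_stack()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are `<prefix><layer>.asc`.
#' @inheritParams write_ascii_grid
#' @return named vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "", nodata = -9999, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], p, nodata = nodata, digits = digits)
    p
  }, character(1L))
  invisible(paths)
}
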