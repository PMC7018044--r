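#' Filter occurrence records for modelling
#'
#' Applies the record-quality filters used for presence-background SDMs:
#' species identity resolved to the target species, collection date no
#' earlier than `min_date`, finite coordinates, and location on a land
#' (non-nodata) cell of the modelling grid. Each rejected record is
#' attributed to exactly one filter — the first failing filter in the fixed
#' order `identity`, `date`, `coords`, `land` — so rejection counts always
#' sum to `n_raw - n_retained`.
#'
#' @param records occurrence data.frame as from [read_occurrences()].
#' @param species target species name.
#' @param grid `raster_grid` providing the land mask.
#' @param min_date earliest admissible date (`Date` or `YYYY-MM-DD` string).
#' @param keep_undated keep records with missing dates instead of rejecting
#'   them (default `FALSE`: a missing date cannot demonstrate the record is
#'   recent enough).
#' @return list with `records` (retained rows), `rejections` (data.frame
#'   `row`, `filter`) and `counts` (named rejection counts per filter).
#' @export
filter_records <- function(records, species, grid,
                           min_date = as.Date("1950-01-01"),
                           keep_undated = FALSE) {
  min_date <- as.Date(min_date)
  n <- nrow(records)
  fail <- character(n)

  ok_identity <- records$species == species
  fail[!ok_identity] <- "identity"

  date_ok <- if (keep_undated) {
    is.na(records$date) | records$date >= min_date
  } else {
    !is.na(records$date) & records$date >= min_date
  }
  fail[ok_identity & !date_ok] <- "date"

  coord_ok <- is.finite(records$x) & is.finite(records$y)
  fail[ok_identity & date_ok & !coord_ok] <- "coords"

  cells <- rep(NA_integer_, n)
  idx <- ok_identity & date_ok & coord_ok
  cells[idx] <- point_to_cell(grid, records$x[idx], records$y[idx])
  land_ok <- !is.na(cells) & !is.na(cell_values(grid, pmax(cells, 1L)))
  fail[idx & !land_ok] <- "land"

  keep <- !nzchar(fail)
  counts <- table(factor(fail[!keep],
                         levels = c("identity", "date", "coords", "land")))
  if (!any(keep)) {
    dominant <- names(counts)[which.max(counts)]
    stop(sprintf(
      "no records survive filtering (dominant rejection cause: %s, %d of %d)",
      dominant, max(counts), n), call. = FALSE)
  }
  ret <- records[keep, , drop = FALSE]
  ret$cell <- cells[keep]
  rownames(ret) <- NULL
  list(
    records = ret,
    rejections = data.frame(row = which(!keep), filter = fail[!keep],
                            stringsAsFactors = FALSE),
    counts = as.integer(counts) |> stats::setNames(names(counts))
  )
}

#' Collapse filtered records to one presence per grid cell
#'
#' Duplicate records within a cell would silently reweight the presence
#' likelihood, so presences are thinned to the set of unique occupied cells.
#' Idempotent.
#'
#' @param filtered result of [filter_records()], or a data.frame of retained
#'   records carrying a `cell` column.
#' @param grid the modelling `raster_grid` (used when records lack a
#'   precomputed `cell` column).
#' @param species species name to record (defaults to the records' species).
#' @return an object of class `presence_data`: `species`, sorted integer
#'   `presence_cells`, `m` (cell count), `n_raw_records`, `filter_counts`.
#' @export
thin_to_cells <- function(filtered, grid = NULL, species = NULL) {
  if (is.data.frame(filtered)) {
    records <- filtered
    rejections <- data.frame(row = integer(), filter = character())
    counts <- c(identity = 0L, date = 0L, coords = 0L, land = 0L)
  } else {
    records <- filtered$records
    rejections <- filtered$rejections
    counts <- filtered$counts
  }
  if (is.null(records$cell)) {
    if (is.null(grid)) stop("`grid` is required when records carry no cell",
                            call. = FALSE)
    records$cell <- point_to_cell(grid, records$x, records$y)
  }
  if (anyNA(records$cell)) {
    stop("records contain points outside the grid; run filter_records first",
         call. = FALSE)
  }
  structure(
    list(
      species = species %||% records$species[1L],
      presence_cells = sort(unique(as.integer(records$cell))),
      m = length(unique(records$cell)),
      n_raw_records = nrow(records) + nrow(rejections),
      filter_counts = counts
    ),
    class = "presence_data"
  )
}

#' @export
print.presence_data <- function(x, ...) {
  cat(sprintf("<presence_data> %s: %d presence cells (from %d records)\n",
              x$species, x$m, x$n_raw_records))
  invisible(x)
}

#' Sample background cells within a buffer of the presences
#'
#' The eligible set is every land cell whose center lies within `buffer_km`
#' (map units; the grid is assumed to be an equal-area projection scaled in
#' km) of the center of any presence cell. A uniform random subset of
#' `min(max_n, n_eligible)` cells is drawn without replacement — "up to"
#' `max_n`: when fewer cells are eligible, all of them are returned.
#' Presence cells are part of the eligible set, so the fitted model's
#' normalizer covers the sampled landscape.
#'
#' @param presence a `presence_data`.
#' @param grid the modelling `raster_grid`.
#' @param buffer_km buffer radius in map units (default 200).
#' @param max_n maximum number of background cells (default 100000).
#' @param seed integer seed for the random subset.
#' @param include_presence keep presence cells in the eligible set
#'   (default `TRUE`).
#' @return an object of class `background_data`: sorted
#'   `background_cells`, `buffer_km`, `requested_n`, `achieved_n`, `seed`.
#' @export
sample_background <- function(presence, grid, buffer_km = 200,
                              max_n = 100000, seed = 1,
                              include_presence = TRUE) {
  stopifnot(inherits(presence, "presence_data"))
  if (length(presence$presence_cells) == 0L) {
    stop("presence set is empty", call. = FALSE)
  }
  land <- land_cells(grid)
  pc <- cell_centers(grid, presence$presence_cells)
  lc <- cell_centers(grid, land)
  # min squared distance of each land cell to any presence cell
  d2min <- rep(Inf, length(land))
  for (i in seq_len(nrow(pc))) {
    d2 <- (lc[, "x"] - pc[i, "x"])^2 + (lc[, "y"] - pc[i, "y"])^2
    d2min <- pmin(d2min, d2)
  }
  eligible <- land[d2min <= buffer_km^2]
  if (setequal(eligible, presence$presence_cells)) {
    warning("buffer admits no cells beyond the presence cells themselves",
            call. = FALSE)
  }
  n_take <- min(max_n, length(eligible))
  chosen <- with_seed(seed, {
    if (n_take == length(eligible)) eligible
    else sample(eligible, n_take, replace = FALSE)
  })
  structure(
    list(background_cells = sort(as.integer(chosen)),
         buffer_km = buffer_km, requested_n = max_n,
         achieved_n = n_take, seed = seed,
         include_presence = include_presence),
    class = "background_data"
  )
}

#' @export
print.background_data <- function(x, ...) {
  cat(sprintf(
    "<background_data> %d cells (requested %d) within %g map units\n",
    x$achieved_n, x$requested_n, x$buffer_km))
  invisible(x)
}

#' Greedy collinearity screening of candidate predictors
#'
#' Walks the candidates in the given order and keeps a variable iff its
#' absolute Pearson correlation with every already-kept variable, computed
#' over `sample_cells`, stays below `r_max`. Zero-variance candidates are
#' excluded with a warning. The full correlation matrix over the candidates
#' is attached for reporting.
#'
#' @param stack a `climate_stack`.
#' @param candidates candidate layer names, in priority order.
#' @param sample_cells cell indices over which correlations are computed.
#' @param r_max absolute-correlation retention threshold (default 0.8).
#' @return character vector of retained variable names, with attribute
#'   `correlations` (the candidate correlation matrix).
#' @export
screen_collinearity <- function(stack, candidates = names(stack$layers),
                                sample_cells, r_max = 0.8) {
  if (length(candidates) < 2L) stop("need at least 2 candidates",
                                    call. = FALSE)
  if (length(sample_cells) == 0L) stop("`sample_cells` is empty",
                                       call. = FALSE)
  V <- stack_values(stack, sample_cells, candidates)
  sds <- apply(V, 2L, stats::sd)
  usable <- sds > 0
  if (any(!usable)) {
    warning(sprintf("zero-variance variable(s) excluded: %s",
                    paste(candidates[!usable], collapse = ", ")),
            call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(V))
  kept <- character(0)
  for (v in candidates[usable]) {
    if (all(abs(cm[v, kept]) < r_max)) kept <- c(kept, v)
  }
  attr(kept, "correlations") <- cm
  kept
}
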