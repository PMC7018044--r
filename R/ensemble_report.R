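#' Majority consensus across scenario projections
#'
#' A cell is consensus-suitable iff it is suitable in at least `min_agree`
#' of the scenario binary maps — with a 6-scenario ensemble and the default
#' majority rule, suitable in fewer than 4 scenarios maps to 0 and in 4 or
#' more to 1. All maps must share species and period.
#'
#' @param binaries list of [project_binary()] results, one per scenario.
#' @param min_agree agreement count needed (default `floor(n/2) + 1`, the
#'   majority).
#' @return an object of class `consensus_map`: a 0/1 `raster_grid` plus
#'   `species`, `period_label`, `n_scenarios`, `min_agree`.
#' @export
consensus <- function(binaries, min_agree = floor(length(binaries) / 2) + 1) {
  stopifnot(length(binaries) >= 1L)
  ref <- binaries[[1L]]
  for (b in binaries) {
    stopifnot(inherits(b, "binary_map"))
    if (!same_geometry(ref$grid, b$grid)) {
      stop("scenario maps are not co-registered", call. = FALSE)
    }
    if (b$species != ref$species || b$period_label != ref$period_label) {
      stop("consensus refused: maps mix species or periods", call. = FALSE)
    }
  }
  land <- land_cells(ref$grid)
  total <- Reduce(`+`, lapply(binaries, function(b) {
    cell_values(b$grid, land)
  }))
  structure(
    list(grid = grid_from_cells(ref$grid, land,
                                as.numeric(total >= min_agree)),
         species = ref$species, period_label = ref$period_label,
         n_scenarios = length(binaries), min_agree = min_agree),
    class = "consensus_map"
  )
}

#' Treat a single binary map as a 1-scenario consensus
#'
#' Used for the baseline period, which has one climate stack and therefore
#' no ensemble to agree over.
#' @param binary a [project_binary()] result.
#' @return a `consensus_map` with `n_scenarios = 1`, `min_agree = 1`.
#' @export
as_consensus <- function(binary) {
  stopifnot(inherits(binary, "binary_map"))
  structure(
    list(grid = binary$grid, species = binary$species,
         period_label = binary$period_label, n_scenarios = 1L,
         min_agree = 1L),
    class = "consensus_map"
  )
}

#' @export
print.consensus_map <- function(x, ...) {
  land <- land_cells(x$grid)
  cat(sprintf(
    "<consensus_map> %s / %s (%d of %d scenarios): %.1f%% of land suitable\n",
    x$species, x$period_label, x$min_agree, x$n_scenarios,
    100 * mean(cell_values(x$grid, land))))
  invisible(x)
}

#' Stack per-species consensus maps into a species-count hotspot map
#'
#' The per-cell integer count of species whose consensus map marks the cell
#' suitable — hotspots are cells suitable for multiple pest species.
#'
#' @param consensus_maps list of [consensus()] results, one per species,
#'   co-registered and sharing a period.
#' @return an object of class `hotspot_map`: integer-count `raster_grid`,
#'   `period_label`, `species` (vector).
#' @export
stack_species <- function(consensus_maps) {
  stopifnot(length(consensus_maps) >= 1L)
  ref <- consensus_maps[[1L]]
  for (cm in consensus_maps) {
    stopifnot(inherits(cm, "consensus_map"))
    if (!same_geometry(ref$grid, cm$grid)) {
      stop("consensus maps are not co-registered", call. = FALSE)
    }
    if (cm$period_label != ref$period_label) {
      stop("hotspot stack refused: maps mix periods", call. = FALSE)
    }
  }
  land <- land_cells(ref$grid)
  total <- Reduce(`+`, lapply(consensus_maps, function(cm) {
    cell_values(cm$grid, land)
  }))
  structure(
    list(grid = grid_from_cells(ref$grid, land, total),
         period_label = ref$period_label,
         species = vapply(consensus_maps, `[[`, character(1L), "species")),
    class = "hotspot_map"
  )
}

#' @export
print.hotspot_map <- function(x, ...) {
  land <- land_cells(x$grid)
  v <- cell_values(x$grid, land)
  cat(sprintf("<hotspot_map> %s: %d species, counts 0..%d over %d cells\n",
              x$period_label, length(x$species), max(v), length(land)))
  invisible(x)
}

#' Land-area accounting by species count
#'
#' For each species-count class `0..S`, the percentage of land cells in the
#' class, side by side for the unmasked and novelty-masked hotspot maps.
#' Percentages per variant always sum to 100 because masking reassigns
#' cells to class 0 instead of dropping them from the denominator.
#'
#' @param hotspot_unmasked,hotspot_masked [stack_species()] results built
#'   from unmasked and novelty-masked consensus maps.
#' @param land_mask `raster_grid` supplying the land denominator (default:
#'   the unmasked hotspot grid itself).
#' @return an object of class `area_summary`: data.frame (`count`,
#'   `pct_unmasked`, `pct_masked`, `cells_unmasked`, `cells_masked`) with
#'   attribute `land_cells` (denominator).
#' @export
area_summary <- function(hotspot_unmasked, hotspot_masked,
                         land_mask = hotspot_unmasked$grid) {
  stopifnot(inherits(hotspot_unmasked, "hotspot_map"),
            inherits(hotspot_masked, "hotspot_map"))
  if (!same_geometry(hotspot_unmasked$grid, hotspot_masked$grid)) {
    stop("hotspot maps are not co-registered", call. = FALSE)
  }
  land <- land_cells(land_mask)
  if (length(land) == 0L) stop("land mask has no land cells", call. = FALSE)
  s_max <- length(hotspot_unmasked$species)
  classes <- 0:s_max
  tally <- function(hs) {
    v <- cell_values(hs$grid, land)
    as.integer(table(factor(v, levels = classes)))
  }
  cu <- tally(hotspot_unmasked)
  cm <- tally(hotspot_masked)
  out <- data.frame(
    count = classes,
    pct_unmasked = 100 * cu / length(land),
    pct_masked = 100 * cm / length(land),
    cells_unmasked = cu,
    cells_masked = cm
  )
  structure(out, land_cells = length(land),
            period_label = hotspot_unmasked$period_label,
            class = c("area_summary", "data.frame"))
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("Area by species count, %% of %d land cells (%s):\n",
              attr(x, "land_cells"), attr(x, "period_label")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %2d  %5.1f%% (%.1f%%)\n", x$count[i],
                x$pct_unmasked[i], x$pct_masked[i]))
  }
  cat("  (bracketed values: novel environments excluded)\n")
  invisible(x)
}

#' Write an area summary as a report-style CSV
#'
#' Percentages are rounded to 1 decimal place with the masked variant in
#' brackets (report precision); the full-precision columns are retained in
#' the same file for machine use.
#' @param summary an [area_summary()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_summary <- function(summary, path) {
  out <- data.frame(
    count = summary$count,
    suitable_area = sprintf("%.1f%% (%.1f%%)", summary$pct_unmasked,
                            summary$pct_masked),
    pct_unmasked = summary$pct_unmasked,
    pct_masked = summary$pct_masked,
    cells_unmasked = summary$cells_unmasked,
    cells_masked = summary$cells_masked
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify cell-wise range change between two consensus maps
#'
#' Per-cell comparison of a baseline and a future consensus map:
#' stable-suitable (1 to 1), stable-unsuitable (0 to 0), gain (0 to 1),
#' loss (1 to 0), reported as counts and percentages of land.
#'
#' @param baseline,future co-registered [consensus()] results for the same
#'   species.
#' @return data.frame (`class`, `cells`, `pct`), class `range_change`.
#' @export
range_change <- function(baseline, future) {
  stopifnot(inherits(baseline, "consensus_map"),
            inherits(future, "consensus_map"))
  if (!same_geometry(baseline$grid, future$grid)) {
    stop("maps are not co-registered", call. = FALSE)
  }
  land <- land_cells(baseline$grid)
  b <- cell_values(baseline$grid, land)
  f <- cell_values(future$grid, land)
  cls <- c("stable_unsuitable", "gain", "loss", "stable_suitable")
  counts <- c(sum(b == 0 & f == 0), sum(b == 0 & f == 1),
              sum(b == 1 & f == 0), sum(b == 1 & f == 1))
  structure(
    data.frame(class = cls, cells = counts,
               pct = 100 * counts / length(land)),
    class = c("range_change", "data.frame")
  )
}
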