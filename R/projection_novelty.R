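#' Project a fitted model onto a stack as a binary suitability map
#'
#' A land cell is suitable (1) iff its predicted score on the threshold's
#' scale is `>=` the threshold; otherwise unsuitable (0). Because the three
#' output scales are strictly increasing transforms of one another, the
#' resulting map depends only on cell ranking — but the threshold and the
#' prediction must still be on the same scale, and a mismatch is refused.
#'
#' @param model a `maxent_model`.
#' @param stack target [climate_stack()].
#' @param threshold a [threshold_p10()] result.
#' @param scale output scale to predict on; must equal `threshold$scale`.
#' @return an object of class `binary_map`: a 0/1 `raster_grid` plus
#'   `species`, `scenario_label`, `period_label` and the threshold used.
#' @export
project_binary <- function(model, stack, threshold,
                           scale = threshold$scale) {
  stopifnot(inherits(threshold, "threshold_result"))
  if (scale != threshold$scale) {
    stop(sprintf(
      "threshold was computed on the '%s' scale but projection is '%s'",
      threshold$scale, scale), call. = FALSE)
  }
  pred <- predict(model, stack, scale = scale)
  land <- land_cells(pred)
  vals <- as.numeric(cell_values(pred, land) >= threshold$threshold)
  structure(
    list(grid = grid_from_cells(pred, land, vals),
         species = model$species %||% "species",
         scenario_label = stack$scenario_label,
         period_label = stack$period_label,
         threshold = threshold),
    class = "binary_map"
  )
}

#' @export
print.binary_map <- function(x, ...) {
  land <- land_cells(x$grid)
  cat(sprintf(
    "<binary_map> %s / %s / %s: %d of %d land cells suitable (%.1f%%)\n",
    x$species, x$scenario_label, x$period_label,
    sum(cell_values(x$grid, land)), length(land),
    100 * mean(cell_values(x$grid, land))))
  invisible(x)
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For each cell and variable with projected value `p`, let `fr` be 100
#' times the fraction of reference values strictly less than `p` (ties at
#' `p` count to neither side). The per-variable similarity is
#' * `(p - min_ref) / (max_ref - min_ref) * 100` if `fr = 0`;
#' * `2 * fr` if `0 < fr <= 50`;
#' * `2 * (100 - fr)` if `50 < fr < 100`;
#' * `(max_ref - p) / (max_ref - min_ref) * 100` if `fr = 100`;
#'
#' and the cell's similarity `S` is the minimum over variables. Negative
#' `S` flags environmentally novel (extrapolated) cells. A zero-range
#' reference variable gets similarity 0 where `p` equals the constant and
#' `-Inf` elsewhere, with a warning.
#'
#' @param reference matrix of reference-cell variable values (cells x
#'   variables, named columns) — conventionally the model's training
#'   environment (presence plus background cells); needs >= 2 rows.
#' @param stack target [climate_stack()].
#' @param variables variable names (default: reference columns).
#' @return an object of class `mess_map`: `similarity` (`raster_grid` of
#'   `S`), `per_variable` (list of per-variable similarity grids) and the
#'   per-variable reference summary.
#' @export
mess <- function(reference, stack, variables = colnames(reference)) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 2L) stop("need at least 2 reference cells",
                                 call. = FALSE)
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) {
    stop(sprintf("stack is missing variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  land <- land_cells(stack_ref_grid(stack))
  P <- stack_values(stack, land, variables)
  per_var <- vector("list", length(variables))
  names(per_var) <- variables
  S <- rep(Inf, length(land))
  for (v in variables) {
    ref <- sort(reference[, v])
    rmin <- ref[1L]; rmax <- ref[length(ref)]
    p <- P[, v]
    if (rmax == rmin) {
      warning(sprintf(
        "reference range of '%s' is zero; similarity is 0 at the constant",
        v), call. = FALSE)
      sim <- ifelse(p == rmin, 0, -Inf)
    } else {
      fr <- 100 * findInterval(p, ref, left.open = TRUE) / length(ref)
      sim <- ifelse(fr == 0, (p - rmin) / (rmax - rmin) * 100,
             ifelse(fr <= 50, 2 * fr,
             ifelse(fr < 100, 2 * (100 - fr),
                    (rmax - p) / (rmax - rmin) * 100)))
    }
    per_var[[v]] <- grid_from_cells(stack_ref_grid(stack), land, sim)
    S <- pmin(S, sim)
  }
  structure(
    list(similarity = grid_from_cells(stack_ref_grid(stack), land, S),
         per_variable = per_var,
         reference_summary = data.frame(
           variable = variables,
           min_ref = apply(reference[, variables, drop = FALSE], 2L, min),
           max_ref = apply(reference[, variables, drop = FALSE], 2L, max),
           n_ref = nrow(reference))),
    class = "mess_map"
  )
}

#' @export
print.mess_map <- function(x, ...) {
  land <- land_cells(x$similarity)
  s <- cell_values(x$similarity, land)
  cat(sprintf(
    "<mess_map> %d land cells, %.1f%% novel (S < 0), S range [%.1f, %.1f]\n",
    length(land), 100 * mean(s < 0), min(s), max(s)))
  invisible(x)
}

#' Fraction of land cells flagged as novel by a MESS map
#' @param messmap a [mess()] result.
#' @return fraction in `[0, 1]`.
#' @export
novel_fraction <- function(messmap) {
  s <- cell_values(messmap$similarity, land_cells(messmap$similarity))
  mean(s < 0)
}

#' Mask environmentally novel cells out of a binary map
#'
#' Cells with MESS similarity `< 0` are set to 0 (unsuitable) rather than
#' nodata, so that downstream area percentages keep a fixed land
#' denominator and still sum to 100. Idempotent, and can only shrink the
#' suitable area.
#'
#' @param binary a [project_binary()] result.
#' @param messmap a co-registered [mess()] result.
#' @return a `binary_map` with novel cells zeroed.
#' @export
mask_novel <- function(binary, messmap) {
  stopifnot(inherits(binary, "binary_map"), inherits(messmap, "mess_map"))
  if (!same_geometry(binary$grid, messmap$similarity)) {
    stop("binary map and MESS map are not co-registered", call. = FALSE)
  }
  land <- land_cells(binary$grid)
  b <- cell_values(binary$grid, land)
  s <- cell_values(messmap$similarity, land)
  b[s < 0] <- 0
  out <- binary
  out$grid <- grid_from_cells(binary$grid, land, b)
  out$novelty_masked <- TRUE
  out
}
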