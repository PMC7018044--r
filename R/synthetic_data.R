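#' Generate a spatially autocorrelated synthetic climate stack
#'
#' Each layer is the sum of a large-scale planar gradient (random
#' orientation) and Gaussian white noise smoothed with a Gaussian kernel of
#' standard deviation `smoothness` (in cells) and variance-normalized, then
#' shifted/scaled to a plausible bioclim-like range. A single smooth "land
#' mask" field is thresholded so that approximately `land_fraction` of cells
#' are land; the mask is applied identically to every layer. Deterministic
#' given `seed`.
#'
#' @param width,height grid size in cells (each >= 8).
#' @param n_vars number of climate layers (>= 2).
#' @param smoothness correlation length of the noise component, in cells;
#'   must be < `min(width, height)`.
#' @param seed integer seed.
#' @param land_fraction approximate fraction of cells that are land.
#' @param cell_size cell side in map units (km for the buffer semantics).
#' @param var_names layer names (default `bio1`, `bio2`, ...).
#' @return a [climate_stack()] labelled `baseline`.
#' @export
make_climate <- function(width, height, n_vars = 4, smoothness = 5, seed = 1,
                         land_fraction = 0.9, cell_size = 1,
                         var_names = paste0("bio", seq_len(n_vars))) {
  if (width < 8 || height < 8) stop("width and height must be >= 8",
                                    call. = FALSE)
  if (n_vars < 2) stop("n_vars must be >= 2", call. = FALSE)
  if (smoothness >= min(width, height)) {
    stop("`smoothness` must be smaller than the grid: the field degenerates",
         call. = FALSE)
  }
  stopifnot(length(var_names) == n_vars)
  with_seed(seed, {
    gx <- matrix(rep(seq_len(width), each = height), height, width)
    gy <- matrix(rep(seq_len(height), width), height, width)
    gx <- (gx - mean(gx)) / stats::sd(gx)
    gy <- (gy - mean(gy)) / stats::sd(gy)

    layers <- vector("list", n_vars)
    for (k in seq_len(n_vars)) {
      theta <- stats::runif(1, 0, 2 * pi)
      grad <- cos(theta) * gx + sin(theta) * gy
      noise <- smooth_field(matrix(stats::rnorm(width * height),
                                   height, width), smoothness)
      field <- grad + noise
      # bioclim-flavoured offsets/scales; values themselves are arbitrary
      field <- 15 + 5 * k + 5 * field
      layers[[k]] <- field
    }
    # independent smooth field decides land vs ocean
    mask_field <- smooth_field(matrix(stats::rnorm(width * height),
                                      height, width),
                               max(2, min(width, height) / 4))
    ocean <- mask_field < stats::quantile(mask_field, 1 - land_fraction)
    grids <- lapply(layers, function(m) {
      m[ocean] <- NA_real_
      raster_grid(m, xll = 0, yll = 0, cell_size = cell_size)
    })
    names(grids) <- var_names
    climate_stack(grids, scenario_label = "baseline",
                  period_label = "baseline")
  })
}

# Separable Gaussian smoothing of a matrix, variance-normalized.
smooth_field <- function(z, sigma) {
  if (sigma <= 0) return((z - mean(z)) / stats::sd(z))
  k_row <- gauss_kernel(nrow(z), sigma)
  k_col <- gauss_kernel(ncol(z), sigma)
  s <- k_row %*% z %*% t(k_col)
  (s - mean(s)) / stats::sd(s)
}

gauss_kernel <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
  k <- exp(-d / (2 * sigma^2))
  k / rowSums(k)
}

#' Perturb a baseline stack into a family of climate scenarios
#'
#' Each scenario stack is `baseline + offset + noise_scale * smooth
#' perturbation`, emulating an ensemble of downscaled climate-model
#' projections over one or more future periods. With `novelty_target > 0`
#' the per-variable offsets of every scenario x period stack are scaled (by
#' bisection against a brute-force range check) so that approximately that
#' fraction of land cells falls outside the baseline's per-variable range in
#' at least one variable. With `novelty_target = 0` the raw `shift` is
#' applied, growing linearly across periods (`period_scale`).
#'
#' @param baseline a [climate_stack()].
#' @param n number of scenarios per period (default 6, a typical
#'   climate-model ensemble size).
#' @param shift named per-variable mean offset (recycled; default: half a
#'   standard deviation of each baseline variable).
#' @param noise_scale standard deviation of the smooth perturbation, as a
#'   multiple of each variable's baseline standard deviation.
#' @param novelty_target fraction (in `[0, 1)`) of land cells that should be
#'   environmentally novel relative to the baseline; 0 disables calibration.
#' @param seed integer seed.
#' @param periods period labels (default `"2030"`, `"2050"`, `"2070"`).
#' @param period_scale multiplier on the shift per period when
#'   `novelty_target` is 0; defaults to `1, 2, 3, ...`.
#' @param smoothness correlation length of the perturbation field, in cells.
#' @return an object of class `scenario_family`: `baseline`, `periods`, and
#'   `scenarios` — a list over periods, each a list of `n` stacks.
#' @export
make_scenarios <- function(baseline, n = 6, shift = NULL, noise_scale = 0.25,
                           novelty_target = 0, seed = 1,
                           periods = c("2030", "2050", "2070"),
                           period_scale = seq_along(periods),
                           smoothness = 5) {
  stopifnot(inherits(baseline, "climate_stack"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (novelty_target >= 1 || novelty_target < 0) {
    stop("`novelty_target` must be a fraction in [0, 1)", call. = FALSE)
  }
  vars <- names(baseline$layers)
  ref <- stack_ref_grid(baseline)
  land <- land_cells(ref)
  V <- stack_values(baseline, land, vars)
  sds <- apply(V, 2L, stats::sd)
  rng <- apply(V, 2L, range)
  if (is.null(shift)) shift <- sds / 2
  shift <- rep_len(shift, length(vars))
  names(shift) <- vars

  h <- grid_height(ref); w <- grid_width(ref)
  novel_frac <- function(W) {
    out <- rep(FALSE, nrow(W))
    for (j in seq_along(vars)) {
      out <- out | W[, j] < rng[1L, j] | W[, j] > rng[2L, j]
    }
    mean(out)
  }

  fam <- with_seed(seed, {
    lapply(seq_along(periods), function(pi) {
      lapply(seq_len(n), function(si) {
        pert <- vapply(vars, function(v) {
          as.vector(t(smooth_field(matrix(stats::rnorm(w * h), h, w),
                                   smoothness)))[land]
        }, numeric(length(land)))
        base_off <- matrix(rep(shift, each = length(land)),
                           ncol = length(vars))
        noise <- sweep(pert, 2L, noise_scale * sds, `*`)
        scen_values <- function(s) V + s * base_off + noise
        s_use <- if (novelty_target > 0) {
          calibrate_shift_scale(scen_values, novel_frac, novelty_target)
        } else {
          period_scale[pi]
        }
        W <- scen_values(s_use)
        layers <- lapply(seq_along(vars), function(j) {
          grid_from_cells(ref, land, W[, j])
        })
        names(layers) <- vars
        climate_stack(layers,
                      scenario_label = sprintf("scenario%02d", si),
                      period_label = periods[pi])
      })
    })
  })
  names(fam) <- periods
  structure(
    list(baseline = baseline, scenarios = fam, periods = periods,
         n = n, novelty_target = novelty_target, seed = seed),
    class = "scenario_family"
  )
}

# Bisection on the offset scale so the brute-force novel fraction of the
# perturbed values hits `target`. The fraction is monotone in the scale up
# to the (bounded) effect of the fixed noise term.
calibrate_shift_scale <- function(scen_values, novel_frac, target,
                                  iters = 50) {
  lo <- 0; hi <- 1
  while (novel_frac(scen_values(hi)) < target && hi < 1e3) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (novel_frac(scen_values(mid)) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.scenario_family <- function(x, ...) {
  cat(sprintf(
    "<scenario_family> %d scenarios x %d periods (%s), novelty target %g\n",
    x$n, length(x$periods), paste(x$periods, collapse = ", "),
    x$novelty_target))
  invisible(x)
}

#' Define a virtual species with a known suitability truth
#'
#' True suitability is a logistic (inverse-logit) function of linear and
#' quadratic terms of the stack's variables, standardized over land cells:
#' `plogis(intercept + sum(b_l * z_v) + sum(b_q * z_v^2))`. Because the
#' standardization is affine, the truth lies inside the span of the
#' linear+quadratic feature family that the suitability model fits, so
#' parameter-recovery experiments are well-posed. If coefficients are not
#' supplied they are drawn at random (deterministically from `seed`).
#'
#' @param stack baseline [climate_stack()].
#' @param linear named numeric vector of linear coefficients (on
#'   standardized variables); default random `U(-2, 2)`.
#' @param quadratic named numeric vector of quadratic coefficients; default
#'   random `U(-1.5, 0)` (concave responses, a niche optimum per variable).
#' @param intercept real; default -2, giving a moderately low-prevalence
#'   species. In that regime the inverse-logit truth is close to the
#'   exponential family the suitability model fits, so the truth is
#'   recoverable by construction.
#' @param species species label for sampled occurrences.
#' @param seed integer seed (used only when coefficients are drawn).
#' @return an object of class `virtual_species`: coefficients, the
#'   standardization constants, and `true_suitability` (a `raster_grid` in
#'   `(0, 1)` on land).
#' @export
make_virtual_species <- function(stack, linear = NULL, quadratic = NULL,
                                 intercept = -2,
                                 species = "Virtualis exemplaris",
                                 seed = 1) {
  vars <- names(stack$layers)
  land <- land_cells(stack_ref_grid(stack))
  V <- stack_values(stack, land, vars)
  mu <- colMeans(V)
  sds <- apply(V, 2L, stats::sd)
  if (is.null(linear) || is.null(quadratic)) {
    drawn <- with_seed(seed, list(
      linear = stats::setNames(stats::runif(length(vars), -2, 2), vars),
      quadratic = stats::setNames(stats::runif(length(vars), -1.5, 0), vars)
    ))
    if (is.null(linear)) linear <- drawn$linear
    if (is.null(quadratic)) quadratic <- drawn$quadratic
  }
  linear <- linear[vars]; quadratic <- quadratic[vars]
  stopifnot(!anyNA(linear), !anyNA(quadratic))
  Z <- sweep(sweep(V, 2L, mu), 2L, sds, `/`)
  eta <- intercept + Z %*% linear + (Z^2) %*% quadratic
  suit <- stats::plogis(as.vector(eta))
  structure(
    list(species = species, variables = vars,
         linear = linear, quadratic = quadratic, intercept = intercept,
         center = mu, scale = sds,
         true_suitability = grid_from_cells(stack_ref_grid(stack), land,
                                            suit)),
    class = "virtual_species"
  )
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> %s: logistic truth in L+Q terms of %s\n",
              x$species, paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Evaluate a virtual species' true suitability on another stack
#' @param vs a `virtual_species`.
#' @param stack a co-registered [climate_stack()] carrying the species'
#'   variables.
#' @return a `raster_grid` of true suitability on `stack`'s land cells.
#' @export
true_suitability_on <- function(vs, stack) {
  land <- land_cells(stack_ref_grid(stack))
  V <- stack_values(stack, land, vs$variables)
  Z <- sweep(sweep(V, 2L, vs$center), 2L, vs$scale, `/`)
  eta <- vs$intercept + Z %*% vs$linear + (Z^2) %*% vs$quadratic
  grid_from_cells(stack_ref_grid(stack), land, stats::plogis(as.vector(eta)))
}

#' Sample cell indices proportionally to a per-cell weight grid
#'
#' Multinomial sampling with replacement over land cells, weight-proportional;
#' deterministic given `seed`. Used by [sample_presences()] and directly by
#' simulation experiments that need draws from an arbitrary cell
#' distribution.
#'
#' @param weights a `raster_grid` of nonnegative weights (`NA` = excluded).
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of `n` cell indices (with repeats).
#' @export
sample_cells <- function(weights, n, seed = 1) {
  land <- land_cells(weights)
  w <- cell_values(weights, land)
  if (any(w < 0)) stop("sampling weights must be nonnegative", call. = FALSE)
  if (sum(w) <= 0) stop("all sampling weights are zero: empty support",
                        call. = FALSE)
  with_seed(seed, sample(land, n, replace = TRUE, prob = w))
}

#' Sample occurrence records from a virtual species
#'
#' Cells are drawn with replacement with probability proportional to
#' `true_suitability * bias` (bias defaults to uniform effort), then each
#' draw becomes one record at the drawn cell's center — so multiple records
#' can share a cell, mirroring multi-source occurrence data; downstream
#' thinning collapses them.
#'
#' @param vs a `virtual_species`.
#' @param n number of records (>= 1).
#' @param bias optional co-registered `raster_grid` of nonnegative relative
#'   sampling effort.
#' @param seed integer seed.
#' @param date,source values for the record metadata columns.
#' @return occurrence data.frame (`species`, `x`, `y`, `date`, `source`)
#'   with attribute `cells` (the drawn cell indices).
#' @export
sample_presences <- function(vs, n, bias = NULL, seed = 1,
                             date = as.Date("2005-06-15"),
                             source = "simulated") {
  stopifnot(inherits(vs, "virtual_species"), n >= 1)
  suit <- vs$true_suitability
  if (!is.null(bias)) {
    if (!same_geometry(suit, bias)) {
      stop("`bias` is not co-registered with the species' suitability grid",
           call. = FALSE)
    }
    m <- suit$values * bias$values
    suit <- raster_grid(m, suit$xll, suit$yll, suit$cell_size, suit$crs_id)
  }
  cells <- sample_cells(suit, n, seed)
  xy <- cell_centers(vs$true_suitability, cells)
  out <- data.frame(
    species = vs$species, x = xy[, "x"], y = xy[, "y"],
    date = as.Date(date), source = source, stringsAsFactors = FALSE
  )
  attr(out, "cells") <- cells
  out
}
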