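#' Build the linear/quadratic/product feature specification
#'
#' Raw features are `v` and `v^2` per variable and `v_a * v_b` per unordered
#' pair (first-order interactions). Products are formed on the raw
#' (unscaled) variables; every feature column is then affinely rescaled to
#' `[0, 1]` using its min/max over the background cells. Features constant
#' over the background are dropped with a warning. At projection time,
#' values outside `[0, 1]` are clipped to the boundary when `clamp` is on.
#'
#' @param stack training [climate_stack()].
#' @param variables layer names to use.
#' @param kinds subset of `c("linear", "quadratic", "product")`.
#' @param background_cells cell indices defining the scaling bounds.
#' @param clamp clip projected feature values to the training `[0, 1]` range
#'   (default `TRUE`).
#' @return an object of class `feature_spec`: a feature table (`name`,
#'   `kind`, `var1`, `var2`) plus per-feature raw-scale bounds `fmin`,
#'   `fmax`.
#' @export
build_features <- function(stack, variables = names(stack$layers),
                           kinds = c("linear", "quadratic", "product"),
                           background_cells, clamp = TRUE) {
  kinds <- match.arg(kinds, c("linear", "quadratic", "product"),
                     several.ok = TRUE)
  variables <- as.vector(variables)
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) {
    stop(sprintf("stack is missing variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab <- feature_table(variables, kinds)
  V <- stack_values(stack, background_cells, variables)
  Fraw <- raw_features(tab, V)
  fmin <- apply(Fraw, 2L, min)
  fmax <- apply(Fraw, 2L, max)
  keep <- fmax > fmin
  if (any(!keep)) {
    warning(sprintf("dropping constant feature(s) over background: %s",
                    paste(tab$name[!keep], collapse = ", ")), call. = FALSE)
  }
  structure(
    list(variables = variables, kinds = kinds,
         table = tab[keep, , drop = FALSE],
         fmin = fmin[keep], fmax = fmax[keep], clamp = clamp),
    class = "feature_spec"
  )
}

feature_table <- function(variables, kinds) {
  rows <- list()
  if ("linear" %in% kinds) {
    rows <- c(rows, lapply(variables, function(v) {
      data.frame(name = v, kind = "linear", var1 = v, var2 = NA_character_)
    }))
  }
  if ("quadratic" %in% kinds) {
    rows <- c(rows, lapply(variables, function(v) {
      data.frame(name = paste0(v, "^2"), kind = "quadratic", var1 = v,
                 var2 = NA_character_)
    }))
  }
  if ("product" %in% kinds && length(variables) >= 2L) {
    pairs <- utils::combn(variables, 2L)
    rows <- c(rows, lapply(seq_len(ncol(pairs)), function(k) {
      data.frame(name = paste0(pairs[1L, k], "*", pairs[2L, k]),
                 kind = "product", var1 = pairs[1L, k], var2 = pairs[2L, k])
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cells x features raw (unscaled) feature values from a cells x variables
# value matrix
raw_features <- function(tab, V) {
  out <- matrix(NA_real_, nrow(V), nrow(tab))
  colnames(out) <- tab$name
  for (k in seq_len(nrow(tab))) {
    v1 <- V[, tab$var1[k]]
    out[, k] <- switch(tab$kind[k],
      linear = v1,
      quadratic = v1^2,
      product = v1 * V[, tab$var2[k]]
    )
  }
  out
}

#' Evaluate scaled features at a set of cells
#'
#' @param spec a [build_features()] result.
#' @param stack a [climate_stack()] carrying the spec's variables.
#' @param cells cell indices.
#' @param clamp override the spec's clamp flag.
#' @return numeric matrix, cells x features, scaled to the training
#'   `[0, 1]` bounds (clipped there if clamping).
#' @export
feature_matrix <- function(spec, stack, cells, clamp = spec$clamp) {
  V <- stack_values(stack, cells, spec$variables)
  feature_matrix_values(spec, V, clamp)
}

# same, from a raw cells x variables matrix (used by permutation importance)
feature_matrix_values <- function(spec, V, clamp = spec$clamp) {
  Fraw <- raw_features(spec$table, V)
  X <- sweep(sweep(Fraw, 2L, spec$fmin), 2L, spec$fmax - spec$fmin, `/`)
  if (clamp) X <- pmin(pmax(X, 0), 1)
  X
}
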