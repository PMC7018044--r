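#' Permutation importance of model variables
#'
#' For each variable, its raw values over the presence-plus-background cell
#' set are randomly permuted (every feature involving the variable is
#' recomputed), training AUC is recomputed from the permuted predictions,
#' and the drop from the unpermuted training AUC is averaged over `n_perm`
#' permutations. Drops are floored at 0 and normalized to sum to 100.
#'
#' @param model a `maxent_model`.
#' @param presence a `presence_data`.
#' @param background a `background_data`.
#' @param stack the training [climate_stack()].
#' @param n_perm permutations per variable (default 10).
#' @param seed integer seed.
#' @return named numeric vector of percentages summing to 100, class
#'   `importance_table`.
#' @export
permutation_importance <- function(model, presence, background, stack,
                                   n_perm = 10, seed = 1) {
  spec <- model$spec
  vars <- spec$variables
  cells <- sort(unique(c(presence$presence_cells,
                         background$background_cells)))
  is_pres <- cells %in% presence$presence_cells
  V <- stack_values(stack, cells, vars)
  eta0 <- as.vector(feature_matrix_values(spec, V) %*% model$lambda)
  auc0 <- auc(eta0[is_pres], eta0[!is_pres])
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      mean(vapply(seq_len(n_perm), function(i) {
        Vp <- V
        Vp[, v] <- sample(Vp[, v])
        eta <- as.vector(feature_matrix_values(spec, Vp) %*% model$lambda)
        auc0 - auc(eta[is_pres], eta[!is_pres])
      }, numeric(1L)))
    }, numeric(1L))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    # no variable moves the AUC (e.g. null model): report uniform shares
    pct <- rep(100 / length(vars), length(vars))
  } else {
    pct <- 100 * drops / sum(drops)
  }
  structure(stats::setNames(pct, vars), class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  ord <- order(unclass(x), decreasing = TRUE)
  cat("Permutation importance (%):\n")
  for (i in ord) cat(sprintf("  %-12s %6.1f\n", names(x)[i], x[[i]]))
  invisible(x)
}
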