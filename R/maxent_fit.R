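#' Fit a presence-background maximum-entropy model
#'
#' Maximizes the L1-penalized presence-background log-likelihood
#' \deqn{L(\lambda) = \frac{1}{m}\sum_{i \in \mathrm{pres}} \lambda^\top
#'   f(x_i) - \log \sum_{x \in \mathrm{landscape}} e^{\lambda^\top f(x)}
#'   - \sum_j \beta_j |\lambda_j|}
#' where the landscape is the union of background and presence cells, and
#' the per-feature penalty is \eqn{\beta_j = \mathrm{reg\_multiplier} \cdot
#' c \cdot s_j / \sqrt{m}} with \eqn{s_j} the population standard deviation
#' of scaled feature `j` over the presence cells. The base constant `c0`
#' defaults to 0.05, the magnitude of the tuned per-class penalty standard
#' Maxent releases apply to linear/quadratic/product features at moderate
#' sample sizes — so `reg_multiplier = 1` means "the default amount of
#' smoothing". The fit uses proximal-Newton ascent with exact soft-threshold
#' handling of the L1 term, weights initialized at 0 (the null model) and an
#' objective-change stopping rule. At the optimum, the KKT conditions bound
#' each feature's presence mean within \eqn{\beta_j} of its model
#' expectation.
#'
#' @param presence a `presence_data` (needs `m >= 5` presence cells).
#' @param background a `background_data`.
#' @param spec a [build_features()] result.
#' @param stack the training [climate_stack()].
#' @param reg_multiplier global multiplier on the L1 penalties (default 1).
#' @param c0 base constant of the regularization schedule (default 0.05).
#' @param tol convergence tolerance on the objective change per iteration.
#' @param max_iter maximum proximal-Newton iterations.
#' @return an object of class `maxent_model` carrying the feature spec,
#'   weights, penalties, `logZ` (training-landscape normalizer), entropy `H`
#'   of the fitted cell distribution, the sorted landscape raw-output
#'   distribution (for the cumulative scale), training presence raw scores,
#'   and the landscape cell indices.
#' @export
maxent_fit <- function(presence, background, spec, stack,
                       reg_multiplier = 1, c0 = 0.05, tol = 1e-7,
                       max_iter = 200) {
  stopifnot(inherits(presence, "presence_data"),
            inherits(background, "background_data"),
            inherits(spec, "feature_spec"))
  if (presence$m < 5) stop("need at least 5 presence cells", call. = FALSE)
  if (length(background$background_cells) == 0L) {
    stop("background is empty", call. = FALSE)
  }
  landscape <- sort(unique(c(background$background_cells,
                             presence$presence_cells)))
  # spec-governed clamping so training scores match predict() on the
  # training stack exactly
  X <- feature_matrix(spec, stack, landscape)
  pres_idx <- match(presence$presence_cells, landscape)
  m <- length(pres_idx)
  Xp <- X[pres_idx, , drop = FALSE]
  pres_mean <- colMeans(Xp)
  s_j <- sqrt(colMeans(sweep(Xp, 2L, pres_mean)^2))   # population sd
  beta <- reg_multiplier * c0 * s_j / sqrt(m)

  fit <- maxent_optimize(X, pres_mean, beta, tol, max_iter)

  eta <- as.vector(X %*% fit$lambda)
  logZ <- log_sum_exp(eta)
  p <- exp(eta - logZ)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  raw <- p
  structure(
    list(species = presence$species,
         spec = spec, lambda = fit$lambda, beta = beta,
         reg_multiplier = reg_multiplier, c0 = c0,
         logZ = logZ, entropy = H,
         landscape_cells = landscape,
         landscape_raw_sorted = sort(raw),
         presence_cells = presence$presence_cells,
         training_presence_raw = raw[pres_idx],
         objective = fit$objective, iterations = fit$iterations,
         converged = fit$converged),
    class = "maxent_model"
  )
}

# Proximal-Newton ascent on
#   J(lambda) = pres_mean . lambda - logZ(lambda) - sum beta_j |lambda_j|
# Outer iterations build the exact gradient and d x d Hessian of the smooth
# part under the current cell distribution; the L1-penalized quadratic
# subproblem is solved by cyclic coordinate descent with soft thresholding;
# a backtracking line search on the full objective guarantees monotone
# ascent. Deterministic (0-init, cyclic order); exact L1 handling.
maxent_optimize <- function(X, pres_mean, beta, tol, max_iter) {
  d <- ncol(X)
  n <- nrow(X)
  lambda <- numeric(d)
  eta <- numeric(n)
  logZ <- log(n)
  obj <- -logZ
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- exp(eta - logZ)
    Ef <- as.vector(crossprod(X, p))
    g <- pres_mean - Ef
    Xc <- sweep(X, 2L, Ef)
    H <- crossprod(Xc, Xc * p)                 # cov of features under p
    diag(H) <- diag(H) + 1e-10
    # inner CD on: max g.delta - delta' H delta / 2 - sum beta |lambda+delta|
    delta <- numeric(d)
    Hd <- numeric(d)                           # H %*% delta
    for (sweep_i in seq_len(200L)) {
      move <- 0
      for (j in seq_len(d)) {
        gj <- g[j] - Hd[j] + H[j, j] * delta[j]
        target <- soft(lambda[j] + gj / H[j, j], beta[j] / H[j, j]) -
          lambda[j]
        step <- target - delta[j]
        if (step != 0) {
          Hd <- Hd + H[, j] * step
          delta[j] <- target
          move <- max(move, abs(step))
        }
      }
      if (move < 1e-12) break
    }
    if (all(delta == 0)) { converged <- TRUE; break }
    # backtracking line search on the full objective
    t_step <- 1
    improved <- FALSE
    for (bt in 0:50) {
      lam_try <- lambda + t_step * delta
      eta_try <- eta + t_step * as.vector(X %*% delta)
      logZ_try <- log_sum_exp(eta_try)
      obj_try <- sum(pres_mean * lam_try) - logZ_try -
        sum(beta * abs(lam_try))
      if (obj_try > obj) { improved <- TRUE; break }
      t_step <- t_step / 2
    }
    if (!improved) { converged <- TRUE; break }  # no ascent direction left
    gain <- obj_try - obj
    lambda <- lam_try
    eta <- eta_try
    logZ <- logZ_try
    obj <- obj_try
    if (t_step == 1 && gain < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    p <- exp(eta - logZ)
    grad <- pres_mean - as.vector(crossprod(X, p))
    stop(sprintf(
      "maxent fit did not converge in %d iterations (final gradient norm %.3g)",
      max_iter, sqrt(sum(grad^2))), call. = FALSE)
  }
  list(lambda = lambda, objective = obj, iterations = it,
       converged = converged)
}

# penalized objective of a weight vector on a landscape feature matrix
maxent_objective <- function(lambda, X, pres_mean, beta) {
  eta <- as.vector(X %*% lambda)
  sum(pres_mean * lambda) - log_sum_exp(eta) - sum(beta * abs(lambda))
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$lambda != 0)
  cat(sprintf(
    "<maxent_model> %d features (%d active), reg multiplier %g\n",
    length(x$lambda), nz, x$reg_multiplier))
  cat(sprintf(
    "  landscape %d cells, logZ %.4f, entropy %.4f, %d Newton steps\n",
    length(x$landscape_cells), x$logZ, x$entropy, x$iterations))
  invisible(x)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' Three standard output scales:
#' * `raw`: \eqn{e^{\lambda^\top f(x)} / Z} with `Z` the training-landscape
#'   normalizer — sums to 1 over the training landscape;
#' * `cumulative`: `100 *` the summed raw output of all training-landscape
#'   cells whose raw value is `<=` the cell's own (ties included, so the
#'   training maximum maps to exactly 100);
#' * `logistic`: \eqn{e^H \mathrm{raw} / (1 + e^H \mathrm{raw})} with `H`
#'   the entropy of the fitted training distribution.
#'
#' All three are strictly increasing transforms of one another, so cell
#' rankings (and any rank-based threshold) are scale-invariant. Clamping of
#' projected feature values follows the model's feature spec.
#'
#' @param object a `maxent_model`.
#' @param stack a [climate_stack()] carrying the model variables.
#' @param scale output scale: `"raw"`, `"cumulative"` or `"logistic"`.
#' @param cells optional cell indices (default: all land cells of `stack`).
#' @param ... unused.
#' @return a `raster_grid` of predictions (or a bare numeric vector when
#'   `cells` is given explicitly).
#' @export
predict.maxent_model <- function(object, stack, scale = "logistic",
                                 cells = NULL, ...) {
  scale <- match.arg(scale, c("raw", "cumulative", "logistic"))
  as_grid <- is.null(cells)
  if (is.null(cells)) cells <- land_cells(stack_ref_grid(stack))
  X <- feature_matrix(object$spec, stack, cells)
  eta <- as.vector(X %*% object$lambda)
  raw <- exp(eta - object$logZ)
  out <- score_on_scale(object, raw, scale)
  if (as_grid) grid_from_cells(stack_ref_grid(stack), cells, out) else out
}

score_on_scale <- function(model, raw, scale) {
  switch(scale,
    raw = raw,
    cumulative = {
      sr <- model$landscape_raw_sorted
      cum <- cumsum(sr)
      idx <- findInterval(raw, sr)      # count of landscape raw <= raw(x)
      100 * ifelse(idx == 0, 0, cum[pmax(idx, 1L)])
    },
    logistic = {
      eh <- exp(model$entropy) * raw
      eh / (1 + eh)
    }
  )
}

#' Training presence scores of a fitted model on a chosen output scale
#' @param model a `maxent_model`.
#' @param scale `"raw"`, `"cumulative"` or `"logistic"`.
#' @return numeric vector, one score per training presence cell.
#' @export
training_presence_scores <- function(model, scale = "logistic") {
  scale <- match.arg(scale, c("raw", "cumulative", "logistic"))
  score_on_scale(model, model$training_presence_raw, scale)
}
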