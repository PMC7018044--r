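#' Presence-background AUC (rank estimator)
#'
#' The probability that a randomly chosen presence site is ranked above a
#' randomly chosen background site: over all presence x background pairs,
#' a concordant pair counts 1, a tie 0.5, a discordant pair 0, divided by
#' the number of pairs. Computed via midranks, which is algebraically equal
#' to the pairwise count (a brute-force pairwise oracle confirms this in the
#' test suite). Identical scores give exactly 0.5 — discrimination no
#' better than random. Invariant under strictly increasing score
#' transforms.
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("score vectors must be nonempty",
                                 call. = FALSE)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Five-fold cross-validated AUC of the maximum-entropy model
#'
#' Presence cells are randomly partitioned into `k` folds (sizes differing
#' by at most 1). For each fold the model is refitted on the remaining
#' presences — the background is reused in full, as the cross-validation
#' splits presences only — and AUC is computed on the held-out presences
#' against the background. Cross-validation is reporting-only: the final
#' model is the one fitted on all presences.
#'
#' @param presence a `presence_data` with `m >= k`.
#' @param background a `background_data`.
#' @param spec a [build_features()] result.
#' @param stack the training [climate_stack()].
#' @param k fold count (default 5).
#' @param seed integer seed for the partition.
#' @param ... further arguments passed to [maxent_fit()].
#' @return an object of class `cv_report`: `fold_auc` (NA for a failed
#'   fold), `mean_auc`, `sd_auc` (sample SD), `k`, `seed`.
#' @export
cross_validate <- function(presence, background, spec, stack, k = 5,
                           seed = 1, ...) {
  m <- presence$m
  if (m < k) stop(sprintf("need at least k = %d presence cells, have %d",
                          k, m), call. = FALSE)
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(k), m))
  })
  bg_cells <- background$background_cells
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    train_cells <- presence$presence_cells[folds != f]
    test_cells <- presence$presence_cells[folds == f]
    p_train <- structure(
      list(species = presence$species, presence_cells = train_cells,
           m = length(train_cells), n_raw_records = length(train_cells),
           filter_counts = presence$filter_counts),
      class = "presence_data")
    fit <- tryCatch(maxent_fit(p_train, background, spec, stack, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("fold %d fit failed; excluded from the CV summary", f),
              call. = FALSE)
      next
    }
    sc_test <- predict(fit, stack, scale = "raw", cells = test_cells)
    sc_bg <- predict(fit, stack, scale = "raw", cells = bg_cells)
    fold_auc[f] <- auc(sc_test, sc_bg)
  }
  ok <- !is.na(fold_auc)
  structure(
    list(fold_auc = fold_auc,
         mean_auc = mean(fold_auc[ok]),
         sd_auc = stats::sd(fold_auc[ok]),
         k = k, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV AUC: mean %.3f (SD %.3f)\n",
              x$k, x$mean_auc, x$sd_auc))
  cat("  folds:", paste(sprintf("%.3f", x$fold_auc), collapse = " "), "\n")
  invisible(x)
}

#' 10th-percentile training-presence threshold
#'
#' The suitability value below which 10% of the training presences fall:
#' with the scores sorted ascending, the threshold is the
#' `(floor(0.1 * m) + 1)`-th smallest score, and a cell is "suitable" iff
#' its score is `>=` the threshold. The training omission (fraction of
#' training scores strictly below the threshold) equals `floor(0.1 * m) / m`
#' when the scores are distinct — exactly 10% when `m` is a multiple of 10 —
#' and can only be smaller under ties.
#'
#' @param scores numeric vector of training presence scores (`m >= 1`).
#' @param scale label recording which output scale the scores are on.
#' @return an object of class `threshold_result`: `threshold`, `rule`,
#'   `omission_train`, `scale`.
#' @export
threshold_p10 <- function(scores, scale = "logistic") {
  m <- length(scores)
  if (m < 1L) stop("need at least one training score", call. = FALSE)
  s <- sort(scores)
  thr <- s[floor(0.1 * m) + 1L]
  structure(
    list(threshold = thr, rule = "p10_training_presence",
         omission_train = mean(scores < thr), scale = scale),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %s = %.6g (%s scale), training omission %.1f%%\n",
    x$rule, x$threshold, x$scale, 100 * x$omission_train))
  invisible(x)
}
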