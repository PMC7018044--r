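test_that("feature construction: counts, scaling bounds, clamping", {
  h <- 4; w <- 4
  set.seed(81)
  st <- tiny_stack(list(t1 = matrix(stats::rnorm(16), h, w),
                        t2 = matrix(stats::rnorm(16), h, w)))
  cells <- land_cells(stack_ref_grid(st))
  spec <- build_features(st, background_cells = cells)
  # 2 linear + 2 quadratic + 1 product
  expect_equal(nrow(spec$table), 5L)
  expect_setequal(spec$table$kind,
                  c("linear", "quadratic", "product"))
  X <- feature_matrix(spec, st, cells)
  expect_equal(unname(apply(X, 2, min)), rep(0, 5))
  expect_equal(unname(apply(X, 2, max)), rep(1, 5))

  # projection beyond the background range clamps to exactly 1
  st_hot <- tiny_stack(list(t1 = matrix(99, h, w), t2 = matrix(99, h, w)))
  Xh <- feature_matrix(spec, st_hot, cells)
  expect_true(all(Xh == 1))
  Xh_unclamped <- feature_matrix(spec, st_hot, cells, clamp = FALSE)
  expect_true(all(Xh_unclamped > 1))

  # product features are scaled after multiplying the raw variables
  raw_prod <- cell_values(st$layers$t1, cells) *
    cell_values(st$layers$t2, cells)
  expect_equal(unname(X[, "t1*t2"]),
               (raw_prod - min(raw_prod)) / diff(range(raw_prod)))

  # constant features are dropped with a warning
  st_flat <- tiny_stack(list(t1 = matrix(stats::rnorm(16), h, w),
                             flat = matrix(3, h, w)))
  expect_warning(
    spec_flat <- build_features(st_flat,
                                background_cells = cells),
    "constant")
  expect_false(any(grepl("^flat$", spec_flat$table$name)))
})

test_that("presences drawn as the background give the null model", {
  # presence set == landscape: presence means equal landscape means, so
  # lambda = 0 is the KKT point and the raw distribution is uniform
  st <- make_climate(12, 12, n_vars = 2, smoothness = 2, seed = 91,
                     land_fraction = 1)
  g <- stack_ref_grid(st)
  cells <- land_cells(g)
  pres <- structure(list(species = "s", presence_cells = cells,
                         m = length(cells), n_raw_records = length(cells),
                         filter_counts = NULL), class = "presence_data")
  bg <- structure(list(background_cells = cells, buffer_km = 0,
                       requested_n = length(cells),
                       achieved_n = length(cells), seed = 1),
                  class = "background_data")
  spec <- build_features(st, background_cells = cells)
  mod <- maxent_fit(pres, bg, spec, st, reg_multiplier = 0)
  expect_equal(unname(mod$lambda), rep(0, nrow(spec$table)),
               tolerance = 1e-6)
  raw <- predict(mod, st, scale = "raw", cells = cells)
  expect_equal(raw, rep(1 / length(cells), length(cells)),
               tolerance = 1e-8)
})

test_that("converged fits satisfy the KKT bounds of the L1 problem", {
  for (seed in c(2, 7)) {
    tr <- small_training(seed = seed)
    mod <- maxent_fit(tr$presence, tr$background, tr$spec, tr$stack,
                      tol = 1e-12)
    landscape <- mod$landscape_cells
    X <- feature_matrix(tr$spec, tr$stack, landscape)
    p <- predict(mod, tr$stack, scale = "raw", cells = landscape)
    model_exp <- as.vector(crossprod(X, p))
    pres_mean <- colMeans(X[match(tr$presence$presence_cells, landscape), ,
                            drop = FALSE])
    gap <- abs(pres_mean - model_exp)
    expect_true(all(gap <= mod$beta + 1e-6))
    active <- mod$lambda != 0
    expect_true(all(abs(gap[active] - mod$beta[active]) < 1e-6))
  }
})

test_that("the fit matches a generic convex solver on small landscapes", {
  # <= 200-cell landscapes; compare achieved penalized objectives
  for (seed in c(3, 11)) {
    tr <- small_training(seed = seed, width = 14, height = 14, n_rec = 60,
                         max_bg = 150)
    mod <- maxent_fit(tr$presence, tr$background, tr$spec, tr$stack,
                      tol = 1e-12)
    landscape <- mod$landscape_cells
    expect_lte(length(landscape), 200L)
    X <- feature_matrix(tr$spec, tr$stack, landscape)
    pres_mean <- colMeans(X[match(tr$presence$presence_cells, landscape), ,
                            drop = FALSE])
    oracle <- maxent_oracle_objective(X, pres_mean, mod$beta)
    expect_lt(abs(mod$objective - oracle), 1e-6)
  }
})

test_that("raw output is a normalized distribution with closed-form values", {
  tr <- small_training(seed = 5)
  mod <- maxent_fit(tr$presence, tr$background, tr$spec, tr$stack)
  raw <- predict(mod, tr$stack, scale = "raw", cells = mod$landscape_cells)
  expect_lt(abs(sum(raw) - 1), 1e-10)

  # 3-cell landscape with eta = (0, log 2, log 3) -> raw = (1/6, 1/3, 1/2)
  hand <- structure(
    list(spec = structure(
           list(variables = "v", kinds = "linear",
                table = data.frame(name = "v", kind = "linear", var1 = "v",
                                   var2 = NA_character_),
                fmin = c(v = 0), fmax = c(v = 1), clamp = FALSE),
           class = "feature_spec"),
         lambda = 1, beta = 0, reg_multiplier = 0, c0 = 0,
         logZ = log(6), entropy = NA_real_,
         landscape_cells = 1:3,
         landscape_raw_sorted = sort(c(1, 2, 3) / 6),
         presence_cells = 1:3, training_presence_raw = c(1, 2, 3) / 6,
         objective = NA_real_, iterations = 1L, converged = TRUE),
    class = "maxent_model")
  st3 <- tiny_stack(list(v = matrix(c(0, log(2), log(3)), 1, 3)))
  raw3 <- predict(hand, st3, scale = "raw", cells = 1:3)
  expect_equal(raw3, c(1, 2, 3) / 6)
  # cumulative includes ties and the cell itself: max cell -> exactly 100
  expect_equal(predict(hand, st3, scale = "cumulative", cells = 1:3),
               100 * c(1 / 6, 3 / 6, 1))
})

test_that("output scales are monotone transforms sharing one cell ranking", {
  tr <- small_training(seed = 13)
  mod <- maxent_fit(tr$presence, tr$background, tr$spec, tr$stack)
  land <- land_cells(stack_ref_grid(tr$stack))
  raw <- predict(mod, tr$stack, scale = "raw", cells = land)
  cml <- predict(mod, tr$stack, scale = "cumulative", cells = land)
  lgs <- predict(mod, tr$stack, scale = "logistic", cells = land)
  o <- order(raw)
  expect_true(all(diff(lgs[o]) >= 0))
  expect_true(all(diff(cml[o]) >= 0))
  expect_equal(rank(raw), rank(lgs))
  # strictly increasing in raw wherever raw differs
  d_raw <- diff(sort(unique(raw)))
  expect_true(all(diff(sort(unique(lgs))) > 0))
  expect_gt(min(d_raw), 0)
})

test_that("weights recover a known Gibbs truth as regularization vanishes", {
  # presences drawn from p* ~ exp(lambda* . f) over the whole landscape;
  # record multiplicity kept (the likelihood weights cells by records)
  st <- make_climate(30, 30, n_vars = 2, smoothness = 4, seed = 17,
                     land_fraction = 1)
  g <- stack_ref_grid(st)
  cells <- land_cells(g)
  bg <- structure(list(background_cells = cells, buffer_km = 0,
                       requested_n = length(cells),
                       achieved_n = length(cells), seed = 1),
                  class = "background_data")
  spec <- build_features(st, kinds = c("linear", "quadratic"),
                         background_cells = cells)
  X <- feature_matrix(spec, st, cells)
  lambda_star <- c(2.0, -1.0, -1.5, 0.8)
  p_star <- exp(X %*% lambda_star)
  p_star <- p_star / sum(p_star)
  m <- 20000
  draws <- with_seed(23, sample(cells, m, replace = TRUE, prob = p_star))
  pres <- structure(list(species = "gibbs", presence_cells = draws,
                         m = m, n_raw_records = m, filter_counts = NULL),
                    class = "presence_data")
  mod <- maxent_fit(pres, bg, spec, st, reg_multiplier = 1e-8,
                    tol = 1e-12)
  expect_lt(max(abs(mod$lambda - lambda_star)), 0.2)
  expect_gt(stats::cor(mod$lambda, lambda_star), 0.99)
})

test_that("active set shrinks as the regularization multiplier grows", {
  tr <- small_training(seed = 19)
  nonzero <- vapply(c(0.25, 1, 4, 16, 64, 256), function(r) {
    sum(maxent_fit(tr$presence, tr$background, tr$spec, tr$stack,
                   reg_multiplier = r)$lambda != 0)
  }, numeric(1))
  expect_true(all(diff(nonzero) <= 0))
  expect_equal(nonzero[length(nonzero)], 0)  # huge penalty kills all weights
})

test_that("permutation importance isolates informative variables", {
  # truth uses bio1 only; bio2 is pure noise
  st <- make_climate(40, 40, n_vars = 2, smoothness = 5, seed = 29)
  vs <- make_virtual_species(st, linear = c(bio1 = 3, bio2 = 0),
                             quadratic = c(bio1 = -2, bio2 = 0))
  recs <- sample_presences(vs, 400, seed = 31)
  pres <- thin_to_cells(filter_records(recs, vs$species,
                                       stack_ref_grid(st)))
  bg <- sample_background(pres, stack_ref_grid(st), buffer_km = 80,
                          max_n = 2000, seed = 37)
  spec <- build_features(st, kinds = c("linear", "quadratic"),
                         background_cells = bg$background_cells)
  mod <- maxent_fit(pres, bg, spec, st)
  imp <- permutation_importance(mod, pres, bg, st, n_perm = 5, seed = 41)
  expect_equal(sum(imp), 100, tolerance = 0.01)
  expect_gt(imp[["bio1"]], 95)
  expect_true(all(unclass(imp) >= 0))
  # a variable whose every feature weight is zero has importance zero
  zero_vars <- names(which(vapply(spec$variables, function(v) {
    all(mod$lambda[spec$table$var1 == v |
                     (!is.na(spec$table$var2) & spec$table$var2 == v)] == 0)
  }, logical(1))))
  for (v in zero_vars) expect_equal(imp[[v]], 0)
})

test_that("importance is deterministic given the seed", {
  tr <- small_training(seed = 43, width = 20, height = 20, n_rec = 80,
                       max_bg = 300)
  mod <- maxent_fit(tr$presence, tr$background, tr$spec, tr$stack)
  i1 <- permutation_importance(mod, tr$presence, tr$background, tr$stack,
                               n_perm = 3, seed = 47)
  i2 <- permutation_importance(mod, tr$presence, tr$background, tr$stack,
                               n_perm = 3, seed = 47)
  expect_identical(unclass(i1), unclass(i2))
})
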