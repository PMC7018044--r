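# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use the most literal (slow) formulation so they stay
# independent of the package's vectorized implementations.

# Pairwise AUC by explicit enumeration of presence x background pairs.
auc_bruteforce <- function(pres, bg) {
  total <- 0
  for (p in pres) {
    for (b in bg) {
      total <- total + if (p > b) 1 else if (p == b) 0.5 else 0
    }
  }
  total / (length(pres) * length(bg))
}

# MESS similarity by literal per-cell, per-variable evaluation of the
# piecewise formula (fraction strictly below; ties to neither side).
mess_bruteforce <- function(reference, P) {
  n <- nrow(P)
  vars <- colnames(reference)
  S <- rep(Inf, n)
  for (i in seq_len(n)) {
    for (v in vars) {
      ref <- reference[, v]
      p <- P[i, v]
      rmin <- min(ref); rmax <- max(ref)
      fr <- 100 * sum(ref < p) / length(ref)
      sim <- if (fr == 0) {
        (p - rmin) / (rmax - rmin) * 100
      } else if (fr <= 50) {
        2 * fr
      } else if (fr < 100) {
        2 * (100 - fr)
      } else {
        (rmax - p) / (rmax - rmin) * 100
      }
      S[i] <- min(S[i], sim)
    }
  }
  S
}

# Generic convex-solver optimum of the penalized maxent objective, via the
# split lambda = a - b (a, b >= 0) reformulation that makes the L1 term
# smooth, solved with L-BFGS-B. Returns the achieved penalized objective.
maxent_oracle_objective <- function(X, pres_mean, beta) {
  d <- ncol(X)
  fn <- function(ab) {
    lam <- ab[1:d] - ab[(d + 1):(2 * d)]
    eta <- as.vector(X %*% lam)
    m <- max(eta)
    -(sum(pres_mean * lam) - (m + log(sum(exp(eta - m)))) -
        sum(beta * (ab[1:d] + ab[(d + 1):(2 * d)])))
  }
  gr <- function(ab) {
    lam <- ab[1:d] - ab[(d + 1):(2 * d)]
    eta <- as.vector(X %*% lam)
    m <- max(eta)
    p <- exp(eta - m) / sum(exp(eta - m))
    g_lam <- pres_mean - as.vector(crossprod(X, p))
    -c(g_lam - beta, -g_lam - beta)
  }
  fit <- stats::optim(rep(0, 2 * d), fn, gr, method = "L-BFGS-B",
                      lower = rep(0, 2 * d),
                      control = list(maxit = 5000, factr = 10))
  -fit$value
}

# Lag-1 spatial autocorrelation: correlation between horizontally adjacent
# land-cell pairs, computed straight off the value matrix.
lag1_autocorrelation <- function(grid) {
  m <- grid$values
  a <- as.vector(m[, -ncol(m)])
  b <- as.vector(m[, -1])
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}

# A tiny fully-landed stack with hand-specified layer values.
tiny_stack <- function(layers, cell_size = 1) {
  grids <- lapply(layers, function(m) {
    flyclim::raster_grid(m, cell_size = cell_size)
  })
  flyclim::climate_stack(grids)
}

# Deterministic small training setup used by several fitting tests.
small_training <- function(seed = 1, width = 30, height = 30, n_vars = 3,
                           n_rec = 120, max_bg = 500,
                           kinds = c("linear", "quadratic", "product")) {
  st <- flyclim::make_climate(width, height, n_vars = n_vars,
                              smoothness = 4, seed = seed)
  vs <- flyclim::make_virtual_species(st, seed = seed + 50)
  recs <- flyclim::sample_presences(vs, n_rec, seed = seed + 100)
  pres <- flyclim::thin_to_cells(
    flyclim::filter_records(recs, vs$species, flyclim::stack_ref_grid(st)))
  bg <- flyclim::sample_background(pres, flyclim::stack_ref_grid(st),
                                   buffer_km = width * 2, max_n = max_bg,
                                   seed = seed + 150)
  spec <- flyclim::build_features(st, kinds = kinds,
                                  background_cells = bg$background_cells)
  list(stack = st, species = vs, presence = pres, background = bg,
       spec = spec)
}

# A hand-built binary map over a template grid (for ensemble tests).
manual_binary <- function(template, suitable_cells, species = "sp",
                          scenario = "s", period = "p") {
  land <- flyclim::land_cells(template)
  vals <- as.numeric(land %in% suitable_cells)
  structure(
    list(grid = flyclim::grid_from_cells(template, land, vals),
         species = species, scenario_label = scenario,
         period_label = period,
         threshold = flyclim::threshold_p10(1:10 / 10)),
    class = "binary_map"
  )
}
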