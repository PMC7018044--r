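make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r[[1]], x = as.numeric(r[[2]]),
               y = as.numeric(r[[3]]),
               date = as.Date(r[[4]]), source = "test",
               stringsAsFactors = FALSE)
  }))
}

test_that("record filters apply in fixed order with full attribution", {
  g <- raster_grid(matrix(c(1, NA, 3, 4), 2, 2))   # bottom-left cell is ocean
  recs <- make_records(
    list("Bactrocera tryoni", 0.5, 1.5, "2000-06-01"),   # keep (cell 1)
    list("Bactrocera tryoni", 0.5, 1.5, "1949-12-31"),   # date filter
    list("Bactrocera sp.",    0.5, 1.5, "2000-06-01"),   # identity filter
    list("Bactrocera tryoni", 0.5, 0.5, "2000-06-01"),   # ocean cell -> land
    list("Bactrocera tryoni", NA,  1.5, "2000-06-01"),   # coords filter
    list("Bactrocera tryoni", 0.5, 1.5, NA)              # undated -> date
  )
  f <- filter_records(recs, "Bactrocera tryoni", g,
                      min_date = "1950-01-01")
  expect_equal(nrow(f$records), 1L)
  expect_equal(unname(f$counts),
               c(1L, 2L, 1L, 1L))    # identity, date, coords, land
  expect_equal(sum(f$counts), nrow(recs) - nrow(f$records))
  expect_setequal(f$rejections$filter[f$rejections$row %in% c(2, 6)],
                  "date")
  # keep_undated retains the record with no date
  f2 <- filter_records(recs, "Bactrocera tryoni", g,
                       min_date = "1950-01-01", keep_undated = TRUE)
  expect_equal(nrow(f2$records), 2L)
  # retained set is order-free: it equals the intersection of all filters
  expect_true(all(f$records$date >= as.Date("1950-01-01"), na.rm = TRUE))
  # all-rejected input names the dominant cause
  expect_error(filter_records(recs[2:3, ], "Bactrocera tryoni", g),
               "dominant rejection cause")
})

test_that("thinning collapses to unique cells and is idempotent", {
  g <- raster_grid(matrix(1, 4, 4))
  ten_same <- data.frame(species = "s", x = rep(1.5, 10), y = rep(1.5, 10),
                         date = as.Date("2000-01-01"), source = "t")
  p1 <- thin_to_cells(ten_same, grid = g)
  expect_equal(p1$m, 1L)
  three <- data.frame(species = "s", x = c(0.5, 1.5, 2.5), y = rep(0.5, 3),
                      date = as.Date("2000-01-01"), source = "t")
  expect_equal(thin_to_cells(three, grid = g)$m, 3L)
})

test_that("points on shared edges follow the half-open rule, conserving count", {
  g <- raster_grid(matrix(1, 2, 2), xll = 0, yll = 0, cell_size = 1)
  # a point exactly on a shared edge belongs to the cell whose half-open
  # box [edge, edge + cs) starts there — never to both
  pts <- data.frame(x = c(1, 0.5, 1), y = c(0.5, 1, 1))
  cells <- point_to_cell(g, pts$x, pts$y)
  # brute-force assignment oracle over all 4 cells' half-open boxes
  oracle <- apply(pts, 1, function(p) {
    for (cell in 1:4) {
      rc <- c((cell - 1) %/% 2 + 1, (cell - 1) %% 2 + 1)
      x0 <- rc[2] - 1; y0 <- 2 - rc[1]
      if (p["x"] >= x0 && p["x"] < x0 + 1 &&
          p["y"] >= y0 && p["y"] < y0 + 1) return(cell)
    }
    NA_integer_
  })
  expect_equal(cells, as.integer(oracle))
  expect_false(anyNA(cells))           # every edge point lands in one cell
  expect_equal(length(cells), 3L)
})

test_that("background sampling respects the buffer, 'up to' max_n, and seed", {
  st <- make_climate(30, 30, n_vars = 2, smoothness = 3, seed = 61)
  g <- stack_ref_grid(st)
  pres <- structure(list(species = "s", presence_cells = c(100L, 500L),
                         m = 2L, n_raw_records = 2L, filter_counts = NULL),
                    class = "presence_data")
  bg <- sample_background(pres, g, buffer_km = 6, max_n = 100, seed = 5)
  expect_lte(bg$achieved_n, 100)
  expect_equal(length(bg$background_cells), bg$achieved_n)
  expect_false(any(duplicated(bg$background_cells)))
  # brute-force distance check of every returned cell
  pc <- cell_centers(g, pres$presence_cells)
  bc <- cell_centers(g, bg$background_cells)
  for (i in seq_len(nrow(bc))) {
    d <- sqrt((bc[i, "x"] - pc[, "x"])^2 + (bc[i, "y"] - pc[, "y"])^2)
    expect_lte(min(d), 6)
  }
  # deterministic under the same seed
  bg2 <- sample_background(pres, g, buffer_km = 6, max_n = 100, seed = 5)
  expect_identical(bg2$background_cells, bg$background_cells)
  # eligible < max_n returns the whole eligible set ("up to")
  bg_all <- sample_background(pres, g, buffer_km = 6, max_n = 1e5, seed = 5)
  expect_lt(bg_all$achieved_n, 1e5)
  expect_gte(bg_all$achieved_n, bg$achieved_n)
  # buffer 0 leaves exactly the presence cells (with a warning)
  expect_warning(
    bg0 <- sample_background(pres, g, buffer_km = 0, max_n = 10, seed = 1),
    "buffer")
  expect_setequal(bg0$background_cells, pres$presence_cells)
})

test_that("background inclusion is uniform over the eligible set", {
  g <- raster_grid(matrix(1, 6, 5))
  pres <- structure(list(species = "s", presence_cells = 15L, m = 1L,
                         n_raw_records = 1L, filter_counts = NULL),
                    class = "presence_data")
  eligible <- sample_background(pres, g, buffer_km = 100, max_n = 1e4,
                                seed = 1)$background_cells
  n_el <- length(eligible)
  take <- 10L
  n_rep <- 400L
  hits <- stats::setNames(rep(0, n_el), eligible)
  for (s in seq_len(n_rep)) {
    got <- sample_background(pres, g, buffer_km = 100, max_n = take,
                             seed = s)$background_cells
    hits[as.character(got)] <- hits[as.character(got)] + 1
  }
  p_inc <- take / n_el
  # simultaneous binomial band, Bonferroni at 0.1% over cells
  lo <- stats::qbinom(0.0005 / n_el, n_rep, p_inc)
  hi <- stats::qbinom(1 - 0.0005 / n_el, n_rep, p_inc)
  expect_true(all(hits >= lo & hits <= hi))
})

test_that("collinearity screening keeps the first of correlated pairs", {
  n <- 400
  set.seed(71)
  a <- stats::rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * stats::rnorm(n)  # r ~= 0.9 with a
  c_ind <- stats::rnorm(n)                          # r ~= 0.1 with both
  h <- 20; w <- 20
  st <- tiny_stack(list(v1 = matrix(a, h, w), v2 = matrix(b, h, w),
                        v3 = matrix(c_ind, h, w)))
  cells <- land_cells(stack_ref_grid(st))
  kept <- screen_collinearity(st, c("v1", "v2", "v3"), cells, r_max = 0.8)
  expect_equal(as.character(kept), c("v1", "v3"))
  cm <- attr(kept, "correlations")
  expect_equal(dim(cm), c(3L, 3L))
  expect_gt(abs(cm["v1", "v2"]), 0.8)

  # duplicate layer is dropped (|r| = 1); independent noise layers both kept
  st2 <- tiny_stack(list(v1 = matrix(a, h, w), v1b = matrix(a, h, w)))
  expect_equal(as.character(
    screen_collinearity(st2, c("v1", "v1b"), cells)), "v1")

  # zero-variance layer excluded with warning
  st3 <- tiny_stack(list(v1 = matrix(a, h, w), flat = matrix(1, h, w)))
  expect_warning(kept3 <- screen_collinearity(st3, c("v1", "flat"), cells),
                 "zero-variance")
  expect_equal(as.character(kept3), "v1")
})
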