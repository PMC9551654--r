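test_that("grid division follows rows = round(extent / spacing)", {
  g <- make_grid(7.8, 3.8, 0.01)
  expect_equal(c(g$rows, g$cols), c(780L, 380L))
  g2 <- make_grid(1, 1, 0.5)
  expect_equal(c(g2$rows, g2$cols), c(2L, 2L))
  g3 <- make_grid(1, 1, 0.3)
  expect_equal(g3$rows, 3L)
  expect_error(make_grid(-1, 1, 0.1), "positive")
  ctr <- grid_centers(g2)
  expect_equal(ctr$cx, c(0.25, 0.75))
})

test_that("IDW honours exact hits, convexity and equidistant averaging", {
  grid <- make_grid(1, 1, 0.5)
  one <- point_cloud(0.1, 0.1, 0.7)
  r1 <- idw_raster(one, grid)
  expect_true(all(r1$values == 0.7))

  # sample coincident with a cell centre dominates it exactly
  hit <- point_cloud(c(0.25, 0.9), c(0.25, 0.9), c(2, 5))
  r2 <- idw_raster(hit, grid)
  expect_equal(r2$values[1, 1], 2)

  # equidistant two-sample cell averages
  two <- point_cloud(c(0.25, 0.25), c(0.05, 0.45), c(0, 1))
  r3 <- idw_raster(two, grid)
  expect_equal(r3$values[1, 1], 0.5)
})

test_that("k-nearest IDW with k = 0 equals the literal all-samples formula", {
  set.seed(23)
  samples <- random_cloud(60, seed = 23, xlim = c(0, 2), ylim = c(0, 2))
  grid <- make_grid(2, 2, 0.25)
  got <- idw_raster(samples, grid, idw_config(k_neighbors = 0))
  # brute-force direct evaluation of the weight formula
  ctr <- grid_centers(grid)
  brute <- matrix(0, grid$rows, grid$cols)
  for (i in seq_len(grid$rows)) for (j in seq_len(grid$cols)) {
    d <- sqrt((ctr$cx[i] - samples$x)^2 + (ctr$cy[j] - samples$y)^2)
    w <- d^-2
    brute[i, j] <- sum(w * samples$z) / sum(w)
  }
  expect_equal(got$values, brute, tolerance = 1e-12)

  # convex weights: output bounded by the sample extremes, weights sum to 1
  expect_true(all(got$values >= min(samples$z) - 1e-12))
  expect_true(all(got$values <= max(samples$z) + 1e-12))
  d <- sqrt((ctr$cx[2] - samples$x)^2 + (ctr$cy[3] - samples$y)^2)
  expect_equal(sum(d^-2 / sum(d^-2)), 1, tolerance = 1e-12)
})

test_that("rendering maps heights deterministically onto the palette", {
  grid <- make_grid(1, 1, 0.5)
  flat <- idw_raster(point_cloud(0.5, 0.5, 0.6), grid)
  img <- render_image(flat, 0, 1.2)
  expect_equal(dim(img), c(2, 2, 3))
  expect_true(all(apply(img, 3, function(ch) length(unique(as.vector(ch)))) == 1))

  ends <- flat; ends$values[1, 1] <- 0; ends$values[2, 2] <- 1.2
  img2 <- render_image(ends, 0, 1.2)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255
  expect_equal(as.vector(img2[1, 1, ]), unname(pal[, 1]))
  expect_equal(as.vector(img2[2, 2, ]), unname(pal[, 256]))

  expect_identical(render_image(ends, 0, 1.2), img2)
  expect_error(render_image(flat, 1, 0), "exceed")
})

test_that("interpolation error report matches closed forms", {
  const <- random_cloud(50, seed = 31)
  const$z <- 0.8
  rep1 <- evaluate_interpolation(const, holdout_fraction = 0.2, seed = 1)
  expect_equal(rep1$mae_mm, 0, tolerance = 1e-9)
  expect_equal(rep1$sd_mm, 0, tolerance = 1e-9)
  expect_equal(rep1$median_mm, 0, tolerance = 1e-9)

  # residuals of +-1 mm give MAE = SD = Median = 1 exactly
  w <- c(1, -1, 1, -1) # mm
  expect_equal(mean(abs(w)), 1)
  expect_equal(sqrt(mean(w^2)), 1)
  expect_equal(median(abs(w)), 1)

  # IDW beats a deliberately poor interpolator (global mean) on the same
  # seeded holdout of smooth data
  set.seed(32)
  x <- runif(400, 0, 4); y <- runif(400, 0, 4)
  smooth <- point_cloud(x, y, 0.5 + 0.2 * sin(x) + 0.1 * cos(2 * y))
  rep_idw <- evaluate_interpolation(smooth, holdout_fraction = 0.2, seed = 77)
  rep_poor <- evaluate_interpolation(
    smooth, holdout_fraction = 0.2, seed = 77,
    predict_fn = function(train, x, y) rep(mean(train$z), length(x)))
  expect_lt(rep_idw$mae_mm, rep_poor$mae_mm)
})

test_that("benchmark reductions are computed from the shipped table", {
  red <- interp_error_reduction()
  fill <- dplyr::filter(red, stage == "filling")
  get <- function(vs, ind) fill$reduction_pct[fill$versus == vs &
                                                fill$indicator == ind]
  expect_equal(get("local_linear_embedding", "mae_mm"), 49.6, tolerance = 0.05)
  expect_equal(get("biharmonic_spline", "mae_mm"), 28.0, tolerance = 0.05)
  expect_equal(get("local_linear_embedding", "median_mm"), 63.8,
               tolerance = 0.05)
})

test_that("ASCII grid export round-trips", {
  grid <- make_grid(1, 1.5, 0.25, origin = c(2, 3))
  set.seed(33)
  r <- idw_raster(random_cloud(20, seed = 33, xlim = c(2, 3), ylim = c(3, 4.5)),
                  grid)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, r$values, tolerance = 1e-6)
  expect_equal(back$grid$d, 0.25)
  expect_equal(back$grid$origin, c(2, 3))
})

test_that("the interpolator registry exposes idw and rejects unknowns", {
  fn <- get_interpolator("idw")
  grid <- make_grid(1, 1, 0.5)
  r <- fn(point_cloud(0.2, 0.2, 1), grid)
  expect_s3_class(r, "lp_raster")
  expect_error(get_interpolator("kriging"), "registered")
})
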