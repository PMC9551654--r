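test_that("generated truth follows the lodging formulas", {
  cfg <- field_sim_config(point_density = 50)
  up <- generate_plot(cfg, theta = 0, lr = 0, seed = 61)
  expect_equal(up$truth$li, 0)
  expect_equal(as.character(up$truth$class), "non_lodging")

  flat <- generate_plot(cfg, theta = 90, lr = 1, seed = 62)
  expect_equal(flat$truth$li, 1)
  expect_equal(as.character(flat$truth$class), "severe")
  expect_equal(flat$truth$h2, 0, tolerance = 1e-12)

  mid <- generate_plot(cfg, theta = 60, lr = 0.6, seed = 63)
  expect_equal(mid$truth$la, 2 / 3, tolerance = 1e-9)
  expect_equal(mid$truth$li, 0.4, tolerance = 1e-9)
  expect_equal(mid$truth$h2, 0.5, tolerance = 1e-12)

  expect_error(generate_plot(cfg, theta = 100, lr = 0), "theta")
  expect_error(generate_plot(cfg, theta = 10, lr = 2), "lr")
})

test_that("generation is deterministic under a seed and honours the mix", {
  cfg <- field_sim_config(point_density = 40)
  f1 <- generate_field(cfg, n_plots = 4, seed = 64)
  f2 <- generate_field(cfg, n_plots = 4, seed = 64)
  expect_identical(f1$cloud, f2$cloud)
  expect_identical(f1$truth, f2$truth)
  expect_setequal(as.character(f1$truth$class), lodging_classes())

  f3 <- generate_field(cfg, n_plots = 4, seed = 65)
  expect_false(identical(f1$cloud$z, f3$cloud$z))
  expect_error(generate_field(cfg, 2, class_mix = "extreme"), "unknown")
})

test_that("lodged patches cover the requested area fraction", {
  cfg <- field_sim_config(point_density = 400)
  gp <- generate_plot(cfg, theta = 45, lr = 0.35, seed = 66)
  canopy <- gp$cloud[gp$cloud$part == "canopy", ]
  frac <- mean(canopy$lodged)
  expect_lt(abs(frac - 0.35), 0.03)
})

test_that("the pipeline recovers h1 cos(theta) inside the lodged patch", {
  cfg <- field_sim_config(point_density = 150)
  theta <- 50; lr <- 0.5
  gp <- generate_plot(cfg, theta = theta, lr = lr, seed = 67)
  sg <- split_ground(gp$cloud)
  dem <- build_dem(sg$ground, spacing = 0.2)
  norm <- normalize_cloud(gp$cloud, dem)
  aligned <- align_plot(norm)
  grid <- make_grid(diff(range(aligned$x)), diff(range(aligned$y)), 0.1,
                    origin = c(min(aligned$x), min(aligned$y)))
  veg <- aligned[aligned$part == "canopy", ]
  raster <- idw_raster(veg, grid)

  # locate the lodged patch in the aligned frame via the truth labels
  lodged <- aligned[aligned$lodged, ]
  td <- tidy(raster)
  inside <- td$cx >= quantile(lodged$x, 0.05) & td$cx <= quantile(lodged$x, 0.95) &
    td$cy >= quantile(lodged$y, 0.05) & td$cy <= quantile(lodged$y, 0.95)
  h2_hat <- mean(td$z[inside])
  expect_lt(abs(h2_hat - cos(theta * pi / 180)), 0.05)

  # empirical lodged-area fraction from thresholding the raster at the
  # midpoint between upright and lodged canopy heights
  midpoint <- (1 + cos(theta * pi / 180)) / 2
  lr_hat <- mean(td$z < midpoint)
  expect_lt(abs(lr_hat - lr), 0.05)
})

test_that("band fields land in their canopy-height bands", {
  cfg <- field_sim_config(point_density = 60)
  f <- generate_band_field(cfg, n_plots = 8, seed = 68)
  expect_equal(nrow(f$truth), 8)
  h2 <- f$truth$h2
  cls <- as.character(f$truth$class)
  expect_true(all(h2[cls == "non_lodging"] > 0.9))
  expect_true(all(h2[cls == "slight"] > 0.7 & h2[cls == "slight"] < 0.9))
  expect_true(all(h2[cls == "moderate"] > 0.5 & h2[cls == "moderate"] < 0.7))
  expect_true(all(h2[cls == "severe"] < 0.5))
})
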