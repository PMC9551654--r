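test_that("ExG scores follow the chromatic-coordinate formula", {
  pc <- point_cloud(1:3, 1:3, 1:3,
                    r = c(0, 100, 50), g = c(255, 100, 150), b = c(0, 100, 100))
  expect_equal(exg_scores(pc), c(2, 0, 0.5))
  # black pixels score zero rather than NaN
  black <- point_cloud(0, 0, 0, r = 0, g = 0, b = 0)
  expect_equal(exg_scores(black), 0)
  expect_error(exg_scores(point_cloud(0, 0, 0)), "colour")
})

test_that("ground/vegetation split is a partition with the expected sides", {
  gray <- point_cloud(1:5, 1:5, 1:5, r = rep(100, 5), g = rep(100, 5),
                      b = rep(100, 5))
  sp <- split_ground(gray, threshold = 0.0729)
  expect_equal(nrow(sp$ground), 5)
  expect_equal(nrow(sp$vegetation), 0)

  green <- point_cloud(1:5, 1:5, 1:5, r = rep(0, 5), g = rep(255, 5),
                       b = rep(0, 5))
  expect_warning(sp2 <- split_ground(green), "ground")
  expect_equal(nrow(sp2$vegetation), 5)

  mixed <- random_cloud(200, seed = 5, colors = TRUE)
  sp3 <- split_ground(mixed)
  expect_equal(nrow(sp3$ground) + nrow(sp3$vegetation), 200)
})

test_that("ExG split recovers the generator's soil/canopy partition", {
  gp <- generate_plot(field_sim_config(point_density = 100), theta = 30,
                      lr = 0.4, seed = 9)
  sp <- split_ground(gp$cloud)
  truth_soil <- gp$cloud$part == "soil"
  pred_soil <- exg_scores(gp$cloud) < 0.0729
  expect_gte(mean(pred_soil == truth_soil), 0.99)
  expect_setequal(sp$ground$part, "soil")
})

test_that("DEM interpolation reproduces constant and planar terrain", {
  flat <- point_cloud(runif(100, 0, 2), runif(100, 0, 2), rep(5, 100))
  dem <- build_dem(flat, spacing = 0.25)
  expect_true(all(abs(dem$values - 5) < 1e-9))

  g <- expand.grid(x = seq(0, 4, by = 0.1), y = seq(0, 4, by = 0.1))
  plane <- point_cloud(g$x, g$y, 0.01 * g$x + 0.02 * g$y)
  demp <- build_dem(plane, spacing = 0.2, pad = 0)
  ctr <- grid_centers(demp$grid)
  truth <- outer(0.01 * ctr$cx, 0.02 * ctr$cy, "+")
  interior <- 3:(demp$grid$rows - 3)
  expect_lt(max(abs(demp$values - truth)[interior, 3:(demp$grid$cols - 3)]), 1e-3)

  single <- point_cloud(1, 1, 2.5)
  dems <- build_dem(single, spacing = 0.5)
  expect_true(all(dems$values == 2.5))
  expect_error(build_dem(point_cloud(numeric(), numeric(), numeric())), "empty")
})

test_that("normalization subtracts the DEM and is exact on flat terrain", {
  flat <- point_cloud(runif(200, 0, 2), runif(200, 0, 2), rep(5, 200))
  dem <- build_dem(flat, spacing = 0.25)
  veg <- point_cloud(runif(20, 0.2, 1.8), runif(20, 0.2, 1.8), rep(5.9, 20))
  norm <- normalize_cloud(veg, dem)
  expect_equal(norm$z, rep(0.9, 20), tolerance = 1e-9)

  # ground normalized against its own DEM sits near zero
  selfn <- normalize_cloud(flat, dem)
  expect_lt(max(abs(selfn$z)), 1e-9)

  # out-of-extent points are named in the error
  outside <- point_cloud(50, 50, 1)
  expect_error(normalize_cloud(outside, dem), "outside")
})

test_that("pipeline normalization recovers canopy height on synthetic terrain", {
  gp <- generate_plot(field_sim_config(point_density = 150), theta = 0, lr = 0,
                      seed = 21)
  sp <- split_ground(gp$cloud)
  dem <- build_dem(sp$ground, spacing = 0.2)
  norm <- normalize_cloud(gp$cloud, dem)
  veg_mean <- mean(norm$z[norm$part == "canopy"])
  expect_lt(abs(veg_mean - 1.0), 0.05)
  grd_mean <- mean(norm$z[norm$part == "soil"])
  expect_lt(abs(grd_mean), 0.02) # |mean| below the generator noise sigma
})
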