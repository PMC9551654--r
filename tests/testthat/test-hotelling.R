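test_that("centroid and covariance match their defining formulas", {
  expect_equal(unname(pc_centroid(point_cloud(3, 4, 5))), c(3, 4, 5))
  expect_equal(unname(pc_centroid(point_cloud(c(0, 2), c(0, 2), c(0, 2)))),
               c(1, 1, 1))
  pc <- random_cloud(100, seed = 13)
  P <- as.matrix(pc[, c("x", "y", "z")])
  expect_equal(unname(pc_centroid(pc)), unname(colMeans(P)), tolerance = 1e-12)

  expect_equal(unname(pc_covariance(point_cloud(1, 2, 3))), matrix(0, 3, 3))
  two <- point_cloud(c(-1, 1), c(0, 0), c(0, 0))
  expect_equal(unname(pc_covariance(two)), diag(c(1, 0, 0)))

  # uncentred form (1/n) sum P P^T - m m^T as an independent oracle
  pc2 <- random_cloud(200, seed = 14)
  P2 <- as.matrix(pc2[, c("x", "y", "z")])
  m <- colMeans(P2)
  oracle <- crossprod(P2) / nrow(P2) - tcrossprod(m)
  expect_equal(pc_covariance(pc2), oracle, tolerance = 1e-9)
  expect_error(pc_centroid(point_cloud(numeric(), numeric(), numeric())),
               "empty")
})

test_that("principal-axes transform is a proper rigid motion that diagonalizes", {
  set.seed(15)
  pc <- point_cloud(runif(300, 0, 8), runif(300, 0, 2), runif(300, 0, 0.5))
  fit <- hotelling_transform(pc)
  V <- fit$axes
  expect_lt(max(abs(V %*% t(V) - diag(3))), 1e-9)
  expect_equal(det(V), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  ct <- pc_covariance(fit$transformed)
  offdiag <- abs(ct[upper.tri(ct)]) / max(abs(diag(ct)))
  expect_lt(max(offdiag), 1e-9)

  # pairwise distances preserved
  idx <- sample(300, 40)
  d0 <- dist(as.matrix(pc[idx, c("x", "y", "z")]))
  d1 <- dist(as.matrix(fit$transformed[idx, c("x", "y", "z")]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
})

test_that("a rotated cloud recovers the unrotated principal structure", {
  set.seed(16)
  base <- point_cloud(runif(400, 0, 8), runif(400, 0, 2), rnorm(400, 1, 0.1))
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  P <- as.matrix(base[, c("x", "y", "z")]) %*% t(R)
  rotated <- point_cloud(P[, 1], P[, 2], P[, 3])
  f0 <- hotelling_transform(base)
  f1 <- hotelling_transform(rotated)
  expect_equal(f1$eigenvalues, f0$eigenvalues, tolerance = 1e-9)
  ct <- pc_covariance(f1$transformed)
  expect_lt(max(abs(ct[upper.tri(ct)])) / max(diag(ct)), 1e-9)
})

test_that("transforming an aligned cloud changes nothing (idempotence)", {
  set.seed(17)
  pc <- point_cloud(runif(200, 0, 5), runif(200, 0, 1), runif(200, 0, 0.2))
  once <- hotelling_transform(pc)$transformed
  twice <- hotelling_transform(once)$transformed
  expect_equal(as.matrix(twice[, c("x", "y", "z")]),
               as.matrix(once[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("degenerate clouds error and colours are carried through", {
  same <- point_cloud(rep(1, 5), rep(2, 5), rep(3, 5))
  expect_error(hotelling_transform(same), "degenerate")
  expect_error(hotelling_transform(point_cloud(1, 1, 1)), "3 points")

  pc <- random_cloud(50, seed = 18, colors = TRUE)
  fit <- hotelling_transform(pc)
  expect_equal(fit$transformed$r, pc$r)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$var_share), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$det_axes, 1, tolerance = 1e-9)
})

test_that("align_plot keeps heights on the above-ground datum", {
  gp <- generate_plot(field_sim_config(point_density = 80), theta = 0, lr = 0,
                      seed = 19)
  sp <- split_ground(gp$cloud)
  dem <- build_dem(sp$ground, spacing = 0.2)
  norm <- normalize_cloud(gp$cloud, dem)
  aligned <- align_plot(norm)
  veg <- aligned$z[aligned$part == "canopy"]
  expect_lt(abs(mean(veg) - 1.0), 0.05)
})
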