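#' Centroid of a point cloud
#'
#' @param cloud Non-empty point cloud.
#' @return Length-3 numeric `(x, y, z)` mean.
#' @export
pc_centroid <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) rlang::abort("centroid of an empty cloud is undefined")
  c(x = mean(cloud$x), y = mean(cloud$y), z = mean(cloud$z))
}

#' Population covariance of a point cloud
#'
#' The 3x3 covariance with the divide-by-n (population) convention,
#' evaluated in the centred form `(1/n) sum (P_k - m)(P_k - m)^T`, which is
#' algebraically identical to the uncentred `(1/n) sum P_k P_k^T - m m^T`
#' but numerically stable for coordinates far from the origin.
#'
#' @param cloud Non-empty point cloud.
#' @return 3x3 symmetric matrix.
#' @export
pc_covariance <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n == 0) rlang::abort("covariance of an empty cloud is undefined")
  P <- as.matrix(cloud[, c("x", "y", "z")])
  ctr <- sweep(P, 2, colMeans(P))
  crossprod(ctr) / n
}

#' Principal-axes (Hotelling) transform of a point cloud
#'
#' Rotates and translates the cloud into the orthonormal frame of its
#' covariance eigenvectors: `P' = V (P - m)` with `V` rows the eigenvectors
#' in descending-eigenvalue order. The transformed covariance is diagonal,
#' so a field plot ends up with its long side on axis 1, its short side on
#' axis 2 and height on axis 3.
#'
#' Eigenvector signs are pinned for determinism: axis 3 (smallest variance,
#' treated as height) points up (positive dot with (0,0,1)); axis 1 points
#' toward world +x (falling back to +y when orthogonal to x); axis 2 is
#' `axis3 x axis1`, forcing `det(V) = +1` (a proper rotation, no mirroring).
#'
#' @param cloud Point cloud with at least 3 non-identical points.
#' @return An object of class `lp_hotelling`: list with `centroid`,
#'   `covariance`, `axes` (V, rows = eigenvectors), `eigenvalues`
#'   (descending) and `transformed` (the aligned point cloud; colours and
#'   extra columns carried through).
#' @export
hotelling_transform <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n < 3) rlang::abort("need at least 3 points to estimate principal axes")
  C <- pc_covariance(cloud)
  if (max(abs(C)) < 1e-300) rlang::abort("degenerate cloud: all points identical")
  eg <- eigen(C, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  lam <- eg$values[ord]
  V <- t(eg$vectors[, ord, drop = FALSE]) # rows = eigenvectors
  if (lam[2] < 1e-12 * max(lam[1], 1e-300)) {
    rlang::inform("rank-deficient cloud (collinear/coplanar points); axes may be arbitrary in the null space")
  }
  if (abs(lam[1] - lam[2]) < 1e-12 * max(lam[1], 1e-300) ||
      abs(lam[2] - lam[3]) < 1e-12 * max(lam[1], 1e-300)) {
    rlang::inform("near-equal eigenvalues; axis order kept from the decomposition")
  }
  # deterministic orientation
  if (V[3, 3] < 0) V[3, ] <- -V[3, ]
  a1 <- V[1, ]
  ref <- if (abs(a1[1]) > 1e-12) c(1, 0, 0) else c(0, 1, 0)
  if (sum(a1 * ref) < 0) V[1, ] <- -V[1, ]
  V[2, ] <- c(V[3, 2] * V[1, 3] - V[3, 3] * V[1, 2],
              V[3, 3] * V[1, 1] - V[3, 1] * V[1, 3],
              V[3, 1] * V[1, 2] - V[3, 2] * V[1, 1])
  m <- pc_centroid(cloud)
  P <- as.matrix(cloud[, c("x", "y", "z")])
  Pt <- sweep(P, 2, m) %*% t(V)
  out <- cloud
  out$x <- Pt[, 1]; out$y <- Pt[, 2]; out$z <- Pt[, 3]
  structure(list(centroid = m, covariance = C, axes = V, eigenvalues = lam,
                 transformed = as_point_cloud(out)),
            class = "lp_hotelling")
}

#' Align a plot cloud to its principal axes, keeping the height datum
#'
#' Convenience wrapper around [hotelling_transform()] for normalized plot
#' clouds: after the rotation (which centres every axis, including height),
#' the centroid's height is added back along axis 3 so values stay on the
#' above-ground scale the rasters display.
#'
#' @param cloud Normalized plot cloud.
#' @param preserve_height_datum Add the centroid height back on axis 3
#'   (default TRUE).
#' @return The aligned point cloud, with the `lp_hotelling` fit attached as
#'   attribute `"hotelling"`.
#' @export
align_plot <- function(cloud, preserve_height_datum = TRUE) {
  fit <- hotelling_transform(cloud)
  out <- fit$transformed
  if (preserve_height_datum) out$z <- out$z + fit$centroid[["z"]]
  attr(out, "hotelling") <- fit
  out
}

#' @export
print.lp_hotelling <- function(x, ...) {
  cat("Principal-axes (Hotelling) transform\n")
  cat("  centroid   :", sprintf("%.4f", x$centroid), "\n")
  cat("  eigenvalues:", sprintf("%.6g", x$eigenvalues), "\n")
  invisible(x)
}

#' Tidy / glance methods for a Hotelling fit
#'
#' `tidy()` returns one row per principal axis (direction cosines, variance,
#' variance share); `glance()` a one-row model summary.
#'
#' @param x An `lp_hotelling` fit.
#' @param ... Unused.
#' @export
tidy.lp_hotelling <- function(x, ...) {
  tibble::tibble(
    axis = 1:3,
    vx = x$axes[, 1], vy = x$axes[, 2], vz = x$axes[, 3],
    eigenvalue = x$eigenvalues,
    var_share = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' @rdname tidy.lp_hotelling
#' @export
glance.lp_hotelling <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$transformed),
    total_variance = sum(x$eigenvalues),
    planarity = 1 - x$eigenvalues[3] / max(x$eigenvalues[2], 1e-300),
    det_axes = det(x$axes)
  )
}
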