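#' Excess Green index per point
#'
#' ExG = 2g - r - b on chromatic coordinates g = G/(R+G+B) etc., so values
#' range over \[-1, 2\]: high for green vegetation, near zero for grey soil.
#' Black points (R+G+B = 0) score 0. The chromatic form is used (rather than
#' raw 2G-R-B) so thresholds like the default 0.0729 are meaningful.
#'
#' @param cloud A point cloud tibble with colours.
#' @return Numeric vector of per-point ExG scores.
#' @export
exg_scores <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (!has_colors(cloud)) rlang::abort("ExG needs point colours (r, g, b)")
  s <- cloud$r + cloud$g + cloud$b
  ifelse(s == 0, 0, (2 * cloud$g - cloud$r - cloud$b) / s)
}

#' Split a cloud into ground and vegetation by ExG threshold
#'
#' Points with ExG below the threshold are ground (soil reflects little
#' green excess), the rest vegetation; the two parts partition the cloud.
#'
#' @param cloud A coloured point cloud.
#' @param threshold ExG cut point (default 0.0729).
#' @return A list with point clouds `ground` and `vegetation`.
#' @export
split_ground <- function(cloud, threshold = 0.0729) {
  cloud <- as_point_cloud(cloud)
  exg <- exg_scores(cloud)
  grd <- exg < threshold
  if (!any(grd)) {
    rlang::warn("no ground points below the ExG threshold; a DEM cannot be built")
  }
  list(ground = as_point_cloud(cloud[grd, , drop = FALSE]),
       vegetation = as_point_cloud(cloud[!grd, , drop = FALSE]))
}

#' Build a digital elevation model from ground points
#'
#' Interpolates ground elevations onto a coarse grid with IDW; every cell
#' gets a value (IDW predicts everywhere), so the DEM has no holes.
#'
#' @param ground Ground point cloud (non-empty).
#' @param spacing DEM cell size, metres (default 0.1).
#' @param cfg [idw_config()] used for the interpolation.
#' @param pad Margin added around the ground bounding box, metres, so that
#'   vegetation points at the plot edge stay inside the DEM extent.
#' @return An `lp_raster` DEM whose axis 1 is x and axis 2 is y.
#' @export
build_dem <- function(ground, spacing = 0.1, cfg = idw_config(), pad = 0.5) {
  ground <- as_point_cloud(ground)
  if (nrow(ground) == 0) rlang::abort("cannot build a DEM from an empty ground cloud")
  x0 <- min(ground$x) - pad; x1 <- max(ground$x) + pad
  y0 <- min(ground$y) - pad; y1 <- max(ground$y) + pad
  grid <- make_grid(max(x1 - x0, spacing), max(y1 - y0, spacing), spacing,
                    origin = c(x0, y0))
  idw_raster(ground, grid, cfg)
}

# Bilinear sample of an lp_raster at arbitrary (x, y); clamps to the cell-
# centre hull so edge queries use the border cells.
raster_bilinear <- function(raster, x, y, strict = TRUE) {
  g <- raster$grid
  ctr <- grid_centers(g)
  if (strict) {
    out <- which(x < g$origin[1] | x > g$origin[1] + g$rows * g$d |
                 y < g$origin[2] | y > g$origin[2] + g$cols * g$d)
    if (length(out)) {
      rlang::abort(sprintf("point (%.3f, %.3f) lies outside the DEM extent",
                           x[out[1]], y[out[1]]))
    }
  }
  fx <- (x - ctr$cx[1]) / g$d
  fy <- (y - ctr$cy[1]) / g$d
  i0 <- pmin(pmax(floor(fx), 0), g$rows - 1L); i1 <- pmin(i0 + 1, g$rows - 1L)
  j0 <- pmin(pmax(floor(fy), 0), g$cols - 1L); j1 <- pmin(j0 + 1, g$cols - 1L)
  tx <- pmin(pmax(fx - i0, 0), 1); ty <- pmin(pmax(fy - j0, 0), 1)
  v <- raster$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i1, j0) +
    (1 - tx) * ty * idx(i0, j1) + tx * ty * idx(i1, j1)
}

#' Normalize point heights against a DEM
#'
#' Replaces each point's z by its height above ground, `z - DEM(x, y)`,
#' sampling the DEM bilinearly; x, y, colours and any extra columns are
#' unchanged. Negative heights are kept — clamping would mask interpolation
#' bias; rasterization can clip for display.
#'
#' @param cloud Point cloud to normalize.
#' @param dem DEM raster from [build_dem()] (must cover the cloud's xy box).
#' @return The normalized point cloud.
#' @export
normalize_cloud <- function(cloud, dem) {
  cloud <- as_point_cloud(cloud)
  stopifnot(inherits(dem, "lp_raster"))
  if (nrow(cloud) == 0) return(cloud)
  elev <- raster_bilinear(dem, cloud$x, cloud$y, strict = TRUE)
  cloud$z <- cloud$z - elev
  cloud
}
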