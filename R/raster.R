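#' Define a regular rasterization grid
#'
#' Cell counts follow `rows = round(delta_x / d)`, `cols = round(delta_y / d)`
#' with half-away-from-zero rounding, so a 7.8 m x 3.8 m plot at d = 0.01 m
#' gives exactly 780 x 380 despite binary floating point. Cell centres sit at
#' `origin + (i - 0.5) * d`.
#'
#' @param delta_x Extent along the first (row) axis, metres.
#' @param delta_y Extent along the second (column) axis, metres.
#' @param d Cell spacing, metres.
#' @param origin Length-2 lower corner `(min axis-1, min axis-2)`.
#' @return A `lp_grid` list with `rows`, `cols`, `d`, `origin`, extents.
#' @export
make_grid <- function(delta_x, delta_y, d, origin = c(0, 0)) {
  if (delta_x <= 0 || delta_y <= 0 || d <= 0) {
    rlang::abort("grid extents and spacing must be positive")
  }
  half_away <- function(v) trunc(v + 0.5 * sign(v))
  rows <- max(1L, as.integer(half_away(delta_x / d)))
  cols <- max(1L, as.integer(half_away(delta_y / d)))
  structure(list(rows = rows, cols = cols, d = as.numeric(d),
                 delta_x = as.numeric(delta_x), delta_y = as.numeric(delta_y),
                 origin = as.numeric(origin)),
            class = "lp_grid")
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [make_grid()] spec.
#' @return A list with vectors `cx` (length `rows`, axis-1 centres) and
#'   `cy` (length `cols`, axis-2 centres).
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "lp_grid"))
  list(cx = grid$origin[1] + (seq_len(grid$rows) - 0.5) * grid$d,
       cy = grid$origin[2] + (seq_len(grid$cols) - 0.5) * grid$d)
}

#' Configure inverse-distance-weighted interpolation
#'
#' Weights are `K_i = d_i^-power / sum d_j^-power` over the neighbour set,
#' with `d_i` the Euclidean xy distance from the cell centre to sample i.
#' `k_neighbors = 0` uses every sample (the literal formula); the default 12
#' nearest keeps large plots tractable. Cell centres within `exact_hit_eps`
#' of a sample take the mean of those coincident samples (the weight formula
#' is singular at zero distance).
#'
#' @param power Distance exponent (default 2).
#' @param k_neighbors Neighbours per cell; 0 = all samples.
#' @param exact_hit_eps Coincidence tolerance, metres.
#' @return An `lp_idw` config list.
#' @export
idw_config <- function(power = 2, k_neighbors = 12L, exact_hit_eps = 1e-9) {
  if (k_neighbors < 0) rlang::abort("k_neighbors must be >= 0")
  structure(list(power = power, k_neighbors = as.integer(k_neighbors),
                 exact_hit_eps = exact_hit_eps), class = "lp_idw")
}

# IDW prediction at arbitrary xy targets; chunked brute-force neighbour
# search (vectorised distance blocks) — scales fine to the package's grids.
idw_predict <- function(sx, sy, sz, tx, ty, cfg = idw_config()) {
  m <- length(sx)
  if (m == 0) rlang::abort("IDW needs at least one sample")
  n <- length(tx)
  out <- numeric(n)
  k <- cfg$k_neighbors
  chunk <- max(1L, as.integer(2e6 %/% max(1L, m)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    d2 <- outer(tx[lo:hi], sx, "-")^2 + outer(ty[lo:hi], sy, "-")^2
    if (k > 0L && k < m) {
      res <- numeric(hi - lo + 1L)
      for (i in seq_len(hi - lo + 1L)) {
        di2 <- d2[i, ]
        nb <- order(di2)[seq_len(k)]
        res[i] <- idw_combine(sqrt(di2[nb]), sz[nb], cfg)
      }
      out[lo:hi] <- res
    } else {
      for (i in seq_len(hi - lo + 1L)) {
        out[lo + i - 1L] <- idw_combine(sqrt(d2[i, ]), sz, cfg)
      }
    }
  }
  out
}

idw_combine <- function(d, z, cfg) {
  hit <- d < cfg$exact_hit_eps
  if (any(hit)) return(mean(z[hit]))
  w <- d^(-cfg$power)
  sum(w * z) / sum(w)
}

#' Interpolate sample heights onto a grid (IDW)
#'
#' Evaluates inverse-distance-weighted interpolation of the cloud's `z` at
#' every cell centre of `grid`, using the cloud's `x` as axis 1 and `y` as
#' axis 2.
#'
#' @param cloud Sample point cloud (non-empty); `z` holds the values.
#' @param grid A [make_grid()] spec.
#' @param cfg An [idw_config()].
#' @return An `lp_raster` list: `grid`, `values` (rows x cols matrix), and a
#'   logical `mask` of unsupported cells (always all-FALSE for IDW, which
#'   predicts everywhere).
#' @export
idw_raster <- function(cloud, grid, cfg = idw_config()) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) rlang::abort("cannot interpolate from an empty cloud")
  ctr <- grid_centers(grid)
  tx <- rep(ctr$cx, times = grid$cols)
  ty <- rep(ctr$cy, each = grid$rows)
  vals <- idw_predict(cloud$x, cloud$y, cloud$z, tx, ty, cfg)
  structure(list(grid = grid,
                 values = matrix(vals, nrow = grid$rows, ncol = grid$cols),
                 mask = matrix(FALSE, grid$rows, grid$cols)),
            class = "lp_raster")
}

# --- pluggable interpolator registry ---------------------------------------

.lp_interpolators <- new.env(parent = emptyenv())

#' Register or fetch a grid interpolator
#'
#' Interpolators map `(cloud, grid, ...)` to an `lp_raster`, so alternative
#' schemes can be benchmarked against the bundled IDW through one interface.
#' Only `"idw"` ships with the package.
#'
#' @param name Interpolator name.
#' @param fn For `register_interpolator`, a `function(cloud, grid, ...)`.
#' @return `get_interpolator` returns the function; registering returns the
#'   name invisibly.
#' @export
register_interpolator <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .lp_interpolators)
  invisible(name)
}

#' @rdname register_interpolator
#' @export
get_interpolator <- function(name) {
  if (!exists(name, envir = .lp_interpolators)) {
    rlang::abort(paste0("no interpolator registered under '", name,
                        "'; available: ",
                        paste(ls(.lp_interpolators), collapse = ", ")))
  }
  get(name, envir = .lp_interpolators)
}

#' Tidy a raster into a long tibble
#'
#' @param x An `lp_raster`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `cx`, `cy`, `z`.
#' @export
tidy.lp_raster <- function(x, ...) {
  ctr <- grid_centers(x$grid)
  tibble::tibble(
    row = rep(seq_len(x$grid$rows), times = x$grid$cols),
    col = rep(seq_len(x$grid$cols), each = x$grid$rows),
    cx = rep(ctr$cx, times = x$grid$cols),
    cy = rep(ctr$cy, each = x$grid$rows),
    z = as.vector(x$values)
  )
}

#' Render a height raster to an RGB image
#'
#' Heights are clipped to `[z_min, z_max]`, scaled linearly and mapped
#' through a colour palette; output is deterministic for fixed inputs.
#'
#' @param raster An `lp_raster`.
#' @param z_min,z_max Height range mapped onto the palette, metres.
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default "viridis", perceptually uniform).
#' @param n_colors Palette resolution.
#' @return A `rows x cols x 3` numeric array in \[0, 1\].
#' @export
render_image <- function(raster, z_min = 0, z_max = 1.2, colormap = "viridis",
                         n_colors = 256L) {
  stopifnot(inherits(raster, "lp_raster"))
  if (z_max <= z_min) rlang::abort("z_max must exceed z_min")
  v <- raster$values
  if (!length(v)) rlang::abort("empty raster")
  u <- pmin(pmax((v - z_min) / (z_max - z_min), 0), 1)
  idx <- pmin(n_colors, 1L + floor(u * (n_colors - 1L) + 0.5))
  pal <- grDevices::hcl.colors(n_colors, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  img <- array(0, dim = c(nrow(v), ncol(v), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, idx], nrow(v), ncol(v))
  img
}

#' Write an RGB array as PNG
#'
#' @param img Array `H x W x 3` in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Hold-out evaluation of grid interpolation error
#'
#' Holds out a seeded random fraction of samples, interpolates from the rest
#' at the held-out xy positions and summarizes residuals
#' `w_i = predicted - actual`: MAE = mean |w_i|, SD = sqrt(mean w_i^2),
#' Median = median |w_i|, all reported in millimetres.
#'
#' @param cloud Sample point cloud.
#' @param cfg An [idw_config()].
#' @param holdout_fraction Fraction held out, in (0, 1); default 0.2.
#' @param seed Integer seed for the holdout draw.
#' @param predict_fn Function `(train_cloud, x, y) -> z` used to predict at
#'   the held-out positions; defaults to IDW under `cfg`, and is the hook
#'   for benchmarking alternative interpolators on the same holdout.
#' @return A tibble with one row: `n_holdout`, `mae_mm`, `sd_mm`,
#'   `median_mm`, plus the residual vector in a list-column `residuals_mm`.
#' @export
evaluate_interpolation <- function(cloud, cfg = idw_config(),
                                   holdout_fraction = 0.2, seed = 1L,
                                   predict_fn = NULL) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    rlang::abort("holdout_fraction must be in (0, 1)")
  }
  n_hold <- round(n * holdout_fraction)
  if (n_hold < 1 || n_hold >= n) rlang::abort("degenerate holdout split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hold <- sample.int(n, n_hold)
  train <- cloud[-hold, ]
  test <- cloud[hold, ]
  pred <- if (is.null(predict_fn)) {
    idw_predict(train$x, train$y, train$z, test$x, test$y, cfg)
  } else {
    predict_fn(train, test$x, test$y)
  }
  w_mm <- (pred - test$z) * 1000
  tibble::tibble(
    n_holdout = n_hold,
    mae_mm = mean(abs(w_mm)),
    sd_mm = sqrt(mean(w_mm^2)),
    median_mm = stats::median(abs(w_mm)),
    residuals_mm = list(w_mm)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Percentage error reduction between interpolation methods
#'
#' Given a benchmark table of interpolation error indicators (columns
#' `method`, `stage`, `mae_mm`, `sd_mm`, `median_mm`), computes for each
#' stage and indicator the percentage reduction of the reference method's
#' error relative to each other method:
#' `100 * (other - reference) / other`.
#'
#' @param benchmarks Tibble/data frame of per-method, per-stage errors. The
#'   default loads the benchmark table shipped with the package
#'   (field-survey averages over 10 plots per lodging degree).
#' @param reference Method name whose reduction is reported (default
#'   `"idw"`).
#' @return A long tibble: `stage`, `versus`, `indicator`, `reference_value`,
#'   `other_value`, `reduction_pct`.
#' @export
interp_error_reduction <- function(benchmarks = read_interp_benchmarks(),
                                   reference = "idw") {
  df <- tibble::as_tibble(benchmarks)
  need <- c("method", "stage", "mae_mm", "sd_mm", "median_mm")
  stopifnot(all(need %in% names(df)))
  long <- tidyr::pivot_longer(df, dplyr::all_of(c("mae_mm", "sd_mm", "median_mm")),
                              names_to = "indicator", values_to = "value")
  ref <- dplyr::filter(long, .data$method == reference) |>
    dplyr::select("stage", "indicator", reference_value = "value")
  dplyr::filter(long, .data$method != reference) |>
    dplyr::rename(versus = "method", other_value = "value") |>
    dplyr::inner_join(ref, by = c("stage", "indicator")) |>
    dplyr::mutate(reduction_pct = 100 * (.data$other_value - .data$reference_value) /
                    .data$other_value) |>
    dplyr::select("stage", "versus", "indicator", "reference_value",
                  "other_value", "reduction_pct")
}

#' @rdname interp_error_reduction
#' @export
read_interp_benchmarks <- function() {
  path <- system.file("extdata", "interp_error_benchmarks.csv",
                      package = "lodgepoint", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# --- ASCII grid (ESRI dialect) export --------------------------------------

#' Read/write a raster as an ESRI ASCII grid
#'
#' Plain-text matrix with the 6-line ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value header. Rows of the file run north-to-south, i.e.
#' the last matrix row is written first.
#'
#' @param raster An `lp_raster` (values matrix rows = axis 1).
#' @param path File path.
#' @param nodata Value standing in for masked cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an `lp_raster`.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "lp_raster"))
  g <- raster$grid
  v <- raster$values
  v[raster$mask] <- nodata
  hdr <- c(paste("ncols", g$rows), paste("nrows", g$cols),
           paste("xllcorner", g$origin[1]), paste("yllcorner", g$origin[2]),
           paste("cellsize", g$d), paste("NODATA_value", nodata))
  body <- apply(t(v)[g$cols:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2]), 0),
                        tolower(vapply(hdr, `[`, "", 1)))
  ncols <- as.integer(kv[["ncols"]]); nrows <- as.integer(kv[["nrows"]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  values <- t(m[nrows:1, , drop = FALSE])
  grid <- make_grid(ncols * kv[["cellsize"]], nrows * kv[["cellsize"]],
                    kv[["cellsize"]], origin = c(kv[["xllcorner"]], kv[["yllcorner"]]))
  mask <- values == kv[["nodata_value"]]
  values[mask] <- NA_real_
  structure(list(grid = grid, values = values, mask = mask), class = "lp_raster")
}
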