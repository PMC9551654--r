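# Synthetic wheat-field point clouds with known ground truth: undulating
# terrain, a green canopy at height h1 with lodged patches at canopy height
# h1*cos(theta), brown soil points, Gaussian height noise. Every pipeline
# stage can be checked against the generator's truth labels.

#' Configure the synthetic field generator
#'
#' Defaults emulate a surveyed wheat plot: 7.8 m x 3.8 m footprint, canopy
#' height 1.0 m, ~500 points per square metre (about a fifth of them soil
#' returns through canopy gaps), 0.02 m height noise, gently undulating
#' terrain (plane plus sinusoid), green canopy and brown soil colours with
#' jitter.
#'
#' @param plot_length,plot_width Plot footprint, metres.
#' @param point_density Points per square metre (canopy + soil together).
#' @param soil_fraction Fraction of points that are soil returns.
#' @param h1 Upright canopy height, metres.
#' @param terrain Named list: `base` elevation (m), `slope_x`, `slope_y`
#'   (m/m), `amplitude` and `wavelength` (m) of the sinusoidal undulation.
#' @param noise_sigma Gaussian height noise SD, metres.
#' @param canopy_rgb,soil_rgb Mean colours (0-255).
#' @param color_jitter SD of colour jitter (0-255 scale).
#' @return An `lp_sim_config` list.
#' @export
field_sim_config <- function(plot_length = 7.8, plot_width = 3.8,
                             point_density = 500, soil_fraction = 0.2,
                             h1 = 1.0,
                             terrain = list(base = 20, slope_x = 0.01,
                                            slope_y = 0.02, amplitude = 0.05,
                                            wavelength = 6),
                             noise_sigma = 0.02,
                             canopy_rgb = c(60, 140, 50),
                             soil_rgb = c(135, 92, 78),
                             color_jitter = 8) {
  stopifnot(plot_length > 0, plot_width > 0, point_density > 0,
            soil_fraction >= 0, soil_fraction < 1, h1 > 0, noise_sigma >= 0)
  structure(list(plot_length = plot_length, plot_width = plot_width,
                 point_density = point_density, soil_fraction = soil_fraction,
                 h1 = h1, terrain = terrain, noise_sigma = noise_sigma,
                 canopy_rgb = canopy_rgb, soil_rgb = soil_rgb,
                 color_jitter = color_jitter),
            class = "lp_sim_config")
}

terrain_height <- function(cfg, x, y) {
  t <- cfg$terrain
  t$base + t$slope_x * x + t$slope_y * y +
    t$amplitude * (sin(2 * pi * x / t$wavelength) + cos(2 * pi * y / t$wavelength))
}

# Axis-aligned rectangular lodged patch of area fraction lr inside the plot
# footprint [x0, x0+L] x [y0, y0+W]; position seeded by the caller's RNG.
lodged_patch <- function(cfg, lr, x0, y0, shape = c("rectangle", "circle")) {
  shape <- match.arg(shape)
  L <- cfg$plot_length; W <- cfg$plot_width
  if (lr <= 0) return(function(x, y) rep(FALSE, length(x)))
  if (lr >= 1) return(function(x, y) rep(TRUE, length(x)))
  if (shape == "rectangle") {
    lx <- L * sqrt(lr); ly <- W * sqrt(lr)
    px <- x0 + stats::runif(1, 0, L - lx)
    py <- y0 + stats::runif(1, 0, W - ly)
    function(x, y) x >= px & x < px + lx & y >= py & y < py + ly
  } else {
    r <- sqrt(lr * L * W / pi)
    cx <- x0 + stats::runif(1, min(r, L / 2), L - min(r, L / 2))
    cy <- y0 + stats::runif(1, min(r, W / 2), W - min(r, W / 2))
    function(x, y) (x - cx)^2 + (y - cy)^2 < r^2
  }
}

#' Generate one synthetic plot with ground truth
#'
#' Points are uniform over the plot footprint. Soil points sit on the
#' terrain; canopy points sit at `terrain + h1` when upright or
#' `terrain + h1 * cos(theta)` inside the lodged patch (the geometric
#' inverse of the lodging-angle formula, so the lodging module recovers
#' theta exactly in expectation). Gaussian height noise is added to all
#' points. The returned cloud carries truth columns `part`
#' ("soil"/"canopy") and `lodged`.
#'
#' @param cfg A [field_sim_config()].
#' @param theta Lodging angle, degrees in \[0, 90\].
#' @param lr Lodged-area fraction in \[0, 1\].
#' @param plot_id Identifier stored in the truth row.
#' @param origin Plot lower-left corner `(x0, y0)`, metres.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param patch_shape `"rectangle"` (default) or `"circle"`.
#' @param thresholds [lodging_thresholds()] used for the truth class
#'   (default the survey-derived mu = 0.40, alpha = 0.274).
#' @return List with `cloud` (point cloud tibble) and `truth` (one-row
#'   tibble: plot_id, h1, theta, h2, lr, la, li, class).
#' @export
generate_plot <- function(cfg = field_sim_config(), theta = 0, lr = 0,
                          plot_id = 1L, origin = c(0, 0), seed = NULL,
                          patch_shape = "rectangle",
                          thresholds = lodging_thresholds(mu = 0.40, alpha = 0.274)) {
  stopifnot(inherits(cfg, "lp_sim_config"))
  if (theta < 0 || theta > 90) rlang::abort("theta must lie in [0, 90] degrees")
  if (lr < 0 || lr > 1) rlang::abort("lr must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  n <- max(10L, round(cfg$point_density * cfg$plot_length * cfg$plot_width))
  x <- stats::runif(n, origin[1], origin[1] + cfg$plot_length)
  y <- stats::runif(n, origin[2], origin[2] + cfg$plot_width)
  soil <- stats::runif(n) < cfg$soil_fraction
  in_patch <- lodged_patch(cfg, lr, origin[1], origin[2], patch_shape)(x, y)
  h2 <- cfg$h1 * cos(theta * pi / 180)
  veg_h <- ifelse(in_patch, h2, cfg$h1)
  z <- terrain_height(cfg, x, y) + ifelse(soil, 0, veg_h) +
    stats::rnorm(n, 0, cfg$noise_sigma)
  jitter <- function(mu) {
    m <- matrix(rep(mu, each = n), n, 3) +
      matrix(stats::rnorm(3 * n, 0, cfg$color_jitter), n, 3)
    pmin(pmax(m, 0), 255)
  }
  cols <- jitter(cfg$canopy_rgb)
  cols[soil, ] <- jitter(cfg$soil_rgb)[soil, ]
  cloud <- point_cloud(x, y, z, r = cols[, 1], g = cols[, 2], b = cols[, 3],
                       part = ifelse(soil, "soil", "canopy"),
                       lodged = !soil & in_patch)
  la <- lodging_la(cfg$h1, h2)
  li <- lodging_index(la, lr)
  truth <- tibble::tibble(plot_id = plot_id, h1 = cfg$h1, theta = theta,
                          h2 = h2, lr = lr, la = la, li = li,
                          class = classify_li(li, thresholds))
  list(cloud = cloud, truth = truth)
}

# Draw (theta, lr) whose lodging index lands inside the class interval.
draw_spec_for_class <- function(class, thresholds, margin = 0.02) {
  b <- thresholds$boundaries
  iv <- switch(class,
               non_lodging = c(0, b[1]), slight = c(b[1], b[2]),
               moderate = c(b[2], b[3]), severe = c(b[3], 1))
  li <- stats::runif(1, iv[1] + margin * diff(iv), iv[2] - margin * diff(iv))
  if (li < 1e-3) return(list(theta = 0, lr = 0))
  la <- stats::runif(1, max(li, 0.15), 1)
  list(theta = la * 90, lr = li / la)
}

#' Generate a multi-plot synthetic field
#'
#' Tiles `n_plots` plots into a strip layout, draws each plot's lodging
#' spec to hit the requested class mix, and concatenates the clouds. Fully
#' deterministic under `seed`.
#'
#' @param cfg A [field_sim_config()].
#' @param n_plots Number of plots (>= 1).
#' @param class_mix `"balanced"` (default) cycles through the four classes;
#'   or a character vector of class names recycled over plots.
#' @param seed Integer seed.
#' @param n_cols Plots per layout row.
#' @param thresholds Truth-labelling [lodging_thresholds()].
#' @return List with `cloud` (whole-field point cloud with `plot_id`
#'   column), `truth` (tibble, one row per plot), and `layout` (the
#'   [plot_layout()] used).
#' @export
generate_field <- function(cfg = field_sim_config(), n_plots = 4L,
                           class_mix = "balanced", seed = 1L, n_cols = NULL,
                           thresholds = lodging_thresholds(mu = 0.40, alpha = 0.274)) {
  stopifnot(n_plots >= 1)
  classes <- if (identical(class_mix, "balanced")) {
    rep(lodging_classes(), length.out = n_plots)
  } else {
    bad <- setdiff(class_mix, lodging_classes())
    if (length(bad)) rlang::abort(paste0("unknown class(es): ",
                                         paste(bad, collapse = ", ")))
    rep(class_mix, length.out = n_plots)
  }
  if (is.null(n_cols)) n_cols <- max(1L, ceiling(sqrt(n_plots)))
  n_rows <- ceiling(n_plots / n_cols)
  layout <- plot_layout(origin = c(0, 0), plot_length = cfg$plot_length,
                        plot_width = cfg$plot_width,
                        n_rows = n_rows, n_cols = n_cols)
  rects <- layout_rectangles(layout)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  clouds <- vector("list", n_plots)
  truths <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    spec <- draw_spec_for_class(classes[i], thresholds)
    gp <- generate_plot(cfg, theta = spec$theta, lr = spec$lr, plot_id = i,
                        origin = c(rects$x_lo[i], rects$y_lo[i]),
                        thresholds = thresholds)
    gp$cloud$plot_id <- i
    clouds[[i]] <- gp$cloud
    truths[[i]] <- gp$truth
  }
  truth <- dplyr::bind_rows(truths)
  if (!identical(class_mix, "balanced") || n_plots >= 4) {
    miss <- setdiff(unique(classes), as.character(truth$class))
    if (length(miss)) {
      rlang::warn(paste0("requested class(es) not realized: ",
                         paste(miss, collapse = ", ")))
    }
  }
  list(cloud = as_point_cloud(dplyr::bind_rows(clouds)), truth = truth,
       layout = layout)
}

#' Generate height-band plots for classifier experiments
#'
#' Produces fully lodged / upright plots whose canopy heights fall into the
#' four cleanly separated bands observed for the lodging degrees
#' (non-lodging above 0.9 m, slight 0.7-0.9 m, moderate 0.5-0.7 m, severe
#' below 0.5 m): each plot's lodging angle is drawn so h2 = h1 cos(theta)
#' lands inside its band, with the whole plot lodged (lr = 1) for the three
#' lodged classes.
#'
#' @param cfg A [field_sim_config()] (h1 = 1.0 matches the bands).
#' @param n_plots Number of plots.
#' @param seed Integer seed.
#' @return As [generate_field()]: `cloud`, `truth` (class = band label),
#'   `layout`.
#' @export
generate_band_field <- function(cfg = field_sim_config(), n_plots = 40L,
                                seed = 1L) {
  bands <- list(non_lodging = c(0.93, 1.0), slight = c(0.72, 0.88),
                moderate = c(0.52, 0.68), severe = c(0.15, 0.45))
  classes <- rep(lodging_classes(), length.out = n_plots)
  n_cols <- max(1L, ceiling(sqrt(n_plots)))
  layout <- plot_layout(origin = c(0, 0), plot_length = cfg$plot_length,
                        plot_width = cfg$plot_width,
                        n_rows = ceiling(n_plots / n_cols), n_cols = n_cols)
  rects <- layout_rectangles(layout)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  clouds <- vector("list", n_plots); truths <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    band <- bands[[classes[i]]]
    h2 <- stats::runif(1, band[1] * cfg$h1, band[2] * cfg$h1)
    theta <- acos(h2 / cfg$h1) * 180 / pi
    lr <- if (classes[i] == "non_lodging") 0 else 1
    gp <- generate_plot(cfg, theta = if (lr == 0) 0 else theta, lr = lr,
                        plot_id = i, origin = c(rects$x_lo[i], rects$y_lo[i]))
    gp$cloud$plot_id <- i
    gp$truth$class <- factor(classes[i], levels = lodging_classes(),
                             ordered = TRUE)
    clouds[[i]] <- gp$cloud; truths[[i]] <- gp$truth
  }
  list(cloud = as_point_cloud(dplyr::bind_rows(clouds)),
       truth = dplyr::bind_rows(truths), layout = layout)
}
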