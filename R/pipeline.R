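# One-command end-to-end run: simulate (or ingest) -> normalize -> align ->
# rasterize -> label -> train -> evaluate, with per-stage artifacts under an
# output directory and a JSON run report.

#' Assemble a pipeline configuration
#'
#' Either `simulate` (synthetic field) or `input` (path to an XYZ-TXT field
#' cloud plus layout) must be given. Every stage draws its randomness from
#' `seed`, so all artifacts are re-derivable from the config alone.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param simulate NULL or list: `n_plots`, `mode` ("li" draws lodging
#'   specs per class interval, "bands" the four canopy-height bands),
#'   `point_density`, `noise_sigma`, `h1`.
#' @param input NULL or list: `cloud` (file path), `layout` (a
#'   [plot_layout()]).
#' @param normalize List: `exg_threshold`, `dem_spacing`.
#' @param rasterize List: `spacing`, `k_neighbors`, `z_min`, `z_max`,
#'   `colormap`, `image_size`.
#' @param label List: `mu`, `alpha` (NULL recomputes from the data's LI).
#' @param classify NULL to skip training, else list: `model`, `width_mult`,
#'   `augment_total`, `max_epochs`, `patience`, `batch_size`,
#'   `learning_rate`.
#' @return An `lp_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            simulate = list(n_plots = 8L, mode = "bands",
                                            point_density = 120,
                                            noise_sigma = 0.02, h1 = 1.0),
                            input = NULL,
                            normalize = list(exg_threshold = 0.0729,
                                             dem_spacing = 0.1),
                            rasterize = list(spacing = 0.1, k_neighbors = 12L,
                                             z_min = 0, z_max = 1.2,
                                             colormap = "viridis",
                                             image_size = 32L),
                            label = list(mu = 0.40, alpha = 0.274),
                            classify = list(model = "mobilenetv2",
                                            width_mult = 0.25,
                                            augment_total = 50L,
                                            max_epochs = 5L, patience = 3L,
                                            batch_size = 4L,
                                            learning_rate = 0.001)) {
  if (is.null(simulate) && is.null(input)) {
    rlang::abort("pipeline needs either a simulate spec or an input cloud")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input = input, normalize = normalize,
                 rasterize = rasterize, label = label, classify = classify),
            class = "lp_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return An `lp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$input) && !is.null(args$input$layout)) {
    lay <- args$input$layout
    args$input$layout <- plot_layout(
      origin = c(lay$origin[[1]], lay$origin[[2]]),
      plot_length = lay$plot_length, plot_width = lay$plot_width,
      n_rows = lay$n_rows, n_cols = lay$n_cols)
  }
  do.call(pipeline_config, args)
}

# Normalize -> align -> rasterize for one plot cloud.
process_plot <- function(cloud, cfg) {
  sg <- split_ground(cloud, threshold = cfg$normalize$exg_threshold)
  dem <- build_dem(sg$ground, spacing = cfg$normalize$dem_spacing)
  norm <- normalize_cloud(cloud, dem)
  aligned <- align_plot(norm)
  ext_x <- diff(range(aligned$x)); ext_y <- diff(range(aligned$y))
  grid <- make_grid(max(ext_x, cfg$rasterize$spacing),
                    max(ext_y, cfg$rasterize$spacing),
                    cfg$rasterize$spacing,
                    origin = c(min(aligned$x), min(aligned$y)))
  veg <- if ("part" %in% names(aligned)) {
    aligned[aligned$part != "soil", , drop = FALSE]
  } else aligned
  if (!nrow(veg)) veg <- aligned
  raster <- idw_raster(veg, grid,
                       idw_config(k_neighbors = cfg$rasterize$k_neighbors))
  list(normalized = norm, aligned = aligned, raster = raster)
}

#' Run the full lodging-assessment pipeline
#'
#' Executes the configured stages in order, writes per-stage artifacts
#' (per-plot rasters as PNG + ASCII grids, a labelled plot table, the
#' dataset manifest, training history and evaluation metrics) under
#' `out_dir`, and returns the run report (also written as
#' `report.json`).
#'
#' @param config An [pipeline_config()] or path to a YAML file.
#' @return The run report, a named list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "lp_pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  png_dir <- file.path(cfg$out_dir, "rasters")
  dir.create(png_dir, showWarnings = FALSE)
  report <- list(seed = cfg$seed)

  # --- acquire plots --------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    scfg <- field_sim_config(point_density = sim$point_density %||% 120,
                             noise_sigma = sim$noise_sigma %||% 0.02,
                             h1 = sim$h1 %||% 1.0)
    field <- if (identical(sim$mode %||% "bands", "bands")) {
      generate_band_field(scfg, n_plots = sim$n_plots %||% 8L, seed = cfg$seed)
    } else {
      generate_field(scfg, n_plots = sim$n_plots %||% 8L, seed = cfg$seed)
    }
    plots <- crop_plots(field$cloud, field$layout)
    truth <- field$truth
  } else {
    if (!file.exists(cfg$input$cloud)) {
      rlang::abort(paste0("input cloud not found: ", cfg$input$cloud),
                   class = "lp_missing_input")
    }
    cloud <- read_xyz_txt(cfg$input$cloud)
    plots <- crop_plots(cloud, cfg$input$layout)
    truth <- NULL
  }
  report$n_plots <- nrow(plots)

  # --- normalize / align / rasterize per plot -------------------------------
  rasters <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    pr <- process_plot(plots$cloud[[i]], cfg)
    rasters[[i]] <- pr$raster
    img <- render_image(pr$raster, cfg$rasterize$z_min, cfg$rasterize$z_max,
                        cfg$rasterize$colormap)
    write_image_png(img, file.path(png_dir, sprintf("plot_%03d.png",
                                                    plots$plot_id[i])))
    write_ascii_grid(pr$raster,
                     file.path(png_dir, sprintf("plot_%03d.asc",
                                                plots$plot_id[i])))
  }
  report$rasters <- file.path(png_dir, sprintf("plot_%03d.png", plots$plot_id))

  # --- label ----------------------------------------------------------------
  if (!is.null(truth)) {
    thr <- if (!is.null(cfg$label$mu)) {
      lodging_thresholds(mu = cfg$label$mu, alpha = cfg$label$alpha)
    } else {
      lodging_thresholds(truth$li)
    }
    labelled <- truth
    if (!"class" %in% names(labelled)) {
      labelled <- label_plots(labelled, thr)
    }
    utils::write.csv(labelled, file.path(cfg$out_dir, "plot_labels.csv"),
                     row.names = FALSE)
    report$labels <- table(labelled$class)
  }

  # --- classify -------------------------------------------------------------
  if (!is.null(cfg$classify) && !is.null(truth)) {
    cl <- cfg$classify
    size <- cfg$rasterize$image_size %||% 32L
    samples <- dplyr::bind_rows(purrr::map(seq_len(nrow(plots)), function(i) {
      raster_to_sample(rasters[[i]],
                       label = as.character(truth$class[truth$plot_id ==
                                                          plots$plot_id[i]]),
                       source_plot = plots$plot_id[i], size = size,
                       z_min = cfg$rasterize$z_min, z_max = cfg$rasterize$z_max,
                       colormap = cfg$rasterize$colormap)
    }))
    samples <- augment_dataset(samples, cl$augment_total %||% nrow(samples),
                               seed = cfg$seed)
    splits <- split_dataset(samples, seed = cfg$seed)
    manifest <- dplyr::bind_rows(purrr::imap(splits, function(df, nm) {
      tibble::tibble(label = as.character(df$label),
                     source_plot = df$source_plot,
                     augmented = df$augmented, split = nm)
    }))
    utils::write.csv(manifest, file.path(cfg$out_dir, "dataset_manifest.csv"),
                     row.names = FALSE)
    tcfg <- train_config(model_name = cl$model %||% "mobilenetv2",
                         learning_rate = cl$learning_rate %||% 0.001,
                         batch_size = cl$batch_size %||% 4L,
                         max_epochs = cl$max_epochs %||% 5L,
                         patience = cl$patience %||% 3L,
                         seed = cfg$seed, input_size = size,
                         width_mult = cl$width_mult %||% 0.25)
    fit <- train_model(splits$train, splits$validation, tcfg)
    utils::write.csv(fit$history, file.path(cfg$out_dir, "training_history.csv"),
                     row.names = FALSE)
    ev <- evaluate_model(fit$model, splits$test)
    metrics <- glance.lp_eval(ev)
    jsonlite::write_json(as.list(metrics),
                         file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    report$split_sizes <- vapply(splits, nrow, 0L)
    report$metrics <- as.list(metrics)
    report$per_class <- tidy.lp_eval(ev)
  }

  jsonlite::write_json(purrr::map(report, ~ if (inherits(.x, "table"))
    as.list(.x) else if (tibble::is_tibble(.x)) NULL else .x),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
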