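#' Construct a point cloud tibble
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (metres) and, optionally, integer colour columns `r`, `g`, `b` in
#' \[0, 255\]. All package functions accept and return this shape, so point
#' clouds compose with dplyr verbs. Extra columns (e.g. ground-truth labels
#' from the synthetic generator) are carried through untouched.
#'
#' @param x,y,z Numeric coordinate vectors of equal length, metres.
#' @param r,g,b Optional colour channels, integers in \[0, 255\].
#' @param ... Further equal-length columns to carry along.
#' @return A tibble of class `lp_cloud` with one row per point.
#' @examples
#' point_cloud(x = c(0, 1), y = c(0, 0), z = c(0.5, 0.7))
#' @export
point_cloud <- function(x, y, z, r = NULL, g = NULL, b = NULL, ...) {
  pc <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(r) || !is.null(g) || !is.null(b)) {
    if (is.null(r) || is.null(g) || is.null(b)) {
      rlang::abort("supply all of r, g, b or none")
    }
    pc$r <- as.numeric(r); pc$g <- as.numeric(g); pc$b <- as.numeric(b)
  }
  extra <- rlang::list2(...)
  for (nm in names(extra)) pc[[nm]] <- extra[[nm]]
  as_point_cloud(pc)
}

#' Validate and tag a data frame as a point cloud
#'
#' @param df A data frame with columns `x`, `y`, `z` and optionally
#'   `r`, `g`, `b`.
#' @return The validated tibble with class `lp_cloud` prepended.
#' @export
as_point_cloud <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss)) {
    rlang::abort(paste0("point cloud lacks column(s): ", paste(miss, collapse = ", ")))
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) > 0 && !all(is.finite(coords))) {
    rlang::abort("point cloud coordinates must all be finite")
  }
  if (has_colors(df)) {
    cols <- as.matrix(df[, c("r", "g", "b")])
    if (any(!is.finite(cols)) || any(cols < 0) || any(cols > 255)) {
      rlang::abort("point colours must be finite and in [0, 255]")
    }
  }
  class(df) <- unique(c("lp_cloud", class(df)))
  df
}

#' @rdname as_point_cloud
#' @export
has_colors <- function(df) all(c("r", "g", "b") %in% names(df))

#' Read an XYZ text point cloud
#'
#' Reads plain-text clouds with one point per line: 3 columns (`x y z`) or 6
#' (`x y z r g b`). Fields may be separated by whitespace or commas; lines
#' starting with `#` and blank lines are ignored. This tolerant dialect
#' covers TXT exports from common point-cloud software.
#'
#' @param path Path to the text file.
#' @param has_colors `NA` (default) autodetects from the first data line;
#'   `TRUE`/`FALSE` force 6- or 3-column parsing.
#' @return A point cloud tibble; row order follows the file.
#' @export
read_xyz_txt <- function(path, has_colors = NA) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(point_cloud(numeric(), numeric(), numeric()))
  toks <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  arity <- lengths(toks)
  want <- if (is.na(has_colors)) arity[1] else if (isTRUE(has_colors)) 6L else 3L
  if (!want %in% c(3L, 6L)) {
    rlang::abort(paste0("line ", keep[1], ": expected 3 or 6 fields, got ", want))
  }
  bad <- which(arity != want)
  if (length(bad)) {
    rlang::abort(paste0("line ", keep[bad[1]], ": expected ", want,
                        " fields, got ", arity[bad[1]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  nas <- which(is.na(vals))
  if (length(nas)) {
    rlang::abort(paste0("line ", keep[ceiling(nas[1] / want)], ": non-numeric field"))
  }
  m <- matrix(vals, ncol = want, byrow = TRUE)
  if (want == 3L) {
    point_cloud(m[, 1], m[, 2], m[, 3])
  } else {
    point_cloud(m[, 1], m[, 2], m[, 3], r = m[, 4], g = m[, 5], b = m[, 6])
  }
}

#' Write an XYZ text point cloud
#'
#' One point per line, space separated; colours appended as three extra
#' columns when present. Coordinates are written with enough digits for a
#' lossless-to-reading round trip at typical field precision.
#'
#' @param cloud A point cloud tibble (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_txt <- function(cloud, path) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) rlang::abort("refusing to write an empty point cloud")
  cols <- c("x", "y", "z", if (has_colors(cloud)) c("r", "g", "b"))
  m <- as.matrix(cloud[, cols])
  lines <- apply(format(m, digits = 9, trim = TRUE, scientific = FALSE), 1,
                 paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII or binary-little-endian PLY point cloud
#'
#' Convenience reader for PLY files with vertex properties `x y z`
#' (float/double) and optionally `red green blue` (uchar). XYZ text is the
#' normative interchange format; PLY support covers common exports.
#'
#' @param path Path to a `.ply` file.
#' @return A point cloud tibble.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) rlang::abort("PLY header not terminated")
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  if (!identical(trimws(header[1]), "ply")) rlang::abort("not a PLY file")
  fmt <- sub("^format\\s+(\\S+).*$", "\\1", grep("^format", header, value = TRUE)[1])
  elems <- grep("^element", header)
  vline <- grep("^element\\s+vertex", header)
  if (!length(vline)) rlang::abort("PLY file has no vertex element")
  nvert <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*$", "\\1", header[vline[1]]))
  stop_at <- c(elems[elems > vline[1]], length(header))[1]
  props <- header[seq(vline[1] + 1, stop_at - 1)]
  props <- props[grepl("^property", props)]
  ptype <- sub("^property\\s+(\\S+)\\s+\\S+$", "\\1", props)
  pname <- sub("^property\\s+\\S+\\s+(\\S+)$", "\\1", props)
  need <- c("x", "y", "z")
  if (!all(need %in% pname)) rlang::abort("PLY vertex element lacks x/y/z")
  if (identical(fmt, "ascii")) {
    rows <- readLines(con, n = nvert)
    m <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                ncol = length(pname), byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
               int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
               float = 4, float32 = 4, double = 8, float64 = 8)
    sz <- sizes[ptype]
    if (any(is.na(sz))) rlang::abort("unsupported PLY property type")
    m <- matrix(NA_real_, nrow = nvert, ncol = length(pname))
    for (i in seq_len(nvert)) {
      for (j in seq_along(pname)) {
        tp <- ptype[j]
        m[i, j] <- if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", 1, size = sz[j], endian = "little")
        } else {
          readBin(con, "integer", 1, size = sz[j], signed = !grepl("^u", tp),
                  endian = "little")
        }
      }
    }
  } else {
    rlang::abort(paste0("unsupported PLY format: ", fmt))
  }
  colnames(m) <- pname
  if (all(c("red", "green", "blue") %in% pname)) {
    point_cloud(m[, "x"], m[, "y"], m[, "z"],
                r = m[, "red"], g = m[, "green"], b = m[, "blue"])
  } else {
    point_cloud(m[, "x"], m[, "y"], m[, "z"])
  }
}

#' Define a rectangular grid of field plots
#'
#' Describes how a field strip is tiled into equal rectangular plots, e.g.
#' the 3.8 m x 7.8 m wheat plots a field cloud is cut into.
#'
#' @param origin Numeric length-2, `(x0, y0)` of the layout's lower-left
#'   corner, metres.
#' @param plot_length Plot extent along x, metres (> 0).
#' @param plot_width Plot extent along y, metres (> 0).
#' @param n_rows,n_cols Number of plots along y and x (>= 1).
#' @return A `lp_layout` list.
#' @export
plot_layout <- function(origin = c(0, 0), plot_length = 7.8, plot_width = 3.8,
                        n_rows = 1L, n_cols = 1L) {
  stopifnot(length(origin) == 2, is.finite(origin))
  if (plot_length <= 0 || plot_width <= 0) rlang::abort("plot dimensions must be positive")
  if (n_rows < 1 || n_cols < 1) rlang::abort("n_rows and n_cols must be >= 1")
  structure(list(origin = as.numeric(origin),
                 plot_length = as.numeric(plot_length),
                 plot_width = as.numeric(plot_width),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "lp_layout")
}

#' Rectangles of every plot in a layout
#'
#' @param layout A [plot_layout()].
#' @return A tibble with `plot_id`, `x_lo`, `x_hi`, `y_lo`, `y_hi`;
#'   `plot_id` runs row-major (along x first) from the layout origin.
#' @export
layout_rectangles <- function(layout) {
  stopifnot(inherits(layout, "lp_layout"))
  grid <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
  tibble::tibble(
    plot_id = seq_len(nrow(grid)),
    x_lo = layout$origin[1] + (grid$col - 1) * layout$plot_length,
    x_hi = layout$origin[1] + grid$col * layout$plot_length,
    y_lo = layout$origin[2] + (grid$row - 1) * layout$plot_width,
    y_hi = layout$origin[2] + grid$row * layout$plot_width
  )
}

#' Cut a field cloud into per-plot clouds
#'
#' Points are assigned by their (x, y) to half-open plot rectangles
#' `[x_lo, x_hi) x [y_lo, y_hi)` — lower edges inclusive, upper exclusive —
#' so every point lands in at most one plot and shared boundaries are
#' deterministic. Points outside all plots are dropped.
#'
#' @param cloud A point cloud tibble.
#' @param layout A [plot_layout()].
#' @return A tibble with columns `plot_id` and `cloud` (list-column of
#'   per-plot point clouds); plots that received no points are omitted.
#' @export
crop_plots <- function(cloud, layout) {
  cloud <- as_point_cloud(cloud)
  rects <- layout_rectangles(layout)
  if (nrow(cloud) == 0 ||
      max(cloud$x) < min(rects$x_lo) || min(cloud$x) >= max(rects$x_hi) ||
      max(cloud$y) < min(rects$y_lo) || min(cloud$y) >= max(rects$y_hi)) {
    rlang::warn("plot layout does not intersect the point cloud; nothing cropped")
    return(tibble::tibble(plot_id = integer(), cloud = list()))
  }
  col <- floor((cloud$x - layout$origin[1]) / layout$plot_length)
  row <- floor((cloud$y - layout$origin[2]) / layout$plot_width)
  inside <- col >= 0 & col < layout$n_cols & row >= 0 & row < layout$n_rows
  pid <- ifelse(inside, row * layout$n_cols + col + 1, NA_integer_)
  keep <- which(!is.na(pid))
  if (!length(keep)) {
    rlang::warn("no points fall inside the layout")
    return(tibble::tibble(plot_id = integer(), cloud = list()))
  }
  split_idx <- split(keep, pid[keep])
  tibble::tibble(
    plot_id = as.integer(names(split_idx)),
    cloud = purrr::map(split_idx, ~ as_point_cloud(cloud[.x, , drop = FALSE]))
  ) |> dplyr::arrange(.data$plot_id)
}
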