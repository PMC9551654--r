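#' Lodging angle from plant and canopy heights
#'
#' For a stem of sloping length `h1` whose canopy now stands at height `h2`,
#' the lodging angle from the vertical is `theta = 90 - asin(h2 / h1)` in
#' degrees: 0 for upright plants (h2 = h1), 90 for plants flat on the
#' ground (h2 = 0).
#'
#' @param h1 Actual (sloping) plant height, metres; > 0.
#' @param h2 Canopy height, metres; `0 <= h2 <= h1`. Vectorized.
#' @return Lodging angle(s) in degrees.
#' @export
lodging_angle <- function(h1, h2) {
  if (any(h1 <= 0)) rlang::abort("h1 must be positive")
  if (any(h2 < 0 | h2 > h1 + 1e-12)) rlang::abort("h2 must satisfy 0 <= h2 <= h1")
  90 - asin(pmin(h2 / h1, 1)) * 180 / pi
}

#' Lodging-angle score LA
#'
#' `LA = 2 theta / pi` (theta in radians), i.e. the lodging angle as a
#' fraction of a right angle: 0 upright, 1 flat, 2/3 at h2 = h1/2.
#'
#' @inheritParams lodging_angle
#' @return LA in \[0, 1\].
#' @export
lodging_la <- function(h1, h2) {
  lodging_angle(h1, h2) / 90
}

#' Lodging index LI
#'
#' `LI = LA * LR`: severity of lodging combining how far plants lean (LA)
#' with how much of the plot leans (LR, area fraction).
#'
#' @param la Lodging-angle score(s) in \[0, 1\].
#' @param lr Lodged-area fraction(s) in \[0, 1\].
#' @return LI in \[0, 1\].
#' @export
lodging_index <- function(la, lr) {
  if (any(la < 0 | la > 1)) rlang::abort("LA must lie in [0, 1]")
  if (any(lr < 0 | lr > 1)) rlang::abort("LR must lie in [0, 1]")
  la * lr
}

#' Per-plot lodging measurement from field samples
#'
#' Field protocol support: several (h1, h2) sample pairs per plot; the
#' per-sample lodging angles are averaged before LA, then combined with the
#' plot's lodged-area fraction.
#'
#' @param measurements Tibble with columns `plot_id`, `h1`, `h2`, `lr`
#'   (one row per sample; `lr` constant within plot).
#' @return Tibble with one row per plot: `plot_id`, `h1`, `h2`, `theta`,
#'   `la`, `lr`, `li`.
#' @export
measure_plots <- function(measurements) {
  df <- tibble::as_tibble(measurements)
  stopifnot(all(c("plot_id", "h1", "h2", "lr") %in% names(df)))
  df |>
    dplyr::mutate(theta_i = lodging_angle(.data$h1, .data$h2)) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(h1 = mean(.data$h1), h2 = mean(.data$h2),
                     theta = mean(.data$theta_i), lr = .data$lr[1],
                     .groups = "drop") |>
    dplyr::mutate(la = .data$theta / 90,
                  li = lodging_index(.data$la, .data$lr))
}

#' Double-threshold class boundaries from lodging indices
#'
#' The four lodging-degree intervals come from the mean and population
#' standard deviation of LI over plots: cut points at `mu - alpha`, `mu`,
#' `mu + alpha`. Either supply the per-plot LI values, or inject `mu` and
#' `alpha` directly (e.g. survey-derived values 0.40 and 0.274).
#'
#' @param li Numeric vector of per-plot LI values (>= 2 plots), or NULL if
#'   `mu`/`alpha` are given.
#' @param mu,alpha Injected mean / standard deviation of LI.
#' @return An `lp_thresholds` list with `mu`, `alpha` and `boundaries`
#'   `(mu - alpha, mu, mu + alpha)`.
#' @export
lodging_thresholds <- function(li = NULL, mu = NULL, alpha = NULL) {
  if (is.null(mu) != is.null(alpha)) rlang::abort("supply both mu and alpha, or li")
  if (is.null(mu)) {
    if (is.null(li) || length(li) < 2) rlang::abort("need at least 2 LI values")
    if (any(li < 0 | li > 1)) rlang::abort("LI values must lie in [0, 1]")
    mu <- mean(li)
    alpha <- sqrt(mean((li - mu)^2)) # population SD
  }
  if (alpha <= 0) rlang::abort("degenerate thresholds: alpha must be positive")
  b <- c(mu - alpha, mu, mu + alpha)
  if (b[1] < 0 || b[3] > 1) {
    rlang::abort(sprintf(
      "boundaries (%.3f, %.3f, %.3f) fall outside [0, 1]; the double-threshold scheme needs 0 <= mu - alpha and mu + alpha <= 1",
      b[1], b[2], b[3]))
  }
  structure(list(mu = mu, alpha = alpha, boundaries = b), class = "lp_thresholds")
}

#' @export
print.lp_thresholds <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("Lodging-degree thresholds (mu = %.3f, alpha = %.3f)\n", x$mu, x$alpha))
  cat(sprintf("  non-lodging [0, %.3f)  slight [%.3f, %.3f)  moderate [%.3f, %.3f)  severe [%.3f, 1]\n",
              b[1], b[1], b[2], b[2], b[3], b[3]))
  invisible(x)
}

#' Lodging degree classes
#'
#' @return Character vector of the four classes in severity order.
#' @export
lodging_classes <- function() c("non_lodging", "slight", "moderate", "severe")

#' Classify lodging indices into the four degrees
#'
#' Intervals are half-open on the right (a boundary value belongs to the
#' more severe class), the last closed at 1: non-lodging `[0, mu-alpha)`,
#' slight `[mu-alpha, mu)`, moderate `[mu, mu+alpha)`, severe `[mu+alpha, 1]`.
#'
#' @param li LI value(s) in \[0, 1\].
#' @param thresholds An [lodging_thresholds()] object.
#' @return Ordered factor with levels [lodging_classes()].
#' @export
classify_li <- function(li, thresholds) {
  stopifnot(inherits(thresholds, "lp_thresholds"))
  if (any(li < 0 | li > 1)) rlang::abort("LI must lie in [0, 1]")
  idx <- findInterval(li, thresholds$boundaries, left.open = FALSE) + 1L
  factor(lodging_classes()[idx], levels = lodging_classes(), ordered = TRUE)
}

#' Label a table of plot measurements with lodging degrees
#'
#' @param plots Tibble with column `li` (e.g. from [measure_plots()]).
#' @param thresholds [lodging_thresholds()]; default recomputed from the
#'   table's own LI values.
#' @return `plots` with a `class` factor column appended.
#' @export
label_plots <- function(plots, thresholds = NULL) {
  df <- tibble::as_tibble(plots)
  stopifnot("li" %in% names(df))
  if (is.null(thresholds)) thresholds <- lodging_thresholds(df$li)
  dplyr::mutate(df, class = classify_li(.data$li, thresholds))
}
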