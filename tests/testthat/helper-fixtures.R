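# Shared fixtures: small deterministic clouds and images built in code.

# n random points in a box, optionally coloured; seeded.
random_cloud <- function(n, seed = 1, xlim = c(0, 2), ylim = c(0, 3),
                         zlim = c(0, 1), colors = FALSE) {
  set.seed(seed)
  pc <- if (colors) {
    point_cloud(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2]),
                runif(n, zlim[1], zlim[2]),
                r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
                b = sample(0:255, n, TRUE))
  } else {
    point_cloud(runif(n, xlim[1], xlim[2]), runif(n, ylim[1], ylim[2]),
                runif(n, zlim[1], zlim[2]))
  }
  pc
}

# rotation matrix about axis by angle (radians)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * outer(a, a)
}

# solid-colour image sample set for classifier contract tests
solid_image_samples <- function(n_per_class, size = 16, means = c(0.2, 0.8),
                                seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_along(means)) {
    for (i in seq_len(n_per_class)) {
      img <- array(means[ci] + rnorm(size * size * 3, 0, 0.03),
                   c(size, size, 3))
      rows[[length(rows) + 1]] <- tibble::tibble(
        image = list(img), label = paste0("class", ci),
        source_plot = NA_integer_, augmented = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

# random labelled images (content uninformative) for split/augment tests
random_image_samples <- function(n, classes = 4, size = 8, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n), function(i) tibble::tibble(
    image = list(array(runif(size * size * 3), c(size, size, 3))),
    label = paste0("c", 1 + (i - 1) %% classes),
    source_plot = i, augmented = FALSE)))
}
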