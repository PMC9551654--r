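test_that("xyz text files parse, round-trip and reject malformed lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "0 0 0", "1 0 0", "0, 1, 2"), path)
  pc <- read_xyz_txt(path)
  expect_equal(nrow(pc), 3)
  expect_equal(pc$z, c(0, 0, 2))

  cloud <- random_cloud(50, seed = 3, colors = TRUE)
  out <- withr::local_tempfile(fileext = ".txt")
  write_xyz_txt(cloud, out)
  back <- read_xyz_txt(out)
  expect_true(has_colors(back))
  expect_equal(back$x, cloud$x, tolerance = 1e-6)
  expect_equal(back$z, cloud$z, tolerance = 1e-6)
  expect_equal(back$g, cloud$g)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0", "1 2"), bad)
  expect_error(read_xyz_txt(bad), "line 2")
  expect_error(read_xyz_txt(file.path(tempdir(), "nope.txt")), "not found")
  expect_error(write_xyz_txt(point_cloud(numeric(), numeric(), numeric()),
                             out), "empty")
})

test_that("point cloud invariants are enforced", {
  expect_error(point_cloud(c(0, NA), c(0, 0), c(0, 0)), "finite")
  expect_error(point_cloud(0, 0, 0, r = 300, g = 0, b = 0), "255")
  pc <- point_cloud(1.5, 2.5, 0.25)
  path <- withr::local_tempfile(fileext = ".txt")
  write_xyz_txt(pc, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("ascii PLY files read back coordinates and colours", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header", "0.5 1.5 0.25 10 200 30", "1 2 3 0 0 0"), path)
  pc <- read_ply(path)
  expect_equal(pc$x, c(0.5, 1))
  expect_equal(pc$g, c(200, 0))
})

test_that("crop_plots conserves points and uses half-open rectangles", {
  layout <- plot_layout(origin = c(0, 0), plot_length = 1, plot_width = 1,
                        n_rows = 1, n_cols = 2)
  pc <- point_cloud(c(runif(10, 0, 1), runif(7, 1, 2)), runif(17), runif(17))
  plots <- crop_plots(pc, layout)
  expect_equal(plots$plot_id, c(1L, 2L))
  expect_equal(unname(sapply(plots$cloud, nrow)), c(10L, 7L))

  # boundary point x = 1 belongs to plot 2 only
  edge <- point_cloud(1, 0.5, 0)
  pe <- crop_plots(edge, layout)
  expect_equal(pe$plot_id, 2L)

  # nothing inside -> warning and empty result
  far <- point_cloud(10, 10, 0)
  expect_warning(res <- crop_plots(far, layout), "intersect|inside")
  expect_equal(nrow(res), 0)
})

test_that("crop_plots matches a brute-force point-in-rectangle scan", {
  layout <- plot_layout(origin = c(-1, 0.5), plot_length = 1.3,
                        plot_width = 0.9, n_rows = 3, n_cols = 2)
  set.seed(42)
  pc <- point_cloud(runif(1000, -2, 3), runif(1000, 0, 4), runif(1000))
  plots <- crop_plots(pc, layout)
  rects <- layout_rectangles(layout)
  brute <- vapply(seq_len(nrow(rects)), function(i) {
    sum(pc$x >= rects$x_lo[i] & pc$x < rects$x_hi[i] &
          pc$y >= rects$y_lo[i] & pc$y < rects$y_hi[i])
  }, 0L)
  got <- integer(nrow(rects))
  got[plots$plot_id] <- vapply(plots$cloud, nrow, 0L)
  expect_equal(got, brute)
  expect_lte(sum(got), nrow(pc))
})
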