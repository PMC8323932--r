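# Probe geometry, pseudo-AFM rendering, noise and height-map I/O.

test_that("tip contact height closed forms are geometrically consistent", {
  # on-axis contact: apex rests on top of the atom sphere
  expect_equal(tip_height_over_atom(probe_shape(1, 10), 0, 0.5, 0), 0.5)

  # sphere and cone branches agree at the regime boundary
  for (ang in c(5, 20, 45)) {
    p <- probe_shape(2, ang)
    R <- 2 + 0.15
    d0 <- R * cos(ang * pi / 180)
    expect_equal(tip_height_over_atom(p, 1, 0.15, d0),
                 1 + R * sin(ang * pi / 180) - 2, tolerance = 1e-12)
  }

  # spot checks against the brute-force surface-descent oracle
  p <- probe_shape(2, 20)
  for (case in list(c(1, 0.15, 3), c(0.8, 0.15, 0.7), c(2.5, 0.3, 4.5))) {
    expect_equal(tip_height_over_atom(p, case[1], case[2], case[3]),
                 descent_tip_height(p, case[1], case[2], case[3]),
                 tolerance = 1e-6)
  }
  expect_error(tip_height_over_atom(p, 1, 0.15, -1), ">= 0")
})

test_that("rendering reproduces the per-pixel collision loop", {
  m <- ground_on_stage(make_blob(40, c(6, 4, 2), seed = 2, radius = 0.25))
  p <- probe_shape(1.5, 25)
  img <- render_afm(m, p, 0.5)
  expect_identical(img$heights, naive_render(m, p, img))
  expect_true(all(img$heights >= 0))

  # empty model and single-atom cases
  empty <- afm_model(matrix(numeric(0), 0, 3), numeric(0))
  expect_true(all(render_afm(empty, p, 1)$heights == 0))

  one <- afm_model(matrix(c(0, 0, 1.0), 1), 0.3)
  fine <- render_afm(one, p, 0.05)
  # on-axis maximum: atom top height, within half-pixel lateral quantization
  expect_lt(abs(max(fine$heights) - 1.3), 0.005)
  expect_error(render_afm(one, p, -1), "pixel_size")
})

test_that("rendered heights grow monotonically with probe size", {
  m <- ground_on_stage(make_blob(30, c(5, 3, 2), seed = 4, radius = 0.25))
  frame <- list(origin = c(-8, -8), nx = 32, ny = 32)
  h1 <- render_afm(m, probe_shape(1, 15), 0.5, frame = frame)$heights
  h2 <- render_afm(m, probe_shape(3, 15), 0.5, frame = frame)$heights
  h3 <- render_afm(m, probe_shape(3, 30), 0.5, frame = frame)$heights
  expect_true(all(h2 - h1 >= -1e-12))  # dilation in radius
  expect_true(all(h3 - h2 >= -1e-12))  # dilation in angle

  # large blunt probe over a single small atom: sphere regime only,
  # image top approaches the atom top height
  one <- afm_model(matrix(c(0, 0, 0.5), 1), 0.2)
  big <- render_afm(one, probe_shape(50, 10), 0.02)
  expect_lt(abs(max(big$heights) - 0.7), 1e-4)
})

test_that("rendering is equivariant under integer-pixel translation", {
  m <- ground_on_stage(make_blob(30, c(5, 3, 2), seed = 6, radius = 0.25))
  frame <- list(origin = c(-10, -10), nx = 40, ny = 40)
  h0 <- render_afm(m, probe_shape(2, 15), 0.5, frame = frame)$heights
  sh <- transform_model(m, translation = c(3 * 0.5, 2 * 0.5, 0))
  h1 <- render_afm(sh, probe_shape(2, 15), 0.5, frame = frame)$heights
  expect_equal(h1[(1 + 2):40, (1 + 3):40], h0[1:(40 - 2), 1:(40 - 3)],
               tolerance = 1e-12)
})

test_that("gaussian pixel noise is calibrated, seeded and unclipped", {
  img <- afm_image(matrix(0, 200, 200), 1)
  expect_identical(add_noise(img, 0), img)
  n1 <- add_noise(img, 0.3, seed = 42)
  n2 <- add_noise(img, 0.3, seed = 42)
  expect_identical(n1$heights, n2$heights)
  expect_gt(sd(n1$heights), 0.29)
  expect_lt(sd(n1$heights), 0.31)
  expect_lt(min(n1$heights), 0)  # no clipping at the stage
  # caller's RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(add_noise(img, 0.3, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("height maps round-trip through the text format", {
  set.seed(8)
  img <- afm_image(matrix(runif(30, 0, 4), 5, 6), pixel_size = 0.8,
                   origin = c(-2, 1.5))
  path <- tempfile(fileext = ".tsv")
  write_afm_image(img, path)
  back <- read_afm_image(path)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(back$origin, img$origin)
  expect_lt(max(abs(back$heights - img$heights)), 1e-4)
  # a written file reloads and rewrites bit-identically
  path2 <- tempfile(fileext = ".tsv")
  write_afm_image(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # comma-separated bodies are accepted
  pathc <- tempfile(fileext = ".csv")
  writeLines(c("# pixel_size_nm=2", "1,2", "3,4"), pathc)
  expect_equal(read_afm_image(pathc)$heights, matrix(c(1, 3, 2, 4), 2))
})
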