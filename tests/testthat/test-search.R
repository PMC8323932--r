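# Orientation/translation/Z grids and the exhaustive fit.

test_that("sphere directions follow the ring construction", {
  d90 <- sphere_directions(90)
  expect_equal(nrow(d90), 6)  # octahedron: 2 poles + 4 on the equator
  want <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0))
  match_dist <- sapply(seq_len(6), function(i)
    min(sqrt(rowSums(sweep(d90, 2, want[i, ])^2))))
  expect_lt(max(match_dist), 1e-12)

  d10 <- sphere_directions(10)
  expect_equal(nrow(d10), 2 + 4 * sum(1:17))  # 614
  expect_lt(max(abs(sqrt(rowSums(d10^2)) - 1)), 1e-12)

  # equatorial ring is divided at exactly the step spacing
  eq <- d10[abs(d10[, 3]) < 1e-12, , drop = FALSE]
  expect_equal(nrow(eq), 36)
  az <- sort((atan2(eq[, 2], eq[, 1]) * 180 / pi) %% 360)
  expect_equal(diff(az), rep(10, 35))

  # literal n-per-ring scheme kept for comparison
  expect_equal(nrow(sphere_directions(10, ring_scheme = "n")),
               2 + sum(1:17))
  expect_error(sphere_directions(7), "multiple of 4")
  expect_error(sphere_directions(120), "multiple of 4")
})

test_that("orientation grids have the expected size and are proper", {
  g90 <- orientation_grid(90)
  expect_equal(dim(g90)[3], 24)  # the rotational octahedral group
  for (k in seq_len(24)) {
    R <- g90[, , k]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # all 24 are distinct
  flat <- apply(g90, 3, function(R) paste(round(R, 9), collapse = ","))
  expect_equal(length(unique(flat)), 24)

  g10 <- orientation_grid(10)
  expect_equal(dim(g10)[3], 614 * 36)
  set.seed(31)
  for (k in sample(dim(g10)[3], 20)) {
    R <- g10[, , k]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_gt(det(R), 0)
  }
})

test_that("translation grid counts all in-frame placements", {
  win <- function(nr, nc, h, w) {
    s <- matrix(0, nr, nc); s[1:h, 1:w] <- 1; s
  }
  expect_equal(nrow(translation_grid(win(3, 3, 3, 3), matrix(0, 5, 5))), 9)
  expect_equal(nrow(translation_grid(win(4, 4, 4, 4), matrix(0, 4, 4))), 1)
  expect_equal(nrow(translation_grid(win(6, 4, 4, 2), matrix(0, 10, 6))),
               (10 - 4 + 1) * (6 - 2 + 1))
  expect_warning(g <- translation_grid(win(4, 4, 4, 4), matrix(0, 3, 3)),
                 "larger")
  expect_equal(nrow(g), 0)
})

test_that("z offsets trigger only when the reference is taller", {
  expect_equal(z_offsets(matrix(5), matrix(4)), 0)
  expect_equal(z_offsets(matrix(4), matrix(4)), 0)
  expect_equal(z_offsets(matrix(4), matrix(4.2), step = 0.064),
               c(0, 0.064, 0.128, 0.192))
  expect_error(z_offsets(matrix(1), matrix(2), step = 0), "> 0")
})

test_that("noiseless on-grid self-fit is recovered exactly", {
  m <- ground_on_stage(make_blob(40, c(6, 4, 2), seed = 12, radius = 0.3))
  probe <- probe_shape(2, 15)
  ref <- render_afm(m, probe, 1, margin = 2)
  fit <- exhaustive_fit(m, ref,
                        probes = probe_grid(radii = c(1, 2),
                                            angles = c(15, 25)),
                        score = "cosine", angle_step = 90, top_k = 5)
  best <- fit$top[1, ]
  expect_equal(best$cost, 0, tolerance = 1e-12)
  expect_equal(best$radius, 2)
  expect_equal(best$angle, 15)
  expect_lt(structure_rmsd(apply_fit(fit), m), 1e-9)
  # ranked costs are non-decreasing
  expect_true(all(diff(fit$top$cost) >= 0))
  # rendering the fit reproduces the reference exactly
  expect_lt(max(abs(render_fit(fit)$heights - ref$heights)), 1e-9)
})

test_that("exhaustive fit equals the naive quadruple-loop oracle", {
  m <- ground_on_stage(make_blob(12, c(2.5, 2, 1.2), seed = 13,
                                 radius = 0.3))
  ref_model <- ground_on_stage(transform_model(m, rot_z(45)))
  clean <- render_afm(ref_model, probe_shape(1, 15), 1,
                      frame = list(origin = c(-4, -4), nx = 8, ny = 8))
  ref <- add_noise(clean, 0.3, seed = 5)
  probes <- probe_grid(radii = c(1, 2), angles = 15)

  for (sc in c("cosine", "correlation", "pixel_rmsd", "penalty")) {
    fit <- exhaustive_fit(m, ref, probes = probes, score = sc,
                          angle_step = 90, top_k = 1)
    oracle <- naive_fit(m, ref, probes, 90, 0.064, sc)
    got <- matrix(fit$results$cost, nrow = dim(fit$rotations)[3],
                  byrow = TRUE)
    expect_equal(got, oracle$costs, tolerance = 1e-10)
    best <- fit$top[1, ]
    expect_equal(best$cost, oracle$best$cost, tolerance = 1e-10)
    expect_equal(best$orientation, oracle$best$orientation)
    expect_equal(best$probe, oracle$best$probe)
    expect_equal(best$off_row, oracle$best$off_row)
    expect_equal(best$off_col, oracle$best$off_col)
    expect_equal(best$z_idx, oracle$best$z_idx)
  }
})

test_that("fit respects the score invariances of the reference image", {
  m <- ground_on_stage(make_blob(25, c(5, 3, 2), seed = 14, radius = 0.3))
  ref <- add_noise(render_afm(m, probe_shape(1.5, 20), 1, margin = 2),
                   0.2, seed = 9)
  probes <- probe_grid(radii = c(1, 1.5, 3), angles = 20)

  # scaling the reference leaves the cosine argmin unchanged
  f1 <- exhaustive_fit(m, ref, probes = probes, score = "cosine",
                       angle_step = 90)
  ref_s <- afm_image(2.5 * ref$heights, ref$pixel_size, ref$origin)
  f2 <- exhaustive_fit(m, ref_s, probes = probes, score = "cosine",
                       angle_step = 90)
  expect_equal(f1$top[1, c("orientation", "probe", "off_row", "off_col")],
               f2$top[1, c("orientation", "probe", "off_row", "off_col")])

  # adding a constant leaves correlation-based results unchanged
  f3 <- exhaustive_fit(m, ref, probes = probes, score = "correlation",
                       angle_step = 90)
  ref_c <- afm_image(ref$heights + 1.7, ref$pixel_size, ref$origin)
  f4 <- exhaustive_fit(m, ref_c, probes = probes, score = "correlation",
                       angle_step = 90)
  expect_equal(f3$top[1, c("orientation", "probe", "off_row", "off_col")],
               f4$top[1, c("orientation", "probe", "off_row", "off_col")])
  expect_equal(f3$top$cost[1], f4$top$cost[1], tolerance = 1e-9)

  # determinism: identical calls give identical tables
  expect_identical(f1$results, exhaustive_fit(m, ref, probes = probes,
                                              score = "cosine",
                                              angle_step = 90)$results)
})
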