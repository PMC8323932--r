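# Structure reading, grounding, transforms and structure-RMSD.

pdb_line <- function(eleno, elety, resno, x, y, z, elem = "C",
                     type = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, "ALA", "A", resno, x, y, z, 1, 0, elem)
}

write_mini_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB reading converts angstrom to nm and assigns radii", {
  path <- write_mini_pdb(pdb_line(1, "C", 1, 10, 0, 0))
  m <- read_structure(path)
  expect_equal(unname(m$xyz[1, ]), c(1, 0, 0))
  expect_equal(m$radii, 0.170)

  m2 <- read_structure(path, radius_scheme = "uniform",
                       uniform_radius = 0.2)
  expect_equal(m2$radii, 0.2)

  # per-element van der Waals radii
  path3 <- write_mini_pdb(c(pdb_line(1, "N", 1, 0, 0, 0, "N"),
                            pdb_line(2, "O", 1, 1, 0, 0, "O"),
                            pdb_line(3, "SG", 1, 2, 0, 0, "S")))
  m3 <- read_structure(path3)
  expect_equal(m3$radii, c(0.155, 0.152, 0.180))
})

test_that("three-atom centroid matches hand arithmetic and waters drop", {
  path <- write_mini_pdb(c(pdb_line(1, "C", 1, 0, 0, 0),
                           pdb_line(2, "C", 1, 3, 0, 0),
                           pdb_line(3, "C", 1, 0, 6, 3)))
  m <- read_structure(path)
  expect_equal(unname(colMeans(m$xyz)), c(0.1, 0.2, 0.1))

  wat <- sub("ALA", "HOH", sub("ATOM  ", "HETATM",
                               pdb_line(4, "O", 2, 9, 9, 9, "O")))
  mw <- read_structure(write_mini_pdb(c(pdb_line(1, "C", 1, 0, 0, 0), wat)))
  expect_equal(n_atoms(mw), 1L)

  empty <- write_mini_pdb(sub("ALA", "HOH", sub("ATOM  ", "HETATM",
                                                pdb_line(1, "O", 1, 0, 0, 0,
                                                         "O"))))
  expect_error(read_structure(empty), "empty")
})

test_that("structure round-trips through PDB at coordinate precision", {
  set.seed(42)
  m <- make_blob(25, c(5, 3, 2), seed = 5)
  path <- tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- read_structure(path, radius_scheme = "uniform",
                       uniform_radius = 0.2)
  expect_lt(max(abs(m2$xyz - m$xyz)), 1e-4)  # 1e-3 angstrom
})

box_points <- function(ext) {
  g <- as.matrix(expand.grid(x = seq(-ext[1] / 2, ext[1] / 2, length.out = 5),
                             y = seq(-ext[2] / 2, ext[2] / 2, length.out = 4),
                             z = seq(-ext[3] / 2, ext[3] / 2, length.out = 3)))
  afm_model(g, rep(0.1, nrow(g)))
}

test_that("grounding lays the largest OBB face on the stage", {
  # a 4 x 2 x 1 box standing on its 2 x 1 face
  standing <- transform_model(box_points(c(4, 2, 1)), rot_y(90))
  g <- ground_on_stage(standing)
  ext <- apply(g$xyz, 2, function(v) diff(range(v)))
  expect_equal(unname(ext), c(4, 2, 1), tolerance = 1e-9)
  expect_equal(min(g$xyz[, 3] - g$radii), 0, tolerance = 1e-12)
})

test_that("grounding is idempotent and sorts extents for a random box", {
  set.seed(7)
  b <- box_points(c(6, 3, 1.5))
  rb <- transform_model(b, rot_x(37) %*% rot_y(111) %*% rot_z(205))
  g1 <- ground_on_stage(rb)
  g2 <- ground_on_stage(g1)
  expect_lt(max(abs(g1$xyz - g2$xyz)), 1e-9)
  ext <- apply(g1$xyz, 2, function(v) diff(range(v)))
  expect_equal(unname(ext), unname(sort(ext, decreasing = TRUE)),
               tolerance = 1e-9)

  line <- afm_model(cbind(1:5, 0, 0), rep(0.1, 5))
  expect_error(ground_on_stage(line), "degenerate")
})

test_that("structure RMSD matches hand values and a loop oracle", {
  m <- make_blob(20, seed = 3)
  expect_equal(structure_rmsd(m, m), 0)
  t1 <- transform_model(m, translation = c(0.3, 0.4, 0))
  expect_equal(structure_rmsd(m, t1), 0.5)

  set.seed(11)
  b <- afm_model(m$xyz + matrix(rnorm(60, 0, 0.4), ncol = 3), m$radii)
  loop <- sqrt(mean(sapply(seq_len(20), function(i)
    sum((m$xyz[i, ] - b$xyz[i, ])^2))))
  expect_equal(structure_rmsd(m, b), loop)

  # translation covariance: rmsd(a + t, b + t) = rmsd(a, b)
  t <- c(1.2, -0.7, 3.1)
  expect_equal(structure_rmsd(transform_model(m, translation = t),
                              transform_model(b, translation = t)),
               structure_rmsd(m, b))

  expect_error(structure_rmsd(m, make_blob(5, seed = 1)), "differ")
})

test_that("windowed filament RMSD scans all registrations", {
  mono <- make_blob(8, c(2, 1.5, 1.2), seed = 9)
  truth <- make_filament(mono, 7, rise = 2, twist = 0, ground = FALSE)
  first <- afm_model(truth$xyz[1:24, ], truth$radii[1:24])
  last <- afm_model(truth$xyz[33:56, ], truth$radii[33:56])
  expect_equal(windowed_filament_rmsd(first, truth, 8), 0)
  expect_equal(windowed_filament_rmsd(last, truth, 8), 0)

  # off-register prediction: equals an explicit window loop
  pred <- transform_model(first, translation = c(0, 0, 1))
  loop <- min(sapply(0:4, function(s) {
    idx <- (s * 8 + 1):((s + 3) * 8)
    sqrt(mean(rowSums((pred$xyz - truth$xyz[idx, ])^2)))
  }))
  expect_equal(windowed_filament_rmsd(pred, truth, 8), loop)

  expect_error(windowed_filament_rmsd(truth, first, 8), "longer")
})
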