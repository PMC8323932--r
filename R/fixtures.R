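# Synthetic ground-truth generators: every module is testable without any
# structure download.

#' Synthetic anisotropic blob model
#'
#' A reproducible cluster of spherical atoms sampled uniformly inside an
#' ellipsoid of the requested extents, with a mild shear along X so the
#' shape is asymmetric and orientation recovery is non-degenerate.  Stands
#' in for globular test proteins in twin experiments.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param extent full extents (nm) along the three principal directions.
#' @param seed integer seed; the generator is seed-deterministic.
#' @param radius per-atom collision radius in nm.
#' @return An [afm_model].
#' @export
make_blob <- function(n_atoms = 60, extent = c(8, 4, 2), seed = 1,
                      radius = 0.2) {
  stopifnot(n_atoms >= 1)
  half <- extent / 2
  xyz <- with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n_atoms) {
      cand <- matrix(runif(3 * n_atoms * 2, -1, 1), ncol = 3)
      keep <- rowSums(cand^2) <= 1
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n_atoms), , drop = FALSE]
    if (n_atoms > 1) {  # normalize the sampled ranges to the extents
      for (k in 1:3) {
        rg <- range(pts[, k])
        pts[, k] <- if (diff(rg) > 0)
          (pts[, k] - mean(rg)) / diff(rg) * 2 else pts[, k]
      }
    }
    pts <- sweep(pts, 2, half, "*")
    # shear makes the blob chiral/asymmetric
    pts[, 3] <- pts[, 3] + 0.15 * half[3] * pts[, 1] / max(half[1], 1e-9)
    pts
  })
  afm_model(xyz, rep(radius, n_atoms))
}

#' Synthetic helical filament model
#'
#' Helical repetition of a monomer about the Z axis (per-unit rise and
#' twist), then grounded on the stage.  Default parameters give an
#' actin-like scale (2.75 nm rise, -166.7 degree twist) but the model is
#' purely synthetic; no structural fidelity is claimed.  With a chiral
#' monomer the two filament ends are distinguishable.
#'
#' @param monomer an [afm_model] used as the repeating unit.
#' @param n_units number of monomers (>= 1).
#' @param rise axial rise per unit in nm.
#' @param twist rotation per unit in degrees.
#' @param ground ground the filament on the stage after stacking.
#' @return An [afm_model] with `n_units * n_atoms(monomer)` atoms, ordered
#'   unit by unit.
#' @export
make_filament <- function(monomer, n_units, rise = 2.75, twist = -166.7,
                          ground = TRUE) {
  stopifnot(n_units >= 1)
  units <- lapply(seq_len(n_units) - 1L, function(k)
    transform_model(monomer, rot_z(k * twist), c(0, 0, k * rise))$xyz)
  mod <- afm_model(do.call(rbind, units),
                   rep(monomer$radii, n_units))
  if (ground && n_units * nrow(monomer$xyz) >= 3)
    mod <- ground_on_stage(mod)
  mod
}

#' Synthetic reference AFM image with known ground truth
#'
#' Grounds the model, renders it with the given probe (with a zero-height
#' margin so the translational search has room), and adds Gaussian pixel
#' noise.  The ground truth (grounded model, probe, seed) is returned
#' alongside the image so twin experiments can score recovery.
#'
#' @param model an [afm_model].
#' @param probe the ground-truth [probe_shape].
#' @param pixel_size pixel edge in nm.
#' @param noise_sd Gaussian pixel noise sd in nm (0.3 nm is the typical
#'   level measured in high-speed AFM backgrounds).
#' @param seed integer seed for the noise.
#' @param margin zero-height margin in pixels around the rendered
#'   footprint.
#' @return A list of class `afm_reference`: `image` (noisy [afm_image]),
#'   `clean` (noise-free render) and `truth` (list: grounded `model`,
#'   `probe`, `noise_sd`, `seed`).
#' @export
make_reference <- function(model, probe, pixel_size = 1, noise_sd = 0.3,
                           seed = 1, margin = 2) {
  grounded <- ground_on_stage(model)
  clean <- render_afm(grounded, probe, pixel_size, margin = margin)
  noisy <- add_noise(clean, noise_sd, seed = seed)
  structure(list(image = noisy, clean = clean,
                 truth = list(model = grounded, probe = probe,
                              noise_sd = noise_sd, seed = seed)),
            class = "afm_reference")
}

#' Write / read a ground-truth record
#'
#' Stores the ground truth of a synthetic reference (probe shape, grounding
#' transform as a quaternion + translation, noise sd, seed) as a small JSON
#' file, so a reference image on disk can be traced back to its generator.
#'
#' @param ref an `afm_reference` from [make_reference].
#' @param path JSON file path.
#' @return `write_truth_record` invisibly returns `path`;
#'   `read_truth_record` returns the record list.
#' @export
write_truth_record <- function(ref, path) {
  tr <- attr(ref$truth$model, "transform")
  rec <- list(probe_radius_nm = ref$truth$probe$radius,
              probe_angle_deg = ref$truth$probe$angle,
              noise_sd_nm = ref$truth$noise_sd,
              seed = ref$truth$seed,
              quaternion = if (!is.null(tr))
                rotation_to_quaternion(tr$rotation) else c(1, 0, 0, 0),
              translation_nm = if (!is.null(tr)) tr$translation
                               else c(0, 0, 0))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Rotation matrix to unit quaternion
#'
#' @param R a 3 x 3 proper rotation matrix.
#' @return Numeric `(w, x, y, z)` with `w >= 0`.
#' @export
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}
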