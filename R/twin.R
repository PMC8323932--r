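# Twin-experiment harness: generate a synthetic "experimental" image with
# known ground truth, run the exhaustive fit, and score recovery.

#' Run a twin experiment
#'
#' The model is grounded by its oriented bounding box and rendered with the
#' ground-truth probe; each replicate adds an independent Gaussian noise
#' realization, randomly re-orients the search template about the X, Y and
#' Z axes (so the exact truth orientation is off the search grid), runs
#' [exhaustive_fit], and records the globally best probe shape, its cost
#' and the structure-RMSD of the placed template against the ground truth.
#'
#' @param model ground-truth [afm_model].
#' @param truth_probe ground-truth [probe_shape].
#' @param pixel_size pixel edge in nm.
#' @param n_replicates number of independent noise realizations.
#' @param noise_sd Gaussian pixel noise sd in nm.
#' @param score cost function name (see [exhaustive_fit]).
#' @param probes probe search grid, as from [probe_grid].
#' @param angle_step orientation step in degrees.
#' @param z_step Z-offset step in nm.
#' @param seed base seed; replicate i uses `seed + i` for its noise and
#'   `seed + 10000 + i` for its template perturbation.
#' @param template structure fitted into the image; defaults to `model`.
#'   When it is a sub-filament of `model`, give `atoms_per_monomer` so the
#'   windowed structure-RMSD is used.
#' @param atoms_per_monomer atoms per monomer for
#'   [windowed_filament_rmsd]; `NULL` for plain [structure_rmsd].
#' @param perturb randomly re-orient the template per replicate (the
#'   production protocol).  Set `FALSE` to keep the truth placement on the
#'   search grid, e.g. for noiseless self-consistency checks.
#' @param margin zero-height margin (pixels) around the reference render.
#' @param ring_scheme azimuth rule of [sphere_directions].
#' @return An object of class `twin_report`: data.frame with one row per
#'   replicate (best probe radius/angle, cost, structure-RMSD, recovered
#'   flag) and attributes `truth_probe` and `n_replicates`.
#' @export
run_twin <- function(model, truth_probe, pixel_size = 1, n_replicates = 10,
                     noise_sd = 0.3,
                     score = c("cosine", "correlation", "pixel_rmsd",
                               "penalty"),
                     probes = probe_grid(), angle_step = 10,
                     z_step = 0.064, seed = 1, template = NULL,
                     atoms_per_monomer = NULL, perturb = TRUE,
                     margin = 2, ring_scheme = "4n") {
  score <- match.arg(score)
  template <- template %||% model
  truth <- ground_on_stage(model)
  clean <- render_afm(truth, truth_probe, pixel_size, margin = margin)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    ref <- add_noise(clean, noise_sd, seed = seed + i)
    tmpl <- if (perturb) {
      pert <- with_seed(seed + 10000 + i,
                        rot_z(runif(1, 0, 360)) %*%
                          rot_y(runif(1, 0, 360)) %*%
                          rot_x(runif(1, 0, 360)))
      transform_model(template, pert)
    } else if (identical(template, model)) truth else template
    fit <- exhaustive_fit(tmpl, ref, probes = probes, score = score,
                          angle_step = angle_step, z_step = z_step,
                          top_k = 1, ring_scheme = ring_scheme)
    best <- fit$top[1, ]
    placed <- apply_fit(fit, rank = 1)
    rmsd <- if (is.null(atoms_per_monomer))
      structure_rmsd(placed, truth)
    else
      windowed_filament_rmsd(placed, truth, atoms_per_monomer)
    rows[[i]] <- data.frame(replicate = i, radius = best$radius,
                            angle = best$angle, cost = best$cost,
                            structure_rmsd = rmsd,
                            recovered = best$radius == truth_probe$radius &
                              best$angle == truth_probe$angle)
  }
  rep <- do.call(rbind, rows)
  structure(rep, class = c("twin_report", "data.frame"),
            truth_probe = truth_probe, n_replicates = n_replicates,
            score = score)
}

#' @export
print.twin_report <- function(x, ...) {
  tp <- attr(x, "truth_probe")
  cat(sprintf(
    "twin_report (%s): truth %.2f nm / %.0f deg; probe recovered %d / %d\n",
    attr(x, "score"), tp$radius, tp$angle, recovery_count(x),
    attr(x, "n_replicates")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Probe recovery count of a twin report
#'
#' Number of replicates whose globally best probe equals the ground-truth
#' probe (exact grid-cell equality on both radius and angle).
#'
#' @param report a `twin_report`.
#' @param truth_probe override the stored ground-truth probe.
#' @return Integer count.
#' @export
recovery_count <- function(report, truth_probe = NULL) {
  tp <- truth_probe %||% attr(report, "truth_probe")
  sum(report$radius == tp$radius & report$angle == tp$angle)
}

#' Radius recovery count of a twin report
#'
#' Like [recovery_count] but comparing only the tip radius, the quantity
#' most robustly recovered in twin experiments.
#'
#' @inheritParams recovery_count
#' @return Integer count.
#' @export
radius_recovery_count <- function(report, truth_probe = NULL) {
  tp <- truth_probe %||% attr(report, "truth_probe")
  sum(report$radius == tp$radius)
}
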