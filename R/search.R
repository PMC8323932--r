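# Exhaustive discrete search over orientation, translation, Z offset and
# probe shape.

#' Evenly distributed directions on the sphere
#'
#' Latitude rings are placed at polar angles `n * step` for
#' `n = 0 .. 180/step`, starting from the +Z pole.  With the default
#' `"4n"` scheme ring `n` carries `4n` evenly spaced azimuths (the poles
#' carry one point each), so the equatorial ring is divided at exactly the
#' step spacing.  The literal `"n"` scheme (one azimuth per ring index) is
#' available for comparison but samples the sphere much more coarsely.
#'
#' @param step angular step in degrees; must divide 360 into a multiple
#'   of 4.
#' @param ring_scheme `"4n"` (default) or `"n"` azimuths on ring `n`.
#' @return A k x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(step, ring_scheme = c("4n", "n")) {
  ring_scheme <- match.arg(ring_scheme)
  check_step(step)
  nring <- 180 / step
  out <- list()
  for (n in 0:nring) {
    polar <- n * step * pi / 180
    m <- if (n == 0 || n == nring) 1L
         else if (ring_scheme == "4n") 4L * n else n
    az <- (seq_len(m) - 1) * 2 * pi / m
    out[[n + 1]] <- cbind(sin(polar) * cos(az), sin(polar) * sin(az),
                          rep(cos(polar), m))
  }
  do.call(rbind, out)
}

check_step <- function(step) {
  if (!is.finite(step) || step <= 0 || 360 %% step != 0 ||
      (360 / step) %% 4 != 0)
    stop("step must divide 360 degrees into a multiple of 4")
  invisible(step)
}

#' Orientation grid
#'
#' For every direction of [sphere_directions], the rotation mapping +Z onto
#' that direction is composed with each spin about the new Z axis in
#' increments of `step` (360/step spins, applied uniformly including at the
#' poles).  Every returned matrix is a proper rotation.
#'
#' @inheritParams sphere_directions
#' @return A 3 x 3 x K array of rotation matrices with attribute
#'   `direction` (direction index of each rotation).
#' @export
orientation_grid <- function(step, ring_scheme = c("4n", "n")) {
  ring_scheme <- match.arg(ring_scheme)
  dirs <- sphere_directions(step, ring_scheme)
  nspin <- as.integer(360 / step)
  K <- nrow(dirs) * nspin
  rots <- array(0, c(3, 3, K))
  dir_idx <- integer(K)
  k <- 0L
  for (i in seq_len(nrow(dirs))) {
    A <- align_z_to(dirs[i, ])
    for (s in seq_len(nspin) - 1L) {
      k <- k + 1L
      rots[, , k] <- A %*% rot_z(s * step)
      dir_idx[k] <- i
    }
  }
  attr(rots, "direction") <- dir_idx
  rots
}

#' Translation grid of a pseudo image inside a reference
#'
#' All integer pixel offsets at which the minimum bounding rectangle of
#' non-zero pixels of `sim` stays fully inside `ref`.
#'
#' @param sim pseudo-AFM [afm_image] (or matrix).
#' @param ref reference [afm_image] (or matrix).
#' @return A data.frame with 0-based integer columns `row`, `col`
#'   (row-major order); zero rows, with a warning, when the window does not
#'   fit.
#' @export
translation_grid <- function(sim, ref) {
  s <- if (inherits(sim, "afm_image")) sim$heights else as.matrix(sim)
  r <- if (inherits(ref, "afm_image")) ref$heights else as.matrix(ref)
  nz <- which(s > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("pseudo-AFM image has no non-zero pixel")
  h <- diff(range(nz[, 1])) + 1
  w <- diff(range(nz[, 2])) + 1
  if (h > nrow(r) || w > ncol(r)) {
    warning("trimming window larger than the reference image")
    return(data.frame(row = integer(0), col = integer(0)))
  }
  g <- expand.grid(col = 0:(ncol(r) - w), row = 0:(nrow(r) - h))
  data.frame(row = g$row, col = g$col)
}

#' Z-offset grid
#'
#' The molecule is shifted along Z only when the reference image contains a
#' pixel higher than every pixel of the pseudo image: offsets
#' `0, step, 2 step, ...` up to `max(ref) - max(sim)` are searched,
#' otherwise only 0.
#'
#' @param sim pseudo-AFM [afm_image] (or matrix).
#' @param ref reference [afm_image] (or matrix).
#' @param step Z step in nm (default 0.064 nm, finer than the typical
#'   vertical resolution of high-speed AFM).
#' @return Numeric vector of Z offsets in nm.
#' @export
z_offsets <- function(sim, ref, step = 0.064) {
  if (step <= 0) stop("step must be > 0")
  s <- if (inherits(sim, "afm_image")) sim$heights else as.matrix(sim)
  r <- if (inherits(ref, "afm_image")) ref$heights else as.matrix(ref)
  ms <- max(s); mr <- max(r)
  if (ms >= mr) return(0)
  (0:floor((mr - ms) / step)) * step
}

#' Default probe-shape search grid
#'
#' Tip radii from 0.5 to 5 nm (six values) crossed with half-apex angles
#' from 5 to 30 degrees, the range of probes typically encountered in
#' high-speed AFM.
#'
#' @param radii tip radii in nm.
#' @param angles half-apex angles in degrees.
#' @return A data.frame with columns `radius`, `angle` (radius-major
#'   order).
#' @export
probe_grid <- function(radii = c(0.5, 1, 2, 3, 4, 5),
                       angles = c(5, 10, 15, 20, 25, 30)) {
  g <- expand.grid(angle = angles, radius = radii)
  data.frame(radius = g$radius, angle = g$angle)
}

#' Exhaustive rigid-body fit of a model to a reference AFM image
#'
#' Evaluates every combination of orientation (discrete grid on SO(3)),
#' integer-pixel XY translation, Z offset and probe shape.  For each
#' orientation the model is re-grounded (`min(z - radius) = 0`) before
#' rendering; the pseudo image is trimmed to its non-zero bounding
#' rectangle, slid over the reference, and Z offsets are applied by raising
#' the non-zero pixels.  Ties are broken by enumeration order (orientation,
#' then row-major offset, then Z index, then probe index), so the result is
#' fully deterministic.
#'
#' @param model an [afm_model]; its initial orientation is irrelevant.
#' @param ref reference [afm_image].
#' @param probes probe grid as from [probe_grid], or a single
#'   [probe_shape].
#' @param score cost function name: `"cosine"`, `"correlation"`,
#'   `"pixel_rmsd"` or `"penalty"`.
#' @param angle_step orientation step in degrees (must divide 360 into a
#'   multiple of 4; 10 degrees is the production default, coarser steps cut
#'   cost for smoke tests).
#' @param z_step Z-offset step in nm.
#' @param top_k number of top-ranked candidates to return.
#' @param ring_scheme azimuth population rule of [sphere_directions].
#' @param penalty [penalty_params] for the penalty score.
#' @param max_frame safety cap on the rendering frame edge (pixels).
#' @return An object of class `afm_fit`: list with
#'   \describe{
#'     \item{results}{data.frame of the best placement per (orientation,
#'       probe) pair: cost, 0-based pixel offsets, Z offset and the full
#'       rigid transform (`tx, ty, tz` with the rotation index).}
#'     \item{top}{the `top_k` best rows, ranked by cost.}
#'     \item{best_per_probe}{lowest-cost row for every probe shape.}
#'     \item{rotations}{the orientation grid used.}
#'     \item{probes, score, ref}{inputs, for reporting and refitting.}
#'   }
#' @export
exhaustive_fit <- function(model, ref, probes = probe_grid(),
                           score = c("cosine", "correlation", "pixel_rmsd",
                                     "penalty"),
                           angle_step = 10, z_step = 0.064, top_k = 10,
                           ring_scheme = c("4n", "n"),
                           penalty = penalty_params(), max_frame = 4096) {
  score <- match.arg(score)
  ring_scheme <- match.arg(ring_scheme)
  if (inherits(probes, "probe_shape"))
    probes <- data.frame(radius = probes$radius, angle = probes$angle)
  stopifnot(nrow(probes) >= 1, inherits(ref, "afm_image"))
  rots <- orientation_grid(angle_step, ring_scheme)
  K <- dim(rots)[3]
  raw <- cpp_search(model$xyz, model$radii, as.numeric(rots), K,
                    as.matrix(probes[, c("radius", "angle")]),
                    ref$heights, ref$origin[1], ref$origin[2],
                    ref$pixel_size, z_step, score_id(score),
                    penalty$thickness, penalty$k_penalty, penalty$k_reward,
                    as.integer(max_frame))
  res <- data.frame(orientation = as.integer(raw[, 1]),
                    probe = as.integer(raw[, 2]),
                    radius = probes$radius[raw[, 2]],
                    angle = probes$angle[raw[, 2]],
                    cost = raw[, 3],
                    off_row = as.integer(raw[, 4]),
                    off_col = as.integer(raw[, 5]),
                    z_idx = as.integer(raw[, 6]),
                    z_offset = raw[, 7],
                    tx = raw[, 8], ty = raw[, 9], tz = raw[, 10],
                    win_rows = as.integer(raw[, 11]),
                    win_cols = as.integer(raw[, 12]))
  if (!any(is.finite(res$cost)))
    stop("search failed: no orientation produced a feasible placement")
  ord <- order(res$cost, res$orientation, res$off_row, res$off_col,
               res$z_idx, res$probe)
  top <- res[ord[seq_len(min(top_k, sum(is.finite(res$cost))))], ]
  rownames(top) <- NULL
  bpp <- do.call(rbind, lapply(split(res, res$probe), function(d)
    d[order(d$cost, d$orientation, d$off_row, d$off_col, d$z_idx), ][1, ]))
  bpp <- bpp[order(bpp$probe), ]
  rownames(bpp) <- NULL
  structure(list(results = res, top = top, best_per_probe = bpp,
                 rotations = rots, probes = probes, score = score,
                 ref = ref, model = model, z_step = z_step),
            class = "afm_fit")
}

#' @export
print.afm_fit <- function(x, ...) {
  b <- x$top[1, ]
  cat(sprintf(
    "afm_fit (%s): best cost %.6g with probe %.2f nm / %.0f deg\n",
    x$score, b$cost, b$radius, b$angle))
  cat(sprintf("  offset (%d, %d) px, z offset %.3f nm, %d orientations x %d probes\n",
              b$off_row, b$off_col, b$z_offset, dim(x$rotations)[3],
              nrow(x$probes)))
  invisible(x)
}

#' Apply a fitted placement to a model
#'
#' Reconstructs the placed structure for one row of an [exhaustive_fit]
#' result: the grid rotation followed by the grounding + search
#' translation, in reference-frame coordinates.
#'
#' @param fit an `afm_fit`.
#' @param model the model that was fitted (defaults to the one stored in
#'   `fit`).
#' @param rank which row of `fit$top` to apply.
#' @param row alternatively, a single-row data.frame from `fit$results`.
#' @return The placed [afm_model].
#' @export
apply_fit <- function(fit, model = fit$model, rank = 1, row = NULL) {
  r <- row %||% fit$top[rank, ]
  R <- fit$rotations[, , r$orientation]
  transform_model(model, R, c(r$tx, r$ty, r$tz))
}

#' Render the pseudo-AFM image of a fitted placement
#'
#' @inheritParams apply_fit
#' @return An [afm_image] on the reference frame, with the fitted Z offset
#'   applied to non-zero pixels.
#' @export
render_fit <- function(fit, rank = 1, row = NULL) {
  r <- row %||% fit$top[rank, ]
  placed <- apply_fit(fit, rank = rank, row = r)
  # the Z offset raises the image, not the collision geometry
  placed$xyz[, 3] <- placed$xyz[, 3] - r$z_offset
  ref <- fit$ref
  img <- render_afm(placed, probe_shape(r$radius, r$angle),
                    pixel_size = ref$pixel_size,
                    frame = list(origin = ref$origin,
                                 nx = ncol(ref$heights),
                                 ny = nrow(ref$heights)))
  h <- img$heights
  h[h > 0] <- h[h > 0] + r$z_offset
  afm_image(h, ref$pixel_size, ref$origin)
}
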